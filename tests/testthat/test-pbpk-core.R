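test_that("the ODE right-hand side matches an independently hand-written derivative", {
  set.seed(42)
  y <- stats::setNames(runif(21, 0, 5), rownames(pbpk_matrix(ph0, ch0)))
  got <- build_rhs(ph0, ch0)(0, y)[[1]]

  # hand expansion of the model equations, written out term by term
  p <- ph0; ch <- ch0
  QC <- p$QCC * p$BW
  Qm <- p$QMC * QC; Qr <- p$QRC * QC; Ql <- p$QLC * QC; Qk <- p$QKC * QC
  Vl <- p$VLC * p$BW; Vk <- p$VKC * p$BW; Vm <- p$VMC * p$BW; Vr <- p$VRC * p$BW
  Vart <- p$VartC * p$BW; Vven <- p$VvenC * p$BW
  Vlu <- p$VLUC * p$BW
  Vlub <- p$VLUB * Vlu; Vlui <- p$VLUI * Vlu; Vlut <- p$VLUT * Vlu
  CLb <- ch$KbileC * p$BW; CLu <- ch$KurineC * p$BW
  Cart <- y["art"] / Vart; Cven <- y["ven"] / Vven
  Cl <- y["liver"] / Vl; Ck <- y["kidney"] / Vk
  Cm <- y["muscle"] / Vm; Cr <- y["rest"] / Vr
  Club <- y["lung_blood"] / Vlub; Clui <- y["lung_if"] / Vlui
  Clut <- y["lung_tissue"] / Vlut
  # calibrated lung form: permeability clearances on free concentrations,
  # fast pair blood<->IF, slow pair IF<->tissue
  f_bi <- ch$KIT * (1 - ch$PB) * Club
  f_ib <- ch$KTI * Clui
  f_it <- ch$KBI * Clui
  f_ti <- ch$KIB * (1 - ch$PT) * Clut
  hand <- c(
    depot_slow = -ch$Kdiss * y["depot_slow"],
    depot_fast = ch$Kdiss * y["depot_slow"] - ch$Kim * y["depot_fast"],
    ven = ch$Kim * y["depot_fast"] + Qm * Cm / ch$PM + Qr * Cr / ch$PR +
      Ql * Cl / ch$PL + Qk * Ck / ch$PK - QC * Cven,
    art = QC * Club - (Ql + Qk + Qm + Qr) * Cart,
    lung_blood = QC * Cven - QC * Club - f_bi + f_ib,
    lung_if = f_bi - f_ib - f_it + f_ti,
    lung_tissue = f_it - f_ti,
    liver = Ql * (Cart - Cl / ch$PL) - CLb * Cl / ch$PL,
    kidney = Qk * (Cart - Ck / ch$PK) - CLu * Ck / ch$PK,
    muscle = Qm * (Cart - Cm / ch$PM),
    rest = Qr * (Cart - Cr / ch$PR),
    urine = CLu * Ck / ch$PK,
    bile = CLb * Cl / ch$PL
  )
  expect_equal(got[1:13], unname(hand), tolerance = 1e-12)
})

test_that("an all-zero state is stationary and a closed system conserves mass", {
  rhs <- build_rhs(ph0, ch0)
  expect_equal(rhs(0, numeric(21))[[1]], numeric(21))

  ch_closed <- chem_params(KbileC = 0, KurineC = 0)
  set.seed(7)
  y <- runif(21, 0, 10)
  d <- build_rhs(ph0, ch_closed)(0, y)[[1]]
  expect_equal(sum(d[1:13]), 0, tolerance = 1e-10)
})

test_that("mass balance holds through a multi-dose simulation with clearances on", {
  sim <- simulate_pbpk(ph0, ch0, dosing_regimen(2, 24, 5), t_end = 216,
                       dt = 0.5)
  mb <- mass_balance(sim)
  expect_lte(max(abs(mb$rel_error[mb$administered > 0])), 1e-6)
  # terminal partitioning: everything ends up in urine + bile
  expect_equal(sum(sim$amounts[nrow(sim$amounts), c("urine", "bile")]),
               250, tolerance = 0.02)
})

test_that("solver output matches the matrix-exponential solution of the same system", {
  tt <- seq(1, 30, length.out = 10)
  sim <- simulate_pbpk(ph0, ch0, reg_single, t_end = 30,
                       times = sort(unique(c(0, tt))))
  oracle <- expm_solution(ph0, ch0, 50, tt)
  got <- sim$amounts[match(tt, sim$time), ]
  scale <- 1e-8 * 50  # mg floor for states passing through zero
  expect_lt(max(rel_dev(got, oracle, floor = scale)), 1e-5)
})

test_that("multi-dose response is the superposition of shifted single-dose responses", {
  grid <- seq(0, 48, by = 0.5)
  multi <- simulate_pbpk(ph0, ch0, dosing_regimen(2, 12, 3), t_end = 48,
                         times = grid)
  single <- simulate_pbpk(ph0, ch0, reg_single, t_end = 48, times = grid)
  for (cp in c("plasma", "lung_if", "kidney")) {
    tr <- single$conc[, cp]
    shift <- function(lag) {
      idx <- match(grid - lag, grid)
      out <- ifelse(is.na(idx), 0, tr[pmax(idx, 1)])
      out[grid < lag] <- 0
      out
    }
    expected <- tr + shift(12) + shift(24)
    expect_lt(max(abs(multi$conc[, cp] - expected)) / max(expected), 1e-6)
  }
})

test_that("with clearances off, tissues equilibrate to their partition coefficients", {
  ch_closed <- chem_params(KbileC = 0, KurineC = 0)
  sim <- simulate_pbpk(ph0, ch_closed, reg_single, t_end = 2000,
                       times = c(0, 1000, 2000))
  last <- nrow(sim$conc)
  # partition is defined against the perfusing (arterial) blood
  cb <- sim$conc[last, "arterial"]
  ratio <- function(cp) unname(sim$conc[last, cp] / cb)
  expect_equal(ratio("liver"), ch_closed$PL, tolerance = 1e-4)
  expect_equal(ratio("kidney"), ch_closed$PK, tolerance = 1e-4)
  expect_equal(ratio("muscle"), ch_closed$PM, tolerance = 1e-4)
  expect_equal(ratio("rest"), ch_closed$PR, tolerance = 1e-4)
})

test_that("a zero dose yields identically zero traces", {
  sim <- simulate_pbpk(ph0, ch0, dosing_regimen(0), t_end = 12)
  expect_true(all(sim$conc == 0))
  expect_true(all(sim$amounts == 0))
})

test_that("states stay non-negative across random admissible parameter sets", {
  set.seed(123)
  for (i in 1:5) {
    ch <- chem_params(PLU = runif(1, 0.5, 3), PL = runif(1, 2, 10),
                      PK = runif(1, 5, 25), PM = runif(1, 0.05, 0.5),
                      PR = runif(1, 0.05, 0.5), Kim = runif(1, 2, 10),
                      Kdiss = runif(1, 0.01, 0.2),
                      KurineC = runif(1, 0.1, 0.6),
                      KIT = runif(1, 1, 6), KTI = runif(1, 1, 5))
    sim <- simulate_pbpk(ph0, ch, dosing_regimen(runif(1, 1, 5), 12, 2),
                         t_end = 48, dt = 0.5)
    expect_true(all(sim$amounts >= 0))
    expect_true(all(sim$conc >= 0))
  }
})

test_that("AUC accumulators agree with trapezoid integration of the traces", {
  sim <- simulate_pbpk(ph0, ch0, reg_single, t_end = 24, dt = 0.01)
  for (cp in c("plasma", "kidney", "lung_if")) {
    acc <- pk_auc(sim, cp, 0, 24)
    tz <- sum(diff(sim$time) * (utils::head(sim$conc[, cp], -1) +
                                  utils::tail(sim$conc[, cp], -1)) / 2)
    expect_equal(acc, tz, tolerance = 1e-3)
  }
  expect_equal(pk_auc(sim, "plasma_free"), (1 - ch0$PB) * pk_auc(sim, "plasma"))
  expect_error(pk_auc(sim, "brain"), "unknown compartment")
  expect_error(pk_auc(sim, "plasma", 0, 48), "within the simulated span")
})

test_that("simulation input contracts are enforced", {
  expect_error(simulate_pbpk(ph0, ch0, dosing_regimen(2, 24, 3), t_end = 24),
               "last dose")
  expect_error(simulate_pbpk(ph0, ch0, reg_single, t_end = 10,
                             times = c(0, 5, 5)), "strictly increasing")
})
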