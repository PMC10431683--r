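test_that("R-squared behaves as a coefficient of determination", {
  obs <- c(1, 2, 3, 4)
  expect_equal(r_squared(obs, obs), 1)
  expect_equal(r_squared(obs, rep(mean(obs), 4)), 0)
  # hand least-squares oracle: 1 - SS_res / SS_tot computed term by term
  o <- c(1, 2, 3); p <- c(1.1, 1.9, 3.2)
  ss_res <- (1 - 1.1)^2 + (2 - 1.9)^2 + (3 - 3.2)^2
  ss_tot <- (1 - 2)^2 + 0 + (3 - 2)^2
  expect_equal(r_squared(o, p), 1 - ss_res / ss_tot)
  expect_warning(out <- r_squared(c(2, 2, 2), c(1, 2, 3)), "zero variance")
  expect_true(is.na(out))
})

test_that("R-squared is invariant to a common affine rescaling", {
  set.seed(9)
  o <- runif(10, 1, 5); p <- o + rnorm(10, 0, 0.3)
  for (i in 1:5) {
    a <- runif(1, 0.1, 10); b <- runif(1, -3, 3)
    expect_equal(r_squared(a * o + b, a * p + b), r_squared(o, p),
                 tolerance = 1e-10)
  }
})

test_that("MAPE and its classification bands follow the convention", {
  expect_equal(mape(c(3, 4, 5), c(3, 4, 5)), 0)
  expect_equal(mape(c(10, 10), c(9, 11)), 10)
  expect_equal(mape(2, 1), 50)
  expect_equal(mape_class(mape(2, 1)), "not acceptable")  # 50% boundary
  expect_equal(mape_class(c(5, 15, 35, 75)),
               c("excellent", "good", "acceptable", "not acceptable"))
  expect_error(mape(c(0, 1), c(1, 1)), "observed values must be > 0")
})

test_that("the twofold rule counts predictions within half to double", {
  obs <- c(1, 1, 1, 1)
  expect_equal(twofold_fraction(obs, obs), 1)
  expect_equal(twofold_fraction(obs, 2.01 * obs), 0)
  expect_equal(twofold_fraction(obs, c(0.4, 0.6, 1.5, 2.5)), 0.5)
})

test_that("fitting with no free parameters returns the initial set unchanged", {
  dat <- data.frame(study_id = "s", time_h = c(1, 2, 4),
                    compartment = "plasma", concentration = c(2, 1, 0.5))
  fit <- fit_parameters(dat, list(s = reg_single), fit_spec(character(0)),
                        ph0, ch0)
  expect_identical(fit$chem, ch0)
  expect_true(fit$report$converged)
})

test_that("renal clearance is recovered within 1% from noise-free synthetic data", {
  times <- c(0.25, 0.5, 1, 2, 4, 6, 8, 12)
  des <- study_design(reg_single, "plasma", times, n_animals = 1)
  dat <- generate_study(des, noise_model(cv = 0, lloq = 0), ph0, ch0,
                        study_id = "truth")
  start <- chem_params(KurineC = 0.22)
  fit <- fit_parameters(dat, list(truth = reg_single),
                        fit_spec("KurineC",
                                 lower = c(KurineC = 0.05),
                                 upper = c(KurineC = 1)),
                        ph0, start)
  expect_lt(abs(fit$chem$KurineC - 0.3) / 0.3, 0.01)
  expect_true(fit$report$converged)
  expect_lt(fit$report$per_study$mape, 1)
})

test_that("a shifted generating clearance is recovered under noise", {
  set.seed(31)
  times <- c(0.25, 0.5, 1, 2, 3, 4, 6, 8, 10, 12)
  truth <- chem_params(KurineC = 0.4)
  des <- study_design(reg_single, "plasma", times, n_animals = 3)
  dat <- generate_study(des, noise_model(cv = 0.10, lloq = 0), ph0, truth,
                        study_id = "noisy")
  fit <- fit_parameters(dat, list(noisy = reg_single),
                        fit_spec("KurineC",
                                 lower = c(KurineC = 0.05),
                                 upper = c(KurineC = 1)),
                        ph0, chem_params(KurineC = 0.3))
  expect_lt(abs(fit$chem$KurineC - 0.4) / 0.4, 0.05)
})

test_that("fit specification validates its inputs", {
  expect_error(fit_spec("NotAParam"), "unknown chemical parameters")
  expect_error(fit_spec("KurineC", lower = c(KurineC = -1),
                        upper = c(KurineC = 2)), "bounds")
  dat <- data.frame(study_id = "s", time_h = 1, compartment = "plasma",
                    concentration = 1)
  expect_error(
    fit_parameters(dat, list(s = reg_single),
                   fit_spec("KurineC", lower = c(KurineC = 0.5),
                            upper = c(KurineC = 1)), ph0, ch0),
    "within bounds")
})
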