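test_that("a noiseless single-animal study equals the deterministic prediction", {
  times <- c(0.5, 1, 2, 4, 8)
  des <- study_design(reg_single, c("plasma", "kidney"), times, n_animals = 1)
  ds <- generate_study(des, noise_model(cv = 0, lloq = 0), ph0, ch0)
  sim <- simulate_pbpk(ph0, ch0, reg_single, t_end = 8,
                       times = c(0, times))
  for (cp in c("plasma", "kidney")) {
    got <- ds$concentration[ds$compartment == cp]
    want <- sim$conc[match(times, sim$time), cp]
    expect_equal(got, unname(want), tolerance = 1e-10)
  }
})

test_that("study generation is reproducible from the seed", {
  des <- study_design(reg_single, "plasma", c(1, 2, 4), n_animals = 3,
                      distributions = default_mc_distributions())
  a <- generate_study(des, noise_model(), ph0, ch0, seed = 77)
  b <- generate_study(des, noise_model(), ph0, ch0, seed = 77)
  expect_identical(a, b)
})

test_that("the residual noise has the configured coefficient of variation", {
  set.seed(55)
  des <- study_design(reg_single, "plasma", 2, n_animals = 100)
  ds <- generate_study(des, noise_model(cv = 0.2, lloq = 0), ph0, ch0)
  cv_hat <- stats::sd(ds$concentration) / mean(ds$concentration)
  expect_gte(cv_hat, 0.15)
  expect_lte(cv_hat, 0.25)
})

test_that("LLOQ handling censors or drops sub-LLOQ observations", {
  des <- study_design(reg_single, "plasma", c(1, 24, 48, 72), n_animals = 1)
  cen <- generate_study(des, noise_model(cv = 0, lloq = 0.05,
                                         below_lloq = "censor"), ph0, ch0)
  expect_true(all(is.na(cen$concentration) | cen$concentration >= 0.05))
  expect_true(any(cen$censored))
  drp <- generate_study(des, noise_model(cv = 0, lloq = 0.05,
                                         below_lloq = "drop"), ph0, ch0)
  expect_true(all(drp$concentration >= 0.05))
  expect_lt(nrow(drp), nrow(cen))
})

test_that("dialysate generation round-trips through the ISF correction", {
  des <- study_design(reg_single, "lung_if", dialysate_sampling_times(),
                      n_animals = 1)
  dia <- generate_dialysate_study(des, in_vivo_rr = 0.288,
                                  noise = noise_model(cv = 0, lloq = 0),
                                  phys = ph0, chem = ch0)
  expect_true(all(dia$compartment == "dialysate"))
  sim <- simulate_pbpk(ph0, ch0, reg_single, t_end = 11.25,
                       times = c(0, dialysate_sampling_times()))
  truth <- sim$conc[match(dialysate_sampling_times(), sim$time), "lung_if"]
  corrected <- correct_isf(dia$time_h, dia$concentration, 0.288)
  expect_equal(corrected$concentration, unname(truth), tolerance = 1e-10)
  # rr = 1 with no noise returns the ISF trace itself
  dia1 <- generate_dialysate_study(des, in_vivo_rr = 1,
                                   noise = noise_model(cv = 0, lloq = 0),
                                   phys = ph0, chem = ch0)
  expect_equal(dia1$concentration, unname(truth), tolerance = 1e-10)
  expect_error(generate_dialysate_study(des, in_vivo_rr = 1.2),
               "in_vivo_rr")
})

test_that("NCA of a corrected dialysate profile approximates the model AUC", {
  des <- study_design(reg_single, "lung_if", dialysate_sampling_times(),
                      n_animals = 1)
  dia <- generate_dialysate_study(des, in_vivo_rr = 0.288,
                                  noise = noise_model(cv = 0, lloq = 0),
                                  phys = ph0, chem = ch0)
  corrected <- correct_isf(dia$time_h, dia$concentration, 0.288)
  res <- nca(corrected$time_h, corrected$concentration)
  sim <- simulate_pbpk(ph0, ch0, reg_single, t_end = 11.25)
  model_auc <- pk_auc(sim, "lung_if", 0.25, 11.25)
  expect_equal(res$AUC_last, model_auc, tolerance = 0.05)
})

test_that("study designs validate their inputs", {
  expect_error(study_design(reg_single, "plasma", c(2, 1)), "increasing")
  expect_error(study_design(reg_single, "plasma", 1, n_animals = 0),
               "n_animals")
})
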