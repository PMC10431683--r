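# printed truncation bounds of the eleven population parameters
published_bounds <- data.frame(
  name   = c("QCC", "QKC", "PL", "PK", "PM", "PR", "PLU", "KIT", "KTI",
             "KurineC", "PT"),
  lower  = c(2.04, 0.06, 3.99, 10.11, 0.07, 0.07, 1.00, 1.92, 1.40, 0.16,
             0.16),
  upper  = c(7.85, 0.22, 8.67, 21.97, 0.14, 0.14, 2.17, 6.06, 4.43, 0.51,
             0.51)
)

test_that("analytic truncation bounds reproduce every published bound to 0.01", {
  dists <- default_mc_distributions()
  expect_setequal(names(dists), published_bounds$name)
  for (i in seq_len(nrow(published_bounds))) {
    d <- dists[[published_bounds$name[i]]]
    b <- truncation_bounds(d$family, d$mean, d$cv)
    expect_lt(abs(b[1] - published_bounds$lower[i]), 0.0105)
    expect_lt(abs(b[2] - published_bounds$upper[i]), 0.0105)
  }
})

test_that("bounds collapse to the mean as CV goes to zero", {
  expect_equal(unname(truncation_bounds("normal", 5, 0)), c(5, 5))
  expect_equal(unname(truncation_bounds("lognormal", 5, 0)), c(5, 5))
  expect_error(truncation_bounds("normal", -1, 0.2), "mean")
  expect_error(truncation_bounds("lognormal", 1, -0.2), "cv")
})

test_that("truncated sampling respects bounds, mean, and the analytic law", {
  d <- param_distribution("QCC", "normal", 4.944, 0.3)
  x <- sample_parameters(list(QCC = d), 1e5, seed = 42)[, 1]
  expect_true(all(x >= d$lower & x <= d$upper))
  # mean of the symmetric truncated normal equals the untruncated mean
  expect_lt(abs(mean(x) - 4.944) / 4.944, 0.01)

  dl <- param_distribution("PL", "lognormal", 6, 0.2)
  y <- sample_parameters(list(PL = dl), 1e5, seed = 43)[, 1]
  expect_true(all(y >= dl$lower & y <= dl$upper))
  s2 <- log(1 + 0.2^2); mu <- log(6) - s2 / 2
  trunc_cdf <- function(q) {
    (stats::plnorm(q, mu, sqrt(s2)) - stats::plnorm(dl$lower, mu, sqrt(s2))) /
      (stats::plnorm(dl$upper, mu, sqrt(s2)) - stats::plnorm(dl$lower, mu, sqrt(s2)))
  }
  ks <- suppressWarnings(stats::ks.test(y, trunc_cdf))
  expect_gt(ks$p.value, 0.01)
})

test_that("sampling is reproducible and degenerate distributions are constant", {
  dists <- default_mc_distributions()
  a <- sample_parameters(dists, 50, seed = 7)
  b <- sample_parameters(dists, 50, seed = 7)
  expect_identical(a, b)
  d0 <- param_distribution("PL", "lognormal", 6, 0)
  expect_true(all(sample_parameters(list(PL = d0), 20, seed = 1) == 6))
  expect_error(sample_parameters(dists, 0), "n must be")
})

test_that("a zero-variance population collapses onto the deterministic run", {
  dists <- lapply(default_mc_distributions(), function(d)
    param_distribution(d$name, d$family, d$mean, 0))
  ens <- simulate_population(ph0, ch0, reg_single, t_end = 12,
                             distributions = dists, n = 3, seed = 1,
                             dt = 0.5)
  det <- simulate_pbpk(ph0, ch0, reg_single, t_end = 12, times = ens$time)
  for (i in 1:3)
    expect_equal(ens$traces$plasma[, i], unname(det$conc[, "plasma"]),
                 tolerance = 1e-10)
})

test_that("the population median tracks the deterministic trace and bands are ordered", {
  ens <- simulate_population(ph0, ch0, reg_single, t_end = 24, n = 150,
                             seed = 2, dt = 0.5)
  p <- percentiles(ens, "plasma", c(10, 50, 90))
  expect_true(all(p[, "p10"] <= p[, "p50"] + 1e-12))
  expect_true(all(p[, "p50"] <= p[, "p90"] + 1e-12))
  det <- simulate_pbpk(ph0, ch0, reg_single, t_end = 24, times = ens$time)
  # median within Monte Carlo error of the deterministic solution where
  # exposure is appreciable
  sel <- det$conc[, "plasma"] > 0.5
  expect_lt(median(abs(p[sel, "p50"] - det$conc[sel, "plasma"]) /
                     det$conc[sel, "plasma"]), 0.15)
})

test_that("percentile bands widen monotonically with the population CV", {
  scale_cv <- function(k) lapply(default_mc_distributions(), function(d)
    param_distribution(d$name, d$family, d$mean, d$cv * k))
  width <- vapply(c(0.5, 1, 2), function(k) {
    ens <- simulate_population(ph0, ch0, reg_single, t_end = 6,
                               distributions = scale_cv(k), n = 120,
                               seed = 3, dt = 1, keep = "plasma")
    p <- percentiles(ens, "plasma", c(10, 90))
    at <- which.max(p[, "p90"])
    p[at, "p90"] - p[at, "p10"]
  }, numeric(1))
  expect_true(all(diff(width) > 0))
})

test_that("percentiles of a single-individual ensemble equal its trace", {
  ens <- simulate_population(ph0, ch0, reg_single, t_end = 6, n = 1,
                             seed = 4, dt = 1, keep = "plasma")
  p <- percentiles(ens, "plasma", c(10, 50, 90))
  for (j in 1:3) expect_equal(p[, j], ens$traces$plasma[, 1])
  expect_error(percentiles(ens, "plasma", c(0, 50)), "strictly between")
  expect_error(percentiles(ens, "liver"), "not retained")
})

test_that("every accepted draw lies within its distribution bounds", {
  ens <- simulate_population(ph0, ch0, reg_single, t_end = 2, n = 60,
                             seed = 5, dt = 1, keep = "plasma")
  dists <- default_mc_distributions()
  for (nm in colnames(ens$draws)) {
    expect_true(all(ens$draws[, nm] >= dists[[nm]]$lower))
    expect_true(all(ens$draws[, nm] <= dists[[nm]]$upper))
  }
})
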