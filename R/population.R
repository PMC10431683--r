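#' Truncation bounds of a population parameter distribution
#'
#' 2.5th and 97.5th percentiles of a normal or lognormal distribution
#' specified by its natural-scale mean and coefficient of variation (CV).
#' For the lognormal, the log-scale parameters are `sigma^2 = ln(1 + CV^2)`
#' and `mu = ln(mean) - sigma^2 / 2`, so that `mean` is the natural-scale
#' arithmetic mean. Sampling is truncated to these bounds (the 95%
#' confidence interval of the distribution).
#'
#' @param family `"normal"` or `"lognormal"`
#' @param mean natural-scale mean (> 0)
#' @param cv coefficient of variation (>= 0); `cv = 0` collapses the bounds
#'   to `(mean, mean)`
#' @return numeric `c(lower, upper)`
#' @export
#' @examples
#' truncation_bounds("normal", 4.944, 0.3)    # c(2.04, 7.85)
#' truncation_bounds("lognormal", 6, 0.2)     # c(3.99, 8.67)
truncation_bounds <- function(family = c("normal", "lognormal"), mean, cv) {
  family <- match.arg(family)
  if (!is.finite(mean) || mean <= 0) stop("mean must be > 0", call. = FALSE)
  if (!is.finite(cv) || cv < 0) stop("cv must be >= 0", call. = FALSE)
  if (cv == 0) return(c(lower = mean, upper = mean))
  z <- stats::qnorm(0.975)
  if (family == "normal") {
    sd <- mean * cv
    c(lower = mean - z * sd, upper = mean + z * sd)
  } else {
    s2 <- log(1 + cv^2)
    mu <- log(mean) - s2 / 2
    c(lower = exp(mu - z * sqrt(s2)), upper = exp(mu + z * sqrt(s2)))
  }
}

#' Population distribution of one model parameter
#'
#' @inheritParams truncation_bounds
#' @param name parameter name (a scalar field of [phys_params()] or
#'   [chem_params()])
#' @return object of class `ceq_dist`: list with `name`, `family`, `mean`,
#'   `cv`, `sd`, `lower`, `upper`
#' @export
param_distribution <- function(name, family, mean, cv) {
  b <- truncation_bounds(family, mean, cv)
  structure(list(name = name, family = match.arg(family,
                 c("normal", "lognormal")), mean = mean, cv = cv,
                 sd = mean * cv, lower = unname(b[1]), upper = unname(b[2])),
            class = "ceq_dist")
}

#' Default Monte Carlo distributions of the influential parameters
#'
#' The eleven parameters carried into the population layer: physiological
#' parameters (cardiac output, kidney flow fraction) as truncated normals
#' with CV 0.3; partition coefficients as truncated lognormals with CV 0.2;
#' lung transfer constants, renal clearance and lung tissue binding as
#' truncated lognormals with CV 0.3. Means are the deterministic defaults.
#' All other parameters stay fixed at their means.
#'
#' @return named list of [param_distribution()] objects
#' @export
default_mc_distributions <- function() {
  spec <- list(
    list("QCC", "normal", 4.944, 0.3),
    list("QKC", "normal", 0.1398, 0.3),
    list("PL",  "lognormal", 6.00, 0.2),
    list("PK",  "lognormal", 15.2, 0.2),
    list("PM",  "lognormal", 0.10, 0.2),
    list("PR",  "lognormal", 0.10, 0.2),
    list("PLU", "lognormal", 1.50, 0.2),
    list("KIT", "lognormal", 3.56, 0.3),
    list("KTI", "lognormal", 2.60, 0.3),
    list("KurineC", "lognormal", 0.30, 0.3),
    list("PT",  "lognormal", 0.30, 0.3)
  )
  out <- lapply(spec, function(s) param_distribution(s[[1]], s[[2]], s[[3]], s[[4]]))
  stats::setNames(out, vapply(out, `[[`, "", "name"))
}

#' Sample parameter sets from truncated distributions
#'
#' Independent draws per parameter; draws outside `[lower, upper]` are
#' rejected and redrawn, so the truncated density is preserved without
#' probability atoms at the bounds. Reproducible from `seed`.
#'
#' @param distributions named list of [param_distribution()] objects
#' @param n number of parameter sets
#' @param seed integer RNG seed; `NULL` continues the current RNG state
#' @param max_rounds redraw budget per parameter
#' @return matrix `n` x `length(distributions)` with parameter columns
#' @export
sample_parameters <- function(distributions, n, seed = NULL,
                              max_rounds = 1000) {
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  draw1 <- function(d, k) {
    if (d$cv == 0) return(rep(d$mean, k))
    if (d$family == "normal") stats::rnorm(k, d$mean, d$sd)
    else {
      s2 <- log(1 + d$cv^2)
      stats::rlnorm(k, log(d$mean) - s2 / 2, sqrt(s2))
    }
  }
  cols <- lapply(distributions, function(d) {
    x <- draw1(d, n)
    for (round in seq_len(max_rounds)) {
      bad <- which(x < d$lower | x > d$upper)
      if (!length(bad)) break
      x[bad] <- draw1(d, length(bad))
    }
    if (any(x < d$lower | x > d$upper))
      stop("rejection sampling failed for ", d$name,
           ": bounds exclude essentially all mass", call. = FALSE)
    x
  })
  out <- do.call(cbind, cols)
  colnames(out) <- vapply(distributions, `[[`, "", "name")
  out
}

# fold one row of sampled parameters into (phys, chem)
apply_draw <- function(phys, chem, draw) {
  p <- unclass(phys); ch <- unclass(chem)
  for (nm in names(draw)) {
    if (nm %in% names(p)) p[[nm]] <- unname(draw[[nm]])
    else if (nm %in% names(ch)) ch[[nm]] <- unname(draw[[nm]])
    else stop("sampled parameter not in model: ", nm, call. = FALSE)
  }
  class(p) <- "ceq_phys"; class(ch) <- "ceq_chem"
  list(phys = p, chem = ch)
}

#' Monte Carlo population simulation
#'
#' Simulates `n` virtual animals, each with influential parameters drawn
#' from the truncated population distributions and all other parameters at
#' their means. Flow fractions are not renormalized after sampling the
#' kidney flow (documented caveat: the rest-of-body flow keeps its mean
#' share, so total tissue inflow varies slightly across individuals).
#'
#' Individual solver failures are resampled (fresh parameter draw) and
#' counted in the result.
#'
#' @inheritParams simulate_pbpk
#' @param distributions named list of [param_distribution()] objects
#'   (default [default_mc_distributions()])
#' @param n number of virtual animals
#' @param seed integer RNG seed for reproducibility
#' @param keep reported compartments whose full traces are retained
#'   (`time` x `n` matrices); ignored entries cost memory, so keep few
#' @param reduce optional `function(sim)` applied to each individual
#'   simulation; its results are collected in `$reduced` and traces are
#'   not stored
#' @param max_resample per-individual resampling budget on solver failure
#' @return object of class `ceq_ensemble`: list with `time`, `traces`
#'   (named list of matrices, unless `reduce` given), `reduced` (list,
#'   if `reduce` given), `draws` (the accepted parameter matrix), `n`,
#'   `seed`, `n_resampled`, and the baseline inputs
#' @export
simulate_population <- function(phys, chem, regimen, t_end,
                                distributions = default_mc_distributions(),
                                n = 1000, seed = 1, dt = 0.05,
                                keep = c("plasma", "plasma_free", "lung_if",
                                         "liver", "kidney"),
                                reduce = NULL, max_resample = 20,
                                rtol = 1e-8, atol = 1e-10) {
  draws <- sample_parameters(distributions, n, seed)
  tgrid <- sort(unique(c(seq(0, t_end, by = dt),
                         dose_times(regimen))))
  use_reduce <- !is.null(reduce)
  traces <- if (!use_reduce)
    stats::setNames(lapply(keep, function(cp)
      matrix(NA_real_, length(tgrid), n)), keep)
  reduced <- if (use_reduce) vector("list", n)
  n_resampled <- 0L

  for (i in seq_len(n)) {
    draw <- draws[i, ]
    for (try in seq_len(max_resample + 1)) {
      pars <- apply_draw(phys, chem, draw)
      sim <- tryCatch(
        simulate_pbpk(pars$phys, pars$chem, regimen, t_end, times = tgrid,
                      rtol = rtol, atol = atol, validate = FALSE),
        error = function(e) e)
      if (!inherits(sim, "error")) break
      n_resampled <- n_resampled + 1L
      draw <- sample_parameters(distributions, 1)[1, ]
    }
    if (inherits(sim, "error"))
      stop("individual ", i, " failed after ", max_resample,
           " resamples: ", conditionMessage(sim), call. = FALSE)
    draws[i, ] <- draw
    if (use_reduce) reduced[[i]] <- reduce(sim)
    else for (cp in keep) traces[[cp]][, i] <- sim$conc[, cp]
  }
  structure(list(time = tgrid, traces = if (!use_reduce) traces,
                 reduced = if (use_reduce) reduced,
                 draws = draws, n = n, seed = seed,
                 n_resampled = n_resampled,
                 phys = phys, chem = chem, regimen = regimen),
            class = "ceq_ensemble")
}

#' @export
print.ceq_ensemble <- function(x, ...) {
  cat(sprintf("population ensemble: n = %d, seed = %s, %d resampled\n",
              x$n, format(x$seed), x$n_resampled))
  print(x$regimen)
  invisible(x)
}

#' Pointwise percentile traces of a population ensemble
#'
#' Empirical percentiles (linear-interpolation order statistic,
#' `stats::quantile` type 7) across individuals at every output time.
#'
#' @param ensemble a [simulate_population()] result holding full traces
#' @param compartment one of the retained compartments
#' @param probs percentiles in (0, 100)
#' @return matrix `length(time)` x `length(probs)` with columns `p<prob>`
#' @export
percentiles <- function(ensemble, compartment, probs = c(10, 50, 90)) {
  if (is.null(ensemble$traces))
    stop("ensemble was reduced; full traces not retained", call. = FALSE)
  if (!compartment %in% names(ensemble$traces))
    stop("compartment not retained: ", compartment, call. = FALSE)
  if (any(probs <= 0) || any(probs >= 100))
    stop("probs must lie strictly between 0 and 100", call. = FALSE)
  if (ensemble$n < 1) stop("empty ensemble", call. = FALSE)
  m <- t(apply(ensemble$traces[[compartment]], 1, stats::quantile,
               probs = probs / 100, type = 7, names = FALSE))
  if (length(probs) == 1) m <- matrix(m, ncol = 1)
  colnames(m) <- paste0("p", probs)
  m
}
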