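#' Assay noise model for synthetic observations
#'
#' Multiplicative lognormal residual error (mean 1, the stated CV) with
#' lower-limit-of-quantitation handling, emulating chromatographic assay
#' error.
#'
#' @param cv residual coefficient of variation (default 0.20)
#' @param lloq lower limit of quantitation (ug/mL; default 0.05)
#' @param below_lloq `"censor"` (concentration set to `NA`, row kept and
#'   flagged) or `"drop"` (row removed)
#' @return object of class `ceq_noise`
#' @export
noise_model <- function(cv = 0.20, lloq = 0.05,
                        below_lloq = c("censor", "drop")) {
  below_lloq <- match.arg(below_lloq)
  if (cv < 0 || lloq < 0) stop("cv and lloq must be >= 0", call. = FALSE)
  structure(list(cv = cv, lloq = lloq, below_lloq = below_lloq),
            class = "ceq_noise")
}

#' Synthetic study design
#'
#' Describes a simulated animal experiment: the dosing regimen, the sampled
#' compartments and times, the number of animals, and the inter-animal
#' parameter distributions (reusing the population layer; `NULL` for
#' identical animals).
#'
#' @param regimen a [dosing_regimen()]
#' @param compartments reported traces of [simulate_pbpk()] to sample
#' @param times sampling times (h), sorted
#' @param n_animals number of animals (>= 1)
#' @param distributions named list of [param_distribution()] objects for
#'   inter-animal variability, or `NULL` for none
#' @return object of class `ceq_design`
#' @export
study_design <- function(regimen, compartments, times, n_animals = 4,
                         distributions = NULL) {
  if (n_animals < 1) stop("n_animals must be >= 1", call. = FALSE)
  if (is.unsorted(times, strictly = TRUE))
    stop("times must be strictly increasing", call. = FALSE)
  structure(list(regimen = regimen, compartments = compartments,
                 times = times, n_animals = n_animals,
                 distributions = distributions),
            class = "ceq_design")
}

# sampling schedule of the lung microdialysis experiment (h after dosing)
#' @rdname generate_dialysate_study
#' @export
dialysate_sampling_times <- function() {
  c(0.25, 0.5, 0.75, 1, 1.25, 1.75, 2.25, 3.25, 4.25, 5.25, 7.25, 9.25,
    10.25, 11.25)
}

# one lognormal noise factor matrix with mean 1 and the requested CV
noise_factors <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  s2 <- log(1 + cv^2)
  stats::rlnorm(n, -s2 / 2, sqrt(s2))
}

#' Generate a synthetic observed dataset
#'
#' Per animal: draw individual parameters from the design's population
#' distributions (or use the baseline exactly), simulate the PBPK model,
#' evaluate the sampled compartments at the design's sampling times, apply
#' multiplicative lognormal noise, then apply the LLOQ rule. The generating
#' truth (per-animal parameter draws) is attached for parameter-recovery
#' experiments.
#'
#' @param design a [study_design()]
#' @param noise a [noise_model()]
#' @param phys,chem baseline parameters
#' @param study_id study label for the output table
#' @param seed RNG seed; `NULL` continues the current stream
#' @return data.frame with columns `study_id`, `animal`, `time_h`,
#'   `compartment`, `concentration`, `lloq`, `censored`; attributes
#'   `truth` (list: per-animal parameter draws, baseline phys/chem,
#'   regimen) and `free_or_total`
#' @export
generate_study <- function(design, noise = noise_model(),
                           phys = phys_params(), chem = chem_params(),
                           study_id = "synthetic", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  draws <- if (!is.null(design$distributions))
    sample_parameters(design$distributions, design$n_animals)
  rows <- list()
  t_end <- max(design$times, dose_times(design$regimen))
  for (a in seq_len(design$n_animals)) {
    pars <- if (is.null(draws)) list(phys = phys, chem = chem)
            else apply_draw(phys, chem, draws[a, ])
    sim <- simulate_pbpk(pars$phys, pars$chem, design$regimen, t_end = t_end,
                         times = sort(unique(c(0, design$times, t_end))),
                         validate = FALSE)
    for (cp in design$compartments) {
      pred <- stats::approx(sim$time, sim$conc[, cp],
                            xout = design$times)$y
      obs <- pred * noise_factors(length(pred), noise$cv)
      rows[[length(rows) + 1L]] <- data.frame(
        study_id = study_id, animal = a, time_h = design$times,
        compartment = cp, concentration = obs, lloq = noise$lloq,
        row.names = NULL)
    }
  }
  out <- do.call(rbind, rows)
  below <- out$concentration < noise$lloq
  if (noise$below_lloq == "drop") {
    out <- out[!below, , drop = FALSE]
    out$censored <- FALSE
  } else {
    out$censored <- below
    out$concentration[below] <- NA_real_
  }
  attr(out, "truth") <- list(draws = draws, phys = phys, chem = chem,
                             regimen = design$regimen)
  out
}

#' Generate a synthetic microdialysis dialysate study
#'
#' Dialysate observation = in vivo relative recovery x simulated lung
#' interstitial-fluid concentration x noise; the generated profile
#' round-trips with [correct_isf()]. `dialysate_sampling_times()` returns
#' the default lung-probe sampling schedule.
#'
#' @inheritParams generate_study
#' @param in_vivo_rr probe in vivo relative recovery, fraction in (0, 1]
#' @return data.frame as in [generate_study()] with
#'   `compartment = "dialysate"`; attribute `in_vivo_rr`
#' @export
generate_dialysate_study <- function(design, in_vivo_rr,
                                     noise = noise_model(),
                                     phys = phys_params(),
                                     chem = chem_params(),
                                     study_id = "dialysate", seed = NULL) {
  if (in_vivo_rr <= 0 || in_vivo_rr > 1)
    stop("in_vivo_rr must lie in (0, 1]", call. = FALSE)
  design$compartments <- "lung_if"
  out <- generate_study(design, noise_model(noise$cv, lloq = 0),
                        phys, chem, study_id, seed)
  out$compartment <- "dialysate"
  out$concentration <- out$concentration * in_vivo_rr
  out$lloq <- noise$lloq
  below <- !is.na(out$concentration) & out$concentration < noise$lloq
  if (noise$below_lloq == "drop") out <- out[!below, , drop = FALSE]
  else { out$censored <- below; out$concentration[below] <- NA_real_ }
  attr(out, "in_vivo_rr") <- in_vivo_rr
  out
}
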