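#' Goodness-of-fit metrics for model calibration and validation
#'
#' `r_squared` is the coefficient of determination of predictions against
#' observations, `1 - SS_res / SS_tot` with residuals `obs - pred` and total
#' sum of squares about the observed mean: 1 for perfect prediction, 0 when
#' the model does no better than the observed mean, negative when worse.
#' A value of at least 0.75 is the conventional threshold for a good PBPK
#' prediction. `mape` is the mean absolute percentage error,
#' `100 * mean(|obs - pred| / obs)`; below 50% is conventionally acceptable.
#' `twofold_fraction` is the share of predictions within twofold of the
#' observation (`0.5 <= pred/obs <= 2`), the WHO-style model-acceptance rule.
#'
#' @param observed,predicted paired numeric vectors
#' @return `r_squared`: unitless in (-Inf, 1], `NA` with a warning when the
#'   observations have zero variance; `mape`: percent; `twofold_fraction`:
#'   fraction in `[0, 1]`
#' @name fit_metrics
NULL

#' @rdname fit_metrics
#' @export
r_squared <- function(observed, predicted) {
  check_paired(observed, predicted)
  ss_tot <- sum((observed - mean(observed))^2)
  if (ss_tot == 0) {
    warning("observed values have zero variance; R^2 undefined")
    return(NA_real_)
  }
  1 - sum((observed - predicted)^2) / ss_tot
}

#' @rdname fit_metrics
#' @export
mape <- function(observed, predicted) {
  check_paired(observed, predicted, min_n = 1)
  if (any(observed <= 0))
    stop("MAPE undefined: observed values must be > 0", call. = FALSE)
  100 * mean(abs(observed - predicted) / observed)
}

#' MAPE prediction-quality class
#'
#' @param mape_value percent error from [mape()]
#' @return one of "excellent" (<10%), "good" (10-20%), "acceptable" (<50%),
#'   "not acceptable"
#' @export
mape_class <- function(mape_value) {
  ifelse(mape_value < 10, "excellent",
    ifelse(mape_value < 20, "good",
      ifelse(mape_value < 50, "acceptable", "not acceptable")))
}

#' @rdname fit_metrics
#' @export
twofold_fraction <- function(observed, predicted) {
  check_paired(observed, predicted, min_n = 1)
  if (any(observed <= 0))
    stop("twofold rule undefined: observed values must be > 0", call. = FALSE)
  ratio <- predicted / observed
  mean(ratio >= 0.5 & ratio <= 2)
}

check_paired <- function(observed, predicted, min_n = 3) {
  if (length(observed) != length(predicted))
    stop("observed and predicted must have equal length", call. = FALSE)
  if (length(observed) < min_n)
    stop("need at least ", min_n, " paired values", call. = FALSE)
  if (any(!is.finite(observed)) || any(!is.finite(predicted)))
    stop("observed and predicted must be finite", call. = FALSE)
  invisible(NULL)
}

#' Specification of a parameter-fitting problem
#'
#' @param free names of free chemical parameters (subset of [chem_params()]
#'   numeric fields)
#' @param lower,upper named bounds per free parameter (finite, positive)
#' @param objective residual scale: `"log"` (default; appropriate when
#'   concentrations span orders of magnitude) or `"linear"`
#' @return object of class `ceq_fitspec`
#' @export
fit_spec <- function(free, lower = NULL, upper = NULL,
                     objective = c("log", "linear")) {
  objective <- match.arg(objective)
  fields <- setdiff(names(chem_params()), c("plu_mode", "lung_model"))
  bad <- setdiff(free, fields)
  if (length(bad))
    stop("unknown chemical parameters: ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (is.null(lower)) lower <- stats::setNames(rep(1e-6, length(free)), free)
  if (is.null(upper)) upper <- stats::setNames(rep(1e3, length(free)), free)
  lower <- lower[free]; upper <- upper[free]
  if (any(!is.finite(lower)) || any(!is.finite(upper)) ||
      any(lower <= 0) || any(upper <= lower))
    stop("bounds must be finite, positive, and upper > lower", call. = FALSE)
  structure(list(free = free, lower = lower, upper = upper,
                 objective = objective),
            class = "ceq_fitspec")
}

# predict model concentrations at the rows of an observed-data table
predict_at <- function(data, regimens, phys, chem) {
  preds <- numeric(nrow(data))
  for (sid in unique(data$study_id)) {
    rows <- which(data$study_id == sid)
    reg <- regimens[[sid]]
    if (is.null(reg))
      stop("no regimen supplied for study_id ", sid, call. = FALSE)
    tmax <- max(data$time_h[rows], max(dose_times(reg)))
    sim <- simulate_pbpk(phys, chem, reg, t_end = tmax,
                         times = sort(unique(c(0, data$time_h[rows], tmax))))
    for (cp in unique(data$compartment[rows])) {
      sel <- rows[data$compartment[rows] == cp]
      preds[sel] <- stats::approx(sim$time, sim$conc[, cp],
                                  xout = data$time_h[sel])$y
    }
  }
  preds
}

#' Fit chemical parameters to observed concentration data
#'
#' Bounded nonlinear least squares (Levenberg-Marquardt via
#' \pkg{minpack.lm}) of selected chemical parameters against one or more
#' observed datasets. Residuals are on the log scale by default; every
#' observation carries equal weight; observations below their `lloq` are
#' excluded from the objective.
#'
#' @param data observed dataset: data.frame with columns `study_id`,
#'   `time_h`, `compartment` (a reported trace name of [simulate_pbpk()]),
#'   `concentration`, and optionally `lloq`
#' @param regimens named list of [dosing_regimen()] objects keyed by
#'   `study_id`
#' @param spec a [fit_spec()]
#' @param phys physiological parameters (fixed)
#' @param chem_init starting chemical parameter set
#' @return list with `chem` (fitted [chem_params()]), `report` (objective,
#'   convergence flag and message, iterations, per-study R^2 and MAPE)
#' @export
fit_parameters <- function(data, regimens, spec, phys,
                           chem_init = chem_params()) {
  stopifnot(inherits(spec, "ceq_fitspec"))
  need <- c("study_id", "time_h", "compartment", "concentration")
  if (!all(need %in% names(data)))
    stop("data must have columns ", paste(need, collapse = ", "), call. = FALSE)
  if (!nrow(data)) stop("data is empty", call. = FALSE)
  lloq <- if ("lloq" %in% names(data)) data$lloq else 0
  use <- data$concentration >= lloq & data$concentration > 0
  dq <- data[use, , drop = FALSE]

  if (length(spec$free) == 0) {
    return(list(chem = chem_init,
                report = list(converged = TRUE, objective = NA_real_,
                              message = "no free parameters", niter = 0L,
                              per_study = NULL)))
  }
  start <- unlist(chem_init[spec$free])
  if (any(start < spec$lower) || any(start > spec$upper))
    stop("initial values must lie within bounds", call. = FALSE)

  make_chem <- function(theta) {
    ch <- unclass(chem_init)
    ch[spec$free] <- as.list(theta)
    class(ch) <- "ceq_chem"
    ch
  }
  residfun <- function(theta) {
    pred <- predict_at(dq, regimens, phys, make_chem(theta))
    if (spec$objective == "log") {
      log(pmax(pred, 1e-12)) - log(dq$concentration)
    } else {
      pred - dq$concentration
    }
  }
  fit <- minpack.lm::nls.lm(par = start, lower = spec$lower,
                            upper = spec$upper, fn = residfun,
                            control = minpack.lm::nls.lm.control(
                              maxiter = 200, ftol = 1e-12, ptol = 1e-12,
                              # finite-difference step must stay well above
                              # the ODE solver tolerance or the numerical
                              # jacobian measures integrator noise
                              epsfcn = 1e-6))
  chem_fit <- make_chem(fit$par)
  pred <- predict_at(dq, regimens, phys, chem_fit)
  per_study <- do.call(rbind, lapply(split(seq_len(nrow(dq)), dq$study_id),
    function(idx) {
      data.frame(study_id = dq$study_id[idx[1]], n = length(idx),
                 r_squared = if (length(idx) >= 3)
                   r_squared(dq$concentration[idx], pred[idx]) else NA_real_,
                 mape = mape(dq$concentration[idx], pred[idx]),
                 row.names = NULL)
    }))
  converged <- fit$info %in% 1:4
  if (!converged)
    warning("fit did not converge: ", fit$message, "; best-so-far returned")
  list(chem = chem_fit,
       report = list(converged = converged,
                     objective = fit$deviance,
                     message = fit$message,
                     niter = fit$niter,
                     estimates = stats::setNames(as.numeric(fit$par), spec$free),
                     per_study = per_study))
}
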