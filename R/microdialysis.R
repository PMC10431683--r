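#' Microdialysis probe calibration arithmetic
#'
#' In vitro relative recovery, retrodialysis delivery, and in vivo relative
#' recovery (RR) of a microdialysis probe, all in percent. Recovery is the
#' dialysate:medium concentration ratio; delivery and in vivo RR measure the
#' fractional loss of drug from the perfusate across the probe membrane.
#'
#' @param C_dialysate dialysate concentration (ug/mL)
#' @param C_medium surrounding-medium concentration (ug/mL), in vitro
#' @param C_perfusate perfusate ("input") concentration (ug/mL)
#' @return percent (vectorized)
#' @name probe_calibration
#' @examples
#' recovery_pct(0.2759, 1)      # 27.59 %
#' in_vivo_rr_pct(0.75, 0.534)  # 28.8 %
NULL

#' @rdname probe_calibration
#' @export
recovery_pct <- function(C_dialysate, C_medium) {
  check_nonneg(C_dialysate, "C_dialysate")
  if (any(C_medium <= 0))
    stop("C_medium must be > 0", call. = FALSE)
  100 * C_dialysate / C_medium
}

#' @rdname probe_calibration
#' @export
delivery_pct <- function(C_dialysate, C_perfusate) {
  check_nonneg(C_dialysate, "C_dialysate")
  if (any(C_perfusate <= 0))
    stop("C_perfusate must be > 0", call. = FALSE)
  100 * (1 - C_dialysate / C_perfusate)
}

#' @rdname probe_calibration
#' @export
in_vivo_rr_pct <- function(C_perfusate, C_dialysate) {
  check_nonneg(C_dialysate, "C_dialysate")
  if (any(C_perfusate <= 0))
    stop("C_perfusate must be > 0", call. = FALSE)
  100 * (C_perfusate - C_dialysate) / C_perfusate
}

check_nonneg <- function(x, what) {
  if (any(!is.finite(x)) || any(x < 0))
    stop(what, " must be finite and >= 0", call. = FALSE)
  invisible(x)
}

#' Correct a dialysate profile to interstitial-fluid concentration
#'
#' Divides each dialysate concentration by the probe's in vivo relative
#' recovery, giving the free interstitial-fluid (ISF) concentration
#' `C_ISF = C_dialysate / RR`.
#'
#' @param time sampling times (h)
#' @param concentration dialysate concentrations (ug/mL)
#' @param rr_fraction in vivo relative recovery as a fraction in (0, 1]
#' @return data.frame `time_h`, `concentration` (free ISF, ug/mL) with
#'   attribute `free_or_total = "free"`
#' @export
correct_isf <- function(time, concentration, rr_fraction) {
  if (length(rr_fraction) != 1 || !is.finite(rr_fraction) ||
      rr_fraction <= 0 || rr_fraction > 1)
    stop("rr_fraction must be a single value in (0, 1]", call. = FALSE)
  check_nonneg(concentration, "concentration")
  out <- data.frame(time_h = time, concentration = concentration / rr_fraction)
  attr(out, "free_or_total") <- "free"
  out
}

#' Non-compartmental analysis of a concentration-time profile
#'
#' Model-free PK summary: Cmax and Tmax from the grid maximum, AUC to the
#' last quantifiable point by the linear trapezoid rule, terminal slope
#' `lambda_z` by log-linear least squares, half-life `ln(2)/lambda_z`, and
#' mean residence time `AUMC/AUC`.
#'
#' The terminal window is chosen among the last 3 to `max_terminal`
#' quantifiable points as the one maximizing the adjusted R-squared of the
#' log-linear fit. Values below `lloq` are excluded throughout (treated as
#' missing). With fewer than 3 quantifiable terminal points, `lambda_z` and
#' derived quantities are `NA` and the result is flagged.
#'
#' @param time sampling times (h), strictly increasing
#' @param concentration concentrations (ug/mL)
#' @param lloq lower limit of quantitation (ug/mL); observations below it
#'   are dropped
#' @param max_terminal largest terminal-window size considered
#' @param extrapolate_inf also report `AUC_inf = AUC_last + C_last/lambda_z`
#' @return object of class `ceq_nca`: list with `Cmax`, `Tmax`, `AUC_last`,
#'   `lambda_z`, `T_half`, `MRT`, `AUMC_last`, optionally `AUC_inf`,
#'   `n_terminal`, `adj_r_squared`, `flagged`
#' @export
#' @examples
#' t <- 0:12
#' nca(t, 10 * exp(-0.5 * t))$T_half  # ln(2) / 0.5
nca <- function(time, concentration, lloq = 0, max_terminal = 5,
                extrapolate_inf = FALSE) {
  if (length(time) != length(concentration))
    stop("time and concentration must have equal length", call. = FALSE)
  if (any(diff(time) <= 0))
    stop("time must be strictly increasing", call. = FALSE)
  if (length(time) < 3)
    stop("NCA requires at least 3 time points", call. = FALSE)
  check_nonneg(concentration, "concentration")

  keep <- concentration >= lloq & concentration > 0
  tq <- time[keep]; cq <- concentration[keep]
  res <- list(Cmax = if (length(cq)) max(cq) else 0,
              Tmax = if (length(cq)) tq[which.max(cq)] else NA_real_,
              AUC_last = NA_real_, AUMC_last = NA_real_,
              lambda_z = NA_real_, T_half = NA_real_, MRT = NA_real_,
              n_terminal = NA_integer_, adj_r_squared = NA_real_,
              flagged = FALSE)
  class(res) <- "ceq_nca"
  if (length(cq) < 2) { res$flagged <- TRUE; res$AUC_last <- 0; return(res) }

  res$AUC_last  <- sum(diff(tq) * (utils::head(cq, -1) + utils::tail(cq, -1)) / 2)
  mom <- tq * cq
  res$AUMC_last <- sum(diff(tq) * (utils::head(mom, -1) + utils::tail(mom, -1)) / 2)
  res$MRT <- res$AUMC_last / res$AUC_last

  if (length(cq) >= 3) {
    best <- NULL
    for (k in 3:min(max_terminal, length(cq))) {
      idx <- seq(length(cq) - k + 1, length(cq))
      x <- tq[idx]; y <- log(cq[idx])
      sxx <- sum((x - mean(x))^2); syy <- sum((y - mean(y))^2)
      slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
      r2 <- if (syy > 0) slope^2 * sxx / syy else 0
      ar2 <- 1 - (1 - r2) * (k - 1) / (k - 2)
      if (is.null(best) || (is.finite(ar2) && ar2 > best$ar2))
        best <- list(k = k, ar2 = ar2, slope = slope)
    }
    if (!is.null(best) && is.finite(best$slope) && best$slope < 0) {
      res$lambda_z <- -best$slope
      res$T_half <- log(2) / res$lambda_z
      res$n_terminal <- best$k
      res$adj_r_squared <- best$ar2
    } else res$flagged <- TRUE
  } else res$flagged <- TRUE

  if (extrapolate_inf) {
    res$AUC_inf <- if (is.finite(res$lambda_z))
      res$AUC_last + cq[length(cq)] / res$lambda_z else NA_real_
  }
  res
}

#' @export
print.ceq_nca <- function(x, ...) {
  cat(sprintf(paste0("NCA: Cmax %.3g at %.3g h; AUC_last %.4g ug*h/mL; ",
                     "lambda_z %.4g /h (t1/2 %.3g h); MRT %.3g h%s\n"),
              x$Cmax, x$Tmax, x$AUC_last, x$lambda_z, x$T_half, x$MRT,
              if (isTRUE(x$flagged)) " [flagged]" else ""))
  invisible(x)
}
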