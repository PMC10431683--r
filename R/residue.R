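#' Maximum residue limit specification
#'
#' Regulatory ceilings for cefquinome residues in edible tissues; the
#' defaults are the EU/China limits of 0.1 ug/g in liver and 0.2 ug/g in
#' kidney.
#'
#' @param liver,kidney limits (ug/g), both > 0
#' @return named numeric vector
#' @export
mrl_spec <- function(liver = 0.1, kidney = 0.2) {
  if (liver <= 0 || kidney <= 0) stop("MRLs must be > 0", call. = FALSE)
  c(liver = liver, kidney = kidney)
}

#' Population residue-depletion simulation
#'
#' Simulates total liver and kidney concentrations across a Monte Carlo
#' population for a multi-dose regimen and evaluates them on a daily grid
#' after the last dose (the slaughter-day convention). Tissue
#' concentrations are total drug per tissue volume at unit density
#' (ug/g).
#'
#' @inheritParams simulate_population
#' @param horizon_days days after the last dose to cover
#' @param probs percentiles reported per day (percent scale)
#' @return object of class `ceq_depletion`: `days` (0:horizon), `p`
#'   (array day x tissue x percentile), `values` (array individual x day x
#'   tissue), `regimen`, `n`, `seed`
#' @export
simulate_residue_depletion <- function(phys = phys_params(),
                                       chem = chem_params(), regimen,
                                       horizon_days = 6,
                                       distributions = default_mc_distributions(),
                                       n = 1000, seed = 1,
                                       probs = c(1, 50, 99)) {
  last <- max(dose_times(regimen))
  eval_t <- last + 24 * (0:horizon_days)
  t_end <- max(eval_t)
  tissues <- c("liver", "kidney")
  red <- function(sim) {
    vapply(tissues, function(ts)
      stats::approx(sim$time, sim$conc[, ts], xout = eval_t)$y,
      numeric(length(eval_t)))
  }
  ens <- simulate_population(phys, chem, regimen, t_end = t_end,
                             distributions = distributions, n = n,
                             seed = seed, dt = 0.5, reduce = red)
  values <- array(NA_real_,
                  dim = c(n, length(eval_t), length(tissues)),
                  dimnames = list(NULL, paste0("day", 0:horizon_days), tissues))
  for (i in seq_len(n)) values[i, , ] <- ens$reduced[[i]]
  p <- array(NA_real_,
             dim = c(length(eval_t), length(tissues), length(probs)),
             dimnames = list(paste0("day", 0:horizon_days), tissues,
                             paste0("p", probs)))
  for (j in seq_along(eval_t)) for (k in seq_along(tissues))
    p[j, k, ] <- stats::quantile(values[, j, k], probs / 100, type = 7,
                                 names = FALSE)
  structure(list(days = 0:horizon_days, p = p, values = values,
                 regimen = regimen, n = n, seed = seed,
                 n_resampled = ens$n_resampled),
            class = "ceq_depletion")
}

#' Withdrawal-interval estimation by the 99th-percentile rule
#'
#' The withdrawal interval (WDI) is the smallest whole number of days after
#' the last dose at which the empirical 99th percentile of the simulated
#' residue concentration is at or below the maximum residue limit in both
#' liver and kidney simultaneously.
#'
#' @param depletion a [simulate_residue_depletion()] result
#' @param mrls an [mrl_spec()] vector
#' @return object of class `ceq_wdi`: `wdi_days`, `limiting_tissue` (the
#'   tissue still exceeding its limit on the previous day, `NA` when WDI is
#'   0), and `table` (day, tissue, p99, mrl, compliant)
#' @export
estimate_wdi <- function(depletion, mrls = mrl_spec()) {
  tissues <- c("liver", "kidney")
  p99 <- depletion$p[, tissues, "p99"]
  comp <- sweep(p99, 2, mrls[tissues], `<=`)
  ok <- which(rowSums(comp) == length(tissues))
  if (!length(ok))
    stop("no compliant day within the simulated horizon; ",
         "rerun with a larger horizon_days", call. = FALSE)
  wdi <- depletion$days[min(ok)]
  limiting <- NA_character_
  if (wdi > 0) {
    prev <- which(depletion$days == wdi) - 1
    over <- tissues[!comp[prev, ]]
    limiting <- if (length(over)) over[which.max(
      p99[prev, over] / mrls[over])] else NA_character_
  }
  tab <- data.frame(
    day = rep(depletion$days, length(tissues)),
    tissue = rep(tissues, each = length(depletion$days)),
    p99 = as.vector(p99),
    mrl = rep(unname(mrls[tissues]), each = length(depletion$days)),
    compliant = as.vector(comp), row.names = NULL)
  structure(list(wdi_days = wdi, limiting_tissue = limiting, table = tab,
                 mrls = mrls, regimen = depletion$regimen),
            class = "ceq_wdi")
}

#' @export
print.ceq_wdi <- function(x, ...) {
  print(x$regimen)
  cat(sprintf("WDI = %d day(s) after the last dose (99th percentile vs MRL liver %g / kidney %g ug/g)\n",
              x$wdi_days, x$mrls["liver"], x$mrls["kidney"]))
  if (!is.na(x$limiting_tissue))
    cat("limiting tissue:", x$limiting_tissue, "\n")
  invisible(x)
}
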