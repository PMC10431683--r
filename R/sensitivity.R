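#' Parameter roster for the local sensitivity screen
#'
#' All scalar model inputs from the physiological and chemical parameter
#' tables except the balancing remainders `QRC` and `VRC`, which are derived
#' quantities rather than independent inputs: 31 parameters in total.
#'
#' @return character vector of parameter names
#' @export
default_sensitivity_parameters <- function() {
  phys <- setdiff(names(phys_params()), c("QRC", "VRC"))
  chem <- setdiff(names(chem_params()), c("plu_mode", "lung_model"))
  c(phys, chem)
}

# apply a multiplicative perturbation to one named parameter, wherever it
# lives. The balancing remainders (QRC for flow fractions, VRC for volume
# fractions, VLUT for lung sub-volumes) absorb the perturbation of their
# siblings, so a flow perturbation redistributes flow from the rest-of-body
# compartment instead of changing total venous return - otherwise the
# recirculation offset masks about half of a flow parameter's true effect.
.balance_map <- c(QMC = "QRC", QLC = "QRC", QKC = "QRC",
                  VLUC = "VRC", VMC = "VRC", VLC = "VRC", VKC = "VRC",
                  VartC = "VRC", VvenC = "VRC",
                  VLUB = "VLUT", VLUI = "VLUT")

perturb_parameter <- function(phys, chem, parameter, factor) {
  if (parameter %in% names(phys)) {
    p <- unclass(phys)
    delta <- p[[parameter]] * (factor - 1)
    p[[parameter]] <- p[[parameter]] * factor
    bal <- .balance_map[parameter]
    if (!is.na(bal)) {
      p[[bal]] <- p[[bal]] - delta
      if (p[[bal]] <= 0)
        stop("perturbation of ", parameter,
             " exhausts the balancing remainder ", bal, call. = FALSE)
    }
    class(p) <- "ceq_phys"
    list(phys = p, chem = chem)
  } else if (parameter %in% names(chem) &&
             !parameter %in% c("plu_mode", "lung_model")) {
    p <- unclass(chem); p[[parameter]] <- p[[parameter]] * factor
    class(p) <- "ceq_chem"
    list(phys = phys, chem = p)
  } else {
    stop("unknown scalar parameter: ", parameter, call. = FALSE)
  }
}

# 24-h AUC of one reported compartment via the exact ODE accumulator;
# a two-point output grid suffices because the integral is a solver state
auc_at_horizon <- function(phys, chem, regimen, compartment, t_horizon) {
  sim <- simulate_pbpk(phys, chem, regimen, t_end = t_horizon,
                       times = c(0, t_horizon / 2, t_horizon),
                       validate = FALSE)
  pk_auc(sim, compartment, 0, t_horizon)
}

#' Normalized sensitivity coefficient of a compartment AUC
#'
#' Local sensitivity of the AUC over `[0, t_horizon]` of a reported
#' compartment with respect to one scalar parameter:
#' `NSC = ((AUC' - AUC) / AUC) / (delta_p / p)`, with the perturbed AUC'
#' computed at `p * (1 + delta_frac)` (forward difference; a central
#' difference is available). A parameter is conventionally called
#' influential when `|NSC| > 0.25`.
#'
#' @param phys,chem,regimen model inputs at baseline
#' @param parameter scalar parameter name (see
#'   [default_sensitivity_parameters()])
#' @param compartment reported compartment with an AUC accumulator
#'   (`plasma`, `liver`, `kidney`, `muscle`, `rest`, `lung`, `lung_blood`,
#'   `lung_if`)
#' @param t_horizon AUC horizon (h)
#' @param delta_frac relative perturbation (default 0.10, i.e. +10%)
#' @param central use a central difference
#'   (`(AUC(1+d) - AUC(1-d)) / (2 d AUC)`) instead of forward
#' @return object of class `ceq_nsc`: list with `parameter`, `compartment`,
#'   `baseline_auc`, `delta_p`, `delta_auc`, `nsc`, `influential`, `flagged`
#' @export
nsc <- function(phys, chem, regimen, parameter, compartment,
                t_horizon = 24, delta_frac = 0.10, central = FALSE) {
  if (!is.finite(delta_frac) || delta_frac <= 0)
    stop("delta_frac must be > 0", call. = FALSE)
  base <- auc_at_horizon(phys, chem, regimen, compartment, t_horizon)
  up <- perturb_parameter(phys, chem, parameter, 1 + delta_frac)
  auc_up <- auc_at_horizon(up$phys, up$chem, regimen, compartment, t_horizon)
  if (central) {
    dn <- perturb_parameter(phys, chem, parameter, 1 - delta_frac)
    auc_dn <- auc_at_horizon(dn$phys, dn$chem, regimen, compartment, t_horizon)
    delta_auc <- (auc_up - auc_dn) / 2
  } else {
    delta_auc <- auc_up - base
  }
  flagged <- !is.finite(base) || base <= 0
  val <- if (flagged) NA_real_ else (delta_auc / base) / delta_frac
  p0 <- if (parameter %in% names(phys)) phys[[parameter]] else chem[[parameter]]
  structure(list(parameter = parameter, compartment = compartment,
                 baseline_auc = base, delta_p = delta_frac * p0,
                 delta_auc = delta_auc, nsc = val,
                 influential = isTRUE(abs(val) > 0.25), flagged = flagged),
            class = "ceq_nsc")
}

#' @export
print.ceq_nsc <- function(x, ...) {
  cat(sprintf("NSC(%s -> AUC %s) = %+.3f%s\n", x$parameter, x$compartment,
              x$nsc, if (x$influential) " [influential]" else ""))
  invisible(x)
}

#' Full local sensitivity screen
#'
#' Forward-difference NSC of every parameter against the AUCs of the
#' requested compartments at the given horizon (one simulation per
#' perturbed parameter set; the exact AUC accumulator makes each cheap).
#'
#' @inheritParams nsc
#' @param parameters parameter names
#'   (default: [default_sensitivity_parameters()])
#' @param compartments reported compartments to screen
#' @return data.frame: `parameter`, `compartment`, `baseline_auc`, `nsc`,
#'   `influential`
#' @export
#' @examples
#' \donttest{
#' scr <- sensitivity_screen(phys_params(), chem_params(), dosing_regimen(2),
#'                           compartments = "plasma")
#' scr[scr$influential, ]
#' }
sensitivity_screen <- function(phys, chem, regimen,
                               parameters = default_sensitivity_parameters(),
                               compartments = c("plasma", "liver", "kidney",
                                                "muscle", "lung", "lung_if"),
                               t_horizon = 24, delta_frac = 0.10) {
  if (!is.finite(delta_frac) || delta_frac <= 0)
    stop("delta_frac must be > 0", call. = FALSE)
  base <- vapply(compartments, function(cp)
    auc_at_horizon(phys, chem, regimen, cp, t_horizon), numeric(1))
  rows <- lapply(parameters, function(p) {
    pert <- perturb_parameter(phys, chem, p, 1 + delta_frac)
    auc_up <- vapply(compartments, function(cp)
      auc_at_horizon(pert$phys, pert$chem, regimen, cp, t_horizon), numeric(1))
    val <- ((auc_up - base) / base) / delta_frac
    data.frame(parameter = p, compartment = compartments,
               baseline_auc = unname(base), nsc = unname(val),
               influential = abs(unname(val)) > 0.25, row.names = NULL)
  })
  do.call(rbind, rows)
}
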