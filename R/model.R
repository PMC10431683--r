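# State layout of the cefquinome PBPK system. Amounts are mg; the system is
# linear time-invariant between dose events, so the whole right-hand side is
# a constant matrix acting on the state vector. AUC accumulator states carry
# the running time-integral of the reported concentrations (mg*h/L).
.state_names <- c("depot_slow", "depot_fast", "ven", "art",
                  "lung_blood", "lung_if", "lung_tissue",
                  "liver", "kidney", "muscle", "rest",
                  "urine", "bile",
                  "auc_plasma", "auc_liver", "auc_kidney", "auc_muscle",
                  "auc_rest", "auc_lung", "auc_lung_blood", "auc_lung_if")

.n_core <- 13L  # states 1..13 are amounts; the rest are AUC accumulators

# derived_quantities without invariant checks, for perturbed parameter sets
# (local sensitivity analysis moves one fraction at a time without
# rebalancing the remainders)
.derived <- function(phys) {
  QC <- phys$QCC * phys$BW
  V_lung <- phys$VLUC * phys$BW
  list(QC = QC,
       Q_muscle = phys$QMC * QC, Q_rest = phys$QRC * QC,
       Q_liver = phys$QLC * QC, Q_kidney = phys$QKC * QC,
       Q_lung = phys$QLUC * QC,
       V_lung = V_lung, V_muscle = phys$VMC * phys$BW,
       V_rest = phys$VRC * phys$BW, V_liver = phys$VLC * phys$BW,
       V_kidney = phys$VKC * phys$BW, V_art = phys$VartC * phys$BW,
       V_ven = phys$VvenC * phys$BW,
       V_lung_blood = phys$VLUB * V_lung, V_lung_if = phys$VLUI * V_lung,
       V_lung_tissue = phys$VLUT * V_lung)
}

#' System matrix of the linear PBPK ODE system
#'
#' Builds the constant coefficient matrix `M` such that `d(state)/dt = M %*%
#' state` between dose events. The first 13 states are amounts (mg): the two
#' depot pools, venous and arterial blood, the three lung sub-compartments,
#' the four perfusion-limited tissues, and cumulative urine and bile output.
#' The remaining states accumulate the AUC of each reported concentration.
#'
#' Perfusion-limited tissues follow `dA_T/dt = Q_T * (C_art - C_T / P_T)`;
#' the lung sits in series with the circulation (venous blood -> lung blood ->
#' arterial blood, carrying the whole cardiac output) and exchanges free drug
#' with its interstitial-fluid (IF) and tissue sub-compartments. Hepatic and
#' renal clearance drain the venous-equilibrated organ concentrations
#' `C_liver / PL` and `C_kidney / PK` into bile and urine.
#'
#' The lung exchange fluxes depend on `chem$lung_model`; see [chem_params()]
#' for the two formulations and the rationale for the default.
#'
#' @inheritParams simulate_pbpk
#' @param validate check parameter invariants (disable for one-at-a-time
#'   sensitivity perturbations, which deliberately unbalance the fractional
#'   sums)
#' @return matrix with dimnames from the internal state layout
#' @export
pbpk_matrix <- function(phys, chem, validate = TRUE) {
  if (validate) { validate_phys(phys); validate_chem(chem) }
  d <- .derived(phys)
  n <- length(.state_names)
  M <- matrix(0, n, n, dimnames = list(.state_names, .state_names))
  CLbile  <- chem$KbileC * phys$BW    # L/h
  CLurine <- chem$KurineC * phys$BW   # L/h
  plu_div <- if (identical(chem$plu_mode, "tissue_partition")) chem$PLU else 1

  M["depot_slow", "depot_slow"] <- -chem$Kdiss
  M["depot_fast", "depot_slow"] <-  chem$Kdiss
  M["depot_fast", "depot_fast"] <- -chem$Kim

  # venous blood: depot absorption + tissue venous return - flow to lung
  M["ven", "depot_fast"] <- chem$Kim
  M["ven", "muscle"] <- d$Q_muscle / (chem$PM * d$V_muscle)
  M["ven", "rest"]   <- d$Q_rest   / (chem$PR * d$V_rest)
  M["ven", "liver"]  <- d$Q_liver  / (chem$PL * d$V_liver)
  M["ven", "kidney"] <- d$Q_kidney / (chem$PK * d$V_kidney)
  M["ven", "ven"]    <- -d$QC / d$V_ven

  # lung in series: the whole cardiac output flows venous -> lung blood ->
  # arterial; lung exchange rate coefficients (per hour, acting on the
  # stated amount or concentration) by formulation:
  if (identical(chem$lung_model, "calibrated")) {
    # permeability-clearance form on free concentrations, with the fast
    # rate-constant pair at the blood-IF interface
    bi <- chem$KIT * (1 - chem$PB) / d$V_lung_blood
    ib <- chem$KTI / d$V_lung_if
    it <- chem$KBI / d$V_lung_if
    ti <- chem$KIB * (1 - chem$PT) / (plu_div * d$V_lung_tissue)
  } else {
    # first-order rates on free amounts, blood-IF pair KBI/KIB
    bi <- chem$KBI * (1 - chem$PB)
    ib <- chem$KIB
    it <- chem$KIT
    ti <- chem$KTI * (1 - chem$PT) / plu_div
  }
  M["lung_blood", "ven"] <- d$QC / d$V_ven
  M["lung_blood", "lung_blood"] <- -d$QC / d$V_lung_blood - bi
  M["lung_blood", "lung_if"] <- ib
  M["lung_if", "lung_blood"] <- bi
  M["lung_if", "lung_if"] <- -(ib + it)
  M["lung_if", "lung_tissue"] <- ti
  M["lung_tissue", "lung_if"] <- it
  M["lung_tissue", "lung_tissue"] <- -ti
  M["art", "lung_blood"] <- d$QC / d$V_lung_blood
  # arterial outflow equals the sum of tissue inflows (the printed flow
  # fractions sum to 1.003, not exactly 1), so no mass is created
  M["art", "art"] <- -(d$Q_liver + d$Q_kidney + d$Q_muscle + d$Q_rest) / d$V_art

  # perfusion-limited tissues; clearance drains C_organ / P
  M["liver", "art"] <- d$Q_liver / d$V_art
  M["liver", "liver"] <- -(d$Q_liver + CLbile) / (chem$PL * d$V_liver)
  M["kidney", "art"] <- d$Q_kidney / d$V_art
  M["kidney", "kidney"] <- -(d$Q_kidney + CLurine) / (chem$PK * d$V_kidney)
  M["muscle", "art"] <- d$Q_muscle / d$V_art
  M["muscle", "muscle"] <- -d$Q_muscle / (chem$PM * d$V_muscle)
  M["rest", "art"] <- d$Q_rest / d$V_art
  M["rest", "rest"] <- -d$Q_rest / (chem$PR * d$V_rest)

  M["urine", "kidney"] <- CLurine / (chem$PK * d$V_kidney)
  M["bile", "liver"]   <- CLbile  / (chem$PL * d$V_liver)

  # AUC accumulators of reported concentrations
  M["auc_plasma", "ven"] <- 1 / d$V_ven
  M["auc_liver", "liver"] <- 1 / d$V_liver
  M["auc_kidney", "kidney"] <- 1 / d$V_kidney
  M["auc_muscle", "muscle"] <- 1 / d$V_muscle
  M["auc_rest", "rest"] <- 1 / d$V_rest
  if (identical(chem$plu_mode, "tissue_partition")) {
    M["auc_lung", c("lung_blood", "lung_if", "lung_tissue")] <- 1 / d$V_lung
  } else {
    # reported whole-lung concentration is the equilibrium PLU * C_lung_blood
    M["auc_lung", "lung_blood"] <- chem$PLU / d$V_lung_blood
  }
  M["auc_lung_blood", "lung_blood"] <- 1 / d$V_lung_blood
  M["auc_lung_if", "lung_if"] <- 1 / d$V_lung_if
  M
}

#' Right-hand side of the PBPK ODE system
#'
#' Returns a derivative function `f(t, state)` (also usable directly by
#' \pkg{deSolve}) implementing the flow-limited tissue, series lung and
#' two-step depot structure described in [pbpk_matrix()].
#'
#' @inheritParams simulate_pbpk
#' @return function of `(t, state, ...)` returning `list(dstate)`
#' @export
build_rhs <- function(phys, chem) {
  M <- pbpk_matrix(phys, chem)
  function(t, state, parms = NULL) list(as.vector(M %*% state))
}

#' Simulate the cefquinome PBPK model
#'
#' Integrates the six-compartment PBPK system for an intramuscular dosing
#' regimen. Each dose is applied as an instantaneous addition to the depot
#' pools (`Frac` of the dose to the slow pool, the remainder to the fast
#' pool); the stiff-capable `lsoda` integrator is restarted at each dose
#' event and is supplied the constant analytic Jacobian.
#'
#' @param phys a [phys_params()] object
#' @param chem a [chem_params()] object
#' @param regimen a [dosing_regimen()] object
#' @param t_end end of simulation (h); must cover the last dose
#' @param dt output grid spacing (h)
#' @param times optional explicit output grid overriding `dt`
#' @param rtol,atol solver tolerances (relative; absolute, mg)
#' @param validate check parameter invariants before simulating
#' @return an object of class `ceq_sim`: list with `time` (h), `conc`
#'   (matrix of concentrations, mg/L for fluids and ug/g for tissues at unit
#'   density: columns plasma, plasma_free, arterial, arterial_free, liver,
#'   kidney, muscle, rest, lung, lung_blood, lung_if), `amounts` (mg),
#'   `auc` (running AUC accumulators, mg*h/L), and the inputs.
#'   The `lung_if` trace is a free concentration by construction; `plasma`
#'   and tissue traces are total concentrations. At a dose time the reported
#'   state is the pre-dose (trough) state.
#' @export
#' @examples
#' sim <- simulate_pbpk(phys_params(), chem_params(), dosing_regimen(2), t_end = 24)
#' max(sim$conc[, "plasma"])
simulate_pbpk <- function(phys, chem, regimen, t_end,
                          dt = 0.05, times = NULL,
                          rtol = 1e-8, atol = 1e-10, validate = TRUE) {
  dtimes <- dose_times(regimen)
  if (t_end < max(dtimes))
    stop("t_end must be at or after the last dose time", call. = FALSE)
  if (is.null(times)) times <- seq(0, t_end, by = dt)
  if (any(diff(times) <= 0) || any(times < 0) || max(times) > t_end)
    stop("output times must be strictly increasing within [0, t_end]", call. = FALSE)
  times <- sort(unique(c(times, dtimes[dtimes <= t_end])))

  dose_mg <- regimen$dose_per_kg * phys$BW
  M <- pbpk_matrix(phys, chem, validate = validate)
  y0 <- stats::setNames(numeric(length(.state_names)), .state_names)

  events <- data.frame(
    var = rep(c("depot_slow", "depot_fast"), length(dtimes)),
    time = rep(dtimes, each = 2),
    value = rep(c(dose_mg * chem$Frac, dose_mg * (1 - chem$Frac)),
                length(dtimes)),
    method = "add"
  )

  rhs <- function(t, y, p) list(as.vector(M %*% y))
  jac <- function(t, y, p) M
  # solver warnings signal truncated or degraded output (e.g. "returning
  # early"); treat them as failures so callers (notably the population
  # layer) can resample or adjust tolerances rather than consume bad traces
  out <- withCallingHandlers(
    deSolve::ode(y = y0, times = times, func = rhs, parms = NULL,
                 method = "lsoda", jacfunc = jac, jactype = "fullusr",
                 events = list(data = events),
                 rtol = rtol, atol = atol, maxsteps = 50000),
    warning = function(w)
      stop("ODE integration unreliable: ", conditionMessage(w),
           call. = FALSE))
  if (attr(out, "istate")[1] < 0 || anyNA(out))
    stop("ODE integration failed; solver diagnostics: istate = ",
         attr(out, "istate")[1], call. = FALSE)
  amounts <- unclass(out)[, 1 + seq_len(.n_core), drop = FALSE]
  aucs    <- unclass(out)[, 1 + (.n_core + 1):length(.state_names), drop = FALSE]
  tgrid   <- unclass(out)[, 1]

  worst <- min(amounts)
  if (worst < -1e-6 * max(dose_mg * regimen$n_doses, 1))
    stop("negative state beyond solver tolerance: ", worst, call. = FALSE)
  amounts[amounts < 0] <- 0

  d <- .derived(phys)
  c_ven <- amounts[, "ven"] / d$V_ven
  c_art <- amounts[, "art"] / d$V_art
  lung_conc <- if (identical(chem$plu_mode, "tissue_partition")) {
    (amounts[, "lung_blood"] + amounts[, "lung_if"] + amounts[, "lung_tissue"]) / d$V_lung
  } else {
    chem$PLU * amounts[, "lung_blood"] / d$V_lung_blood
  }
  conc <- cbind(
    plasma = c_ven,
    plasma_free = (1 - chem$PB) * c_ven,
    arterial = c_art,
    arterial_free = (1 - chem$PB) * c_art,
    liver = amounts[, "liver"] / d$V_liver,
    kidney = amounts[, "kidney"] / d$V_kidney,
    muscle = amounts[, "muscle"] / d$V_muscle,
    rest = amounts[, "rest"] / d$V_rest,
    lung = lung_conc,
    lung_blood = amounts[, "lung_blood"] / d$V_lung_blood,
    lung_if = amounts[, "lung_if"] / d$V_lung_if
  )

  structure(list(time = tgrid, conc = conc, amounts = amounts, auc = aucs,
                 phys = phys, chem = chem, regimen = regimen,
                 dose_total = dose_mg * regimen$n_doses),
            class = "ceq_sim")
}

#' @export
print.ceq_sim <- function(x, ...) {
  cat(sprintf("PBPK simulation: %d time points over [%g, %g] h\n",
              length(x$time), min(x$time), max(x$time)))
  print(x$regimen)
  cat(sprintf("Cmax plasma %.3f ug/mL; Cmax lung IF %.3f ug/mL\n",
              max(x$conc[, "plasma"]), max(x$conc[, "lung_if"])))
  invisible(x)
}

#' Mass balance of a simulation
#'
#' Total administered dose versus drug in the body, the depot pools and the
#' cumulative urine and bile output at each output time. At dose times the
#' solver reports the pre-dose state, so doses are counted strictly before
#' each output time.
#'
#' @param sim a `ceq_sim` object
#' @return data.frame with `time`, `administered` (mg, doses given so far),
#'   `accounted` (mg) and `rel_error`
#' @export
mass_balance <- function(sim) {
  given <- vapply(sim$time, function(t) {
    sum(dose_times(sim$regimen) < t - 1e-12)
  }, numeric(1)) * sim$regimen$dose_per_kg * sim$phys$BW
  accounted <- rowSums(sim$amounts)  # all 13 core states are amounts
  rel <- ifelse(given > 0, (accounted - given) / given, accounted)
  data.frame(time = sim$time, administered = given,
             accounted = accounted, rel_error = rel)
}

#' Area under the concentration-time curve
#'
#' AUC of a reported compartment over `[t_start, t_end]`. For compartments
#' with an ODE accumulator (`plasma`, `liver`, `kidney`, `muscle`, `rest`,
#' `lung`, `lung_blood`, `lung_if`, and the free-plasma scaling) the exact
#' integral carried by the solver is used, interpolated linearly between grid
#' points; other traces fall back to the trapezoid rule on the output grid.
#'
#' @param sim a `ceq_sim` object
#' @param compartment column name of `sim$conc`
#' @param t_start,t_end integration window (h); defaults to the whole grid
#' @return AUC in mg*h/L (equivalently ug*h/mL)
#' @export
pk_auc <- function(sim, compartment, t_start = 0, t_end = max(sim$time)) {
  if (!compartment %in% colnames(sim$conc))
    stop("unknown compartment: ", compartment, call. = FALSE)
  if (t_end < t_start || t_start < min(sim$time) || t_end > max(sim$time))
    stop("AUC window must lie within the simulated span", call. = FALSE)
  if (compartment == "plasma_free")
    return((1 - sim$chem$PB) * pk_auc(sim, "plasma", t_start, t_end))
  acc_map <- c(plasma = "auc_plasma", liver = "auc_liver",
               kidney = "auc_kidney", muscle = "auc_muscle",
               rest = "auc_rest", lung = "auc_lung",
               lung_blood = "auc_lung_blood", lung_if = "auc_lung_if")
  if (compartment %in% names(acc_map)) {
    acc <- sim$auc[, acc_map[[compartment]]]
    val <- stats::approx(sim$time, acc, xout = c(t_start, t_end))$y
    return(val[2] - val[1])
  }
  trapz_auc(sim$time, sim$conc[, compartment], t_start, t_end)
}

# trapezoid AUC on a grid, restricted to [t0, t1] with linear interpolation
# at the window edges
trapz_auc <- function(time, conc, t0 = min(time), t1 = max(time)) {
  keep <- time > t0 & time < t1
  tt <- c(t0, time[keep], t1)
  cc <- c(stats::approx(time, conc, xout = t0)$y, conc[keep],
          stats::approx(time, conc, xout = t1)$y)
  sum(diff(tt) * (utils::head(cc, -1) + utils::tail(cc, -1)) / 2)
}

#' Export a simulation as a tidy concentration table
#'
#' @param sim a `ceq_sim` object
#' @param compartments which traces to include
#' @return data.frame with columns `time_h`, `compartment`, `concentration`,
#'   `units`, `free_or_total`
#' @export
as_concentration_table <- function(sim,
    compartments = c("plasma", "plasma_free", "liver", "kidney", "lung",
                     "lung_if")) {
  compartments <- match.arg(compartments, colnames(sim$conc), several.ok = TRUE)
  free <- c(plasma_free = TRUE, arterial_free = TRUE, lung_if = TRUE)
  units <- c(liver = "ug/g", kidney = "ug/g", muscle = "ug/g", rest = "ug/g",
             lung = "ug/g")
  do.call(rbind, lapply(compartments, function(cp) {
    data.frame(time_h = sim$time, compartment = cp,
               concentration = sim$conc[, cp],
               units = if (cp %in% names(units)) units[[cp]] else "ug/mL",
               free_or_total = if (isTRUE(free[cp])) "free" else "total",
               row.names = NULL)
  }))
}
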