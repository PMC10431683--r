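#' Physiological parameters of the growing pig
#'
#' Constructor for the physiological parameter set of the swine PBPK model:
#' body weight, cardiac output, fractional organ blood flows and fractional
#' organ volumes, including the lung sub-compartment volume fractions of the
#' permeability-limited lung. Defaults describe a 25-kg nursery pig.
#'
#' Fractional blood flows (`QMC`, `QRC`, `QLC`, `QKC`) are fractions of cardiac
#' output; the whole cardiac output passes through the lung (`QLUC = 1`).
#' Fractional volumes (`VLUC`, `VMC`, `VRC`, `VLC`, `VKC`, `VartC`, `VvenC`)
#' are fractions of body weight; `VLUB`, `VLUI`, `VLUT` partition the total
#' lung volume into blood, interstitial fluid (IF) and tissue. `QRC` and
#' `VRC`, `VLUT` are balancing remainders, so flow and lung-volume fractions
#' must each sum to 1 within 1%.
#'
#' @param BW body weight (kg)
#' @param QCC cardiac output (L/h/kg)
#' @param QMC,QRC,QLC,QKC fractional blood flow to muscle, rest-of-body,
#'   liver, kidney (unitless)
#' @param QLUC fraction of cardiac output through lung (must be 1)
#' @param VLUC,VMC,VRC,VLC,VKC fractional volume of lung, muscle, rest,
#'   liver, kidney (fraction of BW)
#' @param VartC,VvenC arterial and venous blood volume fractions of BW
#' @param VLUB,VLUI,VLUT lung blood / IF / tissue volumes as fractions of
#'   total lung volume
#' @return an object of class `ceq_phys` (named list)
#' @export
#' @examples
#' p <- phys_params()
#' derived_quantities(p)$QC  # cardiac output, L/h
phys_params <- function(BW = 25, QCC = 4.944,
                        QMC = 0.2524, QRC = 0.3055, QLC = 0.3053, QKC = 0.1398,
                        QLUC = 1,
                        VLUC = 0.01, VMC = 0.4, VRC = 0.232, VLC = 0.0294,
                        VKC = 0.004, VartC = 0.016, VvenC = 0.044,
                        VLUB = 0.262, VLUI = 0.188, VLUT = 0.55) {
  p <- list(BW = BW, QCC = QCC, QMC = QMC, QRC = QRC, QLC = QLC, QKC = QKC,
            QLUC = QLUC, VLUC = VLUC, VMC = VMC, VRC = VRC, VLC = VLC,
            VKC = VKC, VartC = VartC, VvenC = VvenC,
            VLUB = VLUB, VLUI = VLUI, VLUT = VLUT)
  class(p) <- "ceq_phys"
  validate_phys(p)
  p
}

validate_phys <- function(p) {
  num <- unlist(p)
  if (any(!is.finite(num)) || any(num <= 0))
    stop("all physiological parameters must be finite and > 0", call. = FALSE)
  frac <- num[setdiff(names(num), c("BW", "QCC"))]
  if (any(frac > 1))
    stop("fractional physiological parameters must lie in (0, 1]", call. = FALSE)
  if (abs(p$QLUC - 1) > 1e-12)
    stop("QLUC must equal 1: the whole cardiac output perfuses the lung", call. = FALSE)
  qsum <- p$QMC + p$QRC + p$QLC + p$QKC
  if (qsum < 0.99 || qsum > 1.01)
    stop(sprintf("fractional flows sum to %.4f; must be within [0.99, 1.01]", qsum),
         call. = FALSE)
  vsum <- p$VLUB + p$VLUI + p$VLUT
  if (vsum < 0.99 || vsum > 1.01)
    stop(sprintf("lung sub-volume fractions sum to %.4f; must be within [0.99, 1.01]", vsum),
         call. = FALSE)
  invisible(p)
}

#' Chemical-specific parameters of cefquinome
#'
#' Constructor for the drug-specific parameter set: tissue-to-blood partition
#' coefficients, the two-step intramuscular depot constants, hepatic and renal
#' clearances, protein-binding fractions, and the first-order transfer rates of
#' the permeability-limited lung. Defaults are the calibrated cefquinome
#' values for swine.
#'
#' The intramuscular dose is split on administration: a fraction `Frac` enters
#' a slow pool released at rate `Kdiss` into the fast pool, and the remainder
#' enters the fast pool directly; the fast pool is absorbed into venous blood
#' at `Kim`.
#'
#' `lung_model` selects the formulation of the permeability-limited lung
#' exchange, which only free drug crosses:
#' \describe{
#'   \item{`"calibrated"`}{(default) transfer as permeability clearances
#'     acting on free concentrations, with the fast rate-constant pair
#'     (`KIT`, `KTI`) at the blood-IF interface (blood to IF on the unbound
#'     lung-blood concentration, IF to blood on the IF concentration) and
#'     the slow pair (`KBI`, `KIB`) at the IF-tissue interface (tissue
#'     return on the unbound tissue concentration). This assignment is the
#'     one that reproduces both the observed interstitial-fluid kinetics
#'     (peak about an hour after dosing, terminal half-life close to
#'     plasma) and the published population dosage table; the slow pair
#'     cannot carry the blood-IF exchange on any reading of the units.}
#'   \item{`"amount"`}{first-order rates per hour acting on free amounts,
#'     with `KBI`/`KIB` at the blood-IF interface and `KIT`/`KTI` at the
#'     IF-tissue interface, following the nominal parameter labels. This
#'     produces a slow, flat interstitial-fluid profile; it is retained as
#'     the literal reading of the parameter table.}
#' }
#'
#' `plu_mode` controls where the lung partition coefficient `PLU` acts, a
#' structural choice the source model family leaves open:
#' \describe{
#'   \item{`"report"`}{(default) `PLU` scales only the reported equilibrium
#'     whole-lung concentration (`PLU` times the lung-blood concentration);
#'     it does not enter the kinetics, so the lung-IF profile is insensitive
#'     to it.}
#'   \item{`"tissue_partition"`}{`PLU` acts as the lung tissue:IF partition,
#'     dividing the tissue-to-IF return flux, and the reported whole-lung
#'     concentration is the volume-weighted total over the three
#'     sub-compartments.}
#' }
#'
#' @param PLU,PM,PR,PL,PK tissue-to-blood partition coefficients for lung,
#'   muscle, rest, liver, kidney (unitless)
#' @param Kim fast depot absorption rate (/h)
#' @param Frac fraction of each dose entering the slow depot pool (unitless)
#' @param Kdiss slow depot release rate (/h)
#' @param KbileC hepatic clearance (L/h/kg)
#' @param KurineC renal clearance (L/h/kg)
#' @param PB plasma protein-bound fraction (unitless)
#' @param PT lung-tissue protein-bound fraction (unitless)
#' @param KBI,KIB slow lung transfer rate pair (/h)
#' @param KIT,KTI fast lung transfer rate pair (/h)
#' @param lung_model lung exchange formulation, see Details
#' @param plu_mode placement of `PLU`, see Details
#' @return an object of class `ceq_chem` (named list)
#' @export
chem_params <- function(PLU = 1.5, PM = 0.1, PR = 0.1, PL = 6, PK = 15.2,
                        Kim = 7, Frac = 0.1, Kdiss = 0.05,
                        KbileC = 0.01, KurineC = 0.3,
                        PB = 0.188, PT = 0.3,
                        KBI = 0.110, KIB = 0.052, KIT = 3.56, KTI = 2.60,
                        lung_model = c("calibrated", "amount"),
                        plu_mode = c("report", "tissue_partition")) {
  lung_model <- match.arg(lung_model)
  plu_mode <- match.arg(plu_mode)
  p <- list(PLU = PLU, PM = PM, PR = PR, PL = PL, PK = PK,
            Kim = Kim, Frac = Frac, Kdiss = Kdiss,
            KbileC = KbileC, KurineC = KurineC, PB = PB, PT = PT,
            KBI = KBI, KIB = KIB, KIT = KIT, KTI = KTI,
            lung_model = lung_model, plu_mode = plu_mode)
  class(p) <- "ceq_chem"
  validate_chem(p)
  p
}

validate_chem <- function(p) {
  num <- unlist(p[setdiff(names(p), c("plu_mode", "lung_model"))])
  if (any(!is.finite(num)) || any(num < 0))
    stop("all chemical parameters must be finite and >= 0", call. = FALSE)
  for (f in c("Frac", "PB", "PT"))
    if (p[[f]] > 1)
      stop(sprintf("%s is a fraction and must lie in [0, 1]", f), call. = FALSE)
  invisible(p)
}

#' Absolute flows and volumes from fractional parameters
#'
#' Scales fractional flows by cardiac output and fractional volumes by body
#' weight, giving the absolute quantities (L/h and L) used by the ODE
#' right-hand side. Lung sub-compartment volumes are fractions of the total
#' lung volume `VLUC * BW`.
#'
#' @param phys a [phys_params()] object
#' @return named list: `QC` and `Q_*` flows (L/h); `V_*` volumes (L)
#' @export
derived_quantities <- function(phys) {
  validate_phys(phys)
  QC <- phys$QCC * phys$BW
  V_lung <- phys$VLUC * phys$BW
  list(
    QC = QC,
    Q_muscle = phys$QMC * QC,
    Q_rest   = phys$QRC * QC,
    Q_liver  = phys$QLC * QC,
    Q_kidney = phys$QKC * QC,
    Q_lung   = phys$QLUC * QC,
    V_lung   = V_lung,
    V_muscle = phys$VMC * phys$BW,
    V_rest   = phys$VRC * phys$BW,
    V_liver  = phys$VLC * phys$BW,
    V_kidney = phys$VKC * phys$BW,
    V_art    = phys$VartC * phys$BW,
    V_ven    = phys$VvenC * phys$BW,
    V_lung_blood  = phys$VLUB * V_lung,
    V_lung_if     = phys$VLUI * V_lung,
    V_lung_tissue = phys$VLUT * V_lung
  )
}

#' Intramuscular dosing regimen
#'
#' @param dose_per_kg dose per administration (mg/kg)
#' @param interval hours between administrations (required when `n_doses > 1`)
#' @param n_doses number of administrations
#' @param start_time time of the first dose (h)
#' @param route administration route; only intramuscular is modelled
#' @return an object of class `ceq_regimen`
#' @export
#' @examples
#' dosing_regimen(2)                     # single label dose
#' dosing_regimen(3, interval = 12, n_doses = 10)  # extra-label, twice daily x 5 d
dosing_regimen <- function(dose_per_kg, interval = 24, n_doses = 1,
                           start_time = 0, route = "IM") {
  if (!identical(route, "IM"))
    stop("only intramuscular (IM) administration is modelled", call. = FALSE)
  if (!is.finite(dose_per_kg) || dose_per_kg < 0)
    stop("dose_per_kg must be a non-negative number", call. = FALSE)
  if (n_doses < 1 || n_doses != round(n_doses))
    stop("n_doses must be a positive integer", call. = FALSE)
  if (n_doses > 1 && (!is.finite(interval) || interval <= 0))
    stop("interval must be > 0 when n_doses > 1", call. = FALSE)
  r <- list(dose_per_kg = dose_per_kg, interval = interval,
            n_doses = as.integer(n_doses), start_time = start_time,
            route = "IM")
  class(r) <- "ceq_regimen"
  r
}

#' @export
print.ceq_regimen <- function(x, ...) {
  cat(sprintf("IM regimen: %g mg/kg x %d dose(s)%s, first dose at %g h\n",
              x$dose_per_kg, x$n_doses,
              if (x$n_doses > 1) sprintf(" q%gh", x$interval) else "",
              x$start_time))
  invisible(x)
}

#' Dose event times of a regimen
#' @param regimen a [dosing_regimen()] object
#' @return numeric vector of administration times (h)
#' @export
dose_times <- function(regimen) {
  regimen$start_time + regimen$interval * (seq_len(regimen$n_doses) - 1)
}
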