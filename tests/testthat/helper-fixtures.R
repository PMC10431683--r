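# shared fixtures: default parameter sets and small cached simulations
ph0 <- phys_params()
ch0 <- chem_params()
reg_single <- dosing_regimen(2)

# matrix-exponential solution of the core linear system between dose events;
# independent integration route used as the oracle for the ODE solver
expm_solution <- function(phys, chem, dose_mg, times) {
  M <- pbpk_matrix(phys, chem)[1:13, 1:13]
  y0 <- stats::setNames(numeric(13), rownames(M))
  y0["depot_slow"] <- dose_mg * chem$Frac
  y0["depot_fast"] <- dose_mg * (1 - chem$Frac)
  t(vapply(times, function(t)
    as.numeric(Matrix::expm(M * t) %*% y0), numeric(13))) |>
    `colnames<-`(rownames(M))
}

# relative deviation with a scale floor so zero-valued states compare sanely
rel_dev <- function(a, b, floor = 1e-9) {
  abs(a - b) / pmax(abs(b), floor)
}
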