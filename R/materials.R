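# ---------------------------------------------------------------------------
# Constitutive laws.  Myocardium: orthotropic exponential (Fung-type) strain
# energy
#   Psi = mu/2 (exp(alpha Q) - 1) + kappa/2 (log J)^2,
#   Q = b_ff E_ff^2 + b_ss E_ss^2 + b_nn E_nn^2
#       + b_fs (E_fs^2 + E_sf^2) + b_fn (E_fn^2 + E_nf^2) + b_ns (E_ns^2 + E_sn^2)
# with E_ij the Green-Lagrange strain in the fiber frame.  Passive non-
# myocardial tissue (valve plugs, vessels, pericardial layer): Neo-Hookean
#   Psi = mu/2 (tr(C^) - 3) + kappa/2 (J - 1)^2,  C^ = J^(-2/3) C.
# Ablation scar: isotropized b coefficients (diagonal 1, off-diagonal 0.5)
# with mu doubled and alpha five times the myocardial value.
# Units: Pa, mm; density in kg/m^3 (used consistently as ug/mm^3).
# ---------------------------------------------------------------------------

#' Constitutive parameters by tissue type
#'
#' @param tissue one of "myocardium", "scar", "valve_plug", "vessel",
#'   "pericardium_apical", "pericardium_basal"
#' @return named list: `model`, `mu` (Pa), `alpha`, `kappa` (Pa), `rho0`
#'   (kg/m^3), and for the orthotropic model the six `b` coefficients
#'   (ff, ss, nn, fs, fn, ns)
#' @export
material_params <- function(tissue = c("myocardium", "scar", "valve_plug",
                                       "vessel", "pericardium_apical",
                                       "pericardium_basal")) {
  tissue <- match.arg(tissue)
  myo_b <- c(ff = 1, ss = 0.4, nn = 0.3, fs = 0.7, fn = 0.6, ns = 0.2)
  switch(tissue,
    myocardium = list(model = "orthotropic-exponential", mu = 325.56,
                      alpha = 22, kappa = 1e6, rho0 = 1082, b = myo_b),
    scar = scar_material(material_params("myocardium")),
    valve_plug = list(model = "neo-hookean", mu = 1e6, kappa = 1e6, rho0 = 1082),
    vessel = list(model = "neo-hookean", mu = 14.9e3, kappa = 1e6, rho0 = 1082),
    pericardium_apical = list(model = "neo-hookean", mu = 2e3, kappa = 1e6,
                              rho0 = 1082),
    pericardium_basal = list(model = "neo-hookean", mu = 2e3, kappa = 5e4,
                             rho0 = 1082))
}

#' Derive the stiffened isotropic scar material from a base myocardium
#'
#' Scar tissue is modeled as isotropic (no preferred collagen alignment) and
#' stiffer: `mu` is doubled and `alpha` five times higher than in the bulk
#' tissue; the anisotropic scalings become `b_ff = b_ss = b_nn = 1`,
#' `b_fs = b_fn = b_ns = 0.5`.
#'
#' @param base myocardial parameter list
#' @param mu_factor,alpha_factor stiffness multipliers (sensitivity knob)
#' @param isotropic keep the isotropized b coefficients (set `FALSE` to keep
#'   the anisotropic myocardial b, as in the softest sensitivity variant)
#' @return parameter list
#' @export
scar_material <- function(base = material_params("myocardium"),
                          mu_factor = 2, alpha_factor = 5, isotropic = TRUE) {
  out <- base
  out$mu <- base$mu * mu_factor
  out$alpha <- base$alpha * alpha_factor
  if (isotropic)
    out$b <- c(ff = 1, ss = 1, nn = 1, fs = 0.5, fn = 0.5, ns = 0.5)
  out
}

#' Strain energy density
#'
#' @param E Green-Lagrange strain tensor (3x3, in the frame given)
#' @param J determinant of the deformation gradient
#' @param params material parameter list
#' @param frame optional list(f0, s0, n0); identity frame by default (E
#'   already expressed in fiber coordinates)
#' @return energy density in Pa
#' @export
strain_energy <- function(E, J, params, frame = NULL) {
  if (J <= 0) stop("J must be positive")
  if (max(abs(E - t(E))) > 1e-12) stop("E must be symmetric")
  if (!is.null(frame)) {
    Qm <- cbind(frame$f0, frame$s0, frame$n0)
    E <- t(Qm) %*% E %*% Qm
  }
  if (params$model == "neo-hookean") {
    C <- 2 * E + diag(3)
    return(params$mu / 2 * (J^(-2 / 3) * sum(diag(C)) - 3) +
             params$kappa / 2 * (J - 1)^2)
  }
  b <- params$b
  Q <- b["ff"] * E[1, 1]^2 + b["ss"] * E[2, 2]^2 + b["nn"] * E[3, 3]^2 +
    b["fs"] * (E[1, 2]^2 + E[2, 1]^2) + b["fn"] * (E[1, 3]^2 + E[3, 1]^2) +
    b["ns"] * (E[2, 3]^2 + E[3, 2]^2)
  unname(params$mu / 2 * (exp(params$alpha * Q) - 1) +
           params$kappa / 2 * log(J)^2)
}

#' Passive second Piola-Kirchhoff stress (analytic)
#'
#' Analytic derivative of the strain energy with respect to the
#' Green-Lagrange strain, `S_pas = dPsi/dE`.
#'
#' @param F deformation gradient (3x3)
#' @param frame list(f0, s0, n0) unit vectors (ignored by the isotropic
#'   Neo-Hookean model)
#' @param params material parameter list
#' @return 3x3 symmetric stress tensor (Pa)
#' @export
pk2_stress <- function(F, frame, params) {
  J <- det(F)
  if (J <= 0) stop("J must be positive")
  C <- t(F) %*% F
  Ci <- solve(C)
  if (params$model == "neo-hookean") {
    return(params$mu * J^(-2 / 3) * (diag(3) - sum(diag(C)) / 3 * Ci) +
             params$kappa * (J - 1) * J * Ci)
  }
  E <- (C - diag(3)) / 2
  f <- frame$f0; s <- frame$s0; n <- frame$n0
  Eff <- drop(f %*% E %*% f); Ess <- drop(s %*% E %*% s)
  Enn <- drop(n %*% E %*% n)
  Efs <- drop(f %*% E %*% s); Efn <- drop(f %*% E %*% n)
  Ens <- drop(s %*% E %*% n)
  b <- params$b
  Q <- b[["ff"]] * Eff^2 + b[["ss"]] * Ess^2 + b[["nn"]] * Enn^2 +
    2 * b[["fs"]] * Efs^2 + 2 * b[["fn"]] * Efn^2 + 2 * b[["ns"]] * Ens^2
  coef <- params$mu * params$alpha * exp(params$alpha * Q)
  dQdE2 <- b[["ff"]] * Eff * (f %o% f) + b[["ss"]] * Ess * (s %o% s) +
    b[["nn"]] * Enn * (n %o% n) +
    b[["fs"]] * Efs * (f %o% s + s %o% f) +
    b[["fn"]] * Efn * (f %o% n + n %o% f) +
    b[["ns"]] * Ens * (s %o% n + n %o% s)
  coef * dQdE2 + params$kappa * log(J) * Ci
}
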