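# ---------------------------------------------------------------------------
# Courtemanche-Ramirez-Nattel human atrial ionic model (21 state variables).
# Units: mV, ms, mM; currents in pA/pF (= uA/uF).  All rate functions are
# vectorized over nodes so the same code serves single-cell integration and
# the tissue reaction step.
# ---------------------------------------------------------------------------

cm_constants <- function() {
  list(R = 8.3143, Temp = 310, Fd = 96.4867, Cm = 100,
       Vi = 13668, Vup = 1109.52, Vrel = 96.48,
       Ko = 5.4, Nao = 140, Cao = 1.8,
       gNa = 7.8, gK1 = 0.09, gto = 0.1652, gKr = 0.029411765,
       gKs = 0.12941176, gCaL = 0.12375, gbCa = 0.001131,
       gbNa = 0.0006744375,
       INaK_max = 0.59933874, INaCa_max = 1600, IpCa_max = 0.275,
       Iup_max = 0.005, Kq10 = 3, gam = 0.35,
       KmNai = 10, KmKo = 1.5, KmNa = 87.5, KmCa = 1.38, ksat = 0.1,
       krel = 30, kup = 0.00092, Caup_max = 15, tau_tr = 180, tau_fca = 2,
       tau_u = 8, Cmdn_max = 0.05, Trpn_max = 0.07, Csqn_max = 10,
       KmCmdn = 0.00238, KmTrpn = 0.0005, KmCsqn = 0.8)
}

cm_state_names <- function() {
  c("V", "m", "h", "j", "oa", "oi", "ua", "ui", "xr", "xs",
    "d", "f", "fca", "u", "v", "w", "Nai", "Ki", "Cai", "Caup", "Carel")
}

#' Published resting state of the atrial ionic model
#'
#' Initial values from the original publication (quiescent steady state).
#'
#' @return named numeric vector of the 21 state variables
#' @export
courtemanche_init <- function() {
  setNames(c(-81.18, 2.908e-3, 0.9649, 0.9775, 3.043e-2, 0.9992,
             4.966e-3, 0.9986, 3.296e-5, 1.869e-2, 1.367e-4, 0.9996,
             0.7755, 0, 1, 0.9992, 11.17, 139.0, 1.013e-4, 1.488, 1.488),
           cm_state_names())
}

# guarded x/(1-exp(-x))-type terms at removable singularities
.safe_div <- function(num, den, lim) ifelse(abs(den) < 1e-10, lim, num / den)

cm_gate_coeffs <- function(V, Cai, Fn, cst = cm_constants()) {
  am <- .safe_div(0.32 * (V + 47.13), 1 - exp(-0.1 * (V + 47.13)), 3.2)
  bm <- 0.08 * exp(-V / 11)
  low <- V < -40
  ah <- ifelse(low, 0.135 * exp((V + 80) / -6.8), 0)
  bh <- ifelse(low, 3.56 * exp(0.079 * V) + 3.1e5 * exp(0.35 * V),
               1 / (0.13 * (1 + exp((V + 10.66) / -11.1))))
  aj <- ifelse(low,
               (-1.2714e5 * exp(0.2444 * V) - 3.474e-5 * exp(-0.04391 * V)) *
                 (V + 37.78) / (1 + exp(0.311 * (V + 79.23))), 0)
  bj <- ifelse(low,
               0.1212 * exp(-0.01052 * V) / (1 + exp(-0.1378 * (V + 40.14))),
               0.3 * exp(-2.535e-7 * V) / (1 + exp(-0.1 * (V + 32))))
  aoa <- 0.65 / (exp(-(V + 10) / 8.5) + exp(-(V - 30) / 59))
  boa <- 0.65 / (2.5 + exp((V + 82) / 17))
  aoi <- 1 / (18.53 + exp((V + 113.7) / 10.95))
  boi <- 1 / (35.56 + exp(-(V + 1.26) / 7.44))
  aui <- 1 / (21 + exp(-(V - 185) / 28))
  bui <- exp((V - 158) / 16)
  axr <- .safe_div(0.0003 * (V + 14.1), 1 - exp(-(V + 14.1) / 5), 0.0015)
  bxr <- .safe_div(7.3898e-5 * (V - 3.3328), exp((V - 3.3328) / 5.1237) - 1,
                   7.3898e-5 * 5.1237)
  axs <- .safe_div(4e-5 * (V - 19.9), 1 - exp(-(V - 19.9) / 17), 4e-5 * 17)
  bxs <- .safe_div(3.5e-5 * (V - 19.9), exp((V - 19.9) / 9) - 1, 3.5e-5 * 9)
  ed <- exp(-(V + 10) / 6.24)
  tau_d <- .safe_div((1 - ed), 0.035 * (V + 10) * (1 + ed),
                     1 / (2 * 0.035 * 6.24))
  tau_f <- 9 / (0.0197 * exp(-(0.0337^2) * (V + 10)^2) + 0.02)
  ew <- exp(-(V - 7.9) / 5)
  tau_w <- .safe_div(6 * (1 - ew), (1 + 0.3 * ew) * (V - 7.9), 6 * 0.2 / 1.3)
  K <- cst$Kq10
  sig <- 13.67e-16
  list(
    inf = cbind(
      m = am / (am + bm), h = ah / (ah + bh), j = aj / (aj + bj),
      oa = 1 / (1 + exp(-(V + 20.47) / 17.54)),
      oi = 1 / (1 + exp((V + 43.1) / 5.3)),
      ua = 1 / (1 + exp(-(V + 30.3) / 9.6)),
      ui = 1 / (1 + exp((V - 99.45) / 27.48)),
      xr = 1 / (1 + exp(-(V + 14.1) / 6.5)),
      xs = 1 / sqrt(1 + exp(-(V - 19.9) / 12.7)),
      d = 1 / (1 + exp(-(V + 10) / 8)),
      f = 1 / (1 + exp((V + 28) / 6.9)),
      fca = 1 / (1 + Cai / 0.00035),
      u = 1 / (1 + exp(-(Fn - 3.4175e-13) / sig)),
      v = 1 - 1 / (1 + exp(-(Fn - 6.835e-14) / sig)),
      w = 1 - 1 / (1 + exp(-(V - 40) / 17))),
    tau = cbind(
      m = 1 / (am + bm), h = 1 / (ah + bh), j = 1 / (aj + bj),
      oa = 1 / ((aoa + boa) * K), oi = 1 / ((aoi + boi) * K),
      ua = 1 / ((aoa + boa) * K), ui = 1 / ((aui + bui) * K),
      xr = 1 / (axr + bxr), xs = 0.5 / (axs + bxs),
      d = tau_d, f = tau_f, fca = rep(cst$tau_fca, length(V)),
      u = rep(cst$tau_u, length(V)),
      v = 1.91 + 2.09 / (1 + exp(-(Fn - 3.4175e-13) / sig)),
      w = tau_w))
}

cm_currents <- function(S, cst = cm_constants()) {
  V <- S[, "V"]; Nai <- S[, "Nai"]; Ki <- S[, "Ki"]; Cai <- S[, "Cai"]
  RTF <- cst$R * cst$Temp / cst$Fd
  ENa <- RTF * log(cst$Nao / Nai)
  EK <- RTF * log(cst$Ko / Ki)
  ECa <- RTF / 2 * log(cst$Cao / Cai)
  gKur <- 0.005 + 0.05 / (1 + exp(-(V - 15) / 13))
  fNaK <- 1 / (1 + 0.1245 * exp(-0.1 * V / RTF) +
                 0.0365 * ((exp(cst$Nao / 67.3) - 1) / 7) * exp(-V / RTF))
  expg <- exp(cst$gam * V / RTF)
  expg1 <- exp((cst$gam - 1) * V / RTF)
  list(
    INa = cst$gNa * S[, "m"]^3 * S[, "h"] * S[, "j"] * (V - ENa),
    IK1 = cst$gK1 * (V - EK) / (1 + exp(0.07 * (V + 80))),
    Ito = cst$gto * S[, "oa"]^3 * S[, "oi"] * (V - EK),
    IKur = gKur * S[, "ua"]^3 * S[, "ui"] * (V - EK),
    IKr = cst$gKr * S[, "xr"] * (V - EK) / (1 + exp((V + 15) / 22.4)),
    IKs = cst$gKs * S[, "xs"]^2 * (V - EK),
    ICaL = cst$gCaL * S[, "d"] * S[, "f"] * S[, "fca"] * (V - 65),
    IpCa = cst$IpCa_max * Cai / (0.0005 + Cai),
    INaK = cst$INaK_max * fNaK / (1 + (cst$KmNai / Nai)^1.5) *
      cst$Ko / (cst$Ko + cst$KmKo),
    INaCa = cst$INaCa_max *
      (expg * Nai^3 * cst$Cao - expg1 * cst$Nao^3 * Cai) /
      ((cst$KmNa^3 + cst$Nao^3) * (cst$KmCa + cst$Cao) *
         (1 + cst$ksat * expg1)),
    IbNa = cst$gbNa * (V - ENa),
    IbCa = cst$gbCa * (V - ECa))
}

#' Time derivatives of the atrial ionic model
#'
#' @param state named vector, or matrix with one row per node and the 21
#'   state variables as columns
#' @param I_ext external stimulus current (uA/uF), positive depolarizing
#' @return list with `dstate` (same shape as `state`) and `I_ion`, the total
#'   ionic current (uA/uF)
#' @export
courtemanche_rhs <- function(state, I_ext = 0) {
  vec <- is.null(dim(state))
  S <- if (vec) matrix(state, 1, dimnames = list(NULL, names(state))) else state
  if (any(!is.finite(S))) stop("non-finite cell state")
  cst <- cm_constants()
  cur <- cm_currents(S, cst)
  V <- S[, "V"]; Cai <- S[, "Cai"]
  Irel <- cst$krel * S[, "u"]^2 * S[, "v"] * S[, "w"] *
    (S[, "Carel"] - Cai)
  Itr <- (S[, "Caup"] - S[, "Carel"]) / cst$tau_tr
  Iup <- cst$Iup_max / (1 + cst$kup / Cai)
  Iupleak <- S[, "Caup"] * cst$Iup_max / cst$Caup_max
  Fn <- 1e3 * (1e-15 * cst$Vrel * Irel -
    1e-15 / (2 * cst$Fd) * (0.5 * cur$ICaL * cst$Cm - 0.4 * cur$INaCa * cst$Cm))
  gc <- cm_gate_coeffs(V, Cai, Fn, cst)
  I_ion <- cur$INa + cur$IK1 + cur$Ito + cur$IKur + cur$IKr + cur$IKs +
    cur$ICaL + cur$IpCa + cur$INaK + cur$INaCa + cur$IbNa + cur$IbCa
  FVi <- cst$Fd * cst$Vi
  dNai <- cst$Cm * (-3 * cur$INaK - 3 * cur$INaCa - cur$IbNa - cur$INa) / FVi
  dKi <- cst$Cm * (2 * cur$INaK - cur$IK1 - cur$Ito - cur$IKur -
                     cur$IKr - cur$IKs) / FVi
  B1 <- cst$Cm * (2 * cur$INaCa - cur$IpCa - cur$ICaL - cur$IbCa) /
    (2 * FVi) + (cst$Vup * (Iupleak - Iup) + Irel * cst$Vrel) / cst$Vi
  B2 <- 1 + cst$Trpn_max * cst$KmTrpn / (Cai + cst$KmTrpn)^2 +
    cst$Cmdn_max * cst$KmCmdn / (Cai + cst$KmCmdn)^2
  dCaup <- Iup - Iupleak - Itr * cst$Vrel / cst$Vup
  dCarel <- (Itr - Irel) /
    (1 + cst$Csqn_max * cst$KmCsqn / (S[, "Carel"] + cst$KmCsqn)^2)
  gn <- colnames(gc$inf)
  dG <- (gc$inf - S[, gn, drop = FALSE]) / gc$tau
  d <- cbind(V = -I_ion + I_ext, dG, Nai = dNai, Ki = dKi,
             Cai = B1 / B2, Caup = dCaup, Carel = dCarel)
  d <- d[, cm_state_names(), drop = FALSE]
  list(dstate = if (vec) setNames(drop(d), cm_state_names()) else d,
       I_ion = if (vec) unname(I_ion) else I_ion)
}

# One hybrid step for tissue simulation: exponential (Rush-Larsen) update of
# the gates, forward Euler for concentrations; returns the updated non-voltage
# state and the ionic current to use in the voltage reaction step.
courtemanche_step <- function(S, dt, cst = cm_constants()) {
  cur <- cm_currents(S, cst)
  V <- S[, "V"]; Cai <- S[, "Cai"]
  Irel <- cst$krel * S[, "u"]^2 * S[, "v"] * S[, "w"] * (S[, "Carel"] - Cai)
  Itr <- (S[, "Caup"] - S[, "Carel"]) / cst$tau_tr
  Iup <- cst$Iup_max / (1 + cst$kup / Cai)
  Iupleak <- S[, "Caup"] * cst$Iup_max / cst$Caup_max
  Fn <- 1e3 * (1e-15 * cst$Vrel * Irel -
    1e-15 / (2 * cst$Fd) * (0.5 * cur$ICaL * cst$Cm - 0.4 * cur$INaCa * cst$Cm))
  gc <- cm_gate_coeffs(V, Cai, Fn, cst)
  gn <- colnames(gc$inf)
  S[, gn] <- gc$inf + (S[, gn, drop = FALSE] - gc$inf) * exp(-dt / gc$tau)
  I_ion <- cur$INa + cur$IK1 + cur$Ito + cur$IKur + cur$IKr + cur$IKs +
    cur$ICaL + cur$IpCa + cur$INaK + cur$INaCa + cur$IbNa + cur$IbCa
  FVi <- cst$Fd * cst$Vi
  S[, "Nai"] <- S[, "Nai"] +
    dt * cst$Cm * (-3 * cur$INaK - 3 * cur$INaCa - cur$IbNa - cur$INa) / FVi
  S[, "Ki"] <- S[, "Ki"] + dt * cst$Cm *
    (2 * cur$INaK - cur$IK1 - cur$Ito - cur$IKur - cur$IKr - cur$IKs) / FVi
  B1 <- cst$Cm * (2 * cur$INaCa - cur$IpCa - cur$ICaL - cur$IbCa) /
    (2 * FVi) + (cst$Vup * (Iupleak - Iup) + Irel * cst$Vrel) / cst$Vi
  B2 <- 1 + cst$Trpn_max * cst$KmTrpn / (Cai + cst$KmTrpn)^2 +
    cst$Cmdn_max * cst$KmCmdn / (Cai + cst$KmCmdn)^2
  S[, "Cai"] <- Cai + dt * B1 / B2
  S[, "Caup"] <- S[, "Caup"] + dt * (Iup - Iupleak - Itr * cst$Vrel / cst$Vup)
  S[, "Carel"] <- S[, "Carel"] + dt * (Itr - Irel) /
    (1 + cst$Csqn_max * cst$KmCsqn / (S[, "Carel"] + cst$KmCsqn)^2)
  list(S = S, I_ion = I_ion)
}

#' Save / restore a cell state snapshot as JSON
#'
#' Named-variable JSON snapshots make tissue initializations reproducible.
#'
#' @param state named numeric vector
#' @param path file path
#' @export
cell_state_save <- function(state, path) {
  jsonlite::write_json(as.list(state), path, auto_unbox = TRUE, digits = NA)
}

#' @rdname cell_state_save
#' @export
cell_state_load <- function(path) {
  unlist(jsonlite::read_json(path, simplifyVector = TRUE))
}
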