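# ---------------------------------------------------------------------------
# Phenomenological active tension transient and the active second
# Piola-Kirchhoff stress.  The transient is
#   S_A = S_peak * phi(lambda) * tanh^2(t_s/tau_c) * tanh^2((t_dur-t_s)/tau_r)
# for 0 < t_s < t_dur (zero otherwise), with
#   phi(lambda) = max(tanh(ld*(lambda - lambda0)), 0),
#   tau_c = tau_c0 + ld_up*(1 - phi(lambda)),
#   t_s = t - t_A(x) - t_emd.
# Tension development is triggered by the local activation time t_A; tissue
# that never reaches the activation threshold (scar, isolated regions)
# develops no tension.
# ---------------------------------------------------------------------------

#' Active tension parameters
#'
#' Region defaults are implementation choices in the spirit of the source
#' transient model: the atrial twitch is substantially shorter than the
#' ventricular one, calibrated so that atrial and ventricular tension
#' development do not overlap in time under the default activation timing
#' (atrial stimulus at 0, ventricles 160 ms later).
#'
#' @param region "ventricle", "atrium" or "scar"
#' @return named list: `S_peak` (kPa), `t_dur`, `tau_c0`, `tau_r`, `ld_up`,
#'   `t_emd` (ms), `ld`, `lambda0` (dimensionless)
#' @export
tension_params <- function(region = c("ventricle", "atrium", "scar")) {
  region <- match.arg(region)
  base <- list(S_peak = 120, t_dur = 350, tau_c0 = 60, tau_r = 50,
               ld = 5, ld_up = 500, lambda0 = 0.7, t_emd = 20)
  if (region == "atrium") {
    base$S_peak <- 60; base$t_dur <- 120; base$tau_c0 <- 30; base$tau_r <- 30
  }
  if (region == "scar") base$S_peak <- 0
  base
}

#' Active tension transient
#'
#' @param t current time (ms)
#' @param t_A local activation time (ms); `NA` (never activated) gives zero
#'   tension
#' @param lambda fiber stretch ratio
#' @param params parameter list from [tension_params()]
#' @return S_A in kPa (same shape as the broadcast arguments)
#' @export
tension <- function(t, t_A, lambda, params = tension_params("ventricle")) {
  if (any(!is.finite(t)) || any(!is.finite(lambda)))
    stop("non-finite inputs to the tension transient")
  phi <- pmax(tanh(params$ld * (lambda - params$lambda0)), 0)
  tau_c <- params$tau_c0 + params$ld_up * (1 - phi)
  ts <- t - t_A - params$t_emd
  on <- !is.na(ts) & ts > 0 & ts < params$t_dur
  ts[!on | is.na(ts)] <- 0
  out <- params$S_peak * phi * tanh(ts / tau_c)^2 *
    tanh((params$t_dur - ts) / params$tau_r)^2
  out[!on] <- 0
  out
}

#' Active second Piola-Kirchhoff stress
#'
#' `S_act = S_A * sum_k n_k (k0 x k0) / lambda_k` with
#' `lambda_k = |F k0|`.  The default orthotropic weights activate the fiber
#' direction only (`n_f = 1`, `n_s = n_n = 0`).
#'
#' @param F deformation gradient (3x3)
#' @param S_A scalar active tension (kPa)
#' @param frame list with unit vectors `f0`, `s0`, `n0`
#' @param weights activation weights `c(n_f, n_s, n_n)`
#' @return 3x3 stress tensor (kPa)
#' @export
active_stress <- function(F, S_A, frame, weights = c(1, 0, 0)) {
  if (det(F) <= 0) stop("deformation gradient must have positive determinant")
  if (any(weights < 0)) stop("activation weights must be nonnegative")
  S <- matrix(0, 3, 3)
  dirs <- list(frame$f0, frame$s0, frame$n0)
  for (k in 1:3) {
    if (weights[k] == 0) next
    k0 <- dirs[[k]]
    lam <- sqrt(sum((F %*% k0)^2))
    if (lam == 0) stop("zero stretch along an activation direction")
    S <- S + S_A * weights[k] * (k0 %o% k0) / lam
  }
  S
}
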