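# ---------------------------------------------------------------------------
# Reduced ventricular surrogate: a two-variable excitable model
# (Mitchell-Schaeffer form) mapped to physical voltage, parameterized for a
# ventricular-like action-potential duration (~250-300 ms at 1.2 s pacing).
# It stands in for a full human ventricular ionic model, which is outside the
# scope of this desk-scale pipeline.
# ---------------------------------------------------------------------------

#' Parameters of the ventricular surrogate model
#'
#' `tau_in`/`tau_out` control the upstroke and repolarization speed,
#' `tau_open`/`tau_close` the recovery gate (and thereby the action-potential
#' duration and its restitution), `v_gate` the dimensionless threshold.
#' `V_rest` and `V_amp` map the dimensionless voltage to mV.
#'
#' @return named list of parameters
#' @export
surrogate_params <- function() {
  list(tau_in = 0.3, tau_out = 6, tau_open = 120, tau_close = 158,
       v_gate = 0.13, V_rest = -84, V_amp = 100.8)
}

#' @rdname surrogate_params
#' @export
surrogate_init <- function() c(V = surrogate_params()$V_rest, hgate = 1)

#' Time derivatives of the ventricular surrogate
#'
#' @param state named vector `c(V, hgate)` or a matrix (nodes x 2)
#' @param I_ext stimulus current (uA/uF), positive depolarizing
#' @param p parameter list from [surrogate_params()]
#' @return list with `dstate` and `I_ion` (sign convention as the atrial
#'   model: `dV = -I_ion + I_ext`)
#' @export
ventricular_surrogate_rhs <- function(state, I_ext = 0, p = surrogate_params()) {
  vec <- is.null(dim(state))
  S <- if (vec) matrix(state, 1, dimnames = list(NULL, names(state))) else state
  if (any(!is.finite(S))) stop("non-finite cell state")
  v <- (S[, "V"] - p$V_rest) / p$V_amp
  h <- S[, "hgate"]
  I_ion <- -p$V_amp * (h * v^2 * (1 - v) / p$tau_in - v / p$tau_out)
  dh <- ifelse(v < p$v_gate, (1 - h) / p$tau_open, -h / p$tau_close)
  d <- cbind(V = -I_ion + I_ext, hgate = dh)
  list(dstate = if (vec) setNames(drop(d), c("V", "hgate")) else d,
       I_ion = if (vec) unname(I_ion) else I_ion)
}

surrogate_step <- function(S, dt, p = surrogate_params()) {
  v <- (S[, "V"] - p$V_rest) / p$V_amp
  h <- S[, "hgate"]
  I_ion <- -p$V_amp * (h * v^2 * (1 - v) / p$tau_in - v / p$tau_out)
  # exponential gate update toward its piecewise target
  hinf <- ifelse(v < p$v_gate, 1, 0)
  htau <- ifelse(v < p$v_gate, p$tau_open, p$tau_close)
  S[, "hgate"] <- hinf + (h - hinf) * exp(-dt / htau)
  list(S = S, I_ion = I_ion)
}

cell_model <- function(name = c("courtemanche", "surrogate")) {
  name <- match.arg(name)
  if (name == "courtemanche") {
    list(name = name, init = courtemanche_init(), rhs = courtemanche_rhs,
         step = function(S, dt) courtemanche_step(S, dt))
  } else {
    list(name = name, init = surrogate_init(), rhs = ventricular_surrogate_rhs,
         step = function(S, dt) surrogate_step(S, dt))
  }
}
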