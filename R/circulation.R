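# ---------------------------------------------------------------------------
# 0D closed-loop circulation: four heart chambers (time-varying elastance)
# plus systemic/pulmonary arterial and venous RC compartments, smooth
# diode-resistance valves, a stroke-volume-difference state for the
# automated limit-cycle stopping criterion, and the scalar 3D-0D
# volume-consistency coupling.
# Units here: mL, s, mmHg (the 0D community convention).  Parameter values
# are implementation defaults for a resting adult, not reproductions of any
# subject-specific calibration.
# ---------------------------------------------------------------------------

#' Default circulation parameters
#'
#' @return nested list: compartment elastances `E` (mmHg/mL) and unstressed
#'   volumes `V0` (mL), resistances `R` (mmHg s/mL), chamber elastance
#'   parameters, activation timing (s), total blood volume (mL), and the
#'   coupling spec (tolerance 1e-7 mL, stopping threshold 1 mL, cycle
#'   length 1.2 s)
#' @export
circ_params <- function() {
  list(
    E = c(SysArt = 0.8, SysVen = 0.0125, PulArt = 0.25, PulVen = 0.05),
    V0 = c(SysArt = 600, SysVen = 2900, PulArt = 100, PulVen = 350),
    R = c(sys = 0.9, pul = 0.07, ven_sys = 0.03, ven_pul = 0.03,
          mitral = 0.004, aortic = 0.006, tricuspid = 0.004,
          pulmonary = 0.006),
    chambers = list(
      LV = list(Emin = 0.08, Emax = 2.5, V0 = 10),
      RV = list(Emin = 0.045, Emax = 0.6, V0 = 15),
      LA = list(Emin = 0.14, Eact = 0.22, V0 = 6),
      RA = list(Emin = 0.11, Eact = 0.15, V0 = 6)),
    timing = list(cycle_length = 1.2, t_atrial = 0, t_ventricular = 0.16),
    blood_volume = 5300,
    valve_width = 0.3,    # mmHg scale of the smooth valve opening
    coupling = coupling_spec()
  )
}

#' 3D-0D coupling specification
#'
#' @param eps volume-consistency tolerance (mL)
#' @param max_iter maximal coupling sub-iterations
#' @param threshold stopping-criterion threshold on the per-cycle stroke
#'   volume difference (mL)
#' @param cycle_length cycle length (s)
#' @return a `coupling_spec`
#' @export
coupling_spec <- function(eps = 1e-7, max_iter = 60, threshold = 1,
                          cycle_length = 1.2) {
  if (eps <= 0) stop("coupling tolerance must be positive")
  structure(list(eps = eps, max_iter = max_iter, threshold = threshold,
                 cycle_length = cycle_length), class = "coupling_spec")
}

# normalized activation shapes built on the active-tension transient at
# constant unit stretch-sensitivity (phi = 1)
activation_shape <- function(t_ms, t_dur, tau_c, tau_r) {
  s <- ifelse(t_ms > 0 & t_ms < t_dur,
              tanh(t_ms / tau_c)^2 * tanh((t_dur - t_ms) / tau_r)^2, 0)
  peak <- tanh(t_dur / 2 / tau_c)^2 * tanh(t_dur / 2 / tau_r)^2
  s / peak
}

# chamber elastances over one cycle; la_drive overrides the atrial shape
# with an EP-derived drive (function of time in s, in [0, 1])
chamber_elastance <- function(pars, chamber, t, la_drive = NULL,
                              la_pas_factor = 1) {
  tim <- pars$timing
  tc <- t %% tim$cycle_length
  ch <- pars$chambers[[chamber]]
  if (chamber %in% c("LV", "RV")) {
    tp <- tension_params("ventricle")
    a <- activation_shape((tc - tim$t_ventricular) * 1000,
                          tp$t_dur, tp$tau_c0, tp$tau_r)
    ch$Emin + (ch$Emax - ch$Emin) * a
  } else if (chamber == "LA" && !is.null(la_drive)) {
    ch$Emin * la_pas_factor + ch$Eact * la_drive(tc)
  } else {
    tp <- tension_params("atrium")
    a <- activation_shape((tc - tim$t_atrial) * 1000,
                          tp$t_dur, tp$tau_c0, tp$tau_r)
    pf <- if (chamber == "LA") la_pas_factor else 1
    ch$Emin * pf + ch$Eact * a
  }
}

smooth_valve <- function(dp, width) 1 / (1 + exp(-dp / width))

circ_state_names <- function() {
  c("V_LA", "V_LV", "V_RA", "V_RV", "V_SysArt", "V_SysVen",
    "V_PulArt", "V_PulVen", "SV_diff")
}

circ_pressures <- function(y, pars, t, la_drive = NULL, la_pas_factor = 1) {
  ch <- pars$chambers
  c(p_LA = unname(chamber_elastance(pars, "LA", t, la_drive, la_pas_factor) *
                    (y[["V_LA"]] - ch$LA$V0)),
    p_LV = unname(chamber_elastance(pars, "LV", t) * (y[["V_LV"]] - ch$LV$V0)),
    p_RA = unname(chamber_elastance(pars, "RA", t) * (y[["V_RA"]] - ch$RA$V0)),
    p_RV = unname(chamber_elastance(pars, "RV", t) * (y[["V_RV"]] - ch$RV$V0)),
    p_SysArt = unname(pars$E[["SysArt"]] * (y[["V_SysArt"]] - pars$V0[["SysArt"]])),
    p_SysVen = unname(pars$E[["SysVen"]] * (y[["V_SysVen"]] - pars$V0[["SysVen"]])),
    p_PulArt = unname(pars$E[["PulArt"]] * (y[["V_PulArt"]] - pars$V0[["PulArt"]])),
    p_PulVen = unname(pars$E[["PulVen"]] * (y[["V_PulVen"]] - pars$V0[["PulVen"]])))
}

circ_flows <- function(p, pars) {
  R <- pars$R; w <- pars$valve_width
  c(Q_mitral = unname(smooth_valve(p[["p_LA"]] - p[["p_LV"]], w) *
      (p[["p_LA"]] - p[["p_LV"]]) / R[["mitral"]]),
    Q_SysArt = unname(smooth_valve(p[["p_LV"]] - p[["p_SysArt"]], w) *
      (p[["p_LV"]] - p[["p_SysArt"]]) / R[["aortic"]]),
    Q_sys = unname((p[["p_SysArt"]] - p[["p_SysVen"]]) / R[["sys"]]),
    Q_ven_sys = unname((p[["p_SysVen"]] - p[["p_RA"]]) / R[["ven_sys"]]),
    Q_tricuspid = unname(smooth_valve(p[["p_RA"]] - p[["p_RV"]], w) *
      (p[["p_RA"]] - p[["p_RV"]]) / R[["tricuspid"]]),
    Q_PulArt = unname(smooth_valve(p[["p_RV"]] - p[["p_PulArt"]], w) *
      (p[["p_RV"]] - p[["p_PulArt"]]) / R[["pulmonary"]]),
    Q_pul = unname((p[["p_PulArt"]] - p[["p_PulVen"]]) / R[["pul"]]),
    Q_ven_pul = unname((p[["p_PulVen"]] - p[["p_LA"]]) / R[["ven_pul"]]))
}

#' Time derivatives of the 0D circulation
#'
#' Volume-state formulation: chamber/compartment volumes advance by the
#' inter-compartment flows, so total blood volume is conserved identically;
#' pressures follow from the (time-varying) elastances.  The last state is
#' the stroke-volume-difference integrator
#' `d(SV_diff)/dt = Q_SysArt - Q_PulArt`.
#'
#' @param t time (s)
#' @param y named state vector (see `circ_state_names()`)
#' @param pars parameter list from [circ_params()]
#' @param la_drive optional EP-derived atrial drive function
#' @param la_pas_factor passive LA stiffening factor (scarred atria)
#' @return list(dy) in deSolve convention, with pressures and flows as
#'   attributes
#' @export
circulation_rhs <- function(t, y, pars, la_drive = NULL, la_pas_factor = 1) {
  if (any(y[seq_len(8)] < -1e-9)) stop("negative compartment volume")
  p <- circ_pressures(y, pars, t, la_drive, la_pas_factor)
  q <- circ_flows(p, pars)
  dy <- c(
    V_LA = q[["Q_ven_pul"]] - q[["Q_mitral"]],
    V_LV = q[["Q_mitral"]] - q[["Q_SysArt"]],
    V_RA = q[["Q_ven_sys"]] - q[["Q_tricuspid"]],
    V_RV = q[["Q_tricuspid"]] - q[["Q_PulArt"]],
    V_SysArt = q[["Q_SysArt"]] - q[["Q_sys"]],
    V_SysVen = q[["Q_sys"]] - q[["Q_ven_sys"]],
    V_PulArt = q[["Q_PulArt"]] - q[["Q_pul"]],
    V_PulVen = q[["Q_pul"]] - q[["Q_ven_pul"]],
    SV_diff = q[["Q_SysArt"]] - q[["Q_PulArt"]])
  list(dy, p = p, q = q)
}

circ_init_state <- function(pars) {
  # distribute the blood volume with plausible initial loading
  y <- c(V_LA = 50, V_LV = 120, V_RA = 50, V_RV = 120,
         V_SysArt = 720, V_PulArt = 160, V_PulVen = 500)
  y <- c(y, V_SysVen = pars$blood_volume - sum(y))
  y <- y[c("V_LA", "V_LV", "V_RA", "V_RV", "V_SysArt", "V_SysVen",
           "V_PulArt", "V_PulVen")]
  c(y, SV_diff = 0)
}

#' Simulate the closed loop to its limit cycle
#'
#' Integrates cycle by cycle; at each integer multiple of the cycle length
#' the accumulated |SV_diff| is compared to the stopping threshold (1 mL)
#' and reset if the criterion is not yet met.
#'
#' @param pars parameters from [circ_params()]
#' @param la_drive optional EP-derived LA activation drive (function of
#'   time within a cycle, seconds)
#' @param la_pas_factor passive LA stiffening factor
#' @param max_cycles maximum number of cycles
#' @param min_cycles minimum number before convergence may be declared
#' @param sample_dt output cadence (s)
#' @param init optional initial state
#' @return a `circ_result`: `traces` (last cycle), `all_traces`, `converged`,
#'   `n_cycles`, `sv_diff_history`
#' @export
simulate_circulation <- function(pars = circ_params(), la_drive = NULL,
                                 la_pas_factor = 1, max_cycles = 40,
                                 min_cycles = 3, sample_dt = 0.005,
                                 init = NULL) {
  cl <- pars$coupling$cycle_length
  y <- if (is.null(init)) circ_init_state(pars) else init
  f <- function(t, y, parms) circulation_rhs(t, y, pars, la_drive,
                                             la_pas_factor)
  svh <- numeric(0)
  traces <- NULL
  converged <- FALSE
  for (cyc in seq_len(max_cycles)) {
    times <- seq(0, cl, by = sample_dt)
    out <- deSolve::ode(y = y, times = times, func = f, parms = NULL,
                        method = "lsoda", rtol = 1e-8, atol = 1e-8)
    y <- setNames(as.numeric(out[nrow(out), 2:10]), circ_state_names())
    sv <- y[["SV_diff"]]
    svh <- c(svh, sv)
    traces <- out
    if (abs(sv) < pars$coupling$threshold && cyc >= min_cycles) {
      converged <- TRUE
      break
    }
    y[["SV_diff"]] <- 0   # criterion not met: reset the accumulator
  }
  tr <- as.data.frame(traces[, 1:10, drop = FALSE])
  press <- t(vapply(seq_len(nrow(tr)), function(i)
    circ_pressures(setNames(as.numeric(tr[i, 2:10]), circ_state_names()),
                   pars, tr$time[i], la_drive, la_pas_factor), numeric(8)))
  flows <- t(vapply(seq_len(nrow(tr)), function(i)
    circ_flows(press[i, ], pars), numeric(8)))
  structure(list(traces = cbind(tr, press, flows), converged = converged,
                 n_cycles = cyc, sv_diff_history = svh, pars = pars),
            class = "circ_result")
}

#' @export
print.circ_result <- function(x, ...) {
  cat("circ_result:", x$n_cycles, "cycles;",
      if (x$converged) "converged" else "NOT converged",
      "(|SV_diff| =", signif(abs(tail(x$sv_diff_history, 1)), 3), "mL)\n")
  tr <- x$traces
  cat("  LA volume range:", round(min(tr$V_LA), 1), "-",
      round(max(tr$V_LA), 1), "mL;  LV:", round(min(tr$V_LV), 1), "-",
      round(max(tr$V_LV), 1), "mL\n")
  invisible(x)
}

#' Stroke-volume-difference stopping criterion
#'
#' Integrates the aortic minus pulmonary flow difference over one cycle and
#' compares the magnitude to the threshold.
#'
#' @param t time samples over one cycle (s)
#' @param Q_SysArt,Q_PulArt flow traces (mL/s)
#' @param threshold convergence threshold (mL)
#' @return list with `SV_diff` (mL, signed) and `converged`
#' @export
stopping_criterion <- function(t, Q_SysArt, Q_PulArt, threshold = 1) {
  dq <- Q_SysArt - Q_PulArt
  sv <- sum((dq[-1] + dq[-length(dq)]) / 2 * diff(t))
  list(SV_diff = sv, converged = abs(sv) < threshold)
}

#' Scalar 3D-0D chamber coupling
#'
#' Finds the chamber pressure at which the 3D (mechanics) and 0D
#' (circulation) chamber volumes agree to within the coupling tolerance:
#' safeguarded secant/bisection with bracket expansion.
#'
#' @param V3d function p (mmHg) -> volume (mL), monotone increasing
#' @param V0d function p (mmHg) -> volume (mL), monotone decreasing in p
#' @param p_init initial pressure guess (mmHg)
#' @param spec a [coupling_spec()]
#' @return list with `p` (mmHg), `residual` (mL), `iters`
#' @export
couple_chamber <- function(V3d, V0d, p_init = 5, spec = coupling_spec()) {
  f <- function(p) V3d(p) - V0d(p)
  lo <- p_init - 1; hi <- p_init + 1
  flo <- f(lo); fhi <- f(hi)
  it <- 0
  while (flo * fhi > 0 && it < 60) {
    if (abs(flo) < abs(fhi)) { lo <- lo - 2^(it / 8); flo <- f(lo) }
    else { hi <- hi + 2^(it / 8); fhi <- f(hi) }
    it <- it + 1
  }
  if (flo * fhi > 0) stop("coupling root not bracketed within pressure bounds")
  if (abs(flo) < spec$eps)
    return(list(p = lo, residual = abs(flo), iters = it))
  if (abs(fhi) < spec$eps)
    return(list(p = hi, residual = abs(fhi), iters = it))
  for (k in seq_len(spec$max_iter)) {
    # secant trial within the bracket, bisection fallback
    pm <- hi - fhi * (hi - lo) / (fhi - flo)
    if (!is.finite(pm) || pm <= lo || pm >= hi) pm <- (lo + hi) / 2
    fm <- f(pm)
    it <- it + 1
    if (abs(fm) < spec$eps)
      return(list(p = pm, residual = abs(fm), iters = it))
    if (flo * fm < 0) { hi <- pm; fhi <- fm } else { lo <- pm; flo <- fm }
  }
  list(p = (lo + hi) / 2, residual = abs(f((lo + hi) / 2)), iters = it)
}
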