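# ---------------------------------------------------------------------------
# Pipeline driver and quantitative analysis: run lesion cases end-to-end
# (geometry -> lesion masks -> monodomain EP -> activation-driven atrial
# elastance + closed-loop circulation to the limit cycle -> biomarkers),
# the lesion-vs-dEF regression, the scar-stiffness sensitivity metric and
# the conduction-velocity-reduction experiment.
# ---------------------------------------------------------------------------

#' Bundled lesion-function table
#'
#' The printed per-case left-atrial function indicators (stroke volume SV in
#' mL, ejection fraction EF in %, EF loss dEF in percentage points vs
#' Control, ablated-tissue fraction AT and inactive-tissue fraction IT in %)
#' for the Control case and the nine studied ablation cases, shipped as a
#' package fixture for the regression analysis.
#'
#' @return data.frame with columns case, SV, EF, dEF, AT, IT
#' @export
ablation_table <- function() {
  path <- system.file("extdata", "table3.csv", package = "ablamech")
  if (path == "") path <- file.path("inst", "extdata", "table3.csv")
  read.csv(path, stringsAsFactors = FALSE)
}

#' Build the geometry fixture once for a set of case runs
#'
#' @param config configuration list (see [default_config()])
#' @return list with `mech` (mechanics mesh) and `ep` (nested EP mesh)
#' @export
build_geometry <- function(config = default_config()) {
  g <- config$geometry
  mech <- make_la_shell(radius = g$radius, wall_thickness = g$wall_thickness,
                        resolution = g$resolution,
                        ostium_radius = g$ostium_radius,
                        annulus_theta = g$annulus_theta)
  ep <- build_ep_mesh(mech, levels = g$ep_levels)
  list(mech = mech, ep = ep)
}

# element-level activation times (ms) on the EP mesh: mean over activated
# nodes; NA if fewer than half the nodes activated
element_activation <- function(sol, mesh) {
  tA <- sol$t_A
  t4 <- mesh$tets
  m <- cbind(tA[t4[, 1]], tA[t4[, 2]], tA[t4[, 3]], tA[t4[, 4]])
  nact <- rowSums(!is.na(m))
  out <- rowMeans(m, na.rm = TRUE)
  out[nact < 2] <- NA
  out[sol$scar_mask] <- NA
  out
}

# EP-derived normalized LA contraction drive: volume-weighted mean of the
# per-element tension transients (unit stretch), as a function of time in
# seconds within the cycle
la_drive_from_activation <- function(elem_tA, vols, tp = tension_params("atrium")) {
  act <- !is.na(elem_tA)
  wtot <- sum(vols)
  peak <- tanh(tp$t_dur / 2 / tp$tau_c0)^2 * tanh(tp$t_dur / 2 / tp$tau_r)^2
  tAa <- elem_tA[act]; va <- vols[act]
  function(t_s) {
    ts <- t_s * 1000 - tAa - tp$t_emd
    on <- ts > 0 & ts < tp$t_dur
    s <- numeric(length(tAa))
    s[on] <- tanh(ts[on] / tp$tau_c0)^2 * tanh((tp$t_dur - ts[on]) / tp$tau_r)^2
    sum(va * s) / (wtot * peak)
  }
}

#' Run one ablation case end-to-end
#'
#' EP solve on the nested mesh, activation map and inactive-tissue fraction,
#' then the closed-loop circulation to its limit cycle with the left-atrial
#' chamber driven by the EP activation pattern (time-varying elastance whose
#' active drive is the volume-weighted tension transient of the activated
#' tissue, and whose passive stiffness increases with the scarred fraction).
#' Deterministic for a fixed seed and configuration.
#'
#' @param case_name one of the ten case names ("Control", "PVI+AL+BL", ...)
#' @param config configuration list
#' @param seed integer seed (the pipeline is deterministic; the seed is
#'   recorded and applied for reproducibility of any stochastic option)
#' @param geometry optional prebuilt geometry from [build_geometry()]
#' @param sigma_scale atrial conductivity scaling (1 = baseline; used by the
#'   conduction-velocity-reduction experiment)
#' @return a `case_result`: biomarker row, EP solution summary, circulation
#'   result
#' @export
run_case <- function(case_name, config = default_config(), seed = 1L,
                     geometry = NULL, sigma_scale = 1) {
  set.seed(as.integer(seed))
  if (is.null(geometry)) geometry <- build_geometry(config)
  ep_mesh <- geometry$ep
  case_name <- normalize_case_name(case_name)
  lesions <- combine_lesions(ep_mesh, case_name, width = config$lesions$width)

  epc <- config$ep
  cond <- conductivity_field(ep_mesh,
                             sigma_f = epc$sigma_f * sigma_scale,
                             sigma_s = epc$sigma_f / epc$anisotropy * sigma_scale,
                             sigma_n = epc$sigma_f / epc$anisotropy * sigma_scale,
                             scar_mask = lesions$ep_mask)
  stim <- la_sinus_protocol(ep_mesh, delays = epc$delays,
                            amplitude = epc$stim_amplitude,
                            duration = epc$stim_duration)
  sol <- solve_monodomain(ep_mesh, cond, stim, duration = epc$duration,
                          dt = epc$dt, cell = epc$cell,
                          sample_dt = epc$sample_dt)
  at <- ablated_fraction(ep_mesh, lesions)
  it <- inactive_fraction(sol, ep_mesh)

  vols <- abs(tet_volumes(ep_mesh))
  elem_tA <- element_activation(sol, ep_mesh)
  drive <- la_drive_from_activation(elem_tA, vols, config$tension$atrium)
  pas_factor <- 1 + config$scar$pas_stiffening * at / 100 *
    sqrt(config$scar$mu_factor * config$scar$alpha_factor / 10)
  circ <- simulate_circulation(config$circulation, la_drive = drive,
                               la_pas_factor = pas_factor,
                               max_cycles = config$limit_cycle$max_cycles,
                               min_cycles = config$limit_cycle$min_cycles)
  bm <- la_biomarkers(circ)
  row <- data.frame(case = case_name, SV = bm$SV, EF = bm$EF, dEF = NA_real_,
                    AT = at, IT = it,
                    peak_LA_pressure = bm$peak_p,
                    LA_emptying_time = bm$t_min,
                    LV_EDV = bm$LV_EDV, LV_ESV = bm$LV_ESV,
                    total_activation_time = sol$total_activation_time)
  structure(list(case = case_name, biomarkers = row, lesions = lesions,
                 ep = sol, circ = circ, seed = seed),
            class = "case_result")
}

la_biomarkers <- function(circ) {
  tr <- circ$traces
  ef <- ef_from_volumes(tr$time, tr$V_LA)
  list(SV = ef$SV, EF = ef$EF, t_min = ef$t_min,
       peak_p = max(tr$p_LA),
       LV_EDV = max(tr$V_LV), LV_ESV = min(tr$V_LV))
}

#' @export
print.case_result <- function(x, ...) {
  cat("case_result:", x$case, "\n")
  print(x$biomarkers, row.names = FALSE)
  invisible(x)
}

#' Stroke volume and ejection fraction from a chamber volume trace
#'
#' `SV = V_max - V(peak systole)` where peak systole is the time of maximal
#' blood output (the volume minimum of the emptying phase);
#' `EF = 100 SV / V_max`.
#'
#' @param t times over one full cycle
#' @param V chamber volume trace (mL)
#' @return list with `SV` (mL), `EF` (%), `V_max`, `t_min` (time of peak
#'   systole)
#' @export
ef_from_volumes <- function(t, V) {
  if (length(t) < 3 || diff(range(t)) <= 0) stop("need one full cycle")
  vmax <- max(V)
  imin <- which.min(V)
  sv <- vmax - V[imin]
  list(SV = sv, EF = if (vmax > 0) 100 * sv / vmax else 0,
       V_max = vmax, t_min = t[imin])
}

#' EF loss versus Control in percentage points
#'
#' @param table biomarker table with columns `case` and `EF`
#' @param case case name
#' @return `EF(Control) - EF(case)` (pp)
#' @export
delta_ef <- function(table, case) {
  ic <- match("Control", table$case)
  if (is.na(ic)) stop("Control row missing")
  i <- match(normalize_case_name(case), table$case)
  if (is.na(i)) stop("case not in table: ", case)
  table$EF[ic] - table$EF[i]
}

#' Run all ten lesion cases and tabulate biomarkers
#'
#' @param config configuration list
#' @param seed integer seed
#' @param cases case names (default: all ten)
#' @return data.frame of biomarker rows with `dEF` filled in vs Control
#' @export
run_all_cases <- function(config = default_config(), seed = 1L,
                          cases = lesion_case_names()) {
  geometry <- build_geometry(config)
  rows <- lapply(cases, function(cs)
    run_case(cs, config, seed = seed, geometry = geometry)$biomarkers)
  tab <- do.call(rbind, rows)
  if ("Control" %in% tab$case)
    tab$dEF <- tab$EF[tab$case == "Control"] - tab$EF
  class(tab) <- c("biomarker_table", class(tab))
  tab
}

#' Ordinary least-squares regression of EF loss on a lesion burden measure
#'
#' @param x ablated- or inactive-tissue fractions (%)
#' @param y EF differences vs Control (pp)
#' @return list with `slope`, `intercept`, `r2`, and the fitted `lm`
#' @export
lesion_regression <- function(x, y) {
  if (length(x) < 3) stop("need at least 3 points")
  if (stats::var(x) == 0) stop("zero variance in x")
  fit <- lm(y ~ x)
  ss_res <- sum(residuals(fit)^2)
  ss_tot <- sum((y - mean(y))^2)
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r2 = 1 - ss_res / ss_tot, fit = fit)
}

#' Normalized sensitivity difference traces
#'
#' `x_diff = (x - x_ref) / (max(x_ref) - min(x_ref))`, the per-time-point
#' difference to a reference trace normalized by the reference peak-to-peak
#' amplitude.
#'
#' @param x variant trace
#' @param x_ref reference trace (same sampling)
#' @return numeric trace of the same length
#' @export
x_diff <- function(x, x_ref) {
  pp <- max(x_ref) - min(x_ref)
  if (pp <= 0) stop("constant reference trace (zero peak-to-peak)")
  (x - x_ref) / pp
}

#' Scar-stiffness sensitivity sweep
#'
#' Reruns the PVI+AL+BL case (by default) with scar-material variants and
#' reports the normalized pressure/volume difference traces of the left
#' atrium against the reference variant (mu doubled, alpha five times).
#'
#' @param variants list of `list(mu_factor=, alpha_factor=, isotropic=)`
#' @param case_name lesion case
#' @param config,seed,geometry as in [run_case()]
#' @return list with per-variant `x_diff` traces for `p_LA` and `V_LA`, the
#'   variant table, and the reference case result
#' @export
sensitivity_sweep <- function(variants = list(
                                soft = list(mu_factor = 1, alpha_factor = 1,
                                            isotropic = FALSE),
                                stiff = list(mu_factor = 4, alpha_factor = 10,
                                             isotropic = TRUE)),
                              case_name = "PVI+AL+BL",
                              config = default_config(), seed = 1L,
                              geometry = NULL) {
  if (is.null(geometry)) geometry <- build_geometry(config)
  ref <- run_case(case_name, config, seed, geometry)
  out <- list()
  for (nm in names(variants)) {
    v <- variants[[nm]]
    cfg <- config
    cfg$scar$mu_factor <- v$mu_factor
    cfg$scar$alpha_factor <- v$alpha_factor
    if (!is.null(v$isotropic)) cfg$scar$isotropic <- v$isotropic
    res <- run_case(case_name, cfg, seed, geometry)
    out[[nm]] <- list(
      p_LA = x_diff(res$circ$traces$p_LA, ref$circ$traces$p_LA),
      V_LA = x_diff(res$circ$traces$V_LA, ref$circ$traces$V_LA),
      time = res$circ$traces$time)
  }
  list(reference = ref, variants = out, spec = variants)
}

#' Conduction-velocity-reduction experiment
#'
#' Reruns a case with the atrial conductivity reduced by the given fraction
#' (a conductivity reduction `r` lowers the conduction velocity by about
#' `1 - sqrt(1 - r)`), and reports the activation delay and the shift of
#' the left-atrial emptying time.
#'
#' @param case_name lesion case
#' @param reduction conductivity reduction fraction (0.25 or 0.5 in the
#'   study conditions; 0 reproduces the baseline)
#' @param config,seed,geometry as in [run_case()]
#' @param baseline optional precomputed baseline `case_result`
#' @return list with both runs, `activation_delay` (ms) and
#'   `emptying_shift` (s)
#' @export
cv_reduction_experiment <- function(case_name, reduction,
                                    config = default_config(), seed = 1L,
                                    geometry = NULL, baseline = NULL) {
  if (reduction < 0 || reduction >= 1) stop("reduction must be in [0, 1)")
  if (is.null(geometry)) geometry <- build_geometry(config)
  if (is.null(baseline)) baseline <- run_case(case_name, config, seed, geometry)
  red <- run_case(case_name, config, seed, geometry,
                  sigma_scale = 1 - reduction)
  list(baseline = baseline, reduced = red,
       activation_delay = red$ep$total_activation_time -
         baseline$ep$total_activation_time,
       emptying_shift = red$biomarkers$LA_emptying_time -
         baseline$biomarkers$LA_emptying_time)
}
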