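# Shared fixtures, built once per test run.  The geometry and the EP control
# run are the expensive pieces; everything downstream reuses them.

.fix <- new.env(parent = emptyenv())

fix_config <- function() {
  cfg <- default_config()
  # desk-scale test settings: the reduced ventricular surrogate resolves
  # activation maps at this mesh resolution with a cheaper reaction term
  cfg$ep$cell <- "surrogate"
  cfg$ep$sigma_f <- 0.8
  cfg
}

fix_geometry <- function() {
  if (is.null(.fix$geo)) .fix$geo <- build_geometry(fix_config())
  .fix$geo
}

fix_case <- function(case_name) {
  key <- paste0("case_", gsub("[^A-Za-z]", "", case_name))
  if (is.null(.fix[[key]]))
    .fix[[key]] <- run_case(case_name, fix_config(), seed = 1,
                            geometry = fix_geometry())
  .fix[[key]]
}

fix_cable_sol <- function(sigma = 0.3, resolution = 0.5, len = 15, dt = 0.02) {
  key <- sprintf("cab_%g_%g_%g_%g", sigma, resolution, len, dt)
  if (is.null(.fix[[key]])) {
    cab <- make_cable(len, resolution)
    cond <- conductivity_field(cab, sigma, sigma / 4, sigma / 4)
    seg <- which(cab$vertices[, 1] <= max(1, 4 * resolution))
    stim <- stimulus_protocol(list(list(vertices = seg, t0 = 0,
                                        duration = 2, amplitude = 80)))
    sol <- solve_monodomain(cab, cond, stim, duration = 120, dt = dt,
                            cell = "surrogate", sample_dt = 0.5)
    .fix[[key]] <- list(mesh = cab, sol = sol)
  }
  .fix[[key]]
}

fix_small_shell <- function() {
  if (is.null(.fix$sshell)) .fix$sshell <- make_spherical_shell(8, 2, 4)
  .fix$sshell
}
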