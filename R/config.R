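# ---------------------------------------------------------------------------
# Pipeline configuration: one nested list, YAML round-trippable, with the
# study conditions as defaults.  Desk-scale overrides (coarser EP time step,
# fewer cycles) are explicit choices of the caller, not hidden switches.
# ---------------------------------------------------------------------------

#' Default pipeline configuration
#'
#' Geometry of the idealized LA shell, EP solver settings (conductivities
#' calibrated so the Control total atrial activation is about 100 ms on the
#' default mesh), lesion width, tension parameters, circulation parameters
#' and the coupling/stopping spec.
#'
#' @return nested configuration list
#' @export
default_config <- function() {
  list(
    geometry = list(radius = 20, wall_thickness = 4.5, resolution = 3.5,
                    ostium_radius = 3, annulus_theta = 130, ep_levels = 1),
    ep = list(sigma_f = 1.2, anisotropy = 4, dt = 0.05, duration = 220,
              cell = "courtemanche", sample_dt = 1,
              delays = c(bachmann = 29, posterior_sup = 36,
                         posterior_mid = 40, coronary_sinus = 50),
              stim_amplitude = 60, stim_duration = 3, av_delay = 160),
    lesions = list(width = 5),
    tension = list(atrium = tension_params("atrium"),
                   ventricle = tension_params("ventricle")),
    scar = list(mu_factor = 2, alpha_factor = 5, isotropic = TRUE,
                pas_stiffening = 0.6),
    circulation = circ_params(),
    limit_cycle = list(max_cycles = 40, min_cycles = 3)
  )
}

#' Read / write a configuration as YAML
#'
#' @param path YAML file
#' @param config configuration list
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- default_config()
  modifyList(base, cfg)
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}
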