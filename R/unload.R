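# ---------------------------------------------------------------------------
# Backward-displacement unloading and pressure-volume inflation curves.
# The imaged (diastatic) configuration is observed under load; the unloaded
# reference is recovered by the fixed point X_unl <- X_img - u(X_unl, p),
# where u is the static displacement of inflating the current unloaded guess
# at the imaging pressures.  The same unloaded configuration is reused for
# all lesion cases.
# ---------------------------------------------------------------------------

#' Mechanics model of the LA shell
#'
#' Convenience builder: scar material on the lesion mask, annulus anchoring
#' springs, cavity metering on the endocardium.
#'
#' @param mesh mechanics LA shell mesh
#' @param lesions optional `lesion_set` (its `mech_mask` is used)
#' @param scar_params scar material (e.g. sensitivity variants via
#'   [scar_material()])
#' @param spring_k annulus spring stiffness (uN/mm per node)
#' @param contact optional `contact_spec`
#' @return an `fe_model`
#' @export
la_mech_model <- function(mesh, lesions = NULL,
                          scar_params = scar_material(),
                          spring_k = 1e4, contact = NULL) {
  mask <- NULL
  if (!is.null(lesions)) {
    mask <- lesions$mech_mask
    if (length(mask) != n_elements(mesh))
      stop("lesion mechanics mask does not match the mesh")
  }
  fe_model(mesh, scar_mask = mask, scar_params = scar_params,
           spring_k = spring_k, contact = contact)
}

#' Backward-displacement unloading
#'
#' Recovers the pressure-free reference configuration whose inflation at the
#' stated pressure reproduces the imaged geometry.  Fixed-point iteration;
#' the returned history of maximal nodal errors should decrease.
#'
#' @param mesh imaged-configuration mesh
#' @param p_mmHg chamber pressure at imaging (mmHg); typical diastatic
#'   pressures are 8 mmHg for the left and 4 mmHg for the right side
#' @param lesions,scar_params,spring_k model options (see [la_mech_model()])
#' @param maxit maximal fixed-point iterations
#' @param tol convergence tolerance on the maximal nodal error (mm)
#' @param relax under-relaxation factor of the fixed-point update
#' @return list with `mesh` (unloaded), `errors` (per iteration, mm),
#'   `converged`
#' @export
unload <- function(mesh, p_mmHg, lesions = NULL,
                   scar_params = scar_material(), spring_k = 1e4,
                   maxit = 12, tol = 0.1, relax = 0.7) {
  X_img <- mesh$vertices
  work <- mesh
  errors <- numeric(0)
  U <- NULL
  for (k in seq_len(maxit)) {
    model <- la_mech_model(work, lesions = lesions,
                           scar_params = scar_params, spring_k = spring_k)
    sol <- static_solve(model, p_mmHg, U0 = U, nsteps = if (k == 1) 3 else 1)
    U <- sol$U
    err <- max(abs(work$vertices + U - X_img))
    errors <- c(errors, err)
    if (err < tol) break
    if (k > 3 && err > 2 * errors[k - 1])
      stop("backward-displacement iteration diverging; error history: ",
           paste(signif(errors, 3), collapse = ", "))
    # under-relaxed update: the plain fixed point overshoots for soft
    # exponential materials at low strain
    work$vertices <- work$vertices + relax * (X_img - U - work$vertices)
  }
  list(mesh = work, errors = errors, converged = err < tol)
}

#' End-diastolic pressure-volume relationship by quasi-static inflation
#'
#' Inflates the (unloaded) configuration over a pressure grid and records
#' the cavity volume, reusing each converged state as the next initial
#' guess.
#'
#' @param model an `fe_model` (typically from [la_mech_model()] on the
#'   unloaded mesh)
#' @param pressures_mmHg increasing pressure grid (mmHg)
#' @return data.frame with columns `p` (mmHg) and `V` (mL)
#' @export
edpvr <- function(model, pressures_mmHg = seq(0, 10, by = 2)) {
  U <- matrix(0, model$nv, 3)
  attr(U, "pressure") <- 0
  out <- data.frame(p = pressures_mmHg, V = NA_real_)
  for (i in seq_along(pressures_mmHg)) {
    p <- pressures_mmHg[i]
    if (p == 0) {
      out$V[i] <- cavity_volume(model, U)
      next
    }
    sol <- static_solve(model, p, U0 = U, nsteps = if (i <= 2) 3 else 1)
    U <- sol$U
    out$V[i] <- sol$volume
  }
  out
}
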