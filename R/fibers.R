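# ---------------------------------------------------------------------------
# Rule-based fiber assignment.  Simplified stand-ins for the published
# rule-based atlas methods: only the qualitative anisotropy matters at this
# scale.
# ---------------------------------------------------------------------------

#' Assign per-element fiber frames by a named rule
#'
#' Rules:
#' \describe{
#'   \item{`axial`}{fibers along +x (cable fixture).}
#'   \item{`ventricular_slab`}{transmural rotation on a slab: fiber (helix)
#'     angle interpolates linearly from 60 deg on the endocardium to -60 deg
#'     on the epicardium, sheet angle from -65 deg to 25 deg.}
#'   \item{`la_circumferential`}{atrial shell rule: fibers tangent to the
#'     shell midsurface, predominantly circumferential near the mitral
#'     annulus and rotating toward the meridional direction at the roof
#'     (a roof-to-annulus gradient); sheet in-plane transverse, sheet-normal
#'     radial (transmural).}
#' }
#'
#' @param mesh a `labeled_mesh` (the slab/shell rules need the `aux`
#'   transmural/angular coordinates the builders attach)
#' @param rule rule name
#' @return the mesh with `frame` set (orthonormal triads `f0`, `s0`, `n0`)
#' @export
assign_fibers <- function(mesh, rule = c("la_circumferential",
                                         "ventricular_slab", "axial")) {
  rule <- match.arg(rule)
  ne <- n_elements(mesh)
  if (rule == "axial") {
    f0 <- matrix(rep(c(1, 0, 0), each = ne), ne, 3)
    s0 <- matrix(rep(c(0, 1, 0), each = ne), ne, 3)
    mesh$frame <- orthonormalize_frame(f0, s0)
    return(mesh)
  }
  if (is.null(mesh$aux)) stop("mesh lacks the aux coordinates this rule needs")
  if (rule == "ventricular_slab") {
    xi <- mesh$aux$xi            # 0 = endocardium, 1 = epicardium
    af <- fiber_angle_ventricular(xi) * pi / 180
    as_ <- sheet_angle_ventricular(xi) * pi / 180
    f0 <- cbind(cos(af), sin(af), 0)
    # sheet tilts out of the wall plane by the sheet angle
    inplane <- cbind(-sin(af), cos(af), 0)
    s0 <- cos(as_) * inplane + sin(as_) * matrix(rep(c(0, 0, 1), each = ne), ne, 3)
    mesh$frame <- orthonormalize_frame(f0, s0)
    return(mesh)
  }
  # la_circumferential
  d <- cbind(mesh$aux$dx, mesh$aux$dy, mesh$aux$dz)
  z <- matrix(rep(c(0, 0, 1), each = ne), ne, 3)
  ephi <- cbind(z[, 2] * d[, 3] - z[, 3] * d[, 2],
                z[, 3] * d[, 1] - z[, 1] * d[, 3],
                z[, 1] * d[, 2] - z[, 2] * d[, 1])
  nrm <- sqrt(rowSums(ephi^2))
  deg <- nrm < 1e-8
  if (any(deg)) ephi[deg, ] <- matrix(rep(c(1, 0, 0), each = sum(deg)), ncol = 3)
  ephi <- ephi / sqrt(rowSums(ephi^2))
  eth <- cbind(d[, 2] * ephi[, 3] - d[, 3] * ephi[, 2],
               d[, 3] * ephi[, 1] - d[, 1] * ephi[, 3],
               d[, 1] * ephi[, 2] - d[, 2] * ephi[, 1])
  theta <- mesh$aux$theta
  tmax <- if (!is.null(mesh$meta$annulus_theta))
    mesh$meta$annulus_theta * pi / 180 else max(theta)
  beta <- (60 * pi / 180) * pmax(0, 1 - theta / tmax)  # roof-to-annulus gradient
  f0 <- cos(beta) * ephi + sin(beta) * eth
  s0 <- -sin(beta) * ephi + cos(beta) * eth
  mesh$frame <- orthonormalize_frame(f0, s0)   # n0 = f0 x s0 = radial
  mesh
}

#' Transmural ventricular fiber (helix) angle rule
#' @param xi transmural coordinate, 0 endocardium to 1 epicardium
#' @return angle in degrees
#' @export
fiber_angle_ventricular <- function(xi) 60 - 120 * xi

#' @rdname fiber_angle_ventricular
#' @export
sheet_angle_ventricular <- function(xi) -65 + 90 * xi
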