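# ---------------------------------------------------------------------------
# Idealized left-atrial shell: a closed spherical shell (cube-sphere surface
# grid, radially extruded) with the mitral annulus opening cut at a southern
# latitude, four pulmonary-vein ostia holes on the postero-superior aspect,
# an appendage bulge and landmark sets for the interatrial entry sites.
# Orientation convention: +z superior (roof), +y posterior, +x septal/right.
# ---------------------------------------------------------------------------

la_anatomy_directions <- function() {
  ang <- function(theta, psi) {
    t <- theta * pi / 180; p <- psi * pi / 180
    c(sin(t) * cos(p), sin(t) * sin(p), cos(t))
  }
  # PV ostia spread so the enclosed posterior wall holds a realistic share
  # of the shell surface (the posterior box isolates a substantial area)
  list(
    pv = list(rspv = ang(50, 45), lspv = ang(50, 135),
              ripv = ang(100, 40), lipv = ang(100, 140)),
    appendage = ang(70, 230),
    entry = list(bachmann = ang(45, 300),      # anterior, from Bachmann bundle
                 posterior_sup = ang(60, 10),  # upper posterior connection
                 posterior_mid = ang(95, 8),   # middle posterior connection
                 coronary_sinus = ang(122, 105)),
    mil_annulus = ang(128, 145),               # mitral-isthmus anchor on annulus
    al_annulus = ang(128, 270)                 # anterior-line anchor on annulus
  )
}

cube_sphere_quads <- function(n) {
  # 6 faces, n x n quads each, vertices merged on shared edges.
  grid1 <- seq(-1, 1, length.out = n + 1L)
  pts <- matrix(0, 0, 3); key <- character(0)
  quads <- matrix(0L, 0, 4)
  idx_of <- new.env(hash = TRUE)
  add_pt <- function(p) {
    k <- paste(round(p, 9), collapse = ",")
    i <- idx_of[[k]]
    if (is.null(i)) {
      pts <<- rbind(pts, p)
      i <- nrow(pts)
      idx_of[[k]] <- i
    }
    i
  }
  faces <- list(function(u, v) c(1, u, v), function(u, v) c(-1, u, v),
                function(u, v) c(u, 1, v), function(u, v) c(u, -1, v),
                function(u, v) c(u, v, 1), function(u, v) c(u, v, -1))
  for (f in faces) {
    ids <- matrix(0L, n + 1L, n + 1L)
    for (i in 1:(n + 1L)) for (j in 1:(n + 1L))
      ids[i, j] <- add_pt(f(grid1[i], grid1[j]))
    for (i in 1:n) for (j in 1:n) {
      q <- c(ids[i, j], ids[i + 1L, j], ids[i + 1L, j + 1L], ids[i, j + 1L])
      quads <- rbind(quads, q)
    }
  }
  dirs <- pts / sqrt(rowSums(pts^2))
  # fix quad orientation so footprint normals point outward
  for (q in seq_len(nrow(quads))) {
    v <- dirs[quads[q, ], ]
    nrm <- crossprod_3(v[2, ] - v[1, ], v[3, ] - v[1, ])
    if (sum(nrm * colMeans(v)) < 0) quads[q, ] <- quads[q, c(1, 4, 3, 2)]
  }
  list(dirs = dirs, quads = quads)
}

crossprod_3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

angdist <- function(dirs, d0) {
  acos(pmin(1, pmax(-1, dirs %*% d0)))
}

#' Idealized left-atrial shell mesh
#'
#' Builds a closed spherical shell with four pulmonary-vein ostia openings,
#' a mitral annulus opening, an appendage bulge and vertex landmark sets for
#' the interatrial entry sites (Bachmann bundle insertion, two posterior
#' connections, coronary sinus).  The construction is deterministic; `seed`
#' only controls the optional vertex jitter.
#'
#' @param radius midsurface radius (mm)
#' @param wall_thickness shell thickness (mm); the mean atrial wall thickness
#'   of the emulated anatomy is 4.5 mm
#' @param resolution target in-plane element edge length (mm)
#' @param seed integer seed for the optional jitter
#' @param ostium_radius pulmonary-vein ostium hole radius (mm)
#' @param annulus_theta polar angle (degrees from superior pole) below which
#'   the shell is cut to form the mitral annulus opening
#' @param jitter vertex jitter amplitude (mm, default 0)
#' @param nlayer transmural element layers; default keeps at least two
#'   elements through the wall
#' @return a `labeled_mesh` with frames assigned by the circumferential
#'   atrial fiber rule
#' @export
make_la_shell <- function(radius = 20, wall_thickness = 4.5, resolution = 3.5,
                          seed = 1L, ostium_radius = 3, annulus_theta = 130,
                          jitter = 0, nlayer = NULL) {
  if (wall_thickness <= 0 || wall_thickness >= radius)
    stop("require 0 < wall_thickness < radius")
  if (resolution <= 0) stop("resolution must be positive")
  n <- max(4L, as.integer(round(radius * pi / 2 / resolution)))
  if (is.null(nlayer)) nlayer <- max(2L, as.integer(round(wall_thickness / resolution)))
  cs <- cube_sphere_quads(n)
  anat <- la_anatomy_directions()
  qc <- t(vapply(seq_len(nrow(cs$quads)), function(q)
    colMeans(cs$dirs[cs$quads[q, ], ]), numeric(3)))
  qc <- qc / sqrt(rowSums(qc^2))
  theta <- acos(qc[, 3]) * 180 / pi
  hole_ang <- atan(ostium_radius / radius)
  keep <- theta <= annulus_theta
  for (nm in names(anat$pv)) {
    inhole <- angdist(qc, anat$pv[[nm]]) < hole_ang
    if (!any(inhole))
      stop("resolution too coarse to resolve the ", toupper(nm),
           " ostium: no element column falls inside the ",
           signif(ostium_radius, 3), " mm hole; refine below ",
           signif(ostium_radius * 1.5, 3), " mm")
    keep <- keep & !inhole
  }
  quads <- cs$quads[keep, , drop = FALSE]
  used <- sort(unique(as.vector(quads)))
  remap <- integer(nrow(cs$dirs)); remap[used] <- seq_along(used)
  quads[] <- remap[quads]
  dirs <- cs$dirs[used, , drop = FALSE]
  nsurf <- nrow(dirs)

  # appendage bulge: smooth outward radial scaling around the appendage axis
  gam <- as.numeric(angdist(dirs, anat$appendage))
  bulge <- 1 + 0.25 * exp(-(gam / (20 * pi / 180))^2)

  jit <- matrix(0, nsurf, 3)
  if (jitter > 0) {
    set.seed(as.integer(seed))
    jit <- matrix(rnorm(3L * nsurf, sd = jitter), nsurf, 3)
  }
  r_in <- radius - wall_thickness / 2
  pos <- function(s, k) {
    r <- (r_in + wall_thickness * k / nlayer) * bulge[s]
    dirs[s, , drop = FALSE] * r + jit[s, , drop = FALSE]
  }
  ex <- extrude_quads(quads, nsurf, nlayer, pos)
  ne <- nrow(ex$tets)
  qdir <- qc[keep, , drop = FALSE][ex$column, , drop = FALSE]
  aux <- data.frame(column = ex$column, layer = ex$layer,
                    xi = (ex$layer - 0.5) / nlayer,
                    dx = qdir[, 1], dy = qdir[, 2], dz = qdir[, 3],
                    theta = acos(pmin(1, pmax(-1, qdir[, 3]))),
                    phi = atan2(qdir[, 2], qdir[, 1]))
  mesh <- new_labeled_mesh(ex$vertices, ex$tets, region = rep("LA", ne),
                           aux = aux)
  mesh$surfaces <- extract_named_surfaces(mesh, ex$layer, nlayer)
  mesh$meta <- list(radius = radius, wall_thickness = wall_thickness,
                    resolution = resolution, nlayer = nlayer,
                    ostium_radius = ostium_radius, hole_ang = hole_ang,
                    annulus_theta = annulus_theta, anatomy = anat,
                    kind = "la_shell")

  # landmark sets ------------------------------------------------------------
  vdir <- ex$vertices / sqrt(rowSums(ex$vertices^2))
  vtheta <- acos(pmin(1, pmax(-1, vdir[, 3]))) * 180 / pi
  rimv <- sort(unique(as.vector(mesh$surfaces$rim)))
  lm_v <- list()
  lm_v$mitral_annulus <- rimv[vtheta[rimv] > annulus_theta - 1.2 * resolution / radius * 180 / pi]
  for (nm in names(anat$pv)) {
    near <- angdist(vdir[rimv, , drop = FALSE], anat$pv[[nm]]) < hole_ang * 2.5
    lm_v[[paste0("pv_", nm)]] <- rimv[near & !(rimv %in% lm_v$mitral_annulus)]
  }
  site_ang <- max(9, 1.2 * resolution / radius * 180 / pi) * pi / 180
  for (nm in names(anat$entry))
    lm_v[[nm]] <- which(angdist(vdir, anat$entry[[nm]]) < site_ang)
  lm_v$sinus_entry <- lm_v$bachmann  # earliest LA breakthrough site
  mesh$landmarks_v <- lm_v

  eang <- function(d0) angdist(qdir, d0)
  lm_e <- list(
    appendage = which(as.numeric(eang(anat$appendage)) < 22 * pi / 180),
    roof = which(aux$theta < 35 * pi / 180))
  mesh$landmarks_e <- lm_e
  assign_fibers(mesh, rule = "la_circumferential")
}

#' Build the nested electrophysiology mesh
#'
#' The EP mesh is a uniform 1:8 refinement (per level) of the mechanics mesh,
#' so every EP element lies in exactly one mechanics element and the
#' EP-to-mechanics element map is exact by construction.
#'
#' @param mesh mechanics `labeled_mesh`
#' @param levels number of refinement levels (>= 1)
#' @return refined `labeled_mesh` with `ep_to_mech_map` set
#' @export
build_ep_mesh <- function(mesh, levels = 1L) {
  out <- mesh
  map <- seq_len(n_elements(mesh))
  for (l in seq_len(levels)) {
    r <- refine_mesh(out)
    map <- map[r$parent]
    out <- r$mesh
  }
  out$ep_to_mech_map <- map
  out
}

#' Closed spherical shell fixture
#'
#' A hole-free thin spherical shell (cube-sphere grid), used as the closed
#' cavity, contact and unloading test fixture.
#'
#' @param radius midsurface radius (mm)
#' @param wall_thickness shell thickness (mm)
#' @param resolution target in-plane edge length (mm)
#' @param nlayer transmural element layers
#' @return a `labeled_mesh` with circumferential fibers
#' @export
make_spherical_shell <- function(radius = 10, wall_thickness = 2,
                                 resolution = 4, nlayer = 2L) {
  n <- max(3L, as.integer(round(radius * pi / 2 / resolution)))
  cs <- cube_sphere_quads(n)
  nsurf <- nrow(cs$dirs)
  r_in <- radius - wall_thickness / 2
  pos <- function(s, k)
    cs$dirs[s, , drop = FALSE] * (r_in + wall_thickness * k / nlayer)
  ex <- extrude_quads(cs$quads, nsurf, nlayer, pos)
  ne <- nrow(ex$tets)
  qc <- t(vapply(seq_len(nrow(cs$quads)), function(q)
    colMeans(cs$dirs[cs$quads[q, ], ]), numeric(3)))
  qc <- qc / sqrt(rowSums(qc^2))
  qdir <- qc[ex$column, , drop = FALSE]
  aux <- data.frame(column = ex$column, layer = ex$layer,
                    xi = (ex$layer - 0.5) / nlayer,
                    dx = qdir[, 1], dy = qdir[, 2], dz = qdir[, 3],
                    theta = acos(pmin(1, pmax(-1, qdir[, 3]))),
                    phi = atan2(qdir[, 2], qdir[, 1]))
  mesh <- new_labeled_mesh(ex$vertices, ex$tets, region = rep("LA", ne),
                           aux = aux)
  mesh$surfaces <- extract_named_surfaces(mesh, ex$layer, nlayer)
  mesh$meta <- list(radius = radius, wall_thickness = wall_thickness,
                    resolution = resolution, nlayer = nlayer,
                    kind = "sphere_shell")
  assign_fibers(mesh, "la_circumferential")
}
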