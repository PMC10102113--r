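#' @importFrom Matrix sparseMatrix Diagonal Cholesky solve t crossprod
#' @importFrom stats uniroot lm coef residuals setNames approx rnorm
#' @importFrom utils read.csv write.csv head tail
NULL

# ---------------------------------------------------------------------------
# labeled_mesh: tetrahedral mesh with per-element region labels, fiber frames,
# named landmark sets and (optionally) a nested EP->mechanics element map.
# Vertices in mm; element/vertex indices are 1-based (R convention); file
# writers emit the 0-based/1-based indexing their format requires.
# ---------------------------------------------------------------------------

new_labeled_mesh <- function(vertices, tets, region, frame = NULL,
                             landmarks_v = list(), landmarks_e = list(),
                             surfaces = list(), aux = NULL,
                             ep_to_mech_map = NULL) {
  storage.mode(tets) <- "integer"
  dimnames(vertices) <- NULL
  dimnames(tets) <- NULL
  m <- structure(list(
    vertices = vertices, tets = tets, region = region, frame = frame,
    landmarks_v = landmarks_v, landmarks_e = landmarks_e,
    surfaces = surfaces, aux = aux, ep_to_mech_map = ep_to_mech_map
  ), class = "labeled_mesh")
  m
}

#' Number of vertices / elements of a mesh
#' @param mesh a `labeled_mesh`
#' @return integer count
#' @export
n_vertices <- function(mesh) nrow(mesh$vertices)

#' @rdname n_vertices
#' @export
n_elements <- function(mesh) nrow(mesh$tets)

#' Signed tetrahedron volumes
#'
#' Volumes are positive for positively oriented elements; the mesh builders
#' guarantee positive orientation, and downstream assembly relies on it.
#'
#' @param mesh a `labeled_mesh`
#' @return numeric vector of volumes in mm^3
#' @export
tet_volumes <- function(mesh) {
  v <- mesh$vertices; t4 <- mesh$tets
  a <- v[t4[, 2], , drop = FALSE] - v[t4[, 1], , drop = FALSE]
  b <- v[t4[, 3], , drop = FALSE] - v[t4[, 1], , drop = FALSE]
  d <- v[t4[, 4], , drop = FALSE] - v[t4[, 1], , drop = FALSE]
  (a[, 1] * (b[, 2] * d[, 3] - b[, 3] * d[, 2]) +
   a[, 2] * (b[, 3] * d[, 1] - b[, 1] * d[, 3]) +
   a[, 3] * (b[, 1] * d[, 2] - b[, 2] * d[, 1])) / 6
}

tet_centroids <- function(mesh) {
  v <- mesh$vertices; t4 <- mesh$tets
  (v[t4[, 1], , drop = FALSE] + v[t4[, 2], , drop = FALSE] +
   v[t4[, 3], , drop = FALSE] + v[t4[, 4], , drop = FALSE]) / 4
}

# --- layered extrusion ------------------------------------------------------
# A quad surface mesh (nsurf vertices, quads given as cyclic 4-tuples of
# surface ids) is extruded through `nlayer + 1` vertex layers.  Global vertex
# index of surface vertex s at layer k (k = 0..nlayer) is k*nsurf + s.  Each
# hex cell is split into two vertical prisms along the diagonal through the
# smallest surface id of its footprint, and each prism into three tets so
# that every quad face is split by the diagonal through its smallest global
# vertex.  That rule is face-local, hence the triangulation conforms across
# neighbouring cells for any quad surface mesh.

prism_tets <- function(tri, nsurf, k) {
  # tri: 3 surface ids; bottom layer k, top layer k+1
  i <- which.min(tri)
  p <- tri[((i - 1 + 0:2) %% 3) + 1]   # rotate so p[1] is the minimum
  a <- p[1] + (k - 1L) * nsurf; b <- p[2] + (k - 1L) * nsurf
  cc <- p[3] + (k - 1L) * nsurf
  A <- a + nsurf; B <- b + nsurf; C <- cc + nsurf
  if (p[2] < p[3]) {
    rbind(c(a, b, cc, C), c(a, b, C, B), c(a, B, C, A))
  } else {
    rbind(c(a, cc, b, B), c(a, cc, B, C), c(a, C, B, A))
  }
}

extrude_quads <- function(quads, nsurf, nlayer, position) {
  # position(surf_id_vector, layer_index 0..nlayer) -> n x 3 coordinates
  tets <- vector("list", nrow(quads) * nlayer * 2L)
  colid <- integer(0); layid <- integer(0)
  idx <- 1L
  cols <- integer(nrow(quads) * nlayer * 6L)
  lays <- integer(nrow(quads) * nlayer * 6L)
  out <- matrix(0L, nrow(quads) * nlayer * 6L, 4L)
  r <- 0L
  for (q in seq_len(nrow(quads))) {
    quad <- quads[q, ]
    i <- which.min(quad)
    qq <- quad[((i - 1 + 0:3) %% 4) + 1]
    tris <- rbind(qq[c(1, 2, 3)], qq[c(1, 3, 4)])
    for (k in seq_len(nlayer)) {
      for (tr in 1:2) {
        tt <- prism_tets(tris[tr, ], nsurf, k)
        out[r + 1:3, ] <- tt
        cols[r + 1:3] <- q
        lays[r + 1:3] <- k
        r <- r + 3L
      }
    }
  }
  verts <- do.call(rbind, lapply(0:nlayer, function(k)
    position(seq_len(nsurf), k)))
  # enforce positive orientation
  a <- verts[out[, 2], ] - verts[out[, 1], ]
  b <- verts[out[, 3], ] - verts[out[, 1], ]
  d <- verts[out[, 4], ] - verts[out[, 1], ]
  vol6 <- a[, 1] * (b[, 2] * d[, 3] - b[, 3] * d[, 2]) +
          a[, 2] * (b[, 3] * d[, 1] - b[, 1] * d[, 3]) +
          a[, 3] * (b[, 1] * d[, 2] - b[, 2] * d[, 1])
  flip <- vol6 < 0
  if (any(flip)) out[flip, c(3, 4)] <- out[flip, c(4, 3)]
  list(vertices = verts, tets = out, column = cols, layer = lays)
}

# --- boundary surface extraction -------------------------------------------

tet_faces <- function(tets) {
  # outward-oriented faces of positively oriented tets
  rbind(tets[, c(1, 3, 2)], tets[, c(1, 2, 4)],
        tets[, c(2, 3, 4)], tets[, c(1, 4, 3)])
}

boundary_faces <- function(mesh) {
  f <- tet_faces(mesh$tets)
  key <- apply(f, 1, function(x) paste(sort(x), collapse = "-"))
  tab <- table(key)
  bnd <- key %in% names(tab)[tab == 1L]
  owner <- rep(seq_len(n_elements(mesh)), 4L)
  list(faces = f[bnd, , drop = FALSE], owner = owner[bnd])
}

face_key <- function(f) {
  paste(pmin(f[, 1], pmin(f[, 2], f[, 3])),
        f[, 1] + f[, 2] + f[, 3],
        pmax(f[, 1], pmax(f[, 2], f[, 3])), sep = "-")
}

# Boundary edge loops of a triangle set (edges used once), as ordered vertex
# cycles.  Used to close cavity openings with a centroid fan.
surface_rims <- function(tris) {
  e <- rbind(tris[, 1:2], tris[, 2:3], tris[, c(3, 1)])
  ek <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  tab <- table(ek)
  be <- e[ek %in% names(tab)[tab == 1L], , drop = FALSE]
  if (nrow(be) == 0) return(list())
  loops <- list()
  nxt <- split(seq_len(nrow(be)), be[, 1])
  used <- rep(FALSE, nrow(be))
  for (s in seq_len(nrow(be))) {
    if (used[s]) next
    loop <- c(be[s, 1]); cur <- be[s, 2]; used[s] <- TRUE
    repeat {
      loop <- c(loop, cur)
      cand <- nxt[[as.character(cur)]]
      cand <- cand[!used[cand]]
      if (length(cand) == 0) break
      used[cand[1]] <- TRUE
      cur <- be[cand[1], 2]
      if (cur == loop[1]) break
    }
    loops[[length(loops) + 1L]] <- loop
  }
  loops
}

# --- frame utilities --------------------------------------------------------

orthonormalize_frame <- function(f, s) {
  nf <- f / sqrt(rowSums(f^2))
  s <- s - nf * rowSums(s * nf)
  ns <- s / sqrt(rowSums(s^2))
  nn <- cbind(nf[, 2] * ns[, 3] - nf[, 3] * ns[, 2],
              nf[, 3] * ns[, 1] - nf[, 1] * ns[, 3],
              nf[, 1] * ns[, 2] - nf[, 2] * ns[, 1])
  list(f0 = nf, s0 = ns, n0 = nn)
}

#' Check orthonormality of per-element fiber frames
#'
#' @param mesh a `labeled_mesh` with frames assigned
#' @param tol tolerance on deviations from orthonormality
#' @return largest deviation found (invisibly); errors are not raised
#' @export
frame_orthonormality_error <- function(mesh, tol = 1e-10) {
  fr <- mesh$frame
  if (is.null(fr)) stop("mesh has no frames")
  dev <- c(abs(rowSums(fr$f0^2) - 1), abs(rowSums(fr$s0^2) - 1),
           abs(rowSums(fr$n0^2) - 1), abs(rowSums(fr$f0 * fr$s0)),
           abs(rowSums(fr$f0 * fr$n0)), abs(rowSums(fr$s0 * fr$n0)))
  max(dev)
}

frame_determinants <- function(mesh) {
  fr <- mesh$frame
  f <- fr$f0; s <- fr$s0; n <- fr$n0
  f[, 1] * (s[, 2] * n[, 3] - s[, 3] * n[, 2]) +
  f[, 2] * (s[, 3] * n[, 1] - s[, 1] * n[, 3]) +
  f[, 3] * (s[, 1] * n[, 2] - s[, 2] * n[, 1])
}

#' @export
print.labeled_mesh <- function(x, ...) {
  cat("labeled_mesh:", n_vertices(x), "vertices,", n_elements(x), "tets\n")
  cat("  regions:", paste(sprintf("%s (%d)", names(table(x$region)),
                                  table(x$region)), collapse = ", "), "\n")
  if (length(x$landmarks_v))
    cat("  vertex landmarks:", paste(names(x$landmarks_v), collapse = ", "), "\n")
  if (length(x$landmarks_e))
    cat("  element landmarks:", paste(names(x$landmarks_e), collapse = ", "), "\n")
  if (!is.null(x$ep_to_mech_map))
    cat("  nested EP mesh: maps onto", max(x$ep_to_mech_map), "parent elements\n")
  invisible(x)
}

# ---------------------------------------------------------------------------
# Cable and slab fixtures
# ---------------------------------------------------------------------------

#' Quasi-1D cable mesh for conduction-velocity tuning
#'
#' A thin strand of tetrahedra along the x axis with uniform fiber direction
#' along the axis, one element across the cross-section.  Used as the fixture
#' on which tissue conductivities are tuned to target conduction velocities.
#'
#' @param length cable length (mm)
#' @param resolution target element edge length (mm)
#' @return a `labeled_mesh` with `start`/`end` vertex landmark sets and a
#'   `probe` vertex set along the axis
#' @export
make_cable <- function(length, resolution) {
  if (length <= 0 || resolution <= 0)
    stop("cable dimensions must be positive")
  nx <- max(2L, as.integer(round(length / resolution)))
  make_slab(lx = length, ly = resolution, lz = resolution,
            nx = nx, ny = 1L, nz = 1L, fiber = c(1, 0, 0))
}

#' Rectangular slab mesh
#'
#' Structured tetrahedral box; the z direction is treated as transmural
#' (used by the ventricular fiber rotation rule and the fast endocardial
#' layer fixture).
#'
#' @param lx,ly,lz box dimensions (mm)
#' @param nx,ny,nz element subdivisions; default from `resolution`
#' @param resolution target edge length (mm) when subdivisions not given
#' @param fiber constant fiber direction, or NULL to leave frames unassigned
#' @return a `labeled_mesh`
#' @export
make_slab <- function(lx, ly, lz, resolution = NULL,
                      nx = NULL, ny = NULL, nz = NULL, fiber = c(1, 0, 0)) {
  if (any(c(lx, ly, lz) <= 0)) stop("slab dimensions must be positive")
  if (is.null(nx)) nx <- max(1L, as.integer(round(lx / resolution)))
  if (is.null(ny)) ny <- max(1L, as.integer(round(ly / resolution)))
  if (is.null(nz)) nz <- max(1L, as.integer(round(lz / resolution)))
  # surface grid in x-y, layers along z
  xs <- seq(0, lx, length.out = nx + 1L)
  ys <- seq(0, ly, length.out = ny + 1L)
  nsurf <- (nx + 1L) * (ny + 1L)
  sid <- function(i, j) i + 1L + (nx + 1L) * j   # i=0..nx, j=0..ny
  quads <- matrix(0L, nx * ny, 4L)
  q <- 1L
  for (j in 0:(ny - 1L)) for (i in 0:(nx - 1L)) {
    quads[q, ] <- c(sid(i, j), sid(i + 1L, j), sid(i + 1L, j + 1L), sid(i, j + 1L))
    q <- q + 1L
  }
  pos <- function(s, k) {
    i <- (s - 1L) %% (nx + 1L); j <- (s - 1L) %/% (nx + 1L)
    cbind(xs[i + 1L], ys[j + 1L], lz * k / nz)
  }
  ex <- extrude_quads(quads, nsurf, nz, pos)
  ne <- nrow(ex$tets)
  frame <- NULL
  if (!is.null(fiber)) {
    f0 <- matrix(rep(fiber / sqrt(sum(fiber^2)), each = ne), ne, 3)
    sref <- if (abs(fiber[3]) < 0.9) c(0, 0, 1) else c(0, 1, 0)
    s0 <- matrix(rep(sref, each = ne), ne, 3)
    frame <- orthonormalize_frame(f0, s0)
  }
  cent <- (ex$vertices[ex$tets[, 1], ] + ex$vertices[ex$tets[, 2], ] +
           ex$vertices[ex$tets[, 3], ] + ex$vertices[ex$tets[, 4], ]) / 4
  aux <- data.frame(column = ex$column, layer = ex$layer,
                    xi = (ex$layer - 0.5) / nz,
                    cx = cent[, 1], cy = cent[, 2], cz = cent[, 3])
  v <- ex$vertices
  lm_v <- list(start = which(v[, 1] < 1e-9),
               end = which(v[, 1] > lx - 1e-9),
               probe = which(abs(v[, 2]) < 1e-9 & abs(v[, 3]) < 1e-9))
  mesh <- new_labeled_mesh(v, ex$tets, region = rep("LA", ne), frame = frame,
                           landmarks_v = lm_v, aux = aux)
  mesh$surfaces <- extract_named_surfaces(mesh, ex$layer, nz)
  mesh
}

extract_named_surfaces <- function(mesh, elem_layer, nlayer) {
  bf <- boundary_faces(mesh)
  lay <- elem_layer[bf$owner]
  # classify endo (inner/bottom layer) vs epi (outer/top layer) by the face's
  # vertices all lying on layer-0 or layer-n vertex sheets
  nsurf <- n_vertices(mesh) / (nlayer + 1L)
  vl <- (seq_len(n_vertices(mesh)) - 1L) %/% nsurf  # vertex layer
  fl <- matrix(vl[bf$faces], ncol = 3)
  endo <- rowSums(fl == 0L) == 3L
  epi <- rowSums(fl == nlayer) == 3L
  list(endo = bf$faces[endo, , drop = FALSE],
       epi = bf$faces[epi, , drop = FALSE],
       rim = bf$faces[!endo & !epi, , drop = FALSE],
       endo_owner = bf$owner[endo], epi_owner = bf$owner[epi])
}
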