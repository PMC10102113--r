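# Uniform 1:8 tetrahedron refinement.  Corner tets keep the parent corners;
# the interior octahedron is split along the m13-m24 diagonal.  Parent faces
# are split into the same four triangles seen from both neighbours, so the
# refined mesh conforms.

refine_mesh <- function(mesh) {
  t4 <- mesh$tets
  ne <- nrow(t4)
  ed <- rbind(t4[, c(1, 2)], t4[, c(1, 3)], t4[, c(1, 4)],
              t4[, c(2, 3)], t4[, c(2, 4)], t4[, c(3, 4)])
  ekey <- paste(pmin(ed[, 1], ed[, 2]), pmax(ed[, 1], ed[, 2]))
  uk <- !duplicated(ekey)
  eid <- match(ekey, ekey[uk])
  newv <- (mesh$vertices[ed[uk, 1], , drop = FALSE] +
           mesh$vertices[ed[uk, 2], , drop = FALSE]) / 2
  nv0 <- n_vertices(mesh)
  mid <- matrix(nv0 + eid, ne, 6)  # m12 m13 m14 m23 m24 m34 per parent
  v1 <- t4[, 1]; v2 <- t4[, 2]; v3 <- t4[, 3]; v4 <- t4[, 4]
  m12 <- mid[, 1]; m13 <- mid[, 2]; m14 <- mid[, 3]
  m23 <- mid[, 4]; m24 <- mid[, 5]; m34 <- mid[, 6]
  children <- rbind(
    cbind(v1, m12, m13, m14), cbind(v2, m12, m24, m23),
    cbind(v3, m13, m23, m34), cbind(v4, m14, m34, m24),
    cbind(m13, m24, m12, m23), cbind(m13, m24, m23, m34),
    cbind(m13, m24, m34, m14), cbind(m13, m24, m14, m12))
  parent <- rep(seq_len(ne), 8L)
  verts <- rbind(mesh$vertices, newv)
  a <- verts[children[, 2], ] - verts[children[, 1], ]
  b <- verts[children[, 3], ] - verts[children[, 1], ]
  d <- verts[children[, 4], ] - verts[children[, 1], ]
  vol6 <- a[, 1] * (b[, 2] * d[, 3] - b[, 3] * d[, 2]) +
          a[, 2] * (b[, 3] * d[, 1] - b[, 1] * d[, 3]) +
          a[, 3] * (b[, 1] * d[, 2] - b[, 2] * d[, 1])
  flip <- vol6 < 0
  if (any(flip)) children[flip, c(3, 4)] <- children[flip, c(4, 3)]

  child <- new_labeled_mesh(verts, children, region = mesh$region[parent])
  if (!is.null(mesh$frame))
    child$frame <- list(f0 = mesh$frame$f0[parent, , drop = FALSE],
                        s0 = mesh$frame$s0[parent, , drop = FALSE],
                        n0 = mesh$frame$n0[parent, , drop = FALSE])
  if (!is.null(mesh$aux)) child$aux <- mesh$aux[parent, , drop = FALSE]
  child$landmarks_v <- mesh$landmarks_v   # parent vertices keep their indices
  child$landmarks_e <- lapply(mesh$landmarks_e, function(s)
    which(parent %in% s))
  child$meta <- mesh$meta
  list(mesh = child, parent = parent)
}

# Barycentric point-in-tet test used by the nestedness property check.
points_in_tet <- function(mesh, elems, pts, tol = 1e-9) {
  v <- mesh$vertices; t4 <- mesh$tets[elems, , drop = FALSE]
  ok <- logical(length(elems))
  for (i in seq_along(elems)) {
    A <- cbind(v[t4[i, 2], ] - v[t4[i, 1], ],
               v[t4[i, 3], ] - v[t4[i, 1], ],
               v[t4[i, 4], ] - v[t4[i, 1], ])
    lam <- try(solve(A, pts[i, ] - v[t4[i, 1], ]), silent = TRUE)
    if (inherits(lam, "try-error")) { ok[i] <- FALSE; next }
    ok[i] <- all(lam >= -tol) && sum(lam) <= 1 + tol
  }
  ok
}
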