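# ---------------------------------------------------------------------------
# Total-Lagrangian finite-element mechanics on linear tetrahedra (one-point
# quadrature).  Residual: M a + D v + f_int(u) = f_ext(u, t) with the
# internal force from the nonlinear constitutive laws, Rayleigh damping
# D = alpha1 M + alpha2 K_ref (tangent frozen at the reference state),
# follower pressure loads on cavity surfaces, annulus anchoring springs and
# an optional pericardial penalty contact.
# Units: mm, ms, Pa; density kg/m^3 (= ug/mm^3), force uN, pressure Pa.
# ---------------------------------------------------------------------------

MMHG_PA <- 133.322

# scatter-add element values into a nodal vector
accum <- function(idx, vals, n) {
  as.numeric(Matrix::sparseMatrix(i = idx, j = rep(1L, length(idx)),
                                  x = vals, dims = c(n, 1)))
}

#' Build a mechanics model
#'
#' Bundles mesh, per-element materials, boundary conditions and cavity
#' definitions into the assembly-ready form used by the static and dynamic
#' solvers.
#'
#' @param mesh `labeled_mesh` with frames
#' @param scar_mask logical element mask given the scar material
#' @param scar_params scar material (default from [scar_material()])
#' @param base_params bulk myocardial material
#' @param dirichlet vertex indices with zero-displacement conditions
#' @param spring_nodes,spring_k vertex indices anchored by linear springs to
#'   their reference position, and the per-node stiffness (uN/mm)
#' @param contact optional pericardial contact spec from [contact_spec()]
#' @param cavity_name name of the metered cavity ("LA")
#' @return an `fe_model`
#' @export
fe_model <- function(mesh, scar_mask = NULL,
                     scar_params = scar_material(),
                     base_params = material_params("myocardium"),
                     dirichlet = integer(0),
                     spring_nodes = NULL, spring_k = 1e4,
                     contact = NULL, cavity_name = "LA") {
  ne <- n_elements(mesh); nv <- n_vertices(mesh)
  sg <- tet_shape_grads(mesh)
  if (any(sg$vol <= 0)) stop("inverted element in reference mesh")
  if (is.null(scar_mask)) scar_mask <- rep(FALSE, ne)
  pick <- function(field, default = NA) {
    b <- base_params[[field]]; s <- scar_params[[field]]
    out <- rep(if (is.null(b)) default else b, ne)
    out[scar_mask] <- if (is.null(s)) default else s
    out
  }
  mat <- list(model = ifelse(rep(base_params$model, ne) == "neo-hookean", 2L, 1L),
              mu = pick("mu"), alpha = pick("alpha", 0), kappa = pick("kappa"),
              rho = pick("rho0"))
  bmat <- matrix(rep(base_params$b, each = ne), ne, 6)
  if (!is.null(scar_params$b))
    bmat[scar_mask, ] <- matrix(rep(scar_params$b, each = sum(scar_mask)),
                                sum(scar_mask), 6)
  colnames(bmat) <- c("ff", "ss", "nn", "fs", "fn", "ns")
  Mlump <- accum(as.vector(mesh$tets), rep(mat$rho * sg$vol / 4, 4), nv)

  if (is.null(spring_nodes)) {
    # anchor the annulus ring where one exists; otherwise tether every node
    # weakly so rigid-body modes stay constrained
    spring_nodes <- if (!is.null(mesh$landmarks_v$mitral_annulus))
      mesh$landmarks_v$mitral_annulus else seq_len(nv)
    if (length(spring_nodes) == nv) spring_k <- min(spring_k, 1)
  }
  cav <- NULL
  if (!is.null(mesh$surfaces$endo) && nrow(mesh$surfaces$endo) > 0) {
    tris <- mesh$surfaces$endo
    rims <- surface_rims(tris)
    cav <- list(tris = tris, rims = rims)
  }
  epi_area <- NULL
  if (!is.null(contact) && !is.null(mesh$surfaces$epi)) {
    tr <- mesh$surfaces$epi
    x <- mesh$vertices
    e1 <- x[tr[, 2], ] - x[tr[, 1], ]; e2 <- x[tr[, 3], ] - x[tr[, 1], ]
    a2 <- sqrt(rowSums(cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
                             e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
                             e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])^2)) / 2
    epi_area <- accum(as.vector(tr), rep(a2 / 3, 3), nv)
  }
  structure(list(mesh = mesh, sg = sg, mat = mat, b = bmat,
                 scar_mask = scar_mask, M = Mlump,
                 dirichlet = dirichlet, spring_nodes = spring_nodes,
                 spring_k = spring_k, contact = contact, cavity = cav,
                 epi_area = epi_area, cavity_name = cavity_name,
                 nv = nv, ne = ne), class = "fe_model")
}

#' Pericardial contact specification
#'
#' Frictionless permanent penalty contact between the epicardial surface and
#' a target surface, with the regularized gap function: quadratic
#' `|x-x_proj|^2/(2 d)` below the transition distance `d`, linear
#' `|x-x_proj| - d/2` up to the maximal distance `d_M`, and zero beyond
#' `d_M` (contact released).
#'
#' @param surface list describing the target: `list(type="sphere", center=,
#'   radius=)` or `list(type="plane", point=, normal=)`
#' @param k_epi penalty stiffness (Pa/mm); default 10 MPa/mm
#' @param d transition distance (mm)
#' @param d_M maximal contact distance (mm)
#' @return a `contact_spec`
#' @export
contact_spec <- function(surface, k_epi = 1e7, d = 0.1, d_M = 8) {
  if (!(d > 0 && d < d_M)) stop("require 0 < d < d_M")
  structure(list(surface = surface, k_epi = k_epi, d = d, d_M = d_M),
            class = "contact_spec")
}

#' Regularized contact gap function
#'
#' @param x points (n x 3) on the contacting surface
#' @param surface target surface description (see [contact_spec()])
#' @param spec a `contact_spec` (for `d`, `d_M`)
#' @return list with `g` (mm), `dist` (mm) and `dir` (n x 3 unit vectors
#'   toward the projection; zero rows where no projection exists)
#' @export
gap <- function(x, surface, spec) {
  if (is.null(dim(x))) x <- matrix(x, 1)
  n <- nrow(x)
  if (surface$type == "sphere") {
    r <- sweep(x, 2, surface$center)
    rn <- sqrt(rowSums(r^2))
    dist <- abs(rn - surface$radius)
    dir <- (surface$radius - rn) / pmax(rn, 1e-12) * r  # toward projection
    nd <- sqrt(rowSums(dir^2))
    dir <- dir / ifelse(nd > 1e-12, nd, 1)
  } else if (surface$type == "plane") {
    h <- as.numeric(sweep(x, 2, surface$point) %*% surface$normal)
    dist <- abs(h)
    dir <- -sign(h) %o% surface$normal
  } else stop("unknown contact surface type; treated as no contact")
  g <- ifelse(dist > spec$d_M, 0,
              ifelse(dist < spec$d, dist^2 / (2 * spec$d), dist - spec$d / 2))
  list(g = g, dist = dist, dir = dir)
}

# --- vectorized element kinematics and stress (ne x 9 row-major tensors) ---

elem_defgrad <- function(model, U) {
  t4 <- model$mesh$tets; G <- model$sg$G
  ne <- model$ne
  F <- matrix(0, ne, 9)
  F[, c(1, 5, 9)] <- 1
  for (a in 1:4) {
    Ua <- U[t4[, a], , drop = FALSE]
    g <- G[[a]]
    for (i in 1:3) for (j in 1:3)
      F[, 3 * (i - 1) + j] <- F[, 3 * (i - 1) + j] + Ua[, i] * g[, j]
  }
  F
}

m9 <- function(i, j) 3L * (i - 1L) + j

mat9_det <- function(A) {
  A[, 1] * (A[, 5] * A[, 9] - A[, 6] * A[, 8]) -
  A[, 2] * (A[, 4] * A[, 9] - A[, 6] * A[, 7]) +
  A[, 3] * (A[, 4] * A[, 8] - A[, 5] * A[, 7])
}

mat9_inv <- function(A, detA = mat9_det(A)) {
  I <- matrix(0, nrow(A), 9)
  I[, 1] <- (A[, 5] * A[, 9] - A[, 6] * A[, 8]) / detA
  I[, 2] <- (A[, 3] * A[, 8] - A[, 2] * A[, 9]) / detA
  I[, 3] <- (A[, 2] * A[, 6] - A[, 3] * A[, 5]) / detA
  I[, 4] <- (A[, 6] * A[, 7] - A[, 4] * A[, 9]) / detA
  I[, 5] <- (A[, 1] * A[, 9] - A[, 3] * A[, 7]) / detA
  I[, 6] <- (A[, 3] * A[, 4] - A[, 1] * A[, 6]) / detA
  I[, 7] <- (A[, 4] * A[, 8] - A[, 5] * A[, 7]) / detA
  I[, 8] <- (A[, 2] * A[, 7] - A[, 1] * A[, 8]) / detA
  I[, 9] <- (A[, 1] * A[, 5] - A[, 2] * A[, 4]) / detA
  I
}

mat9_t9 <- function(A) A[, c(1, 4, 7, 2, 5, 8, 3, 6, 9), drop = FALSE]

mat9_mul <- function(A, B) {
  C <- matrix(0, nrow(A), 9)
  for (i in 1:3) for (j in 1:3)
    C[, m9(i, j)] <- A[, m9(i, 1)] * B[, m9(1, j)] +
      A[, m9(i, 2)] * B[, m9(2, j)] + A[, m9(i, 3)] * B[, m9(3, j)]
  C
}

# second Piola-Kirchhoff stress for all elements; S_A in Pa (active fiber
# tension, zero where NULL)
elem_pk2 <- function(model, F, SA = NULL) {
  ne <- model$ne
  C <- matrix(0, ne, 9)
  for (i in 1:3) for (j in 1:3)
    C[, m9(i, j)] <- F[, m9(1, i)] * F[, m9(1, j)] +
      F[, m9(2, i)] * F[, m9(2, j)] + F[, m9(3, i)] * F[, m9(3, j)]
  J2 <- mat9_det(C)
  if (any(J2 <= 0)) stop("element inversion (J <= 0) in elements ",
                         paste(utils::head(which(J2 <= 0), 3), collapse = ", "))
  J <- sqrt(J2)
  Ci <- mat9_inv(C, J2)
  S <- matrix(0, ne, 9)
  io <- which(model$mat$model == 1L)
  if (length(io)) {
    fr <- model$mesh$frame
    f <- fr$f0[io, , drop = FALSE]; s <- fr$s0[io, , drop = FALSE]
    n <- fr$n0[io, , drop = FALSE]
    E <- C[io, , drop = FALSE] / 2
    E[, c(1, 5, 9)] <- E[, c(1, 5, 9)] - 0.5
    quadE <- function(a, b) {
      out <- numeric(length(io))
      for (i in 1:3) for (j in 1:3)
        out <- out + a[, i] * E[, m9(i, j)] * b[, j]
      out
    }
    Eff <- quadE(f, f); Ess <- quadE(s, s); Enn <- quadE(n, n)
    Efs <- quadE(f, s); Efn <- quadE(f, n); Ens <- quadE(s, n)
    b <- model$b[io, , drop = FALSE]
    mu <- model$mat$mu[io]; al <- model$mat$alpha[io]
    kap <- model$mat$kappa[io]; lJ <- log(J[io])
    Q <- b[, "ff"] * Eff^2 + b[, "ss"] * Ess^2 + b[, "nn"] * Enn^2 +
      2 * (b[, "fs"] * Efs^2 + b[, "fn"] * Efn^2 + b[, "ns"] * Ens^2)
    coef <- mu * al * exp(pmin(Q * al, 60))
    cff <- coef * b[, "ff"] * Eff; css <- coef * b[, "ss"] * Ess
    cnn <- coef * b[, "nn"] * Enn; cfs <- coef * b[, "fs"] * Efs
    cfn <- coef * b[, "fn"] * Efn; cns <- coef * b[, "ns"] * Ens
    for (i in 1:3) for (j in 1:3)
      S[io, m9(i, j)] <- cff * f[, i] * f[, j] + css * s[, i] * s[, j] +
        cnn * n[, i] * n[, j] +
        cfs * (f[, i] * s[, j] + s[, i] * f[, j]) +
        cfn * (f[, i] * n[, j] + n[, i] * f[, j]) +
        cns * (s[, i] * n[, j] + n[, i] * s[, j]) +
        kap * lJ * Ci[io, m9(i, j)]
  }
  inh <- which(model$mat$model == 2L)
  if (length(inh)) {
    Cs <- C[inh, , drop = FALSE]
    trC <- Cs[, 1] + Cs[, 5] + Cs[, 9]
    Js <- J[inh]
    Jm23 <- Js^(-2 / 3)
    mu <- model$mat$mu[inh]; kap <- model$mat$kappa[inh]
    for (i in 1:3) for (j in 1:3)
      S[inh, m9(i, j)] <- mu * Jm23 *
        ((i == j) - trC / 3 * Ci[inh, m9(i, j)]) +
        kap * (Js - 1) * Js * Ci[inh, m9(i, j)]
  }
  if (!is.null(SA)) {
    fr <- model$mesh$frame$f0
    lamf2 <- numeric(ne)
    for (i in 1:3) {
      Ff <- F[, m9(i, 1)] * fr[, 1] + F[, m9(i, 2)] * fr[, 2] +
        F[, m9(i, 3)] * fr[, 3]
      lamf2 <- lamf2 + Ff^2
    }
    fac <- SA / sqrt(pmax(lamf2, 1e-12))
    for (i in 1:3) for (j in 1:3)
      S[, m9(i, j)] <- S[, m9(i, j)] + fac * fr[, i] * fr[, j]
  }
  S
}

# local (ne x 12) internal force from local displacement columns
elem_force_local <- function(model, Ulocal, SA = NULL) {
  ne <- model$ne; G <- model$sg$G
  F <- matrix(0, ne, 9); F[, c(1, 5, 9)] <- 1
  for (a in 1:4) for (i in 1:3) {
    ua <- Ulocal[, 3L * (a - 1L) + i]
    g <- G[[a]]
    F[, m9(i, 1)] <- F[, m9(i, 1)] + ua * g[, 1]
    F[, m9(i, 2)] <- F[, m9(i, 2)] + ua * g[, 2]
    F[, m9(i, 3)] <- F[, m9(i, 3)] + ua * g[, 3]
  }
  S <- elem_pk2(model, F, SA)
  P <- mat9_mul(F, S)
  out <- matrix(0, ne, 12)
  for (a in 1:4) {
    g <- G[[a]]
    for (i in 1:3)
      out[, 3L * (a - 1L) + i] <- model$sg$vol *
        (P[, m9(i, 1)] * g[, 1] + P[, m9(i, 2)] * g[, 2] +
         P[, m9(i, 3)] * g[, 3])
  }
  out
}

local_disp <- function(model, U) {
  t4 <- model$mesh$tets
  Ul <- matrix(0, model$ne, 12)
  for (a in 1:4) for (i in 1:3)
    Ul[, 3L * (a - 1L) + i] <- U[t4[, a], i]
  Ul
}

internal_force <- function(model, U, SA = NULL) {
  fl <- elem_force_local(model, local_disp(model, U), SA)
  t4 <- model$mesh$tets
  f <- matrix(0, model$nv, 3)
  for (a in 1:4) for (i in 1:3)
    f[, i] <- f[, i] + accum(t4[, a], fl[, 3L * (a - 1L) + i], model$nv)
  f
}

# follower pressure forces on the cavity surface; p in Pa
pressure_force <- function(model, U, p) {
  f <- matrix(0, model$nv, 3)
  if (is.null(model$cavity) || p == 0) return(f)
  tr <- model$cavity$tris
  x <- model$mesh$vertices + U
  e1 <- x[tr[, 2], , drop = FALSE] - x[tr[, 1], , drop = FALSE]
  e2 <- x[tr[, 3], , drop = FALSE] - x[tr[, 1], , drop = FALSE]
  nA <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]) / 2
  # stored endo triangles are oriented into the cavity; pressure pushes the
  # wall away from the cavity
  for (i in 1:3) {
    fi <- -p * nA[, i] / 3
    f[, i] <- f[, i] + accum(tr[, 1], fi, model$nv) +
      accum(tr[, 2], fi, model$nv) + accum(tr[, 3], fi, model$nv)
  }
  f
}

contact_force <- function(model, U) {
  f <- matrix(0, model$nv, 3)
  if (is.null(model$contact)) return(f)
  nodes <- which(model$epi_area > 0)
  x <- model$mesh$vertices[nodes, , drop = FALSE] + U[nodes, , drop = FALSE]
  gp <- gap(x, model$contact$surface, model$contact)
  mag <- model$contact$k_epi * gp$g * model$epi_area[nodes]
  f[nodes, ] <- mag * gp$dir
  f
}

spring_force <- function(model, U) {
  f <- matrix(0, model$nv, 3)
  if (!is.null(model$spring_nodes))
    f[model$spring_nodes, ] <- model$spring_k * U[model$spring_nodes, , drop = FALSE]
  f
}

#' Assemble the nodal force residual
#'
#' Residual of the discrete balance of momentum: internal + spring + contact
#' forces minus pressure loads, plus inertial (`M a`) and Rayleigh damping
#' (`D v`) terms when velocities/accelerations are supplied.  Dirichlet rows
#' are zeroed.
#'
#' @param model an `fe_model`
#' @param U displacement (nv x 3, mm)
#' @param p cavity pressure (Pa)
#' @param SA per-element active fiber tension (Pa), or NULL
#' @param V,A velocity / acceleration fields for the dynamic residual
#' @param damping precomputed Rayleigh damping operator (from
#'   [rayleigh_damping()])
#' @return nv x 3 residual (uN)
#' @export
assemble_residual <- function(model, U, p = 0, SA = NULL, V = NULL, A = NULL,
                              damping = NULL) {
  R <- internal_force(model, U, SA) + spring_force(model, U) +
    contact_force(model, U) - pressure_force(model, U, p)
  if (!is.null(A)) R <- R + model$M * A
  if (!is.null(V) && !is.null(damping))
    R <- R + matrix(damping %*% as.vector(t(V)), ncol = 3, byrow = TRUE)
  if (length(model$dirichlet)) R[model$dirichlet, ] <- 0
  R
}

# FD tangent of internal + pressure + spring + contact forces
assemble_tangent <- function(model, U, p = 0, SA = NULL, h = 1e-6) {
  ne <- model$ne; nv <- model$nv; t4 <- model$mesh$tets
  Ul <- local_disp(model, U)
  scale <- max(1, max(abs(U)))
  hh <- h * scale
  ii <- jj <- xx <- vector("list", 0)
  gdof <- function(a, i) 3L * (t4[, a] - 1L) + i
  for (d in 1:12) {
    Up <- Ul; Up[, d] <- Up[, d] + hh
    Um <- Ul; Um[, d] <- Um[, d] - hh
    dF <- (elem_force_local(model, Up, SA) -
             elem_force_local(model, Um, SA)) / (2 * hh)
    ad <- (d - 1L) %/% 3L + 1L; id <- (d - 1L) %% 3L + 1L
    jcol <- gdof(ad, id)
    for (a in 1:4) for (i in 1:3) {
      ii[[length(ii) + 1L]] <- gdof(a, i)
      jj[[length(jj) + 1L]] <- jcol
      xx[[length(xx) + 1L]] <- dF[, 3L * (a - 1L) + i]
    }
  }
  K <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                            dims = c(3 * nv, 3 * nv))
  if (!is.null(model$cavity) && p != 0)
    K <- K - pressure_tangent(model, U, p, hh)
  if (!is.null(model$spring_nodes)) {
    sd <- as.vector(outer(3L * (model$spring_nodes - 1L), 1:3, "+"))
    K <- K + Matrix::sparseMatrix(i = sd, j = sd, x = rep(model$spring_k,
                                                          length(sd)),
                                  dims = c(3 * nv, 3 * nv))
  }
  if (!is.null(model$contact)) K <- K + contact_tangent(model, U, hh)
  dir <- model$dirichlet
  if (length(dir)) {
    dd <- as.vector(outer(3L * (dir - 1L), 1:3, "+"))
    K[dd, ] <- 0; K[, dd] <- 0
    K <- K + Matrix::sparseMatrix(i = dd, j = dd, x = rep(1, length(dd)),
                                  dims = c(3 * nv, 3 * nv))
  }
  K
}

pressure_tangent <- function(model, U, p, hh) {
  tr <- model$cavity$tris
  nt <- nrow(tr); nv <- model$nv
  X <- model$mesh$vertices
  xl <- matrix(0, nt, 9)
  for (a in 1:3) for (i in 1:3)
    xl[, 3L * (a - 1L) + i] <- X[tr[, a], i] + U[tr[, a], i]
  tri_force <- function(xl) {
    e1 <- xl[, 4:6] - xl[, 1:3]; e2 <- xl[, 7:9] - xl[, 1:3]
    nA <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
                e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
                e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]) / 2
    cbind(-p * nA / 3, -p * nA / 3, -p * nA / 3)
  }
  ii <- jj <- xx <- vector("list", 0)
  gdof <- function(a, i) 3L * (tr[, a] - 1L) + i
  for (d in 1:9) {
    xp <- xl; xp[, d] <- xp[, d] + hh
    xm <- xl; xm[, d] <- xm[, d] - hh
    dF <- (tri_force(xp) - tri_force(xm)) / (2 * hh)
    ad <- (d - 1L) %/% 3L + 1L; id <- (d - 1L) %% 3L + 1L
    jcol <- gdof(ad, id)
    for (a in 1:3) for (i in 1:3) {
      ii[[length(ii) + 1L]] <- gdof(a, i)
      jj[[length(jj) + 1L]] <- jcol
      xx[[length(xx) + 1L]] <- dF[, 3L * (a - 1L) + i]
    }
  }
  Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                       dims = c(3 * nv, 3 * nv))
}

contact_tangent <- function(model, U, hh) {
  nodes <- which(model$epi_area > 0)
  nv <- model$nv
  X <- model$mesh$vertices[nodes, , drop = FALSE]
  fx <- function(x) {
    gp <- gap(x, model$contact$surface, model$contact)
    model$contact$k_epi * gp$g * model$epi_area[nodes] * gp$dir
  }
  x0 <- X + U[nodes, , drop = FALSE]
  ii <- jj <- xx <- vector("list", 0)
  for (d in 1:3) {
    xp <- x0; xp[, d] <- xp[, d] + hh
    xm <- x0; xm[, d] <- xm[, d] - hh
    dF <- (fx(xp) - fx(xm)) / (2 * hh)
    for (i in 1:3) {
      ii[[length(ii) + 1L]] <- 3L * (nodes - 1L) + i
      jj[[length(jj) + 1L]] <- 3L * (nodes - 1L) + d
      xx[[length(xx) + 1L]] <- dF[, i]
    }
  }
  Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                       dims = c(3 * nv, 3 * nv))
}

#' Rayleigh damping operator
#'
#' `D = alpha1 M + alpha2 K_ref` with the stiffness tangent frozen at the
#' reference configuration (keeping D constant over time).
#'
#' @param model an `fe_model`
#' @param alpha1 mass coefficient (1/ms); the physical 500 1/s is 0.5 1/ms
#' @param alpha2 stiffness coefficient (ms); 0.005 s is 5 ms
#' @return sparse damping matrix (3nv x 3nv)
#' @export
rayleigh_damping <- function(model, alpha1 = 0.5, alpha2 = 5) {
  K0 <- assemble_tangent(model, matrix(0, model$nv, 3))
  Mv <- rep(model$M, each = 3)
  alpha1 * Matrix::Diagonal(x = Mv) + alpha2 * K0
}

solve_free <- function(model, K, R) {
  as.numeric(Matrix::solve(K, as.vector(t(R))))
}

# Newton iteration for the (static or dynamic) residual; `resfun(U)` returns
# the residual, `tanfun(U)` the Jacobian.
newton_iterate <- function(model, U0, resfun, tanfun, tol = 1e-8,
                           maxit = 25, retangent_every = 1L) {
  U <- U0
  R <- resfun(U)
  nr0 <- sqrt(sum(R^2))
  if (nr0 < 1e-12) return(list(U = U, converged = TRUE, iters = 0, resid = nr0))
  K <- NULL
  nr <- nr0
  for (it in seq_len(maxit)) {
    if (is.null(K) || (it - 1L) %% retangent_every == 0L)
      K <- tryCatch(tanfun(U), error = function(e) NULL)
    if (is.null(K)) return(list(U = U, converged = FALSE, iters = it,
                                resid = nr))
    dU <- tryCatch(matrix(Matrix::solve(K, as.vector(t(R))), ncol = 3,
                          byrow = TRUE), error = function(e) NULL)
    if (is.null(dU)) return(list(U = U, converged = FALSE, iters = it,
                                 resid = nr))
    # Newton on this problem converges without enforcing monotone residual
    # decrease (pressure-loaded exponential materials overshoot transiently);
    # backtrack only on inadmissible trial states (element inversion) or
    # runaway residual growth
    step <- 1
    for (ls in 1:8) {
      Utry <- U - step * dU
      Rtry <- tryCatch(resfun(Utry), error = function(e) NULL)
      if (!is.null(Rtry) && all(is.finite(Rtry)) &&
          sqrt(sum(Rtry^2)) < 100 * nr) break
      step <- step / 2
      Rtry <- NULL
    }
    if (is.null(Rtry)) return(list(U = U, converged = FALSE, iters = it,
                                   resid = nr))
    U <- Utry; R <- Rtry
    nr <- sqrt(sum(R^2))
    if (nr < tol * max(nr0, 1) || nr < 1e-9)
      return(list(U = U, converged = TRUE, iters = it, resid = nr))
  }
  list(U = U, converged = nr < 1e-4 * max(nr0, 1), iters = maxit, resid = nr)
}

#' Static equilibrium at a given cavity pressure
#'
#' Newton's method with pressure continuation (load stepping).
#'
#' @param model an `fe_model`
#' @param p_mmHg cavity pressure (mmHg)
#' @param U0 initial displacement guess
#' @param nsteps number of load steps from the initial state
#' @param SA optional per-element active tension (Pa)
#' @param tol relative Newton tolerance
#' @return list with `U`, `converged`, `volume` (cavity volume, mL)
#' @export
static_solve <- function(model, p_mmHg, U0 = NULL, nsteps = 4, SA = NULL,
                         tol = 1e-8) {
  if (is.null(U0)) U0 <- matrix(0, model$nv, 3)
  U <- U0
  p_target <- p_mmHg * MMHG_PA
  p_cur <- attr(U0, "pressure")
  if (is.null(p_cur)) p_cur <- 0
  dp <- (p_target - p_cur) / nsteps
  dp_min <- abs(p_target - p_cur) / 512
  while (abs(p_target - p_cur) > 1e-12) {
    if (abs(dp) < 1e-12) break
    p_try <- if (abs(p_target - p_cur) <= abs(dp)) p_target else p_cur + dp
    out <- newton_iterate(model, U,
      resfun = function(UU) assemble_residual(model, UU, p = p_try, SA = SA),
      tanfun = function(UU) assemble_tangent(model, UU, p = p_try, SA = SA),
      tol = tol, retangent_every = 2L)
    if (out$converged) {
      U <- out$U
      p_cur <- p_try
      if (out$iters <= 6) dp <- dp * 1.5   # cheap step: grow the increment
    } else {
      dp <- dp / 2
      if (abs(dp) < dp_min)
        stop("static solve failed at p = ", signif(p_try / MMHG_PA, 4),
             " mmHg (load increment underflow)")
    }
  }
  # re-equilibrate at the target even when the warm start already carries it
  # (the model geometry or active tension may have changed)
  out <- newton_iterate(model, U,
    resfun = function(UU) assemble_residual(model, UU, p = p_target, SA = SA),
    tanfun = function(UU) assemble_tangent(model, UU, p = p_target, SA = SA),
    tol = tol, maxit = 40, retangent_every = 1L)
  if (!out$converged) {
    # warm start too far off (e.g. after a geometry update): restart cold
    U0c <- matrix(0, model$nv, 3)
    return(static_solve(model, p_mmHg, U0 = U0c, nsteps = max(nsteps, 6),
                        SA = SA, tol = tol))
  }
  U <- out$U
  attr(U, "pressure") <- p_target
  list(U = U, converged = TRUE,
       volume = cavity_volume(model, U))
}

#' Cavity volume by the divergence theorem
#'
#' The endocardial surface is closed with centroid fans over each opening
#' rim (annulus, ostia) and the enclosed volume evaluated from the surface
#' integral of `x . n`.
#'
#' @param model an `fe_model` (with a cavity) or `labeled_mesh`
#' @param U displacement field (default zero)
#' @return volume in mL (1 mL = 1000 mm^3)
#' @export
cavity_volume <- function(model, U = NULL) {
  if (inherits(model, "labeled_mesh")) model <- fe_model(model)
  if (is.null(model$cavity)) return(NA_real_)
  if (is.null(U)) U <- matrix(0, model$nv, 3)
  x <- model$mesh$vertices + U
  tr <- model$cavity$tris
  vol6 <- sum(x[tr[, 1], 1] * (x[tr[, 2], 2] * x[tr[, 3], 3] -
                               x[tr[, 2], 3] * x[tr[, 3], 2]) +
              x[tr[, 1], 2] * (x[tr[, 2], 3] * x[tr[, 3], 1] -
                               x[tr[, 2], 1] * x[tr[, 3], 3]) +
              x[tr[, 1], 3] * (x[tr[, 2], 1] * x[tr[, 3], 2] -
                               x[tr[, 2], 2] * x[tr[, 3], 1]))
  for (rim in model$cavity$rims) {
    rim <- rim[rim <= model$nv]
    if (length(rim) < 3) next
    ctr <- colMeans(x[rim, , drop = FALSE])
    k2 <- c(seq_along(rim)[-1], 1)
    a <- x[rim, , drop = FALSE]; bmat <- x[rim[k2], , drop = FALSE]
    vol6 <- vol6 + sum(ctr[1] * (a[, 2] * bmat[, 3] - a[, 3] * bmat[, 2]) +
                       ctr[2] * (a[, 3] * bmat[, 1] - a[, 1] * bmat[, 3]) +
                       ctr[3] * (a[, 1] * bmat[, 2] - a[, 2] * bmat[, 1]))
  }
  abs(vol6) / 6 / 1000
}

#' Newmark time-integration parameters
#'
#' @param beta,gamma Newmark parameters (default 0.3 and 0.6, numerically
#'   dissipative)
#' @param dt time step (ms)
#' @param alpha1,alpha2 Rayleigh damping coefficients (1/ms, ms)
#' @return a `dynamics_spec`
#' @export
dynamics_spec <- function(beta = 0.3, gamma = 0.6, dt = 1,
                          alpha1 = 0.5, alpha2 = 5) {
  if (dt <= 0) stop("dt must be positive")
  structure(list(beta = beta, gamma = gamma, dt = dt,
                 alpha1 = alpha1, alpha2 = alpha2), class = "dynamics_spec")
}

#' One implicit Newmark step
#'
#' Solves the nonlinear balance of momentum at `t + dt` for the displacement
#' with Newton's method; velocity and acceleration are reconstructed from
#' the Newmark update formulas.
#'
#' @param model an `fe_model`
#' @param state list with `U`, `V`, `A` (nv x 3 each)
#' @param spec a [dynamics_spec()]
#' @param p cavity pressure (Pa) at the new time
#' @param SA active tension (Pa per element) at the new time
#' @param damping Rayleigh damping matrix (precompute with
#'   [rayleigh_damping()])
#' @return updated state list
#' @export
newmark_step <- function(model, state, spec, p = 0, SA = NULL,
                         damping = NULL) {
  dt <- spec$dt; beta <- spec$beta; gam <- spec$gamma
  U0 <- state$U; V0 <- state$V; A0 <- state$A
  pred <- U0 + dt * V0 + (0.5 - beta) * dt^2 * A0
  acc <- function(U) (U - pred) / (beta * dt^2)
  vel <- function(U) V0 + (1 - gam) * dt * A0 + gam * dt * acc(U)
  if (is.null(damping)) damping <- rayleigh_damping(model, spec$alpha1, spec$alpha2)
  resf <- function(U) assemble_residual(model, U, p = p, SA = SA,
                                        V = vel(U), A = acc(U),
                                        damping = damping)
  tanf <- function(U) {
    K <- assemble_tangent(model, U, p = p, SA = SA)
    Kdyn <- K + Matrix::Diagonal(x = rep(model$M, each = 3) /
                                   (beta * dt^2)) + (gam / (beta * dt)) * damping
    dir <- model$dirichlet
    if (length(dir)) {
      dd <- as.vector(outer(3L * (dir - 1L), 1:3, "+"))
      Kdyn[dd, ] <- 0; Kdyn[, dd] <- 0
      Kdyn <- Kdyn + Matrix::sparseMatrix(i = dd, j = dd,
                                          x = rep(1, length(dd)),
                                          dims = dim(Kdyn))
    }
    Kdyn
  }
  out <- newton_iterate(model, U0, resf, tanf, retangent_every = 3L)
  if (!out$converged) stop("Newmark step did not converge (residual ",
                           signif(out$resid, 3), ")")
  U <- out$U
  list(U = U, V = vel(U), A = acc(U))
}
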