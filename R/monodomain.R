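# ---------------------------------------------------------------------------
# Monodomain tissue electrophysiology: reaction-diffusion of the
# transmembrane voltage with the anisotropic conductivity tensor
#   sigma(x) = sigma_f f0xf0 + sigma_s s0xs0 + sigma_n n0xn0,
# solved with first-order operator splitting: explicit (Rush-Larsen hybrid)
# reaction step per node, implicit (backward Euler) diffusion step, linear
# tetrahedral finite elements with lumped mass, homogeneous Neumann
# boundaries.  Units: mV, ms, mm; conductivities in S/m.
# ---------------------------------------------------------------------------

# Surface-to-volume ratio (1/m) and membrane capacitance (F/m^2).  Only the
# product beta*Cm matters for propagation: it converts conductivity into a
# voltage diffusivity, and conduction-velocity tuning absorbs its value.
ep_beta_cm <- function() 1400   # (1/m) * (F/m^2) = F/m^3

#' Anisotropic conductivity field
#'
#' @param mesh a `labeled_mesh` with frames
#' @param sigma_f,sigma_s,sigma_n conductivities along fiber, sheet and
#'   sheet-normal directions (S/m); must satisfy
#'   `sigma_f >= sigma_s >= sigma_n >= 0`
#' @param scar_mask logical element mask where conductivity is set to zero
#'   (perfectly isolating ablation scar)
#' @param fast_layer_mask logical element mask of the fast endocardial layer;
#'   conductivity there is multiplied by `fast_factor`
#' @param fast_factor conductivity multiplier in the fast layer (4 doubles
#'   the local conduction velocity)
#' @return a `conductivity_field`
#' @export
conductivity_field <- function(mesh, sigma_f, sigma_s = sigma_f,
                               sigma_n = sigma_s, scar_mask = NULL,
                               fast_layer_mask = NULL, fast_factor = 4) {
  if (!(sigma_f >= sigma_s && sigma_s >= sigma_n && sigma_n >= 0))
    stop("require sigma_f >= sigma_s >= sigma_n >= 0")
  ne <- n_elements(mesh)
  sf <- rep(sigma_f, ne); ss <- rep(sigma_s, ne); sn <- rep(sigma_n, ne)
  if (!is.null(fast_layer_mask)) {
    sf[fast_layer_mask] <- sf[fast_layer_mask] * fast_factor
    ss[fast_layer_mask] <- ss[fast_layer_mask] * fast_factor
    sn[fast_layer_mask] <- sn[fast_layer_mask] * fast_factor
  }
  if (!is.null(scar_mask)) { sf[scar_mask] <- 0; ss[scar_mask] <- 0; sn[scar_mask] <- 0 }
  structure(list(sigma_f = sf, sigma_s = ss, sigma_n = sn,
                 scar_mask = if (is.null(scar_mask)) rep(FALSE, ne) else scar_mask),
            class = "conductivity_field")
}

# Gradients of the linear shape functions, vectorized: returns list of
# G[[a]] (ne x 3) with grad N_a, plus element volumes.
tet_shape_grads <- function(mesh) {
  v <- mesh$vertices; t4 <- mesh$tets
  x1 <- v[t4[, 1], , drop = FALSE]; x2 <- v[t4[, 2], , drop = FALSE]
  x3 <- v[t4[, 3], , drop = FALSE]; x4 <- v[t4[, 4], , drop = FALSE]
  e1 <- x2 - x1; e2 <- x3 - x1; e3 <- x4 - x1
  # rows of inverse Jacobian via cross products
  c23 <- cbind(e2[, 2] * e3[, 3] - e2[, 3] * e3[, 2],
               e2[, 3] * e3[, 1] - e2[, 1] * e3[, 3],
               e2[, 1] * e3[, 2] - e2[, 2] * e3[, 1])
  c31 <- cbind(e3[, 2] * e1[, 3] - e3[, 3] * e1[, 2],
               e3[, 3] * e1[, 1] - e3[, 1] * e1[, 3],
               e3[, 1] * e1[, 2] - e3[, 2] * e1[, 1])
  c12 <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
               e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
               e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  det6 <- rowSums(e1 * c23)   # 6 * volume
  g2 <- c23 / det6; g3 <- c31 / det6; g4 <- c12 / det6
  g1 <- -(g2 + g3 + g4)
  list(G = list(g1, g2, g3, g4), vol = det6 / 6)
}

# Per-element 3x3 diffusivity tensors (mm^2/ms) flattened to ne x 9.
element_diffusivity <- function(mesh, cond) {
  # sigma [S/m] / (beta*Cm) [F/m^3] = m^2/s = 1e3 mm^2/ms / 1e3 ... -> see below
  # 1 m^2/s = 1e6 mm^2 / 1e3 ms = 1e3 mm^2/ms
  sc <- 1e3 / ep_beta_cm()
  fr <- mesh$frame
  D <- matrix(0, n_elements(mesh), 9)
  for (k in 1:3) {
    a <- list(fr$f0, fr$s0, fr$n0)[[k]]
    s <- list(cond$sigma_f, cond$sigma_s, cond$sigma_n)[[k]] * sc
    D <- D + s * cbind(a[, 1] * a[, 1], a[, 1] * a[, 2], a[, 1] * a[, 3],
                       a[, 2] * a[, 1], a[, 2] * a[, 2], a[, 2] * a[, 3],
                       a[, 3] * a[, 1], a[, 3] * a[, 2], a[, 3] * a[, 3])
  }
  D
}

assemble_diffusion <- function(mesh, cond) {
  sg <- tet_shape_grads(mesh)
  D <- element_diffusivity(mesh, cond)
  ne <- n_elements(mesh); nv <- n_vertices(mesh)
  ii <- jj <- xx <- vector("list", 16)
  idx <- 1L
  DG <- vector("list", 4)
  for (b in 1:4) {
    g <- sg$G[[b]]
    DG[[b]] <- cbind(D[, 1] * g[, 1] + D[, 2] * g[, 2] + D[, 3] * g[, 3],
                     D[, 4] * g[, 1] + D[, 5] * g[, 2] + D[, 6] * g[, 3],
                     D[, 7] * g[, 1] + D[, 8] * g[, 2] + D[, 9] * g[, 3])
  }
  for (a in 1:4) for (b in 1:4) {
    ii[[idx]] <- mesh$tets[, a]
    jj[[idx]] <- mesh$tets[, b]
    xx[[idx]] <- sg$vol * rowSums(sg$G[[a]] * DG[[b]])
    idx <- idx + 1L
  }
  K <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                            dims = c(nv, nv))
  M <- as.numeric(Matrix::sparseMatrix(i = unlist(lapply(1:4, function(a) mesh$tets[, a])),
                                       j = rep(1L, 4L * ne),
                                       x = rep(sg$vol / 4, 4),
                                       dims = c(nv, 1)))
  list(K = Matrix::forceSymmetric((K + Matrix::t(K)) / 2), M = M)
}

#' Stimulation protocol
#'
#' A set of stimulus sites, each a vertex set with an onset time.  The
#' default left-atrial protocol stimulates the interatrial entry-site
#' landmarks with physiologically motivated delays relative to the sinus
#' stimulus (Bachmann-bundle breakthrough at 29 ms); ventricular fixtures use
#' root sites placed by normalized coordinates with radial extent
#' `delta_rad` and transmural extent `delta_m`.
#'
#' @param sites list of `list(vertices=, t0=, duration=, amplitude=)`
#' @param av_delay atrioventricular stimulation delay (ms)
#' @param delta_rad,delta_m radial (mm) / transmural extents for root sites
#' @return a `stimulus_protocol`
#' @export
stimulus_protocol <- function(sites, av_delay = 160, delta_rad = 3,
                              delta_m = 0.05) {
  if (av_delay < 0) stop("AV delay must be nonnegative")
  structure(list(sites = sites, av_delay = av_delay,
                 delta_rad = delta_rad, delta_m = delta_m),
            class = "stimulus_protocol")
}

#' Default sinus-rhythm stimulation of the LA shell
#'
#' @param mesh LA shell mesh
#' @param delays named onset delays (ms) for the entry-site landmarks
#' @param amplitude,duration stimulus strength (uA/uF) and length (ms)
#' @return a `stimulus_protocol`
#' @export
la_sinus_protocol <- function(mesh,
                              delays = c(bachmann = 29, posterior_sup = 36,
                                         posterior_mid = 40,
                                         coronary_sinus = 50),
                              amplitude = 40, duration = 2) {
  sites <- lapply(names(delays), function(nm) {
    vs <- mesh$landmarks_v[[nm]]
    if (is.null(vs)) stop("missing landmark set: ", nm)
    list(vertices = vs, t0 = unname(delays[[nm]]), duration = duration,
         amplitude = amplitude)
  })
  stimulus_protocol(sites)
}

#' Solve the monodomain equation on a mesh
#'
#' First-order operator splitting: per-node explicit reaction step (hybrid
#' Rush-Larsen for gating variables) followed by an implicit backward-Euler
#' diffusion solve with a pre-factorized sparse system.  Scar elements have
#' zero conductivity and their interior nodes are excluded from stimulation.
#'
#' @param mesh `labeled_mesh` with frames
#' @param cond a [conductivity_field()]
#' @param stim a [stimulus_protocol()]
#' @param duration simulated time (ms)
#' @param dt time step (ms); default 0.01 ms
#' @param cell "courtemanche" or "surrogate"
#' @param init optional limit-cycle single-cell state used at every node
#' @param sample_dt voltage sampling cadence (ms, <= 1 ms for activation maps)
#' @return an `ep_solution` with the sampled voltage history
#' @export
solve_monodomain <- function(mesh, cond, stim, duration, dt = 0.01,
                             cell = "courtemanche", init = NULL,
                             sample_dt = 1) {
  mdl <- cell_model(cell)
  nv <- n_vertices(mesh)
  asm <- assemble_diffusion(mesh, cond)
  A <- Matrix::Diagonal(x = asm$M) + dt * asm$K
  ch <- Matrix::Cholesky(Matrix::forceSymmetric(A), LDL = FALSE)
  y0 <- if (is.null(init)) mdl$init else init
  S <- matrix(rep(y0, each = nv), nv, length(y0),
              dimnames = list(NULL, names(y0)))
  # nodes interior to the scar (touching no conducting element) are not
  # stimulated and stay at rest
  scar_nodes <- setdiff(unique(as.vector(mesh$tets[cond$scar_mask, ])),
                        unique(as.vector(mesh$tets[!cond$scar_mask, ])))
  nstep <- as.integer(round(duration / dt))
  every <- max(1L, as.integer(round(sample_dt / dt)))
  nsamp <- nstep %/% every + 1L
  Vh <- matrix(NA_real_, nv, nsamp)
  Vh[, 1] <- S[, "V"]
  tsamp <- numeric(nsamp); tsamp[1] <- 0
  si <- 1L
  site_nodes <- lapply(stim$sites, function(s) setdiff(s$vertices, scar_nodes))
  # once every node outside the scar interior has crossed the activation
  # threshold the map is complete and the simulation can stop early
  crossed <- rep(FALSE, nv)
  crossed[scar_nodes] <- TRUE
  last_stim <- max(vapply(stim$sites, function(s) s$t0 + s$duration, 0))
  for (k in seq_len(nstep)) {
    t0 <- (k - 1) * dt
    I_ext <- numeric(nv)
    for (j in seq_along(stim$sites)) {
      s <- stim$sites[[j]]
      if (t0 >= s$t0 && t0 < s$t0 + s$duration)
        I_ext[site_nodes[[j]]] <- I_ext[site_nodes[[j]]] + s$amplitude
    }
    st <- mdl$step(S, dt)
    S <- st$S
    Vstar <- S[, "V"] + dt * (-st$I_ion + I_ext)
    Vnew <- as.numeric(Matrix::solve(ch, asm$M * Vstar, system = "A"))
    S[, "V"] <- Vnew
    if (any(!is.finite(Vnew))) stop("NaN in monodomain state at t = ", t0)
    if (k %% every == 0L) {
      si <- si + 1L
      Vh[, si] <- Vnew
      tsamp[si] <- k * dt
      crossed <- crossed | Vnew >= -20
      if (all(crossed) && k * dt > last_stim + 10) break
    }
  }
  sol <- structure(list(times = tsamp[1:si], Vm = Vh[, 1:si, drop = FALSE],
                        dt = dt, cell = cell, scar_mask = cond$scar_mask,
                        mesh_n = c(nv = nv, ne = n_elements(mesh))),
                   class = "ep_solution")
  am <- activation_map(sol)
  sol$t_A <- am$t_A
  sol$inactive_mask <- am$inactive_mask
  sol$total_activation_time <- am$total_activation_time
  sol
}

#' Activation-time map from a sampled voltage history
#'
#' The local activation time is the first upward crossing of the -20 mV
#' threshold, linearly interpolated between samples; nodes that never cross
#' are marked inactive.
#'
#' @param sol an `ep_solution` (or a list with `times` and `Vm`)
#' @param threshold activation threshold (mV)
#' @return list with `t_A` (ms, NA where inactive), `inactive_mask`, and
#'   `total_activation_time` (ms, over activated nodes)
#' @export
activation_map <- function(sol, threshold = -20) {
  V <- sol$Vm; tt <- sol$times
  nv <- nrow(V)
  t_A <- rep(NA_real_, nv)
  alive <- rep(TRUE, nv)
  for (k in seq_len(ncol(V) - 1L)) {
    cross <- alive & V[, k] < threshold & V[, k + 1L] >= threshold
    if (any(cross)) {
      frac <- (threshold - V[cross, k]) / (V[cross, k + 1L] - V[cross, k])
      t_A[cross] <- tt[k] + frac * (tt[k + 1L] - tt[k])
      alive[cross] <- FALSE
    }
  }
  start_above <- V[, 1] >= threshold
  t_A[start_above] <- tt[1]
  list(t_A = t_A, inactive_mask = is.na(t_A),
       total_activation_time = if (all(is.na(t_A))) NA_real_ else
         max(t_A, na.rm = TRUE))
}

#' Conduction velocity from a planar-wave activation map
#'
#' Least-squares slope of distance along `axis` versus activation time over
#' the probe nodes, restricted to the central part of the fixture to avoid
#' boundary effects.
#'
#' @param sol `ep_solution` with activation map
#' @param mesh the mesh the solution lives on
#' @param axis propagation direction (3-vector)
#' @param probe vertex indices to use (default: the cable `probe` landmark)
#' @param trim fraction trimmed at both ends of the probe range
#' @return conduction velocity in m/s (mm/ms)
#' @export
measure_cv <- function(sol, mesh, axis = c(1, 0, 0), probe = NULL,
                       trim = 0.2) {
  if (is.null(probe)) probe <- mesh$landmarks_v$probe
  if (is.null(probe)) probe <- seq_len(n_vertices(mesh))
  x <- as.numeric(mesh$vertices[probe, , drop = FALSE] %*%
                    (axis / sqrt(sum(axis^2))))
  tA <- sol$t_A[probe]
  rng <- range(x)
  keep <- x >= rng[1] + trim * diff(rng) & x <= rng[2] - trim * diff(rng)
  x <- x[keep]; tA <- tA[keep]
  ok <- !is.na(tA)
  if (sum(ok) < 3) stop("fewer than 3 activated probe nodes")
  fit <- lm(x[ok] ~ tA[ok])
  unname(coef(fit)[2])   # mm/ms = m/s
}

#' Tune a conductivity to a target conduction velocity
#'
#' Direct root finding on the cable fixture: the conductivity is adjusted
#' until the measured planar-wave velocity matches the target.  The monodomain
#' scaling CV proportional to sqrt(sigma) provides the initial bracket.
#'
#' @param target_cv target velocity (m/s)
#' @param fixture list with cable `length` (mm), `resolution` (mm),
#'   `dt` (ms), `cell`, and optionally `init` state
#' @param tol relative tolerance on the achieved velocity
#' @return list with `sigma` (S/m), `achieved_cv`, and the evaluation `trace`
#' @export
tune_conductivity <- function(target_cv,
                              fixture = list(length = 20, resolution = 0.25,
                                             dt = 0.01, cell = "surrogate"),
                              tol = 0.02) {
  if (target_cv <= 0) stop("target conduction velocity must be positive")
  trace <- data.frame(sigma = numeric(0), cv = numeric(0))
  cvf <- function(sigma) {
    # a wave that fails to traverse the fixture counts as arbitrarily slow
    cv <- tryCatch(cable_cv(sigma, fixture), error = function(e) 0)
    trace[nrow(trace) + 1L, ] <<- c(sigma, cv)
    cv
  }
  sig0 <- 0.2
  cv0 <- cvf(sig0)
  sig_guess <- sig0 * (target_cv / cv0)^2
  lo <- sig_guess / 2; hi <- sig_guess * 2
  flo <- cvf(lo) - target_cv
  fhi <- cvf(hi) - target_cv
  it <- 0
  while (flo > 0 && it < 8) { lo <- lo / 2; flo <- cvf(lo) - target_cv; it <- it + 1 }
  while (fhi < 0 && it < 16) { hi <- hi * 2; fhi <- cvf(hi) - target_cv; it <- it + 1 }
  if (flo > 0 || fhi < 0) stop("target conduction velocity not bracketable")
  r <- uniroot(function(s) cvf(s) - target_cv, c(lo, hi),
               tol = sig_guess * 1e-3)
  achieved <- cvf(r$root)
  if (abs(achieved - target_cv) > tol * target_cv)
    warning("achieved CV misses target by more than ", 100 * tol, "%")
  list(sigma = r$root, achieved_cv = achieved, trace = trace)
}

#' Planar-wave conduction velocity on the cable fixture
#'
#' @param sigma conductivity along the propagation axis (S/m)
#' @param fixture cable fixture spec (see [tune_conductivity()])
#' @return measured velocity (m/s)
#' @export
cable_cv <- function(sigma, fixture = list(length = 20, resolution = 0.25,
                                           dt = 0.01, cell = "surrogate")) {
  cab <- make_cable(fixture$length, fixture$resolution)
  dir <- if (is.null(fixture$direction)) "fiber" else fixture$direction
  if (dir == "sheet") {
    # rotate the frame so propagation along the cable runs in the sheet
    # direction; the fiber direction (kept faster) lies across the strand
    ne <- n_elements(cab)
    f0 <- matrix(rep(c(0, 1, 0), each = ne), ne, 3)
    s0 <- matrix(rep(c(1, 0, 0), each = ne), ne, 3)
    cab$frame <- orthonormalize_frame(f0, s0)
    cond <- conductivity_field(cab, sigma_f = 4 * sigma, sigma_s = sigma,
                               sigma_n = sigma)
  } else {
    cond <- conductivity_field(cab, sigma_f = sigma, sigma_s = sigma / 4,
                               sigma_n = sigma / 4)
  }
  # stimulate a short end segment: a few-node point source fails to capture
  # at high conductivity (source-sink mismatch)
  seg <- which(cab$vertices[, 1] <= max(1, 4 * fixture$resolution))
  stim <- stimulus_protocol(list(list(vertices = seg, t0 = 0, duration = 2,
                                      amplitude = 80)))
  cell <- if (is.null(fixture$cell)) "surrogate" else fixture$cell
  # generous upper bound on the transit time at slow velocities
  dur <- min(200, 15 + fixture$length / 0.12)
  sol <- solve_monodomain(cab, cond, stim, duration = dur,
                          dt = if (is.null(fixture$dt)) 0.01 else fixture$dt,
                          cell = cell, init = fixture$init, sample_dt = 0.5)
  measure_cv(sol, cab, axis = c(1, 0, 0))
}

#' Inactive-tissue fraction
#'
#' Percentage of left-atrial myocardial volume that never activates,
#' including the scar itself and any tissue it electrically isolates.
#' An element counts as inactive when it is scar or when at least half of
#' its vertices never cross the activation threshold.
#'
#' @param sol `ep_solution`
#' @param mesh the mesh the solution lives on
#' @return percentage in [0, 100]
#' @export
inactive_fraction <- function(sol, mesh) {
  myo <- mesh$region == "LA"
  vol <- abs(tet_volumes(mesh))
  node_inactive <- sol$inactive_mask
  frac <- (node_inactive[mesh$tets[, 1]] + node_inactive[mesh$tets[, 2]] +
           node_inactive[mesh$tets[, 3]] + node_inactive[mesh$tets[, 4]]) / 4
  elem_inactive <- sol$scar_mask | frac >= 0.5
  100 * sum(vol[elem_inactive & myo]) / sum(vol[myo])
}

#' @export
print.ep_solution <- function(x, ...) {
  cat("ep_solution:", x$mesh_n["nv"], "nodes,", length(x$times), "samples to",
      max(x$times), "ms (cell:", x$cell, ")\n")
  cat("  total activation time:", round(x$total_activation_time, 1), "ms;",
      sum(x$inactive_mask), "nodes never activated\n")
  invisible(x)
}
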