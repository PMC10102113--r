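frame_id <- list(f0 = c(1, 0, 0), s0 = c(0, 1, 0), n0 = c(0, 0, 1))

test_that("strain energy vanishes in the reference state for both models", {
  expect_equal(strain_energy(matrix(0, 3, 3), 1, material_params("myocardium")), 0)
  expect_equal(strain_energy(matrix(0, 3, 3), 1, material_params("vessel")), 0)
  expect_error(strain_energy(matrix(0, 3, 3), -1, material_params("vessel")),
               "positive")
})

test_that("scar material is isotropized and exactly (2 mu, 5 alpha)", {
  myo <- material_params("myocardium")
  sc <- material_params("scar")
  expect_equal(sc$mu, 2 * myo$mu)
  expect_equal(sc$mu, 651.12)
  expect_equal(sc$alpha, 5 * myo$alpha)
  expect_equal(sc$alpha, 110)
  expect_equal(unname(sc$b), c(1, 1, 1, 0.5, 0.5, 0.5))
  # energy invariant under relabeling of the frame axes
  set.seed(3)
  E <- crossprod(matrix(rnorm(9, sd = 0.1), 3, 3)) - diag(3) * 0.01
  E <- (E + t(E)) / 2
  J <- sqrt(det(2 * E + diag(3)))
  perms <- list(c(1, 2, 3), c(2, 3, 1), c(3, 1, 2), c(2, 1, 3))
  vals <- vapply(perms, function(p)
    strain_energy(E[p, p], J, sc), numeric(1))
  expect_lt(diff(range(vals)), 1e-10 * abs(vals[1]))
})

test_that("analytic passive stress matches central differences of the energy", {
  set.seed(11)
  F <- diag(3) + matrix(rnorm(9, sd = 0.06), 3, 3)
  C <- t(F) %*% F; E <- (C - diag(3)) / 2
  h <- 1e-6
  for (tissue in c("myocardium", "scar", "vessel")) {
    pm <- material_params(tissue)
    S <- pk2_stress(F, frame_id, pm)
    expect_equal(S, t(S), tolerance = 1e-12)
    Sfd <- matrix(0, 3, 3)
    for (i in 1:3) for (j in 1:3) {
      dE <- matrix(0, 3, 3)
      dE[i, j] <- dE[i, j] + h / 2; dE[j, i] <- dE[j, i] + h / 2
      Jp <- sqrt(det(2 * (E + dE) + diag(3)))
      Jm <- sqrt(det(2 * (E - dE) + diag(3)))
      Sfd[i, j] <- (strain_energy(E + dE, Jp, pm) -
                      strain_energy(E - dE, Jm, pm)) / (2 * h)
    }
    expect_lt(max(abs(S - Sfd)) / max(abs(S)), 1e-6)
  }
  expect_equal(pk2_stress(diag(3), frame_id, material_params("myocardium")),
               matrix(0, 3, 3))
})

test_that("fiber stretch is stiffer than sheet stretch (b_ff > b_ss)", {
  pm <- material_params("myocardium")
  lam <- 1.15
  Ff <- diag(c(lam, 1, 1)); Fs <- diag(c(1, lam, 1))
  Sf <- pk2_stress(Ff, frame_id, pm)[1, 1]
  Ss <- pk2_stress(Fs, frame_id, pm)[2, 2]
  expect_gt(Sf, Ss)
})

test_that("energy and stress norm are objective under rigid rotations", {
  set.seed(5)
  F <- diag(3) + matrix(rnorm(9, sd = 0.05), 3, 3)
  th <- 0.7
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  pm <- material_params("myocardium")
  S1 <- pk2_stress(F, frame_id, pm)
  S2 <- pk2_stress(R %*% F, frame_id, pm)
  expect_lt(max(abs(S1 - S2)), 1e-9 * max(abs(S1)))
})

test_that("the contact gap function matches its three branches and is continuous", {
  spec <- contact_spec(list(type = "plane", point = c(0, 0, 0),
                            normal = c(0, 0, 1)))
  gat <- function(z) gap(c(0, 0, z), spec$surface, spec)$g
  expect_equal(gat(0.1), 0.05)            # both branches agree at d
  expect_equal(gat(0.1 - 1e-9), 0.05, tolerance = 1e-7)
  expect_equal(gat(0.2), 0.15)            # linear branch: 0.2 - 0.1/2
  expect_equal(gat(8.1), 0)               # beyond d_M contact releases
  expect_equal(gat(0.05), 0.05^2 / 0.2)   # quadratic branch
  expect_error(contact_spec(list(type = "plane"), d = 2, d_M = 1), "d < d_M")
})

test_that("contact forces vanish identically when all gaps exceed d_M", {
  sh <- fix_small_shell()
  # target sphere far beyond d_M = 8 mm from the shell (outer radius 9 mm)
  ct <- contact_spec(list(type = "sphere", center = c(0, 0, 0), radius = 30))
  mod <- fe_model(sh, spring_nodes = seq_len(n_vertices(sh)), spring_k = 1,
                  contact = ct)
  f <- ablamech:::contact_force(mod, matrix(0, mod$nv, 3))
  expect_equal(max(abs(f)), 0)
  # bring the target within reach: forces appear
  ct2 <- contact_spec(list(type = "sphere", center = c(0, 0, 0), radius = 12))
  mod2 <- fe_model(sh, spring_nodes = seq_len(n_vertices(sh)), spring_k = 1,
                   contact = ct2)
  f2 <- ablamech:::contact_force(mod2, matrix(0, mod2$nv, 3))
  expect_gt(max(abs(f2)), 0)
})

test_that("the residual vanishes at the reference state and pressure balances on a closed cavity", {
  sh <- fix_small_shell()
  mod <- fe_model(sh, spring_nodes = integer(0))
  U0 <- matrix(0, mod$nv, 3)
  expect_equal(max(abs(assemble_residual(mod, U0))), 0)
  # rigid translation: net pressure force on the closed surface is zero
  U <- matrix(rep(c(1, -2, 0.5), each = mod$nv), mod$nv, 3)
  fp <- ablamech:::pressure_force(mod, U, 1000)
  expect_lt(max(abs(colSums(fp))), 1e-8)
})

test_that("the assembled tangent matches finite differences of the residual", {
  sl <- make_slab(2, 1, 1, nx = 2, ny = 1, nz = 1)
  mod <- fe_model(sl, spring_nodes = integer(0),
                  dirichlet = which(sl$vertices[, 1] < 1e-9))
  set.seed(1)
  U <- matrix(rnorm(3 * mod$nv, sd = 0.02), mod$nv, 3)
  U[mod$dirichlet, ] <- 0
  K <- assemble_tangent(mod, U)
  h <- 1e-6
  for (d in c(10, 14, 17, 21)) {
    node <- (d - 1) %/% 3 + 1; comp <- (d - 1) %% 3 + 1
    if (node %in% mod$dirichlet) next
    Up <- U; Up[node, comp] <- Up[node, comp] + h
    Um <- U; Um[node, comp] <- Um[node, comp] - h
    fd <- (as.vector(t(assemble_residual(mod, Up))) -
             as.vector(t(assemble_residual(mod, Um)))) / (2 * h)
    expect_lt(max(abs(fd - K[, d])) / max(1, max(abs(fd))), 1e-5)
  }
})

test_that("inflation is monotone, near-incompressible, and Newmark relaxes to the static state", {
  sh <- fix_small_shell()
  mod <- fe_model(sh, spring_nodes = seq_len(n_vertices(sh)), spring_k = 1)
  v0 <- cavity_volume(mod)
  s4 <- static_solve(mod, 4, nsteps = 3)
  expect_gt(s4$volume, v0)
  s8 <- static_solve(mod, 8, U0 = s4$U, nsteps = 2)
  expect_gt(s8$volume, s4$volume)
  # near-incompressibility: |J - 1| small at the inflated state
  F <- ablamech:::elem_defgrad(mod, s8$U)
  J <- sqrt(ablamech:::mat9_det(
    ablamech:::mat9_mul(ablamech:::mat9_t9(F), F)))
  expect_lt(max(abs(J - 1)), 0.05)
  # Newmark with damping: ramping the pressure 4 -> 8 mmHg dynamically
  # settles onto the static 8 mmHg solution
  spec <- dynamics_spec(dt = 1)
  damping <- rayleigh_damping(mod, spec$alpha1, spec$alpha2)
  st <- list(U = s4$U, V = matrix(0, mod$nv, 3), A = matrix(0, mod$nv, 3))
  p4 <- 4 * ablamech:::MMHG_PA; p8 <- 8 * ablamech:::MMHG_PA
  for (k in 1:80) {
    p <- p4 + (p8 - p4) * min(1, k / 30)
    st <- newmark_step(mod, st, spec, p = p, damping = damping)
  }
  # the weakly tethered closed shell has near-free rigid translation and
  # rotation modes; compare rigid-invariant quantities
  expect_equal(cavity_volume(mod, st$U), s8$volume, tolerance = 0.02)
  expect_lt(max(abs(st$V)), 5e-3)
  # zero load, zero motion: a fixed point
  st0 <- list(U = matrix(0, mod$nv, 3), V = matrix(0, mod$nv, 3),
              A = matrix(0, mod$nv, 3))
  st1 <- newmark_step(mod, st0, spec, p = 0, damping = damping)
  expect_lt(max(abs(st1$U)), 1e-10)
})

test_that("backward-displacement unloading inverts inflation", {
  sh <- fix_small_shell()
  un <- unload(sh, p_mmHg = 4, spring_k = 1, maxit = 6, tol = 0.05)
  expect_true(un$converged)
  # error history decreases over the first iterations
  if (length(un$errors) >= 3)
    expect_true(all(diff(un$errors[1:3]) < 0))
  # round trip: inflating the unloaded mesh reproduces the imaged shape
  mod_u <- fe_model(un$mesh, spring_nodes = seq_len(n_vertices(un$mesh)),
                    spring_k = 1)
  s <- static_solve(mod_u, 4, nsteps = 3)
  expect_lt(max(abs(un$mesh$vertices + s$U - sh$vertices)), 0.06)
  # zero pressure: unloading is the identity
  un0 <- unload(sh, p_mmHg = 0, spring_k = 1, maxit = 2, tol = 0.01)
  expect_equal(un0$mesh$vertices, sh$vertices)
})

test_that("the EDPVR is strictly increasing and starts at the unloaded volume", {
  sh <- fix_small_shell()
  mod <- fe_model(sh, spring_nodes = seq_len(n_vertices(sh)), spring_k = 1)
  cur <- edpvr(mod, pressures_mmHg = c(0, 2, 4, 8))
  expect_equal(cur$V[1], cavity_volume(mod))
  expect_true(all(diff(cur$V) > 0))
})
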