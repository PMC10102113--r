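test_that("conductivity ordering is enforced and scars zero the tensor", {
  cab <- make_cable(5, 0.5)
  expect_error(conductivity_field(cab, 0.1, 0.2, 0.1), "sigma_f >= sigma_s")
  mask <- rep(FALSE, n_elements(cab)); mask[1:10] <- TRUE
  cond <- conductivity_field(cab, 0.3, 0.2, 0.1, scar_mask = mask)
  expect_true(all(cond$sigma_f[mask] == 0))
  expect_true(all(cond$sigma_f[!mask] == 0.3))
})

test_that("without sources a uniform resting state stays uniform", {
  cab <- make_cable(6, 0.5)
  cond <- conductivity_field(cab, 0.3, 0.1, 0.1)
  stim <- stimulus_protocol(list(list(vertices = integer(0), t0 = 0,
                                      duration = 1, amplitude = 0)))
  sol <- solve_monodomain(cab, cond, stim, duration = 5, dt = 0.05,
                          cell = "surrogate", sample_dt = 1)
  expect_lt(max(sol$Vm) - min(sol$Vm), 1e-6)
  expect_true(all(sol$inactive_mask))
})

test_that("a stimulated cable develops a planar wave that activates every node once", {
  fx <- fix_cable_sol()
  expect_true(all(!fx$sol$inactive_mask))
  expect_true(all(diff(sort(fx$sol$t_A[fx$mesh$landmarks_v$probe])) >= 0))
  cv <- measure_cv(fx$sol, fx$mesh, axis = c(1, 0, 0))
  expect_gt(cv, 0.1); expect_lt(cv, 2)
})

test_that("activation times interpolate linearly between samples", {
  # node crossing -20 mV between samples at 10 ms (-40 mV) and 11 ms (0 mV)
  Vm <- rbind(c(-80, -60, -40, 0, 10),
              c(-80, -80, -80, -80, -80))
  sol <- list(times = c(9, 9.5, 10, 11, 12), Vm = Vm)
  am <- activation_map(sol, threshold = -20)
  expect_equal(am$t_A[1], 10.5)
  expect_true(is.na(am$t_A[2]))
  expect_true(am$inactive_mask[2])
})

test_that("a constructed linear activation field yields its slope as CV", {
  cab <- make_cable(10, 0.5)
  sol <- list(t_A = cab$vertices[, 1] / 0.5, inactive_mask = rep(FALSE, n_vertices(cab)))
  expect_equal(measure_cv(sol, cab, axis = c(1, 0, 0)), 0.5, tolerance = 1e-10)
  sol$t_A[] <- NA
  expect_error(measure_cv(sol, cab), "fewer than 3")
})

test_that("conduction velocity scales as the square root of conductivity", {
  fx <- fix_cable_sol(sigma = 0.3)
  fx2 <- fix_cable_sol(sigma = 0.15)
  cv1 <- measure_cv(fx$sol, fx$mesh)
  cv2 <- measure_cv(fx2$sol, fx2$mesh)
  expect_equal(cv2 / cv1, 1 / sqrt(2), tolerance = 0.03)
})

test_that("the fast endocardial layer doubles the local conduction velocity", {
  # fully fast-marked tissue: the 4x conductivity multiplier must double CV
  sl <- make_slab(15, 1, 2, nx = 30, ny = 1, nz = 4, fiber = c(1, 0, 0))
  seg <- which(sl$vertices[, 1] <= 1.5)
  stim <- stimulus_protocol(list(list(vertices = seg, t0 = 0, duration = 2,
                                      amplitude = 80)))
  endo_nodes <- which(abs(sl$vertices[, 3]) < 1e-9)
  run <- function(cond) {
    sol <- solve_monodomain(sl, cond, stim, duration = 100, dt = 0.02,
                            cell = "surrogate", sample_dt = 0.5)
    measure_cv(sol, sl, probe = endo_nodes)
  }
  cv_plain <- run(conductivity_field(sl, 0.3, 0.3, 0.3))
  cv_fast <- run(conductivity_field(sl, 0.3, 0.3, 0.3,
                                    fast_layer_mask = rep(TRUE, n_elements(sl)),
                                    fast_factor = 4))
  expect_equal(cv_fast / cv_plain, 2, tolerance = 0.05)
  # a fast layer on the endocardial half of the wall speeds the whole front:
  # through-wall electrotonic coupling makes the wall move together, between
  # the slow and fast speeds
  fast <- sl$aux$xi < 0.5
  cv_layer <- run(conductivity_field(sl, 0.3, 0.3, 0.3,
                                     fast_layer_mask = fast, fast_factor = 4))
  expect_gt(cv_layer, 1.2 * cv_plain)
  expect_lt(cv_layer, cv_fast)
})

test_that("tune_conductivity rejects degenerate targets and is monotone", {
  expect_error(tune_conductivity(0), "positive")
  fx <- list(length = 10, resolution = 0.5, dt = 0.02, cell = "surrogate")
  t1 <- tune_conductivity(0.3, fixture = fx)
  t2 <- tune_conductivity(0.45, fixture = fx)
  expect_gt(t2$sigma, t1$sigma)
  expect_equal(t1$achieved_cv, 0.3, tolerance = 0.02)
  expect_equal(t2$achieved_cv, 0.45, tolerance = 0.02)
})

test_that("tune_conductivity recovers a conductivity the simulator generated", {
  fx <- list(length = 10, resolution = 0.5, dt = 0.02, cell = "surrogate")
  sigma_true <- 0.35
  cv_target <- cable_cv(sigma_true, fx)
  rec <- tune_conductivity(cv_target, fixture = fx)
  expect_equal(rec$sigma, sigma_true, tolerance = 0.02 * sigma_true)
})

test_that("inactive fraction spans its limits", {
  geo <- fix_geometry()
  ctrl <- fix_case("Control")
  expect_equal(ctrl$biomarkers$IT, 0)
  # fully scarred atrium never activates
  ep <- geo$ep
  cond <- conductivity_field(ep, 0.8, 0.2, 0.2,
                             scar_mask = rep(TRUE, n_elements(ep)))
  stim <- la_sinus_protocol(ep)
  sol <- solve_monodomain(ep, cond, stim, duration = 5, dt = 0.05,
                          cell = "surrogate", sample_dt = 1)
  expect_equal(inactive_fraction(sol, ep), 100)
})
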