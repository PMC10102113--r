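test_that("the active tension transient vanishes where the model says it must", {
  tp <- tension_params("ventricle")
  tt <- seq(-50, 800, by = 1)
  # below the stretch offset phi clamps to zero
  expect_true(all(tension(tt, t_A = 0, lambda = tp$lambda0, tp) == 0))
  expect_true(all(tension(tt, t_A = 0, lambda = 0.5, tp) == 0))
  # zero at the onset and the end of the twitch window
  expect_equal(tension(tp$t_emd, t_A = 0, lambda = 1, tp), 0)
  expect_equal(tension(tp$t_emd + tp$t_dur, t_A = 0, lambda = 1, tp), 0)
  # never-activated tissue develops no tension
  expect_true(all(tension(tt, t_A = NA_real_, lambda = 1, tp) == 0))
  expect_error(tension(NaN, 0, 1, tp), "non-finite")
})

test_that("tension is nonnegative, bounded by S_peak*phi, and the bound is approached", {
  tp <- tension_params("ventricle")
  for (lam in c(0.8, 1, 1.15)) {
    phi <- max(tanh(tp$ld * (lam - tp$lambda0)), 0)
    s <- tension(seq(0, 1200, by = 0.5), t_A = 0, lambda = lam, tp)
    expect_true(all(s >= 0))
    expect_true(all(s <= tp$S_peak * phi + 1e-12))
  }
  # with t_dur >> tau_c, tau_r the plateau reaches the bound
  long <- tp; long$t_dur <- 5000; long$ld_up <- 0
  phi1 <- tanh(long$ld * (1 - long$lambda0))
  smax <- max(tension(seq(0, 6000, by = 1), 0, 1, long))
  expect_equal(smax, long$S_peak * phi1, tolerance = 1e-6)
})

test_that("tension is continuous in time and stretch", {
  tp <- tension_params("atrium")
  tt <- seq(0, 400, by = 0.05)
  s <- tension(tt, t_A = 10, lambda = 1.05, tp)
  expect_lt(max(abs(diff(s))), tp$S_peak * 0.01)
  lam <- seq(0.5, 1.3, by = 0.001)
  sl <- tension(120, t_A = 10, lambda = lam, tp)
  expect_lt(max(abs(diff(sl))), tp$S_peak * 0.02)
})

test_that("active stress activates the fiber direction scaled by inverse stretch", {
  fr <- list(f0 = c(1, 0, 0), s0 = c(0, 1, 0), n0 = c(0, 0, 1))
  S <- active_stress(diag(3), S_A = 10, fr)
  expect_equal(S, diag(c(10, 0, 0)))
  expect_equal(active_stress(diag(3), 0, fr), matrix(0, 3, 3))
  lam <- 1.2
  F <- diag(c(lam, 1 / sqrt(lam), 1 / sqrt(lam)))
  S2 <- active_stress(F, 10, fr)
  expect_equal(S2[1, 1], 10 / lam)
  expect_equal(S2[2, 2], 0)
  expect_error(active_stress(diag(c(-1, 1, 1)), 1, fr), "positive determinant")
  # orthotropic weights distribute across directions
  S3 <- active_stress(diag(3), 10, fr, weights = c(1, 0.3, 0))
  expect_equal(diag(S3), c(10, 3, 0))
})

test_that("atrial and ventricular tension development do not overlap under default timing", {
  # mean drives under the pipeline's default timing: atrial stimulus at 0,
  # ventricles 160 ms later; atrial activation times from the Control map
  ctrl <- fix_case("Control")
  ep <- fix_geometry()$ep
  elem_tA <- ablamech:::element_activation(ctrl$ep, ep)
  vols <- abs(tet_volumes(ep))
  tpa <- tension_params("atrium")
  tpv <- tension_params("ventricle")
  drive_a <- ablamech:::la_drive_from_activation(elem_tA, vols, tpa)
  tt <- seq(0, 1.2, by = 0.002)
  a <- vapply(tt, drive_a, numeric(1))
  av_delay <- 160
  v <- tension(tt * 1000, t_A = av_delay, lambda = 1, tpv) / tpv$S_peak
  v <- v / max(v)
  # atrial activation completes before ventricular tension onset
  expect_lt(max(elem_tA, na.rm = TRUE), av_delay + tpv$t_emd)
  both <- pmin(a / max(a), v)
  expect_lt(max(both), 0.10)
})
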