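test_that("cable mesh has the requested subdivisions, axial fibers and valid frames", {
  cb <- make_cable(20, 0.25)
  # 80 axial subdivisions -> 81 probe nodes along the axis
  expect_length(cb$landmarks_v$probe, 81)
  expect_true(all(tet_volumes(cb) > 0))
  expect_lt(frame_orthonormality_error(cb), 1e-10)
  expect_true(all(abs(frame_determinants(cb) - 1) < 1e-10))
  expect_true(all(abs(cb$frame$f0[, 1] - 1) < 1e-12))
  # halving the resolution doubles the axial vertex count
  cb2 <- make_cable(20, 0.125)
  expect_length(cb2$landmarks_v$probe, 161)
  expect_error(make_cable(-1, 0.25), "positive")
  expect_error(make_cable(20, 0), "positive")
})

test_that("LA shell carries the anatomical landmark sets and is deterministic", {
  sh <- make_la_shell(seed = 7)
  for (nm in c("pv_rspv", "pv_lspv", "pv_ripv", "pv_lipv", "mitral_annulus",
               "bachmann", "posterior_sup", "posterior_mid", "coronary_sinus"))
    expect_gt(length(sh$landmarks_v[[nm]]), 0)
  expect_gt(length(sh$landmarks_e$appendage), 0)
  # PV ostium rims pairwise disjoint
  pv <- sh$landmarks_v[c("pv_rspv", "pv_lspv", "pv_ripv", "pv_lipv")]
  for (i in 1:3) for (j in (i + 1):4)
    expect_length(intersect(pv[[i]], pv[[j]]), 0)
  sh2 <- make_la_shell(seed = 7)
  expect_identical(sh$vertices, sh2$vertices)
  expect_true(all(tet_volumes(sh) > 0))
  expect_lt(frame_orthonormality_error(sh), 1e-10)
  expect_true(all(abs(frame_determinants(sh) - 1) < 1e-8))
})

test_that("shell wall keeps at least two elements transmurally", {
  sh <- make_la_shell(wall_thickness = 4.5, resolution = 1.5, nlayer = NULL)
  expect_gte(sh$meta$nlayer, 2)
  # every column stacks nlayer hex layers, each at least one tet thick
  expect_true(all(tapply(sh$aux$layer, sh$aux$column,
                         function(l) length(unique(l))) >= 2))
})

test_that("too-coarse resolution is rejected with a diagnostic", {
  expect_error(make_la_shell(resolution = 9, ostium_radius = 1.2),
               "too coarse")
})

test_that("EP mesh is an exact nested refinement of the mechanics mesh", {
  geo <- fix_geometry()
  ep <- geo$ep; mech <- geo$mech
  expect_equal(n_elements(ep), 8 * n_elements(mech))
  expect_equal(max(ep$ep_to_mech_map), n_elements(mech))
  # volumes of children sum to the parent volume
  vc <- tapply(abs(tet_volumes(ep)), ep$ep_to_mech_map, sum)
  expect_equal(as.numeric(vc), abs(tet_volumes(mech)), tolerance = 1e-10)
  # point-in-element check on a sample of EP centroids
  set.seed(42)
  idx <- sample(n_elements(ep), 300)
  cen <- (ep$vertices[ep$tets[idx, 1], ] + ep$vertices[ep$tets[idx, 2], ] +
          ep$vertices[ep$tets[idx, 3], ] + ep$vertices[ep$tets[idx, 4], ]) / 4
  ok <- ablamech:::points_in_tet(mech, ep$ep_to_mech_map[idx], cen,
                                 tol = 1e-8)
  expect_true(all(ok))
})

test_that("ventricular slab fiber rule interpolates the transmural angles", {
  expect_equal(fiber_angle_ventricular(0), 60)
  expect_equal(fiber_angle_ventricular(1), -60)
  expect_equal(fiber_angle_ventricular(0.5), 0)
  expect_equal(sheet_angle_ventricular(0), -65)
  expect_equal(sheet_angle_ventricular(1), 25)
  sl <- make_slab(10, 10, 4, resolution = 2)
  sl <- assign_fibers(sl, "ventricular_slab")
  expect_lt(frame_orthonormality_error(sl), 1e-10)
  # endocardial-most elements close to +60 degrees
  endo <- sl$aux$xi < 0.3
  ang <- atan2(sl$frame$f0[endo, 2], sl$frame$f0[endo, 1]) * 180 / pi
  expect_true(all(ang > 20))
})

test_that("atrial circumferential fibers are tangent to the shell surface", {
  sh <- fix_geometry()$mech
  d <- cbind(sh$aux$dx, sh$aux$dy, sh$aux$dz)
  radial_comp <- abs(rowSums(sh$frame$f0 * d))
  expect_lt(max(radial_comp), 1e-8)
})

test_that("mesh writers round-trip through VTU and MSH", {
  sh <- fix_small_shell()
  tmp <- tempfile(fileext = ".vtu")
  write_vtu(sh, tmp, cell_data = list(scar = as.numeric(seq_len(n_elements(sh)) %% 2)))
  back <- read_vtu(tmp)
  expect_equal(back$vertices, unname(sh$vertices), tolerance = 1e-8)
  expect_identical(back$tets, sh$tets)
  expect_equal(back$frame$f0, sh$frame$f0, tolerance = 1e-6)
  tmp2 <- tempfile(fileext = ".msh")
  write_msh(sh, tmp2)
  back2 <- read_msh(tmp2)
  expect_equal(back2$vertices, unname(sh$vertices), tolerance = 1e-8)
  expect_identical(back2$tets, sh$tets)
  unlink(c(tmp, tmp2))
})
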