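test_that("PVI bands isolate each vein: no conducting path from ostium rim to annulus", {
  mesh <- fix_geometry()$mech
  mask <- build_lesion(mesh, "PVI", width = 5)
  expect_gt(sum(mask), 0)
  ann_elems <- which(apply(matrix(mesh$tets %in% mesh$landmarks_v$mitral_annulus,
                                  ncol = 4), 1, any))
  for (nm in c("pv_rspv", "pv_lspv", "pv_ripv", "pv_lipv")) {
    rim <- mesh$landmarks_v[[nm]]
    rim_elems <- which(apply(matrix(mesh$tets %in% rim, ncol = 4), 1, any))
    rim_elems <- setdiff(rim_elems, which(mask))
    expect_false(ablamech:::elements_connected(mesh, rim_elems, ann_elems,
                                               blocked = mask))
  }
})

test_that("the posterior box lesion contains the roof line element-wise", {
  mesh <- fix_geometry()$mech
  rl <- build_lesion(mesh, "RL", width = 5)
  bl <- build_lesion(mesh, "BL", width = 5)
  expect_true(all(bl[rl]))
  expect_gt(sum(bl), sum(rl))
})

test_that("degenerate or unresolvable widths are rejected", {
  mesh <- fix_geometry()$mech
  expect_error(build_lesion(mesh, "PVI", width = 0), "positive")
  expect_error(build_lesion(mesh, "RL", width = 0.5), "below the mesh resolution")
  expect_error(combine_lesions(mesh, "PVI+XX"), "unknown lesion case")
})

test_that("lesion masks are transmural: a masked column is masked on every layer", {
  mesh <- fix_geometry()$mech
  for (cs in c("PVI", "PVI+AL+BL", "PVI+MIL+RL")) {
    ls <- combine_lesions(mesh, cs)
    cols <- mesh$aux$column
    in_cols <- unique(cols[ls$ep_mask])
    expect_true(all(ls$ep_mask[cols %in% in_cols]))
  }
})

test_that("Control is empty and case masks are unions of their components", {
  ep <- fix_geometry()$ep
  ctrl <- combine_lesions(ep, "Control")
  expect_equal(sum(ctrl$ep_mask), 0)
  expect_equal(ablated_fraction(ep, ctrl), 0)
  comb <- combine_lesions(ep, "PVI+AL+BL")
  manual <- build_lesion(ep, "PVI") | build_lesion(ep, "AL") |
    build_lesion(ep, "BL")
  expect_identical(comb$ep_mask, unname(manual))
  expect_setequal(comb$component_lesions, c("PVI", "AL", "BL"))
  # names tolerate spaces around '+'
  expect_identical(combine_lesions(ep, "PVI + AL + BL")$name, "PVI+AL+BL")
})

test_that("EP and mechanics masks cover the same myocardial fraction", {
  geo <- fix_geometry()
  for (cs in c("PVI", "PVI+AL+BL")) {
    ls <- combine_lesions(geo$ep, cs)
    f_ep <- ablated_fraction(geo$ep, ls$ep_mask)
    f_mech <- ablated_fraction(geo$mech, ls$mech_mask)
    expect_lt(abs(f_ep - f_mech), 0.5)   # percentage points
  }
})

test_that("ablated fraction is scale invariant and monotone under union", {
  geo <- fix_geometry()
  ep <- geo$ep
  pvi <- combine_lesions(ep, "PVI")
  pvibl <- combine_lesions(ep, "PVI+BL")
  f1 <- ablated_fraction(ep, pvi)
  f2 <- ablated_fraction(ep, pvibl)
  expect_gte(f2, f1)
  # uniform volume scaling leaves the fraction unchanged
  scaled <- ep
  scaled$vertices <- scaled$vertices * 2^(1 / 3)
  expect_equal(ablated_fraction(scaled, pvi), f1, tolerance = 1e-12)
})

test_that("ablated fractions increase with the number of component lesions", {
  ep <- fix_geometry()$ep
  at <- vapply(c("PVI", "PVI+MIL", "PVI+AL+BL"), function(cs)
    ablated_fraction(ep, combine_lesions(ep, cs)), numeric(1))
  expect_true(at[1] < at[2] && at[2] < at[3])
})
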