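test_that("equal pressures with open valves give zero flows", {
  pars <- circ_params()
  # pick a diastolic instant where all activation shapes are zero and set
  # every compartment to the same pressure
  t <- 1.05
  p <- 8
  ch <- pars$chambers
  y <- c(V_LA = ch$LA$V0 + p / ch$LA$Emin,
         V_LV = ch$LV$V0 + p / ch$LV$Emin,
         V_RA = ch$RA$V0 + p / ch$RA$Emin,
         V_RV = ch$RV$V0 + p / ch$RV$Emin,
         V_SysArt = pars$V0[["SysArt"]] + p / pars$E[["SysArt"]],
         V_SysVen = pars$V0[["SysVen"]] + p / pars$E[["SysVen"]],
         V_PulArt = pars$V0[["PulArt"]] + p / pars$E[["PulArt"]],
         V_PulVen = pars$V0[["PulVen"]] + p / pars$E[["PulVen"]],
         SV_diff = 0)
  r <- circulation_rhs(t, y, pars)
  expect_lt(max(abs(r[[1]])), 1e-10)
  expect_error(circulation_rhs(t, replace(y, 1, -5), pars), "negative")
})

test_that("compartment volume derivatives sum to zero at every instant", {
  pars <- circ_params()
  y <- ablamech:::circ_init_state(pars)
  for (t in c(0, 0.05, 0.2, 0.5, 0.9)) {
    r <- circulation_rhs(t, y, pars)
    expect_lt(abs(sum(r[[1]][1:8])), 1e-10)
  }
})

test_that("the closed loop reaches a limit cycle with balanced mean flows", {
  cr <- simulate_circulation(max_cycles = 40)
  expect_true(cr$converged)
  tr <- cr$traces
  # blood volume conserved to far below 1e-6 mL over the cycle
  tot <- rowSums(tr[, c("V_LA", "V_LV", "V_RA", "V_RV", "V_SysArt",
                        "V_SysVen", "V_PulArt", "V_PulVen")])
  expect_lt(max(tot) - min(tot), 1e-6)
  # mean aortic flow equals mean pulmonary flow at the limit cycle
  mq <- function(q) mean(q[-length(q)] + diff(q) / 2)
  expect_lt(abs(mean(tr$Q_SysArt) - mean(tr$Q_PulArt)),
            0.02 * mean(tr$Q_SysArt))
  # pressures physiologic in range
  expect_gt(max(tr$p_SysArt), 90)
  expect_lt(min(tr$V_LV), max(tr$V_LV))
})

test_that("the stopping criterion integrates the flow difference per cycle", {
  t <- seq(0, 1.2, by = 0.01)
  q <- 80 * pmax(sin(2 * pi * t / 1.2), 0)
  same <- stopping_criterion(t, q, q)
  expect_equal(same$SV_diff, 0)
  expect_true(same$converged)
  # constant 1 mL/s imbalance over a 1.2 s cycle accumulates 1.2 mL
  off <- stopping_criterion(t, q + 1, q)
  expect_equal(off$SV_diff, 1.2, tolerance = 1e-10)
  expect_false(off$converged)
})

test_that("a converged limit cycle stays converged under unchanged forcing", {
  cr <- simulate_circulation(max_cycles = 40)
  y_end <- setNames(as.numeric(cr$traces[nrow(cr$traces), 2:10]),
                    ablamech:::circ_state_names())
  y_end[["SV_diff"]] <- 0
  cr2 <- simulate_circulation(init = y_end, max_cycles = 3, min_cycles = 1)
  expect_true(cr2$converged)
  expect_equal(cr2$n_cycles, 1)
})

test_that("3D-0D coupling meets the volume-consistency tolerance", {
  # linear compliance chamber against a linear 0D law: root has a closed form
  V3d <- function(p) 20 + 3 * p
  V0d <- function(p) 80 - 2 * p
  out <- couple_chamber(V3d, V0d, p_init = 5)
  expect_equal(out$p, 12, tolerance = 1e-9)
  expect_lt(out$residual, 1e-7)
  # identical laws converge immediately at any pressure
  out2 <- couple_chamber(V3d, V3d, p_init = 3)
  expect_lt(out2$residual, 1e-7)
  # a nonlinear 3D law still meets the 1e-7 mL tolerance
  V3n <- function(p) 15 * (1 - exp(-p / 6)) + 22
  out3 <- couple_chamber(V3n, V0d, p_init = 1)
  expect_lt(out3$residual, 1e-7)
})

test_that("coupling a mechanics cavity law to the 0D chamber law converges", {
  # tabulated inflation curve from the shell fixture stands in for the
  # mechanics solve: monotone V(p) interpolated from a few static solves
  sh <- fix_small_shell()
  mod <- fe_model(sh, spring_nodes = seq_len(n_vertices(sh)), spring_k = 1)
  pr <- c(0, 2, 4, 8)
  cur <- edpvr(mod, pr)
  V3d <- stats::approxfun(cur$p, cur$V, rule = 2)
  V0d <- function(p) 6 - 0.2 * p
  out <- couple_chamber(V3d, V0d, p_init = 2)
  expect_lt(out$residual, 1e-7)
  expect_equal(V3d(out$p), V0d(out$p), tolerance = 1e-6)
})
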