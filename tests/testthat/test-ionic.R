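test_that("the published atrial resting state is quiescent", {
  y <- courtemanche_init()
  r <- courtemanche_rhs(y)
  expect_lt(abs(r$dstate[["V"]]), 0.01)           # mV/ms
  expect_lt(max(abs(r$dstate[c("m", "h", "j", "d", "f")])), 1e-3)
  expect_error(courtemanche_rhs(replace(y, 1, NaN)), "non-finite")
})

test_that("gate derivatives push clamped gates back into [0, 1]", {
  y <- courtemanche_init()
  gates <- c("m", "h", "j", "oa", "oi", "ua", "ui", "xr", "xs", "d", "f",
             "fca", "u", "v", "w")
  y0 <- y; y0[gates] <- 0
  d0 <- courtemanche_rhs(y0)$dstate
  expect_true(all(d0[gates] >= -1e-12))
  y1 <- y; y1[gates] <- 1
  d1 <- courtemanche_rhs(y1)$dstate
  expect_true(all(d1[gates] <= 1e-12))
})

test_that("a suprathreshold stimulus elicits an upstroke within 10 ms", {
  y <- courtemanche_init()
  dt <- 0.02
  S <- matrix(y, 1, dimnames = list(NULL, names(y)))
  t <- 0
  crossed <- FALSE
  while (t < 10) {
    st <- ablamech:::courtemanche_step(S, dt)
    S <- st$S
    I <- if (t < 2) 30 else 0
    S[, "V"] <- S[, "V"] + dt * (-st$I_ion + I)
    t <- t + dt
    if (S[, "V"] > 0) { crossed <- TRUE; break }
  }
  expect_true(crossed)
})

test_that("pacing returns the initial state for zero cycles and ignores subthreshold stimuli", {
  p0 <- pacing_protocol(n_cycles = 0)
  out <- pace_to_limit_cycle(p0, "courtemanche")
  expect_identical(out$state, courtemanche_init())
  psub <- pacing_protocol(n_cycles = 1, stim_amplitude = 0.5)
  sub <- pace_to_limit_cycle(psub, "courtemanche")
  expect_lt(max(abs(sub$last_beat$V - sub$last_beat$V[1])), 5)
})

test_that("paced beats approach a limit cycle with a stable APD90", {
  p <- pacing_protocol(n_cycles = 6)
  out <- pace_to_limit_cycle(p, "courtemanche")
  expect_true(all(is.finite(out$apd90)))
  expect_gt(out$apd90[1], 200)
  expect_lt(out$apd90[1], 400)
  n <- length(out$apd90)
  expect_lt(abs(out$apd90[n] - out$apd90[n - 1]), 1)
})

test_that("integration tolerance refinement leaves APD90 unchanged to 0.5 ms", {
  # adaptive-integrator analogue of a step-size halving study
  p <- pacing_protocol(n_cycles = 1)
  mdl <- ablamech:::cell_model("courtemanche")
  run <- function(rtol) {
    f <- function(t, y, parms) {
      I <- if (t < p$stim_duration) p$stim_amplitude else 0
      list(courtemanche_rhs(setNames(y, names(mdl$init)), I_ext = I)$dstate)
    }
    out <- deSolve::ode(y = mdl$init, times = seq(0, 1200, by = 1), func = f,
                        parms = NULL, method = "lsoda", rtol = rtol,
                        atol = 1e-9, maxsteps = 50000)
    apd90(out[, "time"], out[, "V"])
  }
  expect_lt(abs(run(1e-6) - run(1e-8)), 0.5)
})

test_that("the ventricular surrogate rests, excites once and outlasts the atrial AP", {
  y <- surrogate_init()
  r <- ventricular_surrogate_rhs(y)
  expect_lt(max(abs(r$dstate)), 1e-9)   # rest is a fixed point
  out_v <- pace_to_limit_cycle(pacing_protocol(n_cycles = 2), "surrogate")
  expect_true(is.finite(out_v$apd90[2]))
  expect_gt(out_v$apd90[2], 250)
  expect_lt(out_v$apd90[2], 320)
  # returns to rest after the beat
  expect_lt(abs(tail(out_v$last_beat$V, 1) - surrogate_params()$V_rest), 2)
  out_a <- pace_to_limit_cycle(pacing_protocol(n_cycles = 2), "courtemanche")
  expect_gt(out_v$apd90[2], out_a$apd90[2])
})

test_that("both models show APD restitution: shorter APD at faster pacing", {
  for (m in c("courtemanche", "surrogate")) {
    slow <- pace_to_limit_cycle(pacing_protocol(cycle_length = 1.2,
                                                n_cycles = 3), m)
    fast <- pace_to_limit_cycle(pacing_protocol(cycle_length = 0.6,
                                                n_cycles = 3), m)
    expect_lt(tail(fast$apd90, 1), tail(slow$apd90, 1))
  }
})

test_that("cell state snapshots round-trip through JSON", {
  y <- courtemanche_init()
  tmp <- tempfile(fileext = ".json")
  cell_state_save(y, tmp)
  back <- cell_state_load(tmp)
  expect_equal(back, y, tolerance = 1e-12)
  unlink(tmp)
})
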