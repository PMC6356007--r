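test_that("sigmoid activation matches its closed form and is monotone", {
  expect_equal(sigmoid_activation(4, a = 1, theta = 4), 0.5)
  expect_equal(sigmoid_activation(0, a = 1, theta = 4), 1 / (1 + exp(4)))
  ## saturation
  expect_lt(abs(sigmoid_activation(60) - 1), 1e-20)
  expect_lt(sigmoid_activation(-60), 1e-20)
  ## monotone, bounded in (0, 1) over random inputs
  set.seed(1)
  x <- sort(rnorm(200, sd = 10))
  s <- sigmoid_activation(x, a = 0.7, theta = -2)
  expect_true(all(diff(s) > 0))
  expect_true(all(s > 0 & s < 1))
  expect_error(sigmoid_activation(Inf), "finite")
  expect_error(sigmoid_activation(NA_real_), "finite")
  expect_error(sigmoid_activation(1, a = -1), "positive")
})

test_that("model drift matches hand evaluation and tau scaling", {
  p0 <- tc_params(tau1 = 1, tau2 = 1, tau3 = 1, tau4 = 1,
                  c1 = 0, c2 = 0, c3 = 0, c4 = 0, c5 = 0, c6 = 0,
                  c7 = 0, c8 = 0, c9 = 0,
                  h_py = 0, h_in = 0, h_tc = 0, h_re = 0)
  d <- model_drift(c(0, 0, 0, 0), p0)
  s0 <- 1 / (1 + exp(4))
  expect_equal(unname(d), c(s0, s0, 0, 0))

  ## doubling every tau halves every derivative at a fixed state
  p <- tc_params()
  p2 <- tc_params(tau1 = 2 * p$tau1, tau2 = 2 * p$tau2,
                  tau3 = 2 * p$tau3, tau4 = 2 * p$tau4)
  st <- c(0.3, 0.2, 1.1, 0.4)
  expect_equal(model_drift(st, p2), model_drift(st, p) / 2)

  ## drift vanishes at a numerically located fixed point
  run <- simulate_deterministic(tc_preset("default"), t_end = 10)
  fp <- run$states[nrow(run$states), ]
  expect_lt(max(abs(model_drift(fp, tc_preset("default")))), 1e-6)
  expect_error(model_drift(c(0, 0, Inf, 0), p), "finite")
})

test_that("deterministic solver is constant at a fixed point and self-converges", {
  p <- tc_preset("default")
  run <- simulate_deterministic(p, t_end = 10)
  fp <- as.double(run$states[nrow(run$states), ])
  again <- simulate_deterministic(p, init = fp, t_end = 2)
  expect_lt(diff(range(again$states[, "py"])), 1e-6)

  ## halving the tolerance moves the final state by less than the bound
  f1 <- simulate_deterministic(p, t_end = 3, rtol = 1e-6, atol = 1e-8)
  f2 <- simulate_deterministic(p, t_end = 3, rtol = 5e-7, atol = 5e-9)
  expect_lt(max(abs(f1$states[nrow(f1$states), ] -
                      f2$states[nrow(f2$states), ])), 1e-5)

  ## independent oracle: deSolve lsoda agrees on the final state
  de <- deSolve::ode(
    y = c(0, 0, 0, 0), times = seq(0, 3, by = 0.002),
    func = function(t, y, parms) list(as.numeric(model_drift(y, p))),
    method = "lsoda", rtol = 1e-10, atol = 1e-12)
  mine <- simulate_deterministic(p, t_end = 3)
  expect_lt(max(abs(de[nrow(de), -1] - mine$states[nrow(mine$states), ])),
            1e-6)
})

test_that("spike-wave runs are periodic with a stable period", {
  traj <- simulate_deterministic(tc_preset("swd"), t_end = 10)
  py <- traj$states[, "py"]
  win <- function(a, b) py[traj$times >= a & traj$times < b]
  f_a <- ictogen:::dominant_frequency(win(2, 6), 500)
  f_b <- ictogen:::dominant_frequency(win(6, 10), 500)
  expect_lt(abs(f_a - f_b), 0.3)
  ## autocorrelation-based period estimate as an independent check
  lag_at <- function(x) {
    a <- stats::acf(x, lag.max = 500, plot = FALSE)$acf[-1]
    which.max(a[50:500]) + 49
  }
  expect_lt(abs(lag_at(win(2, 6)) - lag_at(win(6, 10))) /
              lag_at(win(2, 6)), 0.05)
})

test_that("Euler-Maruyama honours its seed and the zero-noise limit", {
  p <- tc_preset("bistable")
  a <- simulate_stochastic(p, t_end = 1, seed = 42)
  b <- simulate_stochastic(p, t_end = 1, seed = 42)
  expect_identical(a$states, b$states)
  c2 <- simulate_stochastic(p, t_end = 1, seed = 43)
  expect_false(identical(a$states, c2$states))

  ## alpha = 0 reproduces a hand-rolled fixed-step Euler exactly
  p0 <- tc_params(alpha = 0, dt = 1 / 15000)
  tr <- simulate_stochastic(p0, t_end = 0.05, seed = 1, fs = 15000)
  y <- c(0, 0, 0, 0)
  for (i in seq_len(750)) y <- y + (1 / 15000) * model_drift(y, p0)
  expect_equal(as.double(tr$states[nrow(tr$states), ]), unname(y),
               tolerance = 1e-12)
})

test_that("Euler-Maruyama converges to the smooth solution at first order", {
  p <- tc_preset("default")
  ref <- simulate_deterministic(p, t_end = 0.5, fs = 500)
  rf <- ref$states[nrow(ref$states), ]
  final_em <- function(dt) {
    pp <- do.call(tc_params, modifyList(as.list(unclass(p)),
                                        list(dt = dt, alpha = 0)))
    tr <- simulate_stochastic(pp, t_end = 0.5, seed = 1, fs = 500)
    tr$states[nrow(tr$states), ]
  }
  e1 <- max(abs(final_em(1 / 15000) - rf))
  e2 <- max(abs(final_em(1 / 30000) - rf))
  expect_gt(e1 / e2, 1.7)
  expect_lt(e1 / e2, 2.3)
})

test_that("noise drives transitions between coexisting attractors", {
  ## in the bistable regime a moderately noisy run wanders between the
  ## quiescent and the oscillatory attractor; membership is decided by
  ## switching the noise off from sampled states (independent oracle)
  p <- tc_preset("bistable")
  eq <- ictogen:::find_equilibrium(p, default_inits(p)$run_in)
  m <- simulate_stochastic(p, init = eq$state, t_end = 20, seed = 2)
  labs <- vapply(seq(2, 19), function(ts) {
    st <- m$states[which.min(abs(m$times - ts)), ]
    classify_trajectory(simulate_deterministic(p, st, t_end = 10))$label
  }, "")
  expect_true("FIXED_POINT" %in% labs)
  expect_true(any(labs != "FIXED_POINT"))
})

test_that("all shipped presets stay bounded over 10 s", {
  for (nm in c("default", "bistable", "swd")) {
    tr <- simulate_deterministic(tc_preset(nm), t_end = 10)
    expect_lt(max(abs(tr$states)), 1e3)
    ts <- simulate_stochastic(tc_preset(nm), t_end = 10, seed = 5)
    expect_lt(max(abs(ts$states)), 1e3)
  }
})

test_that("divergent states abort with a diagnostic naming the point", {
  expect_error(
    simulate_deterministic(tc_params(), init = c(0, 0, 9e5, 9e5),
                           t_end = 1, bound = 1e6),
    "c1=11.*c8=1.2")
})

test_that("synthetic EEG removes DC and preserves in-band amplitude", {
  ## constant PY gives an all-zero trace
  e0 <- synthetic_eeg(fake_traj(rep(0.7, 5001)))
  expect_lt(max(abs(e0$eeg)), 1e-9)

  ## a 3 Hz unit sinusoid passes with less than 5% attenuation
  t <- seq(0, 10, by = 1 / 500)
  e3 <- synthetic_eeg(fake_traj(0.5 + sin(2 * pi * 3 * t)))
  mid <- e3$time_s > 2 & e3$time_s < 8
  expect_gt(max(e3$eeg[mid]), 0.95)
  expect_lt(max(e3$eeg[mid]), 1.05)

  ## too-short input errors
  expect_error(synthetic_eeg(fake_traj(rep(0.5, 500))), "3 filter time")

  ## DC-removal contract on an actual spike-wave simulation
  tr <- simulate_deterministic(tc_preset("swd"), t_end = 8)
  e <- synthetic_eeg(tr)
  expect_lt(abs(mean(e$eeg)), 1e-6 * sd(e$eeg))
})

test_that("trajectory CSV export uses the canonical header", {
  tr <- simulate_deterministic(tc_preset("default"), t_end = 0.1)
  f <- withr::local_tempfile(fileext = ".csv")
  write_trajectory_csv(tr, f)
  df <- read.csv(f, check.names = FALSE)
  expect_identical(names(df), c("time_s", "py", "in", "tc", "re"))
  expect_identical(df$py, unname(tr$states[, "py"]))
})
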