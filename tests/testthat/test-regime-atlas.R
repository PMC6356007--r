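test_that("classifier labels canonical waveforms correctly", {
  ## constant trace
  z <- classify_trajectory(fake_traj(rep(0.42, 5501)))
  expect_identical(z$label, "FIXED_POINT")

  ## 3 Hz sawtooth-plus-spike (two maxima per period)
  z <- classify_trajectory(fake_traj(sawtooth_spike()))
  expect_identical(z$label, "SWD")
  expect_lt(abs(z$fundamental_hz - 3), 0.3)
  expect_gte(z$extrema_per_cycle, 2)

  ## 25 Hz sinusoid
  t <- seq(0, 10.5, by = 1 / 500)
  z <- classify_trajectory(fake_traj(0.5 + 0.2 * sin(2 * pi * 25 * t)))
  expect_identical(z$label, "FAST_OSC")
  expect_lt(abs(z$fundamental_hz - 25), 0.3)

  ## too little post-transient signal errors
  expect_error(classify_trajectory(fake_traj(rep(0.4, 1000))), "8 s")
})

test_that("extrema of a pure sinusoid are its two amplitudes", {
  t <- seq(0, 4, by = 1 / 500)
  x <- 1.7 * sin(2 * pi * 5 * t)
  hi <- x[ictogen:::local_maxima(x)]
  lo <- -(-x)[ictogen:::local_maxima(-x)]
  expect_equal(unique(round(hi, 3)), 1.7)
  expect_equal(unique(round(lo, 3)), -1.7)
})

test_that("parameter-point classification detects mono- and bistability", {
  ## decoupled, all-zero couplings: every population contracts to a unique
  ## equilibrium, every initial condition gives the same fixed point
  p0 <- tc_params(c1 = 0, c2 = 0, c3 = 0, c4 = 0, c5 = 0, c6 = 0,
                  c7 = 0, c8 = 0, c9 = 0,
                  h_py = 2, h_in = 3, h_tc = 1, h_re = -1)
  expect_identical(classify_parameter_point(p0)$label, "FIXED_POINT")

  ## shipped bistable preset: the spike-wave attractor is reached from a
  ## generic state while a linearly stable equilibrium coexists
  pb <- tc_preset("bistable")
  z <- classify_parameter_point(pb)
  expect_identical(z$label, "BISTABLE")
  from_origin <- classify_trajectory(
    simulate_deterministic(pb, c(0, 0, 0, 0), t_end = 10))
  expect_identical(from_origin$label, "SWD")
  eq <- ictogen:::find_equilibrium(pb, default_inits(pb)$run_in)
  expect_true(eq$stable)
  from_eq <- classify_trajectory(
    simulate_deterministic(pb, eq$state, t_end = 10))
  expect_identical(from_eq$label, "FIXED_POINT")

  ## monostable spike-wave preset
  expect_identical(classify_parameter_point(tc_preset("swd"))$label, "SWD")
})

test_that("a 1x1 scan equals point classification and axes transpose", {
  base <- tc_preset("default")
  inits <- default_inits(base)
  sc <- scan_plane(base, "c1", "c8", 9, 3, inits = inits)
  expect_identical(dim(sc$labels), c(1L, 1L))
  p <- base; p$c1 <- 9; p$c8 <- 3
  expect_identical(sc$labels[1, 1],
                   classify_parameter_point(p, inits = inits)$label)

  xs <- c(9, 11.5, 14); ys <- c(0.5, 2, 3.5)
  s_a <- scan_plane(base, "c1", "c8", xs, ys, inits = inits)
  s_b <- scan_plane(base, "c8", "c1", ys, xs, inits = inits)
  expect_identical(s_a$labels, t(s_b$labels))
})

test_that("grid validation rejects non-increasing axes", {
  expect_error(scan_plane(tc_params(), "c1", "c8", c(2, 1), c(0, 1)),
               "increasing")
  expect_error(bifurcation_diagram(tc_params(), "c8", c(3, 1)),
               "increasing")
})

test_that("frontier orientation recovers constructed frontiers", {
  xs <- seq(0, 10, by = 1); ys <- seq(0, 10, by = 1)
  ## seizure iff y > x: positive slope, seizure above
  lab <- outer(ys, xs, function(y, x)
    ifelse(y > x, "SWD", "FIXED_POINT"))
  fo <- frontier_orientation(fake_scan(lab, xs, ys))
  expect_identical(fo$slope_sign, 1L)
  expect_identical(fo$seizure_side, "ABOVE")
  expect_equal(fo$slope, 1, tolerance = 0.05)

  ## seizure iff y < -x + 10: negative slope, seizure below
  lab2 <- outer(ys, xs, function(y, x)
    ifelse(y < -x + 10, "SWD", "FIXED_POINT"))
  fo2 <- frontier_orientation(fake_scan(lab2, xs, ys))
  expect_identical(fo2$slope_sign, -1L)
  expect_identical(fo2$seizure_side, "BELOW")

  ## the logistic-surface cross-check agrees on both
  expect_identical(frontier_orientation(fake_scan(lab, xs, ys),
                                        method = "logistic")$slope_sign, 1L)
  expect_identical(frontier_orientation(fake_scan(lab2, xs, ys),
                                        method = "logistic")$slope_sign,
                   -1L)

  ## single-class scans have no frontier
  lab3 <- matrix("SWD", 11, 11)
  expect_error(frontier_orientation(fake_scan(lab3, xs, ys)),
               "single class")
})

test_that("epileptogenic routes walk the grid as specified", {
  xs <- seq(1, 5); ys <- seq(1, 5)
  lab <- matrix("FIXED_POINT", 5, 5)
  lab[4, 3] <- "SWD"                       # directly above the centre
  lab[, 1] <- "SWD"                        # left edge
  sc <- fake_scan(lab, xs, ys)
  r <- epileptogenic_routes(sc, c(3, 3))
  expect_true(r$inc_y$reachable)
  expect_identical(r$inc_y$steps, 1L)
  expect_equal(r$inc_y$dy, 1)
  expect_true(r$dec_x$reachable)
  expect_identical(r$dec_x$steps, 2L)
  expect_true(r$diagonal$reachable)

  ## all-non-seizure scan: nothing reachable
  sc0 <- fake_scan(matrix("FIXED_POINT", 5, 5), xs, ys)
  r0 <- epileptogenic_routes(sc0, c(3, 3))
  expect_false(r0$dec_x$reachable)
  expect_false(r0$inc_y$reachable)
  expect_false(r0$diagonal$reachable)

  expect_error(epileptogenic_routes(sc, c(99, 3)), "outside")
  expect_error(epileptogenic_routes(sc, c(1, 3)), "seizure-supporting")
})

test_that("bifurcation sweep separates fixed points from oscillations", {
  base <- tc_preset("default")
  bd <- bifurcation_diagram(base, "c8", c(0.2, 0.8), init = c(0, 0, 2, 2))
  expect_true(all(lengths(bd$extrema) == 1))

  base2 <- tc_preset("swd")
  bd2 <- bifurcation_diagram(base2, "c8", c(0.2, 5.2), init = c(0, 0, 2, 2))
  expect_identical(lengths(bd2$extrema)[1], 1L)
  expect_gte(lengths(bd2$extrema)[2], 4L)
  expect_gte(length(unique(bd2$extrema[[2]])), 4L)
})

test_that("classification is stable under doubling the transient window", {
  base <- tc_preset("default")
  inits <- default_inits(base)
  xs <- seq(6, 13, length.out = 4); ys <- seq(0.5, 6, length.out = 4)
  a <- scan_plane(base, "c1", "c8", xs, ys, t_end = 10, transient = 2,
                  inits = inits)
  b <- scan_plane(base, "c1", "c8", xs, ys, t_end = 18, transient = 10,
                  inits = inits)
  expect_gte(mean(a$labels == b$labels), 15 / 16)
})

test_that("plane scans survive the TSV + JSON round trip", {
  base <- tc_preset("default")
  sc <- scan_plane(base, "c1", "c8", c(9, 14), c(0.5, 2),
                   inits = default_inits(base))
  pre <- withr::local_tempfile()
  write_plane_scan(sc, pre)
  tsv <- read.delim(paste0(pre, "_labels.tsv"), check.names = FALSE)
  expect_identical(dim(tsv), c(2L, 3L))
  expect_identical(as.matrix(tsv[, -1]), matrix(sc$labels, 2, 2,
                                                dimnames = dimnames(as.matrix(tsv[, -1]))))
  meta <- jsonlite::read_json(paste0(pre, "_params.json"),
                              simplifyVector = TRUE)
  expect_identical(meta$x_param, "c1")
  expect_equal(meta$params_base$c9, base$c9)
})
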