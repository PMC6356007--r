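#' Sigmoid activation function
#'
#' The saturating activation applied to the summed input of the cortical
#' populations: `S(x) = 1 / (1 + exp(-a * (x - theta)))`.
#'
#' @param x input (any finite real; vectorised).
#' @param a steepness, positive.
#' @param theta offset.
#' @return Values in (0, 1), strictly increasing in `x`.
#' @examples
#' sigmoid_activation(4)          # midpoint: 0.5
#' sigmoid_activation(0)          # 1 / (1 + e^4)
#' @export
sigmoid_activation <- function(x, a = 1, theta = 4) {
  if (!is.numeric(x) || anyNA(x) || any(!is.finite(x)))
    stop("'x' must be finite")
  if (!is.numeric(a) || length(a) != 1 || !is.finite(a) || a <= 0)
    stop("'a' must be a positive scalar")
  1 / (1 + exp(-a * (x - theta)))
}

#' Drift of the thalamocortical model
#'
#' The deterministic right-hand side of the four coupled equations (the
#' noise term on TC is excluded).  The cortical equations wrap their whole
#' input in the sigmoid; the thalamic equations are linear in their inputs:
#' \deqn{\tau_1 \dot{PY} = -PY + S(c_1 PY - c_3 IN + c_9 TC + h_{py})}
#' \deqn{\tau_2 \dot{IN} = -IN + S(c_2 PY + h_{in})}
#' \deqn{\tau_3 \dot{TC} = -TC + c_7 PY - c_6 RE + h_{tc}}
#' \deqn{\tau_4 \dot{RE} = -RE + c_8 PY - c_4 RE + c_5 TC + h_{re}}
#'
#' @param state numeric length-4 vector `(py, in, tc, re)`.
#' @param params a [tc_params()] object.
#' @return Named numeric vector of the four time derivatives (per second).
#' @examples
#' model_drift(c(0, 0, 0, 0), tc_params())
#' @export
model_drift <- function(state, params) {
  stopifnot(inherits(params, "tc_params"))
  state <- as.double(state)
  if (length(state) != 4 || any(!is.finite(state)))
    stop("'state' must be 4 finite values (py, in, tc, re)")
  p <- params
  py <- state[1]; in_ <- state[2]; tc <- state[3]; re <- state[4]
  c(py = (-py + sigmoid_activation(p$c1 * py - p$c3 * in_ + p$c9 * tc +
                                     p$h_py, p$a, p$theta)) / p$tau1,
    "in" = (-in_ + sigmoid_activation(p$c2 * py + p$h_in, p$a,
                                      p$theta)) / p$tau2,
    tc = (-tc + p$c7 * py - p$c6 * re + p$h_tc) / p$tau3,
    re = (-re + p$c8 * py - p$c4 * re + p$c5 * tc + p$h_re) / p$tau4)
}

new_trajectory <- function(mat, params, stochastic, seed = NULL) {
  colnames(mat) <- c("time_s", "py", "in", "tc", "re")
  structure(list(times = mat[, 1], states = mat[, -1, drop = FALSE],
                 params = params, stochastic = stochastic, seed = seed,
                 fs = 1 / mean(diff(mat[, 1]))),
            class = "tc_trajectory")
}

#' Deterministic model solution
#'
#' Integrates the noise-free model with an adaptive Dormand-Prince 5(4)
#' Runge-Kutta scheme and dense output on a uniform grid.  The result does
#' not depend on the random number generator state.
#'
#' @param params a [tc_params()] object (`alpha` is ignored).
#' @param init initial state `(py, in, tc, re)`.
#' @param t_end simulation length in seconds, positive.
#' @param fs output sampling rate in Hz.
#' @param rtol,atol relative and absolute local error tolerances.
#' @param bound divergence guard: integration aborts with an error naming
#'   the parameter point if any state magnitude exceeds this.
#' @return A `tc_trajectory`: times (s), a states matrix with columns
#'   `py`, `in`, `tc`, `re`, and the generating parameters.
#' @examples
#' traj <- simulate_deterministic(tc_preset("swd"), t_end = 4)
#' range(traj$states[, "py"])
#' @export
simulate_deterministic <- function(params, init = c(0, 0, 0, 0), t_end,
                                   fs = 500, rtol = 1e-8, atol = 1e-10,
                                   bound = 1e6) {
  stopifnot(inherits(params, "tc_params"), t_end > 0)
  init <- as.double(init)
  stopifnot(length(init) == 4, all(is.finite(init)))
  times <- seq(0, t_end, by = 1 / fs)
  mat <- tryCatch(
    .Call(C_simulate_dp45, par_vec(params), init, as.double(times),
          as.double(rtol), as.double(atol), as.double(bound)),
    error = function(e) stop("deterministic integration failed at ",
                             par_point_label(params), ": ",
                             conditionMessage(e), call. = FALSE))
  new_trajectory(mat, params, stochastic = FALSE)
}

#' Stochastic model solution (Euler-Maruyama)
#'
#' Fixed-step Euler-Maruyama integration at step `params$dt`.  At each step
#' the TC population receives an additional increment
#' `(alpha / tau3) * sqrt(dt) * xi` with `xi` standard normal.  With
#' `alpha = 0` the scheme is exactly the fixed-step Euler method.  The same
#' seed always yields the identical trajectory.
#'
#' @param params a [tc_params()] object; `alpha` and `dt` are taken from it.
#' @param init initial state `(py, in, tc, re)`.
#' @param t_end simulation length in seconds, positive.
#' @param seed integer seed for the noise stream.
#' @param fs output sampling rate in Hz; states are recorded at the solver
#'   step and kept every `1/(fs*dt)`-th step (must divide evenly).
#' @param bound divergence guard as in [simulate_deterministic()].
#' @return A `tc_trajectory` with `stochastic = TRUE` and the seed stored.
#' @examples
#' traj <- simulate_stochastic(tc_preset("bistable"), t_end = 2, seed = 7)
#' @export
simulate_stochastic <- function(params, init = c(0, 0, 0, 0), t_end, seed,
                                fs = 500, bound = 1e6) {
  stopifnot(inherits(params, "tc_params"), t_end > 0)
  init <- as.double(init)
  stopifnot(length(init) == 4, all(is.finite(init)))
  dt <- params$dt
  thin <- round(1 / (fs * dt))
  if (abs(thin - 1 / (fs * dt)) > 1e-8)
    stop("1/(fs*dt) must be an integer; got fs = ", fs, ", dt = ", dt)
  nstep <- round(t_end / dt)
  if (!missing(seed) && !is.null(seed)) set.seed(seed) else seed <- NULL
  mat <- tryCatch(
    .Call(C_simulate_em, par_vec(params), as.double(params$alpha), init,
          as.integer(nstep), as.double(dt), as.integer(thin),
          as.double(bound)),
    error = function(e) stop("stochastic integration failed at ",
                             par_point_label(params), ": ",
                             conditionMessage(e), call. = FALSE))
  new_trajectory(mat, params, stochastic = TRUE, seed = seed)
}

#' @export
print.tc_trajectory <- function(x, ...) {
  cat(sprintf("tc_trajectory: %.3f s at %g Hz (%s)%s\n",
              max(x$times), round(x$fs),
              if (x$stochastic) "stochastic" else "deterministic",
              if (!is.null(x$seed)) paste0(", seed ", x$seed) else ""))
  cat(sprintf("  PY range [%.4g, %.4g]\n",
              min(x$states[, "py"]), max(x$states[, "py"])))
  invisible(x)
}

#' @export
as.data.frame.tc_trajectory <- function(x, ...) {
  data.frame(time_s = x$times, py = x$states[, "py"],
             "in" = x$states[, "in"], tc = x$states[, "tc"],
             re = x$states[, "re"], check.names = FALSE)
}

#' @export
plot.tc_trajectory <- function(x, which = c("py", "in", "tc", "re"), ...) {
  which <- match.arg(which, several.ok = TRUE)
  matplot(x$times, x$states[, which, drop = FALSE], type = "l", lty = 1,
          xlab = "time (s)", ylab = "activity", ...)
  legend("topright", legend = which, lty = 1, col = seq_along(which),
         bty = "n")
  invisible(x)
}

#' Write a trajectory to CSV
#'
#' Columns `time_s, py, in, tc, re` with a mandatory header row.
#'
#' @param traj a `tc_trajectory`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(traj, path) {
  stopifnot(inherits(traj, "tc_trajectory"))
  write_csv_precise(as.data.frame(traj), path)
}

#' Synthetic EEG from a simulated trajectory
#'
#' The model's EEG correlate is the pyramidal (PY) activity with the DC
#' component removed by a zero-phase (forward-backward) second-order
#' Butterworth high-pass filter.
#'
#' @param traj a uniformly sampled `tc_trajectory`.
#' @param cutoff_hz high-pass cutoff in Hz.
#' @return Object of class `tc_eeg`: data frame with columns `time_s`,
#'   `eeg`.
#' @examples
#' traj <- simulate_deterministic(tc_preset("swd"), t_end = 5)
#' eeg <- synthetic_eeg(traj)
#' abs(mean(eeg$eeg)) < 1e-6 * sd(eeg$eeg)
#' @export
synthetic_eeg <- function(traj, cutoff_hz = 1.0) {
  stopifnot(inherits(traj, "tc_trajectory"), cutoff_hz > 0)
  dts <- diff(traj$times)
  if (max(abs(dts - dts[1])) > 1e-9 * dts[1])
    stop("trajectory must be uniformly sampled")
  fs <- 1 / dts[1]
  if (max(traj$times) - min(traj$times) < 3 / cutoff_hz)
    stop("trajectory shorter than 3 filter time constants (",
         3 / cutoff_hz, " s)")
  bf <- signal::butter(2, W = cutoff_hz / (fs / 2), type = "high")
  py <- traj$states[, "py"]
  ## centre before filtering so the forward-backward pass sees no DC step
  ## at the record edges, then remove the residual filter-transient mean
  eeg <- signal::filtfilt(bf, py - mean(py))
  eeg <- eeg - mean(eeg)
  structure(data.frame(time_s = traj$times, eeg = eeg),
            class = c("tc_eeg", "data.frame"), fs = fs)
}

#' Write a synthetic EEG trace to CSV
#'
#' @param eeg a `tc_eeg` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_eeg_csv <- function(eeg, path) {
  stopifnot(inherits(eeg, "tc_eeg"))
  write_csv_precise(as.data.frame(eeg), path)
}

## full-precision CSV writer so that generated artefacts round-trip
## bit-identically
write_csv_precise <- function(df, path) {
  out <- df
  for (j in seq_along(out))
    if (is.double(out[[j]])) out[[j]] <- sprintf("%.17g", out[[j]])
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
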