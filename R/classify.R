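## ---- regime classification -------------------------------------------

## dominant frequency by raw periodogram (detrended, untapered)
dominant_frequency <- function(x, fs) {
  sp <- spec.pgram(stats::ts(x, frequency = fs), taper = 0, detrend = TRUE,
                   fast = TRUE, plot = FALSE)
  sp$freq[which.max(sp$spec)]
}

## local extrema with a prominence filter: an extremum is kept only if it
## stands out from the adjacent opposite extrema by `frac` of the signal
## range.  Returns indices.
local_maxima <- function(x, frac = 0.05) {
  r <- diff(range(x))
  if (r == 0) return(integer(0))
  d <- diff(x)
  s <- sign(d)
  s[s == 0] <- 1          # plateaus ride the preceding slope
  idx <- which(diff(s) < 0) + 1
  if (!length(idx)) return(integer(0))
  mins <- which(diff(s) > 0) + 1
  keep <- vapply(idx, function(i) {
    lo <- mins[mins < i]; hi <- mins[mins > i]
    ref <- max(c(if (length(lo)) x[max(lo)], if (length(hi)) x[min(hi)],
                 min(x)))
    x[i] - ref > frac * r
  }, logical(1))
  idx[keep]
}

count_extrema <- function(x, frac = 0.05) {
  length(local_maxima(x, frac)) + length(local_maxima(-x, frac))
}

new_regime_label <- function(label, fundamental_hz = NA_real_,
                             extrema_per_cycle = NA_real_,
                             warning_flag = FALSE) {
  structure(list(label = label, fundamental_hz = fundamental_hz,
                 extrema_per_cycle = extrema_per_cycle,
                 warning_flag = warning_flag), class = "regime_label")
}

#' @export
print.regime_label <- function(x, ...) {
  cat("regime:", x$label)
  if (!is.na(x$fundamental_hz))
    cat(sprintf(" (fundamental %.2f Hz, %.2f extrema/cycle)",
                x$fundamental_hz, x$extrema_per_cycle))
  if (x$warning_flag) cat("  [non-settled]")
  cat("\n")
  invisible(x)
}

#' Classify a simulated trajectory into a dynamical regime
#'
#' After discarding an initial transient, the pyramidal (PY) series is
#' labelled `FIXED_POINT` when its peak-to-peak range is below `tol_amp`.
#' Otherwise the fundamental frequency is the dominant periodogram peak:
#' oscillations at or above `fast_cutoff_hz` are `FAST_OSC`; slower
#' oscillations whose extrema (minima plus maxima) recur at least
#' `min_extrema_per_cycle` times per fundamental period are `SWD`
#' (spike-wave morphology: at minimum one spike extremum and one wave
#' extremum per cycle).  Degenerate slow waveforms failing the extrema
#' test are flagged and labelled by their extremal structure.
#'
#' @param traj a `tc_trajectory` (deterministic) or any object with
#'   `times` and a `py` state column.
#' @param transient seconds discarded from the start.
#' @param tol_amp fixed-point amplitude tolerance, as peak-to-peak PY
#'   range (the sigmoid output range is 1).
#' @param fast_cutoff_hz boundary between spike-wave and fast oscillatory
#'   dynamics.
#' @param min_extrema_per_cycle morphological threshold for the spike-wave
#'   label; the nominal spike-plus-wave count of 2 is tested with head
#'   room for periodogram bin quantisation.
#' @return A `regime_label`: list with `label` (one of `FIXED_POINT`,
#'   `SWD`, `FAST_OSC`), `fundamental_hz`, `extrema_per_cycle`,
#'   `warning_flag`.
#' @export
classify_trajectory <- function(traj, transient = 2, tol_amp = 1e-5,
                                fast_cutoff_hz = 15,
                                min_extrema_per_cycle = 1.5) {
  stopifnot(inherits(traj, "tc_trajectory"))
  keep <- traj$times >= transient
  if ((max(traj$times) - transient) < 8 - 1e-9)
    stop("need at least 8 s of post-transient signal; got ",
         signif(max(traj$times) - transient, 3), " s")
  py <- traj$states[keep, "py"]
  ## the settled amplitude is judged on the final 2 s, so slowly decaying
  ## spirals towards a focus are not mistaken for sustained oscillations:
  ## an attractor holds its amplitude, a focus loses most of it between
  ## the first and last stretch of the window
  late <- traj$states[traj$times >= max(traj$times) - 2, "py"]
  early <- traj$states[traj$times >= transient &
                         traj$times < transient + 2, "py"]
  r_late <- diff(range(late))
  if (r_late < tol_amp || r_late < 0.2 * diff(range(early)))
    return(new_regime_label("FIXED_POINT"))
  fs <- traj$fs
  f0 <- dominant_frequency(py, fs)
  dur <- length(py) / fs
  epc <- count_extrema(py) / (dur * f0)
  if (f0 >= fast_cutoff_hz)
    return(new_regime_label("FAST_OSC", f0, epc))
  if (epc >= min_extrema_per_cycle)
    return(new_regime_label("SWD", f0, epc))
  ## non-settled / degenerate slow waveform
  lab <- if (count_extrema(py) > 2) "SWD" else "FAST_OSC"
  new_regime_label(lab, f0, epc, warning_flag = TRUE)
}

#' Default initial-condition spread for bistability probing
#'
#' Five states: the origin, the endpoint of a short run-in from the
#' origin, and three corners of the explored state-space box
#' (PY, IN in \[0, 1\]; TC, RE in \[0, 2\]).
#'
#' @param params a [tc_params()] object (used for the run-in).
#' @param run_in run-in length in seconds.
#' @return List of five length-4 state vectors.
#' @export
default_inits <- function(params, run_in = 2) {
  run <- simulate_deterministic(params, c(0, 0, 0, 0), t_end = run_in)
  endpoint <- run$states[nrow(run$states), ]
  list(origin = c(0, 0, 0, 0),
       run_in = as.double(endpoint),
       corner_high = c(1, 1, 2, 2),
       corner_thal = c(0, 0, 2, 2),
       corner_py = c(1, 0, 0, 0))
}

## analytic Jacobian of the drift
drift_jacobian <- function(state, p) {
  py <- state[1]; in_ <- state[2]; tc <- state[3]
  sp <- function(u) {
    s <- 1 / (1 + exp(-p$a * (u - p$theta)))
    p$a * s * (1 - s)
  }
  d1 <- sp(p$c1 * py - p$c3 * in_ + p$c9 * tc + p$h_py)
  d2 <- sp(p$c2 * py + p$h_in)
  matrix(c(
    (-1 + d1 * p$c1) / p$tau1, -d1 * p$c3 / p$tau1, d1 * p$c9 / p$tau1, 0,
    d2 * p$c2 / p$tau2, -1 / p$tau2, 0, 0,
    p$c7 / p$tau3, 0, -1 / p$tau3, -p$c6 / p$tau3,
    p$c8 / p$tau4, 0, p$c5 / p$tau4, -(1 + p$c4) / p$tau4),
    4, 4, byrow = TRUE)
}

## Newton search for an equilibrium of the drift; returns the state or
## NULL, plus a stability flag from the Jacobian eigenvalues
find_equilibrium <- function(params, start, max_iter = 60, tol = 1e-11) {
  x <- as.double(start)
  for (k in seq_len(max_iter)) {
    f <- as.double(model_drift(x, params))
    if (max(abs(f)) < tol) {
      ev <- eigen(drift_jacobian(x, params), only.values = TRUE)$values
      return(list(state = x, stable = all(Re(ev) < 0)))
    }
    step <- tryCatch(solve(drift_jacobian(x, params), f),
                     error = function(e) NULL)
    if (is.null(step)) return(NULL)
    x <- x - as.double(step)
    if (any(!is.finite(x)) || max(abs(x)) > 1e6) return(NULL)
  }
  NULL
}

#' Classify a parameter point, probing for bistability
#'
#' Simulates deterministically from a spread of initial conditions.  If
#' both a fixed point and an oscillatory regime are reached the point is
#' `BISTABLE` (with the oscillatory attractor's fundamental); otherwise
#' the common label is returned.
#'
#' Because the fixed-point basin can be much smaller than any generic
#' initial-condition spread near the seizure frontier, an oscillatory
#' verdict is additionally cross-examined with a Newton search for an
#' equilibrium: if a linearly stable equilibrium coexists with the
#' simulated oscillation, the point is `BISTABLE` even though no
#' trajectory of the spread settled there.
#'
#' @param params a [tc_params()] object.
#' @param inits list of at least 5 initial states; default
#'   [default_inits()].
#' @param t_end simulation length per initial condition (seconds).
#' @param transient transient discard (seconds).
#' @param ... passed to [classify_trajectory()].
#' @return A `regime_label` whose `label` may also be `BISTABLE`.
#' @export
classify_parameter_point <- function(params, inits = NULL, t_end = 10,
                                     transient = 2, ...) {
  if (is.null(inits)) inits <- default_inits(params)
  stopifnot(length(inits) >= 5)
  labs <- lapply(inits, function(i0)
    classify_trajectory(simulate_deterministic(params, i0, t_end),
                        transient = transient, ...))
  ll <- vapply(labs, `[[`, "", "label")
  if (any(ll == "FIXED_POINT") && any(ll != "FIXED_POINT")) {
    osc <- labs[[which(ll != "FIXED_POINT")[1]]]
    return(new_regime_label("BISTABLE", osc$fundamental_hz,
                            osc$extrema_per_cycle,
                            any(vapply(labs, `[[`, TRUE, "warning_flag"))))
  }
  if (all(ll != "FIXED_POINT")) {
    ## all trajectories oscillate; a coexisting stable equilibrium still
    ## makes the point bistable
    for (i0 in inits) {
      eq <- find_equilibrium(params, i0)
      if (!is.null(eq) && eq$stable) {
        osc <- labs[[1]]
        return(new_regime_label("BISTABLE", osc$fundamental_hz,
                                osc$extrema_per_cycle,
                                any(vapply(labs, `[[`, TRUE,
                                           "warning_flag"))))
      }
    }
  }
  labs[[1]]
}
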