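#' Thalamocortical model parameters
#'
#' Container for all constants of the four-population thalamocortical
#' model: time constants, connectivity weights, external inputs, the
#' sigmoid activation shape, the noise amplitude and the stochastic solver
#' step.
#'
#' The four populations are cortical pyramidal cells (PY), cortical
#' inhibitory interneurons (IN), thalamocortical relay cells (TC) and
#' thalamic reticular nucleus neurons (RE).  The connectivity weights
#' follow the circuit arrows: `c1` PY self-excitation, `c2` PY to IN,
#' `c3` IN to PY inhibition, `c4` RE self-inhibition, `c5` TC to RE,
#' `c6` RE to TC inhibition, `c7` PY to TC, `c8` PY to RE, `c9` TC to PY.
#'
#' The shipped defaults are a calibrated operating point (see the methods
#' vignette): the cortical pair sits just above a 20-30 Hz
#' oscillatory drive band, so that reducing `c1` or raising `c8` moves the
#' circuit into seizure dynamics.
#'
#' @param tau1,tau2,tau3,tau4 time constants in seconds for PY, IN, TC, RE;
#'   must be positive.
#' @param c1,c2,c3,c4,c5,c6,c7,c8,c9 non-negative connectivity weights
#'   (dimensionless).
#' @param h_py,h_in,h_tc,h_re external input levels (dimensionless),
#'   interpretable as population excitability offsets.
#' @param a sigmoid steepness (dimensionless, positive).
#' @param theta sigmoid offset (dimensionless).
#' @param alpha noise amplitude on the TC population; non-negative.
#' @param dt stochastic (Euler-Maruyama) solver step in seconds.
#' @return An object of class `tc_params`: a named list with the fields
#'   above.
#' @examples
#' p <- tc_params()
#' p$c8
#' p2 <- tc_params(c8 = 4)   # strengthen the cortico-reticular projection
#' @seealso [tc_preset()] for the shipped named presets,
#'   [simulate_deterministic()], [simulate_stochastic()].
#' @export
tc_params <- function(tau1 = 0.006, tau2 = 0.012, tau3 = 0.25, tau4 = 0.25,
                      c1 = 11, c2 = 12, c3 = 10, c4 = 0.2, c5 = 3, c6 = 2,
                      c7 = 1.5, c8 = 1.2, c9 = 6,
                      h_py = -1, h_in = -2, h_tc = 6.9, h_re = -2,
                      a = 1, theta = 4, alpha = 0, dt = 1 / 15000) {
  p <- list(tau1 = tau1, tau2 = tau2, tau3 = tau3, tau4 = tau4,
            c1 = c1, c2 = c2, c3 = c3, c4 = c4, c5 = c5, c6 = c6,
            c7 = c7, c8 = c8, c9 = c9,
            h_py = h_py, h_in = h_in, h_tc = h_tc, h_re = h_re,
            a = a, theta = theta, alpha = alpha, dt = dt)
  p <- lapply(p, as.double)
  validate_tc_params(p)
  structure(p, class = "tc_params")
}

validate_tc_params <- function(p) {
  stopifnot(is.list(p))
  bad <- names(p)[!vapply(p, function(v) length(v) == 1 && is.finite(v),
                          logical(1))]
  if (length(bad))
    stop("non-finite or non-scalar parameter(s): ", paste(bad, collapse = ", "))
  for (f in c("tau1", "tau2", "tau3", "tau4", "dt", "a"))
    if (p[[f]] <= 0) stop("'", f, "' must be positive")
  for (f in paste0("c", 1:9))
    if (p[[f]] < 0) stop("'", f, "' must be non-negative")
  if (p$alpha < 0) stop("'alpha' must be non-negative")
  invisible(p)
}

#' @export
print.tc_params <- function(x, ...) {
  cat("Thalamocortical model parameters\n")
  cat(sprintf("  tau (PY,IN,TC,RE): %g %g %g %g s\n",
              x$tau1, x$tau2, x$tau3, x$tau4))
  cat("  connectivity:", paste0("c", 1:9, "=",
                                vapply(paste0("c", 1:9),
                                       function(f) format(x[[f]]), "")),
      "\n")
  cat(sprintf("  inputs: h_py=%g h_in=%g h_tc=%g h_re=%g\n",
              x$h_py, x$h_in, x$h_tc, x$h_re))
  cat(sprintf("  sigmoid: a=%g theta=%g;  noise alpha=%g;  dt=%g s\n",
              x$a, x$theta, x$alpha, x$dt))
  invisible(x)
}

## C-side parameter vector (sigmoid and drift constants; noise and dt are
## passed separately)
par_vec <- function(p) {
  as.double(c(p$tau1, p$tau2, p$tau3, p$tau4,
              p$c1, p$c2, p$c3, p$c4, p$c5, p$c6, p$c7, p$c8, p$c9,
              p$h_py, p$h_in, p$h_tc, p$h_re, p$a, p$theta))
}

## compact label used in divergence diagnostics
par_point_label <- function(p) {
  paste0("c1=", format(p$c1), ", c7=", format(p$c7),
         ", c8=", format(p$c8), ", c9=", format(p$c9))
}

#' Load a shipped parameter preset
#'
#' Three presets are installed with the package: `"default"` (the healthy
#' operating point, a stable fixed point), `"bistable"` (fixed point and
#' spike-wave attractor coexist; nonzero noise amplitude so stochastic runs
#' show seizure transitions) and `"swd"` (monostable spike-wave discharge
#' at about 4 Hz).
#'
#' @param name preset name.
#' @return A [tc_params()] object.
#' @examples
#' tc_preset("bistable")$alpha
#' @export
tc_preset <- function(name = c("default", "bistable", "swd")) {
  name <- match.arg(name)
  read_params(system.file("extdata", "presets", paste0(name, ".yaml"),
                          package = "ictogen", mustWork = TRUE))
}

#' Read model parameters from a YAML or JSON file
#'
#' The file must contain one key per [tc_params()] field; unknown keys are
#' rejected, missing keys take the calibrated defaults.
#'
#' @param path file path; format chosen by extension (`.yaml`/`.yml` or
#'   `.json`).
#' @return A [tc_params()] object.
#' @export
read_params <- function(path) {
  vals <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  known <- names(formals(tc_params))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop("unknown parameter key(s) in '", path, "': ",
         paste(unknown, collapse = ", "))
  do.call(tc_params, lapply(vals, as.double))
}

#' Write model parameters to a YAML file
#'
#' @param params a [tc_params()] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_params <- function(params, path) {
  stopifnot(inherits(params, "tc_params"))
  yaml::write_yaml(lapply(unclass(params), as.double), path)
  invisible(path)
}
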