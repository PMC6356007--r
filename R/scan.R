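## ---- regime atlas: plane scans, frontiers, routes ---------------------

SEIZURE_LABELS <- c("SWD", "FAST_OSC", "BISTABLE")

#' Chart model regimes over a two-parameter plane
#'
#' Classifies every cell of a grid over one connectivity-parameter pair
#' (typically the cortico-cortical weight `c1` against one of the
#' cortico-thalamic weights `c7`, `c8`, `c9`) with
#' [classify_parameter_point()].  The scan is deterministic given the base
#' parameters and the grids.
#'
#' @param base a [tc_params()] object; all parameters except the scanned
#'   pair are held at these values.
#' @param x_param,y_param names of the scanned parameters (fields of
#'   [tc_params()], usually among `c1`, `c7`, `c8`, `c9`).
#' @param x_grid,y_grid strictly increasing numeric grids.
#' @param t_end,transient simulation length and transient discard per
#'   cell, in seconds.
#' @param inits initial-condition spread; default [default_inits()] of
#'   `base`, computed once and reused across cells.
#' @param ... passed to [classify_trajectory()].
#' @return A `plane_scan`: label matrix (rows = `y_grid`, columns =
#'   `x_grid`), matching matrices of fundamental frequencies and warning
#'   flags, the grids, parameter names and `base`.
#' @examples
#' \donttest{
#' sc <- scan_plane(tc_preset("default"), "c1", "c8",
#'                  seq(8, 14, length.out = 5), seq(0, 4, length.out = 5))
#' table(sc$labels)
#' }
#' @export
scan_plane <- function(base, x_param, y_param, x_grid, y_grid,
                       t_end = 10, transient = 2, inits = NULL, ...) {
  stopifnot(inherits(base, "tc_params"),
            x_param %in% names(base), y_param %in% names(base),
            x_param != y_param)
  x_grid <- as.double(x_grid); y_grid <- as.double(y_grid)
  if (length(x_grid) > 1 && any(diff(x_grid) <= 0))
    stop("'x_grid' must be strictly increasing")
  if (length(y_grid) > 1 && any(diff(y_grid) <= 0))
    stop("'y_grid' must be strictly increasing")
  if (is.null(inits)) inits <- default_inits(base)
  nx <- length(x_grid); ny <- length(y_grid)
  labels <- matrix(NA_character_, ny, nx)
  fund <- matrix(NA_real_, ny, nx)
  warn <- matrix(FALSE, ny, nx)
  for (j in seq_len(nx)) {
    for (i in seq_len(ny)) {
      p <- base
      p[[x_param]] <- x_grid[j]
      p[[y_param]] <- y_grid[i]
      z <- tryCatch(
        classify_parameter_point(p, inits = inits, t_end = t_end,
                                 transient = transient, ...),
        error = function(e)
          stop("scan failed at cell (", x_param, " = ", x_grid[j], ", ",
               y_param, " = ", y_grid[i], "): ", conditionMessage(e),
               call. = FALSE))
      labels[i, j] <- z$label
      fund[i, j] <- z$fundamental_hz
      warn[i, j] <- z$warning_flag
    }
  }
  structure(list(x_param = x_param, y_param = y_param,
                 x_values = x_grid, y_values = y_grid,
                 labels = labels, fundamental_hz = fund,
                 warning_flags = warn, params_base = base),
            class = "plane_scan")
}

#' @export
print.plane_scan <- function(x, ...) {
  cat(sprintf("plane_scan: %s [%g..%g] x %s [%g..%g], %d x %d cells\n",
              x$x_param, min(x$x_values), max(x$x_values),
              x$y_param, min(x$y_values), max(x$y_values),
              length(x$x_values), length(x$y_values)))
  print(table(factor(x$labels,
                     c("FIXED_POINT", "SWD", "FAST_OSC", "BISTABLE"))))
  invisible(x)
}

#' @export
plot.plane_scan <- function(x, ...) {
  lv <- c("FIXED_POINT", "SWD", "FAST_OSC", "BISTABLE")
  cols <- c("#4477AA", "#EE7733", "#BBBBBB", "#CCBB44")
  z <- matrix(match(x$labels, lv), nrow(x$labels))
  image(x$x_values, x$y_values, t(z), zlim = c(1, 4),
        col = cols, xlab = x$x_param, ylab = x$y_param, ...)
  legend("topright", legend = lv[sort(unique(as.vector(z)))],
         fill = cols[sort(unique(as.vector(z)))], bg = "white", cex = .8)
  invisible(x)
}

seizure_matrix <- function(scan, seizure_labels = SEIZURE_LABELS) {
  m <- matrix(scan$labels %in% seizure_labels, nrow(scan$labels))
  m
}

#' Orientation of the seizure frontier in a plane scan
#'
#' Cells are binarised into seizure (`SWD`, `FAST_OSC`, `BISTABLE`) versus
#' non-seizure.  For each grid column the frontier ordinate is the first
#' label flip going up the column; when a column flips more than once, the
#' flip nearest the plane's median first-flip is used.  A least-squares
#' line through the frontier points gives the slope sign and which side of
#' the line carries the seizure labels.  A ridge of the same information
#' can also be extracted from a logistic surface fit
#' (`method = "logistic"`), kept as an internal cross-check of the
#' column-flip extraction.
#'
#' @param scan a [scan_plane()] result.
#' @param method `"flips"` (column-wise first flip + least squares) or
#'   `"logistic"` (two-covariate logistic fit; boundary is its 0.5 level
#'   line).
#' @param seizure_labels labels counted as seizure-supporting.
#' @return List with `slope_sign` (-1, 0, +1), `seizure_side` (`"ABOVE"`
#'   or `"BELOW"`), the fitted `slope` and `intercept`, and the frontier
#'   points used (for `method = "flips"`).
#' @export
frontier_orientation <- function(scan, method = c("flips", "logistic"),
                                 seizure_labels = SEIZURE_LABELS) {
  stopifnot(inherits(scan, "plane_scan"))
  method <- match.arg(method)
  seiz <- seizure_matrix(scan, seizure_labels)
  if (all(seiz) || !any(seiz))
    stop("no seizure/non-seizure frontier in this scan (single class)")
  xs <- scan$x_values; ys <- scan$y_values
  if (method == "logistic") {
    df <- data.frame(seiz = as.vector(seiz),
                     x = rep(xs, each = length(ys)),
                     y = rep(ys, times = length(xs)))
    fit <- suppressWarnings(stats::glm(seiz ~ x + y, binomial(), df))
    b <- coef(fit)
    if (abs(b["y"]) < 1e-12)
      stop("logistic boundary is vertical in this plane")
    slope <- -b["x"] / b["y"]
    intercept <- -b["(Intercept)"] / b["y"]
    side <- if (b["y"] > 0) "ABOVE" else "BELOW"
    return(list(slope_sign = sign_tol(slope), seizure_side = side,
                slope = unname(slope), intercept = unname(intercept),
                frontier_points = NULL, method = method))
  }
  flips <- lapply(seq_along(xs), function(j) {
    col <- seiz[, j]
    fl <- which(col[-1] != col[-length(col)])
    if (!length(fl)) return(NULL)
    (ys[fl] + ys[fl + 1]) / 2
  })
  first <- vapply(flips, function(f) if (is.null(f)) NA_real_ else f[1],
                  0)
  if (all(is.na(first)))
    stop("no seizure/non-seizure frontier in this scan (no column flips)")
  med <- median(first, na.rm = TRUE)
  yf <- vapply(flips, function(f) {
    if (is.null(f)) return(NA_real_)
    f[which.min(abs(f - med))]
  }, 0)
  ok <- !is.na(yf)
  fit <- lm(yf[ok] ~ xs[ok])
  slope <- unname(coef(fit)[2])
  if (is.na(slope)) slope <- 0   # single usable column
  intercept <- unname(coef(fit)[1])
  pred <- matrix(rep(intercept + slope * xs, each = length(ys)),
                 length(ys))
  above <- sum(outer(ys, rep(1, length(xs))) > pred & seiz) / sum(seiz)
  list(slope_sign = sign_tol(slope),
       seizure_side = if (above > 0.5) "ABOVE" else "BELOW",
       slope = slope, intercept = intercept,
       frontier_points = data.frame(x = xs[ok], y = yf[ok]),
       method = method)
}

sign_tol <- function(s, tol = 1e-10) {
  if (abs(s) <= tol) 0L else if (s > 0) 1L else -1L
}

#' Epileptogenic routes from a healthy parameter point
#'
#' Given a non-seizure cell of a plane scan, finds for each of the three
#' direction families - decrease of the x parameter, increase of the y
#' parameter, and the joint diagonal - the minimal displacement along the
#' grid whose endpoint is seizure-labelled.
#'
#' @param scan a [scan_plane()] result.
#' @param healthy_point length-2 numeric `(x, y)` inside the scanned
#'   grids.
#' @param seizure_labels labels counted as seizure-supporting.
#' @return List with one entry per family (`dec_x`, `inc_y`, `diagonal`):
#'   each has `reachable`, and when reachable the number of grid steps,
#'   the displacement `(dx, dy)` and the endpoint values.
#' @export
epileptogenic_routes <- function(scan, healthy_point,
                                 seizure_labels = SEIZURE_LABELS) {
  stopifnot(inherits(scan, "plane_scan"), length(healthy_point) == 2)
  xs <- scan$x_values; ys <- scan$y_values
  if (healthy_point[1] < min(xs) || healthy_point[1] > max(xs) ||
      healthy_point[2] < min(ys) || healthy_point[2] > max(ys))
    stop("healthy_point lies outside the scanned grid")
  j0 <- which.min(abs(xs - healthy_point[1]))
  i0 <- which.min(abs(ys - healthy_point[2]))
  seiz <- seizure_matrix(scan, seizure_labels)
  if (seiz[i0, j0])
    stop("healthy_point is classified as seizure-supporting (",
         scan$labels[i0, j0], ")")
  walk <- function(di, dj) {
    i <- i0; j <- j0; steps <- 0L
    repeat {
      i <- i + di; j <- j + dj; steps <- steps + 1L
      if (i < 1 || i > length(ys) || j < 1 || j > length(xs))
        return(list(reachable = FALSE))
      if (seiz[i, j])
        return(list(reachable = TRUE, steps = steps,
                    dx = xs[j] - xs[j0], dy = ys[i] - ys[i0],
                    endpoint = c(x = xs[j], y = ys[i]),
                    label = scan$labels[i, j]))
    }
  }
  list(dec_x = walk(0L, -1L), inc_y = walk(1L, 0L),
       diagonal = walk(1L, -1L))
}

#' Brute-force bifurcation diagram along one parameter
#'
#' For each parameter value the deterministic model is run from a fixed
#' initial state; the post-transient local extrema of PY are recorded.
#' Fixed-point cells yield a single value (the equilibrium level).
#'
#' @param base a [tc_params()] object.
#' @param param_name scanned parameter name.
#' @param grid strictly increasing values.
#' @param init initial state used for every value.
#' @param t_end,transient run length and transient discard (seconds).
#' @param prominence extrema prominence filter (fraction of signal range).
#' @return A `bifurcation_diagram`: the grid and a list of extrema-value
#'   vectors (singleton for fixed points), with a `plot()` method.
#' @export
bifurcation_diagram <- function(base, param_name, grid,
                                init = c(0, 0, 0, 0), t_end = 10,
                                transient = 2, prominence = 0.05) {
  stopifnot(inherits(base, "tc_params"), param_name %in% names(base))
  grid <- as.double(grid)
  if (length(grid) > 1 && any(diff(grid) <= 0))
    stop("'grid' must be strictly increasing")
  extrema <- lapply(grid, function(v) {
    p <- base
    p[[param_name]] <- v
    traj <- simulate_deterministic(p, init, t_end)
    py <- traj$states[traj$times >= transient, "py"]
    if (diff(range(py)) < 1e-5) return(mean(py))
    sort(c(py[local_maxima(py, prominence)],
           py[local_maxima(-py, prominence)]))
  })
  structure(list(param_name = param_name, param_values = grid,
                 extrema = extrema, params_base = base),
            class = "bifurcation_diagram")
}

#' @export
plot.bifurcation_diagram <- function(x, ...) {
  xx <- rep(x$param_values, lengths(x$extrema))
  yy <- unlist(x$extrema)
  plot(xx, yy, pch = 16, cex = .4, xlab = x$param_name, ylab = "PY extrema",
       ...)
  invisible(x)
}

#' Export a plane scan as TSV plus a JSON parameter sidecar
#'
#' Writes `<prefix>_labels.tsv` (label matrix with axis values as header
#' row and first column) and `<prefix>_params.json` (base parameters and
#' scan metadata).
#'
#' @param scan a [scan_plane()] result.
#' @param prefix output path prefix.
#' @return The two paths, invisibly.
#' @export
write_plane_scan <- function(scan, prefix) {
  stopifnot(inherits(scan, "plane_scan"))
  lab <- scan$labels
  df <- data.frame(y = scan$y_values, lab, check.names = FALSE)
  colnames(df) <- c(scan$y_param, sprintf("%.10g", scan$x_values))
  p_lab <- paste0(prefix, "_labels.tsv")
  utils::write.table(df, p_lab, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  p_json <- paste0(prefix, "_params.json")
  jsonlite::write_json(list(x_param = scan$x_param, y_param = scan$y_param,
                            x_values = scan$x_values,
                            y_values = scan$y_values,
                            params_base = unclass(scan$params_base)),
                       p_json, auto_unbox = TRUE, digits = NA)
  invisible(c(p_lab, p_json))
}
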