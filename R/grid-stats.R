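## ---- threshold-grid statistics ---------------------------------------

#' Validate and normalise a cohort table
#'
#' @param cohort data frame with columns `subject_id`, `group`
#'   (`PATIENT`/`CONTROL`), `age` (years, positive) and `sex` (`M`/`F`).
#' @return The cohort with columns coerced, invisibly usable downstream.
#' @export
as_cohort <- function(cohort) {
  need <- c("subject_id", "group", "age", "sex")
  if (!all(need %in% names(cohort)))
    stop("cohort must have columns ", paste(need, collapse = ", "))
  cohort$subject_id <- as.character(cohort$subject_id)
  cohort$group <- toupper(as.character(cohort$group))
  cohort$sex <- toupper(as.character(cohort$sex))
  if (anyDuplicated(cohort$subject_id)) stop("subject ids must be unique")
  if (!all(cohort$group %in% c("PATIENT", "CONTROL")))
    stop("group must be PATIENT or CONTROL")
  if (!all(cohort$sex %in% c("M", "F"))) stop("sex must be M or F")
  if (any(!is.finite(cohort$age)) || any(cohort$age <= 0))
    stop("ages must be positive and finite")
  cohort
}

#' Regress age and sex out of a per-subject measure
#'
#' Ordinary least squares of the values on an intercept, age and a sex
#' indicator, fitted over the whole cohort (patients and controls
#' pooled; group is not in the model).  Residuals are returned and are
#' numerically orthogonal to both covariates.
#'
#' @param values numeric vector, one value per cohort row.
#' @param cohort a cohort table (see [as_cohort()]) with at least 4 rows.
#' @return Residual vector of the same length.
#' @examples
#' co <- generate_cohort(seed = 1)
#' r <- residualize_covariates(3 * co$age, co)
#' max(abs(r)) < 1e-8
#' @export
residualize_covariates <- function(values, cohort) {
  cohort <- as_cohort(cohort)
  if (length(values) != nrow(cohort))
    stop("length(values) must equal nrow(cohort)")
  if (nrow(cohort) < 4) stop("need at least 4 subjects")
  if (anyNA(values) || anyNA(cohort$age) || anyNA(cohort$sex))
    stop("missing values or covariates")
  X <- cbind(intercept = 1, age = cohort$age,
             sexM = as.numeric(cohort$sex == "M"))
  if (length(unique(cohort$sex)) == 1) {
    warning("single-sex cohort; dropping the sex indicator")
    X <- X[, c("intercept", "age"), drop = FALSE]
  }
  fit <- lm.fit(X, values)
  unname(fit$residuals)
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Exact enumeration when the combined sample size is at most 12 and
#' there are no ties; otherwise the normal approximation with tie
#' correction and continuity correction.  Identical constant samples give
#' p = 1.
#'
#' @param x,y non-empty numeric samples.
#' @return Two-sided p-value.
#' @examples
#' rank_sum_test(c(1, 2, 3), c(4, 5, 6))  # 0.1, exact
#' @export
rank_sum_test <- function(x, y) {
  if (!length(x) || !length(y)) stop("both samples must be non-empty")
  if (length(unique(c(x, y))) == 1) return(1)
  exact <- (length(x) + length(y) <= 12) && !anyDuplicated(c(x, y))
  suppressWarnings(
    wilcox.test(x, y, exact = exact, correct = TRUE)$p.value)
}

#' Benjamini-Hochberg false discovery rate procedure
#'
#' Step-up procedure: with sorted p-values `p_(1) <= ... <= p_(m)`, the
#' rejection set is the largest `k` with `p_(k) <= k q / m` (and all
#' smaller ranks).  Adjusted values are the usual monotone BH adjustment.
#'
#' @param p p-values in \[0, 1\].
#' @param q target false discovery rate.
#' @return List with `p_adjusted` and logical `reject`, both in input
#'   order; empty input gives empty output.
#' @examples
#' bh_fdr(c(0.01, 0.02, 0.04, 0.2))$reject
#' @export
bh_fdr <- function(p, q = 0.05) {
  if (!length(p)) return(list(p_adjusted = numeric(0), reject = logical(0)))
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  m <- length(p)
  o <- order(p)
  k <- which(p[o] <= seq_len(m) * q / m)
  reject <- rep(FALSE, m)
  if (length(k)) reject[o[seq_len(max(k))]] <- TRUE
  list(p_adjusted = p.adjust(p, "BH"), reject = reject)
}

#' Cohen's d with the control-minus-patient convention
#'
#' Standardised mean difference `(mean(control) - mean(patient)) / s_p`
#' with the pooled standard deviation using n - 1 denominators.  A
#' reduction in patients therefore gives positive d; an increase gives
#' negative d.
#'
#' @param control,patient numeric samples, each with at least 2 values.
#' @param hedges if `TRUE`, apply the Hedges small-sample bias correction
#'   `1 - 3 / (4 N - 9)`.
#' @return The effect size.
#' @examples
#' cohens_d(c(2, 3, 4), c(1, 2, 3))  # 1
#' @export
cohens_d <- function(control, patient, hedges = FALSE) {
  n1 <- length(control); n2 <- length(patient)
  if (n1 < 2 || n2 < 2) stop("each group needs at least 2 values")
  sp <- sqrt(((n1 - 1) * stats::var(control) +
                (n2 - 1) * stats::var(patient)) / (n1 + n2 - 2))
  if (sp == 0) stop("pooled standard deviation is zero")
  d <- (mean(control) - mean(patient)) / sp
  if (hedges) d <- d * (1 - 3 / (4 * (n1 + n2) - 9))
  d
}

#' Two-threshold significance grid
#'
#' Implements the grid quantification of connectometry output: at each
#' (tract length, t-score) threshold cell the per-subject mean gFA values
#' are residualised for age and sex, compared between patients and
#' controls by the Wilcoxon rank-sum test, and the p-values are corrected
#' across the grid by Benjamini-Hochberg FDR.  The binary significance
#' mask (`p_fdr < alpha`) is multiplied element-wise with the streamline
#' count mask (`counts >= count_threshold`).
#'
#' Cells with zero detected streamlines get p = 1 and d = 0, are excluded
#' from the FDR family and are masked out.
#'
#' @param grid a `threshold_grid` (see [generate_threshold_grid()] or
#'   [read_grid_csv()]).
#' @param cohort cohort table aligned with the grid's subject ids.
#' @param count_threshold minimum streamline count (`Inf` empties the
#'   mask).
#' @param q FDR level.
#' @param alpha binary threshold applied to the corrected p-values.
#' @return A `grid_mask`: matrices `p_raw`, `p_fdr`, `d`, `count_mask`,
#'   `p_mask`, `final_mask` (rows = length thresholds, columns = t-score
#'   thresholds).
#' @export
grid_significance_mask <- function(grid, cohort, count_threshold = 100,
                                   q = 0.05, alpha = 0.05) {
  stopifnot(inherits(grid, "threshold_grid"))
  cohort <- as_cohort(cohort)
  if (!identical(sort(cohort$subject_id), sort(grid$subject_ids)))
    stop("cohort subject ids do not match the grid")
  cohort <- cohort[match(grid$subject_ids, cohort$subject_id), ]
  pat <- cohort$group == "PATIENT"
  nl <- length(grid$length_values); nt <- length(grid$tscore_values)
  p_raw <- matrix(1, nl, nt)
  d <- matrix(0, nl, nt)
  nonempty <- grid$counts > 0
  for (i in seq_len(nl)) {
    for (j in seq_len(nt)) {
      if (!nonempty[i, j]) next
      vals <- grid$gfa[i, j, ]
      if (diff(range(vals)) == 0) next   # degenerate: no information
      res <- residualize_covariates(vals, cohort)
      p_raw[i, j] <- rank_sum_test(res[pat], res[!pat])
      sp_ok <- sd(res[!pat]) > 0 || sd(res[pat]) > 0
      d[i, j] <- if (sp_ok) cohens_d(res[!pat], res[pat]) else 0
    }
  }
  p_fdr <- matrix(1, nl, nt)
  fam <- which(nonempty)
  if (length(fam)) {
    adj <- bh_fdr(p_raw[fam], q)
    p_fdr[fam] <- adj$p_adjusted
  }
  p_mask <- p_fdr < alpha & nonempty
  count_mask <- grid$counts >= count_threshold
  structure(list(p_raw = p_raw, p_fdr = p_fdr, d = d,
                 count_mask = count_mask, p_mask = p_mask,
                 final_mask = p_mask & count_mask,
                 length_values = grid$length_values,
                 tscore_values = grid$tscore_values,
                 count_threshold = count_threshold, q = q, alpha = alpha),
            class = "grid_mask")
}

#' @export
print.grid_mask <- function(x, ...) {
  cat(sprintf(paste0("grid_mask: %d x %d cells; %d significant after FDR,",
                     " %d pass counts >= %g, %d in final mask\n"),
              nrow(x$p_raw), ncol(x$p_raw), sum(x$p_mask),
              sum(x$count_mask), x$count_threshold, sum(x$final_mask)))
  invisible(x)
}

#' Statistics at one representative grid cell
#'
#' Convenience accessor for box-plot-style reporting at a single
#' threshold pair (default: t-score 1.94 at tract length 30 mm).
#'
#' @param grid a `threshold_grid`.
#' @param cohort aligned cohort table.
#' @param length_mm,tscore the cell; the nearest grid values are used.
#' @return List with the residualised group values, `p` and `d`.
#' @export
grid_cell_stats <- function(grid, cohort, length_mm = 30, tscore = 1.94) {
  stopifnot(inherits(grid, "threshold_grid"))
  cohort <- as_cohort(cohort)
  cohort <- cohort[match(grid$subject_ids, cohort$subject_id), ]
  i <- which.min(abs(grid$length_values - length_mm))
  j <- which.min(abs(grid$tscore_values - tscore))
  res <- residualize_covariates(grid$gfa[i, j, ], cohort)
  pat <- cohort$group == "PATIENT"
  list(length_mm = grid$length_values[i], tscore = grid$tscore_values[j],
       residuals_control = res[!pat], residuals_patient = res[pat],
       p = rank_sum_test(res[pat], res[!pat]),
       d = cohens_d(res[!pat], res[pat]),
       count = grid$counts[i, j])
}

#' Write masks of a grid analysis as TSV matrices
#'
#' Emits `<prefix>_p_raw.tsv`, `<prefix>_p_fdr.tsv`, `<prefix>_d.tsv` and
#' `<prefix>_final_mask.tsv`, each with t-score values as the header row
#' and length values as the first column.
#'
#' @param mask a [grid_significance_mask()] result.
#' @param prefix output path prefix.
#' @return The paths, invisibly.
#' @export
write_grid_mask <- function(mask, prefix) {
  stopifnot(inherits(mask, "grid_mask"))
  emit <- function(m, what) {
    df <- data.frame(length_mm = mask$length_values, m + 0,
                     check.names = FALSE)
    colnames(df) <- c("length_mm", sprintf("%.10g", mask$tscore_values))
    path <- paste0(prefix, "_", what, ".tsv")
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    path
  }
  invisible(c(emit(mask$p_raw, "p_raw"), emit(mask$p_fdr, "p_fdr"),
              emit(mask$d, "d"), emit(mask$final_mask, "final_mask")))
}
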