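## ---- synthetic cohort / feature / grid generators ---------------------

#' Reference patient table of the IGE cohort
#'
#' The 14-patient idiopathic generalised epilepsy cohort used throughout
#' the package documentation: sex, age at scan (mean 34 years), epilepsy
#' duration and onset age, plus the three seizure-type indicator columns
#' (absence 35.7%, myoclonic 50%, generalised tonic-clonic 12/14).
#' Demographics are the published values; the per-patient seizure-type
#' flags are reconstructed to reproduce the published type rates.
#'
#' @return Data frame with one row per patient.
#' @examples
#' mean(reference_patients()$age)   # rounds to 34
#' @export
reference_patients <- function() {
  read.csv(system.file("extdata", "ige_patient_cohort.csv",
                       package = "ictogen", mustWork = TRUE))
}

#' Generate a synthetic study cohort
#'
#' Patients and controls with balanced sexes and ages drawn uniformly
#' within the study's reported ranges (patients 20.6-49.6 years,
#' controls 20.9-46.5 years).  Deterministic for a given seed.
#'
#' @param n_patients,n_controls group sizes (defaults 14 and 18).
#' @param seed integer seed.
#' @param patient_ages optional vector overriding the random patient ages
#'   (e.g. the reference cohort's published ages).
#' @return A cohort data frame with `subject_id`, `group`, `age`, `sex`.
#' @examples
#' co <- generate_cohort(seed = 1)
#' table(co$group, co$sex)
#' @export
generate_cohort <- function(n_patients = 14, n_controls = 18, seed = 1,
                            patient_ages = NULL) {
  stopifnot(n_patients > 0, n_controls > 0)
  set.seed(seed)
  balanced <- function(n) rep(c("M", "F"), length.out = 2 * ceiling(n / 2))[
    seq_len(n)]
  p_age <- if (is.null(patient_ages)) runif(n_patients, 20.6, 49.6) else {
    stopifnot(length(patient_ages) == n_patients)
    as.double(patient_ages)
  }
  co <- data.frame(
    subject_id = c(sprintf("PAT%02d", seq_len(n_patients)),
                   sprintf("CON%02d", seq_len(n_controls))),
    group = rep(c("PATIENT", "CONTROL"), c(n_patients, n_controls)),
    age = c(p_age, runif(n_controls, 20.9, 46.5)),
    sex = c(balanced(n_patients), balanced(n_controls)))
  as_cohort(co)
}

#' Effect specification for a synthetic region
#'
#' Describes the group difference and covariate structure of one
#' region-level gFA measure.  `d` follows the control-minus-patient
#' convention: positive d means the measure is reduced in patients.
#'
#' @param region_name label.
#' @param d target standardised effect size.
#' @param base_mean baseline mean (gFA-like scale).
#' @param sd residual standard deviation, positive.
#' @param age_slope additive age effect per year.
#' @param sex_offset additive offset for male subjects.
#' @return An `effect_spec` list.
#' @export
effect_spec <- function(region_name, d, base_mean = 0.55, sd = 0.03,
                        age_slope = -0.001, sex_offset = 0.005) {
  stopifnot(is.finite(d), sd > 0)
  structure(list(region_name = region_name, d = d, base_mean = base_mean,
                 sd = sd, age_slope = age_slope, sex_offset = sex_offset),
            class = "effect_spec")
}

#' Generate region-level gFA values for a cohort
#'
#' `value = base_mean + age_slope * age + sex_offset * (sex == M) +
#' group_shift + noise` with `noise ~ Normal(0, sd)` and
#' `group_shift = -d * sd` for patients (control-minus-patient
#' convention).
#'
#' @param cohort cohort table.
#' @param spec an [effect_spec()].
#' @param seed integer seed.
#' @return Numeric vector aligned with the cohort rows.
#' @export
generate_region_gfa <- function(cohort, spec, seed = 1) {
  cohort <- as_cohort(cohort)
  stopifnot(inherits(spec, "effect_spec"))
  set.seed(seed)
  n <- nrow(cohort)
  spec$base_mean + spec$age_slope * cohort$age +
    spec$sex_offset * (cohort$sex == "M") -
    spec$d * spec$sd * (cohort$group == "PATIENT") +
    rnorm(n, 0, spec$sd)
}

default_count_profile <- function(length_values, tscore_values) {
  f_len <- 400 - 15 * (length_values - 20)
  g_t <- 400 - 600 * (tscore_values - 1.5)
  counts <- outer(f_len, g_t, pmin)
  matrix(pmax(0L, as.integer(round(counts))), length(length_values))
}

#' Generate a synthetic two-threshold grid
#'
#' Builds per-cell, per-subject mean-gFA values and streamline counts
#' over the (tract length, t-score) threshold grid.  Cells inside
#' `affected_region` carry the group effect of `spec` and at least 100
#' streamlines under the default count profile; cells outside are null.
#' Counts decrease monotonically with both thresholds.  gFA noise shares
#' a per-subject latent term (weight `latent_weight`) across cells, so
#' neighbouring cells are realistically correlated.
#'
#' @param cohort cohort table.
#' @param affected_region list with `length = c(lo, hi)` and
#'   `tscore = c(lo, hi)` (inclusive); `NULL` for a pure-null grid.
#' @param spec an [effect_spec()]; its `d` applies inside the region.
#' @param count_profile either `NULL` for the default profile (counts of
#'   400 at the laxest thresholds, crossing 100 at the default region's
#'   far edge) or a `function(length_values, tscore_values)` returning a
#'   count matrix.
#' @param seed integer seed.
#' @param latent_weight weight of the shared subject-level noise term,
#'   in \[0, 1).
#' @param length_values,tscore_values threshold grids (defaults
#'   20-60 mm by 2 and 1.5-2.5 by 0.05).
#' @return A `threshold_grid`: gFA array (length x t-score x subject),
#'   count matrix, grids, subject ids and the affected-cell mask.
#' @export
generate_threshold_grid <- function(cohort,
                                    affected_region = list(
                                      length = c(20, 40),
                                      tscore = c(1.5, 2.0)),
                                    spec = effect_spec("synthetic", 1.3),
                                    count_profile = NULL, seed = 1,
                                    latent_weight = 0.5,
                                    length_values = seq(20, 60, by = 2),
                                    tscore_values = seq(1.5, 2.5,
                                                        by = 0.05)) {
  cohort <- as_cohort(cohort)
  stopifnot(inherits(spec, "effect_spec"),
            latent_weight >= 0, latent_weight < 1)
  nl <- length(length_values); nt <- length(tscore_values)
  ns <- nrow(cohort)
  counts <- if (is.null(count_profile)) {
    default_count_profile(length_values, tscore_values)
  } else count_profile(length_values, tscore_values)
  stopifnot(identical(dim(counts), c(nl, nt)), all(counts >= 0))
  affected <- matrix(FALSE, nl, nt)
  if (!is.null(affected_region)) {
    affected <- outer(length_values >= affected_region$length[1] &
                        length_values <= affected_region$length[2],
                      tscore_values >= affected_region$tscore[1] &
                        tscore_values <= affected_region$tscore[2], "&")
  }
  set.seed(seed)
  z_subj <- rnorm(ns)
  base_subj <- spec$base_mean + spec$age_slope * cohort$age +
    spec$sex_offset * (cohort$sex == "M")
  shift_subj <- -spec$d * spec$sd * (cohort$group == "PATIENT")
  gfa <- array(NA_real_, c(nl, nt, ns))
  w <- latent_weight
  for (s in seq_len(ns)) {
    eps <- matrix(rnorm(nl * nt), nl, nt)
    gfa[, , s] <- base_subj[s] + affected * shift_subj[s] +
      spec$sd * (w * z_subj[s] + sqrt(1 - w^2) * eps)
  }
  structure(list(length_values = length_values,
                 tscore_values = tscore_values,
                 gfa = gfa, counts = counts,
                 subject_ids = cohort$subject_id,
                 affected_mask = affected),
            class = "threshold_grid")
}

#' @export
print.threshold_grid <- function(x, ...) {
  cat(sprintf(paste0("threshold_grid: %d lengths x %d t-scores x %d ",
                     "subjects; counts %d..%d; %d affected cells\n"),
              length(x$length_values), length(x$tscore_values),
              length(x$subject_ids), min(x$counts), max(x$counts),
              sum(x$affected_mask)))
  invisible(x)
}

## ---- canonical CSV interchange ---------------------------------------

#' Write / read a cohort table as CSV
#'
#' @param cohort cohort table.
#' @param path file path.
#' @return `path` invisibly (writer); the cohort (reader).
#' @export
write_cohort_csv <- function(cohort, path) {
  write_csv_precise(as_cohort(cohort), path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) as_cohort(read.csv(path))

#' Write / read the two-feature table as CSV
#'
#' Columns `subject_id, group, feature_cc, feature_tc`.
#'
#' @param features a [assemble_features()] result.
#' @param path file path.
#' @return `path` invisibly (writer); the features (reader).
#' @export
write_features_csv <- function(features, path) {
  stopifnot(all(c("subject_id", "group", "feature_cc", "feature_tc") %in%
                  names(features)))
  write_csv_precise(features[, c("subject_id", "group", "feature_cc",
                                 "feature_tc")], path)
}

#' @rdname write_features_csv
#' @export
read_features_csv <- function(path) {
  df <- read.csv(path)
  structure(df, class = c("feature_matrix", "data.frame"))
}

#' Write / read a threshold grid as long-format CSV
#'
#' The canonical interchange format: one row per (length, t-score,
#' subject) with columns `length_mm, tscore, subject_id, gfa, count`.
#' Values survive a write/read round trip bit-identically.
#'
#' @param grid a `threshold_grid`.
#' @param path file path.
#' @return `path` invisibly (writer); the grid (reader).
#' @export
write_grid_csv <- function(grid, path) {
  stopifnot(inherits(grid, "threshold_grid"))
  nl <- length(grid$length_values); nt <- length(grid$tscore_values)
  ns <- length(grid$subject_ids)
  df <- data.frame(
    length_mm = rep(grid$length_values, times = nt * ns),
    tscore = rep(rep(grid$tscore_values, each = nl), times = ns),
    subject_id = rep(grid$subject_ids, each = nl * nt),
    gfa = as.vector(grid$gfa),
    count = rep(as.vector(grid$counts), times = ns))
  write_csv_precise(df, path)
}

#' @rdname write_grid_csv
#' @export
read_grid_csv <- function(path) {
  df <- read.csv(path)
  need <- c("length_mm", "tscore", "subject_id", "gfa", "count")
  if (!all(need %in% names(df)))
    stop("grid CSV must have columns ", paste(need, collapse = ", "))
  lv <- as.double(sort(unique(df$length_mm)))
  tv <- as.double(sort(unique(df$tscore)))
  ids <- unique(df$subject_id)
  nl <- length(lv); nt <- length(tv); ns <- length(ids)
  if (nrow(df) != nl * nt * ns) stop("grid CSV is not a complete grid")
  o <- order(match(df$subject_id, ids), match(df$tscore, tv),
             match(df$length_mm, lv))
  df <- df[o, ]
  gfa <- array(df$gfa, c(nl, nt, ns))
  counts <- matrix(df$count[seq_len(nl * nt)], nl, nt)
  structure(list(length_values = lv, tscore_values = tv, gfa = gfa,
                 counts = counts, subject_ids = ids,
                 affected_mask = matrix(NA, nl, nt)),
            class = "threshold_grid")
}
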