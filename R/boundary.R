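## ---- ridge-regularised logistic decision boundary ---------------------

#' Assemble the two-feature matrix for the decision boundary
#'
#' The two features are the mean gFA over the aberrant thalamo-cortical
#' tracts and over the aberrant cortico-cortical tracts.  Both are
#' residualised for age and sex over the pooled cohort before use.
#'
#' @param tc_gfa,cc_gfa per-subject mean gFA vectors aligned with
#'   `cohort` rows.
#' @param cohort cohort table (see [as_cohort()]).
#' @return A `feature_matrix`: data frame with `subject_id`, `group`,
#'   `feature_cc`, `feature_tc`.
#' @export
assemble_features <- function(tc_gfa, cc_gfa, cohort) {
  cohort <- as_cohort(cohort)
  if (length(tc_gfa) != nrow(cohort) || length(cc_gfa) != nrow(cohort))
    stop("feature vectors must align with the cohort rows")
  structure(data.frame(subject_id = cohort$subject_id,
                       group = cohort$group,
                       feature_cc = residualize_covariates(cc_gfa, cohort),
                       feature_tc = residualize_covariates(tc_gfa, cohort)),
            class = c("feature_matrix", "data.frame"))
}

logistic_objective <- function(w, c0, A, y, rho) {
  z <- y * (A %*% w + c0)
  sum(log1p(exp(-z))) + rho / 2 * sum(w^2)
}

#' Fit the ridge-regularised logistic decision boundary
#'
#' Minimises
#' \deqn{\sum_i \log(1 + e^{-y_i (x^\top a_i + c)}) + \frac{\rho}{2}\|x\|_2^2}
#' over the weight vector `x` and unpenalised intercept `c`, with group
#' labels recoded to +1 (patient) / -1 (control).  Optimisation is by
#' stochastic gradient descent: per-epoch shuffling with a fixed seed,
#' step size `step0 / sqrt(epoch)`.  With `rho > 0` the objective is
#' strictly convex in `x`, so runs from different seeds agree closely.
#'
#' @param features a [assemble_features()] result (or any data frame with
#'   `group`, `feature_cc`, `feature_tc`).
#' @param rho ridge weight; default `1/n`.
#' @param seed seed for the shuffling stream.
#' @param epochs number of passes over the data.
#' @param step0 base step size.
#' @param standardize if `TRUE`, features are scaled to unit variance
#'   before fitting (weights are reported on the original scale).
#' @return A `tc_boundary`: weights (named `cc`, `tc`), intercept, `rho`,
#'   the seed and the attained objective, with `coef()`, `predict()` and
#'   [boundary_line()] methods.
#' @export
fit_logistic_ridge <- function(features, rho = NULL, seed = 1,
                               epochs = 200, step0 = 0.1,
                               standardize = FALSE) {
  stopifnot(all(c("group", "feature_cc", "feature_tc") %in%
                  names(features)))
  y <- ifelse(toupper(features$group) == "PATIENT", 1, -1)
  if (length(unique(y)) < 2) stop("both classes must be present")
  A <- cbind(cc = features$feature_cc, tc = features$feature_tc)
  scl <- c(1, 1)
  if (standardize) {
    scl <- apply(A, 2, sd)
    A <- sweep(A, 2, scl, "/")
  }
  n <- nrow(A)
  if (is.null(rho)) rho <- 1 / n
  stopifnot(rho > 0)
  ## precondition: run the schedule in unit-variance coordinates with the
  ## penalty transformed accordingly, so the minimised objective is the
  ## stated one on the original scale regardless of feature units
  s_pre <- pmax(apply(A, 2, sd), .Machine$double.eps)
  As <- sweep(A, 2, s_pre, "/")
  w <- c(0, 0); c0 <- 0
  ## Polyak-Ruppert tail averaging: the reported solution is the mean
  ## iterate over the last half of the epochs, which suppresses the
  ## stationary oscillation of the final iterate
  tail_from <- floor(epochs / 2) + 1
  acc <- c(0, 0, 0); n_acc <- 0
  set.seed(seed)
  for (ep in seq_len(epochs)) {
    eta <- step0 / sqrt(ep)
    for (i in sample.int(n)) {
      z <- y[i] * (sum(w * As[i, ]) + c0)
      g <- -y[i] * plogis(-z)        # d/dz log(1+e^-z) chain factor
      w <- w - eta * g * As[i, ]
      c0 <- c0 - eta * g
      ## proximal (implicit) step for the ridge term: unconditionally
      ## stable for any rho
      w <- w / (1 + eta * rho / (n * s_pre^2))
      if (ep >= tail_from) {
        acc <- acc + c(w, c0); n_acc <- n_acc + 1
      }
    }
  }
  w <- acc[1:2] / n_acc
  c0 <- acc[3] / n_acc
  w <- w / s_pre / scl
  structure(list(weights = c(cc = unname(w[1]), tc = unname(w[2])),
                 intercept = c0, rho = rho, seed = seed,
                 objective = logistic_objective(
                   w, c0, cbind(features$feature_cc, features$feature_tc),
                   y, rho),
                 n = n),
            class = "tc_boundary")
}

#' @export
coef.tc_boundary <- function(object, ...) {
  c(intercept = object$intercept, object$weights)
}

#' @export
print.tc_boundary <- function(x, ...) {
  cat(sprintf(paste0("ridge-logistic boundary: w_cc=%.4g w_tc=%.4g ",
                     "c=%.4g (rho=%.4g, n=%d)\n"),
              x$weights["cc"], x$weights["tc"], x$intercept, x$rho, x$n))
  bl <- try(boundary_line(x), silent = TRUE)
  if (!inherits(bl, "try-error"))
    cat(sprintf("  line: tc = %.4g + %.4g * cc; patients %s\n",
                bl$intercept, bl$slope, tolower(bl$patient_side)))
  invisible(x)
}

#' @export
predict.tc_boundary <- function(object, newdata, type = c("prob", "class"),
                                ...) {
  type <- match.arg(type)
  eta <- object$weights["cc"] * newdata$feature_cc +
    object$weights["tc"] * newdata$feature_tc + object$intercept
  pr <- plogis(as.numeric(eta))
  if (type == "prob") pr else ifelse(pr > 0.5, "PATIENT", "CONTROL")
}

#' Decision boundary as a line in the feature plane
#'
#' The plane has the cortico-cortical feature on the x axis and the
#' thalamo-cortical feature on the y axis.  The boundary is the level set
#' `w_cc * cc + w_tc * tc + c = 0`; `patient_side` is the side with
#' predicted patient probability above one half.
#'
#' @param model a [fit_logistic_ridge()] result.
#' @return List with `slope`, `intercept`, `slope_sign`, `patient_side`
#'   (`"ABOVE"`/`"BELOW"`), and `vertical` flag (slope reported as
#'   `+/-Inf` when the tc weight is zero).
#' @export
boundary_line <- function(model) {
  stopifnot(inherits(model, "tc_boundary"))
  w <- model$weights
  if (w["tc"] == 0) {
    return(list(slope = Inf * sign(-w["cc"]), intercept = NA_real_,
                slope_sign = NA_integer_, patient_side = NA_character_,
                vertical = TRUE))
  }
  slope <- -w["cc"] / w["tc"]
  list(slope = unname(slope),
       intercept = unname(-model$intercept / w["tc"]),
       slope_sign = sign_tol(slope),
       patient_side = if (w["tc"] > 0) "ABOVE" else "BELOW",
       vertical = FALSE)
}

#' Concordance between the imaging boundary and model frontiers
#'
#' A parameter plane is `CONCORDANT` when its seizure frontier has the
#' same slope sign as the imaging decision boundary and the seizure side
#' matches the patient side; a zero slope on either side gives
#' `INDETERMINATE`.
#'
#' @param boundary a [boundary_line()] result (or a list with
#'   `slope_sign` and `patient_side`).
#' @param orientations named list of [frontier_orientation()] results,
#'   one per scanned plane.
#' @return Named character vector of verdicts (`CONCORDANT`,
#'   `DISCORDANT`, `INDETERMINATE`).
#' @export
concordance_check <- function(boundary, orientations) {
  stopifnot(!is.null(boundary$slope_sign), length(orientations) > 0)
  vapply(orientations, function(o) {
    if (is.na(boundary$slope_sign) || boundary$slope_sign == 0 ||
        o$slope_sign == 0)
      return("INDETERMINATE")
    if (o$slope_sign == boundary$slope_sign &&
        o$seizure_side == boundary$patient_side)
      "CONCORDANT"
    else "DISCORDANT"
  }, "")
}
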