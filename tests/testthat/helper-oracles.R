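## Independent oracles and fixture builders used across the suite.

## wrap a raw series as a trajectory object (for classifier fixtures)
fake_traj <- function(x, fs = 500) {
  ictogen:::new_trajectory(
    cbind(seq(0, by = 1 / fs, length.out = length(x)), x, 0, 0, 0),
    tc_params(), stochastic = FALSE)
}

## 3 Hz sawtooth-plus-spike: two maxima per period (wave apex + spike)
sawtooth_spike <- function(dur = 10.5, fs = 500, f0 = 3) {
  t <- seq(0, dur, by = 1 / fs)
  phase <- (t * f0) %% 1
  phase + 0.9 * exp(-(phase - 0.5)^2 / (2 * 0.03^2))
}

## brute-force two-sided rank-sum p-value by full enumeration (no ties)
ranksum_enumerate <- function(x, y) {
  m <- length(x); n <- length(y); N <- m + n
  r <- rank(c(x, y))
  W <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  combos <- utils::combn(N, m)
  allW <- colSums(matrix(seq_len(N)[combos], nrow = m)) - m * (m + 1) / 2
  mean(abs(allW - m * n / 2) >= abs(W - m * n / 2) - 1e-9)
}

## normal approximation with tie and continuity correction (the formula
## wilcox.test documents), written independently
ranksum_normal <- function(x, y) {
  m <- length(x); n <- length(y); N <- m + n
  r <- rank(c(x, y))
  W <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  z <- W - m * n / 2
  nties <- table(r)
  sigma <- sqrt((m * n / 12) *
                  ((N + 1) - sum(nties^3 - nties) / (N * (N - 1))))
  corr <- sign(z) * 0.5
  z <- (z - corr) / sigma
  2 * min(stats::pnorm(z), stats::pnorm(z, lower.tail = FALSE), 0.5)
}

## hand step-up BH: rejections and adjusted values
bh_hand <- function(p, q = 0.05) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  thr <- seq_len(m) * q / m
  k <- which(ps <= thr)
  rej <- rep(FALSE, m)
  if (length(k)) rej[o[seq_len(max(k))]] <- TRUE
  adj <- rev(cummin(rev(pmin(1, ps * m / seq_len(m)))))
  list(reject = rej, p_adjusted = adj[order(o)])
}

## normal-equations least squares residuals
ols_resid <- function(values, X) {
  beta <- solve(t(X) %*% X, t(X) %*% values)
  as.numeric(values - X %*% beta)
}

## full-batch ridge-logistic oracle (BFGS on the exact objective)
logistic_oracle <- function(features, rho) {
  A <- cbind(features$feature_cc, features$feature_tc)
  y <- ifelse(toupper(features$group) == "PATIENT", 1, -1)
  obj <- function(par) {
    z <- y * (A %*% par[1:2] + par[3])
    sum(log1p(exp(-z))) + rho / 2 * sum(par[1:2]^2)
  }
  o <- stats::optim(c(0, 0, 0), obj, method = "BFGS",
                    control = list(maxit = 2000, reltol = 1e-15))
  list(weights = o$par[1:2], intercept = o$par[3], value = o$value)
}

## hand-made plane_scan with given label matrix (rows = y, cols = x)
fake_scan <- function(labels, xs, ys, x_param = "c1", y_param = "c8") {
  structure(list(x_param = x_param, y_param = y_param,
                 x_values = xs, y_values = ys, labels = labels,
                 fundamental_hz = matrix(NA_real_, nrow(labels),
                                         ncol(labels)),
                 warning_flags = matrix(FALSE, nrow(labels), ncol(labels)),
                 params_base = tc_params()),
            class = "plane_scan")
}

## standard two-effect synthetic feature set used in boundary tests
make_features <- function(seed, d_cc = 1.34, d_tc = -1.0) {
  co <- generate_cohort(seed = seed)
  assemble_features(
    tc_gfa = generate_region_gfa(co, effect_spec("tc", d_tc), seed + 500),
    cc_gfa = generate_region_gfa(co, effect_spec("cc", d_cc), seed + 900),
    cohort = co)
}
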