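co32 <- generate_cohort(seed = 7)

test_that("covariate residualisation matches the normal equations", {
  expect_equal(residualize_covariates(rep(0, 32), co32), rep(0, 32))
  ## perfectly explained by age
  expect_lt(max(abs(residualize_covariates(3 * co32$age, co32))), 1e-8)

  set.seed(11)
  v <- rnorm(32)
  X <- cbind(1, co32$age, as.numeric(co32$sex == "M"))
  expect_equal(residualize_covariates(v, co32), ols_resid(v, X),
               tolerance = 1e-10)
  ## orthogonality to both covariates
  r <- residualize_covariates(v, co32)
  expect_lt(abs(sum(r * co32$age)) / sqrt(sum(r^2) * sum(co32$age^2)),
            1e-10)
  expect_lt(abs(sum(r * (co32$sex == "M"))), 1e-8)

  ## single-sex cohort: degenerate column dropped with a warning
  cm <- co32; cm$sex <- "M"
  expect_warning(rm_ <- residualize_covariates(v, cm), "single-sex")
  expect_equal(rm_, ols_resid(v, X[, 1:2]), tolerance = 1e-10)

  expect_error(residualize_covariates(v[1:5], co32), "length")
})

test_that("rank-sum test agrees with enumeration and normal oracles", {
  expect_equal(rank_sum_test(c(1, 2, 3), c(4, 5, 6)), 0.1)
  expect_equal(rank_sum_test(c(5, 5, 5), c(5, 5)), 1)
  expect_equal(rank_sum_test(c(1, 2, 3), c(1, 2, 3)), 1)

  ## exact path vs brute-force enumeration on random small samples
  set.seed(21)
  for (k in 1:20) {
    x <- rnorm(sample(2:6, 1)); y <- rnorm(sample(2:6, 1))
    expect_equal(rank_sum_test(x, y), ranksum_enumerate(x, y),
                 tolerance = 1e-12)
  }
  ## large samples vs the tie/continuity-corrected normal approximation
  for (k in 1:10) {
    x <- round(rnorm(25), 1); y <- round(rnorm(30, 0.3), 1)
    expect_equal(rank_sum_test(x, y), ranksum_normal(x, y),
                 tolerance = 1e-6)
  }
})

test_that("BH procedure equals the hand step-up rule", {
  r <- bh_fdr(c(0.01, 0.02, 0.04, 0.2), q = 0.05)
  expect_identical(r$reject, c(TRUE, TRUE, FALSE, FALSE))
  expect_identical(bh_fdr(rep(0, 5))$reject, rep(TRUE, 5))
  expect_identical(bh_fdr(0.04)$reject, TRUE)
  expect_identical(bh_fdr(0.06)$reject, FALSE)
  expect_identical(bh_fdr(numeric(0))$reject, logical(0))

  set.seed(31)
  for (k in 1:15) {
    p <- runif(40)^sample(1:3, 1)
    mine <- bh_fdr(p, 0.05)
    hand <- bh_hand(p, 0.05)
    expect_identical(mine$reject, hand$reject)
    expect_equal(mine$p_adjusted, hand$p_adjusted, tolerance = 1e-12)
    ## adjusted values are monotone in sorted order and >= raw
    expect_true(all(diff(mine$p_adjusted[order(p)]) >= -1e-12))
    expect_true(all(mine$p_adjusted >= p - 1e-12))
    ## rejections at a smaller q are a subset
    expect_true(all(bh_fdr(p, 0.02)$reject <= mine$reject))
  }
})

test_that("Cohen's d follows the control-minus-patient convention", {
  expect_equal(cohens_d(c(2, 3, 4), c(1, 2, 3)), 1)
  expect_equal(cohens_d(c(1, 2, 8), c(1, 2, 8)), 0)
  set.seed(41)
  a <- rnorm(10); b <- rnorm(12)
  expect_equal(cohens_d(a + 5, b + 5), cohens_d(a, b))
  expect_equal(cohens_d(b, a), -cohens_d(a, b))
  expect_equal(cohens_d(a, b, hedges = TRUE),
               cohens_d(a, b) * (1 - 3 / (4 * 22 - 9)))
  expect_error(cohens_d(rep(1, 3), rep(1, 4)), "zero")
  expect_error(cohens_d(1, c(1, 2)), "at least 2")
})

test_that("grid mask combines FDR and count thresholds element-wise", {
  ## identically distributed groups: no rejections anywhere
  g <- generate_threshold_grid(co32, affected_region = NULL, seed = 3)
  g$gfa <- array(rep(as.vector(g$gfa[, , 1]), 32), dim(g$gfa))
  m <- grid_significance_mask(g, co32)
  expect_identical(sum(m$final_mask), 0L)
  expect_true(all(m$p_raw == 1))

  ## infinite count threshold empties the mask regardless of p
  g2 <- generate_threshold_grid(co32, spec = effect_spec("x", 3), seed = 4)
  m_inf <- grid_significance_mask(g2, co32, count_threshold = Inf)
  expect_identical(sum(m_inf$final_mask), 0L)

  ## monotone non-increasing in the count threshold
  m50 <- grid_significance_mask(g2, co32, count_threshold = 50)
  m100 <- grid_significance_mask(g2, co32, count_threshold = 100)
  m200 <- grid_significance_mask(g2, co32, count_threshold = 200)
  expect_true(all(m100$final_mask <= m50$final_mask))
  expect_true(all(m200$final_mask <= m100$final_mask))

  ## p_fdr dominates p_raw; final mask is the element-wise product
  expect_true(all(m100$p_fdr >= m100$p_raw))
  expect_identical(m100$final_mask, m100$p_mask & m100$count_mask)

  ## zero-count cells are excluded and masked out
  g3 <- g2
  g3$counts[1:3, 1:3] <- 0L
  m3 <- grid_significance_mask(g3, co32)
  expect_true(all(m3$p_raw[1:3, 1:3] == 1))
  expect_true(all(m3$d[1:3, 1:3] == 0))
  expect_true(all(!m3$final_mask[1:3, 1:3]))
})

test_that("an embedded effect region is recovered and nothing outside it", {
  g <- generate_threshold_grid(co32, seed = 2001)
  m <- grid_significance_mask(g, co32)
  expect_true(all(m$final_mask <= g$affected_mask))
  expect_gte(sum(m$final_mask & g$affected_mask) / sum(g$affected_mask),
             0.8)
})

test_that("representative-cell statistics pick the nearest grid cell", {
  g <- generate_threshold_grid(co32, seed = 5)
  cs <- grid_cell_stats(g, co32, length_mm = 30, tscore = 1.94)
  expect_equal(cs$length_mm, 30)
  expect_equal(cs$tscore, 1.95)        # nearest value of the 0.05 grid
  expect_length(cs$residuals_control, 18)
  expect_length(cs$residuals_patient, 14)
  expect_true(cs$p >= 0 && cs$p <= 1)
})

test_that("grid mask TSV export is readable and consistent", {
  g <- generate_threshold_grid(co32, seed = 6)
  m <- grid_significance_mask(g, co32)
  pre <- withr::local_tempfile()
  write_grid_mask(m, pre)
  fm <- read.delim(paste0(pre, "_final_mask.tsv"), check.names = FALSE)
  expect_identical(dim(fm), c(21L, 22L))
  expect_identical(sum(fm[, -1]), sum(m$final_mask))
})
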