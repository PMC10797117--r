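test_that("Spearman is invariant under monotone transforms and matches the rank oracle", {
  x <- c(3, 1, 4, 1.5, 9, 2.6, 5.3)
  expect_equal(spearman(x, x^3)$rho, 1)
  expect_equal(spearman(x, -x)$rho, -1)
  expect_equal(spearman(x, exp(x))$rho, spearman(x, x)$rho)

  set.seed(8)
  for (i in 1:10) {
    xs <- sample(1:6, 30, replace = TRUE)   # heavy ties
    ys <- sample(1:5, 30, replace = TRUE) + 0.1 * xs
    got <- spearman(xs, ys)$rho
    oracle <- stats::cor(avg_rank_oracle(xs), avg_rank_oracle(ys))
    expect_equal(got, oracle, tolerance = 1e-12)
    # cross-check against the reference implementation
    expect_equal(got, suppressWarnings(
      stats::cor.test(xs, ys, method = "spearman")$estimate[[1]]),
      tolerance = 1e-12)
  }
  expect_error(spearman(c(1, 2), c(3, 4)), "3")
  expect_error(spearman(c(1, 2, NA), c(3, 4, 5)), "3")
  expect_true(spearman(rep(1, 5), 1:5)$degenerate)
})

test_that("Spearman p-values: exact enumeration for small n, t-approximation above", {
  # n <= 9: p must be a valid permutation proportion, consistent with the
  # reference exact test on tie-free data
  set.seed(2)
  x <- rnorm(7); y <- 0.8 * x + rnorm(7, 0, 0.5)
  res <- spearman(x, y)
  expect_true(res$p > 0 && res$p <= 1)
  ref <- stats::cor.test(x, y, method = "spearman", exact = TRUE)$p.value
  expect_lt(abs(res$p - ref), 0.02)
  # large-sample t approximation against the reference
  x <- rnorm(60); y <- 0.4 * x + rnorm(60)
  res <- spearman(x, y)
  ref <- stats::cor.test(x, y, method = "spearman", exact = FALSE)$p.value
  expect_equal(res$p, ref, tolerance = 1e-6)
})

test_that("Wilcoxon rank-sum: exact small-sample p equals full enumeration", {
  set.seed(5)
  for (i in 1:5) {
    a <- sample(seq(0, 40, by = 0.5), 4)
    b <- sample(seq(0.1, 40.1, by = 0.7), 4)
    got <- wilcoxon_ranksum(a, b)
    expect_true(got$exact)
    expect_equal(got$p, wilcox_enum_oracle(a, b), tolerance = 1e-12)
  }
  same <- c(1, 2, 3, 4, 5)
  expect_gte(wilcoxon_ranksum(same, sample(same))$p, 0.99)
  expect_lt(wilcoxon_ranksum(1:10, 21:30)$p, 0.05)
  expect_error(wilcoxon_ranksum(numeric(0), 1:3), "nonempty")
})

test_that("inter-patient correlations carry the sign conventions and drop missing TEs", {
  t1 <- matrix(c(1:10, 10:1), ncol = 2)       # TE1 ranks = PBF ranks
  pbf <- 1:10 + 0.5
  qdp <- 100 - 2 * (1:10)                      # anti-monotone in T1 at TE1
  res <- interpatient_correlations(t1, pbf, qdp, te_list = c(70, 500))
  expect_equal(res$rho[res$te == 70 & res$kind == "IPBF"], 1)
  expect_equal(res$rho[res$te == 70 & res$kind == "IQDP"], -1)
  expect_equal(res$rho[res$te == 500 & res$kind == "IPBF"], -1)
  t1[, 2] <- NA                                # one-slice patients: TE absent
  res <- interpatient_correlations(t1, pbf, qdp, te_list = c(70, 500))
  expect_true(all(res$absent[res$te == 500]))
  expect_false(any(res$absent[res$te == 70]))
})

test_that("cohort-level rank coupling is recovered within the n = 22 sampling band", {
  # Gaussian copula with target Spearman 0.6
  set.seed(21)
  r_pearson <- 2 * sin(pi * 0.6 / 6)
  rhos <- replicate(40, {
    z1 <- rnorm(22)
    z2 <- r_pearson * z1 + sqrt(1 - r_pearson^2) * rnorm(22)
    spearman(z1, z2)$rho
  })
  expect_lt(abs(mean(rhos) - 0.6), 0.1)
  expect_lte(stats::median(abs(rhos - 0.6)), 0.2)
})

test_that("registered local correlation: monotone coupling gives 1, permutation gives ~0", {
  truth <- test_truth()
  lung <- truth$labels > 0L
  t1_field <- observed_t1(truth, 70)
  tm <- structure(list(t1 = t1_field, valid = lung & !is.na(t1_field), te = 70,
                       grid = truth$grid, n_fit = sum(lung),
                       n_valid = sum(lung)), class = "t1_map")
  pbf_mono <- exp(t1_field / 400)
  expect_equal(local_correlation_registered(tm, pbf_mono, lung)$rho, 1)
  set.seed(13)
  n <- 1e4
  xs <- rnorm(n); ys <- sample(xs)
  expect_lte(abs(spearman(xs, ys)$rho), 0.1)
})

test_that("defect/normal comparison computes the relative difference and direction flags", {
  t1 <- matrix(NA_real_, 10, 10)
  lung <- matrix(TRUE, 10, 10)
  set.seed(3)
  defect <- matrix(rep(c(TRUE, FALSE), each = 50), 10, 10)
  t1[defect] <- 900 + rnorm(50, 0, 5)
  t1[!defect] <- 1000 + rnorm(50, 0, 5)
  tm <- structure(list(t1 = t1, valid = lung, te = 70, grid = test_grid(10L),
                       n_fit = 100, n_valid = 100), class = "t1_map")
  cmp <- defect_normal_comparison(tm, defect, lung)
  expect_equal(cmp$delta_t1, 100 * (cmp$median_normal - cmp$median_defect) /
                 cmp$median_normal)
  expect_lt(abs(cmp$delta_t1 - 10), 1.5)
  expect_equal(cmp$direction, "defect_shorter")
  # identical distributions: no significant difference
  t1[defect] <- t1[!defect]
  tm$t1 <- t1
  expect_equal(defect_normal_comparison(tm, defect, lung)$direction,
               "no_significant_difference")
  # one class empty: flagged not evaluable
  none <- defect & FALSE
  expect_false(defect_normal_comparison(tm, none, lung)$evaluable)
})

test_that("defect T1 shortening is recovered from the noisy phantom within the estimator's band", {
  cfg <- default_config()
  subj <- make_subject(cfg, seed = 31L, defect_fraction = 0.25)
  tm <- map_t1(subj$ir[[1]], subj$truth$labels > 0L)
  cmp <- defect_normal_comparison(tm, subj$truth$defect,
                                  subj$truth$labels > 0L)
  expect_lt(cmp$p, 0.05)
  expect_equal(cmp$direction, "defect_shorter")

  # oracle: the same estimator applied to synthetic single-class curves at
  # the two true median T1s predicts the recoverable contrast (noise biases
  # the 4-TI magnitude fit, so the prediction - not the noiseless truth -
  # is the right reference)
  t1_true <- observed_t1(subj$truth, 70)
  t1_nor <- stats::median(t1_true[subj$truth$labels > 0L & !subj$truth$defect])
  t1_def <- stats::median(t1_true[subj$truth$defect])
  set.seed(77)
  tis <- subj$ir[[1]]$ti
  sim_median <- function(t1, n = 3000) {
    s <- t(vapply(rep(t1, n), function(t) abs(1 - 2 * exp(-tis / t)),
                  numeric(length(tis)))) +
      matrix(rnorm(n * length(tis), 0, 1 / cfg$snr), n, length(tis))
    f <- fit_ir_curves(s, tis)
    stats::median(f$t1[f$valid])
  }
  predicted <- 100 * (1 - sim_median(t1_def) / sim_median(t1_nor))
  expect_gt(predicted, 0)
  expect_lt(abs(cmp$delta_t1 - predicted), 2.5)
  # and the noiseless pipeline recovers the true contrast itself
  nsub <- noiseless_subject()
  tm0 <- map_t1(nsub$ir[[1]], nsub$truth$labels > 0L)
  cmp0 <- defect_normal_comparison(tm0, nsub$truth$defect,
                                   nsub$truth$labels > 0L)
  t1_true0 <- observed_t1(nsub$truth, 70)
  truth_delta0 <- 100 * (1 - stats::median(t1_true0[nsub$truth$defect]) /
                           stats::median(t1_true0[nsub$truth$labels > 0L &
                                                    !nsub$truth$defect]))
  expect_lt(abs(cmp0$delta_t1 - truth_delta0), 1)
})

test_that("correlation of correlations reproduces the damaged-lung mechanism", {
  expect_equal(correlation_of_correlations(1:8, (1:8)^2)$rho, 1)
  set.seed(17)
  expect_lte(abs(correlation_of_correlations(rnorm(200), rnorm(200))$rho), 0.15)

  # mechanism: patients with near-uniformly defective lungs (low median T1)
  # have little perfusion spread, hence weak local correlations
  set.seed(29)
  n_pat <- 20
  damage <- runif(n_pat, 0.4, 0.95)
  med_t1 <- 1150 - 250 * damage + rnorm(n_pat, 0, 10)
  local_rho <- vapply(damage, function(d) {
    n_areas <- 100
    is_def <- runif(n_areas) < d
    pbf <- ifelse(is_def, 0.01, 0.05 * (1 + 0.5 * runif(n_areas)))
    t1 <- ifelse(is_def, 950, 1150) + rnorm(n_areas, 0, 30)
    spearman(t1, pbf)$rho
  }, numeric(1))
  res <- correlation_of_correlations(med_t1, local_rho)
  expect_gt(res$rho, 0.3)
})
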