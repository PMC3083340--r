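test_that("feature filtering removes exactly the excluded flag patterns", {
  h <- make_hyb(5)
  h$flag_saturated_A <- c(TRUE, TRUE, FALSE, FALSE, FALSE)
  h$flag_saturated_B <- c(FALSE, TRUE, FALSE, FALSE, FALSE)
  h$flag_nonuniform_B <- c(FALSE, FALSE, TRUE, FALSE, FALSE)
  out <- filter_features(h)
  # saturated in A only -> retained; saturated both -> gone;
  # non-uniform in one channel -> gone
  expect_identical(out$probe_id, c("p01", "p04", "p05"))
  # no flags set: identity
  expect_identical(filter_features(make_hyb(4)), make_hyb(4))
  expect_error(filter_features(make_hyb(3)[, 1:4]), "flag")
})

test_that("noise-free null hybridizations normalize to M = 0", {
  sim <- simulate_experiment(noise_free_design(n_genes = 150))
  for (h in sim$comparisons[[2]]) {
    nr <- lowess_normalize(h)
    expect_true(all(abs(nr$M) < 1e-6))
    expect_true(all(nr$usable))
  }
})

test_that("forward and reverse noise-free hybridizations give identical M", {
  sim <- simulate_experiment(noise_free_design(n_genes = 150,
                                               frac_planted = 0.1))
  fwd <- lowess_normalize(sim$comparisons[[1]][[1]])
  rev <- lowess_normalize(sim$comparisons[[1]][[2]])
  expect_equal(fwd$M, rev$M, tolerance = 1e-9)
})

test_that("LOWESS removes an injected smooth dye bias", {
  d <- simulation_design(n_genes = 2000, n_redundant_genes = 0,
                         frac_planted = 0, dye_bias_amplitude = 0.3,
                         n_unannotated_probes = 0, seed = 23)
  sim <- simulate_experiment(d)
  h <- sim$comparisons[[1]][[1]]
  nr <- lowess_normalize(h)
  ok <- nr$usable

  # oracle: before detrending, the raw orientation-corrected ratio carries
  # the generator's own bias curve
  lA <- log2(h$channel_A_intensity + 1)
  lB <- log2(h$channel_B_intensity + 1)
  m_raw <- lA - lB
  bias <- dye_bias_curve(nr$A, 0.3, d$baseline_log2_mean, d$baseline_log2_sd)
  expect_lt(mean(abs(m_raw[ok] - bias[ok])), 0.15)  # raw ratios track the bias
  expect_gt(max(abs(tapply(m_raw[ok], cut(nr$A[ok], 10), mean))), 0.1)

  # after detrending, per-intensity-decile mean residual of null genes < 0.05
  dec <- cut(nr$A[ok], quantile(nr$A[ok], probs = seq(0, 1, 0.1)),
             include.lowest = TRUE)
  expect_true(all(abs(tapply(nr$M[ok], dec, mean)) < 0.05))
})

test_that("normalization rejects bad spans and too few usable probes", {
  h <- make_hyb(10)
  expect_error(lowess_normalize(h, span = 0), "span")
  expect_error(lowess_normalize(h, span = 1.2), "span")
  expect_error(lowess_normalize(h, min_probes = 50), "usable")
})

test_that("replicate combination matches hand-computed weighted statistics", {
  em <- error_model()
  v <- measurement_variance(14, em)  # additive term negligible at A = 14

  # two equal measurements: mean +1, fold +2
  r <- combine_replicates(make_ratios(c(1, 1)), em)
  expect_equal(r$log2_ratio, 1)
  expect_equal(r$fold, 2)
  expect_identical(r$n_used, 2L)

  # opposite measurements cancel: fold reported as +1, p = 1 by symmetry? no -
  # p reflects the (large) empirical spread but the mean is exactly 0
  r <- combine_replicates(make_ratios(c(1, -1)), em)
  expect_equal(r$log2_ratio, 0)
  expect_equal(r$fold, 1)
  expect_equal(r$p, 1)

  # four measurements: oracle = direct arithmetic of the documented formulas
  M <- c(0.8, 1.2, 1.0, 1.0)
  r <- combine_replicates(make_ratios(M), em)
  w <- rep(1 / v, 4)
  xbar <- sum(w * M) / sum(w)
  emp <- (sum(w * (M - xbar)^2) / sum(w)) / 4
  se <- sqrt(max(1 / sum(w), emp))
  p <- 2 * pnorm(-abs(xbar / se))
  expect_equal(r$log2_ratio, xbar, tolerance = 1e-10)
  expect_equal(r$se, se, tolerance = 1e-10)
  expect_equal(r$p, p, tolerance = 1e-10)
  expect_equal(r$fold, 2^xbar, tolerance = 1e-10)
})

test_that("fold-change sign convention and p bounds hold", {
  em <- error_model()
  r <- combine_replicates(make_ratios(c(-1.5, -1.5)), em)
  expect_equal(r$fold, -2^1.5)
  expect_true(r$p > 0 && r$p <= 1)
  expect_true(abs(r$fold) >= 1)
})

test_that("adding replicate measurements never increases the SE", {
  em <- error_model()
  set.seed(31)
  for (rep in 1:50) {
    n <- sample(2:6, 1)
    M <- rnorm(n, sd = 0.3)
    base <- combine_replicates(make_ratios(M), em)
    # duplicating one existing measurement
    plus1 <- combine_replicates(make_ratios(c(M, M[sample(n, 1)])), em)
    expect_lte(plus1$se, base$se + 1e-12)
    # duplicating the whole replicate set
    plus_all <- combine_replicates(make_ratios(c(M, M)), em)
    expect_lte(plus_all$se, base$se + 1e-12)
  }
})

test_that("results are invariant to swapping dye labels and channels together", {
  sim <- simulate_experiment(simulation_design(n_genes = 200, seed = 13))
  hybs <- sim$comparisons[[3]]
  swap <- lapply(hybs, function(h) {
    s <- h
    s$channel_A_intensity <- h$channel_B_intensity
    s$channel_B_intensity <- h$channel_A_intensity
    s$flag_saturated_A <- h$flag_saturated_B
    s$flag_saturated_B <- h$flag_saturated_A
    s$flag_nonuniform_A <- h$flag_nonuniform_B
    s$flag_nonuniform_B <- h$flag_nonuniform_A
    s$dye_orientation <- ifelse(h$dye_orientation == "forward",
                                "reverse", "forward")
    s
  })
  r1 <- combine_replicates(lapply(hybs, lowess_normalize))
  r2 <- combine_replicates(lapply(swap, lowess_normalize))
  expect_equal(r1, r2, tolerance = 1e-12)
})

test_that("the error-model variance is monotone non-increasing with a floor", {
  em <- error_model()
  A <- seq(2, 16, by = 0.25)
  v <- measurement_variance(A, em)
  expect_true(all(diff(v) <= 1e-15))
  expect_true(all(v >= em$sigma_floor^2))
})

test_that("null false-positive rates are calibrated and never anti-conservative", {
  # 8 replicate hybridizations so the empirical variance component is
  # well-estimated; the max(model, empirical) SE rule is conservative by
  # construction, so the rate may sit below alpha but must stay within a
  # factor of two and never exceed alpha beyond binomial noise
  d <- null_design(n_genes = 4000, n_pools = 4, seed = 3)
  sim <- simulate_experiment(d)
  cr <- combine_replicates(lapply(sim$comparisons[[1]], lowess_normalize))
  for (alpha in c(0.05, 0.005)) {
    rate <- mean(cr$p < alpha)
    expect_lte(rate, alpha + 3 * sqrt(alpha * (1 - alpha) / nrow(cr)))
    expect_gte(rate, alpha / 2)
  }
})
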