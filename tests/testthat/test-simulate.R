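test_that("simulation is bit-identical for identical design and seed", {
  d <- simulation_design(n_genes = 120, seed = 11)
  s1 <- simulate_experiment(d)
  s2 <- simulate_experiment(d)
  expect_identical(s1, s2)
  s3 <- simulate_experiment(simulation_design(n_genes = 120, seed = 12))
  expect_false(identical(s1$comparisons, s3$comparisons))
})

test_that("simulation does not disturb the caller's RNG stream", {
  set.seed(99)
  before <- .Random.seed
  invisible(simulate_experiment(simulation_design(n_genes = 60, seed = 5)))
  expect_identical(.Random.seed, before)
})

test_that("null effects with zero noise give channel ratio exactly 1", {
  sim <- simulate_experiment(noise_free_design(n_genes = 80))
  for (hybs in sim$comparisons) {
    for (h in hybs) {
      expect_equal(h$channel_A_intensity / h$channel_B_intensity,
                   rep(1, nrow(h)), tolerance = 1e-12)
    }
  }
})

test_that("planted (1,0,0,1) pattern forces +2 log2 ratio on comparisons 1 and 4", {
  ptab <- data.frame(gene_id = "g00001",
                     call_1 = 1L, call_2 = 0L, call_3 = 0L, call_4 = 1L,
                     magnitude = 2, stringsAsFactors = FALSE)
  d <- noise_free_design(n_genes = 100)
  d$planted_pattern_table <- ptab
  sim <- simulate_experiment(d)
  for (k in 1:4) {
    expected <- if (k %in% c(1, 4)) 2 else 0
    for (h in sim$comparisons[[k]]) {
      i <- match("p_g00001_1", h$probe_id)
      m_raw <- log2(h$channel_A_intensity[i] / h$channel_B_intensity[i])
      # orientation correction: treatment is the numerator again
      if (attr(h, "dye_orientation") == "reverse") m_raw <- -m_raw
      expect_equal(m_raw, expected, tolerance = 1e-9)
    }
  }
})

test_that("dye swap inverts the raw channel ratio exactly at zero noise and bias", {
  sim <- simulate_experiment(noise_free_design(n_genes = 60,
                                               frac_planted = 0.3))
  for (hybs in sim$comparisons) {
    fwd <- hybs[[1]]; rev <- hybs[[2]]
    expect_identical(attr(fwd, "dye_orientation"), "forward")
    expect_identical(attr(rev, "dye_orientation"), "reverse")
    r_f <- fwd$channel_A_intensity / fwd$channel_B_intensity
    r_r <- rev$channel_A_intensity / rev$channel_B_intensity
    expect_equal(r_f * r_r, rep(1, nrow(fwd)), tolerance = 1e-12)
  }
})

test_that("null-gene log2-ratio spread matches a direct Monte-Carlo of the noise model", {
  d <- simulation_design(n_genes = 2000, n_redundant_genes = 0,
                         frac_planted = 0, dye_bias_amplitude = 0,
                         rate_saturated_both = 0, rate_saturated_single = 0,
                         rate_nonuniform = 0, n_unannotated_probes = 0,
                         seed = 17)
  sim <- simulate_experiment(d)
  M <- unlist(lapply(sim$comparisons[[1]], function(h) {
    log2((h$channel_A_intensity + 1) / (h$channel_B_intensity + 1))
  }))
  # oracle: independent resampling of the stated noise model, 1e5 draws
  set.seed(4242)
  n <- 1e5
  b <- rnorm(n, d$baseline_log2_mean, d$baseline_log2_sd)
  IA <- pmax(2^(b + rnorm(n, 0, d$sigma_mult)) + rnorm(n, 0, d$sigma_add), 0)
  IB <- pmax(2^(b + rnorm(n, 0, d$sigma_mult)) + rnorm(n, 0, d$sigma_add), 0)
  sd_oracle <- sd(log2((IA + 1) / (IB + 1)))
  expect_lt(abs(sd(M) - sd_oracle) / sd_oracle, 0.10)
})

test_that("redundant probes share their gene's effects", {
  d <- noise_free_design(n_genes = 50, frac_planted = 0.5)
  d$n_redundant_genes <- 10L
  sim <- simulate_experiment(simulation_design(
    n_genes = 50, n_redundant_genes = 10, frac_planted = 0.5,
    sigma_add = 0, sigma_mult = 0, dye_bias_amplitude = 0,
    rate_saturated_both = 0, rate_saturated_single = 0, rate_nonuniform = 0,
    n_unannotated_probes = 0, seed = 3))
  second <- grep("_2$", sim$probes$probe_id, value = TRUE)
  expect_gt(length(second), 0)
  for (k in 1:4) {
    h <- sim$comparisons[[k]][[1]]
    for (p2 in second) {
      p1 <- sub("_2$", "_1", p2)
      r1 <- log2(h$channel_A_intensity[match(p1, h$probe_id)] /
                   h$channel_B_intensity[match(p1, h$probe_id)])
      r2 <- log2(h$channel_A_intensity[match(p2, h$probe_id)] /
                   h$channel_B_intensity[match(p2, h$probe_id)])
      expect_equal(r1, r2, tolerance = 1e-9)
    }
  }
})

test_that("truth codes are consistent with the classification module", {
  sim <- simulate_experiment(simulation_design(n_genes = 300, seed = 8))
  tr <- sim$truth
  for (i in seq_len(nrow(tr))) {
    code <- compute_tfs(c(tr$call_1[i], tr$call_2[i], tr$call_3[i],
                          tr$call_4[i]))
    expect_identical(tr$tfs[i], code$text)
  }
  expect_identical(tr$class, assign_class(tr$tfs))
})

test_that("invalid designs are rejected", {
  bad <- data.frame(gene_id = "g00001", call_1 = 1L, call_2 = 0L,
                    call_3 = 0L, call_4 = 0L, magnitude = 0,
                    stringsAsFactors = FALSE)
  expect_error(simulation_design(n_genes = 10, planted_pattern_table = bad),
               "magnitudes must be > 0")
  weak <- bad; weak$magnitude <- 0.5
  expect_warning(simulation_design(n_genes = 10, planted_pattern_table = weak),
                 "threshold")
  expect_error(simulation_design(n_genes = 10, rate_nonuniform = 1.5),
               "rates")
  expect_error(simulation_design(n_genes = 10, n_pools = 0), "n_pools")
})

test_that("default pattern table plants the expected share of genes", {
  p <- default_pattern_table(1000, frac_planted = 0.2, effect_size = 2)
  expect_identical(nrow(p), 200L)
  expect_true(all(p$magnitude > 1))
  codes <- tfs_codes(as.matrix(p[paste0("call_", 1:4)]))
  expect_true(all(codes %in% tfs_class_table()$code))
  # every named group gets at least one gene at this size
  expect_identical(length(unique(codes)), 27L)
  expect_identical(nrow(default_pattern_table(100, frac_planted = 0)), 0L)
})
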