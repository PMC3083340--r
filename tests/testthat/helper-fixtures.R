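# Shared fixture builders: all synthetic, generated in code at test time.

# design with every stochastic component switched off
noise_free_design <- function(n_genes = 200, frac_planted = 0, seed = 1,
                              ...) {
  simulation_design(n_genes = n_genes, n_redundant_genes = 0,
                    frac_planted = frac_planted,
                    sigma_add = 0, sigma_mult = 0, dye_bias_amplitude = 0,
                    rate_saturated_both = 0, rate_saturated_single = 0,
                    rate_nonuniform = 0, n_unannotated_probes = 0,
                    seed = seed, ...)
}

# fully null design at default noise, no redundancy / unannotated probes
null_design <- function(n_genes = 2000, seed = 1, ...) {
  simulation_design(n_genes = n_genes, n_redundant_genes = 0,
                    frac_planted = 0, n_unannotated_probes = 0,
                    seed = seed, ...)
}

# bare normalized_ratios table for direct combine_replicates tests
make_ratios <- function(M, A = 14, probe_id = "pr1", gene_id = "g1") {
  lapply(M, function(m) {
    data.frame(probe_id = probe_id, gene_id = gene_id, A = A, M = m,
               usable = TRUE, reason = "", stringsAsFactors = FALSE)
  })
}

# small hybridization table with controllable flags
make_hyb <- function(n = 5, orientation = "forward") {
  data.frame(
    probe_id = sprintf("p%02d", seq_len(n)),
    gene_id = sprintf("g%02d", seq_len(n)),
    channel_A_intensity = seq(100, by = 50, length.out = n),
    channel_B_intensity = seq(120, by = 55, length.out = n),
    dye_orientation = orientation,
    flag_saturated_A = FALSE, flag_saturated_B = FALSE,
    flag_nonuniform_A = FALSE, flag_nonuniform_B = FALSE,
    stringsAsFactors = FALSE
  )
}

# independent hypergeometric upper-tail oracle via log-binomials
hyper_upper_oracle <- function(k, K, N, m) {
  lo <- max(0L, m + K - N)
  hi <- min(m, K)
  if (k > hi) return(0)
  i <- max(k, lo):hi
  sum(exp(lchoose(K, i) + lchoose(N - K, m - i) - lchoose(N, m)))
}
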