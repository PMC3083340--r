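# Synthetic dye-swap two-color microarray experiments with known per-gene
# interaction structure. The generator emulates the study design: pooled
# biological replicates hybridised in both dye orientations for each of the
# four competitive comparisons, a smooth intensity-dependent dye bias, a
# two-component (additive + multiplicative) intensity noise model,
# saturated / non-uniform feature flags, redundant probes, and genes
# planted in known TFS groups.

COMPARISON_LABELS <- c("T_vs_control", "MAA_vs_control",
                       "TplusMAA_vs_T", "TplusMAA_vs_MAA")

#' Default planted-pattern table
#'
#' Assigns a fraction of genes to the 27 named TFS groups, apportioned
#' by the published group sizes (largest-remainder method, deterministic),
#' so the synthetic experiment has a realistic mix of interaction patterns.
#' Remaining genes are null on all four comparisons.
#'
#' @param n_genes total number of genes.
#' @param frac_planted fraction of genes given a non-null pattern
#'   (default 0.2).
#' @param effect_size planted |log2 effect| for each significant comparison
#'   (default 2, i.e. 4-fold, comfortably above the 2-fold call threshold).
#' @return data.frame with columns `gene_id`, `call_1`..`call_4`,
#'   `magnitude`; one row per planted gene. Genes not listed are null.
#' @export
default_pattern_table <- function(n_genes, frac_planted = 0.2,
                                  effect_size = 2) {
  stopifnot(n_genes >= 1, frac_planted >= 0, frac_planted <= 1)
  n_planted <- round(frac_planted * n_genes)
  gene_ids <- sprintf("g%05d", seq_len(n_genes))
  tab <- tfs_class_table()
  if (n_planted == 0L) {
    return(data.frame(gene_id = character(0),
                      call_1 = integer(0), call_2 = integer(0),
                      call_3 = integer(0), call_4 = integer(0),
                      magnitude = numeric(0), stringsAsFactors = FALSE))
  }
  w <- tab$n_genes_reported / sum(tab$n_genes_reported)
  raw <- n_planted * w
  alloc <- floor(raw)
  rem <- n_planted - sum(alloc)
  if (rem > 0) {
    extra <- order(raw - alloc, decreasing = TRUE)[seq_len(rem)]
    alloc[extra] <- alloc[extra] + 1L
  }
  digits <- t(vapply(tab$code, function(cd) parse_tfs(cd)$digits, integer(4)))
  idx <- rep(seq_len(nrow(tab)), alloc)
  data.frame(
    gene_id = gene_ids[seq_len(n_planted)],
    call_1 = digits[idx, 1L], call_2 = digits[idx, 2L],
    call_3 = digits[idx, 3L], call_4 = digits[idx, 4L],
    magnitude = effect_size,
    stringsAsFactors = FALSE
  )
}

#' Smooth intensity-dependent dye-bias curve
#'
#' A low-order polynomial of the mean log2 intensity: with
#' `u = clamp((A - center) / (3 * scale), -1, 1)`, the bias is
#' `amplitude * (2 u^2 - 1)`, ranging over `[-amplitude, +amplitude]`.
#' The bias attaches to the dye channels (channel A reads high by half the
#' bias, channel B low), so it survives dye swapping in the raw ratios and
#' is the component that within-array LOWESS normalization removes.
#'
#' @param A mean log2 intensity.
#' @param amplitude maximum |bias| in log2 units.
#' @param center,scale location/scale of the baseline log2-intensity
#'   distribution.
#' @return log2 bias vector.
#' @export
dye_bias_curve <- function(A, amplitude, center = 10, scale = 1.5) {
  u <- (A - center) / (3 * scale)
  u <- pmin(pmax(u, -1), 1)
  amplitude * (2 * u^2 - 1)
}

#' Specify a synthetic dye-swap experiment
#'
#' @param n_genes number of annotated genes (one probe each, plus a second
#'   probe for redundant genes).
#' @param n_redundant_genes genes represented by two probes with identical
#'   true effects but independent noise (default 10% of genes).
#' @param planted_pattern_table data.frame as produced by
#'   [default_pattern_table()]; genes absent from the table are null.
#' @param frac_planted,effect_size passed to [default_pattern_table()] when
#'   `planted_pattern_table` is `NULL`.
#' @param n_pools number of biological replicate pools (default 2).
#' @param dye_swap if `TRUE` (default) each pool is hybridised in both dye
#'   orientations, giving `n_pools * 2` hybridizations per comparison.
#' @param baseline_log2_mean,baseline_log2_sd location and scale of the
#'   per-probe baseline log2 intensity (defaults 10 and 1.5, i.e. typical
#'   intensities near 1,000 fluorescence units).
#' @param sigma_add additive (background) intensity noise SD, in
#'   fluorescence units (default 20).
#' @param sigma_mult multiplicative noise SD per channel, in log2 units
#'   (default 0.1).
#' @param dye_bias_amplitude amplitude of the smooth intensity-dependent
#'   dye bias, log2 units (default 0.3).
#' @param rate_saturated_both probability a feature is flagged saturated in
#'   both channels (excluded downstream; default 0.005).
#' @param rate_saturated_single additional per-channel probability of a
#'   single-channel saturation flag (retained downstream; default 0.01).
#' @param rate_nonuniform per-channel probability of a non-uniformity flag
#'   (excluded downstream; default 0.005).
#' @param n_unannotated_probes probes with no gene assignment (null
#'   effects; they pass differential-expression analysis but are excluded
#'   from gene-level tables; default 5% of `n_genes`).
#' @param seed RNG seed used by [simulate_experiment()]; the generator
#'   leaves the global RNG state untouched.
#' @return an object of class `simulation_design`.
#' @export
simulation_design <- function(n_genes = 2000,
                              n_redundant_genes = round(0.1 * n_genes),
                              planted_pattern_table = NULL,
                              frac_planted = 0.2,
                              effect_size = 2,
                              n_pools = 2,
                              dye_swap = TRUE,
                              baseline_log2_mean = 10,
                              baseline_log2_sd = 1.5,
                              sigma_add = 20,
                              sigma_mult = 0.1,
                              dye_bias_amplitude = 0.3,
                              rate_saturated_both = 0.005,
                              rate_saturated_single = 0.01,
                              rate_nonuniform = 0.005,
                              n_unannotated_probes = round(0.05 * n_genes),
                              seed = 1) {
  errs <- character(0)
  if (!is.numeric(n_genes) || n_genes < 1) errs <- c(errs, "n_genes must be >= 1")
  if (n_redundant_genes < 0 || n_redundant_genes > n_genes) {
    errs <- c(errs, "n_redundant_genes must be in [0, n_genes]")
  }
  if (n_pools < 1) errs <- c(errs, "n_pools must be >= 1")
  rates <- c(rate_saturated_both, rate_saturated_single, rate_nonuniform)
  if (any(rates < 0 | rates > 1)) errs <- c(errs, "flag rates must be in [0, 1]")
  if (sigma_add < 0 || sigma_mult < 0) errs <- c(errs, "noise SDs must be >= 0")
  if (dye_bias_amplitude < 0) errs <- c(errs, "dye_bias_amplitude must be >= 0")
  if (length(errs)) .stop_many("invalid simulation design:", errs)

  if (is.null(planted_pattern_table)) {
    planted_pattern_table <- default_pattern_table(n_genes, frac_planted,
                                                   effect_size)
  }
  ptab <- planted_pattern_table
  need <- c("gene_id", paste0("call_", 1:4), "magnitude")
  if (!all(need %in% names(ptab))) {
    stop("planted_pattern_table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  calls <- as.matrix(ptab[paste0("call_", 1:4)])
  if (nrow(ptab) > 0 && !all(calls %in% 0:2)) {
    stop("planted direction calls must be in {0, 1, 2}", call. = FALSE)
  }
  nonnull <- nrow(ptab) > 0 & rowSums(calls != 0) > 0
  if (any(nonnull & ptab$magnitude <= 0)) {
    stop("planted effect magnitudes must be > 0 for genes with non-null calls",
         call. = FALSE)
  }
  if (any(nonnull & ptab$magnitude <= 1)) {
    warning("planted |log2 effect| <= 1: planted genes will not exceed the ",
            "2-fold call threshold", call. = FALSE)
  }

  structure(list(
    n_genes = as.integer(n_genes),
    n_redundant_genes = as.integer(n_redundant_genes),
    planted_pattern_table = ptab,
    n_pools = as.integer(n_pools),
    dye_swap = isTRUE(dye_swap),
    baseline_log2_mean = baseline_log2_mean,
    baseline_log2_sd = baseline_log2_sd,
    sigma_add = sigma_add,
    sigma_mult = sigma_mult,
    dye_bias_amplitude = dye_bias_amplitude,
    rate_saturated_both = rate_saturated_both,
    rate_saturated_single = rate_saturated_single,
    rate_nonuniform = rate_nonuniform,
    n_unannotated_probes = as.integer(n_unannotated_probes),
    seed = as.integer(seed)
  ), class = "simulation_design")
}

# run expr with a private RNG stream seeded from `seed`, restoring the
# caller's global RNG state afterwards
.with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }, add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Simulate a dye-swap two-color microarray experiment
#'
#' For each of the four competitive comparisons, generates
#' `n_pools * (2 if dye_swap else 1)` hybridization tables. Channel
#' intensities are built as
#' `2^(baseline +/- effect/2 +/- bias/2 + mult. noise) + additive noise`
#' (truncated at zero); the treatment sample is channel A in forward
#' orientation and channel B in reverse orientation, while the dye bias
#' stays attached to the channels. Redundant probes share their gene's
#' true effects but receive independent baselines and noise. Identical
#' design and seed give bit-identical output.
#'
#' @param design a [simulation_design()].
#' @return an object of class `simulated_experiment`: a list with
#'   `comparisons` (list of 4 lists of hybridization data.frames, each with
#'   attributes `comparison`, `comparison_label`, `pool`, `dye_orientation`),
#'   `truth` (data.frame gene_id, call_1..call_4, tfs, class),
#'   `probes` (probe annotation data.frame), and the `design`.
#' @export
simulate_experiment <- function(design) {
  stopifnot(inherits(design, "simulation_design"))
  .with_seed(design$seed, {
    n_g <- design$n_genes
    gene_ids <- sprintf("g%05d", seq_len(n_g))

    # redundant genes: spread evenly through the gene list so that both
    # planted and null genes acquire a second probe
    n_r <- design$n_redundant_genes
    red_idx <- if (n_r > 0) unique(round(seq(1, n_g, length.out = n_r))) else integer(0)

    probes <- data.frame(
      probe_id = c(sprintf("p_%s_1", gene_ids),
                   sprintf("p_%s_2", gene_ids[red_idx]),
                   sprintf("u%05d", seq_len(design$n_unannotated_probes))),
      gene_id = c(gene_ids, gene_ids[red_idx],
                  rep(NA_character_, design$n_unannotated_probes)),
      stringsAsFactors = FALSE
    )
    n_p <- nrow(probes)

    # per-gene true log2 effects on the four comparisons
    ptab <- design$planted_pattern_table
    eff_gene <- matrix(0, nrow = n_g, ncol = 4L,
                       dimnames = list(gene_ids, COMPARISON_LABELS))
    if (nrow(ptab) > 0) {
      hit <- match(ptab$gene_id, gene_ids)
      if (anyNA(hit)) {
        stop("planted_pattern_table refers to unknown gene ids", call. = FALSE)
      }
      for (k in 1:4) {
        ck <- ptab[[paste0("call_", k)]]
        eff_gene[hit, k] <- ifelse(ck == 1L, ptab$magnitude,
                                   ifelse(ck == 2L, -ptab$magnitude, 0))
      }
    }
    eff <- matrix(0, nrow = n_p, ncol = 4L)
    ann <- !is.na(probes$gene_id)
    eff[ann, ] <- eff_gene[match(probes$gene_id[ann], gene_ids), ]

    baseline <- stats::rnorm(n_p, design$baseline_log2_mean,
                             design$baseline_log2_sd)
    bias <- dye_bias_curve(baseline, design$dye_bias_amplitude,
                           design$baseline_log2_mean, design$baseline_log2_sd)

    orientations <- if (design$dye_swap) c("forward", "reverse") else "forward"
    comparisons <- vector("list", 4L)
    for (k in 1:4) {
      hybs <- list()
      for (pool in seq_len(design$n_pools)) {
        for (orient in orientations) {
          t_eff <- eff[, k]
          l_trt <- baseline + t_eff / 2 +
            stats::rnorm(n_p, 0, design$sigma_mult)
          l_ref <- baseline - t_eff / 2 +
            stats::rnorm(n_p, 0, design$sigma_mult)
          if (orient == "forward") {
            lA <- l_trt; lB <- l_ref
          } else {
            lA <- l_ref; lB <- l_trt
          }
          lA <- lA + bias / 2
          lB <- lB - bias / 2
          IA <- pmax(2^lA + stats::rnorm(n_p, 0, design$sigma_add), 0)
          IB <- pmax(2^lB + stats::rnorm(n_p, 0, design$sigma_add), 0)

          sat_both <- stats::runif(n_p) < design$rate_saturated_both
          satA <- sat_both | stats::runif(n_p) < design$rate_saturated_single
          satB <- sat_both | stats::runif(n_p) < design$rate_saturated_single
          nuA <- stats::runif(n_p) < design$rate_nonuniform
          nuB <- stats::runif(n_p) < design$rate_nonuniform

          h <- data.frame(
            probe_id = probes$probe_id,
            gene_id = probes$gene_id,
            channel_A_intensity = IA,
            channel_B_intensity = IB,
            dye_orientation = orient,
            flag_saturated_A = satA,
            flag_saturated_B = satB,
            flag_nonuniform_A = nuA,
            flag_nonuniform_B = nuB,
            stringsAsFactors = FALSE
          )
          attr(h, "comparison") <- k
          attr(h, "comparison_label") <- COMPARISON_LABELS[k]
          attr(h, "pool") <- pool
          attr(h, "dye_orientation") <- orient
          hybs[[length(hybs) + 1L]] <- h
        }
      }
      comparisons[[k]] <- hybs
    }
    names(comparisons) <- COMPARISON_LABELS

    truth_calls <- matrix(0L, nrow = n_g, ncol = 4L)
    if (nrow(ptab) > 0) {
      hit <- match(ptab$gene_id, gene_ids)
      for (k in 1:4) truth_calls[hit, k] <- as.integer(ptab[[paste0("call_", k)]])
    }
    tfs <- tfs_codes(truth_calls)
    truth <- data.frame(
      gene_id = gene_ids,
      call_1 = truth_calls[, 1L], call_2 = truth_calls[, 2L],
      call_3 = truth_calls[, 3L], call_4 = truth_calls[, 4L],
      tfs = tfs,
      class = assign_class(tfs),
      stringsAsFactors = FALSE
    )

    structure(list(comparisons = comparisons, truth = truth,
                   probes = probes, design = design),
              class = "simulated_experiment")
  })
}

#' @export
print.simulated_experiment <- function(x, ...) {
  n_h <- sum(vapply(x$comparisons, length, integer(1)))
  cat("Simulated dye-swap experiment:",
      nrow(x$probes), "probes,",
      nrow(x$truth), "genes,",
      sum(x$truth$tfs != "0.0000"), "planted non-null;",
      n_h, "hybridizations across 4 comparisons\n")
  invisible(x)
}
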