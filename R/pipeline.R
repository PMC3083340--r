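# End-to-end orchestration: simulate (or load) -> filter/normalize ->
# combine replicates -> TFS classification -> enrichment -> result tables
# and a run report. Fully deterministic for a fixed config + seed.

.default_config <- function() {
  list(
    thresholds = list(fold_min = 2, p_max = 0.005),
    error_model = list(sigma_add = 20, sigma_mult = 0.1, sigma_floor = 0.05,
                       pseudo_intensity = 1),
    normalization = list(lowess_span = 0.3, min_probes = 50, iter = 1),
    enrichment = list(p_cut = 0.001, min_genes = 5, collections = list()),
    output_dir = NULL,
    overwrite = FALSE,
    seed = 1
  )
}

.merge_defaults <- function(x, defaults) {
  for (nm in names(defaults)) {
    if (is.null(x[[nm]])) {
      x[[nm]] <- defaults[[nm]]
    } else if (is.list(defaults[[nm]]) && is.list(x[[nm]])) {
      x[[nm]] <- .merge_defaults(x[[nm]], defaults[[nm]])
    }
  }
  x
}

#' Validate and normalize a pipeline configuration
#'
#' Accepts a YAML file path or a list. Fills documented defaults
#' (thresholds |fold| > 2 and p < 0.005; LOWESS span 0.3; error model
#' sigma_add 20, sigma_mult 0.1, sigma_floor 0.05; enrichment p < 0.001
#' with overlap > 5), resolves GMT paths, and aggregates *all* problems
#' into a single error. Exactly one input source — `simulation` (a list of
#' [simulation_design()] arguments or a ready design) or `manifest_dir`
#' (an experiment directory) — must be present.
#'
#' @param config YAML path or list.
#' @return object of class `pipeline_config`.
#' @export
validate_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("no such config file: ", config,
                                   call. = FALSE)
    config <- yaml::read_yaml(config)
  }
  if (inherits(config, "pipeline_config")) return(config)
  stopifnot(is.list(config))
  cfg <- .merge_defaults(config, .default_config())
  errs <- character(0)

  has_sim <- !is.null(cfg$simulation)
  has_man <- !is.null(cfg$manifest_dir)
  if (has_sim == has_man) {
    errs <- c(errs,
              "exactly one of `simulation` or `manifest_dir` must be given")
  }
  if (has_man && !has_sim && !dir.exists(cfg$manifest_dir)) {
    errs <- c(errs, paste0("manifest_dir does not exist: ", cfg$manifest_dir))
  }
  if (has_sim && !inherits(cfg$simulation, "simulation_design")) {
    sim_args <- cfg$simulation
    if (is.null(sim_args$seed)) sim_args$seed <- cfg$seed
    design <- tryCatch(do.call(simulation_design, sim_args),
                       error = function(e) conditionMessage(e))
    if (is.character(design)) {
      errs <- c(errs, paste0("invalid simulation design: ", design))
    } else {
      cfg$simulation <- design
    }
  }
  th <- tryCatch(do.call(tfs_thresholds, cfg$thresholds),
                 error = function(e) conditionMessage(e))
  if (inherits(th, "tfs_thresholds")) cfg$thresholds <- th else {
    errs <- c(errs, paste0("invalid thresholds: ", th))
  }
  em <- tryCatch(do.call(error_model, cfg$error_model),
                 error = function(e) conditionMessage(e))
  if (inherits(em, "error_model")) cfg$error_model <- em else {
    errs <- c(errs, paste0("invalid error model: ", em))
  }
  sp <- cfg$normalization$lowess_span
  if (!is.numeric(sp) || sp <= 0 || sp > 1) {
    errs <- c(errs, "normalization$lowess_span must be in (0, 1]")
  }
  colls <- cfg$enrichment$collections
  if (length(colls)) {
    for (nm in names(colls)) {
      if (is.character(colls[[nm]]) && !file.exists(colls[[nm]])) {
        errs <- c(errs, paste0("enrichment collection file not found: ",
                               colls[[nm]]))
      }
    }
  }
  if (length(errs)) .stop_many("invalid pipeline configuration:", errs)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the full analysis pipeline
#'
#' Stages: (1) simulate the experiment or read it from `manifest_dir`;
#' (2) per comparison, LOWESS-normalize every hybridization and combine
#' replicates under the error model; (3) call per-comparison significance,
#' compute per-probe TFS codes, collapse same-pattern redundant probes of
#' annotated genes, assign interaction classes and summarise; (4) run
#' gene-set enrichment for any configured GMT collections against the
#' annotated-gene universe; (5) write result tables and a run report.
#' Identical config and seed give byte-identical result tables.
#'
#' @param config a [validate_config()]-acceptable configuration.
#' @return (invisibly) list with `report`, `comparison_results` (merged
#'   per-probe table), `probe_assignments`, `gene_assignments`, `summary`
#'   (a `tfs_summary`), `enrichment`, `truth` (when simulated).
#' @export
run_pipeline <- function(config) {
  cfg <- validate_config(config)

  # stage 1: input
  if (!is.null(cfg$simulation)) {
    sim <- simulate_experiment(cfg$simulation)
    comparisons <- sim$comparisons
    truth <- sim$truth
  } else {
    exp <- read_experiment(cfg$manifest_dir)
    comparisons <- exp$comparisons
    truth <- exp$truth
  }

  # stage 2: normalize + combine, per comparison
  norm_cfg <- cfg$normalization
  cr <- vector("list", 4L)
  stage_counts <- vector("list", 4L)
  for (k in 1:4) {
    hybs <- comparisons[[k]]
    if (length(hybs) == 0L) {
      stop("pipeline stage 'normalize': no hybridizations for comparison ",
           k, call. = FALSE)
    }
    norm <- lapply(hybs, lowess_normalize, span = norm_cfg$lowess_span,
                   pseudo_intensity = cfg$error_model$pseudo_intensity,
                   min_probes = norm_cfg$min_probes, iter = norm_cfg$iter)
    cr[[k]] <- combine_replicates(norm, cfg$error_model)
    probes_in <- length(unique(unlist(lapply(hybs, `[[`, "probe_id"))))
    stage_counts[[k]] <- list(
      comparison = k,
      comparison_label = COMPARISON_LABELS[k],
      n_hybridizations = length(hybs),
      probes_in = probes_in,
      probes_analyzed = nrow(cr[[k]]),
      probes_excluded = probes_in - nrow(cr[[k]]),
      n_significant_p = sum(cr[[k]]$p < cfg$thresholds$p_max)
    )
  }

  # stage 3: classification
  all_probes <- unique(unlist(lapply(cr, `[[`, "probe_id")))
  gene_of <- rep(NA_character_, length(all_probes))
  merged <- data.frame(probe_id = all_probes, stringsAsFactors = FALSE)
  calls <- matrix(0L, nrow = length(all_probes), ncol = 4L)
  for (k in 1:4) {
    idx <- match(merged$probe_id, cr[[k]]$probe_id)
    merged[[paste0("fold_", k)]] <- cr[[k]]$fold[idx]
    merged[[paste0("p_", k)]] <- cr[[k]]$p[idx]
    calls[, k] <- call_significance(cr[[k]]$fold[idx], cr[[k]]$p[idx],
                                    cfg$thresholds)
    gene_new <- cr[[k]]$gene_id[idx]
    gene_of[is.na(gene_of) & !is.na(gene_new)] <-
      gene_new[is.na(gene_of) & !is.na(gene_new)]
  }
  merged$gene_id <- gene_of
  merged$code <- tfs_codes(calls)
  merged$min_p <- do.call(pmin, c(unname(merged[paste0("p_", 1:4)]),
                                  list(na.rm = TRUE)))
  merged <- merged[c("probe_id", "gene_id", "code",
                     paste0("fold_", 1:4), paste0("p_", 1:4), "min_p")]

  annotated <- merged[!is.na(merged$gene_id), , drop = FALSE]
  probe_assign <- annotated[c("gene_id", "probe_id", "code",
                              paste0("fold_", 1:4), paste0("p_", 1:4),
                              "min_p")]
  n_redundant_removed <- nrow(probe_assign)
  gene_assign <- collapse_redundant(probe_assign)
  n_redundant_removed <- n_redundant_removed - nrow(gene_assign)
  gene_assign$class <- assign_class(gene_assign$code)
  summary <- summarize_classes(gene_assign)

  n_tested <- nrow(merged)
  n_sig_any <- sum(merged$code != "0.0000")
  expected_fp <- expected_false_positives(n_tested, cfg$thresholds$p_max)
  fdr <- if (n_sig_any > 0) apparent_fdr(expected_fp, n_sig_any) else NA_real_

  # stage 4: enrichment
  enr <- NULL
  enr_table <- NULL
  colls <- cfg$enrichment$collections
  if (length(colls)) {
    loaded <- lapply(colls, function(x) {
      if (is.character(x)) read_gmt(x) else x
    })
    universe <- unique(annotated$gene_id)
    enr <- run_collections(gene_assign, loaded, universe,
                           p_cut = cfg$enrichment$p_cut,
                           min_genes = cfg$enrichment$min_genes)
    enr_table <- do.call(rbind, lapply(enr, `[[`, "records"))
    rownames(enr_table) <- NULL
  }

  report <- structure(list(
    seed = if (!is.null(cfg$simulation)) cfg$simulation$seed else cfg$seed,
    thresholds = unclass(cfg$thresholds),
    error_model = unclass(cfg$error_model),
    lowess_span = norm_cfg$lowess_span,
    comparisons = stage_counts,
    n_probes_tested = n_tested,
    n_probes_significant_any = n_sig_any,
    expected_by_chance = expected_fp,
    apparent_fdr_pct = fdr,
    n_redundant_probes_removed = n_redundant_removed,
    n_genes_of_interest = summary$n_total,
    n_classified = summary$n_classified,
    pct_classified = summary$pct_classified,
    n_other = summary$n_other,
    n_enriched_sets = if (is.null(enr)) NA_integer_ else {
      sum(vapply(enr, function(e) length(e$selection$sets), integer(1)))
    }
  ), class = "pipeline_report")

  # stage 5: outputs
  if (!is.null(cfg$output_dir)) {
    write_results(list(comparison_results = merged,
                       tfs_assignments = gene_assign,
                       class_summary = summary,
                       enrichment = enr_table),
                  cfg$output_dir, overwrite = cfg$overwrite)
    yaml::write_yaml(.report_as_list(report),
                     file.path(cfg$output_dir, "run_report.yaml"))
  }

  invisible(list(report = report,
                 comparison_results = merged,
                 probe_assignments = probe_assign,
                 gene_assignments = gene_assign,
                 summary = summary,
                 enrichment = enr,
                 truth = truth))
}

.report_as_list <- function(r) {
  out <- unclass(r)
  out$apparent_fdr_pct <- if (is.na(out$apparent_fdr_pct)) NULL else
    out$apparent_fdr_pct
  out
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("Pipeline run report (seed ", x$seed, ")\n", sep = "")
  cat("  thresholds: |fold| > ", x$thresholds$fold_min, ", p < ",
      x$thresholds$p_max, "\n", sep = "")
  for (s in x$comparisons) {
    cat(sprintf("  comparison %d (%s): %d probes in, %d excluded, %d analyzed, %d with p < %g\n",
                s$comparison, s$comparison_label, s$probes_in,
                s$probes_excluded, s$probes_analyzed, s$n_significant_p,
                x$thresholds$p_max))
  }
  cat("  probes tested:", x$n_probes_tested,
      "| significant in >=1 comparison:", x$n_probes_significant_any, "\n")
  cat("  expected by chance:", x$expected_by_chance)
  if (!is.na(x$apparent_fdr_pct)) {
    cat(" | apparent FDR: ", x$apparent_fdr_pct, "%", sep = "")
  }
  cat("\n  redundant probes removed:", x$n_redundant_probes_removed, "\n")
  cat("  genes of interest: ", x$n_genes_of_interest, " (",
      x$n_classified, " classified", sep = "")
  if (!is.na(x$pct_classified)) cat(", ", x$pct_classified, "%", sep = "")
  cat(")\n")
  invisible(x)
}
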