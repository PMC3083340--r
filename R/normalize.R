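# Within-array normalization and the surrogate error model: feature-quality
# filtering, orientation-corrected M/A computation, LOWESS detrending of
# the intensity-dependent dye bias, and error-weighted combination of
# replicate hybridizations into one fold-change and p-value per probe per
# comparison. The per-probe p-values are intentionally uncorrected for
# multiple testing; downstream reporting uses the expected-by-chance /
# apparent-FDR arithmetic instead.

.exclusion_reason <- function(h) {
  reason <- rep("", nrow(h))
  reason[h$flag_nonuniform_A | h$flag_nonuniform_B] <- "nonuniform"
  reason[h$flag_saturated_A & h$flag_saturated_B] <- "saturated_both"
  reason
}

#' Filter features by quality flags
#'
#' Removes exactly the features flagged as saturated in *both* channels or
#' as non-uniformity outliers in *either* channel; a feature saturated in
#' only one channel is retained.
#'
#' @param h hybridization data.frame with the four flag columns.
#' @return the table restricted to usable features.
#' @export
filter_features <- function(h) {
  need <- c("flag_saturated_A", "flag_saturated_B",
            "flag_nonuniform_A", "flag_nonuniform_B")
  if (!all(need %in% names(h))) {
    stop("hybridization table is missing flag columns", call. = FALSE)
  }
  h[.exclusion_reason(h) == "", , drop = FALSE]
}

#' LOWESS-normalize one hybridization
#'
#' Computes, per feature, the mean log2 intensity
#' `A = (log2(I_A + pseudo) + log2(I_B + pseudo)) / 2` and the raw log2
#' ratio `M_raw = log2(I_A + pseudo) - log2(I_B + pseudo)`, negates
#' `M_raw` for reverse-orientation hybridizations so the treatment sample
#' is always the numerator, then subtracts a LOWESS fit of `M_raw` on `A`
#' estimated from the usable features (the fitted curve is subtracted,
#' never divided out). Excluded features keep their exclusion reason and
#' carry `M = NA`.
#'
#' @param h hybridization data.frame.
#' @param span LOWESS span in (0, 1] (default 0.3).
#' @param pseudo_intensity offset added to both channels before logging so
#'   zero intensities stay finite (default 1).
#' @param min_probes minimum number of usable features required to fit the
#'   normalization curve (default 50).
#' @param iter number of LOWESS robustifying iterations (default 1).
#' @return data.frame of class `normalized_ratios`: `probe_id`, `gene_id`,
#'   `A`, `M`, `usable`, `reason`; hybridization attributes are carried
#'   over.
#' @export
lowess_normalize <- function(h, span = 0.3, pseudo_intensity = 1,
                             min_probes = 50, iter = 1) {
  if (!is.numeric(span) || length(span) != 1L || span <= 0 || span > 1) {
    stop("`span` must be in (0, 1]", call. = FALSE)
  }
  reason <- .exclusion_reason(h)
  usable <- reason == ""
  if (sum(usable) < min_probes) {
    stop("only ", sum(usable), " usable features; need at least ",
         min_probes, call. = FALSE)
  }
  lA <- log2(h$channel_A_intensity + pseudo_intensity)
  lB <- log2(h$channel_B_intensity + pseudo_intensity)
  A <- (lA + lB) / 2
  M_raw <- lA - lB
  rev <- h$dye_orientation == "reverse"
  M_raw[rev] <- -M_raw[rev]

  fit <- stats::lowess(A[usable], M_raw[usable], f = span, iter = iter)
  trend <- stats::approx(fit$x, fit$y, xout = A, rule = 2, ties = mean)$y
  M <- M_raw - trend
  M[!usable] <- NA_real_

  out <- data.frame(probe_id = h$probe_id,
                    gene_id = h$gene_id,
                    A = A, M = M,
                    usable = usable, reason = reason,
                    stringsAsFactors = FALSE)
  for (a in c("comparison", "comparison_label", "pool", "dye_orientation")) {
    attr(out, a) <- attr(h, a)
  }
  class(out) <- c("normalized_ratios", "data.frame")
  out
}

#' Surrogate error-model parameters
#'
#' Intensity-dependent variance model for a single log2-ratio measurement:
#' `sigma_i^2 = max(2 * (sigma_add / (ln 2 * 2^A))^2 + 2 * sigma_mult^2,
#' sigma_floor^2)` — a delta-method additive (background) term that decays
#' with intensity, a constant multiplicative term for the two channels,
#' and a variance floor so no measurement claims unbounded precision. The
#' model is monotone non-increasing in `A`.
#'
#' @param sigma_add additive background intensity noise SD, fluorescence
#'   units (default 20).
#' @param sigma_mult per-channel multiplicative noise SD, log2 units
#'   (default 0.1).
#' @param sigma_floor lower bound on the per-measurement SD, log2 units
#'   (default 0.05).
#' @param pseudo_intensity pseudo-count matching [lowess_normalize()]
#'   (default 1).
#' @return object of class `error_model`.
#' @export
error_model <- function(sigma_add = 20, sigma_mult = 0.1,
                        sigma_floor = 0.05, pseudo_intensity = 1) {
  stopifnot(sigma_add >= 0, sigma_mult >= 0, sigma_floor > 0,
            pseudo_intensity >= 0)
  structure(list(sigma_add = sigma_add, sigma_mult = sigma_mult,
                 sigma_floor = sigma_floor,
                 pseudo_intensity = pseudo_intensity),
            class = "error_model")
}

#' Per-measurement log2-ratio variance under the error model
#'
#' @param A mean log2 intensity.
#' @param em an [error_model()].
#' @return variance vector (log2 units squared).
#' @export
measurement_variance <- function(A, em = error_model()) {
  stopifnot(inherits(em, "error_model"))
  add_term <- 2 * (em$sigma_add / (log(2) * 2^A))^2
  pmax(add_term + 2 * em$sigma_mult^2, em$sigma_floor^2)
}

#' Combine replicate hybridizations into per-probe comparison results
#'
#' Error-weighted combination of the usable normalized log2 ratios of all
#' replicate hybridizations of one comparison. Each measurement gets
#' weight `1/sigma_i^2` from [measurement_variance()]; the combined ratio
#' is the weighted mean, and the standard error is
#' `sqrt(max(1 / sum(w), s_w^2 / n))` where `s_w^2` is the weighted
#' variance of the measurements — so overdispersed probes are never
#' anti-conservative. Significance is a two-sided normal tail on
#' `z = xbar / SE`. Probes with no usable measurement get no row.
#'
#' @param ratios list of `normalized_ratios` tables (the replicate
#'   hybridizations of one comparison).
#' @param em an [error_model()].
#' @return data.frame of class `comparison_result`: `probe_id`, `gene_id`,
#'   `log2_ratio`, `se`, `p`, `fold` (signed fold-change, `2^x` for
#'   `x >= 0`, `-2^(-x)` otherwise), `n_used`.
#' @export
combine_replicates <- function(ratios, em = error_model()) {
  stopifnot(inherits(em, "error_model"), is.list(ratios), length(ratios) >= 1)
  parts <- lapply(ratios, function(r) {
    r[r$usable, c("probe_id", "gene_id", "A", "M"), drop = FALSE]
  })
  all <- do.call(rbind, parts)
  if (nrow(all) == 0L) {
    stop("no usable measurements in any replicate", call. = FALSE)
  }
  if (any(!is.finite(all$M)) || any(!is.finite(all$A))) {
    stop("non-finite M or A among usable measurements", call. = FALSE)
  }

  v <- measurement_variance(all$A, em)
  w <- 1 / v
  pid <- all$probe_id
  sw <- rowsum(w, pid)
  swm <- rowsum(w * all$M, pid)
  n <- rowsum(rep(1L, length(w)), pid)
  xbar <- swm / sw
  xb_i <- xbar[match(pid, rownames(sw))]
  sqdev <- rowsum(w * (all$M - xb_i)^2, pid)
  emp_var <- (sqdev / sw) / n      # weighted variance of the M_i, / n
  model_var <- 1 / sw
  se <- sqrt(pmax(model_var, emp_var))
  z <- xbar / se
  p <- 2 * stats::pnorm(-abs(z))
  p <- pmin(pmax(p, .Machine$double.xmin), 1)
  fold <- ifelse(xbar >= 0, 2^xbar, -2^(-xbar))

  gene <- all$gene_id[match(rownames(sw), pid)]
  out <- data.frame(probe_id = rownames(sw),
                    gene_id = gene,
                    log2_ratio = as.vector(xbar),
                    se = as.vector(se),
                    p = as.vector(p),
                    fold = as.vector(fold),
                    n_used = as.vector(n),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("comparison_result", "data.frame")
  out
}
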