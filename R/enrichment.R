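# Per-TFS-group gene-set enrichment: overlap counting against GMT
# collections (GO terms, transcription-factor motif target sets, miRNA
# target sets), fold-enrichment scores, one-sided Fisher's exact
# p-values, the published selection filters, and average-linkage
# hierarchical clustering of the group x set -log10(p) matrix.

#' One-sided Fisher / hypergeometric over-representation p-value
#'
#' Upper-tail probability `P(X >= k)` for a hypergeometric draw of `m`
#' genes from a universe of `N` containing `K` set members — identical to
#' the one-sided (greater) Fisher's exact test on the 2x2 overlap table.
#' `k = 0` returns exactly 1.
#'
#' @param k overlap count.
#' @param m group size.
#' @param K set size within the universe.
#' @param N universe size.
#' @return p-value vector in (0, 1].
#' @export
enrichment_pvalue <- function(k, m, K, N) {
  stopifnot(all(N >= 1), all(m >= 0 & m <= N), all(K >= 0 & K <= N),
            all(k >= 0), all(k <= pmin(m, K)))
  p <- ifelse(k == 0, 1,
              stats::phyper(k - 1, K, N - K, m, lower.tail = FALSE))
  pmin(pmax(p, .Machine$double.xmin), 1)
}

#' Enrichment of one gene set in one TFS group
#'
#' The gene set is intersected with the universe before testing. The
#' score is fold enrichment `(k/m) / (K/N)` (observed over expected
#' overlap); `k = 0` yields score 0 and p = 1.
#'
#' @param group_genes character vector of genes in the TFS group (must be
#'   a subset of the universe).
#' @param gene_set a `gene_set` object from [read_gmt()] or a character
#'   vector of members.
#' @param universe character vector of background genes.
#' @param set_name set label used when `gene_set` is a plain vector.
#' @return one-row data.frame: `tfs_group` (NA, filled by
#'   [run_collections()]), `set_name`, `k`, `m`, `K`, `N`, `score`, `p`.
#' @export
fisher_enrichment <- function(group_genes, gene_set, universe,
                              set_name = NULL) {
  if (inherits(gene_set, "gene_set")) {
    set_name <- set_name %||% gene_set$name
    members <- gene_set$members
  } else {
    members <- gene_set
    set_name <- set_name %||% "set"
  }
  universe <- unique(universe)
  if (length(universe) == 0L) stop("empty universe", call. = FALSE)
  group_genes <- unique(group_genes)
  if (!all(group_genes %in% universe)) {
    stop("group genes must be a subset of the universe", call. = FALSE)
  }
  members <- intersect(unique(members), universe)
  k <- length(intersect(group_genes, members))
  m <- length(group_genes)
  K <- length(members)
  N <- length(universe)
  score <- if (k == 0L || m == 0L || K == 0L) 0 else (k / m) / (K / N)
  data.frame(tfs_group = NA_character_, set_name = set_name,
             k = k, m = m, K = K, N = N,
             score = score, p = enrichment_pvalue(k, m, K, N),
             stringsAsFactors = FALSE)
}

#' Apply the enrichment selection filters
#'
#' A set survives if, in at least one TFS group, its p-value is below
#' `p_cut` *and* its overlap exceeds `min_genes` (both strict); a group
#' survives if at least one surviving set is enriched in it. The defaults
#' (`p_cut = 0.001`, `min_genes = 5`) are the tabulation filter; the
#' stricter display preset `p_cut = 1e-4`, `min_genes = 10` reproduces the
#' heat-map selection.
#'
#' @param records data.frame of enrichment records (from
#'   [run_collections()] or rbind-ed [fisher_enrichment()] rows with
#'   `tfs_group` filled).
#' @param p_cut p-value threshold (strict; default 0.001).
#' @param min_genes overlap-count threshold (strict; default 5).
#' @return list with `records` (surviving records), `sets`, `groups`.
#' @export
select_enriched <- function(records, p_cut = 0.001, min_genes = 5) {
  stopifnot(all(c("tfs_group", "set_name", "k", "p") %in% names(records)))
  pass <- records$p < p_cut & records$k > min_genes
  sets <- unique(records$set_name[pass])
  groups <- unique(records$tfs_group[pass])
  keep <- records$set_name %in% sets & records$tfs_group %in% groups
  list(records = records[keep, , drop = FALSE], sets = sets, groups = groups)
}

#' Build the set x group significance matrix
#'
#' @param records enrichment records covering every (set, group) pair to
#'   be displayed.
#' @param sets,groups row and column selections (defaults: all present).
#' @return numeric matrix of `-log10(p)`, rows = sets, columns = groups.
#' @export
enrichment_matrix <- function(records, sets = NULL, groups = NULL) {
  sets <- sets %||% unique(records$set_name)
  groups <- groups %||% unique(records$tfs_group)
  mat <- matrix(0, nrow = length(sets), ncol = length(groups),
                dimnames = list(sets, groups))
  sel <- records$set_name %in% sets & records$tfs_group %in% groups
  r <- records[sel, , drop = FALSE]
  mat[cbind(match(r$set_name, sets), match(r$tfs_group, groups))] <-
    -log10(r$p)
  mat
}

# correlation distance (1 - Pearson across the other dimension) with a
# deterministic rule for zero-variance rows: identical rows are at
# distance 0, otherwise a flat row is maximally distant (1)
.cor_dist <- function(x) {
  cc <- suppressWarnings(stats::cor(t(x)))
  d <- 1 - cc
  if (anyNA(d)) {
    na_idx <- which(is.na(d), arr.ind = TRUE)
    for (r in seq_len(nrow(na_idx))) {
      i <- na_idx[r, 1L]; j <- na_idx[r, 2L]
      d[i, j] <- if (isTRUE(all.equal(x[i, ], x[j, ]))) 0 else 1
    }
  }
  diag(d) <- 0
  stats::as.dist(d)
}

#' Cluster an enrichment matrix
#'
#' Agglomerative average-linkage clustering on correlation distance
#' (1 - Pearson), applied to rows and columns independently — the default
#' family of the classic microarray clustering tools. Matrices smaller
#' than 2x2 pass through in input order. Deterministic for fixed input.
#'
#' @param mat numeric matrix (finite cells), e.g. from
#'   [enrichment_matrix()].
#' @return list with `row_order`, `col_order` (leaf orderings) and
#'   `row_hclust`, `col_hclust` (dendrograms, `NULL` when degenerate).
#' @export
cluster_matrix <- function(mat) {
  stopifnot(is.matrix(mat))
  if (any(!is.finite(mat))) stop("non-finite cells in matrix", call. = FALSE)
  if (nrow(mat) < 2L || ncol(mat) < 2L) {
    return(list(row_order = seq_len(nrow(mat)),
                col_order = seq_len(ncol(mat)),
                row_hclust = NULL, col_hclust = NULL))
  }
  rh <- stats::hclust(.cor_dist(mat), method = "average")
  ch <- stats::hclust(.cor_dist(t(mat)), method = "average")
  list(row_order = rh$order, col_order = ch$order,
       row_hclust = rh, col_hclust = ch)
}

#' Run enrichment over one or more gene-set collections
#'
#' Computes a [fisher_enrichment()] record for every (TFS group, gene set)
#' pair in every collection, applies the selection filters per collection,
#' and clusters the surviving significance matrix. Warns when fewer than
#' half of the collection's member genes appear in the universe
#' (identifier-space mismatch).
#'
#' @param assignments gene-level data.frame with columns `gene_id`,
#'   `code` (TFS codes; the null code is ignored as a group).
#' @param collections named list of `gene_set_collection` objects (e.g.
#'   `list(go = ..., motif = ..., mirna = ...)`).
#' @param universe background gene vector (default: all genes in
#'   `assignments` — callers should normally pass the full annotated
#'   platform universe instead).
#' @param p_cut,min_genes selection filters, see [select_enriched()].
#' @return named list per collection: `records` (all pairs), `selection`
#'   (from [select_enriched()]), `matrix`, `clustering`.
#' @export
run_collections <- function(assignments, collections, universe = NULL,
                            p_cut = 0.001, min_genes = 5) {
  stopifnot(all(c("gene_id", "code") %in% names(assignments)),
            is.list(collections))
  universe <- unique(universe %||% assignments$gene_id)
  groups <- sort(unique(assignments$code[assignments$code != "0.0000"]))
  group_genes <- lapply(groups, function(g) {
    unique(assignments$gene_id[assignments$code == g])
  })
  names(group_genes) <- groups

  out <- lapply(names(collections), function(cname) {
    coll <- collections[[cname]]
    if (length(coll) > 0L) {
      all_members <- unique(unlist(lapply(coll, `[[`, "members")))
      cov <- length(intersect(all_members, universe)) /
        max(length(all_members), 1L)
      if (cov < 0.5) {
        warning("collection '", cname, "': only ",
                round_half_up(100 * cov), "% of set members occur in the ",
                "universe - identifier-space mismatch?", call. = FALSE)
      }
    }
    recs <- list()
    for (g in groups) {
      for (s in coll) {
        r <- fisher_enrichment(group_genes[[g]], s, universe)
        r$tfs_group <- g
        recs[[length(recs) + 1L]] <- r
      }
    }
    records <- if (length(recs)) {
      do.call(rbind, recs)
    } else {
      data.frame(tfs_group = character(0), set_name = character(0),
                 k = integer(0), m = integer(0), K = integer(0),
                 N = integer(0), score = numeric(0), p = numeric(0),
                 stringsAsFactors = FALSE)
    }
    records$collection <- rep(cname, nrow(records))
    records <- records[c("collection", "tfs_group", "set_name",
                         "k", "m", "K", "N", "score", "p")]
    selection <- select_enriched(records, p_cut, min_genes)
    mat <- enrichment_matrix(records, selection$sets, selection$groups)
    list(records = records, selection = selection, matrix = mat,
         clustering = cluster_matrix(mat))
  })
  names(out) <- names(collections)
  out
}
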