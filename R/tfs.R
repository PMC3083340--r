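# Total-flag-sum (TFS) classification of differential-expression patterns
# across the four competitive comparisons of a dual-treatment (testosterone,
# MAA) design:
#   comparison 1: testosterone vs. control
#   comparison 2: MAA vs. control
#   comparison 3: testosterone + MAA vs. testosterone
#   comparison 4: testosterone + MAA vs. MAA
# Each comparison yields a direction call in {0, 1, 2} (not significant, up,
# down). A significant call on comparison k contributes a binary flag
# 2^(k-1) to the whole-number part of the code; the four direction digits
# are appended after the decimal point, so calls (1,0,0,1) give "9.1001".

#' Significance thresholds for a direction call
#'
#' Combined fold-change / p-value thresholds. Both inequalities are strict:
#' a probe is called only when `|fold| > fold_min` **and** `p < p_max`, so
#' a fold-change of exactly 2 at the default threshold is not significant.
#'
#' @param fold_min signed fold-change magnitude threshold (default 2).
#' @param p_max p-value threshold (default 0.005).
#' @return an object of class `tfs_thresholds`.
#' @export
tfs_thresholds <- function(fold_min = 2, p_max = 0.005) {
  stopifnot(is.numeric(fold_min), length(fold_min) == 1L, fold_min > 1,
            is.numeric(p_max), length(p_max) == 1L, p_max > 0, p_max < 1)
  structure(list(fold_min = fold_min, p_max = p_max),
            class = "tfs_thresholds")
}

#' Direction call for one comparison
#'
#' Applies the combined thresholds to signed fold-changes and p-values.
#' Signed fold-change is defined as `2^x` for a log2 ratio `x >= 0` and
#' `-2^(-x)` otherwise, so `|fold| >= 1` always. Missing values (probes
#' with no usable measurement in a comparison) yield 0.
#'
#' @param fold signed fold-change vector (`|fold| >= 1`).
#' @param p two-sided p-value vector.
#' @param thresholds a [tfs_thresholds()] object.
#' @return integer vector of direction digits: 0 = not significant,
#'   1 = up-regulated, 2 = down-regulated.
#' @examples
#' call_significance(c(2.5, 2.0, -3.0), c(0.001, 0.001, 0.004))
#' @export
call_significance <- function(fold, p, thresholds = tfs_thresholds()) {
  stopifnot(inherits(thresholds, "tfs_thresholds"), length(fold) == length(p))
  ok <- !is.na(fold) & !is.na(p)
  if (any(abs(fold[ok]) < 1)) {
    stop("signed fold-changes must have magnitude >= 1", call. = FALSE)
  }
  d <- integer(length(fold))
  d[ok & fold > thresholds$fold_min & p < thresholds$p_max] <- 1L
  d[ok & fold < -thresholds$fold_min & p < thresholds$p_max] <- 2L
  d
}

#' Compute the TFS code for one gene
#'
#' @param calls four direction digits in \{0, 1, 2\}, one per comparison.
#' @return an object of class `tfs_code` with fields `whole` (sum of the
#'   binary flags 1, 2, 4, 8 of the significant comparisons), `digits`
#'   (the four direction calls) and `text` (canonical form `"W.dddd"`,
#'   always printing all four digits).
#' @examples
#' compute_tfs(c(1, 0, 0, 1))  # "9.1001"
#' compute_tfs(c(0, 2, 2, 0))  # "6.0220"
#' @export
compute_tfs <- function(calls) {
  calls <- as.integer(calls)
  if (length(calls) != 4L || anyNA(calls) || !all(calls %in% 0:2)) {
    stop("`calls` must be four direction digits in {0, 1, 2}", call. = FALSE)
  }
  whole <- sum(2L^(which(calls != 0L) - 1L))
  structure(
    list(whole = as.integer(whole), digits = calls,
         text = sprintf("%d.%s", whole, paste0(calls, collapse = ""))),
    class = "tfs_code"
  )
}

#' @export
format.tfs_code <- function(x, ...) x$text

#' @export
print.tfs_code <- function(x, ...) {
  cat("<TFS code ", x$text, ">\n", sep = "")
  invisible(x)
}

#' @export
as.character.tfs_code <- function(x, ...) x$text

#' Vectorised TFS code text for a matrix of calls
#'
#' @param calls integer matrix with one row per gene/probe and four columns
#'   of direction digits in \{0, 1, 2\}.
#' @return character vector of canonical `"W.dddd"` codes.
#' @export
tfs_codes <- function(calls) {
  calls <- as.matrix(calls)
  stopifnot(ncol(calls) == 4L)
  storage.mode(calls) <- "integer"
  if (anyNA(calls) || !all(calls %in% 0:2)) {
    stop("direction calls must be in {0, 1, 2}", call. = FALSE)
  }
  whole <- (calls[, 1L] != 0L) * 1L + (calls[, 2L] != 0L) * 2L +
    (calls[, 3L] != 0L) * 4L + (calls[, 4L] != 0L) * 8L
  sprintf("%d.%d%d%d%d", whole,
          calls[, 1L], calls[, 2L], calls[, 3L], calls[, 4L])
}

#' Parse a TFS code from its text form
#'
#' Validates both the format and the internal consistency of the code: the
#' whole-number part must equal the binary-flag sum implied by the digits.
#'
#' @param text a single code string such as `"9.1001"`.
#' @return a `tfs_code` object.
#' @export
parse_tfs <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  if (!grepl("^[0-9]{1,2}\\.[0-2]{4}$", text)) {
    stop("malformed TFS code: ", text, call. = FALSE)
  }
  parts <- strsplit(text, ".", fixed = TRUE)[[1L]]
  digits <- as.integer(strsplit(parts[2L], "")[[1L]])
  code <- compute_tfs(digits)
  if (code$whole != as.integer(parts[1L])) {
    stop("inconsistent TFS code: ", text, " (whole part should be ",
         code$whole, ")", call. = FALSE)
  }
  code
}

#' Interaction-class taxonomy of TFS groups
#'
#' The 27 TFS groups with named interaction classes, together with the
#' published gene counts for each group (used by the synthetic generator to
#' apportion planted genes across groups in realistic proportions, and as a
#' worked input for the class summary). Classes: I = no interaction between
#' testosterone (T) and MAA; IIa-IIc = one-way or mutual enhancement;
#' IIIa-IIId = one agent blocks the action of the other.
#'
#' @return data.frame with columns `class`, `description`, `code`,
#'   `n_genes_reported`.
#' @export
tfs_class_table <- function() {
  data.frame(
    class = c(rep("I", 7L), rep("IIa", 4L), rep("IIb", 4L), rep("IIc", 4L),
              rep("IIIa", 2L), rep("IIIb", 2L), rep("IIIc", 2L),
              rep("IIId", 2L)),
    description = c(
      rep("No interaction between T and MAA", 7L),
      rep("MAA enhances action of T", 4L),
      rep("T enhances action of MAA", 4L),
      rep("T enhances action of MAA, and MAA enhances action of T", 4L),
      rep("MAA blocks action of T", 2L),
      rep("T blocks action of MAA", 2L),
      rep("MAA blocks the action of T, but MAA alone shows no activity", 2L),
      rep("T blocks the action of MAA, but T alone shows no activity", 2L)
    ),
    code = c("9.1001", "9.2002", "6.0110", "6.0220", "3.1100", "3.2200",
             "15.2112",
             "8.0001", "8.0002", "14.0111", "14.0222",
             "4.0010", "4.0020", "13.1011", "13.2022",
             "15.1111", "15.2222", "12.0011", "12.0022",
             "1.1000", "1.2000",
             "2.0100", "2.0200",
             "5.1020", "5.2010",
             "10.0102", "10.0201"),
    n_genes_reported = c(472L, 492L, 350L, 174L, 53L, 55L, 59L,
                         421L, 398L, 60L, 24L,
                         355L, 264L, 144L, 56L,
                         77L, 39L, 316L, 81L,
                         329L, 307L,
                         302L, 165L,
                         62L, 52L,
                         107L, 16L),
    stringsAsFactors = FALSE
  )
}

#' Assign interaction classes to TFS codes
#'
#' Exact lookup in the 27-group taxonomy of [tfs_class_table()]; any valid
#' code outside the taxonomy (including the null code `"0.0000"`) maps to
#' `"other"`.
#'
#' @param code character vector of TFS codes (or a single `tfs_code`).
#' @return character vector of class labels in
#'   \{I, IIa, IIb, IIc, IIIa, IIIb, IIIc, IIId, other\}.
#' @examples
#' assign_class(c("8.0001", "5.1020", "7.1110"))
#' @export
assign_class <- function(code) {
  if (inherits(code, "tfs_code")) code <- code$text
  stopifnot(is.character(code))
  for (u in unique(code)) parse_tfs(u)  # validates format + consistency
  tab <- tfs_class_table()
  cls <- tab$class[match(code, tab$code)]
  cls[is.na(cls)] <- "other"
  cls
}

#' Collapse same-pattern redundant probes to one representative per gene
#'
#' Probes of the same gene with an identical TFS code (platform probe
#' redundancy) are collapsed to a single representative; probes of the same
#' gene with *different* codes are all retained. The representative is the
#' probe with the smallest minimum p-value across the four comparisons,
#' ties broken by lexicographic probe id. Idempotent.
#'
#' @param assignments data.frame with columns `gene_id`, `probe_id`, `code`
#'   and either a `min_p` column or p-value columns `p_1` .. `p_4`.
#' @return data.frame with one row per (gene, code) pattern.
#' @export
collapse_redundant <- function(assignments) {
  need <- c("gene_id", "probe_id", "code")
  if (!all(need %in% names(assignments))) {
    stop("`assignments` needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(assignments) == 0L) return(assignments)
  if ("min_p" %in% names(assignments)) {
    mp <- assignments$min_p
  } else {
    pcols <- paste0("p_", 1:4)
    if (!all(pcols %in% names(assignments))) {
      stop("`assignments` needs a `min_p` column or columns p_1..p_4",
           call. = FALSE)
    }
    mp <- do.call(pmin, c(unname(assignments[pcols]), list(na.rm = TRUE)))
  }
  o <- order(assignments$gene_id, assignments$code, mp, assignments$probe_id)
  a <- assignments[o, , drop = FALSE]
  keep <- !duplicated(a[, c("gene_id", "code")])
  out <- a[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Number of probes expected to pass a p-value threshold by chance
#'
#' `n_tests * alpha`, rounded half-up to the nearest integer
#' (6,416 tests at alpha 0.005 -> 32).
#'
#' @param n_tests number of tests performed.
#' @param alpha p-value threshold.
#' @return integer expected count.
#' @export
expected_false_positives <- function(n_tests, alpha) {
  stopifnot(is.numeric(n_tests), length(n_tests) == 1L, n_tests >= 0,
            is.numeric(alpha), length(alpha) == 1L, alpha > 0, alpha < 1)
  as.integer(round_half_up(n_tests * alpha))
}

#' Apparent false discovery rate
#'
#' Expected-by-chance count divided by the observed significant count,
#' as a percentage rounded to two decimals (32 expected of 7,811 observed
#' -> 0.41).
#'
#' @param expected expected-by-chance significant count.
#' @param observed observed significant count (> 0).
#' @return percentage, rounded to 2 decimal places.
#' @export
apparent_fdr <- function(expected, observed) {
  stopifnot(is.numeric(expected), length(expected) == 1L, expected >= 0,
            is.numeric(observed), length(observed) == 1L, observed > 0)
  round_half_up(100 * expected / observed, 2)
}

#' Summarise gene-level TFS assignments into interaction classes
#'
#' Counts genes per TFS group and per interaction class among the genes of
#' interest (genes with at least one significant comparison, i.e. code not
#' `"0.0000"`). Percentages are integer percent of the genes of interest.
#' Subclasses IIa-IIc and IIIa-IIId are also rolled up into major classes
#' II and III. With no genes of interest the summary tables are empty.
#'
#' @param assignments gene-level data.frame with columns `code` and
#'   optionally `class` (computed via [assign_class()] when absent).
#' @return an object of class `tfs_summary`: a list with `group_counts`
#'   (class, description, code, n_genes), `class_counts` (per subclass:
#'   n_genes, n_groups, pct), `major_class_counts` (I, II, III), and scalar
#'   fields `n_total` (genes of interest), `n_classified`, `pct_classified`,
#'   `n_other`, `n_other_groups`.
#' @export
summarize_classes <- function(assignments) {
  stopifnot("code" %in% names(assignments))
  if (!"class" %in% names(assignments)) {
    assignments$class <- assign_class(assignments$code)
  }
  goi <- assignments[assignments$code != "0.0000", , drop = FALSE]
  n_total <- nrow(goi)
  tab <- tfs_class_table()

  if (n_total == 0L) {
    empty_groups <- data.frame(class = character(0), description = character(0),
                               code = character(0), n_genes = integer(0),
                               stringsAsFactors = FALSE)
    empty_cls <- data.frame(class = character(0), n_genes = integer(0),
                            n_groups = integer(0), pct = integer(0),
                            stringsAsFactors = FALSE)
    return(structure(list(group_counts = empty_groups,
                          class_counts = empty_cls,
                          major_class_counts = empty_cls,
                          n_total = 0L, n_classified = 0L,
                          pct_classified = NA_integer_,
                          n_other = 0L, n_other_groups = 0L),
                     class = "tfs_summary"))
  }

  counts <- table(goi$code)
  named <- tab
  named$n_genes <- as.integer(counts[named$code])
  named$n_genes[is.na(named$n_genes)] <- 0L
  named <- named[, c("class", "description", "code", "n_genes")]

  other_codes <- setdiff(names(counts), tab$code)
  n_other <- sum(counts[other_codes])

  cls_split <- split(named$n_genes, named$class)
  cls_order <- c("I", "IIa", "IIb", "IIc", "IIIa", "IIIb", "IIIc", "IIId")
  class_counts <- data.frame(
    class = cls_order,
    n_genes = vapply(cls_order, function(cl) sum(cls_split[[cl]]), integer(1)),
    n_groups = vapply(cls_order,
                      function(cl) sum(cls_split[[cl]] > 0L), integer(1)),
    stringsAsFactors = FALSE
  )
  class_counts$pct <- round_percent(class_counts$n_genes, n_total)

  major <- c(I = "I", IIa = "II", IIb = "II", IIc = "II",
             IIIa = "III", IIIb = "III", IIIc = "III", IIId = "III")
  mc <- data.frame(
    class = c("I", "II", "III"),
    n_genes = vapply(c("I", "II", "III"), function(m) {
      sum(class_counts$n_genes[major[class_counts$class] == m])
    }, integer(1)),
    n_groups = vapply(c("I", "II", "III"), function(m) {
      sum(class_counts$n_groups[major[class_counts$class] == m])
    }, integer(1)),
    stringsAsFactors = FALSE
  )
  mc$pct <- round_percent(mc$n_genes, n_total)
  rownames(mc) <- NULL

  n_classified <- sum(named$n_genes)
  structure(list(
    group_counts = named,
    class_counts = class_counts,
    major_class_counts = mc,
    n_total = as.integer(n_total),
    n_classified = as.integer(n_classified),
    pct_classified = round_percent(n_classified, n_total),
    n_other = as.integer(n_other),
    n_other_groups = length(other_codes)
  ), class = "tfs_summary")
}

#' @export
print.tfs_summary <- function(x, ...) {
  cat("TFS interaction-class summary\n")
  cat("  genes of interest:", x$n_total, "\n")
  if (x$n_total > 0L) {
    cat("  classified: ", x$n_classified, " (", x$pct_classified, "%) in ",
        sum(x$group_counts$n_genes > 0), " named TFS groups\n", sep = "")
    cat("  other: ", x$n_other, " genes in ", x$n_other_groups,
        " unnamed groups\n", sep = "")
    print(x$major_class_counts, row.names = FALSE)
  }
  invisible(x)
}
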