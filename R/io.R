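# On-disk artifacts: hybridization tables, probe annotation, GMT gene-set
# collections, truth tables, manifests and result tables. Everything is
# tab-delimited UTF-8 text with a header; TFS codes are always written and
# read as strings so trailing zeros ("6.0220") survive round-trips.

HYB_COLUMNS <- c("probe_id", "gene_id",
                 "channel_A_intensity", "channel_B_intensity",
                 "dye_orientation",
                 "flag_saturated_A", "flag_saturated_B",
                 "flag_nonuniform_A", "flag_nonuniform_B")

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
}

.read_tsv <- function(path) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    colClasses = "character", na.strings = NULL,
                    check.names = FALSE)
}

.as_numeric_strict <- function(x, col, path) {
  out <- suppressWarnings(as.numeric(x))
  bad <- is.na(out) & !(x %in% c("", "NA"))
  if (any(bad) || any(x %in% c("", "NA"))) {
    if (any(bad)) {
      stop("malformed numeric value(s) in column '", col, "' of ", path,
           ": ", paste(utils::head(x[bad], 3), collapse = ", "),
           call. = FALSE)
    }
    stop("missing numeric value(s) in column '", col, "' of ", path,
         call. = FALSE)
  }
  out
}

.as_logical_strict <- function(x, col, path) {
  up <- toupper(x)
  out <- rep(NA, length(x))
  out[up %in% c("TRUE", "T", "1")] <- TRUE
  out[up %in% c("FALSE", "F", "0")] <- FALSE
  if (anyNA(out)) {
    stop("malformed logical value(s) in column '", col, "' of ", path,
         call. = FALSE)
  }
  out
}

#' Write one hybridization table
#'
#' @param h hybridization data.frame with the standard columns (see
#'   [read_hybridization()]).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_hybridization <- function(h, path) {
  miss <- setdiff(HYB_COLUMNS, names(h))
  if (length(miss)) {
    stop("hybridization table is missing columns: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  .write_tsv(h[HYB_COLUMNS], path)
  invisible(path)
}

#' Read one hybridization table
#'
#' Validates the schema strictly: all nine columns must be present
#' (`probe_id`, `gene_id`, `channel_A_intensity`, `channel_B_intensity`,
#' `dye_orientation`, and the four quality-flag columns), probe ids must be
#' unique within the file, intensities must parse as non-negative numbers
#' (malformed cells are errors, never silent NAs), and the dye orientation
#' must be `forward` or `reverse`.
#'
#' @param path input file path.
#' @return typed hybridization data.frame.
#' @export
read_hybridization <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- .read_tsv(path)
  miss <- setdiff(HYB_COLUMNS, names(raw))
  if (length(miss)) {
    stop("hybridization file ", path, " is missing columns: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(raw$probe_id)) {
    stop("duplicate probe_id in ", path, ": ",
         raw$probe_id[anyDuplicated(raw$probe_id)], call. = FALSE)
  }
  h <- data.frame(
    probe_id = raw$probe_id,
    gene_id = ifelse(raw$gene_id %in% c("", "NA"), NA_character_,
                     raw$gene_id),
    channel_A_intensity = .as_numeric_strict(raw$channel_A_intensity,
                                             "channel_A_intensity", path),
    channel_B_intensity = .as_numeric_strict(raw$channel_B_intensity,
                                             "channel_B_intensity", path),
    dye_orientation = raw$dye_orientation,
    flag_saturated_A = .as_logical_strict(raw$flag_saturated_A,
                                          "flag_saturated_A", path),
    flag_saturated_B = .as_logical_strict(raw$flag_saturated_B,
                                          "flag_saturated_B", path),
    flag_nonuniform_A = .as_logical_strict(raw$flag_nonuniform_A,
                                           "flag_nonuniform_A", path),
    flag_nonuniform_B = .as_logical_strict(raw$flag_nonuniform_B,
                                           "flag_nonuniform_B", path),
    stringsAsFactors = FALSE
  )
  if (any(h$channel_A_intensity < 0) || any(h$channel_B_intensity < 0)) {
    stop("negative intensities in ", path, call. = FALSE)
  }
  if (!all(h$dye_orientation %in% c("forward", "reverse"))) {
    stop("dye_orientation must be 'forward' or 'reverse' in ", path,
         call. = FALSE)
  }
  h
}

#' Read a probe annotation table
#'
#' Two tab-delimited columns, `probe_id` and `gene_id`. Probe ids must be
#' unique; probes with an empty gene id are retained and marked
#' unannotated (`NA`).
#'
#' @param path input file path.
#' @return data.frame with columns `probe_id`, `gene_id`.
#' @export
read_annotation <- function(path) {
  raw <- .read_tsv(path)
  need <- c("probe_id", "gene_id")
  if (!all(need %in% names(raw))) {
    stop("annotation file needs columns probe_id, gene_id", call. = FALSE)
  }
  if (anyDuplicated(raw$probe_id)) {
    stop("duplicate probe_id in annotation file ", path, call. = FALSE)
  }
  data.frame(probe_id = raw$probe_id,
             gene_id = ifelse(raw$gene_id %in% c("", "NA"), NA_character_,
                              raw$gene_id),
             stringsAsFactors = FALSE)
}

#' Read a GMT gene-set collection
#'
#' Broad-dialect GMT: one set per line, tab-separated fields
#' `name`, `description`, then one or more member genes. Duplicate members
#' within a line are deduplicated, empty lines skipped; a line with fewer
#' than three fields or a duplicated set name is an error. Gene
#' identifiers are opaque, case-sensitive tokens.
#'
#' @param path GMT file path.
#' @return an object of class `gene_set_collection`: a named list of
#'   `gene_set` objects (fields `name`, `description`, `members`),
#'   in file order.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[trimws(lines) != ""]
  sets <- vector("list", length(lines))
  nm <- character(length(lines))
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    fields <- fields[fields != ""]
    if (length(fields) < 3L) {
      stop("GMT line ", i, " has fewer than 3 fields in ", path,
           call. = FALSE)
    }
    members <- unique(fields[-(1:2)])
    sets[[i]] <- structure(list(name = fields[1L],
                                description = fields[2L],
                                members = members),
                           class = "gene_set")
    nm[i] <- fields[1L]
  }
  if (anyDuplicated(nm)) {
    stop("duplicate gene-set name(s) in ", path, ": ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "), call. = FALSE)
  }
  names(sets) <- nm
  structure(sets, class = "gene_set_collection")
}

#' Write a GMT gene-set collection
#'
#' @param collection a `gene_set_collection` or plain named list of
#'   character vectors.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(collection, path) {
  lines <- vapply(seq_along(collection), function(i) {
    s <- collection[[i]]
    if (is.character(s)) {
      s <- list(name = names(collection)[i], description = "na", members = s)
    }
    paste(c(s$name, s$description, s$members), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write / read a simulation truth table
#'
#' Tab-delimited, loss-free round trip; the TFS code column is read back
#' as text. Writing an empty truth table is an error.
#'
#' @param truth data.frame with columns `gene_id`, `call_1`..`call_4`,
#'   `tfs`, `class`.
#' @param path file path.
#' @return `path` invisibly ([write_truth()]) or the truth data.frame
#'   ([read_truth()]).
#' @export
write_truth <- function(truth, path) {
  need <- c("gene_id", paste0("call_", 1:4), "tfs", "class")
  if (!all(need %in% names(truth))) {
    stop("truth table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(truth) == 0L) stop("refusing to write an empty truth table",
                              call. = FALSE)
  .write_tsv(truth[need], path)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  raw <- .read_tsv(path)
  need <- c("gene_id", paste0("call_", 1:4), "tfs", "class")
  if (!all(need %in% names(raw))) {
    stop("truth file needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  out <- raw[need]
  for (k in paste0("call_", 1:4)) {
    out[[k]] <- as.integer(.as_numeric_strict(raw[[k]], k, path))
  }
  out
}

#' Write a simulated experiment to a directory
#'
#' One file per hybridization (`hyb_c<comparison>_p<pool>_<fwd|rev>.tsv`),
#' plus `manifest.tsv` mapping files to the four comparisons,
#' `truth.tsv` and `annotation.tsv`.
#'
#' @param sim a `simulated_experiment` from [simulate_experiment()].
#' @param dir output directory (created if needed).
#' @param overwrite allow writing into a directory that already holds a
#'   manifest (default `FALSE`).
#' @return `dir`, invisibly.
#' @export
write_experiment <- function(sim, dir, overwrite = FALSE) {
  stopifnot(inherits(sim, "simulated_experiment"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  man_path <- file.path(dir, "manifest.tsv")
  if (file.exists(man_path) && !overwrite) {
    stop("manifest already exists in ", dir, " (use overwrite = TRUE)",
         call. = FALSE)
  }
  rows <- list()
  for (k in seq_along(sim$comparisons)) {
    for (h in sim$comparisons[[k]]) {
      orient <- attr(h, "dye_orientation")
      fname <- sprintf("hyb_c%d_p%d_%s.tsv", k, attr(h, "pool"),
                       substr(orient, 1, 3))
      write_hybridization(h, file.path(dir, fname))
      rows[[length(rows) + 1L]] <- data.frame(
        file = fname, comparison = k,
        comparison_label = attr(h, "comparison_label"),
        pool = attr(h, "pool"), dye_orientation = orient,
        stringsAsFactors = FALSE
      )
    }
  }
  .write_tsv(do.call(rbind, rows), man_path)
  write_truth(sim$truth, file.path(dir, "truth.tsv"))
  .write_tsv(sim$probes, file.path(dir, "annotation.tsv"))
  invisible(dir)
}

#' Read an experiment manifest
#'
#' @param path manifest file (columns `file`, `comparison`,
#'   `comparison_label`, `pool`, `dye_orientation`).
#' @return manifest data.frame.
#' @export
read_manifest <- function(path) {
  raw <- .read_tsv(path)
  need <- c("file", "comparison", "comparison_label", "pool",
            "dye_orientation")
  if (!all(need %in% names(raw))) {
    stop("manifest needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  raw$comparison <- as.integer(.as_numeric_strict(raw$comparison,
                                                  "comparison", path))
  raw$pool <- as.integer(.as_numeric_strict(raw$pool, "pool", path))
  if (!all(raw$comparison %in% 1:4)) {
    stop("manifest comparisons must be 1-4", call. = FALSE)
  }
  raw
}

#' Read an experiment directory back into memory
#'
#' Inverse of [write_experiment()]; the truth table is optional (a real,
#' non-simulated experiment directory has none).
#'
#' @param dir experiment directory containing `manifest.tsv`.
#' @return list with `comparisons` (list of 4 lists of hybridization
#'   tables), `probes`, and `truth` (`NULL` when absent).
#' @export
read_experiment <- function(dir) {
  man <- read_manifest(file.path(dir, "manifest.tsv"))
  comparisons <- lapply(1:4, function(k) {
    sel <- man[man$comparison == k, , drop = FALSE]
    lapply(seq_len(nrow(sel)), function(i) {
      h <- read_hybridization(file.path(dir, sel$file[i]))
      attr(h, "comparison") <- k
      attr(h, "comparison_label") <- sel$comparison_label[i]
      attr(h, "pool") <- sel$pool[i]
      attr(h, "dye_orientation") <- sel$dye_orientation[i]
      h
    })
  })
  names(comparisons) <- COMPARISON_LABELS
  probes_path <- file.path(dir, "annotation.tsv")
  truth_path <- file.path(dir, "truth.tsv")
  list(
    comparisons = comparisons,
    probes = if (file.exists(probes_path)) read_annotation(probes_path) else NULL,
    truth = if (file.exists(truth_path)) read_truth(truth_path) else NULL
  )
}

#' Write pipeline result tables
#'
#' Writes `comparison_results.tsv` (per-probe fold and p per comparison),
#' `tfs_assignments.tsv` (gene, probe, TFS code, class, fold/p columns),
#' `class_summary.tsv` (per-group counts in taxonomy order) and
#' `enrichment.tsv`. TFS codes are written as text and must be read back
#' with [read_tfs_assignments()] to preserve trailing zeros.
#'
#' @param tables named list with any of `comparison_results`,
#'   `tfs_assignments`, `class_summary` (a `tfs_summary` or data.frame),
#'   `enrichment`.
#' @param out_dir output directory.
#' @param overwrite allow replacing existing result files (default
#'   `FALSE`; colliding with an existing file is otherwise an error).
#' @return character vector of files written, invisibly.
#' @export
write_results <- function(tables, out_dir, overwrite = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  known <- c("comparison_results", "tfs_assignments", "class_summary",
             "enrichment")
  written <- character(0)
  for (nm in intersect(known, names(tables))) {
    obj <- tables[[nm]]
    if (is.null(obj)) next
    if (nm == "class_summary" && inherits(obj, "tfs_summary")) {
      obj <- obj$group_counts
    }
    path <- file.path(out_dir, paste0(nm, ".tsv"))
    if (file.exists(path) && !overwrite) {
      stop("result file already exists: ", path, " (use overwrite = TRUE)",
           call. = FALSE)
    }
    .write_tsv(obj, path)
    written <- c(written, path)
  }
  invisible(written)
}

#' Read back a TFS assignment table
#'
#' @param path `tfs_assignments.tsv` as written by [write_results()].
#' @return data.frame; the `code` column is character, fold/p columns
#'   numeric.
#' @export
read_tfs_assignments <- function(path) {
  raw <- .read_tsv(path)
  if (!all(c("gene_id", "probe_id", "code", "class") %in% names(raw))) {
    stop("tfs assignment file needs columns gene_id, probe_id, code, class",
         call. = FALSE)
  }
  for (cn in grep("^(fold|p)_[1-4]$|^min_p$", names(raw), value = TRUE)) {
    x <- raw[[cn]]
    out <- suppressWarnings(as.numeric(x))
    out[x %in% c("", "NA")] <- NA_real_
    raw[[cn]] <- out
  }
  raw
}
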