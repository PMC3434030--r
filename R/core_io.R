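# Data model and tabular I/O.
#
# Containers are deliberately plain (matrices + data.frames wrapped in light
# S3 lists), following the limma school: every downstream statistic operates
# on a probe/probe-set x sample numeric matrix whose dimnames are the stable
# identifiers.

sa_error <- function(type, msg, call. = FALSE) {
  stop(errorCondition(msg, class = c(paste0("strainarray_", type, "_error"),
                                     "strainarray_error", "error", "condition")))
}

#' Validate a sample metadata table
#'
#' Checks the study-design invariants of a sample table: unique sample ids,
#' sexes coded \code{M}/\code{F}, strictly positive integer pool sizes, and a
#' strain-to-domestication mapping that is consistent across samples (a strain
#' cannot be "wild" in one row and "domesticated" in another).
#'
#' @param samples data.frame with columns \code{sample_id}, \code{strain},
#'   \code{domestication}, \code{sex}, \code{pool_size}.
#' @return The validated data.frame, with \code{strain}, \code{domestication}
#'   and \code{sex} as character vectors.
#' @export
validate_samples <- function(samples) {
  required <- c("sample_id", "strain", "domestication", "sex", "pool_size")
  missing <- setdiff(required, names(samples))
  if (length(missing) > 0L)
    sa_error("metadata", paste("samples table missing column(s):",
                               paste(missing, collapse = ", ")))
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  for (col in c("sample_id", "strain", "domestication", "sex"))
    samples[[col]] <- as.character(samples[[col]])
  if (anyDuplicated(samples$sample_id))
    sa_error("metadata", "duplicate sample_id values in samples table")
  if (!all(samples$domestication %in% c("wild", "domesticated")))
    sa_error("metadata", "domestication must be 'wild' or 'domesticated'")
  if (!all(samples$sex %in% c("M", "F")))
    sa_error("metadata", "sex must be coded 'M' or 'F'")
  if (any(samples$pool_size <= 0) || any(samples$pool_size != round(samples$pool_size)))
    sa_error("metadata", "pool_size must be a positive integer")
  map <- unique(samples[, c("strain", "domestication")])
  if (anyDuplicated(map$strain))
    sa_error("metadata", paste(
      "inconsistent strain-to-domestication mapping for strain(s):",
      paste(unique(map$strain[duplicated(map$strain)]), collapse = ", ")))
  samples
}

#' Construct a probe-level dataset
#'
#' Bundles PM and MM intensity matrices with their probe-to-probe-set mapping
#' and sample metadata, enforcing all structural invariants: identical PM/MM
#' shape and row order, strictly positive intensities, at least 3 probe pairs
#' per probe set, and sample columns aligned with the metadata.
#'
#' @param pm,mm numeric matrices (probes x samples) with row names of the form
#'   \code{"<probeset_id>:<probe_index>"} and column names equal to sample ids.
#' @param samples sample metadata (see [validate_samples()]).
#' @param control_prefix probe sets whose identifier starts with this prefix
#'   are flagged as hybridization/spike-in controls (Affymetrix convention
#'   \code{"AFFX-"}). Controls travel through preprocessing but are excluded
#'   from candidate gene lists.
#' @return An object of class \code{ProbeLevelDataset}: a list with elements
#'   \code{pm}, \code{mm}, \code{probe_map} (data.frame: \code{probe_id},
#'   \code{probeset_id}, \code{probe_index}), \code{samples} and
#'   \code{control_flags} (named logical, one per probe set).
#' @export
probe_level_dataset <- function(pm, mm, samples, control_prefix = "AFFX-") {
  pm <- as.matrix(pm); mm <- as.matrix(mm)
  if (!identical(dim(pm), dim(mm)))
    sa_error("format", sprintf("PM (%d x %d) and MM (%d x %d) shapes differ",
                               nrow(pm), ncol(pm), nrow(mm), ncol(mm)))
  if (is.null(rownames(pm)) || is.null(rownames(mm)))
    sa_error("format", "PM/MM matrices must carry probe row identifiers")
  if (!identical(rownames(pm), rownames(mm)))
    sa_error("format", "PM and MM row identifiers differ or are ordered differently")
  samples <- validate_samples(samples)
  if (is.null(colnames(pm)))
    colnames(pm) <- colnames(mm) <- samples$sample_id
  if (!setequal(colnames(pm), samples$sample_id))
    sa_error("format", "PM/MM columns do not match sample_ids in the samples table")
  pm <- pm[, samples$sample_id, drop = FALSE]
  mm <- mm[, samples$sample_id, drop = FALSE]
  if (any(!is.finite(pm)) || any(!is.finite(mm)))
    sa_error("value", "non-finite intensity values")
  if (any(pm <= 0) || any(mm <= 0))
    sa_error("value", "all PM/MM intensities must be strictly positive")
  m <- regmatches(rownames(pm), regexec("^(.*):([0-9]+)$", rownames(pm)))
  bad <- vapply(m, length, 1L) != 3L
  if (any(bad))
    sa_error("format", paste("probe row identifiers must look like",
                             "'probeset_id:probe_index'; first offender:",
                             rownames(pm)[bad][1L]))
  probe_map <- data.frame(
    probe_id = rownames(pm),
    probeset_id = vapply(m, `[`, "", 2L),
    probe_index = as.integer(vapply(m, `[`, "", 3L)),
    stringsAsFactors = FALSE)
  n_probes <- table(probe_map$probeset_id)
  if (any(n_probes < 3L))
    sa_error("format", sprintf("probe set(s) with fewer than 3 probe pairs: %s",
                               paste(utils::head(names(n_probes)[n_probes < 3L], 5L),
                                     collapse = ", ")))
  probesets <- sort(unique(probe_map$probeset_id))
  control_flags <- startsWith(probesets, control_prefix)
  names(control_flags) <- probesets
  structure(list(pm = pm, mm = mm, probe_map = probe_map,
                 samples = samples, control_flags = control_flags),
            class = "ProbeLevelDataset")
}

#' @export
print.ProbeLevelDataset <- function(x, ...) {
  cat(sprintf("ProbeLevelDataset: %d probes / %d probe sets x %d samples (%d control probe sets)\n",
              nrow(x$pm), length(x$control_flags), ncol(x$pm), sum(x$control_flags)))
  cat(sprintf("strains: %s\n",
              paste(sprintf("%s(%s)", unique(x$samples$strain),
                            x$samples$domestication[!duplicated(x$samples$strain)]),
                    collapse = ", ")))
  invisible(x)
}

#' Load a probe-level dataset from TSV files
#'
#' Reads wide tab-delimited PM and MM tables (rows = probes identified as
#' \code{"probeset_id:probe_index"}, one column per sample) together with the
#' sample metadata table, validates the design, and flags control probe sets.
#'
#' @param pm_path,mm_path,samples_path paths to \code{pm.tsv}, \code{mm.tsv}
#'   and \code{samples.tsv}.
#' @inheritParams probe_level_dataset
#' @return A [probe_level_dataset()] object.
#' @export
load_probe_level_dataset <- function(pm_path, mm_path, samples_path,
                                     control_prefix = "AFFX-") {
  for (p in c(pm_path, mm_path, samples_path))
    if (!file.exists(p)) sa_error("io", paste("file not found:", p))
  read_mat <- function(path) {
    df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
    m <- as.matrix(df[, -1L, drop = FALSE])
    rownames(m) <- df[[1L]]
    storage.mode(m) <- "double"
    m
  }
  samples <- utils::read.delim(samples_path, stringsAsFactors = FALSE)
  probe_level_dataset(read_mat(pm_path), read_mat(mm_path), samples,
                      control_prefix = control_prefix)
}

#' Write a probe-level dataset to a directory
#'
#' Inverse of [load_probe_level_dataset()]: writes \code{pm.tsv},
#' \code{mm.tsv} and \code{samples.tsv} under \code{dir}.
#'
#' @param dataset a \code{ProbeLevelDataset}.
#' @param dir output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_probe_level_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "ProbeLevelDataset"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_mat <- function(m, path) {
    df <- data.frame(probe_id = rownames(m), as.data.frame(m, check.names = FALSE),
                     check.names = FALSE)
    utils::write.table(format(df, digits = 12, scientific = FALSE, trim = TRUE),
                       path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  paths <- file.path(dir, c("pm.tsv", "mm.tsv", "samples.tsv"))
  write_mat(dataset$pm, paths[1L])
  write_mat(dataset$mm, paths[2L])
  utils::write.table(dataset$samples, paths[3L], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}

#' Load a gene-to-category annotation table
#'
#' Reads a tab-delimited table with columns \code{probeset_id},
#' \code{category_id}, \code{category_label}. Duplicate (probe set, category)
#' memberships are removed with a warning. Probe sets may be unannotated
#' (simply absent from the table).
#'
#' @param path path to the annotation TSV.
#' @return An object of class \code{AnnotationTable}: list with
#'   \code{membership} (data.frame \code{probeset_id}, \code{category_id}) and
#'   \code{labels} (named character: category id -> label).
#' @export
load_annotation_table <- function(path) {
  if (!file.exists(path)) sa_error("io", paste("file not found:", path))
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  required <- c("probeset_id", "category_id", "category_label")
  if (!all(required %in% names(df)))
    sa_error("format", paste("annotation table must have columns:",
                             paste(required, collapse = ", ")))
  if (nrow(df) == 0L)
    sa_error("format", "annotation table has a header but no rows")
  dup <- duplicated(df[, c("probeset_id", "category_id")])
  if (any(dup)) {
    warning(sprintf("%d duplicate (probeset, category) membership row(s) removed",
                    sum(dup)))
    df <- df[!dup, , drop = FALSE]
  }
  labels <- df$category_label[!duplicated(df$category_id)]
  names(labels) <- df$category_id[!duplicated(df$category_id)]
  structure(list(membership = df[, c("probeset_id", "category_id")],
                 labels = labels),
            class = "AnnotationTable")
}

#' Write a result table deterministically
#'
#' Writes any tabular result as TSV with a header, rows ordered by adjusted
#' p-value (when such a column exists) and ties broken by identifier, so two
#' runs of the pipeline yield byte-identical outputs. Numeric columns are
#' formatted to 12 significant digits.
#'
#' @param result a data.frame whose first column (or \code{id_col}) is a
#'   stable identifier.
#' @param path output path.
#' @param p_col name of the column to sort by; defaults to the first of
#'   \code{adj_p}, \code{q_value}, \code{p} present in the table.
#' @param id_col identifier column; defaults to the first column.
#' @return Invisibly, \code{path}.
#' @export
write_result_table <- function(result, path, p_col = NULL, id_col = NULL) {
  result <- as.data.frame(result, stringsAsFactors = FALSE)
  if (is.null(id_col)) id_col <- names(result)[1L]
  if (is.null(p_col))
    p_col <- intersect(c("adj_p", "q_value", "p"), names(result))[1L]
  if (nrow(result) > 0L) {
    ord <- if (!is.null(p_col) && !is.na(p_col))
      order(result[[p_col]], result[[id_col]]) else order(result[[id_col]])
    result <- result[ord, , drop = FALSE]
  }
  out <- result
  for (j in seq_along(out))
    if (is.numeric(out[[j]]))
      out[[j]] <- formatC(out[[j]], digits = 12, format = "g")
  con <- tryCatch(file(path, "w"), error = function(e)
    sa_error("io", paste("cannot open for writing:", path)))
  on.exit(close(con))
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read back a result table written by [write_result_table()]
#' @param path path to the TSV.
#' @return data.frame.
#' @export
read_result_table <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
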