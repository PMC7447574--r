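#' Construct an omics matrix
#'
#' A single omics block: a numeric samples-by-features matrix with unique
#' sample IDs as row names and unique feature names as column names.
#' Missing values (\code{NA}) are allowed prior to imputation.
#'
#' @param values Numeric matrix, samples in rows, features in columns, with
#'   dimnames set.
#' @param omics_name Short block label (e.g. \code{"mrna"}), used to prefix
#'   feature names when blocks are concatenated.
#' @return An object of class \code{omics_matrix}.
#' @export
omics_matrix <- function(values, omics_name) {
  if (!is.matrix(values) || !is.numeric(values))
    stop_("'values' must be a numeric matrix")
  sid <- rownames(values)
  fid <- colnames(values)
  if (is.null(sid) || is.null(fid))
    stop_("'values' must carry sample IDs as rownames and feature names as colnames")
  if (anyDuplicated(sid))
    stop_("duplicate sample ID(s): %s", paste(unique(sid[duplicated(sid)]), collapse = ", "))
  if (anyDuplicated(fid))
    stop_("duplicate feature name(s): %s", paste(unique(fid[duplicated(fid)]), collapse = ", "))
  structure(list(omics_name = as.character(omics_name), values = values),
            class = "omics_matrix")
}

#' @export
print.omics_matrix <- function(x, ...) {
  cat(sprintf("omics_matrix '%s': %d samples x %d features (%.1f%% missing)\n",
              x$omics_name, nrow(x$values), ncol(x$values),
              100 * mean(is.na(x$values))))
  invisible(x)
}

#' @rdname omics_matrix
#' @param m An \code{omics_matrix}.
#' @export
sample_ids <- function(m) rownames(m$values)

#' @rdname omics_matrix
#' @export
feature_names <- function(m) colnames(m$values)

detect_sep <- function(line) {
  if (grepl("\t", line)) "\t" else ","
}

#' Read / write a delimited omics matrix
#'
#' Files are plain-text CSV or TSV with a header row of feature names and a
#' first column of sample IDs (default orientation \code{"samples"} =
#' samples as rows). TCGA-style files with features as rows are read with
#' \code{orientation = "features"}, which transposes on load. The delimiter
#' is auto-detected from the header (tab or comma) unless given.
#'
#' @param path File path.
#' @param omics_name Block label stored on the result.
#' @param orientation \code{"samples"} (rows are samples; default) or
#'   \code{"features"} (rows are features, transposed on load).
#' @param sep Field delimiter; \code{NULL} to auto-detect.
#' @return \code{read_omics_matrix} returns an \code{omics_matrix};
#'   \code{write_omics_matrix} returns \code{path} invisibly.
#' @export
read_omics_matrix <- function(path, omics_name = "omics",
                              orientation = c("samples", "features"),
                              sep = NULL) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop_("file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L) stop_("%s: need a header and at least one data row", path)
  sep <- sep %||% detect_sep(lines[1L])
  fields <- strsplit(lines, sep, fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != nf[1L])) {
    bad <- which(nf != nf[1L])[1L]
    stop_("%s: ragged row at line %d (%d fields, expected %d)",
          path, bad, nf[bad], nf[1L])
  }
  header <- fields[[1L]]
  ## header may or may not name the ID column; both "id,f1,f2" and ",f1,f2"
  feat <- header[-1L]
  ids <- vapply(fields[-1L], `[[`, "", 1L)
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])[1L]
    line <- which(ids == dup)[2L] + 1L
    stop_("%s: duplicate row ID '%s' at line %d", path, dup, line)
  }
  vals <- t(vapply(fields[-1L],
                   function(f) suppressWarnings(as.numeric(f[-1L])),
                   numeric(length(feat))))
  if (length(feat) == 1L) vals <- matrix(vals, ncol = 1L)
  dimnames(vals) <- list(ids, feat)
  if (orientation == "features") vals <- t(vals)
  omics_matrix(vals, omics_name)
}

#' @rdname read_omics_matrix
#' @param m An \code{omics_matrix} to write.
#' @export
write_omics_matrix <- function(m, path, sep = ",") {
  df <- data.frame(sample_id = sample_ids(m), m$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a clinical survival table
#'
#' Columns: \code{sample_id}, \code{time} (follow-up, non-negative) and
#' \code{event} (1 = death/event observed, 0 = right-censored).
#'
#' @param path File path (CSV or TSV, auto-detected).
#' @return A data frame with columns sample_id, time, event.
#' @export
read_clinical <- function(path) {
  if (!file.exists(path)) stop_("clinical file not found: %s", path)
  sep <- detect_sep(readLines(path, n = 1L))
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("sample_id", "time", "event")
  if (!all(need %in% names(df)))
    stop_("%s: clinical table must have columns %s", path, paste(need, collapse = ", "))
  validate_clinical(df[need])
  df[need]
}

validate_clinical <- function(df) {
  if (anyDuplicated(df$sample_id))
    stop_("duplicate sample ID(s) in clinical table")
  if (any(!is.finite(df$time)) || any(df$time < 0))
    stop_("clinical times must be finite and non-negative")
  if (!all(df$event %in% c(0, 1)))
    stop_("event indicator must be 0 or 1")
  invisible(df)
}

#' @rdname read_clinical
#' @param clinical Data frame with columns sample_id, time, event.
#' @param sep Field delimiter.
#' @export
write_clinical <- function(clinical, path, sep = ",") {
  utils::write.table(clinical, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Summarize copy-number variations to one value per gene
#'
#' Collapses a long segment table (one row per CNV record) to a gene-level
#' matrix by averaging the copy numbers of all variations recorded on a gene
#' for each sample. A (sample, gene) pair with no record becomes \code{NA}.
#'
#' @param segments Data frame with columns \code{sample_id}, \code{gene_id},
#'   \code{copy_number}; (sample, gene) pairs may repeat.
#' @param omics_name Block label for the result.
#' @return An \code{omics_matrix} with one column per gene.
#' @export
average_cnv_per_gene <- function(segments, omics_name = "cnv") {
  need <- c("sample_id", "gene_id", "copy_number")
  if (!is.data.frame(segments) || !all(need %in% names(segments)))
    stop_("'segments' must have columns %s", paste(need, collapse = ", "))
  if (nrow(segments) == 0L) stop_("empty CNV segment table")
  vals <- tapply(segments$copy_number,
                 list(sample = as.character(segments$sample_id),
                      gene = as.character(segments$gene_id)),
                 mean)
  vals <- vals[unique(as.character(segments$sample_id)),
               unique(as.character(segments$gene_id)), drop = FALSE]
  omics_matrix(unclass(vals), omics_name)
}

#' @rdname average_cnv_per_gene
#' @param path CSV/TSV file with the three segment columns.
#' @export
read_cnv_segments <- function(path) {
  if (!file.exists(path)) stop_("CNV segment file not found: %s", path)
  sep <- detect_sep(readLines(path, n = 1L))
  utils::read.table(path, header = TRUE, sep = sep,
                    stringsAsFactors = FALSE, check.names = FALSE)
}
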