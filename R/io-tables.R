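# Delimited-table readers for the pipeline's tabular inputs. Comma and tab
# are both accepted; the delimiter is sniffed from the header line.

sniff_delim <- function(path) {
  header <- readLines(path, n = 1L, warn = FALSE)
  if (length(header) == 0L) stop_stratmir(sprintf("empty file: %s", path))
  n_tab <- lengths(regmatches(header, gregexpr("\t", header, fixed = TRUE)))
  n_com <- lengths(regmatches(header, gregexpr(",", header, fixed = TRUE)))
  if (n_tab >= n_com) "\t" else ","
}

read_delim_quiet <- function(path, delim) {
  readr::read_delim(path, delim = delim, show_col_types = FALSE,
                    progress = FALSE, trim_ws = TRUE)
}

#' Read a read-count matrix
#'
#' Expects a header row of sample identifiers and a first column of feature
#' (miRNA) identifiers; remaining cells are non-negative integer read
#' counts. Tab- and comma-separated files are both accepted.
#'
#' @param path Path to the count table.
#' @return A named list of class `count_matrix` with elements `counts`
#'   (integer matrix, features x samples), `feature_ids`, `sample_ids`.
#' @export
read_counts <- function(path) {
  df <- read_delim_quiet(path, sniff_delim(path))
  if (ncol(df) < 2L) stop_stratmir("count table needs a feature column and >= 1 sample column")
  feature_ids <- as.character(df[[1L]])
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  if (anyNA(m)) {
    stop_stratmir(sprintf("non-numeric or missing count at feature '%s'",
                          feature_ids[which(rowSums(is.na(m)) > 0)[1L]]))
  }
  bad <- m < 0 | m != floor(m)
  if (any(bad)) {
    row <- which(rowSums(bad) > 0)[1L]
    stop_stratmir(sprintf("negative or non-integer count at feature '%s'",
                          feature_ids[row]))
  }
  storage.mode(m) <- "integer"
  rownames(m) <- feature_ids
  new_count_matrix(m)
}

#' Construct a count matrix object
#'
#' @param counts Integer matrix (features x samples) with row and column
#'   names; all entries must be non-negative integers and identifiers
#'   unique.
#' @return A list of class `count_matrix`.
#' @export
new_count_matrix <- function(counts) {
  if (!is.matrix(counts)) stop_stratmir("`counts` must be a matrix")
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop_stratmir("count matrix needs feature row names and sample column names")
  }
  if (anyDuplicated(rownames(counts))) stop_stratmir("duplicate feature ids")
  if (anyDuplicated(colnames(counts))) stop_stratmir("duplicate sample ids")
  if (any(counts < 0)) stop_stratmir("counts must be >= 0")
  if (any(counts != floor(counts))) stop_stratmir("counts must be integers")
  storage.mode(counts) <- "integer"
  structure(
    list(counts = counts,
         feature_ids = rownames(counts),
         sample_ids = colnames(counts)),
    class = "count_matrix"
  )
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("<count_matrix> %d features x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  invisible(x)
}

#' Write a count matrix to a tab-separated file
#'
#' Rows are written in lexicographic feature order for diffability.
#'
#' @param x A `count_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_counts <- function(x, path) {
  stopifnot(inherits(x, "count_matrix"))
  m <- x$counts[order(x$feature_ids), , drop = FALSE]
  df <- tibble(feature = rownames(m))
  df <- dplyr::bind_cols(df, as_tibble(m))
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}

#' Read a sample metadata table
#'
#' Columns: `sample_id`, `gender` (M/F), `status` (RRMS/HC), and optionally
#' `stage` (relapse/remission, NA for controls). The invariant that stage is
#' missing if and only if a sample is a healthy control is enforced.
#'
#' @param path Path to the sample table (TSV or CSV).
#' @return A tibble with typed factor columns.
#' @export
read_samples <- function(path) {
  df <- read_delim_quiet(path, sniff_delim(path))
  validate_samples(df)
}

#' Validate a sample table
#'
#' @param df Data frame with columns `sample_id`, `gender`, `status` and
#'   optionally `stage`.
#' @return The validated tibble (stage column added as NA if absent).
#' @export
validate_samples <- function(df) {
  need <- c("sample_id", "gender", "status")
  if (!all(need %in% names(df))) {
    stop_stratmir(sprintf("sample table must have columns: %s",
                          paste(need, collapse = ", ")))
  }
  df <- as_tibble(df)
  df$sample_id <- as.character(df$sample_id)
  if (anyDuplicated(df$sample_id)) {
    stop_stratmir(sprintf("duplicate sample_id '%s'",
                          df$sample_id[duplicated(df$sample_id)][1L]))
  }
  if (!all(df$gender %in% c("M", "F"))) {
    bad <- which(!df$gender %in% c("M", "F"))[1L]
    stop_stratmir(sprintf("unknown gender '%s' in row %d (expected M or F)",
                          df$gender[bad], bad))
  }
  if (!all(df$status %in% c("RRMS", "HC"))) {
    bad <- which(!df$status %in% c("RRMS", "HC"))[1L]
    stop_stratmir(sprintf("unknown status '%s' in row %d (expected RRMS or HC)",
                          df$status[bad], bad))
  }
  if (!"stage" %in% names(df)) df$stage <- NA_character_
  df$stage[df$stage %in% c("", "NA")] <- NA_character_
  ok_stage <- is.na(df$stage) | df$stage %in% c("relapse", "remission")
  if (!all(ok_stage)) {
    bad <- which(!ok_stage)[1L]
    stop_stratmir(sprintf("unknown stage '%s' in row %d", df$stage[bad], bad))
  }
  hc_staged <- df$status == "HC" & !is.na(df$stage)
  if (any(hc_staged)) {
    stop_stratmir(sprintf(
      "sample '%s' is a healthy control but carries a disease stage",
      df$sample_id[which(hc_staged)[1L]]))
  }
  ms_unstaged <- df$status == "RRMS" & is.na(df$stage)
  if (any(ms_unstaged)) {
    stop_stratmir(sprintf("RRMS sample '%s' is missing its disease stage",
                          df$sample_id[which(ms_unstaged)[1L]]))
  }
  df[c("sample_id", "gender", "status", "stage")]
}

#' Read a qPCR Ct table
#'
#' Long-format table with columns `sample_id`, `target_id`, `ct`. The
#' endogenous reference (e.g. the small RNA RNU6B) must appear as a target
#' for every sample; each (sample, target) pair may appear at most once.
#'
#' @param path Path to the Ct table (TSV or CSV).
#' @param reference_id Identifier of the endogenous control target.
#' @return A tibble of class `ct_table` with attribute `reference_id`.
#' @export
read_ct <- function(path, reference_id = "RNU6B") {
  df <- read_delim_quiet(path, sniff_delim(path))
  validate_ct(df, reference_id)
}

#' Validate a Ct table
#'
#' @inheritParams read_ct
#' @param df Data frame with columns `sample_id`, `target_id`, `ct`.
#' @return Validated tibble with attribute `reference_id`.
#' @export
validate_ct <- function(df, reference_id = "RNU6B") {
  need <- c("sample_id", "target_id", "ct")
  if (!all(need %in% names(df))) {
    stop_stratmir(sprintf("Ct table must have columns: %s",
                          paste(need, collapse = ", ")))
  }
  df <- as_tibble(df)[need]
  df$sample_id <- as.character(df$sample_id)
  df$target_id <- as.character(df$target_id)
  df$ct <- as.numeric(df$ct)
  if (any(!is.finite(df$ct))) {
    stop_stratmir(sprintf("non-finite Ct in row %d", which(!is.finite(df$ct))[1L]))
  }
  key <- paste(df$sample_id, df$target_id, sep = "\r")
  if (anyDuplicated(key)) {
    d <- which(duplicated(key))[1L]
    stop_stratmir(sprintf("duplicate Ct entry for sample '%s', target '%s'",
                          df$sample_id[d], df$target_id[d]))
  }
  samples <- unique(df$sample_id)
  has_ref <- samples %in% df$sample_id[df$target_id == reference_id]
  if (!all(has_ref)) {
    stop_stratmir(sprintf(
      "reference target '%s' is not measured for sample '%s'",
      reference_id, samples[which(!has_ref)[1L]]))
  }
  attr(df, "reference_id") <- reference_id
  class(df) <- c("ct_table", class(df))
  df
}
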