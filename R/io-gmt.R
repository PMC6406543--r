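#' Read a GMT gene-set collection
#'
#' Parses the tab-separated GMT format used by MSigDB and most pathway
#' resources: one set per line, with fields `name`, `description`, then one
#' or more member gene symbols. Member symbols are deduplicated within a
#' set; line order is preserved. Matching elsewhere in the package is
#' case-sensitive exact string matching — no alias resolution is attempted.
#'
#' @param path Path to a GMT file (UTF-8, tab-separated, no quoting).
#' @return A tibble with one row per gene set and columns `name`,
#'   `description`, and `genes` (a list-column of character vectors).
#' @export
#' @examples
#' tf <- tempfile(fileext = ".gmt")
#' writeLines("S1\tdemo\tTP53\tEGFR", tf)
#' read_gmt(tf)
read_gmt <- function(path) {
  if (!file.exists(path)) {
    stop_stratmir(sprintf("GMT file not found: %s", path))
  }
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    return(tibble(name = character(), description = character(),
                  genes = list()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  n_fields <- lengths(fields)
  if (any(n_fields < 3L)) {
    bad <- which(n_fields < 3L)[1L]
    stop_stratmir(sprintf(
      "GMT line %d has %d field(s); at least 3 (name, description, gene) required",
      bad, n_fields[bad]))
  }
  nm <- vapply(fields, `[[`, character(1), 1L)
  if (anyDuplicated(nm)) {
    dup <- nm[duplicated(nm)][1L]
    line <- which(nm == dup)[2L]
    stop_stratmir(sprintf("duplicate gene-set name '%s' at GMT line %d", dup, line))
  }
  genes <- lapply(fields, function(f) unique(f[-c(1L, 2L)]))
  empty <- vapply(genes, function(g) all(!nzchar(g)), logical(1))
  if (any(empty)) {
    stop_stratmir(sprintf("GMT line %d has no non-empty gene symbols",
                          which(empty)[1L]))
  }
  tibble(
    name = nm,
    description = vapply(fields, `[[`, character(1), 2L),
    genes = genes
  )
}

#' Write a gene-set collection to GMT
#'
#' Inverse of [read_gmt()]: `read_gmt(write_gmt(x, path))` reproduces `x`
#' exactly (names, descriptions, member order after deduplication).
#'
#' @param collection A tibble as returned by [read_gmt()] (columns `name`,
#'   `description`, `genes`).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(collection, path) {
  validate_geneset_collection(collection)
  lines <- purrr::pmap_chr(collection, function(name, description, genes, ...) {
    paste(c(name, description, genes), collapse = "\t")
  })
  ok <- tryCatch({
    writeLines(lines, path, useBytes = TRUE)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop_stratmir(sprintf("cannot write GMT to '%s'", path))
  invisible(path)
}

validate_geneset_collection <- function(x) {
  if (!is.data.frame(x) || !all(c("name", "genes") %in% names(x))) {
    stop_stratmir("a gene-set collection needs columns `name` and `genes`")
  }
  if (anyDuplicated(x$name)) {
    stop_stratmir("gene-set names must be unique")
  }
  if (any(lengths(x$genes) == 0L)) {
    stop_stratmir("gene sets must be non-empty")
  }
  bad <- vapply(x$genes, function(g) !is.character(g) || any(!nzchar(g)),
                logical(1))
  if (any(bad)) {
    stop_stratmir(sprintf("gene set '%s' contains empty or non-character symbols",
                          x$name[which(bad)[1L]]))
  }
  invisible(x)
}
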