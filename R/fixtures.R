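#' Packaged differential-expression screen table
#'
#' Loads the packaged transcription of the published male-stratum screen
#' results: part A holds the 32 miRNAs differentially expressed in male
#' RRMS patients versus healthy controls (6 downregulated, 26 upregulated,
#' all 26 upregulated genes residing in the 14q32 imprinted locus); part B
#' holds the single relapse-versus-remission hit (hsa-miR-1, whose two
#' encoding genes and bands are stored verbatim as slash-joined strings).
#'
#' @param part Which part(s) to return: `"A"`, `"B"` or `"both"`.
#' @return A tibble with columns `part`, `direction`, `number`, `mirna`,
#'   `gene`, `localization`, `log2fc`, `p`, `p_adj`.
#' @export
#' @examples
#' tab <- load_de_screen_fixture()
#' dplyr::count(tab, part, direction)
load_de_screen_fixture <- function(part = c("both", "A", "B")) {
  part <- match.arg(part)
  path <- system.file("extdata", "de_screen_table.csv", package = "stratmir",
                      mustWork = TRUE)
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (part != "both") df <- df[df$part == part, ]
  as_tibble(df)
}

#' Packaged miRNA locus annotation
#'
#' Band-level chromosomal annotation for the screen's differentially
#' expressed miRNAs, plus the miRNA-gene census of the two clusters that
#' make up the DLK1-DIO3 imprinted locus on 14q32 (10 miRNA genes in
#' 14q32.2 and 44 in 14q32.31). The band table enumerates the screen hits
#' verbatim; the cluster census is packaged metadata, since the full
#' 54-gene membership of the locus is not enumerated by name.
#'
#' @return A list of class `locus_table`: `bands` (tibble: `mirna`, `gene`,
#'   `band`) and `cluster_counts` (tibble: `band`, `n_mirna_genes`).
#' @export
load_locus_fixture <- function() {
  bands <- readr::read_tsv(
    system.file("extdata", "locus_annotation.tsv", package = "stratmir",
                mustWork = TRUE),
    show_col_types = FALSE, progress = FALSE)
  counts <- readr::read_csv(
    system.file("extdata", "locus_cluster_counts.csv", package = "stratmir",
                mustWork = TRUE),
    show_col_types = FALSE, progress = FALSE)
  new_locus_table(bands, counts)
}

#' Construct a locus annotation table
#'
#' @param bands Data frame with columns `mirna` and `band` (and optionally
#'   `gene`). Bands must match the cytogenetic pattern
#'   `^\\d{1,2}[pq]\\d+(\\.\\d+)?$`, except for verbatim multi-gene entries
#'   joined with `/`.
#' @param cluster_counts Optional data frame with columns `band`,
#'   `n_mirna_genes`.
#' @return A list of class `locus_table`.
#' @export
new_locus_table <- function(bands, cluster_counts = NULL) {
  if (!all(c("mirna", "band") %in% names(bands))) {
    stop_stratmir("locus table needs columns `mirna` and `band`")
  }
  bands <- as_tibble(bands)
  single <- !grepl("/", bands$band, fixed = TRUE)
  ok <- grepl("^\\d{1,2}[pq]\\d+(\\.\\d+)?$", bands$band)
  if (any(single & !ok)) {
    stop_stratmir(sprintf("malformed band '%s' for miRNA '%s'",
                          bands$band[which(single & !ok)[1L]],
                          bands$mirna[which(single & !ok)[1L]]))
  }
  if (anyDuplicated(bands$mirna)) {
    stop_stratmir(sprintf("duplicate miRNA '%s' in locus table",
                          bands$mirna[duplicated(bands$mirna)][1L]))
  }
  if (!is.null(cluster_counts)) {
    if (!all(c("band", "n_mirna_genes") %in% names(cluster_counts))) {
      stop_stratmir("cluster_counts needs columns `band` and `n_mirna_genes`")
    }
    cluster_counts <- as_tibble(cluster_counts)
  }
  structure(list(bands = bands, cluster_counts = cluster_counts),
            class = "locus_table")
}

#' @export
print.locus_table <- function(x, ...) {
  cat(sprintf("<locus_table> %d annotated miRNAs", nrow(x$bands)))
  if (!is.null(x$cluster_counts)) {
    cat(sprintf("; cluster census over %d band(s)", nrow(x$cluster_counts)))
  }
  cat("\n")
  invisible(x)
}
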