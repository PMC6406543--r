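#' Assign chromosomal bands to miRNA identifiers
#'
#' Exact-name lookup of each queried miRNA in a locus table. Identifiers
#' without an annotation are returned with band `"UNANNOTATED"` rather than
#' dropped, so the mapping is total over the query.
#'
#' @param mirnas Character vector of miRNA identifiers.
#' @param locus A `locus_table` (see [new_locus_table()],
#'   [load_locus_fixture()]).
#' @return A tibble with columns `mirna`, `band`, `annotated` (logical).
#' @export
assign_band <- function(mirnas, locus) {
  stopifnot(inherits(locus, "locus_table"))
  idx <- match(mirnas, locus$bands$mirna)
  tibble(
    mirna = as.character(mirnas),
    band = as.character(ifelse(is.na(idx), "UNANNOTATED",
                               locus$bands$band[idx])),
    annotated = !is.na(idx)
  )
}

#' Band co-localization summary for DE hit sets
#'
#' Counts upregulated and downregulated hits per chromosomal band and
#' reports the fraction of the upregulated set falling in bands that start
#' with a given prefix. Band matching is by string prefix (so `"14q32"`
#' covers both sub-bands 14q32.2 and 14q32.31 of the DLK1-DIO3 imprinted
#' locus); no genome-coordinate arithmetic is performed.
#'
#' @param up,down Character vectors of miRNA identifiers (disjoint sets).
#' @param locus A `locus_table`.
#' @param band_prefix Band prefix of interest (default `"14q32"`).
#' @return A list of class `band_summary`: `by_band` (tibble: `band`,
#'   `n_up`, `n_down`, `up_members`, `down_members`),
#'   `fraction_up_in_band`, `n_up_in_band`, `band_prefix`.
#' @export
colocalization_summary <- function(up, down, locus, band_prefix = "14q32") {
  if (length(intersect(up, down)) > 0L) {
    stop_stratmir("up and down sets must be disjoint")
  }
  a_up <- assign_band(sort(unique(up)), locus)
  a_down <- assign_band(sort(unique(down)), locus)
  bands <- sort(unique(c(a_up$band, a_down$band)))
  by_band <- tibble(
    band = bands,
    n_up = vapply(bands, function(b) sum(a_up$band == b), integer(1)),
    n_down = vapply(bands, function(b) sum(a_down$band == b), integer(1)),
    up_members = lapply(bands, function(b) a_up$mirna[a_up$band == b]),
    down_members = lapply(bands, function(b) a_down$mirna[a_down$band == b])
  )
  in_band <- startsWith(a_up$band, band_prefix)
  structure(
    list(by_band = by_band,
         fraction_up_in_band = if (nrow(a_up) == 0L) NA_real_ else mean(in_band),
         n_up_in_band = sum(in_band),
         n_down_in_band = sum(startsWith(a_down$band, band_prefix)),
         band_prefix = band_prefix),
    class = "band_summary")
}

#' @export
print.band_summary <- function(x, ...) {
  cat(sprintf("<band_summary> %d band(s); %s of upregulated hits in %s*\n",
              nrow(x$by_band),
              ifelse(is.na(x$fraction_up_in_band), "NA",
                     sprintf("%.1f%%", 100 * x$fraction_up_in_band)),
              x$band_prefix))
  invisible(x)
}

#' Census of miRNA genes per locus cluster
#'
#' Sums the packaged (or user-supplied) per-band miRNA-gene counts of a
#' locus table. For the packaged DLK1-DIO3 annotation this returns 10
#' (14q32.2) + 44 (14q32.31) = 54 miRNA genes.
#'
#' @param locus A `locus_table` with a `cluster_counts` element.
#' @return A tibble with one row per band plus a `total` attribute; also
#'   accessible as `sum(census$n_mirna_genes)`.
#' @export
locus_census <- function(locus) {
  stopifnot(inherits(locus, "locus_table"))
  cc <- locus$cluster_counts
  if (is.null(cc) || nrow(cc) == 0L) {
    out <- tibble(band = character(0), n_mirna_genes = integer(0))
    attr(out, "total") <- 0L
    return(out)
  }
  out <- dplyr::arrange(cc, .data$band)
  attr(out, "total") <- sum(out$n_mirna_genes)
  out
}
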