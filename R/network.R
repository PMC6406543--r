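#' Exact one-sided over-representation test
#'
#' Hypergeometric upper-tail test of whether a target-gene set overlaps a
#' pathway more than expected given a gene universe: with `N = |universe|`,
#' `K = |pathway ∩ universe|`, `n = |targets ∩ universe|` and observed
#' overlap `k`, returns `p = P(X >= k)` for `X ~ Hypergeom(N, K, n)`. Both
#' sets are intersected with the universe before testing; the computation
#' is exact (no continuity approximation).
#'
#' @param targets Character vector of target gene symbols.
#' @param pathway Character vector of pathway member gene symbols.
#' @param universe Character vector: the gene background.
#' @return A one-row tibble with columns `k`, `n_target`, `K_pathway`, `N`,
#'   `p`, `flagged` (TRUE when the post-intersection target set is empty).
#' @export
ora_fisher <- function(targets, pathway, universe) {
  universe <- unique(universe)
  if (length(universe) == 0L) stop_stratmir("universe must be non-empty")
  tg <- intersect(unique(targets), universe)
  pw <- intersect(unique(pathway), universe)
  k <- length(intersect(tg, pw))
  n <- length(tg); K <- length(pw); N <- length(universe)
  flagged <- n == 0L
  p <- if (k == 0L) 1 else stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
  tibble(k = k, n_target = n, K_pathway = K, N = N,
         p = min(p, 1), flagged = flagged)
}

#' Full miRNA-by-pathway over-representation grid
#'
#' Runs [ora_fisher()] for every (miRNA, pathway) pair of a target map
#' against a pathway collection.
#'
#' @param target_map Tibble with columns `mirna` and `genes` (list-column),
#'   e.g. from [simulate_genesets()] or built from a GMT via [read_gmt()]
#'   (rename `name` to `mirna`).
#' @param pathways Gene-set collection tibble (columns `name`, `genes`).
#' @param universe `"pathways"` (default: union of all pathway genes, the
#'   standard ORA convention) or `"union"` (pathway genes plus target
#'   genes), or a character vector given explicitly.
#' @return A tibble with one row per (miRNA, pathway) pair: `mirna`,
#'   `pathway`, `k`, `n_target`, `K_pathway`, `N`, `p`, `flagged`.
#' @export
ora_grid <- function(target_map, pathways, universe = "pathways") {
  validate_geneset_collection(
    tibble(name = target_map$mirna, genes = target_map$genes))
  validate_geneset_collection(pathways)
  uni <- if (is.character(universe) && length(universe) == 1L &&
             universe %in% c("pathways", "union")) {
    u <- unique(unlist(pathways$genes, use.names = FALSE))
    if (universe == "union") {
      u <- unique(c(u, unlist(target_map$genes, use.names = FALSE)))
    }
    u
  } else {
    unique(as.character(universe))
  }
  N <- length(uni)
  if (N == 0L) stop_stratmir("universe must be non-empty")
  # integer-coded membership for speed on full grids
  path_idx <- lapply(pathways$genes, function(g) {
    i <- match(unique(g), uni); i[!is.na(i)]
  })
  tg_idx <- lapply(target_map$genes, function(g) {
    i <- match(unique(g), uni); i[!is.na(i)]
  })
  Kv <- lengths(path_idx)
  grid <- tidyr::expand_grid(mi = seq_along(tg_idx), pi = seq_along(path_idx))
  in_tg <- lapply(tg_idx, function(i) {
    v <- logical(N); v[i] <- TRUE; v
  })
  k <- purrr::map2_int(grid$mi, grid$pi,
                       function(mi, pi) sum(in_tg[[mi]][path_idx[[pi]]]))
  n <- lengths(tg_idx)[grid$mi]
  K <- Kv[grid$pi]
  p <- stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
  p[k == 0L] <- 1
  tibble(mirna = target_map$mirna[grid$mi],
         pathway = pathways$name[grid$pi],
         k = k, n_target = n, K_pathway = K, N = N,
         p = pmin(p, 1), flagged = n == 0L)
}

#' Per-pathway miRNA regulator counts
#'
#' Counts, for each pathway, the number of miRNAs whose target genes are
#' significantly over-represented in it (raw ORA `p < alpha` and overlap
#' `k >= 1`). Pathways regulated by no miRNA are dropped.
#'
#' @param ora Tibble from [ora_grid()] (columns `mirna`, `pathway`, `k`, `p`).
#' @param alpha Raw ORA significance threshold (default 0.05, unadjusted).
#' @return A tibble with columns `pathway`, `mirna_count`, sorted by
#'   decreasing count then pathway name.
#' @export
pathway_mirna_counts <- function(ora, alpha = 0.05) {
  out <- ora %>%
    dplyr::filter(.data$p < alpha, .data$k >= 1L) %>%
    dplyr::count(.data$pathway, name = "mirna_count") %>%
    dplyr::arrange(dplyr::desc(.data$mirna_count), .data$pathway)
  out
}

#' Tukey-fence selection of heavily co-targeted pathways
#'
#' Flags pathways whose miRNA regulator count exceeds the upper Tukey
#' fence `Q3 + 1.5 * (Q3 - Q1)` of the count distribution (strictly:
#' counts above, not at, the cutoff are selected). Quartiles use linear
#' interpolation between order statistics by default; the estimator is
#' exposed because integer counts make quartiles estimator-sensitive.
#'
#' @param nodes Tibble with columns `pathway`, `mirna_count` (>= 4 rows).
#' @param quantile_type Quantile algorithm passed to [stats::quantile()]
#'   (default 7, linear interpolation).
#' @return A list of class `fence_selection`: `q1`, `q2`, `q3`, `cutoff`,
#'   `selected` (tibble subset) and `nodes` (input with a `selected`
#'   column).
#' @export
select_outlier_pathways <- function(nodes, quantile_type = 7) {
  if (nrow(nodes) < 4L) {
    stop_stratmir("outlier selection needs >= 4 pathways")
  }
  qs <- stats::quantile(nodes$mirna_count, c(0.25, 0.5, 0.75),
                        type = quantile_type, names = FALSE)
  cutoff <- tukey_fence_cutoff(qs[1L], qs[3L])
  nodes$selected <- nodes$mirna_count > cutoff
  structure(list(q1 = qs[1L], q2 = qs[2L], q3 = qs[3L], cutoff = cutoff,
                 selected = nodes[nodes$selected, ], nodes = nodes),
            class = "fence_selection")
}

#' Upper Tukey fence from quartiles
#'
#' `Q3 + 1.5 * (Q3 - Q1)`; values strictly above the fence are outliers.
#' For the quartiles Q1 = 1, Q3 = 3 this gives a cutoff of 6, i.e. a
#' selection rule of "more than 6".
#'
#' @param q1,q3 First and third quartiles.
#' @return The cutoff value.
#' @export
tukey_fence_cutoff <- function(q1, q3) {
  if (q3 < q1) stop_stratmir("Q3 must be >= Q1")
  q3 + 1.5 * (q3 - q1)
}

#' @export
print.fence_selection <- function(x, ...) {
  cat(sprintf("<fence_selection> Q1=%g Q3=%g cutoff=%g; %d of %d pathways selected\n",
              x$q1, x$q3, x$cutoff, nrow(x$selected), nrow(x$nodes)))
  invisible(x)
}

#' Jaccard-weighted pathway overlap network
#'
#' Builds an undirected network over the given pathways: two pathways are
#' connected whenever their gene sets overlap at all, with edge weight the
#' Jaccard index `|A ∩ B| / |A ∪ B|`. No self-edges; edges are stored in
#' canonical order (`a < b` lexicographically).
#'
#' @param nodes Tibble with columns `pathway` and `mirna_count`.
#' @param pathways Gene-set collection tibble (columns `name`, `genes`)
#'   supplying the gene sets of the nodes.
#' @return An object of class `overlap_network`: `nodes` (tibble `pathway`,
#'   `mirna_count`) and `edges` (tibble `a`, `b`, `weight`).
#' @export
build_overlap_network <- function(nodes, pathways) {
  if (nrow(nodes) < 1L) stop_stratmir("need >= 1 node")
  idx <- match(nodes$pathway, pathways$name)
  if (anyNA(idx)) {
    stop_stratmir(sprintf("pathway '%s' has no gene set",
                          nodes$pathway[which(is.na(idx))[1L]]))
  }
  sets <- lapply(pathways$genes[idx], unique)
  nm <- nodes$pathway
  ord <- order(nm)
  nm <- nm[ord]; sets <- sets[ord]
  n <- length(nm)
  edges <- list()
  if (n >= 2L) {
    pairs <- utils::combn(n, 2L)
    inter <- purrr::map2_int(pairs[1L, ], pairs[2L, ],
                             function(i, j) length(intersect(sets[[i]], sets[[j]])))
    keep <- inter >= 1L
    if (any(keep)) {
      i <- pairs[1L, keep]; j <- pairs[2L, keep]
      uni <- purrr::map2_int(i, j,
                             function(a, b) length(union(sets[[a]], sets[[b]])))
      edges <- tibble(a = nm[i], b = nm[j],
                      weight = inter[keep] / uni)
    }
  }
  if (length(edges) == 0L) {
    edges <- tibble(a = character(0), b = character(0), weight = numeric(0))
  }
  structure(list(nodes = as_tibble(nodes[ord, ]), edges = edges),
            class = "overlap_network")
}

#' @export
print.overlap_network <- function(x, ...) {
  g <- glance.overlap_network(x)
  cat(sprintf("<overlap_network> %d nodes, %d edges (%.1f%% of complete)\n",
              g$n_nodes, g$n_edges, 100 * g$completeness))
  invisible(x)
}

#' Completeness statistics of an overlap network
#'
#' Compares the realized edge count to the complete-graph denominator
#' `n(n-1)/2`. For a single node the ratio is reported as 1 by convention
#' and flagged.
#'
#' @param network An `overlap_network`.
#' @return A one-row tibble: `n_nodes`, `n_edges`, `complete_edges`,
#'   `completeness`, `flagged`.
#' @export
network_completeness <- function(network) {
  stopifnot(inherits(network, "overlap_network"))
  n <- nrow(network$nodes)
  m <- nrow(network$edges)
  full <- n * (n - 1) / 2
  tibble(n_nodes = n, n_edges = m, complete_edges = full,
         completeness = if (full == 0) 1 else m / full,
         flagged = full == 0)
}

#' Subfamily over-representation among selected pathways
#'
#' Tests whether an annotated pathway subfamily (e.g. receptor tyrosine
#' kinase-activated pathways) is over-represented among the selected
#' pathways relative to a background (by default all pathways regulated by
#' at least one miRNA), as a one-sided hypergeometric tail
#' `P(X >= observed)`. This replaces the study's unavailable supplementary
#' calculation with the standard exact enrichment test; the substitution is
#' recorded in the result's `method` field.
#'
#' @param selected Character vector of selected pathway names.
#' @param subfamily Character vector of subfamily pathway names.
#' @param background Character vector of background pathway names
#'   (`selected` must be a subset).
#' @return A one-row tibble: `observed`, `n_selected`, `n_subfamily`,
#'   `n_background`, `p`, `method`.
#' @export
subfamily_overrepresentation <- function(selected, subfamily, background) {
  background <- unique(background)
  if (length(background) == 0L) stop_stratmir("background must be non-empty")
  selected <- unique(selected)
  if (!all(selected %in% background)) {
    stop_stratmir("selected pathways must be a subset of the background")
  }
  subfam <- intersect(unique(subfamily), background)
  k <- length(intersect(selected, subfam))
  N <- length(background); K <- length(subfam); n <- length(selected)
  p <- if (k == 0L) 1 else stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
  tibble(observed = k, n_selected = n, n_subfamily = K, n_background = N,
         p = min(p, 1),
         method = "one-sided hypergeometric (exact), selected vs count>=1 background")
}
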