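#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a stratified DE result
#'
#' @param x A `stratmir_de` object.
#' @param ... Unused.
#' @return The per-feature result tibble (`stratum`, `mirna`, `log2fc`,
#'   `t`, `p`, `p_adj`, `mean_log_expr`).
#' @export
tidy.stratmir_de <- function(x, ...) x$table

#' One-row-per-stratum summary of a DE result
#'
#' @inheritParams tidy.stratmir_de
#' @return A tibble with per-stratum sample sizes, fitted prior degrees of
#'   freedom and the shrinkage mode.
#' @export
glance.stratmir_de <- function(x, ...) {
  purrr::imap_dfr(x$meta$strata, function(m, s) {
    tibble(stratum = s, n_case = m$n_case, n_control = m$n_control,
           d0 = m$d0, s0_sq = m$s0_sq %||% NA_real_,
           shrinkage = x$meta$shrinkage)
  })
}

#' Tidy a qPCR interaction ANOVA result
#'
#' @param x A `stratmir_anova` object.
#' @param ... Unused.
#' @return The per-target tibble of interaction F statistics, raw and
#'   BH-adjusted p-values, and assumption-check p-values.
#' @export
tidy.stratmir_anova <- function(x, ...) x$table

#' One-row summary of a qPCR interaction ANOVA
#'
#' @inheritParams tidy.stratmir_anova
#' @return A one-row tibble: number of targets, number significant at
#'   adjusted p < 0.05, and the adjusted-p range.
#' @export
glance.stratmir_anova <- function(x, ...) {
  tibble(n_targets = nrow(x$table),
         n_significant = sum(x$table$p_adj < 0.05),
         min_p_adj = min(x$table$p_adj),
         max_p_adj = max(x$table$p_adj))
}

#' Tidy an overlap network (edge list)
#'
#' @param x An `overlap_network`.
#' @param ... Unused.
#' @return The edge tibble (`a`, `b`, `weight`).
#' @export
tidy.overlap_network <- function(x, ...) x$edges

#' One-row summary of an overlap network
#'
#' @inheritParams tidy.overlap_network
#' @return The completeness statistics of [network_completeness()].
#' @export
glance.overlap_network <- function(x, ...) network_completeness(x)
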