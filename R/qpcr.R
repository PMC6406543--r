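#' Delta-Ct quantification against an endogenous reference
#'
#' For every (sample, target) pair computes `delta_ct = Ct(target) -
#' Ct(reference)`, its negation `neg_delta_ct` (the log2-expression proxy
#' used by all downstream statistics) and the relative expression
#' `2^(-delta_ct)`. Samples missing a target measurement simply contribute
#' no row for that target; the count of measured rows per target is carried
#' in the result's attributes.
#'
#' @param ct A `ct_table` (see [read_ct()], [validate_ct()]) or a data
#'   frame with columns `sample_id`, `target_id`, `ct`.
#' @param reference_id Endogenous control target; defaults to the table's
#'   `reference_id` attribute, or `"RNU6B"`.
#' @return A tibble with columns `sample_id`, `target_id`, `ct`, `ct_ref`,
#'   `delta_ct`, `neg_delta_ct`, `rel_expr`, one row per measured
#'   non-reference (sample, target) pair.
#' @export
delta_ct <- function(ct, reference_id = NULL) {
  if (is.null(reference_id)) {
    reference_id <- attr(ct, "reference_id") %||% "RNU6B"
  }
  ct <- validate_ct(as_tibble(ct), reference_id)
  ref <- ct[ct$target_id == reference_id, c("sample_id", "ct")]
  names(ref)[2L] <- "ct_ref"
  out <- dplyr::inner_join(ct[ct$target_id != reference_id, ], ref,
                           by = "sample_id")
  out <- dplyr::mutate(as_tibble(out),
                       delta_ct = .data$ct - .data$ct_ref,
                       neg_delta_ct = -.data$delta_ct,
                       rel_expr = 2^(-.data$delta_ct))
  out <- dplyr::arrange(out, .data$target_id, .data$sample_id)
  attr(out, "reference_id") <- reference_id
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Delta-delta-Ct log2 fold change
#'
#' Per target, `log2FC = mean(-dCt, case) - mean(-dCt, control)`, i.e. the
#' negated delta-delta-Ct, with the corresponding fold change `2^log2FC`.
#' A positive value means higher expression in cases.
#'
#' @param dct Output of [delta_ct()].
#' @param case_samples,control_samples Character vectors of sample ids.
#' @return A tibble with columns `target_id`, `log2fc`, `fold_change`,
#'   `n_case`, `n_control`.
#' @export
log2fc_ddct <- function(dct, case_samples, control_samples) {
  if (length(case_samples) == 0L || length(control_samples) == 0L) {
    stop_stratmir("case and control sample sets must be non-empty")
  }
  dct %>%
    dplyr::filter(.data$sample_id %in% c(case_samples, control_samples)) %>%
    dplyr::group_by(.data$target_id) %>%
    dplyr::summarise(
      log2fc = mean(.data$neg_delta_ct[.data$sample_id %in% case_samples]) -
        mean(.data$neg_delta_ct[.data$sample_id %in% control_samples]),
      n_case = sum(.data$sample_id %in% case_samples),
      n_control = sum(.data$sample_id %in% control_samples),
      .groups = "drop") %>%
    dplyr::mutate(fold_change = 2^.data$log2fc) %>%
    dplyr::select("target_id", "log2fc", "fold_change", "n_case", "n_control")
}

#' Z standardization
#'
#' Centers to sample mean 0 and scales to sample standard deviation 1
#' (n - 1 denominator). Affine transformations of the input leave the
#' output unchanged, which is why F statistics computed downstream are
#' identical before and after this transformation.
#'
#' @param x Numeric vector with at least 2 values and nonzero variance.
#' @return Standardized numeric vector.
#' @export
ztransform <- function(x) {
  if (length(x) < 2L) stop_stratmir("ztransform needs >= 2 values")
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) stop_stratmir("ztransform needs nonzero variance")
  (x - mean(x)) / s
}

#' ANOVA assumption checks
#'
#' Shapiro-Wilk normality test on the residuals of the full factorial
#' status-by-gender model, and the Brown-Forsythe variant of Levene's test
#' (median-centered) for homogeneity of variance across the four
#' status-gender cells.
#'
#' @param values Numeric response (typically `neg_delta_ct` for one target).
#' @param status,gender Factors of the same length as `values`.
#' @return A list with `shapiro_p` and `levene_p`.
#' @export
check_assumptions <- function(values, status, gender) {
  status <- factor(status); gender <- factor(gender)
  cell <- interaction(status, gender, drop = TRUE)
  if (any(table(cell) < 2L)) {
    stop_stratmir("Levene's test needs >= 2 observations per cell")
  }
  fit <- stats::lm(values ~ status * gender)
  res <- stats::residuals(fit)
  if (length(res) < 3L) stop_stratmir("need >= 3 residuals for Shapiro-Wilk")
  lev <- car::leveneTest(values ~ cell, center = stats::median)
  list(shapiro_p = stats::shapiro.test(res)$p.value,
       levene_p = lev[["Pr(>F)"]][1L])
}

#' Two-way interaction F-test (single response)
#'
#' Tests the status-by-gender interaction by comparing the full factorial
#' model against the additive model; for a 2x2 design this is an F test on
#' 1 numerator degree of freedom regardless of cell balance.
#'
#' @param values Numeric response.
#' @param status,gender Factors (two levels each); all four cells must be
#'   non-empty.
#' @return A list with `F`, `df1`, `df2`, `p`.
#' @export
anova_interaction <- function(values, status, gender) {
  status <- factor(status); gender <- factor(gender)
  if (nlevels(status) < 2L || nlevels(gender) < 2L ||
      any(table(status, gender) == 0L)) {
    stop_stratmir("all status x gender cells must be non-empty")
  }
  full <- stats::lm(values ~ status * gender)
  add <- stats::lm(values ~ status + gender)
  rss1 <- sum(stats::residuals(full)^2)
  rss0 <- sum(stats::residuals(add)^2)
  df1 <- add$df.residual - full$df.residual
  df2 <- full$df.residual
  if (df2 <= 0) stop_stratmir("no residual degrees of freedom for the full model")
  f <- ((rss0 - rss1) / df1) / (rss1 / df2)
  list(F = f, df1 = df1, df2 = df2,
       p = stats::pf(f, df1, df2, lower.tail = FALSE))
}

#' Per-target interaction ANOVA for a qPCR panel
#'
#' For every target, Z-transforms the `neg_delta_ct` response, fits the
#' two-way status-by-gender factorial, tests the interaction by
#' full-versus-additive model comparison, runs the assumption checks, and
#' finally adjusts the interaction p-values across targets by
#' Benjamini-Hochberg. Samples missing from the metadata are dropped with
#' a warning.
#'
#' @param dct Output of [delta_ct()].
#' @param samples Sample table (see [validate_samples()]).
#' @param ztransform Standardize the response per target before testing
#'   (default TRUE; F is invariant to this affine transformation).
#' @return An object of class `stratmir_anova`: tibble `table` with columns
#'   `target_id`, `F_interaction`, `df1`, `df2`, `p_interaction`, `p_adj`,
#'   `shapiro_p`, `levene_p`, `n`, plus `meta`.
#' @export
qpcr_interaction <- function(dct, samples, ztransform = TRUE) {
  samples <- validate_samples(samples)
  merged <- dplyr::inner_join(dct, samples, by = "sample_id")
  dropped <- setdiff(unique(dct$sample_id), samples$sample_id)
  if (length(dropped) > 0L) {
    warn(sprintf("%d sample(s) missing from metadata were dropped", length(dropped)))
  }
  res <- merged %>%
    dplyr::group_by(.data$target_id) %>%
    dplyr::group_modify(function(d, key) {
      y <- if (ztransform) ztransform(d$neg_delta_ct) else d$neg_delta_ct
      a <- anova_interaction(y, d$status, d$gender)
      chk <- check_assumptions(y, d$status, d$gender)
      tibble(F_interaction = a$F, df1 = a$df1, df2 = a$df2,
             p_interaction = a$p, shapiro_p = chk$shapiro_p,
             levene_p = chk$levene_p, n = nrow(d))
    }) %>%
    dplyr::ungroup()
  res$p_adj <- bh_adjust(res$p_interaction)
  res <- res[c("target_id", "F_interaction", "df1", "df2", "p_interaction",
               "p_adj", "shapiro_p", "levene_p", "n")]
  structure(list(table = res,
                 meta = list(response = "neg_delta_ct",
                             ztransform = ztransform,
                             adjustment = "BH across targets")),
            class = "stratmir_anova")
}

#' @export
print.stratmir_anova <- function(x, ...) {
  cat(sprintf("<stratmir_anova> status x gender interaction, %d target(s)\n",
              nrow(x$table)))
  invisible(x)
}

#' Tukey HSD pairwise contrasts
#'
#' All pairwise mean differences among groups with adjusted p-values from
#' the studentized-range distribution (Tukey HSD), using the Tukey-Kramer
#' standard error for unequal group sizes. When the response is
#' `neg_delta_ct`, the case-versus-control difference within a gender is
#' exactly the delta-delta-Ct log2 fold change.
#'
#' @param values Numeric response.
#' @param groups Factor (or character) of group labels; every group needs
#'   at least 2 observations.
#' @return A tibble with columns `group1`, `group2`, `diff` (mean of
#'   `group1` minus mean of `group2`), `se`, `p_adj`, in canonical
#'   (sorted-label) pair order.
#' @export
tukey_hsd <- function(values, groups) {
  groups <- factor(groups)
  tab <- table(groups)
  if (any(tab < 2L)) {
    stop_stratmir(sprintf("group '%s' has fewer than 2 observations",
                          names(tab)[which(tab < 2L)[1L]]))
  }
  k <- nlevels(groups)
  if (k < 2L) stop_stratmir("need >= 2 groups")
  n <- length(values)
  means <- tapply(values, groups, mean)
  mse <- sum(tapply(values, groups, function(v) sum((v - mean(v))^2))) / (n - k)
  df <- n - k
  lev <- sort(levels(groups))
  pairs <- utils::combn(lev, 2L)
  diff <- means[pairs[1L, ]] - means[pairs[2L, ]]
  se <- sqrt(mse / 2 * (1 / tab[pairs[1L, ]] + 1 / tab[pairs[2L, ]]))
  q <- ifelse(se == 0, ifelse(diff == 0, 0, Inf), abs(diff) / se)
  p <- ifelse(is.infinite(q), 0,
              stats::ptukey(q, nmeans = k, df = df, lower.tail = FALSE))
  p[q == 0] <- 1
  tibble(group1 = pairs[1L, ], group2 = pairs[2L, ],
         diff = as.numeric(diff), se = as.numeric(se), p_adj = as.numeric(p))
}

#' Tukey HSD contrasts for a qPCR panel
#'
#' Runs [tukey_hsd()] per target over the four status-gender cells on the
#' raw `neg_delta_ct` scale, so the RRMS-versus-HC contrast within each
#' gender is directly the qPCR log2 fold change.
#'
#' @inheritParams qpcr_interaction
#' @return A tibble with columns `target_id`, `group1`, `group2`, `diff`
#'   (log2FC for case-vs-control pairs), `se`, `p_adj`. Cell labels are
#'   `"HC-F"`, `"HC-M"`, `"RRMS-F"`, `"RRMS-M"`.
#' @export
qpcr_tukey <- function(dct, samples) {
  samples <- validate_samples(samples)
  merged <- dplyr::inner_join(dct, samples, by = "sample_id")
  merged$cell <- paste(merged$status, merged$gender, sep = "-")
  merged %>%
    dplyr::group_by(.data$target_id) %>%
    dplyr::group_modify(function(d, key) tukey_hsd(d$neg_delta_ct, d$cell)) %>%
    dplyr::ungroup()
}

#' Interaction-plot cell summaries
#'
#' Cell means and standard errors of `neg_delta_ct` per target, the data
#' behind a status-by-gender interaction plot (crossing lines indicate an
#' interaction).
#'
#' @inheritParams qpcr_interaction
#' @return A tibble with columns `target_id`, `status`, `gender`, `n`,
#'   `mean`, `se`.
#' @export
qpcr_cell_means <- function(dct, samples) {
  samples <- validate_samples(samples)
  dplyr::inner_join(dct, samples, by = "sample_id") %>%
    dplyr::group_by(.data$target_id, .data$status, .data$gender) %>%
    dplyr::summarise(n = dplyr::n(),
                     mean = mean(.data$neg_delta_ct),
                     se = stats::sd(.data$neg_delta_ct) / sqrt(dplyr::n()),
                     .groups = "drop")
}
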