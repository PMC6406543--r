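#' Log counts-per-million normalization
#'
#' Converts raw read counts to log2 counts-per-million with a pseudocount:
#' `log2((count + pc) / (library_size + 2 pc) * 1e6)`. The pseudocount
#' stabilizes zeros; doubling all counts and library sizes leaves values
#' essentially unchanged (exactly, up to the pseudocount's vanishing
#' influence at high counts).
#'
#' @param x A `count_matrix` (see [new_count_matrix()]) or an integer
#'   matrix with feature row names and sample column names.
#' @param pseudocount Positive offset added to each count (default 0.5).
#' @return A numeric matrix of log2-CPM values, same dimnames as the input.
#' @export
normalize_log_cpm <- function(x, pseudocount = 0.5) {
  if (inherits(x, "count_matrix")) x <- x$counts
  if (!is.matrix(x)) stop_stratmir("`x` must be a count_matrix or matrix")
  assert_scalar_number(pseudocount, "pseudocount", lower = 0, strict_lower = TRUE)
  lib <- colSums(x)
  if (any(lib == 0)) {
    stop_stratmir(sprintf("sample '%s' has library size 0",
                          colnames(x)[which(lib == 0)[1L]]))
  }
  log2(sweep(x + pseudocount, 2L, lib + 2 * pseudocount, "/") * 1e6)
}

# Newton inversion of the trigamma function, used to fit the
# scaled-inverse-chi-square prior on per-feature variances by moments.
trigamma_inverse <- function(x) {
  if (!is.finite(x) || x <= 0) return(Inf)
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:60) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2L)
    y <- y + dif
    if (abs(dif / y) < 1e-10) break
  }
  y
}

# Fit prior df d0 and prior variance s0^2 from per-feature pooled variances
# s2 on d residual df, by matching moments of log s2 (Fisher's log-variance
# distribution). Returns d0 = Inf with the median variance when the moment
# system has no positive solution.
fit_variance_prior <- function(s2, d) {
  pos <- s2 > 0
  if (sum(pos) < 2L) {
    warn("too few positive variances to fit a prior; using median variance")
    return(list(d0 = Inf, s0_sq = stats::median(s2)))
  }
  z <- log(s2[pos])
  e <- z - digamma(d / 2) + log(d / 2)
  ev <- stats::var(z) - trigamma(d / 2)
  if (!is.finite(ev) || ev <= 0) {
    return(list(d0 = Inf, s0_sq = stats::median(s2)))
  }
  d0 <- 2 * trigamma_inverse(ev)
  if (!is.finite(d0)) return(list(d0 = Inf, s0_sq = stats::median(s2)))
  s0_sq <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
  list(d0 = d0, s0_sq = s0_sq)
}

# vectorized two-group moderated t over the rows of a matrix
moderated_t_rows <- function(m, idx_case, idx_ctrl, shrinkage) {
  n1 <- length(idx_case); n2 <- length(idx_ctrl)
  m1 <- rowMeans(m[, idx_case, drop = FALSE])
  m2 <- rowMeans(m[, idx_ctrl, drop = FALSE])
  lfc <- m1 - m2
  d <- n1 + n2 - 2L
  ss1 <- rowSums((m[, idx_case, drop = FALSE] - m1)^2)
  ss2 <- rowSums((m[, idx_ctrl, drop = FALSE] - m2)^2)
  s2 <- (ss1 + ss2) / d
  if (shrinkage == "eb") {
    prior <- fit_variance_prior(s2, d)
    if (is.infinite(prior$d0)) {
      s2_mod <- rep(prior$s0_sq, length(s2))
      df_total <- Inf
    } else {
      s2_mod <- (prior$d0 * prior$s0_sq + d * s2) / (prior$d0 + d)
      df_total <- prior$d0 + d
    }
  } else {
    prior <- list(d0 = 0, s0_sq = NA_real_)
    s2_mod <- s2
    df_total <- d
  }
  se <- sqrt(s2_mod * (1 / n1 + 1 / n2))
  t <- ifelse(se == 0, ifelse(lfc == 0, 0, sign(lfc) * Inf), lfc / se)
  p <- 2 * stats::pt(abs(t), df = df_total, lower.tail = FALSE)
  p[t == 0] <- 1
  list(log2fc = unname(lfc), t = unname(t), p = unname(p), s2 = unname(s2),
       s2_mod = unname(s2_mod), df = df_total, prior = prior)
}

#' Stratified moderated differential expression
#'
#' Per-feature two-group comparison within each stratum of a stratifying
#' factor (typically gender), using an ordinary pooled-variance t-test or a
#' moderated t whose per-feature variances are shrunk towards an
#' empirical-Bayes prior. The prior is a scaled inverse chi-square fitted
#' across features by moments on the log variances (trigamma inversion);
#' the moderated statistic is `log2fc / (s_tilde * sqrt(1/n1 + 1/n2))` on
#' `d0 + d` degrees of freedom. With `shrinkage = "none"` this reduces
#' exactly to the classical equal-variance two-sample t-test.
#'
#' @param log_expr Numeric matrix of normalized log2 expression (features x
#'   samples), e.g. from [normalize_log_cpm()].
#' @param samples Sample table (see [validate_samples()]) covering the
#'   columns of `log_expr`.
#' @param factor Name of the contrasted factor column (default "status").
#' @param case,control Factor levels compared as case minus control.
#' @param stratify_by Optional factor column defining strata; `NULL` runs a
#'   single unstratified comparison. Strata with fewer than 2 samples per
#'   group are skipped with a warning.
#' @param subset Optional predicate function of the sample table returning
#'   a logical vector, applied before stratification (e.g.
#'   `function(s) s$status == "RRMS"` to restrict a relapse-vs-remission
#'   contrast to cases).
#' @param shrinkage `"eb"` (empirical-Bayes moderated t, default) or
#'   `"none"` (ordinary pooled t).
#' @return An object of class `stratmir_de`: a list with `table` (tibble:
#'   `stratum`, `mirna`, `log2fc`, `t`, `p`, `p_adj`, `mean_log_expr`),
#'   sorted by p within stratum, BH-adjusted within stratum, and `meta`
#'   (per-stratum prior parameters and the analysis choices).
#' @export
moderated_de <- function(log_expr, samples, factor = "status",
                         case = "RRMS", control = "HC",
                         stratify_by = "gender", subset = NULL,
                         shrinkage = c("eb", "none")) {
  shrinkage <- match.arg(shrinkage)
  samples <- as_tibble(samples)
  if (!factor %in% names(samples)) {
    stop_stratmir(sprintf("factor column '%s' not in sample table", factor))
  }
  if (identical(case, control)) stop_stratmir("case and control levels must differ")
  if (!is.null(subset)) samples <- samples[subset(samples), , drop = FALSE]
  keep <- samples$sample_id %in% colnames(log_expr)
  samples <- samples[keep, , drop = FALSE]
  strata <- if (is.null(stratify_by)) {
    list(all = samples)
  } else {
    split(samples, samples[[stratify_by]])
  }
  out <- list(); meta <- list()
  for (s in names(strata)) {
    st <- strata[[s]]
    idx_case <- match(st$sample_id[st[[factor]] %in% case], colnames(log_expr))
    idx_ctrl <- match(st$sample_id[st[[factor]] %in% control], colnames(log_expr))
    if (length(idx_case) < 2L || length(idx_ctrl) < 2L) {
      warn(sprintf("stratum '%s' skipped: fewer than 2 samples per group", s))
      next
    }
    res <- moderated_t_rows(log_expr, idx_case, idx_ctrl, shrinkage)
    tab <- tibble(
      stratum = s,
      mirna = rownames(log_expr),
      log2fc = res$log2fc,
      t = res$t,
      p = res$p,
      p_adj = bh_adjust(res$p),
      mean_log_expr = rowMeans(log_expr[, c(idx_case, idx_ctrl), drop = FALSE])
    )
    out[[s]] <- tab[order(tab$p), ]
    meta[[s]] <- list(n_case = length(idx_case), n_control = length(idx_ctrl),
                      d0 = res$prior$d0, s0_sq = res$prior$s0_sq, df = res$df)
  }
  structure(
    list(table = dplyr::bind_rows(out),
         meta = list(strata = meta, factor = factor, case = case,
                     control = control, stratify_by = stratify_by,
                     shrinkage = shrinkage,
                     model = "unweighted linear model on log-CPM (no precision weights, no trend)")),
    class = "stratmir_de")
}

#' @export
print.stratmir_de <- function(x, ...) {
  cat(sprintf("<stratmir_de> %s vs %s, %d strata, %d tests (%s shrinkage)\n",
              x$meta$case, x$meta$control, length(x$meta$strata),
              nrow(x$table), x$meta$shrinkage))
  invisible(x)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment: for p-values sorted ascending,
#' `p_adj(i) = min over j >= i of m * p(j) / j`, capped at 1, returned in
#' the original order. Input p-values must lie in (0, 1].
#'
#' @param p Numeric vector of raw p-values.
#' @return Vector of adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1)) {
    stop_stratmir("p-values must lie in (0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}

#' Effect-size and significance filter for a DE table
#'
#' Splits a differential-expression table into upregulated and
#' downregulated hit sets using strict inequalities: up if
#' `p_adj < alpha` and `log2fc > lfc`; down if `p_adj < alpha` and
#' `log2fc < -lfc`. Boundary values are excluded.
#'
#' @param de Data frame with columns `mirna` (or a first id column),
#'   `log2fc` and `p_adj`. The `table` element of a [moderated_de()] result
#'   works directly.
#' @param alpha Adjusted-p threshold (default 0.05).
#' @param lfc Absolute log2 fold-change threshold (default 1).
#' @return A list with character vectors `up` and `down` and the filtered
#'   tibble `hits`.
#' @export
filter_de <- function(de, alpha = 0.05, lfc = 1) {
  if (inherits(de, "stratmir_de")) de <- de$table
  de <- as_tibble(de)
  id_col <- if ("mirna" %in% names(de)) "mirna" else names(de)[1L]
  if (nrow(de) == 0L) {
    return(list(up = character(0), down = character(0), hits = de))
  }
  up_i <- de$p_adj < alpha & de$log2fc > lfc
  down_i <- de$p_adj < alpha & de$log2fc < -lfc
  list(up = de[[id_col]][up_i],
       down = de[[id_col]][down_i],
       hits = de[up_i | down_i, ])
}

#' Smallest per-group sample size for a two-sample t-test
#'
#' Enumerates group sizes n = 2, 3, ... and returns the smallest n at which
#' an equal-variance two-sample t-test of standardized effect size `d`
#' reaches the target power, computed from the noncentral t distribution
#' with noncentrality `d * sqrt(n / 2)` on `2n - 2` degrees of freedom.
#'
#' @param d Standardized effect size (Cohen's d), > 0.
#' @param alpha Significance level (default 0.05).
#' @param power Target power (default 0.8).
#' @param sides 1 or 2 (default 2, two-sided).
#' @return Integer: the smallest per-group n achieving the target power.
#' @export
#' @examples
#' power_sample_size(2) # effect size 2, alpha 0.05, power 0.8
power_sample_size <- function(d, alpha = 0.05, power = 0.8, sides = 2) {
  assert_scalar_number(d, "d", lower = 0, strict_lower = TRUE)
  assert_scalar_number(alpha, "alpha", 0, 1, TRUE, TRUE)
  assert_scalar_number(power, "power", 0, 1, TRUE, TRUE)
  if (!sides %in% c(1, 2)) stop_stratmir("`sides` must be 1 or 2")
  for (n in 2:1000000) {
    df <- 2L * n - 2L
    ncp <- d * sqrt(n / 2)
    pw <- if (sides == 2) {
      q <- stats::qt(1 - alpha / 2, df)
      stats::pt(q, df, ncp, lower.tail = FALSE) + stats::pt(-q, df, ncp)
    } else {
      stats::pt(stats::qt(1 - alpha, df), df, ncp, lower.tail = FALSE)
    }
    if (pw >= power) return(n)
  }
  stop_stratmir("target power unreachable at n <= 1e6")
}
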