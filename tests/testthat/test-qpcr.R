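test_that("delta-Ct arithmetic and relative expression are exact", {
  d <- delta_ct(toy_ct_table())
  s1 <- d[d$sample_id == "s1", ]
  expect_equal(s1$delta_ct, 3)
  expect_equal(s1$neg_delta_ct, -3)
  expect_equal(s1$rel_expr, 0.125)
  s3 <- d[d$sample_id == "s3", ]
  expect_equal(s3$delta_ct, 0)
  expect_equal(s3$rel_expr, 1)
  # row order of the input does not matter
  shuffled <- toy_ct_table()[sample(8), ]
  expect_identical(delta_ct(shuffled), d)
})

test_that("delta-delta-Ct log2FC has the right sign convention", {
  # case mean dCt 5 vs control mean dCt 8: cases amplify earlier relative
  # to reference -> higher expression -> log2FC = +3
  ct <- tibble::tibble(
    sample_id = rep(c("c1", "c2", "h1", "h2"), each = 2),
    target_id = rep(c("miR-X", "RNU6B"), 4),
    ct = c(30, 25, 30, 25, 33, 25, 33, 25))
  d <- delta_ct(ct)
  fc <- log2fc_ddct(d, c("c1", "c2"), c("h1", "h2"))
  expect_equal(fc$log2fc, 3)
  expect_equal(fc$fold_change, 8)
  # equal groups give zero
  fc0 <- log2fc_ddct(d, c("c1", "h1"), c("c2", "h2"))
  expect_equal(fc0$log2fc, 0)
  expect_error(log2fc_ddct(d, character(0), "h1"), "non-empty")
})

test_that("ddCt estimates recover the planted effect", {
  # planted male log2FC -2.5, sd 0.7, n = 10/group. The estimator is a
  # difference of two cell means, so err ~ N(0, sd * sqrt(2/10)) and
  # P(|err| < 0.5) = 2 * pnorm(0.5 / (0.7 * sqrt(0.2))) - 1 (~0.89): the
  # closed-form oracle the observed rate must match.
  err <- vapply(1:200, function(s) {
    sim <- simulate_ct(n_targets = 1,
                       group_means = c(HC_M = -5, HC_F = -6,
                                       RRMS_M = -7.5, RRMS_F = -6),
                       sd = 0.7, n_case_m = 10, n_case_f = 10,
                       n_ctrl_m = 10, n_ctrl_f = 10, seed = s)
    d <- delta_ct(sim$ct)
    males <- sim$samples[sim$samples$gender == "M", ]
    est <- log2fc_ddct(d, males$sample_id[males$status == "RRMS"],
                       males$sample_id[males$status == "HC"])$log2fc
    abs(est - (-2.5))
  }, numeric(1))
  p_true <- 2 * pnorm(0.5 / (0.7 * sqrt(2 / 10))) - 1
  se_mc <- sqrt(p_true * (1 - p_true) / 200)
  expect_lt(abs(mean(err < 0.5) - p_true), 3.5 * se_mc)
})

test_that("z-transformation standardizes and is affine-invariant", {
  expect_equal(ztransform(c(1, 2, 3)), c(-1, 0, 1))
  set.seed(3)
  x <- rnorm(25, 4, 3)
  z <- ztransform(x)
  expect_lt(abs(mean(z)), 1e-12)
  expect_equal(sd(z), 1)
  expect_equal(ztransform(2.5 * x - 7), z)
  expect_error(ztransform(rep(1, 5)), "nonzero variance")
  expect_error(ztransform(1), ">= 2")
})

test_that("assumption checks are calibrated and have power", {
  # identical value multisets in all cells: Brown-Forsythe F = 0, p = 1
  vals <- rep(c(1, 2, 3), 4)
  status <- rep(c("HC", "RRMS"), each = 6)
  gender <- rep(c("M", "F", "M", "F"), each = 3)
  chk <- check_assumptions(vals, status, gender)
  expect_equal(chk$levene_p, 1)

  gauss <- vapply(1:100, function(s) {
    set.seed(s)
    check_assumptions(rnorm(40), rep(c("HC", "RRMS"), 20),
                      rep(c("M", "M", "F", "F"), 10))$shapiro_p
  }, numeric(1))
  expect_gte(mean(gauss >= 0.05), 0.9)

  cauchy <- vapply(1:100, function(s) {
    set.seed(s)
    check_assumptions(rcauchy(40), rep(c("HC", "RRMS"), 20),
                      rep(c("M", "M", "F", "F"), 10))$shapiro_p
  }, numeric(1))
  expect_gte(mean(cauchy < 0.05), 0.95)

  expect_error(check_assumptions(rnorm(5),
                                 c("HC", "HC", "HC", "HC", "RRMS"),
                                 c("M", "M", "F", "F", "M")),
               ">= 2 observations per cell")
})

test_that("interaction F matches the hand-decomposed balanced toy", {
  y <- c(1, 2, 3, 2, 3, 4, 5, 6, 7, 2, 3, 4)
  status <- rep(c("HC", "HC", "RRMS", "RRMS"), each = 3)
  gender <- rep(c("M", "F", "M", "F"), each = 3)
  a <- anova_interaction(y, status, gender)
  # SS_int = 12 on 1 df, MSE = 1 on 8 df
  expect_equal(a$F, 12, tolerance = 1e-8)
  expect_equal(a$df1, 1)
  expect_equal(a$df2, 8)
  expect_equal(a$p, pf(12, 1, 8, lower.tail = FALSE), tolerance = 1e-10)
  # cross-check against R's own factorial ANOVA
  ref <- anova(lm(y ~ factor(status) * factor(gender)))
  expect_equal(a$F, ref$`F value`[3], tolerance = 1e-10)
})

test_that("additive cell means give a vanishing interaction", {
  base <- c(-0.5, 0, 0.5)
  y <- c(base, base + 1, base + 2, base + 3)  # perfectly additive 2 x 2
  status <- rep(c("HC", "HC", "RRMS", "RRMS"), each = 3)
  gender <- rep(c("M", "F", "M", "F"), each = 3)
  a <- anova_interaction(y, status, gender)
  expect_lt(a$F, 1e-10)
  expect_error(anova_interaction(y[1:9], status[1:9], gender[1:9]),
               "non-empty")
})

test_that("interaction type-I error is nominal under the additive null", {
  rej <- vapply(1:500, function(s) {
    sim <- simulate_ct(n_targets = 1,
                       group_means = c(HC_M = -8, HC_F = -6,
                                       RRMS_M = -5, RRMS_F = -3),
                       sd = 0.7, seed = 1000 + s)
    d <- delta_ct(sim$ct)
    d <- dplyr::inner_join(d, sim$samples, by = "sample_id")
    anova_interaction(d$neg_delta_ct, d$status, d$gender)$p < 0.05
  }, logical(1))
  expect_gte(mean(rej), 0.02)
  expect_lte(mean(rej), 0.08)
})

test_that("interaction F is invariant under z-transformation", {
  sim <- simulate_ct(n_targets = 1, seed = 5)
  d <- delta_ct(sim$ct)
  d <- dplyr::inner_join(d, sim$samples, by = "sample_id")
  a_raw <- anova_interaction(d$neg_delta_ct, d$status, d$gender)
  a_z <- anova_interaction(ztransform(d$neg_delta_ct), d$status, d$gender)
  expect_equal(a_raw$F, a_z$F, tolerance = 1e-8)
})

test_that("qpcr_interaction adjusts across targets and keeps invariants", {
  sim <- simulate_ct(seed = 21)
  res <- qpcr_interaction(delta_ct(sim$ct), sim$samples)
  expect_equal(nrow(res$table), 7L)
  expect_true(all(res$table$p_adj >= res$table$p_interaction))
  expect_true(all(res$table$p_adj <= 1))
  gl <- glance(res)
  expect_equal(gl$n_targets, 7L)
})

test_that("Tukey HSD handles degenerate and strong-signal cases", {
  # identical samples in all groups: zero differences, p = 1
  vals <- rep(c(1, 2), 4)
  grp <- rep(c("a", "b", "c", "d"), each = 2)
  tk <- tukey_hsd(vals, grp)
  expect_equal(nrow(tk), 6L)
  expect_true(all(tk$diff == 0))
  expect_true(all(tk$p_adj == 1))
  # one group shifted by 10 sd: its three contrasts are overwhelming
  set.seed(2)
  vals2 <- c(rnorm(8), rnorm(8), rnorm(8), rnorm(8, mean = 10))
  grp2 <- rep(c("a", "b", "c", "d"), each = 8)
  tk2 <- tukey_hsd(vals2, grp2)
  hit_d <- tk2$p_adj[tk2$group1 == "d" | tk2$group2 == "d"]
  expect_true(all(hit_d < 1e-3))
  expect_error(tukey_hsd(c(1, 2, 3), c("a", "a", "b")), "fewer than 2")
})

test_that("Tukey HSD agrees with R's reference implementation", {
  set.seed(14)
  # unbalanced groups exercise the Kramer correction
  vals <- c(rnorm(6, 0), rnorm(9, 1), rnorm(5, 2), rnorm(10, 0.5))
  grp <- rep(c("g1", "g2", "g3", "g4"), times = c(6, 9, 5, 10))
  mine <- tukey_hsd(vals, grp)
  ref <- TukeyHSD(aov(vals ~ grp))$grp
  # reference reports pairs as "g2-g1" (second minus first)
  key <- paste(mine$group2, mine$group1, sep = "-")
  expect_equal(-mine$diff, unname(ref[key, "diff"]), tolerance = 1e-10)
  expect_equal(mine$p_adj, unname(ref[key, "p adj"]), tolerance = 1e-8)
})

test_that("Tukey contrasts are antisymmetric in group order", {
  set.seed(6)
  vals <- rnorm(20)
  grp <- rep(c("a", "b", "c", "d"), each = 5)
  tk <- tukey_hsd(vals, grp)
  means <- tapply(vals, grp, mean)
  for (i in seq_len(nrow(tk))) {
    expect_equal(tk$diff[i], unname(means[tk$group1[i]] - means[tk$group2[i]]),
                 tolerance = 1e-12)
  }
})

test_that("validation panel reproduces the gender-specific post-hoc pattern", {
  # male-only disease shift +2.8 (-dCt units), sd 0.7, 16/10 men, 20/10
  # women: the male case-control contrast should be significant and the
  # female one not, in at least 90% of replicates
  ok <- vapply(1:200, function(s) {
    sim <- simulate_ct(n_targets = 1, seed = 5000 + s)
    tk <- qpcr_tukey(delta_ct(sim$ct), sim$samples)
    pair <- function(x, y) {
      tk[(tk$group1 == x & tk$group2 == y) | (tk$group1 == y & tk$group2 == x), ]
    }
    male <- pair("RRMS-M", "HC-M")
    female <- pair("RRMS-F", "HC-F")
    male$p_adj < 0.05 && female$p_adj >= 0.05
  }, logical(1))
  expect_gte(mean(ok), 0.9)
})

test_that("noiseless input recovers the planted ddCt exactly", {
  sim <- simulate_ct(n_targets = 2, sd = 1e-9, seed = 3)
  d <- delta_ct(sim$ct)
  males <- sim$samples[sim$samples$gender == "M", ]
  est <- log2fc_ddct(d, males$sample_id[males$status == "RRMS"],
                     males$sample_id[males$status == "HC"])
  expect_equal(est$log2fc, rep(2.8, 2), tolerance = 1e-6)
})
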