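test_that("over-representation test matches hand-enumerated probabilities", {
  uni <- paste0("g", 1:10)
  # N = 10, K = 5, n = 4, k = 4: 5 favorable of C(10,4) = 210 draws
  r <- ora_fisher(uni[1:4], uni[1:5], uni)
  expect_equal(r$p, 5 / 210, tolerance = 1e-12)
  # zero overlap is never significant
  r0 <- ora_fisher(uni[1:3], uni[8:10], uni)
  expect_equal(r0$k, 0L)
  expect_equal(r0$p, 1)
  # pathway = universe forces k = n and p = 1
  rfull <- ora_fisher(uni[1:4], uni, uni)
  expect_equal(rfull$k, 4L)
  expect_equal(rfull$p, 1)
  # empty post-intersection target set is flagged
  rflag <- ora_fisher("not-in-universe", uni[1:5], uni)
  expect_true(rflag$flagged)
  expect_equal(rflag$p, 1)
})

test_that("over-representation tail equals exhaustive enumeration (N <= 12)", {
  set.seed(17)
  for (i in 1:300) {
    N <- sample(4:12, 1)
    uni <- paste0("g", seq_len(N))
    K <- sample(1:N, 1)
    n <- sample(1:N, 1)
    pathway <- uni[seq_len(K)]
    targets <- sample(uni, n)
    r <- ora_fisher(targets, pathway, uni)
    expect_equal(r$p, hyper_tail_enum(N, K, n, r$k), tolerance = 1e-10)
  }
})

test_that("over-representation agrees with one-sided Fisher's exact test", {
  set.seed(23)
  uni <- paste0("g", 1:60)
  for (i in 1:25) {
    targets <- sample(uni, sample(5:25, 1))
    pathway <- sample(uni, sample(5:25, 1))
    r <- ora_fisher(targets, pathway, uni)
    ft <- fisher.test(table(factor(uni %in% targets, c(TRUE, FALSE)),
                            factor(uni %in% pathway, c(TRUE, FALSE))),
                      alternative = "greater")
    expect_equal(r$p, ft$p.value, tolerance = 1e-10)
  }
})

test_that("pathway regulator counts follow the toy grid", {
  ora <- tibble::tibble(
    mirna = rep(c("m1", "m2", "m3"), each = 2),
    pathway = rep(c("P1", "P2"), 3),
    k = 1L,
    p = c(0.01, 0.2, 0.03, 0.04, 0.9, 0.01))
  counts <- pathway_mirna_counts(ora)
  expect_equal(counts$mirna_count[counts$pathway == "P1"], 2L)
  expect_equal(counts$mirna_count[counts$pathway == "P2"], 2L)
  # record order is irrelevant
  expect_equal(pathway_mirna_counts(ora[sample(6), ]), counts)
  # nothing significant -> empty result
  none <- ora; none$p <- 0.5
  expect_equal(nrow(pathway_mirna_counts(none)), 0L)
  # zero-overlap records never count even at tiny p
  zk <- ora; zk$k <- 0L
  expect_equal(nrow(pathway_mirna_counts(zk)), 0L)
})

test_that("Tukey-fence selection reproduces the published cutoff rule", {
  # published quartiles: Q1 = 1, Q3 = 3 miRNAs -> fence at 6, rule 'more than 6'
  expect_equal(tukey_fence_cutoff(1, 3), 6)
  counts <- tibble::tibble(pathway = paste0("P", 1:9),
                           mirna_count = c(1, 1, 1, 2, 2, 3, 3, 3, 10))
  sel <- select_outlier_pathways(counts)
  expect_equal(sel$q1, 1)
  expect_equal(sel$q3, 3)
  expect_equal(sel$cutoff, 6)
  expect_equal(sel$selected$pathway, "P9")
  # equal counts: IQR 0, cutoff at the common value, nothing selected
  flat <- tibble::tibble(pathway = paste0("P", 1:5), mirna_count = rep(4, 5))
  self <- select_outlier_pathways(flat)
  expect_equal(self$cutoff, 4)
  expect_equal(nrow(self$selected), 0L)
  expect_error(select_outlier_pathways(flat[1:3, ]), ">= 4")
})

test_that("raising a count never drops a pathway from the selection", {
  counts <- tibble::tibble(pathway = paste0("P", 1:9),
                           mirna_count = c(1, 1, 1, 2, 2, 3, 3, 3, 10))
  before <- select_outlier_pathways(counts)
  bumped <- counts
  bumped$mirna_count[bumped$pathway == "P9"] <- 12
  after <- select_outlier_pathways(bumped)
  # quartiles unchanged by perturbing an already-extreme value
  expect_equal(after$cutoff, before$cutoff)
  expect_true(all(before$selected$pathway %in% after$selected$pathway))
})

test_that("overlap network edges carry Jaccard weights", {
  pw <- tibble::tibble(
    name = c("X", "Y", "Z", "W"), description = "d",
    genes = list(c("a", "b", "c"), c("b", "c", "d"), c("a", "b", "c"),
                 c("q", "r")))
  nodes <- tibble::tibble(pathway = c("X", "Y", "Z", "W"),
                          mirna_count = c(1L, 2L, 3L, 4L))
  net <- build_overlap_network(nodes, pw)
  w <- function(a, b) net$edges$weight[net$edges$a == a & net$edges$b == b]
  expect_equal(w("X", "Y"), 0.5)       # {a,b,c} vs {b,c,d}: 2/4
  expect_equal(w("X", "Z"), 1.0)       # identical sets
  expect_equal(nrow(net$edges), 3L)    # W is disjoint from everything
  expect_false(any(net$edges$a == net$edges$b))
  expect_true(all(net$edges$a < net$edges$b))
  expect_true(all(net$edges$weight > 0 & net$edges$weight <= 1))
})

test_that("disjoint sets give an edgeless network and completeness flags n = 1", {
  pw <- tibble::tibble(name = c("A", "B"), description = "d",
                       genes = list("x", "y"))
  net <- build_overlap_network(tibble::tibble(pathway = c("A", "B"),
                                              mirna_count = c(1L, 1L)), pw)
  expect_equal(nrow(net$edges), 0L)
  one <- build_overlap_network(tibble::tibble(pathway = "A", mirna_count = 1L),
                               pw)
  comp1 <- network_completeness(one)
  expect_equal(comp1$n_edges, 0L)
  expect_true(comp1$flagged)
  expect_equal(comp1$completeness, 1)
  # triangle of identical sets is complete
  pw3 <- tibble::tibble(name = c("A", "B", "C"), description = "d",
                        genes = list(c("x", "y"), c("x", "y"), c("x", "y")))
  tri <- build_overlap_network(
    tibble::tibble(pathway = c("A", "B", "C"), mirna_count = 1L), pw3)
  expect_equal(network_completeness(tri)$completeness, 1.0)
  expect_true(all(tri$edges$weight == 1))
})

test_that("24 selected pathways have a complete-graph denominator of 276", {
  sg <- simulate_genesets(subfamily_size = 24, subfamily_overlap = 1, seed = 2)
  net <- build_overlap_network(
    tibble::tibble(pathway = sg$subfamily, mirna_count = 1L), sg$pathways)
  comp <- network_completeness(net)
  expect_equal(comp$complete_edges, 276)
  expect_equal(comp$completeness, 1.0)
})

test_that("subfamily over-representation matches enumeration and degenerate cases", {
  bg <- paste0("P", 1:30)
  subfam <- bg[1:10]
  sel <- bg[1:5]  # all five selected are subfamily members
  r <- subfamily_overrepresentation(sel, subfam, bg)
  expect_equal(r$p, choose(10, 5) / choose(30, 5), tolerance = 1e-12)
  expect_equal(r$p, 252 / 142506, tolerance = 1e-9)
  # selection containing no subfamily members is never significant
  r0 <- subfamily_overrepresentation(bg[11:15], subfam, bg)
  expect_equal(r0$p, 1)
  # selecting the whole background forces the observed count, p = 1
  rall <- subfamily_overrepresentation(bg, subfam, bg)
  expect_equal(rall$observed, 10L)
  expect_equal(rall$p, 1)
  expect_error(subfamily_overrepresentation(sel, subfam, character(0)),
               "non-empty")
  expect_error(subfamily_overrepresentation("Q99", subfam, bg), "subset")
})

test_that("subfamily test equals exhaustive enumeration on small instances", {
  set.seed(41)
  for (i in 1:100) {
    N <- sample(4:12, 1)
    bg <- paste0("P", seq_len(N))
    K <- sample(1:N, 1)
    n <- sample(1:N, 1)
    sel <- sample(bg, n)
    r <- subfamily_overrepresentation(sel, bg[seq_len(K)], bg)
    expect_equal(r$p, hyper_tail_enum(N, K, n, r$observed), tolerance = 1e-10)
  }
})

test_that("network summary methods expose edges and completeness", {
  sg <- simulate_genesets(subfamily_size = 5, seed = 3)
  net <- build_overlap_network(
    tibble::tibble(pathway = sg$subfamily, mirna_count = seq_len(5)),
    sg$pathways)
  expect_identical(tidy(net), net$edges)
  gl <- glance(net)
  expect_equal(gl$n_nodes, 5L)
  expect_equal(gl$complete_edges, 10)
})
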