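# Independent oracles used across test files. These deliberately avoid the
# package's own code paths.

# Benjamini-Hochberg by the literal min-over-suffix definition
bh_brute_force <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  for (i in seq_len(m)) {
    j <- ord[i:m]
    # min over all suffix positions of m * p(j) / rank(j)
    adj[ord[i]] <- min(1, min(m * p[j] / seq(i, m)))
  }
  adj
}

# exact hypergeometric upper tail P(X >= k) by exhaustive enumeration of
# all C(N, n) draws of the target set; feasible for N <= 12
hyper_tail_enum <- function(N, K, n, k) {
  if (k <= 0) return(1)
  draws <- utils::combn(N, n)
  in_pathway <- seq_len(N) <= K
  overlaps <- apply(draws, 2, function(d) sum(in_pathway[d]))
  mean(overlaps >= k)
}

# random valid gene-set collection for round-trip property tests
random_collection <- function(n_sets, seed) {
  set.seed(seed)
  genes <- sprintf("g%03d", 1:150)
  tibble::tibble(
    name = sprintf("set_%02d_%d", seq_len(n_sets), seed),
    description = replicate(n_sets, paste(sample(letters, 5), collapse = "")),
    genes = replicate(n_sets, sample(genes, sample(1:20, 1)), simplify = FALSE)
  )
}

# small balanced qPCR design for toy tests
toy_ct_table <- function() {
  samples <- c("s1", "s2", "s3", "s4")
  tibble::tibble(
    sample_id = rep(samples, each = 2),
    target_id = rep(c("miR-X", "RNU6B"), times = 4),
    ct = c(28, 25, 26, 25, 25, 25, 27, 25)
  )
}
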