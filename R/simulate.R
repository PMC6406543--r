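# Seeded generators reproducing the statistical structure of a
# gender-stratified case-control miRNA study: a male-only upregulated
# feature cluster in negative-binomial counts, a qPCR panel with a crossing
# status-by-gender interaction, and a pathway collection containing a
# mutually overlapping subfamily convergently targeted by the cluster.

with_local_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || seed != floor(seed)) {
    stop_stratmir("`seed` must be a single integer")
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

sim_sample_table <- function(n_case_m, n_case_f, n_ctrl_m, n_ctrl_f) {
  mk <- function(n, gender, status, prefix) {
    if (n == 0L) return(NULL)
    stage <- if (status == "RRMS") {
      rep(c("relapse", "remission"), length.out = n)
    } else {
      rep(NA_character_, n)
    }
    tibble(sample_id = sprintf("%s%02d", prefix, seq_len(n)),
           gender = gender, status = status, stage = stage)
  }
  dplyr::bind_rows(
    mk(n_case_m, "M", "RRMS", "M_RRMS_"),
    mk(n_case_f, "F", "RRMS", "F_RRMS_"),
    mk(n_ctrl_m, "M", "HC", "M_HC_"),
    mk(n_ctrl_f, "F", "HC", "F_HC_"))
}

#' Simulate a gender-stratified miRNA count screen
#'
#' Negative-binomial read counts (variance `mu + dispersion * mu^2`) for a
#' two-gender case-control design, with a planted cluster of co-upregulated
#' features and a handful of downregulated features whose fold changes act
#' in male cases only — the structure reported for the male RRMS stratum.
#' Per-feature baseline means are log-uniform over `baseline_mean_range`
#' and per-sample library-size factors log-uniform over
#' `library_size_range`, so normalization is actually exercised.
#'
#' Default group sizes are the screen's: 8 male and 8 female cases, 4 male
#' and 4 female controls; case stages alternate relapse/remission (4/4 per
#' gender).
#'
#' @param n_features Total number of features (default 800).
#' @param cluster_size Number of planted upregulated cluster features
#'   (default 26).
#' @param n_down Number of planted downregulated features (default 6).
#' @param n_case_m,n_case_f,n_ctrl_m,n_ctrl_f Group sizes (defaults
#'   8/8/4/4).
#' @param planted_lfc_range Range (low, high) of planted log2 fold changes,
#'   drawn uniformly per feature (default `c(1.1, 6)`, the published
#'   cluster span; use `c(2, 2)` for a fixed effect, `c(0, 0)` for a null).
#' @param dispersion Negative-binomial dispersion alpha > 0 (default 0.1).
#' @param baseline_mean_range Range of per-feature baseline mean counts
#'   (default `c(5, 500)`, log-uniform).
#' @param planted_mean_range Baseline-mean range for the planted
#'   (cluster and downregulated) features (default `c(5, 50)`): imprinted-
#'   locus miRNAs are lowly expressed in blood cells, and keeping the
#'   planted features in the low-abundance range keeps their large fold
#'   changes from dominating the library composition, as in the study
#'   being emulated.
#' @param library_size_range Range of per-sample library-size factors
#'   (default `c(0.7, 1.4)`, log-uniform).
#' @param seed Integer seed; identical seeds give byte-identical output.
#' @return A list with `counts` (a `count_matrix`), `samples` (tibble) and
#'   `truth` (tibble: `mirna`, `planted_log2fc`, `role` in
#'   cluster/down/null, `band` — `"14q32.31-like"` for cluster features).
#' @export
simulate_counts <- function(n_features = 800, cluster_size = 26, n_down = 6,
                            n_case_m = 8, n_case_f = 8,
                            n_ctrl_m = 4, n_ctrl_f = 4,
                            planted_lfc_range = c(1.1, 6),
                            dispersion = 0.1,
                            baseline_mean_range = c(5, 500),
                            planted_mean_range = c(5, 50),
                            library_size_range = c(0.7, 1.4),
                            seed = 1L) {
  if (cluster_size + n_down > n_features) {
    stop_stratmir("cluster_size + n_down must not exceed n_features")
  }
  assert_scalar_number(dispersion, "dispersion", 0, strict_lower = TRUE)
  for (rng in list(planted_lfc_range, baseline_mean_range, planted_mean_range,
                   library_size_range)) {
    if (length(rng) != 2L || rng[1L] > rng[2L]) {
      stop_stratmir("ranges must be length-2 with low <= high")
    }
  }
  with_local_seed(seed, {
    samples <- sim_sample_table(n_case_m, n_case_f, n_ctrl_m, n_ctrl_f)
    n_s <- nrow(samples)
    features <- sprintf("sim-miR-%04d", seq_len(n_features))
    role <- c(rep("cluster", cluster_size), rep("down", n_down),
              rep("null", n_features - cluster_size - n_down))
    lfc <- numeric(n_features)
    draw <- function(n) stats::runif(n, planted_lfc_range[1L], planted_lfc_range[2L])
    lfc[role == "cluster"] <- draw(cluster_size)
    lfc[role == "down"] <- -draw(n_down)
    base <- exp(stats::runif(n_features, log(baseline_mean_range[1L]),
                             log(baseline_mean_range[2L])))
    planted <- role != "null"
    base[planted] <- exp(stats::runif(sum(planted), log(planted_mean_range[1L]),
                                      log(planted_mean_range[2L])))
    libf <- exp(stats::runif(n_s, log(library_size_range[1L]),
                             log(library_size_range[2L])))
    affected <- samples$gender == "M" & samples$status == "RRMS"
    mu <- outer(base, libf) * 2^(lfc %o% as.numeric(affected))
    counts <- matrix(stats::rnbinom(n_features * n_s, mu = mu,
                                    size = 1 / dispersion),
                     nrow = n_features,
                     dimnames = list(features, samples$sample_id))
    list(counts = new_count_matrix(counts),
         samples = samples,
         truth = tibble(mirna = features, planted_log2fc = lfc, role = role,
                        band = ifelse(role == "cluster", "14q32.31-like",
                                      NA_character_)))
  })
}

#' Simulate a qPCR validation panel
#'
#' Gaussian `-dCt` values per target with cell means set per
#' (status, gender) group and a constant reference Ct of 25 cycles. The
#' default cell means encode the crossing interaction seen in the
#' validation cohort: target expression lower in healthy men than in
#' healthy women, rising in male cases to meet or exceed female cases.
#' Default group sizes are the validation cohort's (16/20 cases,
#' 10/10 controls).
#'
#' @param n_targets Number of miRNA targets (default 7).
#' @param group_means Named numeric vector of cell means of `-dCt` with
#'   names `HC_M`, `HC_F`, `RRMS_M`, `RRMS_F` (defaults -8, -6, -5.2, -6).
#' @param sd Within-cell standard deviation of `-dCt` (default 0.7 cycles).
#' @param n_case_m,n_case_f,n_ctrl_m,n_ctrl_f Group sizes (defaults
#'   16/20/10/10).
#' @param seed Integer seed.
#' @return A list with `ct` (a validated `ct_table` including reference
#'   rows), `samples` (tibble) and `truth` (tibble: `target_id`, `gender`,
#'   `log2fc` — the planted per-gender case-vs-control `-ddCt`).
#' @export
simulate_ct <- function(n_targets = 7,
                        group_means = c(HC_M = -8, HC_F = -6,
                                        RRMS_M = -5.2, RRMS_F = -6),
                        sd = 0.7,
                        n_case_m = 16, n_case_f = 20,
                        n_ctrl_m = 10, n_ctrl_f = 10,
                        seed = 1L) {
  need <- c("HC_M", "HC_F", "RRMS_M", "RRMS_F")
  if (!all(need %in% names(group_means))) {
    stop_stratmir(sprintf("group_means needs all four cells: %s",
                          paste(need, collapse = ", ")))
  }
  assert_scalar_number(sd, "sd", 0, strict_lower = TRUE)
  with_local_seed(seed, {
    samples <- sim_sample_table(n_case_m, n_case_f, n_ctrl_m, n_ctrl_f)
    targets <- sprintf("sim-val-miR-%d", seq_len(n_targets))
    cell <- paste(samples$status, samples$gender, sep = "_")
    mu <- group_means[cell]
    grid <- tidyr::expand_grid(target_id = targets,
                               sample_id = samples$sample_id)
    grid$neg_dct <- stats::rnorm(nrow(grid),
                                 mean = rep(mu, times = n_targets), sd = sd)
    ref_ct <- 25.0
    ct <- dplyr::bind_rows(
      tibble(sample_id = grid$sample_id, target_id = grid$target_id,
             ct = ref_ct - grid$neg_dct),
      tibble(sample_id = samples$sample_id, target_id = "RNU6B", ct = ref_ct))
    truth <- tidyr::expand_grid(target_id = targets, gender = c("M", "F"))
    truth$log2fc <- ifelse(truth$gender == "M",
                           group_means[["RRMS_M"]] - group_means[["HC_M"]],
                           group_means[["RRMS_F"]] - group_means[["HC_F"]])
    list(ct = validate_ct(ct, "RNU6B"), samples = samples, truth = truth)
  })
}

#' Simulate a pathway collection with a convergently targeted subfamily
#'
#' Builds a gene universe, a pathway collection containing a mutually
#' overlapping subfamily (each subfamily pathway takes a fixed fraction
#' `subfamily_overlap` of its members from a shared core gene pool, so
#' pairwise Jaccard overlap rises with that fraction and reaches identity
#' at 1), and a miRNA-to-target map in which each target gene is drawn with
#' probability `convergence` from the union of subfamily genes — emulating
#' a miRNA cluster that convergently regulates one receptor-family branch
#' of the pathway collection.
#'
#' @param n_genes Universe size (default 2000).
#' @param n_pathways Number of pathways (default 500).
#' @param pathway_size Genes per pathway (default 50).
#' @param subfamily_size Number of subfamily pathways (default 17).
#' @param subfamily_overlap Fraction in `[0, 1]` of each subfamily
#'   pathway's genes drawn from the shared core (default 0.8).
#' @param n_mirnas Number of miRNAs (default 26).
#' @param targets_per_mirna Target genes drawn per miRNA (default 100;
#'   duplicates are collapsed).
#' @param convergence Probability in `[0, 1]` that a target gene is drawn
#'   from the subfamily gene union rather than the whole universe
#'   (default 0.9; 0 gives a null with uniform targeting).
#' @param seed Integer seed.
#' @return A list with `pathways` (gene-set tibble), `target_map` (tibble:
#'   `mirna`, `genes` list-column), `subfamily` (character vector of
#'   subfamily pathway names) and `genes` (the universe).
#' @export
simulate_genesets <- function(n_genes = 2000, n_pathways = 500,
                              pathway_size = 50, subfamily_size = 17,
                              subfamily_overlap = 0.8, n_mirnas = 26,
                              targets_per_mirna = 100, convergence = 0.9,
                              seed = 1L) {
  if (subfamily_size > n_pathways) {
    stop_stratmir("subfamily_size must not exceed n_pathways")
  }
  assert_scalar_number(subfamily_overlap, "subfamily_overlap", 0, 1)
  assert_scalar_number(convergence, "convergence", 0, 1)
  if (pathway_size > n_genes) stop_stratmir("pathway_size must not exceed n_genes")
  if (subfamily_size < 2L && subfamily_overlap > 0) {
    warn("subfamily has < 2 pathways; overlap implies no edges")
  }
  with_local_seed(seed, {
    genes <- sprintf("G%05d", seq_len(n_genes))
    core_size <- round(subfamily_overlap * pathway_size)
    core <- sample(genes, pathway_size)  # core pool; first core_size shared
    is_sub <- seq_len(n_pathways) <= subfamily_size
    nm <- sprintf("%s%02d", ifelse(is_sub, "RTK_LIKE_", "PATH_"),
                  ifelse(is_sub, seq_len(n_pathways),
                         seq_len(n_pathways) - subfamily_size))
    sets <- lapply(seq_len(n_pathways), function(i) {
      if (is_sub[i]) {
        fixed <- core[seq_len(core_size)]
        free <- sample(setdiff(genes, fixed), pathway_size - core_size)
        c(fixed, free)
      } else {
        sample(genes, pathway_size)
      }
    })
    pathways <- tibble(name = nm,
                       description = ifelse(is_sub, "subfamily", "background"),
                       genes = sets)
    sub_union <- unique(unlist(sets[is_sub], use.names = FALSE))
    target_map <- tibble(
      mirna = sprintf("sim-miR-%04d", seq_len(n_mirnas)),
      genes = lapply(seq_len(n_mirnas), function(i) {
        k_sub <- stats::rbinom(1L, targets_per_mirna, convergence)
        k_sub <- min(k_sub, length(sub_union))
        unique(c(sample(sub_union, k_sub),
                 sample(genes, targets_per_mirna - k_sub)))
      }))
    list(pathways = pathways, target_map = target_map,
         subfamily = nm[is_sub], genes = genes)
  })
}
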