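#' Default pipeline configuration
#'
#' Returns the fully synthetic demo configuration: every stage enabled,
#' generator settings at the study conditions (screen 8/8 cases vs 4/4
#' controls; validation 16/20 vs 10/10; 26-feature planted cluster), DE
#' filter at adjusted p < 0.05 and |log2FC| > 1, ORA at raw p < 0.05.
#' Supply file paths under `$inputs` to run on real data instead of the
#' generators.
#'
#' @param seed Global integer seed; per-stage substreams are derived from
#'   it by stable hashing of the stage name, so stage randomness does not
#'   depend on execution order.
#' @return A nested configuration list.
#' @export
default_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    stages = list(simulate = TRUE, de = TRUE, locus = TRUE,
                  qpcr = TRUE, network = TRUE),
    inputs = list(),
    simulate = list(
      counts = list(n_features = 800, cluster_size = 26, n_down = 6,
                    planted_lfc_range = c(1.1, 6), dispersion = 0.1),
      ct = list(n_targets = 7, sd = 0.7),
      genesets = list(n_genes = 2000, n_pathways = 500, subfamily_size = 17,
                      subfamily_overlap = 0.8, convergence = 0.9)
    ),
    de = list(alpha = 0.05, lfc = 1, shrinkage = "eb"),
    locus = list(band_prefix = "14q32"),
    qpcr = list(ztransform = TRUE),
    network = list(alpha = 0.05, quantile_type = 7)
  )
}

#' Validate a pipeline configuration
#'
#' Schema-checks a configuration list (or YAML file path): every problem
#' is reported with its config path (e.g. `de.alpha`). Unknown keys
#' produce warnings, not errors, so configs stay forward-compatible;
#' referenced input files must exist.
#'
#' @param config A configuration list as from [default_config()], or the
#'   path to a YAML file holding one.
#' @return A tibble with columns `path`, `severity` (`"error"` or
#'   `"warning"`), `message`. Zero error rows means the config is runnable.
#' @export
validate_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) {
      return(tibble(path = "(file)", severity = "error",
                    message = sprintf("config file not found: %s", config)))
    }
    config <- yaml::read_yaml(config)
  }
  probs <- list()
  note <- function(path, severity, message) {
    probs[[length(probs) + 1L]] <<- tibble(path = path, severity = severity,
                                           message = message)
  }
  known <- c("seed", "stages", "inputs", "simulate", "de", "locus",
             "qpcr", "network")
  for (k in setdiff(names(config), known)) {
    note(k, "warning", "unknown configuration key (ignored)")
  }
  if (is.null(config$seed) || !is.numeric(config$seed) ||
      config$seed != floor(config$seed)) {
    note("seed", "error", "seed must be an integer")
  }
  chk_prob <- function(x, path) {
    if (!is.null(x) && (!is.numeric(x) || x <= 0 || x >= 1)) {
      note(path, "error", "must be a number strictly between 0 and 1")
    }
  }
  chk_prob(config$de$alpha, "de.alpha")
  chk_prob(config$network$alpha, "network.alpha")
  if (!is.null(config$de$lfc) && (!is.numeric(config$de$lfc) || config$de$lfc < 0)) {
    note("de.lfc", "error", "must be a non-negative number")
  }
  if (!is.null(config$de$shrinkage) &&
      !config$de$shrinkage %in% c("eb", "none")) {
    note("de.shrinkage", "error", "must be 'eb' or 'none'")
  }
  for (f in names(config$inputs)) {
    p <- config$inputs[[f]]
    if (!is.character(p) || !file.exists(p)) {
      note(paste0("inputs.", f), "error",
           sprintf("input file not found: %s", p))
    }
  }
  if (length(probs) == 0L) {
    return(tibble(path = character(0), severity = character(0),
                  message = character(0)))
  }
  dplyr::bind_rows(probs)
}

log_stage <- function(stage, msg) {
  message(sprintf("[stratmir] stage=%s %s", stage, msg))
}

write_json_file <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate, differential expression, locus annotation, qPCR
#' statistics and network enrichment in dependency order, writing every
#' stage's artifacts under `out_dir` and returning a run report. With
#' identical configuration and seed the artifacts are reproduced
#' byte-identically; with `resume = TRUE`, stages whose artifacts already
#' exist are skipped.
#'
#' @param config Configuration list (see [default_config()]) or YAML path.
#' @param out_dir Output directory (created if missing).
#' @param resume Skip stages whose outputs already exist (default FALSE).
#' @return A run report list (also written as `report.json` and
#'   `report.md`), with one summary block per executed stage.
#' @export
run_pipeline <- function(config = default_config(), out_dir, resume = FALSE) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  probs <- validate_config(config)
  errs <- probs[probs$severity == "error", ]
  if (nrow(errs) > 0L) {
    stop_stratmir(paste0("invalid configuration:\n",
                         paste(sprintf("  %s: %s", errs$path, errs$message),
                               collapse = "\n")))
  }
  for (i in seq_len(nrow(probs))) {
    warn(sprintf("config %s: %s", probs$path[i], probs$message[i]))
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(config$seed)
  on <- function(stage) isTRUE(config$stages[[stage]] %||% TRUE)
  art <- function(...) file.path(out_dir, ...)
  report <- list(package_version = as.character(utils::packageVersion("stratmir")),
                 config_hash = rlang::hash(config),
                 seed = seed)
  de_filter <- list()

  ## ---- simulate ----
  if (on("simulate")) {
    if (resume && file.exists(art("counts.tsv"))) {
      log_stage("simulate", "resume: artifacts exist, skipping")
    } else {
      log_stage("simulate", "generating synthetic inputs")
      sc <- do.call(simulate_counts,
                    c(config$simulate$counts, list(seed = stage_seed(seed, "counts"))))
      write_counts(sc$counts, art("counts.tsv"))
      readr::write_csv(sc$samples, art("samples.csv"), progress = FALSE)
      readr::write_csv(sc$truth, art("counts_truth.csv"), progress = FALSE)
      st <- do.call(simulate_ct,
                    c(config$simulate$ct, list(seed = stage_seed(seed, "ct"))))
      readr::write_csv(st$ct, art("ct.csv"), progress = FALSE)
      readr::write_csv(st$samples, art("ct_samples.csv"), progress = FALSE)
      readr::write_csv(st$truth, art("ct_truth.csv"), progress = FALSE)
      sg <- do.call(simulate_genesets,
                    c(config$simulate$genesets, list(seed = stage_seed(seed, "genesets"))))
      write_gmt(sg$pathways, art("pathways.gmt"))
      write_gmt(tibble(name = sg$target_map$mirna, description = "targets",
                       genes = sg$target_map$genes), art("targets.gmt"))
      writeLines(sort(sg$subfamily), art("subfamily.txt"))
    }
    report$simulate <- list(counts = "counts.tsv", ct = "ct.csv",
                            pathways = "pathways.gmt")
  }

  inp <- function(name, default) config$inputs[[name]] %||% default

  ## ---- differential expression ----
  if (on("de")) {
    log_stage("de", "stratified moderated differential expression")
    cm <- read_counts(inp("counts", art("counts.tsv")))
    samples <- read_samples(inp("samples", art("samples.csv")))
    logcpm <- normalize_log_cpm(cm)
    de <- moderated_de(logcpm, samples,
                       shrinkage = config$de$shrinkage %||% "eb")
    filt <- list()
    for (s in unique(de$table$stratum)) {
      tab <- de$table[de$table$stratum == s, ]
      readr::write_csv(tab, art(sprintf("de_%s.csv", s)), progress = FALSE)
      f <- filter_de(tab, alpha = config$de$alpha %||% 0.05,
                     lfc = config$de$lfc %||% 1)
      filt[[s]] <- list(n_up = length(f$up), n_down = length(f$down),
                        up = sort(f$up), down = sort(f$down))
    }
    write_json_file(filt, art("de_summary.json"))
    report$de <- lapply(filt, function(f) f[c("n_up", "n_down")])
    de_filter <- filt
  }

  ## ---- locus annotation ----
  if (on("locus")) {
    log_stage("locus", "band co-localization of male-stratum hits")
    locus <- if (!is.null(config$inputs$locus)) {
      new_locus_table(readr::read_tsv(config$inputs$locus,
                                      show_col_types = FALSE, progress = FALSE))
    } else if (on("simulate")) {
      # synthetic annotation from the generator's truth table
      tr <- readr::read_csv(art("counts_truth.csv"), show_col_types = FALSE,
                            progress = FALSE)
      new_locus_table(tibble(
        mirna = tr$mirna,
        band = ifelse(tr$role == "cluster", "14q32.31",
                      ifelse(tr$role == "down", "16q22.1", "1q32.1"))))
    } else {
      load_locus_fixture()
    }
    male <- de_filter[["M"]] %||% list(up = character(0), down = character(0))
    cs <- colocalization_summary(male$up, male$down, locus,
                                 band_prefix = config$locus$band_prefix %||% "14q32")
    by_band <- cs$by_band[c("band", "n_up", "n_down")]
    readr::write_csv(by_band, art("band_summary.csv"), progress = FALSE)
    report$locus <- list(fraction_up_in_band = cs$fraction_up_in_band,
                         n_up_in_band = cs$n_up_in_band,
                         band_prefix = cs$band_prefix)
    write_json_file(report$locus, art("band_summary.json"))
  }

  ## ---- qPCR statistics ----
  if (on("qpcr")) {
    log_stage("qpcr", "delta-delta-Ct, interaction ANOVA, Tukey HSD")
    ct <- read_ct(inp("ct", art("ct.csv")))
    qsamples <- read_samples(inp("ct_samples", art("ct_samples.csv")))
    dct <- delta_ct(ct)
    anova <- qpcr_interaction(dct, qsamples,
                              ztransform = config$qpcr$ztransform %||% TRUE)
    readr::write_csv(anova$table, art("qpcr_anova.csv"), progress = FALSE)
    tuk <- qpcr_tukey(dct, qsamples)
    readr::write_csv(tuk, art("qpcr_tukey.csv"), progress = FALSE)
    cm_tab <- qpcr_cell_means(dct, qsamples)
    readr::write_csv(cm_tab, art("qpcr_cell_means.csv"), progress = FALSE)
    report$qpcr <- list(
      interaction_p_adj = stats::setNames(as.list(anova$table$p_adj),
                                          anova$table$target_id))
  }

  ## ---- network enrichment ----
  if (on("network")) {
    log_stage("network", "ORA, outlier selection, overlap network")
    pathways <- read_gmt(inp("pathways", art("pathways.gmt")))
    tg <- read_gmt(inp("targets", art("targets.gmt")))
    target_map <- tibble(mirna = tg$name, genes = tg$genes)
    ora <- ora_grid(target_map, pathways)
    readr::write_csv(ora, art("ora.csv"), progress = FALSE)
    nodes <- pathway_mirna_counts(ora, alpha = config$network$alpha %||% 0.05)
    sel <- select_outlier_pathways(nodes,
                                   quantile_type = config$network$quantile_type %||% 7)
    readr::write_csv(dplyr::arrange(sel$nodes, .data$pathway),
                     art("pathway_nodes.csv"), progress = FALSE)
    net <- build_overlap_network(sel$selected, pathways)
    export_graph(net, art("network.graphml"), "graphml")
    export_graph(net, art("network.sif"), "sif")
    export_graph(net, art("network_edges.tsv"), "edge-tsv")
    comp <- network_completeness(net)
    subfam_file <- inp("subfamily", art("subfamily.txt"))
    stats_out <- c(as.list(comp[1, c("n_nodes", "n_edges", "complete_edges",
                                     "completeness")]),
                   list(q1 = sel$q1, q3 = sel$q3, cutoff = sel$cutoff))
    if (file.exists(subfam_file)) {
      subfam <- readLines(subfam_file, warn = FALSE)
      sf <- subfamily_overrepresentation(sel$selected$pathway, subfam,
                                         nodes$pathway)
      stats_out$subfamily_p <- sf$p
      stats_out$subfamily_method <- sf$method
    }
    write_json_file(stats_out, art("network_stats.json"))
    report$network <- stats_out
  }

  write_json_file(report, art("report.json"))
  writeLines(render_report_md(report), art("report.md"))
  invisible(report)
}

render_report_md <- function(report) {
  fmt_num <- function(x) formatC(x, digits = 6, format = "g")
  out <- c("# stratmir run report", "",
           sprintf("- package version: %s", report$package_version),
           sprintf("- config hash: %s", report$config_hash),
           sprintf("- seed: %d", report$seed), "")
  if (!is.null(report$de)) {
    out <- c(out, "## Differential expression", "",
             purrr::imap_chr(report$de, function(f, s) {
               sprintf("- stratum %s: %d up, %d down", s, f$n_up, f$n_down)
             }), "")
  }
  if (!is.null(report$locus)) {
    out <- c(out, "## Locus co-localization", "",
             sprintf("- fraction of upregulated hits in %s*: %s",
                     report$locus$band_prefix,
                     fmt_num(report$locus$fraction_up_in_band)), "")
  }
  if (!is.null(report$qpcr)) {
    out <- c(out, "## qPCR interaction ANOVA (BH-adjusted p)", "",
             purrr::imap_chr(report$qpcr$interaction_p_adj, function(p, t) {
               sprintf("- %s: %s", t, fmt_num(p))
             }), "")
  }
  if (!is.null(report$network)) {
    n <- report$network
    out <- c(out, "## Overlap network", "",
             sprintf("- nodes: %d, edges: %d of %d possible (completeness %s)",
                     n$n_nodes, n$n_edges, n$complete_edges,
                     fmt_num(n$completeness)),
             sprintf("- count quartiles Q1=%s Q3=%s, Tukey-fence cutoff %s",
                     fmt_num(n$q1), fmt_num(n$q3), fmt_num(n$cutoff)),
             if (!is.null(n$subfamily_p)) {
               sprintf("- subfamily over-representation p = %s", fmt_num(n$subfamily_p))
             }, "")
  }
  out[!vapply(out, is.null, logical(1))]
}
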