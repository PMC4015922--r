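#' @useDynLib polreg, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

# Deterministic per-stage seed derived from the global seed by a stable
# polynomial hash of the stage name; always in [1, 2^31 - 2].
stage_seed <- function(seed, stage) {
  h <- 0
  for (u in utf8ToInt(stage)) h <- (h * 31 + u) %% 1e6
  as.integer((as.numeric(seed) * 1000003 + h) %% 2147483646) + 1L
}

#' Default pipeline configuration
#'
#' All tunable parameters with their defaults: 1 kb bins, LOWESS span 0.3,
#' pi threshold mean + 3 SD, widest window (-600, +500), rank cut 2000 (or
#' the equivalent corpus fraction), subset size k = 5, 1e6 ensemble
#' iterations, alpha = 5, top 10% candidates, stepwise p <= 0.01, minimum 5
#' reads, SIS threshold mean + 1 SD.
#'
#' @param ... Overrides of individual fields.
#' @return Named list of configuration values.
#' @export
default_config <- function(...) {
  cfg <- list(
    control = NULL, treatment = NULL, annotation = NULL, promoters = NULL,
    pwms = NULL, pwm_format = "jaspar", out_dir = "polreg_out",
    bin_size = 1000, norm_method = "lowess", span = 0.3, pseudocount = 0.5,
    upstream = -600, downstream = 500, band = 0.025, k_sd_pi = 3,
    rank = 2000, top_fraction = NULL, k = 5, n_iter = 1e6, alpha = 5,
    fraction = 0.10, alpha_remove = 0.01, min_reads = 5, k_sd_sis = 1,
    dispersion = "sd", seed = 1)
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown config field(s): ", paste(bad, collapse = ", "))
  utils::modifyList(cfg, over)
}

validate_config <- function(cfg) {
  num_pos <- c("bin_size", "span", "pseudocount", "k", "n_iter", "alpha",
               "fraction", "alpha_remove", "min_reads")
  for (f in num_pos) {
    if (!is.numeric(cfg[[f]]) || cfg[[f]] <= 0) {
      stop("config field '", f, "' must be a positive number")
    }
  }
  if (cfg$span > 1 || cfg$fraction > 1 || cfg$alpha_remove > 1) {
    stop("span, fraction and alpha_remove must be <= 1")
  }
  if (cfg$upstream >= 0 || cfg$downstream <= 0) {
    stop("upstream must be negative and downstream positive")
  }
  if (is.null(cfg$seed)) stop("seed is mandatory")
  for (f in c("control", "treatment", "annotation", "promoters", "pwms")) {
    if (is.null(cfg[[f]])) stop("config field '", f, "' (input path) is required")
    if (!file.exists(cfg[[f]])) stop("input file not found: ", cfg[[f]])
  }
  invisible(cfg)
}

#' Run the full pipeline from a configuration
#'
#' Executes normalize, diffbind, scan, predict and network in order, writing
#' each stage's artifacts plus a JSON run manifest under `out_dir`. Reruns
#' with an identical configuration produce byte-identical outputs.
#'
#' @param config A configuration list (see [default_config()]) or the path to
#'   a YAML file of the same fields.
#' @return Invisibly, a list with the stage results and the manifest.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- do.call(default_config, config)
  validate_config(cfg)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  stages <- list()
  t0 <- Sys.time()
  note <- function(stage, n) {
    stages[[stage]] <<- list(stage = stage, rows = n,
                             elapsed = as.numeric(Sys.time() - t0, units = "secs"))
    message(sprintf("[polreg] %-9s done (%d rows, %.1fs)", stage, n,
                    stages[[stage]]$elapsed))
  }

  ## inputs
  control <- read_binned_track(cfg$control, cfg$bin_size)
  treatment <- read_binned_track(cfg$treatment, cfg$bin_size)
  annotation <- read_gene_annotation(cfg$annotation)
  promoters <- read_promoter_fasta(cfg$promoters)
  pwms <- read_pwm_collection(cfg$pwms, cfg$pwm_format)

  ## 1. normalize
  norm <- normalize_tracks(control, treatment, method = cfg$norm_method,
                           span = cfg$span, pseudocount = cfg$pseudocount)
  write_binned_track(norm$control_adj, file.path(cfg$out_dir, "control_adj.bedgraph"))
  write_binned_track(norm$treatment_adj, file.path(cfg$out_dir, "treatment_adj.bedgraph"))
  ma_cols <- c("chrom", "bin", "M", "A", "M_hat", "M_adj")
  ma_tab <- norm$table[, ma_cols]
  ma_tab <- cbind(key = paste0(ma_tab$chrom, ":", sprintf("%09d", ma_tab$bin)),
                  ma_tab)
  write_results_table(ma_tab, file.path(cfg$out_dir, "ma_diagnostic.tsv"))
  note("normalize", nrow(norm$table))

  ## 2. diffbind (widest window)
  diff <- differential_binding(norm, annotation, cfg$upstream, cfg$downstream,
                               band = cfg$band)
  write_results_table(diff, file.path(cfg$out_dir, "diffbind.tsv"))
  selected <- select_differential(diff, k_sd = cfg$k_sd_pi,
                                  dispersion = cfg$dispersion)
  write_results_table(data.frame(gene_id = as.character(selected)),
                      file.path(cfg$out_dir, "differential_genes.tsv"))
  note("diffbind", nrow(diff))

  ## 3. scan
  scan <- build_binding_matrix(promoters, pwms, rank = cfg$rank,
                               top_fraction = cfg$top_fraction)
  Rdf <- data.frame(gene_id = rownames(scan$R), scan$R, check.names = FALSE)
  write_results_table(Rdf, file.path(cfg$out_dir, "binding_matrix.tsv"))
  if (!is.null(scan$sites)) {
    sdf <- scan$sites
    sdf <- cbind(key = paste(sdf$gene_id, sdf$motif_id, sdf$offset, sdf$strand),
                 sdf)
    write_results_table(sdf, file.path(cfg$out_dir, "sites.tsv"))
  }
  note("scan", sum(scan$R > 0))

  ## 4. predict
  universe <- annotation$gene_id
  min_universe <- max(30, cfg$k + 5)
  if (length(selected) >= min_universe) {
    universe <- as.character(selected)
  } else {
    warning(sprintf(
      "differential set too small (%d < %d); using all genes as universe",
      length(selected), min_universe))
  }
  report <- run_two_step(scan, norm, annotation,
                         genes = universe, k = cfg$k, n_iter = cfg$n_iter,
                         alpha = cfg$alpha, fraction = cfg$fraction,
                         alpha_remove = cfg$alpha_remove,
                         min_reads = cfg$min_reads,
                         seed = stage_seed(cfg$seed, "predict"),
                         scan_upstream = cfg$upstream)
  tf_of <- motif_tf_lookup(scan$tf_map)
  write_results_table(
    data.frame(motif_id = report$merged,
               tf_name = unname(tf_of[report$merged])),
    file.path(cfg$out_dir, "merged_tfs.tsv"))
  cm <- data.frame(motif_id = rownames(report$coefficients),
                   report$coefficients, check.names = FALSE)
  write_results_table(cm, file.path(cfg$out_dir, "coefficient_matrix.tsv"))
  note("predict", length(report$merged))

  ## 5. network
  net <- NULL
  if (length(report$merged_tfs) >= 2) {
    Runi <- scan$R[intersect(universe, rownames(scan$R)), , drop = FALSE]
    counts <- count_cooccurrence(Runi, scan$tf_map, report$merged_tfs)
    edges <- sis_edges(counts)
    net <- build_network(edges, k_sd = cfg$k_sd_sis,
                         dispersion = cfg$dispersion)
    ek <- cbind(key = paste(net$edges$tf_i, net$edges$tf_j), net$edges)
    write_results_table(ek, file.path(cfg$out_dir, "network_edges.tsv"))
    write_results_table(net$hubs, file.path(cfg$out_dir, "hubs.tsv"))
    write_network_graphml(net, file.path(cfg$out_dir, "network.graphml"))
    note("network", nrow(net$edges))
  } else {
    write_results_table(
      data.frame(key = character(0), tf_i = character(0),
                 tf_j = character(0), int = numeric(0), pval = numeric(0),
                 sis = numeric(0)),
      file.path(cfg$out_dir, "network_edges.tsv"))
    note("network", 0L)
  }

  manifest <- list(
    package = "polreg",
    version = as.character(utils::packageVersion("polreg")),
    seed = cfg$seed,
    config = cfg[order(names(cfg))],
    stages = unname(stages))
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  invisible(list(norm = norm, diff = diff, selected = selected, scan = scan,
                 report = report, network = net, manifest = manifest,
                 out_dir = cfg$out_dir))
}
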