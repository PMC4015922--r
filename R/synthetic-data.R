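#' Simulate a complete, ground-truthed PolII promoter-binding study
#'
#' Generates every input the pipeline consumes — a paired control/treatment
#' binned count track, gene annotation, promoter sequences, a PWM collection —
#' together with the ground truth used to generate them. The treatment sample
#' is the control expectation scaled, over each gene's promoter bins, by
#' `2^(sum_j Rtilde[i, j] * beta_j + N(0, sigma))` (`Rtilde` = indicator of a
#' planted consensus instance of causal motif `j` in gene `i`'s promoter) and,
#' genome-wide, by a smooth polynomial depth-bias curve that the MA/LOWESS
#' normalizer is expected to remove.
#'
#' Defaults emulate a PolII ChIP-seq promoter study at modest depth:
#' negative-binomial background (mean 20 per 1 kb bin, gamma dispersion 0.2),
#' 5-fold promoter occupancy enrichment in both samples, 30% of genes
#' responsive with each causal motif planted with probability 0.5 per
#' responsive gene, and causal effect magnitudes of 1-2 log2 units. Causal
#' motifs are drawn wider (9-12 bp) than background motifs (6-12 bp) so that
#' a planted consensus is effectively unique in the promoter corpus.
#'
#' @param n_genes Number of genes (>= 20).
#' @param n_motifs Number of motifs in the PWM collection.
#' @param n_causal Number of causal motifs (<= n_motifs).
#' @param bin_size Track bin width in bp.
#' @param seed Integer seed; identical seeds give identical bundles.
#' @param effect_sizes Optional explicit causal effect vector (log2 units);
#'   default: magnitudes uniform in `effect_range` with random signs.
#' @param effect_range Magnitude range for default effect sizes.
#' @param sigma SD of the per-gene log2 noise in the treatment scaling.
#' @param prop_responsive Fraction of genes eligible for planted instances.
#' @param plant_prob Per responsive gene, per causal motif plant probability.
#' @param bg_mean Negative-binomial background mean per bin.
#' @param bg_dispersion Negative-binomial dispersion (1/size); 0 gives Poisson.
#' @param bg_bin_sd SD (log2 units) of a per-bin depth offset shared by both
#'   samples, emulating heterogeneous genomic coverage; it cancels from every
#'   bin's log-ratio but spreads bins along the A axis, which is what lets a
#'   robust M-vs-A fit treat changed bins as a local minority. Set to 0 for a
#'   flat background (normalization diagnostics).
#' @param promoter_enrichment Occupancy fold-enrichment over promoter windows
#'   (applied to both samples).
#' @param depth_bias `"polynomial"` (default) or `"none"`.
#' @param bias_coef Coefficients (c0, c1, c2) of the log2 bias polynomial in
#'   scaled genomic position t in `[0, 1]`.
#' @param count_noise `"nbinom"` (default) draws counts from the negative
#'   binomial; `"none"` uses rounded expectations (for normalization
#'   diagnostics, where sampling scatter would mask the bias signal).
#' @param gene_spacing Distance between consecutive TSSs in bp.
#' @param upstream,downstream Promoter window offsets (sequence length is
#'   `downstream - upstream`).
#' @return A `polreg_bundle`: list with `control`, `treatment`
#'   (`binned_track`s), `annotation`, `promoters` (named character),
#'   `pwms` (`pwm_collection`), and `truth` (causal_motif_ids, effect_sizes,
#'   sigma, responsive_gene_ids, plants data.frame, gene_effects, seed,
#'   depth_bias description).
#' @export
simulate_genome <- function(n_genes = 500, n_motifs = 60, n_causal = 5,
                            bin_size = 1000, seed = 1,
                            effect_sizes = NULL, effect_range = c(1, 2),
                            sigma = 0.25, prop_responsive = 0.3,
                            plant_prob = 0.5, bg_mean = 20,
                            bg_dispersion = 0.2, bg_bin_sd = 1,
                            promoter_enrichment = 5,
                            depth_bias = c("polynomial", "none"),
                            bias_coef = c(1.0, 1.0, -2.5),
                            count_noise = c("nbinom", "none"),
                            gene_spacing = 10000, upstream = -600,
                            downstream = 500) {
  depth_bias <- match.arg(depth_bias)
  count_noise <- match.arg(count_noise)
  stopifnot(n_causal <= n_motifs, n_genes >= 20, sigma >= 0, plant_prob >= 0,
            plant_prob <= 1)
  set.seed(seed)
  prom_len <- downstream - upstream

  ## --- PWM collection -------------------------------------------------
  motif_ids <- sprintf("M%03d", seq_len(n_motifs))
  causal_ids <- if (n_causal > 0) sort(sample(motif_ids, n_causal)) else character(0)
  widths <- sample(6:12, n_motifs, replace = TRUE)
  widths[motif_ids %in% causal_ids] <- sample(9:12, n_causal, replace = TRUE)
  if (any(widths > prom_len)) stop("motif wider than the promoter window")
  # ~10% of TFs own two motifs
  n_tfs <- max(1L, ceiling(n_motifs * 0.9))
  tf_names <- sprintf("TF%03d", seq_len(n_tfs))
  tf_of <- c(tf_names, sample(tf_names, n_motifs - n_tfs, replace = TRUE))
  motifs <- lapply(seq_len(n_motifs), function(j) {
    counts <- sapply(seq_len(widths[j]), function(k) {
      dom <- sample(4L, 1L)
      v <- rep(1, 4)
      v[dom] <- 17
      v
    })
    finalize_motif(list(motif_id = motif_ids[j], tf_name = tf_of[j],
                        counts = counts),
                   pseudocount = 0.01, background = rep(0.25, 4))
  })
  names(motifs) <- motif_ids
  pwms <- new_pwm_collection(motifs, "synthetic")

  ## --- genes and promoters --------------------------------------------
  gene_ids <- sprintf("G%04d", seq_len(n_genes))
  tss <- 5000 + (seq_len(n_genes) - 1L) * gene_spacing
  strand <- sample(c("+", "-"), n_genes, replace = TRUE)
  annotation <- data.frame(gene_id = gene_ids, chromosome = "chr1",
                           tss = tss, strand = strand,
                           stringsAsFactors = FALSE)
  bases <- c("A", "C", "G", "T")
  seq_mat <- matrix(sample(bases, n_genes * prom_len, replace = TRUE),
                    nrow = n_genes)

  responsive <- sort(sample(gene_ids, round(prop_responsive * n_genes)))
  plants <- list()
  rtilde <- matrix(0L, n_genes, n_causal,
                   dimnames = list(gene_ids, causal_ids))
  for (mid in causal_ids) {
    w <- motifs[[mid]]$width
    consensus <- bases[apply(motifs[[mid]]$freq, 2L, which.max)]
    rc <- rev(c(A = "T", C = "G", G = "C", T = "A")[consensus])
    hosts <- responsive[stats::runif(length(responsive)) < plant_prob]
    for (g in hosts) {
      off <- sample.int(prom_len - w + 1L, 1L) - 1L
      st <- sample(c("+", "-"), 1L)
      ins <- if (st == "+") consensus else rc
      seq_mat[match(g, gene_ids), off + seq_len(w)] <- ins
      rtilde[g, mid] <- 1L
      plants[[length(plants) + 1L]] <- data.frame(
        gene_id = g, motif_id = mid, offset = off, strand = st,
        stringsAsFactors = FALSE)
    }
  }
  plants <- if (length(plants)) do.call(rbind, plants) else
    data.frame(gene_id = character(0), motif_id = character(0),
               offset = integer(0), strand = character(0))
  promoters <- stats::setNames(apply(seq_mat, 1L, paste0, collapse = ""),
                               gene_ids)

  ## --- effect sizes and per-gene scaling ------------------------------
  if (n_causal > 0) {
    if (is.null(effect_sizes)) {
      effect_sizes <- stats::runif(n_causal, effect_range[1], effect_range[2]) *
        sample(c(-1, 1), n_causal, replace = TRUE)
    }
    stopifnot(length(effect_sizes) == n_causal, all(effect_sizes != 0),
              all(is.finite(effect_sizes)))
    names(effect_sizes) <- causal_ids
    gene_effects <- as.numeric(rtilde %*% effect_sizes)
  } else {
    effect_sizes <- stats::setNames(numeric(0), character(0))
    gene_effects <- numeric(n_genes)
  }
  if (sigma > 0) gene_effects <- gene_effects + stats::rnorm(n_genes, 0, sigma)
  names(gene_effects) <- gene_ids

  ## --- tracks ----------------------------------------------------------
  genome_len <- max(tss) + gene_spacing
  n_bins <- ceiling(genome_len / bin_size)
  pos_t <- (seq_len(n_bins) - 1L) / max(1L, n_bins - 1L)
  win <- promoter_windows(annotation, upstream, downstream)
  depth_offset <- if (bg_bin_sd > 0) {
    2^stats::rnorm(n_bins, 0, bg_bin_sd)
  } else rep(1, n_bins)
  mu1 <- rep(bg_mean, n_bins)
  eff_bin <- numeric(n_bins)
  for (i in seq_len(n_genes)) {
    b0 <- win$start[i] %/% bin_size
    b1 <- (win$end[i] - 1L) %/% bin_size
    bins <- (b0:b1) + 1L
    bin_lo <- (bins - 1L) * bin_size
    frac <- (pmin(win$end[i], bin_lo + bin_size) - pmax(win$start[i], bin_lo)) /
      bin_size
    mu1[bins] <- bg_mean * (1 + (promoter_enrichment - 1) * frac)
    eff_bin[bins] <- gene_effects[i]
  }
  mu1 <- mu1 * depth_offset
  log2_bias <- if (depth_bias == "polynomial") {
    bias_coef[1] + bias_coef[2] * pos_t + bias_coef[3] * pos_t^2
  } else rep(0, n_bins)
  mu2 <- mu1 * 2^(eff_bin + log2_bias)
  draw <- function(mu) {
    if (count_noise == "none") return(round(mu))
    if (bg_dispersion <= 0) return(stats::rpois(length(mu), mu))
    stats::rnbinom(length(mu), mu = mu, size = 1 / bg_dispersion)
  }
  control <- new_binned_track(list(chr1 = draw(mu1)), bin_size)
  treatment <- new_binned_track(list(chr1 = draw(mu2)), bin_size)

  truth <- list(causal_motif_ids = causal_ids, effect_sizes = effect_sizes,
                sigma = sigma, responsive_gene_ids = responsive,
                plants = plants, gene_effects = gene_effects, seed = seed,
                depth_bias = if (depth_bias == "polynomial") {
                  sprintf("log2 bias = %g + %g t + %g t^2 (t = scaled position)",
                          bias_coef[1], bias_coef[2], bias_coef[3])
                } else "none")
  structure(list(control = control, treatment = treatment,
                 annotation = annotation, promoters = promoters, pwms = pwms,
                 truth = truth,
                 params = list(n_genes = n_genes, n_motifs = n_motifs,
                               n_causal = n_causal, bin_size = bin_size,
                               upstream = upstream, downstream = downstream,
                               bg_mean = bg_mean,
                               bg_dispersion = bg_dispersion,
                               promoter_enrichment = promoter_enrichment,
                               count_noise = count_noise,
                               gene_spacing = gene_spacing)),
            class = "polreg_bundle")
}

#' @export
print.polreg_bundle <- function(x, ...) {
  cat(sprintf(
    "polreg_bundle: %d genes, %d motifs (%d causal), %d bins of %d bp\n",
    nrow(x$annotation), length(x$pwms$motifs),
    length(x$truth$causal_motif_ids),
    length(x$control$counts$chr1), x$control$bin_size))
  invisible(x)
}

#' Write a simulated bundle to a directory of standard-format files
#'
#' Emits control.bedgraph, treatment.bedgraph, annotation.tsv, promoters.fa,
#' motifs.jaspar, ground_truth.tsv (per-causal-motif effects) and
#' gene_effects.tsv. All files re-parse through the package's readers.
#'
#' @param bundle A `polreg_bundle`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_binned_track(bundle$control, file.path(dir, "control.bedgraph"))
  write_binned_track(bundle$treatment, file.path(dir, "treatment.bedgraph"))
  write_gene_annotation(bundle$annotation, file.path(dir, "annotation.tsv"))
  write_promoter_fasta(bundle$promoters, file.path(dir, "promoters.fa"))
  write_pwm_collection(bundle$pwms, file.path(dir, "motifs.jaspar"))
  gt <- data.frame(motif_id = names(bundle$truth$effect_sizes),
                   beta = as.numeric(bundle$truth$effect_sizes))
  write_results_table(gt, file.path(dir, "ground_truth.tsv"))
  ge <- data.frame(gene_id = names(bundle$truth$gene_effects),
                   log2_effect = as.numeric(bundle$truth$gene_effects),
                   responsive = names(bundle$truth$gene_effects) %in%
                     bundle$truth$responsive_gene_ids)
  write_results_table(ge, file.path(dir, "gene_effects.tsv"))
  invisible(dir)
}

#' Simulate a binary co-occurrence binding matrix
#'
#' Generates a genes x motifs 0/1 matrix with specified per-motif marginal
#' binding probabilities and, optionally, exact pairwise joint probabilities
#' for disjoint motif pairs (each motif may appear in at most one constrained
#' pair); unconstrained motifs are independent.
#'
#' @param n_genes Number of genes (rows).
#' @param p_marginal Named vector of per-motif binding probabilities.
#' @param joint Optional data.frame (motif_i, motif_j, p) of pairwise joint
#'   probabilities.
#' @param seed Integer seed.
#' @return Binary matrix with motif names as columns.
#' @export
simulate_cooccurrence <- function(n_genes, p_marginal, joint = NULL, seed = 1) {
  stopifnot(all(p_marginal >= 0), all(p_marginal <= 1))
  set.seed(seed)
  ids <- names(p_marginal)
  if (is.null(ids)) {
    ids <- sprintf("M%02d", seq_along(p_marginal))
    names(p_marginal) <- ids
  }
  X <- matrix(0L, n_genes, length(ids), dimnames = list(NULL, ids))
  done <- character(0)
  if (!is.null(joint) && nrow(joint)) {
    pair_ids <- c(joint$motif_i, joint$motif_j)
    if (anyDuplicated(pair_ids)) {
      stop("each motif may appear in at most one joint constraint")
    }
    for (r in seq_len(nrow(joint))) {
      i <- joint$motif_i[r]; j <- joint$motif_j[r]; pij <- joint$p[r]
      pi_ <- p_marginal[[i]]; pj_ <- p_marginal[[j]]
      if (pij > min(pi_, pj_) + 1e-12 || pi_ + pj_ - pij > 1 + 1e-12) {
        stop(sprintf("infeasible joint probability for (%s, %s)", i, j))
      }
      cell <- sample(c("11", "10", "01", "00"), n_genes, replace = TRUE,
                     prob = c(pij, pi_ - pij, pj_ - pij,
                              1 - pi_ - pj_ + pij))
      X[, i] <- as.integer(cell %in% c("11", "10"))
      X[, j] <- as.integer(cell %in% c("11", "01"))
      done <- c(done, i, j)
    }
  }
  for (i in setdiff(ids, done)) {
    X[, i] <- stats::rbinom(n_genes, 1L, p_marginal[[i]])
  }
  X
}
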