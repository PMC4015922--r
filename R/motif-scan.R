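#' Scan one sequence with one motif
#'
#' Slides the motif's score matrix over every window of the sequence on one or
#' both strands. Forward windows are scored as the sum over positions of the
#' score-matrix entry for the observed base; reverse-strand windows are scored
#' on the reverse complement. Windows containing a non-ACGT base score `-Inf`
#' and are dropped.
#'
#' @param seq DNA string over A, C, G, T, N (case-insensitive).
#' @param motif A `pwm_motif` (see [read_pwm_collection()]).
#' @param both_strands Scan the reverse strand too (default TRUE).
#' @param scoring `"logodds"` (default) or `"prob"` (log2 probability product,
#'   i.e. no background correction); only shifts all scores per motif, so rank
#'   thresholds select the same sites under either mode.
#' @return data.frame offset (0-based window start), strand, score; one row
#'   per finite-scoring window. Empty if the sequence is shorter than the
#'   motif.
#' @export
scan_sequence <- function(seq, motif, both_strands = TRUE,
                          scoring = c("logodds", "prob")) {
  scoring <- match.arg(scoring)
  mat <- score_matrix(motif, scoring)
  enc <- encode_dna(as.character(seq))
  if (length(enc[[1L]]) < motif$width) {
    return(data.frame(offset = integer(0), strand = character(0),
                      score = numeric(0)))
  }
  hits <- scan_motif_cpp(enc, mat, both_strands)
  keep <- is.finite(hits$score)
  data.frame(offset = hits$offset[keep],
             strand = c("+", "-")[hits$strand[keep] + 1L],
             score = hits$score[keep], stringsAsFactors = FALSE)
}

score_matrix <- function(motif, scoring) {
  switch(scoring, logodds = motif$logodds, prob = log2(motif$freq))
}

#' Rank-based site score threshold
#'
#' The threshold is the `rank`-th largest of the pooled site scores (all
#' promoters, both strands) for one motif; every site scoring at least the
#' threshold passes, so ties at the threshold can let more than `rank` sites
#' through. With fewer than `rank` sites the minimum score is used.
#'
#' @param scores Pooled finite site scores for one motif.
#' @param rank Order statistic to cut at (default 2000).
#' @return The threshold score.
#' @export
calibrate_rank_threshold <- function(scores, rank = 2000) {
  scores <- scores[is.finite(scores)]
  if (!length(scores)) stop("empty score pool")
  stopifnot(rank >= 1)
  if (length(scores) <= rank) return(min(scores))
  n <- length(scores)
  sort(scores, partial = n - rank + 1)[n - rank + 1]
}

#' Build the thresholded promoter binding matrix R
#'
#' Scans every promoter with every motif, calibrates a per-motif rank
#' threshold on the pooled site scores, and sets `R[i, j]` to the best
#' above-threshold site score of motif `j` in promoter `i`, or 0 when no site
#' passes.
#'
#' @param promoters Named character vector of promoter sequences (names are
#'   gene ids; must be unique).
#' @param pwms A `pwm_collection`.
#' @param rank Absolute rank for [calibrate_rank_threshold()]; ignored when
#'   `top_fraction` is given.
#' @param top_fraction If non-NULL, the rank is `ceiling(top_fraction *
#'   n_genes)`, scaling the corpus-wide cut to small gene sets.
#' @param both_strands Scan both strands (default TRUE).
#' @param scoring Site scoring mode, see [scan_sequence()].
#' @param keep_sites Keep the per-site hit table (needed for interval masking
#'   in [run_two_step()]).
#' @return A `binding_scan`: list with `R` (genes x motifs matrix), `sites`
#'   (data.frame gene_id, motif_id, offset, strand, score for passing sites,
#'   if kept), `thresholds` (named per-motif), `tf_map`, `motif_widths`.
#' @export
build_binding_matrix <- function(promoters, pwms, rank = 2000,
                                 top_fraction = NULL, both_strands = TRUE,
                                 scoring = c("logodds", "prob"),
                                 keep_sites = TRUE) {
  scoring <- match.arg(scoring)
  stopifnot(inherits(pwms, "pwm_collection"))
  gene_ids <- names(promoters)
  if (is.null(gene_ids) || anyDuplicated(gene_ids)) {
    stop("promoters must be named with unique gene ids")
  }
  if (!is.null(top_fraction)) {
    rank <- max(1L, as.integer(ceiling(top_fraction * length(promoters))))
  }
  enc <- encode_dna(promoters)
  motif_ids <- names(pwms$motifs)
  R <- matrix(0, nrow = length(promoters), ncol = length(motif_ids),
              dimnames = list(gene_ids, motif_ids))
  thresholds <- stats::setNames(rep(NA_real_, length(motif_ids)), motif_ids)
  site_list <- vector("list", length(motif_ids))
  for (j in seq_along(motif_ids)) {
    m <- pwms$motifs[[j]]
    hits <- scan_motif_cpp(enc, score_matrix(m, scoring), both_strands)
    finite <- is.finite(hits$score)
    sc <- hits$score[finite]
    if (!length(sc)) {
      warning("motif ", m$motif_id, " produced no sites; dropped")
      next
    }
    thr <- calibrate_rank_threshold(sc, rank)
    thresholds[j] <- thr
    pass <- finite & hits$score >= thr
    if (any(pass)) {
      gi <- hits$seq[pass]
      ps <- hits$score[pass]
      best <- tapply(ps, gi, max)
      R[as.integer(names(best)), j] <- best
      if (keep_sites) {
        site_list[[j]] <- data.frame(
          gene_id = gene_ids[gi], motif_id = motif_ids[j],
          offset = hits$offset[pass],
          strand = c("+", "-")[hits$strand[pass] + 1L],
          score = ps, stringsAsFactors = FALSE)
      }
    }
  }
  sites <- if (keep_sites) do.call(rbind, site_list) else NULL
  structure(list(R = R, sites = sites, thresholds = thresholds,
                 tf_map = pwms$tf_map,
                 motif_widths = vapply(pwms$motifs, `[[`, 0L, "width"),
                 rank = rank),
            class = "binding_scan")
}

#' @export
print.binding_scan <- function(x, ...) {
  cat(sprintf("binding_scan: %d genes x %d motifs, rank cut %d, %.1f%% nonzero\n",
              nrow(x$R), ncol(x$R), x$rank, 100 * mean(x$R > 0)))
  invisible(x)
}

#' Mask a binding matrix to a TSS sub-interval
#'
#' Rebuilds `R` keeping only passing sites fully contained in the sub-window
#' `[upstream, downstream)` of the scanned window (offsets TSS-relative).
#' Sites are masked, not rescanned, so per-motif thresholds are unchanged.
#'
#' @param scan A `binding_scan` built with `keep_sites = TRUE`.
#' @param upstream,downstream Sub-interval TSS-relative offsets.
#' @param scan_upstream The upstream offset the scan's window used (default
#'   -600), fixing the mapping from window offsets to TSS offsets.
#' @return The masked genes x motifs matrix.
#' @export
mask_binding_matrix <- function(scan, upstream, downstream,
                                scan_upstream = -600) {
  stopifnot(inherits(scan, "binding_scan"))
  if (is.null(scan$sites)) stop("scan was built with keep_sites = FALSE")
  R <- scan$R
  R[] <- 0
  s <- scan$sites
  if (is.null(s) || !nrow(s)) return(R)
  w <- scan$motif_widths[s$motif_id]
  tss_start <- s$offset + scan_upstream
  keep <- tss_start >= upstream & (tss_start + w) <= downstream
  s <- s[keep, , drop = FALSE]
  if (nrow(s)) {
    key <- paste(s$gene_id, s$motif_id, sep = "\r")
    best <- tapply(s$score, key, max)
    parts <- strsplit(names(best), "\r", fixed = TRUE)
    gid <- vapply(parts, `[[`, "", 1L)
    mid <- vapply(parts, `[[`, "", 2L)
    R[cbind(match(gid, rownames(R)), match(mid, colnames(R)))] <- best
  }
  R
}
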