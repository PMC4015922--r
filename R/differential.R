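#' Strand-oriented promoter windows
#'
#' Converts TSS-relative offsets into genomic 0-based half-open intervals,
#' reflecting the window for minus-strand genes: a gene on `-` at TSS `t` with
#' offsets `(-600, +500)` gets the genomic interval `[t - 500, t + 600)`.
#'
#' @param annotation data.frame with gene_id, chromosome, tss, strand.
#' @param upstream Negative TSS-relative offset (bp), e.g. -600.
#' @param downstream Positive TSS-relative offset (bp), e.g. +500.
#' @return data.frame gene_id, chromosome, start, end, strand.
#' @export
promoter_windows <- function(annotation, upstream = -600, downstream = 500) {
  stopifnot(upstream < 0, downstream > 0)
  plus <- annotation$strand == "+"
  start <- ifelse(plus, annotation$tss + upstream, annotation$tss - downstream)
  end   <- ifelse(plus, annotation$tss + downstream, annotation$tss - upstream)
  data.frame(gene_id = annotation$gene_id, chromosome = annotation$chromosome,
             start = pmax(start, 0), end = end, strand = annotation$strand,
             stringsAsFactors = FALSE)
}

# Pro-rata sum of per-bin values over genomic intervals. Partial bin overlap
# contributes value * overlap_fraction. Windows reaching past a chromosome
# end are truncated (warning).
window_sums <- function(counts_by_chrom, chrom, start, end, bin_size,
                        warn = TRUE) {
  out <- numeric(length(chrom))
  truncated <- FALSE
  for (chr in unique(chrom)) {
    x <- counts_by_chrom[[chr]]
    if (is.null(x)) stop("chromosome '", chr, "' absent from track")
    len_bp <- length(x) * bin_size
    C <- c(0, cumsum(x))
    G <- function(p) {
      p <- pmin(pmax(p, 0), len_bp)
      b <- pmin(p %/% bin_size, length(x) - 1L)
      C[b + 1L] + x[b + 1L] * (p - b * bin_size) / bin_size
    }
    sel <- chrom == chr
    if (any(end[sel] > len_bp)) truncated <- TRUE
    out[sel] <- G(end[sel]) - G(start[sel])
  }
  if (truncated && warn) {
    warning("window(s) extend past chromosome end; truncated")
  }
  out
}

#' Promoter-level PolII quantities for a paired normalized track
#'
#' Sums adjusted bin quantities over each promoter window pro-rata (partial
#' bin overlap counts fractionally) and, the same way, the raw read counts of
#' each sample (rounded to integers for exact testing).
#'
#' @param norm An `ma_norm` object (see [lowess_normalize()]).
#' @param windows data.frame from [promoter_windows()].
#' @return data.frame gene_id, q1, q2 (adjusted quantities), reads1, reads2
#'   (integer raw reads in the window).
#' @export
quantify_promoters <- function(norm, windows) {
  stopifnot(inherits(norm, "ma_norm"))
  bs <- norm$bin_size
  q1 <- window_sums(norm$control_adj$counts, windows$chromosome,
                    windows$start, windows$end, bs)
  q2 <- window_sums(norm$treatment_adj$counts, windows$chromosome,
                    windows$start, windows$end, bs, warn = FALSE)
  r1 <- window_sums(norm$control$counts, windows$chromosome,
                    windows$start, windows$end, bs, warn = FALSE)
  r2 <- window_sums(norm$treatment$counts, windows$chromosome,
                    windows$start, windows$end, bs, warn = FALSE)
  data.frame(gene_id = windows$gene_id, q1 = q1, q2 = q2,
             reads1 = round(r1), reads2 = round(r2),
             stringsAsFactors = FALSE)
}

#' Two-sided Fisher exact p-value for a gene's read-count proportion
#'
#' Tests the 2x2 table `[[gene_c, total_c - gene_c], [gene_t, total_t -
#' gene_t]]` by direct hypergeometric enumeration over the table support,
#' two-sided in the usual sense: the sum of probabilities of all tables (at
#' fixed margins) no more likely than the observed one, with the conventional
#' `1 + 1e-7` relative tolerance for floating-point ties.
#'
#' @param reads_control_gene,reads_treatment_gene Reads in the gene's window.
#' @param total_control,total_treatment Library totals per condition.
#' @return p-value in (0, 1].
#' @export
fisher_pvalue <- function(reads_control_gene, reads_treatment_gene,
                          total_control, total_treatment) {
  a <- as.numeric(reads_control_gene); cc <- as.numeric(reads_treatment_gene)
  stopifnot(a >= 0, cc >= 0, total_control >= a, total_treatment >= cc)
  m <- total_control          # row 1 margin
  n2 <- total_treatment       # row 2 margin
  kk <- a + cc                # first-column margin
  if (kk == 0 || kk == m + n2) return(1)
  support <- max(0, kk - n2):min(kk, m)
  probs <- stats::dhyper(support, m, n2, kk)
  pobs <- stats::dhyper(a, m, n2, kk)
  min(1, sum(probs[probs <= pobs * (1 + 1e-7)]))
}

#' The pi-value: fold change magnitude times -log10 p
#'
#' `pi = phi * (-log10 p)`; non-negative, and larger for changes that are both
#' large and significant. A p-value of exactly 0 is clamped to the smallest
#' positive double, with a warning.
#'
#' @param phi Non-negative log-fold-change magnitude(s).
#' @param pval p-value(s) in (0, 1].
#' @return Numeric pi score(s).
#' @export
pi_value <- function(phi, pval) {
  stopifnot(all(phi >= 0), all(pval <= 1), all(pval >= 0))
  if (any(pval == 0)) {
    warning("p-value of 0 clamped to smallest positive double")
    pval[pval == 0] <- .Machine$double.xmin
  }
  phi * (-log10(pval))
}

#' Select differential genes by a mean + k * dispersion pi threshold
#'
#' Genes whose pi score exceeds `mean(pi) + k_sd * dispersion(pi)` are
#' selected and returned sorted by descending pi. Dispersion is the standard
#' deviation by default; `dispersion = "variance"` applies the threshold to
#' the literal variance instead.
#'
#' @param records data.frame with columns gene_id and pi (see
#'   [differential_binding()]), or a named numeric vector of pi scores.
#' @param k_sd Multiplier on the dispersion (default 3).
#' @param dispersion `"sd"` or `"variance"`.
#' @return Character vector of selected gene ids, descending pi; the threshold
#'   is attached as attribute `"threshold"`.
#' @export
select_differential <- function(records, k_sd = 3,
                                dispersion = c("sd", "variance")) {
  dispersion <- match.arg(dispersion)
  if (is.data.frame(records)) {
    pi_scores <- stats::setNames(records$pi, records$gene_id)
  } else {
    pi_scores <- records
  }
  stopifnot(length(pi_scores) >= 2)
  disp <- if (dispersion == "sd") stats::sd(pi_scores) else stats::var(pi_scores)
  thr <- mean(pi_scores) + k_sd * disp
  sel <- pi_scores > thr
  if (!any(sel)) {
    if (stats::sd(pi_scores) == 0) {
      warning("all pi scores identical; empty selection")
    }
    out <- character(0)
  } else {
    out <- names(sort(pi_scores[sel], decreasing = TRUE))
  }
  attr(out, "threshold") <- thr
  out
}

#' Classify promoter binding change as up / down / constant
#'
#' The relative change is `(q2 - q1) / ((q1 + q2) / 2)`. Changes strictly
#' above `+band` are `up`, strictly below `-band` are `down`, everything else
#' (including exact boundary values) is `constant`. The degenerate
#' `q1 = q2 = 0` case is `constant` by convention and flagged.
#'
#' @param q1,q2 Promoter quantities before/after treatment (vectors).
#' @param band Half-width of the constant band as a fraction (default 0.025,
#'   i.e. +/-2.5 percent).
#' @return data.frame rel_change, call (factor up/constant/down), degenerate.
#' @export
classify_regulation <- function(q1, q2, band = 0.025) {
  stopifnot(length(q1) == length(q2), band >= 0)
  degenerate <- q1 == 0 & q2 == 0
  rel <- ifelse(degenerate, 0, (q2 - q1) / ((q1 + q2) / 2))
  call <- ifelse(rel > band, "up", ifelse(rel < -band, "down", "constant"))
  data.frame(rel_change = rel,
             call = factor(call, levels = c("up", "constant", "down")),
             degenerate = degenerate)
}

#' Per-gene differential PolII binding table
#'
#' Combines promoter quantification, the Fisher exact test on raw window
#' reads against the remaining library, the pi score on log2 quantities
#' (`p(k) = log2(q_k + 1)`), and the up/down/constant call on the adjusted
#' quantities.
#'
#' @param norm An `ma_norm` object.
#' @param annotation Gene annotation data.frame.
#' @param upstream,downstream TSS-relative window offsets.
#' @param band Constant-call band for [classify_regulation()].
#' @return data.frame gene_id, q1, q2, reads1, reads2, p1, p2, x, phi, pval,
#'   pi, rel_change, call.
#' @export
differential_binding <- function(norm, annotation, upstream = -600,
                                 downstream = 500, band = 0.025) {
  win <- promoter_windows(annotation, upstream, downstream)
  q <- quantify_promoters(norm, win)
  t1 <- round(sum(norm$control$counts |> vapply(sum, 0)))
  t2 <- round(sum(norm$treatment$counts |> vapply(sum, 0)))
  pval <- mapply(fisher_pvalue, q$reads1, q$reads2,
                 MoreArgs = list(total_control = t1, total_treatment = t2))
  p1 <- log2(q$q1 + 1)
  p2 <- log2(q$q2 + 1)
  x <- p1 - p2
  phi <- abs(x)
  cls <- classify_regulation(q$q1, q$q2, band)
  data.frame(q, p1 = p1, p2 = p2, x = x, phi = phi, pval = pval,
             pi = pi_value(phi, pval), rel_change = cls$rel_change,
             call = cls$call, stringsAsFactors = FALSE)
}
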