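#' Per-bin M and A values for a paired track
#'
#' For control counts `x1` and treatment counts `x2` in each bin,
#' `M = log2(x1 / x2)` and `A = log2(sqrt(x1 * x2))`. A pseudocount is added
#' to both counts in bins where either is zero, so the logs are defined; bins
#' with both counts zero are flagged ineligible for curve fitting and carry
#' `M = 0` in the output.
#'
#' @param x1,x2 Non-negative per-bin counts (same length); control, treatment.
#' @param pseudocount Added to both counts of a bin when either count is 0.
#' @return data.frame with columns M, A, eligible.
#' @export
compute_ma <- function(x1, x2, pseudocount = 0.5) {
  stopifnot(length(x1) == length(x2), all(x1 >= 0), all(x2 >= 0),
            pseudocount > 0)
  both_zero <- x1 == 0 & x2 == 0
  needs_c <- (x1 == 0 | x2 == 0) & !both_zero
  c1 <- ifelse(needs_c, pseudocount, 0)
  a1 <- x1 + c1
  a2 <- x2 + c1
  M <- ifelse(both_zero, 0, log2(a1 / a2))
  A <- ifelse(both_zero, -Inf, log2(sqrt(a1 * a2)))
  data.frame(M = M, A = A, eligible = !both_zero)
}

#' MA-plot LOWESS normalization of a paired binned track
#'
#' Fits the M-versus-A trend by LOWESS (tricube local linear regression with
#' robustifying iterations, per chromosome), subtracts the fitted curve
#' (`M' = M - M_hat`), and converts back to adjusted bin quantities
#' `x'_1 = 2^(A + M'/2)`, `x'_2 = 2^(A - M'/2)`, which preserves every bin's
#' geometric mean. Per-read weights `r' = x'/n` are emitted where the bin read
#' count `n > 0`; when no separate read track is given `n` defaults to each
#' sample's own counts, making the weight a pure scaling factor.
#'
#' @param control,treatment `binned_track`s with identical chromosomes
#'   (vectors padded to a common length per chromosome).
#' @param span LOWESS span (fraction of points in each local fit).
#' @param pseudocount Passed to [compute_ma()].
#' @param iter Robustifying iterations for the LOWESS fit.
#' @param min_bins Minimum fit-eligible bins per fitting unit; with fewer the
#'   curve is not fitted (identity normalization) and a warning is raised.
#' @param global If `TRUE`, one curve is fitted over pooled chromosomes
#'   instead of per chromosome.
#' @return An `ma_norm` object: list with `table` (per-bin data.frame: chrom,
#'   bin, x1, x2, M, A, M_hat, M_adj, x1_adj, x2_adj, r1, r2, eligible),
#'   adjusted `binned_track`s `control_adj`/`treatment_adj`, `bin_size`,
#'   and the raw input tracks.
#' @export
lowess_normalize <- function(control, treatment, span = 0.3, pseudocount = 0.5,
                             iter = 3, min_bins = 30, global = FALSE) {
  stopifnot(inherits(control, "binned_track"), inherits(treatment, "binned_track"),
            span > 0, span <= 1)
  tab <- paired_bin_table(control, treatment)
  ma <- compute_ma(tab$x1, tab$x2, pseudocount)
  tab <- cbind(tab, ma)
  tab$M_hat <- 0
  unit <- if (global) rep("all", nrow(tab)) else tab$chrom
  for (u in unique(unit)) {
    sel <- unit == u & tab$eligible
    if (sum(sel) < min_bins) {
      warning(sprintf(
        "unit '%s': %d fit-eligible bins (< %d); identity normalization used",
        u, sum(sel), min_bins))
      next
    }
    fit <- stats::lowess(tab$A[sel], tab$M[sel], f = span, iter = iter)
    tab$M_hat[sel] <- stats::approx(fit$x, fit$y, xout = tab$A[sel],
                                    rule = 2, ties = mean)$y
  }
  tab$M_adj <- tab$M - tab$M_hat
  # adjusted quantities; ineligible (both-zero) bins stay zero
  A_eff <- ifelse(tab$eligible, tab$A, 0)
  tab$x1_adj <- ifelse(tab$eligible, 2^(A_eff + tab$M_adj / 2), 0)
  tab$x2_adj <- ifelse(tab$eligible, 2^(A_eff - tab$M_adj / 2), 0)
  tab$r1 <- ifelse(tab$x1 > 0, tab$x1_adj / tab$x1, NA_real_)
  tab$r2 <- ifelse(tab$x2 > 0, tab$x2_adj / tab$x2, NA_real_)
  build_ma_norm(tab, control, treatment)
}

#' Total-mapped-reads (TMR) normalization
#'
#' The global scaling baseline: treatment counts are multiplied by
#' `sum(control) / sum(treatment)`; the control track is unchanged.
#'
#' @inheritParams lowess_normalize
#' @return An `ma_norm` object (with `M_hat` equal to the constant TMR log
#'   scale factor, so `M_adj` is the TMR-corrected log ratio).
#' @export
tmr_normalize <- function(control, treatment, pseudocount = 0.5) {
  tab <- paired_bin_table(control, treatment)
  t1 <- sum(tab$x1); t2 <- sum(tab$x2)
  if (t1 <= 0 || t2 <= 0) stop("TMR normalization requires positive totals")
  f <- t1 / t2
  ma <- compute_ma(tab$x1, tab$x2, pseudocount)
  tab <- cbind(tab, ma)
  tab$M_hat <- ifelse(tab$eligible, -log2(f), 0)
  tab$M_adj <- tab$M - tab$M_hat
  tab$x1_adj <- tab$x1
  tab$x2_adj <- tab$x2 * f
  tab$r1 <- ifelse(tab$x1 > 0, 1, NA_real_)
  tab$r2 <- ifelse(tab$x2 > 0, f, NA_real_)
  build_ma_norm(tab, control, treatment)
}

#' Identity (no-op) normalization
#' @inheritParams lowess_normalize
#' @return An `ma_norm` object with adjusted quantities equal to raw counts.
#' @export
identity_normalize <- function(control, treatment, pseudocount = 0.5) {
  tab <- paired_bin_table(control, treatment)
  ma <- compute_ma(tab$x1, tab$x2, pseudocount)
  tab <- cbind(tab, ma)
  tab$M_hat <- 0
  tab$M_adj <- tab$M
  tab$x1_adj <- tab$x1
  tab$x2_adj <- tab$x2
  tab$r1 <- ifelse(tab$x1 > 0, 1, NA_real_)
  tab$r2 <- ifelse(tab$x2 > 0, 1, NA_real_)
  build_ma_norm(tab, control, treatment)
}

#' Normalize a paired track by a named method
#' @inheritParams lowess_normalize
#' @param method `"lowess"`, `"tmr"` or `"none"`.
#' @param ... Passed to the method.
#' @export
normalize_tracks <- function(control, treatment,
                             method = c("lowess", "tmr", "none"), ...) {
  method <- match.arg(method)
  switch(method,
         lowess = lowess_normalize(control, treatment, ...),
         tmr = tmr_normalize(control, treatment, ...),
         none = identity_normalize(control, treatment, ...))
}

paired_bin_table <- function(control, treatment) {
  stopifnot(control$bin_size == treatment$bin_size)
  chroms <- union(names(control$counts), names(treatment$counts))
  parts <- lapply(chroms, function(chr) {
    v1 <- control$counts[[chr]]; if (is.null(v1)) v1 <- numeric(0)
    v2 <- treatment$counts[[chr]]; if (is.null(v2)) v2 <- numeric(0)
    n <- max(length(v1), length(v2))
    length(v1) <- n; length(v2) <- n
    v1[is.na(v1)] <- 0; v2[is.na(v2)] <- 0
    data.frame(chrom = chr, bin = seq_len(n) - 1L, x1 = v1, x2 = v2,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, parts)
  attr(out, "bin_size") <- control$bin_size
  out
}

build_ma_norm <- function(tab, control, treatment) {
  bs <- control$bin_size
  mk_track <- function(col) {
    counts <- lapply(split(tab[[col]], tab$chrom), identity)
    # preserve bin order within chromosome
    ord <- split(tab$bin, tab$chrom)
    counts <- Map(function(v, o) v[order(o)], counts, ord)
    new_binned_track(counts[unique(tab$chrom)], bs)
  }
  structure(list(table = tab,
                 control_adj = mk_track("x1_adj"),
                 treatment_adj = mk_track("x2_adj"),
                 control = control, treatment = treatment,
                 bin_size = bs),
            class = "ma_norm")
}

#' @export
print.ma_norm <- function(x, ...) {
  el <- x$table$eligible
  cat(sprintf(
    "ma_norm: %d bins (%d fit-eligible), mean M = %.4f, mean M' = %.4f\n",
    nrow(x$table), sum(el), mean(x$table$M[el]), mean(x$table$M_adj[el])))
  invisible(x)
}
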