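# Independent oracles used across test files. These deliberately take naive
# routes (full sorts, nested loops, choose()-arithmetic, lm()) so they share
# no code with the implementation they check.

# Two-sided Fisher exact p by naive enumeration with binomial-coefficient
# arithmetic (no dhyper). Table [[a, b], [c, d]].
oracle_fisher <- function(a, b, c, d) {
  m <- a + b; n2 <- c + d; kk <- a + c
  support <- max(0, kk - n2):min(kk, m)
  prob <- choose(m, support) * choose(n2, kk - support) / choose(m + n2, kk)
  pobs <- choose(m, a) * choose(n2, kk - a) / choose(m + n2, kk)
  min(1, sum(prob[prob <= pobs * (1 + 1e-7)]))
}

# Naive per-position PWM scorer for one sequence and one score matrix
# (4 x w, rows A/C/G/T), both strands, -Inf on N windows.
oracle_scan <- function(seq, mat) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  chars <- strsplit(toupper(seq), "")[[1]]
  w <- ncol(mat)
  out <- list()
  score_window <- function(win) {
    idx <- match(win, c("A", "C", "G", "T"))
    if (anyNA(idx)) return(-Inf)
    sum(mat[cbind(idx, seq_len(w))])
  }
  for (i in seq_len(length(chars) - w + 1)) {
    win <- chars[i:(i + w - 1)]
    out[[length(out) + 1]] <- data.frame(
      offset = i - 1L, strand = "+", score = score_window(win))
    rcwin <- rev(unname(comp[win]))
    out[[length(out) + 1]] <- data.frame(
      offset = i - 1L, strand = "-", score = score_window(rcwin))
  }
  do.call(rbind, out)
}

# Brute-force RC by explicit lm() over an explicit list of subsets.
oracle_rc <- function(R, P, subsets, alpha, eps_guard = 1e-12) {
  rc <- stats::setNames(numeric(ncol(R)), colnames(R))
  for (j in seq_len(ncol(subsets))) {
    cols <- subsets[, j]
    fit <- stats::lm(P ~ R[, cols, drop = FALSE])
    E <- sum(stats::resid(fit)^2)
    rc[cols] <- rc[cols] + (1 / max(E, eps_guard))^alpha
  }
  rc
}

# Nested-loop co-occurrence counting over a logical genes x TFs matrix.
oracle_cooccurrence <- function(bound) {
  m <- ncol(bound)
  Int <- matrix(0, m, m, dimnames = list(colnames(bound), colnames(bound)))
  for (i in seq_len(m)) for (j in seq_len(m)) {
    if (i == j) next
    for (g in seq_len(nrow(bound))) {
      if (bound[g, i] && bound[g, j]) Int[i, j] <- Int[i, j] + 1
    }
  }
  Int
}

# Small deterministic paired track for normalization tests.
make_track <- function(counts, bin_size = 1000, chrom = "chr1") {
  polreg:::new_binned_track(stats::setNames(list(counts), chrom), bin_size)
}
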