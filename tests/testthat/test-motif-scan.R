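make_motif <- function(counts, id = "M1", tf = "TF1") {
  polreg:::finalize_motif(list(motif_id = id, tf_name = tf, counts = counts),
                          pseudocount = 0.01, background = rep(0.25, 4))
}

test_that("the consensus window attains the motif's maximum score", {
  set.seed(2)
  counts <- sapply(1:8, function(k) { v <- rep(1, 4); v[sample(4, 1)] <- 17; v })
  m <- make_motif(counts)
  consensus <- paste(c("A", "C", "G", "T")[apply(m$freq, 2, which.max)],
                     collapse = "")
  hits <- scan_sequence(consensus, m)
  best <- max(hits$score)
  expect_equal(best, sum(apply(m$logodds, 2, max)), tolerance = 1e-12)
})

test_that("palindromic motifs score both strands identically", {
  # consensus ACGT / reverse complement ACGT
  counts <- cbind(c(17, 1, 1, 1), c(1, 17, 1, 1), c(1, 1, 17, 1),
                  c(1, 1, 1, 17))
  m <- make_motif(counts)
  set.seed(5)
  seq <- paste(sample(c("A", "C", "G", "T"), 60, replace = TRUE), collapse = "")
  hits <- scan_sequence(seq, m)
  fwd <- hits[hits$strand == "+", ]
  rev <- hits[hits$strand == "-", ]
  expect_equal(fwd$score[order(fwd$offset)], rev$score[order(rev$offset)],
               tolerance = 1e-12)
})

test_that("scanning matches a naive per-position oracle on random sequence", {
  set.seed(17)
  counts <- sapply(1:7, function(k) rmultinom(1, 40, runif(4))[, 1])
  m <- make_motif(counts)
  seq <- paste(sample(c("A", "C", "G", "T"), 1100, replace = TRUE),
               collapse = "")
  # embed some Ns to exercise the drop rule
  seq <- paste0(substr(seq, 1, 400), "NN", substr(seq, 403, 1100))
  hits <- scan_sequence(seq, m)
  orc <- oracle_scan(seq, m$logodds)
  orc <- orc[is.finite(orc$score), ]
  key <- function(d) d[order(d$offset, d$strand), ]
  expect_equal(key(hits)$score, key(orc)$score, tolerance = 1e-9)
  expect_equal(key(hits)$offset, key(orc)$offset)
})

test_that("sequences shorter than the motif yield no windows", {
  m <- make_motif(cbind(c(17, 1, 1, 1), c(17, 1, 1, 1), c(17, 1, 1, 1)))
  expect_equal(nrow(scan_sequence("AC", m)), 0)
})

test_that("rank thresholds follow the order-statistic and tie rules", {
  expect_equal(calibrate_rank_threshold(c(9, 8, 7, 6, 5), rank = 3), 7)
  expect_equal(calibrate_rank_threshold(c(5, 5, 5, 5), rank = 2), 5)
  # fewer sites than the rank: minimum score
  expect_equal(calibrate_rank_threshold(c(4, 2), rank = 2000), 2)
  expect_error(calibrate_rank_threshold(numeric(0)), "empty")
  # full-sort oracle on a large random pool
  set.seed(31)
  pool <- rnorm(10000)
  expect_equal(calibrate_rank_threshold(pool, 2000),
               sort(pool, decreasing = TRUE)[2000])
})

test_that("binding matrix R contains planted consensus sites above threshold", {
  b <- simulate_genome(n_genes = 60, n_motifs = 8, n_causal = 3, seed = 23)
  scan <- build_binding_matrix(b$promoters, b$pwms, top_fraction = 0.06)
  for (mid in b$truth$causal_motif_ids) {
    hosts <- unique(b$truth$plants$gene_id[b$truth$plants$motif_id == mid])
    expect_true(all(scan$R[hosts, mid] > 0))
  }
  # every nonzero entry respects the motif's threshold
  for (j in colnames(scan$R)) {
    nz <- scan$R[, j][scan$R[, j] > 0]
    if (length(nz)) expect_true(all(nz >= scan$thresholds[j] - 1e-12))
  }
})

test_that("gene order permutations permute R's rows and nothing else", {
  b <- simulate_genome(n_genes = 40, n_motifs = 6, n_causal = 2, seed = 29)
  s1 <- build_binding_matrix(b$promoters, b$pwms, rank = 50)
  set.seed(1); perm <- sample(length(b$promoters))
  s2 <- build_binding_matrix(b$promoters[perm], b$pwms, rank = 50)
  expect_equal(s2$R, s1$R[perm, ])
  expect_equal(s2$thresholds, s1$thresholds)
})

test_that("rank = 1 keeps only each motif's single best site (or ties)", {
  b <- simulate_genome(n_genes = 30, n_motifs = 5, n_causal = 0, seed = 37)
  scan <- build_binding_matrix(b$promoters, b$pwms, rank = 1)
  for (j in colnames(scan$R)) {
    nz <- scan$R[, j][scan$R[, j] > 0]
    expect_true(all(abs(nz - max(nz)) < 1e-12))
  }
})

test_that("per-gene site collapse never exceeds the pooled passing count", {
  b <- simulate_genome(n_genes = 50, n_motifs = 6, n_causal = 2, seed = 41)
  scan <- build_binding_matrix(b$promoters, b$pwms, top_fraction = 0.06)
  pooled <- table(scan$sites$motif_id)
  for (j in names(pooled)) {
    expect_lte(sum(scan$R[, j] > 0), pooled[[j]])
  }
})

test_that("interval masking keeps only fully contained sites", {
  b <- simulate_genome(n_genes = 50, n_motifs = 6, n_causal = 2, seed = 43)
  scan <- build_binding_matrix(b$promoters, b$pwms, top_fraction = 0.06)
  Rm <- mask_binding_matrix(scan, -400, 200)
  w <- scan$motif_widths[scan$sites$motif_id]
  tss_start <- scan$sites$offset - 600
  inwin <- tss_start >= -400 & (tss_start + w) <= 200
  kept <- scan$sites[inwin, ]
  # every masked nonzero entry is witnessed by a contained site and vice versa
  expect_equal(sum(Rm > 0),
               nrow(unique(kept[, c("gene_id", "motif_id")])))
  expect_true(all(Rm[cbind(kept$gene_id, kept$motif_id)] >= kept$score))
  # full-window mask is the identity
  expect_equal(mask_binding_matrix(scan, -600, 500), scan$R)
})
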