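test_that("the TSS interval grid expands (-400,+200) to (-600,+500) in 12 steps", {
  grid <- make_interval_grid()
  expect_equal(nrow(grid), 12)
  expect_equal(c(grid$upstream[1], grid$downstream[1]), c(-400, 200))
  expect_equal(c(grid$upstream[12], grid$downstream[12]), c(-600, 500))
  expect_setequal(unique(grid$upstream), c(-400, -500, -600))
  expect_setequal(unique(grid$downstream), c(200, 300, 400, 500))
  expect_equal(sort(unique(-grid$upstream + grid$downstream)),
               seq(600, 1100, by = 100))
})

test_that("the response filter drops genes under the combined-read minimum", {
  quant <- data.frame(gene_id = paste0("g", 1:6),
                      q1 = c(4, 5, 3, 10, 0, 100),
                      q2 = c(0, 0, 3, 10, 0, 1),
                      reads1 = c(4, 5, 3, 10, 0, 100),
                      reads2 = c(0, 0, 3, 10, 0, 1))
  resp <- build_response(quant, min_reads = 5)
  expect_identical(resp$gene_id, c("g2", "g3", "g4", "g6"))
  # equal quantities give P = 0
  expect_equal(resp$P[resp$gene_id == "g4"], 0)
  expect_equal(resp$P[resp$gene_id == "g3"], 0)
  expect_error(build_response(quant[5, ]), "no genes")
})

test_that("exhaustive RC equals the brute-force all-subsets oracle", {
  set.seed(51)
  n <- 40; m <- 6; k <- 2
  R <- matrix(rbinom(n * m, 1, 0.4) * runif(n * m, 5, 15), n, m,
              dimnames = list(NULL, sprintf("M%02d", 1:m)))
  P <- rnorm(n)
  subsets <- utils::combn(m, k)
  rc <- rc_score(R, P, k = k, alpha = 5, exhaustive = TRUE)
  orc <- oracle_rc(R, P, subsets, alpha = 5)
  expect_equal(rc$rc, unname(orc), tolerance = 1e-8)
  expect_equal(rc$n_selected, rep(choose(m - 1, k - 1), m))
})

test_that("alpha = 0 reduces RC to the selection count", {
  set.seed(52)
  R <- matrix(runif(200), 20, 10, dimnames = list(NULL, paste0("M", 1:10)))
  P <- rnorm(20)
  rc <- rc_score(R, P, k = 3, n_iter = 500, alpha = 0, seed = 9)
  expect_equal(rc$rc, rc$n_selected)
  expect_equal(sum(rc$n_selected), 500 * 3)
})

test_that("sampled RC converges to the enumeration ranking", {
  set.seed(53)
  n <- 60; m <- 12; k <- 2
  R <- matrix(rbinom(n * m, 1, 0.4) * runif(n * m, 5, 15), n, m,
              dimnames = list(NULL, sprintf("M%02d", 1:m)))
  # graded effects across all motifs keep the RC spectrum free of near-ties,
  # which is what a rank-correlation convergence check needs
  beta <- seq(0.3, 0.02, length.out = m)
  P <- as.numeric(R %*% beta) + rnorm(n, sd = 0.5)
  exact <- rc_score(R, P, k = k, alpha = 5, exhaustive = TRUE)
  sampled <- rc_score(R, P, k = k, n_iter = 1e4, alpha = 5, seed = 1)
  expect_gte(cor(exact$rc, sampled$rc, method = "spearman"), 0.95)
})

test_that("a perfect predictor motif attains the maximum RC", {
  set.seed(54)
  n <- 50; m <- 8
  R <- matrix(rbinom(n * m, 1, 0.5) * 10, n, m,
              dimnames = list(NULL, paste0("M", 1:m)))
  P <- 0.3 * R[, 4]          # exact linear function of column 4
  rc <- rc_score(R, P, k = 2, alpha = 2, exhaustive = TRUE, eps_guard = 1e-12)
  expect_equal(which.max(rc$rc), 4L)
})

test_that("RC is reproducible under a seed and equivariant to motif relabeling", {
  set.seed(55)
  R <- matrix(runif(300), 30, 10, dimnames = list(NULL, paste0("M", 1:10)))
  P <- rnorm(30)
  a <- rc_score(R, P, k = 3, n_iter = 2000, seed = 77)
  b <- rc_score(R, P, k = 3, n_iter = 2000, seed = 77)
  expect_identical(a, b)
  # permuting columns permutes RC identically (exhaustive mode)
  perm <- sample(10)
  r1 <- rc_score(R, P, k = 2, exhaustive = TRUE)
  r2 <- rc_score(R[, perm], P, k = 2, exhaustive = TRUE)
  expect_equal(r2$rc[match(r1$motif_id, r2$motif_id)], r1$rc,
               tolerance = 1e-10)
})

test_that("candidate selection keeps ceil(fraction * m) motifs, ties by id", {
  rc <- data.frame(motif_id = sprintf("M%02d", 1:20),
                   rc = c(rep(5, 3), rep(1, 17)), n_selected = 1)
  expect_identical(select_candidates(rc, 0.10), c("M01", "M02"))
  rc460 <- data.frame(motif_id = sprintf("M%03d", 1:460),
                      rc = seq(460, 1), n_selected = 1)
  expect_length(select_candidates(rc460, 0.10), 46)
})

test_that("stepwise recovers a noiseless linear model exactly", {
  set.seed(56)
  n <- 200; m <- 10
  R <- matrix(rbinom(n * m, 1, 0.4) * runif(n * m, 8, 12), n, m,
              dimnames = list(NULL, sprintf("M%02d", 1:m)))
  P <- 2.0 * R[, 3] - 1.5 * R[, 7]
  # exact fits trigger the "essentially perfect fit" note from summary.lm
  fit <- suppressWarnings(stepwise_finalize(R, P, alpha_remove = 0.01))
  expect_setequal(fit$retained, c("M03", "M07"))
  expect_equal(unname(fit$coefficients[c("M03", "M07")]), c(2.0, -1.5),
               tolerance = 1e-6)
})

test_that("stepwise retains nothing on pure noise at roughly the alpha level", {
  set.seed(57)
  retained <- replicate(100, {
    R <- matrix(rbinom(200 * 10, 1, 0.4) * 10, 200, 10,
                dimnames = list(NULL, sprintf("M%02d", 1:10)))
    length(stepwise_finalize(R, rnorm(200), alpha_remove = 0.01)$retained)
  })
  expect_lt(mean(retained), 1)
})

test_that("a single perfect candidate is retained with p ~ 0", {
  set.seed(58)
  R <- matrix(rbinom(100, 1, 0.5) * 10, 100, 1, dimnames = list(NULL, "M01"))
  P <- 0.5 * R[, 1] + rnorm(100, sd = 1e-8)
  fit <- stepwise_finalize(R, P)
  expect_identical(fit$retained, "M01")
  expect_lt(fit$pvalues[["M01"]], 1e-20)
})

test_that("exactly collinear candidates are reduced, later id dropped", {
  set.seed(59)
  base <- rbinom(100, 1, 0.5) * 10
  R <- cbind(M01 = base, M02 = base, M03 = rbinom(100, 1, 0.5) * 10)
  P <- 0.3 * base + rnorm(100, sd = 0.1)
  fit <- stepwise_finalize(R, P)
  expect_identical(fit$dropped_collinear, "M02")
  expect_true("M01" %in% fit$retained)
})

test_that("alpha_remove = 1 keeps the full candidate set", {
  set.seed(60)
  R <- matrix(rbinom(300, 1, 0.5) * 10, 100, 3,
              dimnames = list(NULL, c("M01", "M02", "M03")))
  fit <- stepwise_finalize(R, rnorm(100), alpha_remove = 1)
  expect_setequal(fit$retained, c("M01", "M02", "M03"))
})

test_that("a one-interval grid reduces the two-step run to a single model", {
  b <- simulate_genome(n_genes = 120, n_motifs = 12, n_causal = 2, seed = 61,
                       effect_sizes = c(2, -2), sigma = 0.1)
  norm <- lowess_normalize(b$control, b$treatment)
  scan <- build_binding_matrix(b$promoters, b$pwms, top_fraction = 0.06)
  grid1 <- make_interval_grid()[12, ]          # the full (-600, +500) window
  rep1 <- run_two_step(scan, norm, b$annotation, grid = grid1, k = 3,
                       n_iter = 2e4, fraction = 0.25, seed = 5)
  expect_identical(rep1$merged, sort(rep1$intervals[[1]]$model$retained))
  expect_equal(dim(rep1$coefficients), c(12L, 1L))

  # determinism: identical seed and inputs give identical reports
  rep2 <- run_two_step(scan, norm, b$annotation, grid = grid1, k = 3,
                       n_iter = 2e4, fraction = 0.25, seed = 5)
  expect_identical(rep1, rep2)
})

test_that("a motif planted only upstream survives only unmasked intervals", {
  set.seed(62)
  # plant one motif's consensus exclusively at window offsets 0..100,
  # i.e. TSS -600..-500, in an otherwise motif-free gene set
  b <- simulate_genome(n_genes = 200, n_motifs = 10, n_causal = 0, seed = 63)
  widths <- vapply(b$pwms$motifs, `[[`, 0L, "width")
  mid <- names(which.max(widths))
  w <- widths[[mid]]
  consensus <- paste(c("A", "C", "G", "T")[apply(b$pwms$motifs[[mid]]$freq, 2,
                                                 which.max)], collapse = "")
  hosts <- sample(names(b$promoters), 40)
  for (g in hosts) {
    off <- sample(0:(100 - w), 1)
    s <- b$promoters[[g]]
    substr(s, off + 1, off + w) <- consensus
    b$promoters[[g]] <- s
  }
  scan <- build_binding_matrix(b$promoters, b$pwms, top_fraction = 0.06)
  # restrict to hosts whose passing sites for mid all lie upstream of -500,
  # guarding against rare chance consensus matches elsewhere
  sites <- scan$sites[scan$sites$motif_id == mid, ]
  upstream_only <- setdiff(hosts,
                           sites$gene_id[sites$offset + w > 100])
  expect_gt(length(upstream_only), 10)
  masked_out <- mask_binding_matrix(scan, -400, 200)   # excludes -600..-500
  masked_in <- mask_binding_matrix(scan, -600, 300)
  expect_equal(sum(masked_out[upstream_only, mid] > 0), 0)
  expect_true(all(masked_in[upstream_only, mid] > 0))
})

test_that("motif pattern tables group by TF and flag sign conflicts", {
  cm <- matrix(0, 4, 2, dimnames = list(c("m1", "m2", "m3", "m4"),
                                        c("i1", "i2")))
  cm["m1", ] <- c(1, 2)        # TFa, consistent alone
  cm["m2", ] <- c(1, 0)        # TFb
  cm["m3", ] <- c(-1, 2)       # TFb: conflicting sign with m2 in i1
  report <- structure(list(
    coefficients = cm, grid = make_interval_grid()[1:2, ],
    tf_map = list(TFa = "m1", TFb = c("m2", "m3"), TFc = "m4")),
    class = "prediction_report")
  tab <- motif_pattern_table(report)
  expect_equal(nrow(tab), 3)    # m4 never retained
  expect_true(all(tab$consistent[tab$tf_name == "TFa"]))
  expect_false(any(tab$consistent[tab$tf_name == "TFb"]))
})
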