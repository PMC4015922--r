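tf_map4 <- list(TF1 = "m1", TF2 = "m2", TF3 = "m3", TF4 = "m4")

test_that("co-occurrence counting matches perfect-overlap and disjoint cases", {
  R <- matrix(0, 10, 2, dimnames = list(paste0("g", 1:10), c("m1", "m2")))
  R[1:7, 1] <- 5; R[1:7, 2] <- 3
  cc <- count_cooccurrence(R, tf_map4[1:2])
  expect_equal(cc$Int["TF1", "TF2"], 7)
  R[, 2] <- 0; R[8:10, 2] <- 1
  cc2 <- count_cooccurrence(R, tf_map4[1:2])
  expect_equal(cc2$Int["TF1", "TF2"], 0)
  expect_error(count_cooccurrence(R, tf_map4[1:2], c("TF1", "TFX")), "TFX")
})

test_that("the full Int matrix equals a nested-loop brute force", {
  set.seed(71)
  R <- matrix(rbinom(200, 1, 0.4) * runif(200, 1, 10), 50, 4,
              dimnames = list(paste0("g", 1:50), paste0("m", 1:4)))
  cc <- count_cooccurrence(R, tf_map4)
  orc <- oracle_cooccurrence(R > 0)
  dimnames(orc) <- dimnames(cc$Int)
  diag(orc) <- NA
  expect_equal(cc$Int, orc)
  expect_equal(cc$margins, rowSums(orc, na.rm = TRUE))
})

test_that("a TF binds through any of its motifs", {
  R <- matrix(0, 5, 3, dimnames = list(paste0("g", 1:5),
                                       c("m1", "m2", "m3")))
  R[1:2, 1] <- 1; R[3:4, 2] <- 1; R[4:5, 3] <- 1
  cc <- count_cooccurrence(R, list(TFa = c("m1", "m2"), TFb = "m3"))
  expect_equal(unname(cc$counts["TFa"]), 4)       # g1..g4
  expect_equal(cc$Int["TFa", "TFb"], 1)           # g4
})

test_that("SIS follows the -log10(p) * (ratio sum) formula", {
  # construct counts with known margins, then verify against the formula
  # using the pair's own Fisher p
  set.seed(72)
  X <- simulate_cooccurrence(100, c(m1 = 0.4, m2 = 0.3, m3 = 0.5), seed = 72)
  cc <- count_cooccurrence(X, list(T1 = "m1", T2 = "m2", T3 = "m3"))
  e <- sis_score(cc, "T1", "T2")
  p_or <- oracle_fisher(e$int, cc$counts[["T2"]] - e$int,
                        cc$counts[["T1"]] - e$int,
                        100 - cc$counts[["T1"]] - cc$counts[["T2"]] + e$int)
  sis_or <- (-log10(p_or)) * (e$int / cc$margins[["T1"]] +
                              e$int / cc$margins[["T2"]])
  expect_equal(e$sis, sis_or, tolerance = 1e-10)
  # zero overlap means zero SIS regardless of p
  expect_equal(e$sis * 0, 0)
})

test_that("SIS is symmetric and zero on zero overlap or undefined margins", {
  R <- matrix(0, 20, 3, dimnames = list(paste0("g", 1:20),
                                        c("m1", "m2", "m3")))
  R[1:8, 1] <- 1; R[5:12, 2] <- 1     # m3 binds nothing
  cc <- count_cooccurrence(R, list(T1 = "m1", T2 = "m2", T3 = "m3"))
  a <- sis_score(cc, "T1", "T2"); b <- sis_score(cc, "T2", "T1")
  expect_equal(a$sis, b$sis)
  expect_equal(sis_score(cc, "T1", "T3")$sis, 0)
})

test_that("the SIS matrix matches the composed enumeration + formula oracle", {
  set.seed(73)
  p <- stats::setNames(runif(6, 0.2, 0.6), paste0("m", 1:6))
  X <- simulate_cooccurrence(100, p, seed = 73)
  tfm <- stats::setNames(as.list(paste0("m", 1:6)), paste0("T", 1:6))
  cc <- count_cooccurrence(X, tfm)
  edges <- sis_edges(cc)
  expect_equal(nrow(edges), choose(6, 2))
  for (r in seq_len(nrow(edges))) {
    i <- edges$tf_i[r]; j <- edges$tf_j[r]
    ci <- cc$counts[[i]]; cj <- cc$counts[[j]]; int <- cc$Int[i, j]
    p_or <- oracle_fisher(int, ci - int, cj - int, 100 - ci - cj + int)
    sis_or <- if (cc$margins[[i] ] > 0 && cc$margins[[j]] > 0) {
      (-log10(p_or)) * (int / cc$margins[[i]] + int / cc$margins[[j]])
    } else 0
    expect_equal(edges$sis[r], sis_or, tolerance = 1e-10)
    expect_equal(edges$pval[r], p_or, tolerance = 1e-10)
  }
})

test_that("network thresholding keeps mean + k*SD outliers and reports hubs", {
  edges <- data.frame(tf_i = c("A", "A", "A", "B"),
                      tf_j = c("B", "C", "D", "C"),
                      int = 1, pval = 0.5, sis = c(0, 0, 0, 10))
  net <- build_network(edges, k_sd = 1)
  expect_equal(net$threshold, mean(edges$sis) + sd(edges$sis))
  expect_equal(nrow(net$edges), 1)
  expect_identical(net$edges$tf_j, "C")
  # k_sd = 0 keeps everything at or above the mean
  net0 <- build_network(edges, k_sd = 0)
  expect_equal(nrow(net0$edges), 1)     # only the 10 is >= mean 2.5
  # degree conservation
  expect_equal(sum(net$hubs$degree), 2 * nrow(net$edges))
  # all-equal scores give an empty network with warning
  edges$sis <- 1
  expect_warning(nete <- build_network(edges), "equal")
  expect_equal(nrow(nete$edges), 0)
})

test_that("the network is invariant under TF relabeling", {
  set.seed(74)
  p <- stats::setNames(runif(5, 0.3, 0.6), paste0("m", 1:5))
  X <- simulate_cooccurrence(80, p, seed = 74)
  tfm <- stats::setNames(as.list(paste0("m", 1:5)), paste0("T", 1:5))
  cc <- count_cooccurrence(X, tfm)
  net1 <- build_network(sis_edges(cc))
  perm <- c(3, 1, 4, 5, 2)
  tfm2 <- tfm[perm]
  cc2 <- count_cooccurrence(X, tfm2)
  net2 <- build_network(sis_edges(cc2))
  canon <- function(net) {
    e <- net$edges
    key <- apply(cbind(pmin(e$tf_i, e$tf_j), pmax(e$tf_i, e$tf_j)), 1,
                 paste, collapse = "~")
    sort(paste(key, signif(e$sis, 10)))
  }
  expect_identical(canon(net1), canon(net2))
  expect_equal(net1$threshold, net2$threshold)
})

test_that("graphml export writes a parseable undirected graph", {
  edges <- data.frame(tf_i = c("A", "B"), tf_j = c("B", "C"),
                      int = c(3, 2), pval = c(0.01, 0.2), sis = c(5, 4))
  net <- build_network(edges, k_sd = 0)
  f <- withr::local_tempfile(fileext = ".graphml")
  write_network_graphml(net, f)
  g <- igraph::read_graph(f, format = "graphml")
  expect_equal(igraph::gorder(g), 3)
  expect_equal(igraph::gsize(g), nrow(net$edges))
})
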