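#' TF co-binding counts over a gene universe
#'
#' A TF binds a gene when any of its motifs has a nonzero entry in the
#' binding matrix there. `Int[i, j]` counts genes bound by both TFs; the
#' margin `Int_i.` is the row sum over the other TFs.
#'
#' @param R Genes x motifs binding matrix (typically restricted to the
#'   differential genes).
#' @param tf_map Named list tf_name -> motif ids (as in a `pwm_collection` or
#'   `binding_scan`).
#' @param tfs TFs to include (default: all in `tf_map`); each must own at
#'   least one column of `R`.
#' @return A `cooccurrence_counts`: list with `Int` (symmetric TF x TF
#'   matrix, diagonal NA), `bound` (genes x TFs logical), `counts` (per-TF
#'   bound-gene counts), `margins` (`Int_i.`), `n_genes`.
#' @export
count_cooccurrence <- function(R, tf_map, tfs = names(tf_map)) {
  missing_tf <- setdiff(tfs, names(tf_map))
  if (length(missing_tf)) {
    stop("TF(s) absent from the motif map: ", paste(missing_tf, collapse = ", "))
  }
  bound <- vapply(tfs, function(tf) {
    cols <- intersect(tf_map[[tf]], colnames(R))
    if (!length(cols)) stop("TF '", tf, "' has no motif column in the matrix")
    rowSums(R[, cols, drop = FALSE] != 0) > 0
  }, logical(nrow(R)))
  colnames(bound) <- tfs
  Int <- crossprod(bound * 1)
  diag(Int) <- NA
  margins <- rowSums(Int, na.rm = TRUE)
  structure(list(Int = Int, bound = bound,
                 counts = colSums(bound), margins = margins,
                 n_genes = nrow(R)),
            class = "cooccurrence_counts")
}

#' Significant interaction score (SIS) for one TF pair
#'
#' `SIS_ij = (-log10 P_ij) * (Int_ij / Int_i. + Int_ij / Int_j.)`, where
#' `P_ij` is the two-sided Fisher exact p-value of the 2x2 co-binding table
#' over the gene universe. Pairs with an undefined margin (`Int_i. = 0`)
#' score 0 by convention.
#'
#' @param counts A `cooccurrence_counts`.
#' @param tf_i,tf_j TF names.
#' @return list(tf_i, tf_j, int, pval, sis).
#' @export
sis_score <- function(counts, tf_i, tf_j) {
  stopifnot(inherits(counts, "cooccurrence_counts"))
  # canonical pair order in the Fisher table makes sis(i, j) and sis(j, i)
  # bit-identical, not just equal in exact arithmetic
  ii <- min(tf_i, tf_j); jj <- max(tf_i, tf_j)
  int_ij <- counts$Int[ii, jj]
  ci <- counts$counts[[ii]]; cj <- counts$counts[[jj]]
  n <- counts$n_genes
  pval <- fisher_pvalue(int_ij, ci - int_ij, cj, n - cj)
  mi <- counts$margins[[tf_i]]; mj <- counts$margins[[tf_j]]
  sis <- if (mi > 0 && mj > 0) {
    (-log10(max(pval, .Machine$double.xmin))) * (int_ij / mi + int_ij / mj)
  } else 0
  list(tf_i = tf_i, tf_j = tf_j, int = int_ij, pval = pval, sis = sis)
}

#' All pairwise SIS edges
#' @param counts A `cooccurrence_counts`.
#' @return data.frame tf_i, tf_j, int, pval, sis (one row per unordered pair).
#' @export
sis_edges <- function(counts) {
  tfs <- colnames(counts$Int)
  if (length(tfs) < 2L) stop("need at least 2 TFs")
  pairs <- utils::combn(tfs, 2L)
  rows <- apply(pairs, 2L, function(p) sis_score(counts, p[1L], p[2L]))
  data.frame(tf_i = vapply(rows, `[[`, "", "tf_i"),
             tf_j = vapply(rows, `[[`, "", "tf_j"),
             int = vapply(rows, `[[`, 0, "int"),
             pval = vapply(rows, `[[`, 0, "pval"),
             sis = vapply(rows, `[[`, 0, "sis"),
             stringsAsFactors = FALSE)
}

#' Threshold SIS edges into a TF interaction network
#'
#' Retains edges with `SIS >= mean(SIS) + k_sd * dispersion(SIS)` over all
#' pairs (SD by default, literal variance via `dispersion = "variance"`), and
#' reports hub TFs by descending degree.
#'
#' @param edges data.frame from [sis_edges()].
#' @param k_sd Dispersion multiplier (default 1).
#' @param dispersion `"sd"` or `"variance"`.
#' @return A `tf_network`: list with `edges` (retained), `all_edges`,
#'   `threshold`, `nodes`, `hubs` (data.frame tf, degree, descending).
#' @export
build_network <- function(edges, k_sd = 1, dispersion = c("sd", "variance")) {
  dispersion <- match.arg(dispersion)
  stopifnot(nrow(edges) >= 1)
  disp <- if (dispersion == "sd") stats::sd(edges$sis) else stats::var(edges$sis)
  if (is.na(disp)) disp <- 0
  thr <- mean(edges$sis) + k_sd * disp
  keep <- edges[edges$sis >= thr, , drop = FALSE]
  if (disp == 0 && k_sd > 0) {
    warning("all SIS scores equal; empty edge set")
    keep <- edges[0, , drop = FALSE]
  }
  nodes <- sort(unique(c(edges$tf_i, edges$tf_j)))
  deg <- table(factor(c(keep$tf_i, keep$tf_j), levels = nodes))
  hubs <- data.frame(tf = names(deg), degree = as.integer(deg),
                     stringsAsFactors = FALSE)
  hubs <- hubs[order(-hubs$degree, hubs$tf), , drop = FALSE]
  structure(list(edges = keep, all_edges = edges, threshold = thr,
                 nodes = nodes, hubs = hubs, k_sd = k_sd),
            class = "tf_network")
}

#' @export
print.tf_network <- function(x, ...) {
  cat(sprintf("tf_network: %d node(s), %d/%d edge(s) >= threshold %.4g\n",
              length(x$nodes), nrow(x$edges), nrow(x$all_edges), x$threshold))
  invisible(x)
}

#' Export a TF network as GraphML
#' @param network A `tf_network`.
#' @param path Output path.
#' @export
write_network_graphml <- function(network, path) {
  g <- igraph::graph_from_data_frame(
    network$edges[, c("tf_i", "tf_j", "sis", "pval", "int")],
    directed = FALSE,
    vertices = data.frame(name = network$nodes))
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
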