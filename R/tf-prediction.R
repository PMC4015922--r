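#' The 12-interval TSS window grid
#'
#' All windows from (-400, +200) to (-600, +500), expanding each end
#' independently in 100 bp steps: upstream in \{-400, -500, -600\} (outer,
#' increasing magnitude), downstream in \{+200, +300, +400, +500\} (inner,
#' ascending), giving 12 intervals in a fixed order.
#'
#' @return data.frame interval_id, upstream, downstream.
#' @export
make_interval_grid <- function() {
  ups <- c(-400L, -500L, -600L)
  downs <- c(200L, 300L, 400L, 500L)
  grid <- expand.grid(downstream = downs, upstream = ups,
                      KEEP.OUT.ATTRS = FALSE)[, c("upstream", "downstream")]
  grid$interval_id <- sprintf("%d:%+d", grid$upstream, grid$downstream)
  grid[, c("interval_id", "upstream", "downstream")]
}

#' Per-gene log2 binding change response
#'
#' Drops genes whose combined raw reads over the window fall below
#' `min_reads`, then computes `P = log2((S_t + 1) / (S_c + 1))` from the
#' adjusted promoter quantities of the survivors.
#'
#' @param quant data.frame from [quantify_promoters()] (gene_id, q1, q2,
#'   reads1, reads2).
#' @param min_reads Minimum combined raw reads (default 5); genes with
#'   `reads1 + reads2 < min_reads` are removed.
#' @return data.frame gene_id, P, in input gene order.
#' @export
build_response <- function(quant, min_reads = 5) {
  keep <- quant$reads1 + quant$reads2 >= min_reads
  if (!any(keep)) stop("no genes survive the read filter")
  q <- quant[keep, , drop = FALSE]
  data.frame(gene_id = q$gene_id,
             P = log2((q$q2 + 1) / (q$q1 + 1)),
             stringsAsFactors = FALSE)
}

#' Regulatory-capacity (RC) scores from a random-subset regression ensemble
#'
#' Each iteration samples `k` distinct motif columns of `R` uniformly, fits
#' ordinary least squares of `P` on those columns plus an intercept, takes the
#' residual sum of squares `E`, and adds `1 / max(E, eps_guard)^alpha` to each
#' sampled motif's RC. In `exhaustive` mode every k-subset is evaluated
#' exactly once instead.
#'
#' @param R Genes x motifs matrix (restricted to the gene universe under
#'   study). Columns that are all zero are kept but flagged.
#' @param P Response vector aligned with `R`'s rows.
#' @param k Subset size (default 5).
#' @param n_iter Number of sampled subsets (default 1e6; the pipeline's fast
#'   mode uses 1e5).
#' @param alpha Power on 1/E (default 5).
#' @param seed Integer seed (applied via `set.seed`; required in sampling
#'   mode for reproducibility).
#' @param exhaustive Evaluate all `choose(ncol(R), k)` subsets once.
#' @param eps_guard Lower floor on E before taking the power, guarding exact
#'   fits (default 1e-12).
#' @return data.frame motif_id, rc, n_selected, sorted as `R`'s columns, with
#'   the call parameters attached as attributes.
#' @export
rc_score <- function(R, P, k = 5, n_iter = 1e6, alpha = 5, seed = NULL,
                     exhaustive = FALSE, eps_guard = 1e-12) {
  stopifnot(is.matrix(R), nrow(R) == length(P), nrow(R) > k, ncol(R) >= k)
  if (exhaustive) {
    subsets <- utils::combn(ncol(R), k)
    fit <- rc_enumerate_cpp(R, P, subsets, alpha, eps_guard)
  } else {
    if (!is.null(seed)) set.seed(seed)
    fit <- rc_sample_cpp(R, P, k, n_iter, alpha, eps_guard)
  }
  out <- data.frame(motif_id = colnames(R), rc = as.numeric(fit$rc),
                    n_selected = as.numeric(fit$count),
                    stringsAsFactors = FALSE)
  attr(out, "k") <- k
  attr(out, "alpha") <- alpha
  attr(out, "n_iter") <- if (exhaustive) ncol(subsets) else n_iter
  attr(out, "exhaustive") <- exhaustive
  out
}

#' Top-fraction RC candidates
#'
#' The `ceiling(fraction * n_motifs)` motifs with the highest RC; ties at the
#' boundary are broken by motif id (lexicographic) for determinism.
#'
#' @param rc RC table from [rc_score()].
#' @param fraction Fraction of motifs to keep (default 0.10).
#' @return Character vector of candidate motif ids, descending RC.
#' @export
select_candidates <- function(rc, fraction = 0.10) {
  stopifnot(nrow(rc) >= 1, fraction > 0)
  n_keep <- min(nrow(rc), as.integer(ceiling(fraction * nrow(rc))))
  ord <- order(-rc$rc, rc$motif_id)
  rc$motif_id[ord[seq_len(n_keep)]]
}

#' Backward stepwise finalization of candidate motifs
#'
#' Fits the full linear model of `P` on all candidate columns plus an
#' intercept, then repeatedly removes the variable with the largest
#' coefficient p-value while any p-value exceeds `alpha_remove`, refitting
#' after each removal. Exactly collinear candidates are reduced before
#' fitting by dropping the later (by motif id) members of each dependent
#' group. The retained set may be empty.
#'
#' @param R Genes x motifs matrix restricted to the candidate columns (or a
#'   larger matrix together with `candidates`).
#' @param P Response vector.
#' @param candidates Candidate motif ids (default: all columns of `R`).
#' @param alpha_remove Removal / final significance threshold on the
#'   per-coefficient t-test p-value (default 0.01).
#' @return A `stepwise_model`: list with `retained` (motif ids),
#'   `coefficients`, `pvalues` (named, retained motifs), `intercept`,
#'   `sigma2` (residual variance), `candidates`, `dropped_collinear`.
#' @export
stepwise_finalize <- function(R, P, candidates = colnames(R),
                              alpha_remove = 0.01) {
  X <- R[, candidates, drop = FALSE]
  stopifnot(nrow(X) == length(P))
  # drop exactly collinear columns (later id loses)
  X <- X[, order(colnames(X)), drop = FALSE]
  qrX <- qr(cbind(1, X))
  dropped <- character(0)
  if (qrX$rank < ncol(X) + 1L) {
    keep_idx <- qrX$pivot[seq_len(qrX$rank)]
    keep_idx <- setdiff(keep_idx, 1L) - 1L   # column indices into X
    dropped <- setdiff(colnames(X), colnames(X)[keep_idx])
    X <- X[, sort(keep_idx), drop = FALSE]
  }
  current <- colnames(X)[order(match(colnames(X), candidates))]
  repeat {
    if (!length(current)) break
    fit <- stats::lm(P ~ ., data = as.data.frame(X[, current, drop = FALSE]))
    coefs <- summary(fit)$coefficients
    rows <- rownames(coefs) != "(Intercept)"
    pv <- coefs[rows, 4L]
    names(pv) <- current[match(rownames(coefs)[rows],
                               make.names(current))]
    if (all(is.finite(pv)) && max(pv) <= alpha_remove) break
    worst <- names(pv)[which.max(ifelse(is.finite(pv), pv, Inf))]
    current <- setdiff(current, worst)
  }
  if (length(current)) {
    fit <- stats::lm(P ~ ., data = as.data.frame(X[, current, drop = FALSE]))
    coefs <- summary(fit)$coefficients
    rows <- rownames(coefs) != "(Intercept)"
    est <- stats::setNames(coefs[rows, 1L],
                           current[match(rownames(coefs)[rows],
                                         make.names(current))])
    pv <- stats::setNames(coefs[rows, 4L], names(est))
    intercept <- coefs["(Intercept)", 1L]
    sigma2 <- summary(fit)$sigma^2
  } else {
    est <- stats::setNames(numeric(0), character(0))
    pv <- est
    intercept <- mean(P)
    sigma2 <- stats::var(P)
  }
  structure(list(retained = names(est), coefficients = est, pvalues = pv,
                 intercept = intercept, sigma2 = sigma2,
                 candidates = candidates, dropped_collinear = dropped,
                 alpha_remove = alpha_remove),
            class = "stepwise_model")
}

#' @export
print.stepwise_model <- function(x, ...) {
  cat(sprintf("stepwise_model: %d of %d candidates retained (p <= %g)\n",
              length(x$retained), length(x$candidates), x$alpha_remove))
  if (length(x$retained)) {
    print(data.frame(motif_id = x$retained, coefficient = x$coefficients,
                     pvalue = x$pvalues, row.names = NULL))
  }
  invisible(x)
}

#' Run the two-step TF prediction over a TSS interval grid
#'
#' For each grid interval: masks the binding matrix to sites inside the
#' interval, quantifies promoters over the interval, applies the minimum-read
#' filter, scores motifs by the random-subset RC ensemble, keeps the top
#' RC fraction as candidates, and finalizes them by backward stepwise
#' regression. Per-interval finalized sets are merged by union.
#'
#' @param scan A `binding_scan` over the widest window (built with
#'   `keep_sites = TRUE`).
#' @param norm An `ma_norm` paired normalization result.
#' @param annotation Gene annotation data.frame.
#' @param grid Interval grid (default [make_interval_grid()]).
#' @param genes Gene universe (default: all annotated genes). Typically the
#'   differential set from [select_differential()] when one is available and
#'   large enough.
#' @param k,n_iter,alpha,eps_guard RC ensemble parameters, see [rc_score()].
#' @param fraction Candidate fraction, see [select_candidates()].
#' @param alpha_remove Stepwise threshold, see [stepwise_finalize()].
#' @param min_reads Read filter, see [build_response()].
#' @param seed Integer seed; each interval uses a seed derived from it.
#' @param scan_upstream Upstream offset of the scanned window (default -600).
#' @return A `prediction_report`: list with `merged` (union of retained motif
#'   ids), `merged_tfs` (their TF names), `intervals` (per-interval list:
#'   response, rc, candidates, model), `coefficients` (motif x interval
#'   matrix, 0 where not retained), `grid`, `params`.
#' @export
run_two_step <- function(scan, norm, annotation, grid = make_interval_grid(),
                         genes = annotation$gene_id, k = 5, n_iter = 1e6,
                         alpha = 5, fraction = 0.10, alpha_remove = 0.01,
                         min_reads = 5, seed = 1, eps_guard = 1e-12,
                         scan_upstream = -600) {
  stopifnot(inherits(scan, "binding_scan"), inherits(norm, "ma_norm"))
  ann <- annotation[annotation$gene_id %in% genes, , drop = FALSE]
  motif_ids <- colnames(scan$R)
  coef_mat <- matrix(0, nrow = length(motif_ids), ncol = nrow(grid),
                     dimnames = list(motif_ids, grid$interval_id))
  intervals <- vector("list", nrow(grid))
  names(intervals) <- grid$interval_id
  for (g in seq_len(nrow(grid))) {
    u <- grid$upstream[g]; d <- grid$downstream[g]
    iid <- grid$interval_id[g]
    win <- promoter_windows(ann, u, d)
    quant <- quantify_promoters(norm, win)
    resp <- tryCatch(build_response(quant, min_reads), error = function(e) NULL)
    if (is.null(resp) || nrow(resp) <= k + 2L) {
      warning("interval ", iid, ": no usable genes; skipped")
      intervals[[g]] <- list(skipped = TRUE)
      next
    }
    Rg <- mask_binding_matrix(scan, u, d, scan_upstream)[resp$gene_id, ,
                                                         drop = FALSE]
    active <- colSums(Rg != 0) > 0
    if (sum(active) < k) {
      warning("interval ", iid, ": fewer than k active motifs; skipped")
      intervals[[g]] <- list(skipped = TRUE)
      next
    }
    Ract <- Rg[, active, drop = FALSE]
    rc <- rc_score(Ract, resp$P, k = k, n_iter = n_iter, alpha = alpha,
                   seed = stage_seed(seed, paste0("rc:", iid)),
                   eps_guard = eps_guard)
    cand <- select_candidates(rc, fraction)
    cand <- cand[seq_len(min(length(cand), nrow(Ract) - 3L))]
    model <- stepwise_finalize(Ract, resp$P, candidates = cand,
                               alpha_remove = alpha_remove)
    coef_mat[model$retained, g] <- model$coefficients[model$retained]
    intervals[[g]] <- list(skipped = FALSE, response = resp, rc = rc,
                           candidates = cand, model = model)
  }
  retained_sets <- lapply(intervals, function(x) {
    if (isTRUE(x$skipped)) character(0) else x$model$retained
  })
  merged <- sort(unique(unlist(retained_sets)))
  tf_of <- motif_tf_lookup(scan$tf_map)
  structure(list(merged = merged,
                 merged_tfs = sort(unique(unname(tf_of[merged]))),
                 intervals = intervals, coefficients = coef_mat, grid = grid,
                 tf_map = scan$tf_map,
                 params = list(k = k, n_iter = n_iter, alpha = alpha,
                               fraction = fraction,
                               alpha_remove = alpha_remove,
                               min_reads = min_reads, seed = seed)),
            class = "prediction_report")
}

motif_tf_lookup <- function(tf_map) {
  stats::setNames(rep(names(tf_map), lengths(tf_map)), unlist(tf_map))
}

#' @export
print.prediction_report <- function(x, ...) {
  ok <- vapply(x$intervals, function(i) !isTRUE(i$skipped), TRUE)
  cat(sprintf(
    "prediction_report: %d/%d intervals run, %d motif(s) / %d TF(s) merged\n",
    sum(ok), length(ok), length(x$merged), length(x$merged_tfs)))
  invisible(x)
}

#' Per-TF motif-by-interval coefficient table
#'
#' Groups the report's coefficient matrix by TF, one row per motif, one
#' column per interval, with a per-TF sign-consistency flag: a TF is
#' consistent when, in every interval, all of its retained motifs'
#' coefficients share one sign.
#'
#' @param report A `prediction_report`.
#' @param all_motifs Include motifs never retained (default FALSE).
#' @return data.frame tf_name, motif_id, one column per interval, and
#'   `consistent` (logical, repeated within TF).
#' @export
motif_pattern_table <- function(report, all_motifs = FALSE) {
  cm <- report$coefficients
  tf_of <- motif_tf_lookup(report$tf_map)
  keep <- if (all_motifs) rownames(cm) else {
    rownames(cm)[rowSums(cm != 0) > 0]
  }
  if (!length(keep)) {
    return(data.frame(tf_name = character(0), motif_id = character(0)))
  }
  tf <- unname(tf_of[keep])
  out <- data.frame(tf_name = tf, motif_id = keep,
                    stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(cm[keep, , drop = FALSE]))
  consistent <- vapply(split(keep, tf), function(mids) {
    sub <- cm[mids, , drop = FALSE]
    all(apply(sub, 2L, function(col) {
      nz <- col[col != 0]
      length(nz) <= 1L || all(nz > 0) || all(nz < 0)
    }))
  }, TRUE)
  out$consistent <- consistent[out$tf_name]
  out[order(out$tf_name, out$motif_id), , drop = FALSE]
}
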