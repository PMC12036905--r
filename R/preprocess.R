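# Gene screening.
#
# Fixed pipeline order: drop unexpressed genes -> L2-normalize each cell ->
# build four cell-cell similarity graphs (sparse self-representation,
# Pearson, Spearman, cosine) -> compute a Laplacian score per gene on each
# graph -> retain the top-T genes by the harmonic mean of the four scores.

#' Drop genes expressed in no cell
#'
#' @param x Cells x genes matrix.
#' @return The matrix restricted to genes with at least one non-zero
#'   entry; errors if none remain.
#' @export
drop_unexpressed_genes <- function(x) {
  keep <- colSums(x != 0) > 0
  if (!any(keep)) stop("all genes are unexpressed", call. = FALSE)
  x[, keep, drop = FALSE]
}

#' L2-normalize each cell profile
#'
#' Scales every row to unit Euclidean norm, removing expression-scale
#' differences between cells.
#'
#' @param x Cells x genes matrix with no all-zero rows.
#' @return Row-normalized matrix.
#' @export
l2_normalize_rows <- function(x) {
  rn <- sqrt(rowSums(x^2))
  bad <- rn == 0
  if (any(bad))
    stop("cell(s) with all-zero profile cannot be L2-normalized: ",
         paste(rownames(x)[bad] %||% which(bad), collapse = ", "),
         call. = FALSE)
  x / rn
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Four cell-cell similarity graphs
#'
#' Builds symmetric non-negative m x m graphs over cells from a
#' row-normalized expression matrix:
#' * `sparse` — symmetrized magnitudes of L1-penalized least-squares
#'   self-representation coefficients of each cell on all others (lasso
#'   with penalty `penalty_frac * lambda_max` per cell, solved with
#'   glmnet, no intercept, no standardization);
#' * `pearson`, `spearman` — absolute correlation between cell profiles
#'   (Spearman uses midranks for ties);
#' * `cosine` — absolute cosine similarity.
#'
#' Cells with constant profiles get zero Pearson/Spearman rows with a
#' warning.  All diagonals are zero.
#'
#' @param x Row-normalized cells x genes matrix.
#' @param penalty_frac Lasso penalty as a fraction of the per-cell
#'   `lambda_max` (the smallest penalty with an all-zero solution).
#' @return Named list of four m x m matrices.
#' @export
similarity_graphs <- function(x, penalty_frac = 0.1) {
  m <- nrow(x)
  if (m < 3) stop("need at least 3 cells to build similarity graphs",
                  call. = FALSE)
  xt <- t(x)

  pearson <- suppressWarnings(abs(stats::cor(xt)))
  spearman <- suppressWarnings(abs(stats::cor(xt, method = "spearman")))
  if (anyNA(pearson) || anyNA(spearman)) {
    warning("constant cell profile(s): Pearson/Spearman similarities set to 0")
    pearson[is.na(pearson)] <- 0
    spearman[is.na(spearman)] <- 0
  }
  rn <- sqrt(rowSums(x^2))
  cosine <- abs(tcrossprod(x / rn))

  coefs <- matrix(0, m, m)
  n <- ncol(x)
  for (i in seq_len(m)) {
    y <- x[i, ]
    d <- xt[, -i, drop = FALSE]
    lam_max <- max(abs(crossprod(d, y))) / n
    if (lam_max <= 0) next
    lam <- penalty_frac * lam_max
    path <- exp(seq(log(lam_max), log(lam), length.out = 8))
    fit <- glmnet::glmnet(d, y, family = "gaussian", alpha = 1,
                          lambda = path, intercept = FALSE,
                          standardize = FALSE)
    cf <- as.numeric(stats::coef(fit, s = lam))[-1]  # drop intercept slot
    coefs[i, -i] <- cf
  }
  sparse <- (abs(coefs) + abs(t(coefs))) / 2

  out <- list(sparse = sparse, pearson = pearson, spearman = spearman,
              cosine = cosine)
  lapply(out, function(w) { diag(w) <- 0; dimnames(w) <- NULL; w })
}

#' Laplacian score of one feature on a similarity graph
#'
#' With `D = diag(rowSums(w))`, `L = D - w` and the degree-weighted
#' centering `ft = f - (f' D 1 / 1' D 1) 1`, the score is
#' `ft' L ft / ft' D ft` (non-negative).  A feature that is constant on
#' the graph (`ft' D ft = 0`) gets the sentinel `Inf` and is excluded
#' from selection.
#'
#' @param w Symmetric non-negative m x m similarity matrix.
#' @param f Numeric feature vector of length m (a gene's expression over
#'   cells).
#' @return A non-negative scalar, or `Inf` for degenerate features.
#' @export
laplace_score <- function(w, f) {
  if (!is.matrix(w) || nrow(w) != ncol(w))
    stop("similarity matrix must be square", call. = FALSE)
  if (length(f) != nrow(w))
    stop("feature length does not match graph size", call. = FALSE)
  as.numeric(laplace_scores(w, matrix(f, ncol = 1)))
}

# Vectorized Laplacian scores for all columns of a feature matrix.
laplace_scores <- function(w, feats) {
  d <- rowSums(w)
  sd_ <- sum(d)
  if (sd_ <= 0) return(rep(Inf, ncol(feats)))
  centers <- colSums(feats * d) / sd_
  ft <- sweep(feats, 2, centers)
  den <- colSums(ft^2 * d)
  num <- colSums(ft * (d * ft - w %*% ft))
  # A feature constant on the graph leaves den at rounding-noise level
  # relative to its uncentered energy: flag it with the Inf sentinel.
  tot <- colSums(feats^2 * d)
  degenerate <- den <= 1e-15 * pmax(tot, 1e-300)
  ifelse(degenerate, Inf, pmax(num, 0) / den)
}

#' Score genes and retain the top T
#'
#' Computes the four similarity graphs, a Laplacian score per gene on each
#' graph, and their harmonic mean; genes are ranked by the harmonic mean
#' (largest first under the default `direction = "high"`) and the top `t`
#' retained, ties broken by original gene order.  A harmonic mean is
#' defined as 0 whenever any of the four scores is zero or the `Inf`
#' degenerate-gene sentinel, deprioritizing such genes.
#'
#' With `graph_axis = "genes"` the four graphs are built over genes
#' instead (the literal reading of gene-gene similarity) and each gene is
#' scored by its weighted node degree on each graph; the harmonic-mean
#' selection rule is unchanged.
#'
#' @param x Row-normalized cells x genes matrix.
#' @param t Number of genes to retain (`t <=` available genes).
#' @param direction `"high"` keeps the largest harmonic means, `"low"`
#'   the smallest (classic Laplacian-score convention).
#' @param graph_axis `"cells"` (default) or `"genes"`; see Details.
#' @param penalty_frac Passed to [similarity_graphs()].
#' @return List with `matrix` (cells x t) and `scores`, a data frame with
#'   one row per input gene: the four scores, their harmonic mean and
#'   whether the gene was selected.
#' @export
select_top_genes <- function(x, t, direction = c("high", "low"),
                             graph_axis = c("cells", "genes"),
                             penalty_frac = 0.1) {
  direction <- match.arg(direction)
  graph_axis <- match.arg(graph_axis)
  n <- ncol(x)
  if (t > n)
    stop("t = ", t, " exceeds the ", n, " available genes; use t <= ", n,
         call. = FALSE)
  if (t < 1) stop("t must be at least 1", call. = FALSE)

  if (graph_axis == "cells") {
    graphs <- similarity_graphs(x, penalty_frac = penalty_frac)
    scores <- vapply(graphs, function(w) laplace_scores(w, x), numeric(n))
  } else {
    graphs <- similarity_graphs(t(x), penalty_frac = penalty_frac)
    scores <- vapply(graphs, function(w) rowSums(w), numeric(n))
  }

  hm <- apply(scores, 1, function(s) {
    if (any(!is.finite(s)) || any(s <= 0)) 0 else 4 / sum(1 / s)
  })
  ord <- if (direction == "high") order(-hm, seq_len(n)) else
    order(replace(hm, hm == 0, Inf), seq_len(n))
  sel <- sort(ord[seq_len(t)])  # preserve original gene order

  tab <- data.frame(gene_id = colnames(x) %||% paste0("gene_", seq_len(n)),
                    score_sparse = scores[, "sparse"],
                    score_pearson = scores[, "pearson"],
                    score_spearman = scores[, "spearman"],
                    score_cosine = scores[, "cosine"],
                    harmonic_mean = hm,
                    selected = seq_len(n) %in% sel,
                    row.names = NULL)
  list(matrix = x[, sel, drop = FALSE], scores = tab)
}

# Conventional preprocessing used by the DP ablation: library-size
# normalization to the median depth, log1p, top-t genes by variance, then
# L2 row normalization so the network input is on the same scale as the
# main path.
conventional_preprocess <- function(x, t) {
  depth <- rowSums(x)
  if (any(depth == 0)) stop("cell(s) with zero total expression", call. = FALSE)
  xn <- log1p(x / depth * stats::median(depth))
  v <- apply(xn, 2, stats::var)
  t <- min(t, ncol(xn))
  sel <- sort(order(-v, seq_len(ncol(xn)))[seq_len(t)])
  l2_normalize_rows(xn[, sel, drop = FALSE])
}
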