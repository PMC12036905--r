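# End-to-end pipeline: preprocess -> train autoencoder -> enhance ->
# similarity -> spectral clustering.

#' Cluster cells with the full pipeline
#'
#' Runs the complete method on a raw (or normalized) expression matrix:
#' unexpressed genes are dropped and cells L2-normalized; genes are
#' screened by the harmonic mean of four Laplacian scores (or, under the
#' DP ablation, by conventional library-size/log1p/variance
#' preprocessing); the TPGG autoencoder (or ZINB under the TP ablation)
#' learns the self-expression matrix; second-order proximity enhancement
#' (skipped under the ESM ablation) and symmetrization yield the
#' similarity matrix; SVD normalization, a KNN graph and the unnormalized
#' graph Laplacian feed k-means on the spectral embedding.
#'
#' When `t_genes` is at least the number of genes remaining after the
#' unexpressed-gene drop, top-gene selection is the identity (the tie rule
#' preserves gene order), so the similarity graphs and score table are
#' skipped and `scores` is `NULL` in the result.
#'
#' @param x Cells x genes non-negative expression matrix.
#' @param k Number of clusters (the method takes K as an input; it does
#'   not estimate it).
#' @param config A [scpedssc_config()].
#' @param truth Optional reference labels; if supplied, ARI and NMI are
#'   reported in the result.
#' @param keep_matrices Keep the intermediate m x m matrices
#'   (self-expression, enhanced, similarity) in the result.
#' @return List of class `"scpedssc_result"` with `labels` (a
#'   [partition()]), `losses`, `scores` (gene score table when Laplacian
#'   screening ran), `metrics` (when `truth` given) and, if requested,
#'   `m_matrix`, `m_tilde`, `m_hat`, `embedding`.
#' @export
scpedssc <- function(x, k, config = scpedssc_config(), truth = NULL,
                     keep_matrices = TRUE) {
  if (k < 1 || k > nrow(x)) stop("k must lie in [1, number of cells]",
                                 call. = FALSE)
  x <- expression_matrix(as.matrix(x))
  x <- drop_unexpressed_genes(x)
  scores <- NULL
  if (config$use_laplace_preprocess) {
    xn <- l2_normalize_rows(x)
    if (config$t_genes >= ncol(xn)) {
      # selection with t >= available genes is the identity (the tie rule
      # preserves gene order), so the score computation is skipped and no
      # score table is produced
      xp <- xn
    } else {
      sel <- select_top_genes(xn, t = config$t_genes,
                              direction = config$score_direction,
                              graph_axis = config$graph_axis)
      xp <- sel$matrix
      scores <- sel$scores
    }
  } else {
    xp <- conventional_preprocess(x, config$t_genes)
  }

  fit <- train_autoencoder(xp, config)
  m_tilde <- if (config$use_enhancement) enhance(fit$m_matrix) else
    fit$m_matrix
  m_hat <- build_similarity(m_tilde)

  s <- svd_normalize(m_hat, mode = config$svd_mode)
  a <- knn_adjacency(s, k = min(config$knn_k, nrow(s) - 1),
                     weighted = config$weighted_adjacency)
  emb <- spectral_embed(a, k)
  labels <- cluster_embedding(emb, k, seed = config$seed,
                              nstart = config$kmeans_nstart)
  names(labels) <- NULL

  out <- list(labels = labels, losses = fit$losses, scores = scores,
              cell_ids = rownames(xp), k = k, config = config)
  if (keep_matrices) {
    out$m_matrix <- fit$m_matrix
    out$m_tilde <- m_tilde
    out$m_hat <- m_hat
    out$embedding <- emb
    out$z <- fit$z
  }
  if (!is.null(truth)) out$metrics <- evaluate_clustering(labels, truth)
  structure(out, class = "scpedssc_result")
}

#' @export
print.scpedssc_result <- function(x, ...) {
  cat("scpedssc clustering of", length(x$labels), "cells into", x$k,
      "clusters\n")
  cat("cluster sizes:", paste(table(unclass(x$labels)), collapse = " "),
      "\n")
  final <- x$losses[nrow(x$losses), ]
  cat(sprintf("final loss: total %.4g (rescon %.4g, self %.4g, spar %.4g, likelihood %.4g)\n",
              final$total, final$l_rescon, final$l_self, final$l_spar,
              final$l_tpgg))
  if (!is.null(x$metrics))
    cat(sprintf("ARI %.4f, NMI %.4f against supplied reference labels\n",
                x$metrics$ari, x$metrics$nmi))
  invisible(x)
}
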