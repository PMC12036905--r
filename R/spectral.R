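# Spectral clustering of the similarity matrix: SVD normalization, KNN
# adjacency (K = 10 by default), unnormalized graph Laplacian L = D - A,
# eigen-embedding, k-means.

#' SVD normalization of the similarity matrix
#'
#' Re-expresses the similarity matrix through its left singular vectors
#' before graph construction.  The default `mode = "gram"` uses the
#' singular-value-weighted spectral coordinates `U S^(1/2)`, L2-normalizes
#' each cell's coordinate row, forms the absolute Gram matrix of the
#' normalized rows and scales it by its maximum entry (max norm) — the
#' standard post-processing of learned self-expression similarities in
#' deep subspace clustering; the result is symmetric with zero diagonal.
#' `mode = "sym"` is the literal alternative reading — column-L2
#' normalization of `U`, max-norm scaling and symmetrization
#' `(Ml + Ml')/2` — retained for comparison: its output is close to an
#' orthogonal matrix and carries almost no neighborhood information, so
#' it degrades clustering badly (see the methods vignette).
#' `mode = "none"` passes the similarity matrix through unchanged.
#'
#' @param m_hat Symmetric non-negative similarity matrix.
#' @param mode `"gram"` (default), `"sym"`, or `"none"`.
#' @return Symmetric m x m matrix.
#' @export
svd_normalize <- function(m_hat, mode = c("gram", "sym", "none")) {
  mode <- match.arg(mode)
  if (!is.matrix(m_hat) || nrow(m_hat) != ncol(m_hat))
    stop("similarity matrix must be square", call. = FALSE)
  if (mode == "none") return(m_hat)
  sv <- svd(m_hat)
  if (mode == "gram") {
    coords <- sv$u %*% diag(sqrt(sv$d), length(sv$d))
    norms <- sqrt(rowSums(coords^2))
    norms[norms == 0] <- 1
    coords <- coords / norms
    s <- abs(tcrossprod(coords))
    diag(s) <- 0
    mx <- max(s)
    if (mx > 0) s <- s / mx
    s
  } else {
    u <- sv$u
    norms <- sqrt(colSums(u^2))
    norms[norms == 0] <- 1
    ml <- sweep(u, 2, norms, "/")
    mx <- max(abs(ml))
    if (mx > 0) ml <- ml / mx
    (ml + t(ml)) / 2
  }
}

#' K-nearest-neighbor adjacency from a similarity matrix
#'
#' Connects every cell to its `k` most similar cells (self excluded) and
#' symmetrizes by union, so each node ends with degree at least `k`.
#'
#' @param s Symmetric m x m similarity matrix (larger = more similar).
#' @param k Neighbor count, `k < m`.
#' @param weighted Keep the similarity values on retained edges instead
#'   of binary 0/1 entries.
#' @return Symmetric m x m adjacency matrix with zero diagonal.
#' @export
knn_adjacency <- function(s, k, weighted = FALSE) {
  m <- nrow(s)
  if (!is.matrix(s) || m != ncol(s))
    stop("similarity matrix must be square", call. = FALSE)
  if (k >= m) stop("k must be smaller than the number of cells (", m, ")",
                   call. = FALSE)
  if (k < 1) stop("k must be positive", call. = FALSE)
  a <- matrix(0, m, m)
  for (i in seq_len(m)) {
    sims <- s[i, ]
    sims[i] <- -Inf
    nb <- order(sims, decreasing = TRUE)[seq_len(k)]
    a[i, nb] <- if (weighted) s[i, nb] else 1
  }
  a <- pmax(a, t(a))  # union symmetrization
  diag(a) <- 0
  a
}

#' Eigen-embedding of the unnormalized graph Laplacian
#'
#' Builds `L = D - A` with `D = diag(rowSums(A))` and returns the
#' eigenvectors of the `k` smallest eigenvalues (ascending).  Eigenvector
#' signs are fixed by making each vector's largest-magnitude component
#' positive so runs are reproducible across LAPACK builds.  If the graph
#' has more connected components than `k` (eigenvalue 0 with multiplicity
#' above `k`) a warning is emitted and the embedding is returned anyway.
#'
#' @param a Symmetric adjacency matrix.
#' @param k Number of eigenvectors (the target cluster count).
#' @return List with `vectors` (m x k) and `values` (k ascending
#'   eigenvalues).
#' @export
spectral_embed <- function(a, k) {
  m <- nrow(a)
  if (!isTRUE(all.equal(a, t(a)))) stop("adjacency must be symmetric",
                                        call. = FALSE)
  if (k > m) stop("k cannot exceed the number of cells", call. = FALSE)
  d <- rowSums(a)
  lap <- diag(d, m) - a
  ee <- eigen(lap, symmetric = TRUE)
  idx <- m:(m - k + 1)  # eigen() sorts descending; take the k smallest
  vals <- ee$values[idx]
  vecs <- ee$vectors[, idx, drop = FALSE]
  for (j in seq_len(ncol(vecs))) {
    i0 <- which.max(abs(vecs[, j]))
    if (vecs[i0, j] < 0) vecs[, j] <- -vecs[, j]
  }
  n_zero <- sum(abs(ee$values) < 1e-8)
  if (n_zero > k)
    warning("graph has ", n_zero, " connected components but k = ", k)
  list(vectors = vecs, values = vals)
}

#' Cluster a spectral embedding with k-means
#'
#' @param embedding A list from [spectral_embed()] (or a plain matrix of
#'   embedding coordinates).
#' @param k Cluster count.
#' @param seed Seed for the k-means restarts (a named substream is
#'   derived, so results are reproducible).
#' @param nstart Number of random restarts.
#' @return A [partition()] with labels in `[0, k)`.
#' @export
cluster_embedding <- function(embedding, k, seed = 0L, nstart = 20L) {
  coords <- if (is.list(embedding)) embedding$vectors else embedding
  if (k > nrow(coords)) stop("k cannot exceed the number of cells",
                             call. = FALSE)
  if (k < 1) stop("k must be at least 1", call. = FALSE)
  set.seed(derive_seed(seed, "kmeans"))
  km <- stats::kmeans(coords, centers = k, nstart = nstart, iter.max = 100)
  partition(km$cluster)
}
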