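# Synthetic scRNA-seq-like data with planted low-dimensional subspace
# cluster structure, zero inflation and right-skewed non-zero magnitudes.
#
# Each cluster lives on its own random low-dimensional nonlinear manifold:
# a cell's profile is softplus(low-rank signal + Gaussian noise), scaled
# entrywise by generalized-gamma magnitudes with cluster-specific
# parameters, then masked to zero by independent Bernoulli dropout.  Zeros
# therefore come exclusively from the dropout mask, so the observed zero
# fraction concentrates around `dropout_pi`.

#' Sample from the generalized gamma distribution
#'
#' Uses the transform `X = alpha * G^(1/gamma)` with
#' `G ~ Gamma(shape = beta, scale = 1)`, whose density is the
#' generalized-gamma of [gg_log_density()]; the mean is
#' `alpha * Gamma(beta + 1/gamma) / Gamma(beta)`.
#'
#' @param n Number of draws.
#' @param alpha,beta,gamma Positive parameters.
#' @param seed Optional integer; if given, draws are reproducible.
#' @return Vector of `n` positive values.
#' @export
sample_gg <- function(n, alpha, beta, gamma, seed = NULL) {
  if (alpha <= 0 || beta <= 0 || gamma <= 0)
    stop("alpha, beta, gamma must be strictly positive", call. = FALSE)
  if (!is.null(seed)) set.seed(derive_seed(seed, "sample-gg"))
  alpha * stats::rgamma(n, shape = beta, scale = 1)^(1 / gamma)
}

#' Specification of a synthetic dataset
#'
#' @param m,n,k Cells, genes, clusters (`m >= 3k`).
#' @param subspace_dim Intrinsic dimension of each cluster's subspace.
#' @param dropout_pi Per-entry zero probability; a scalar or a length-`k`
#'   vector (one rate per cluster).
#' @param gg_params Data frame with columns `alpha`, `beta`, `gamma` and
#'   one row per cluster: the generalized-gamma magnitude parameters.
#'   Defaults stagger `alpha` across clusters around 1 with `beta = 2`,
#'   `gamma = 1.5`, giving clearly right-skewed non-zero values.
#' @param noise_sd Standard deviation of the Gaussian noise added to the
#'   low-rank signal before the softplus.
#' @param signal_sd Scale of the per-cell subspace coefficients.
#' @param seed Integer seed.
#' @return A classed list.
#' @export
simulation_spec <- function(m = 300, n = 800, k = 4, subspace_dim = 3,
                            dropout_pi = 0.4, gg_params = NULL,
                            noise_sd = 0.1, signal_sd = 1.5, seed = 0L) {
  if (is.null(gg_params))
    gg_params <- data.frame(alpha = 0.8 + 0.2 * (seq_len(k) - 1),
                            beta = rep(2, k), gamma = rep(1.5, k))
  spec <- list(m = as.integer(m), n = as.integer(n), k = as.integer(k),
               subspace_dim = as.integer(subspace_dim),
               dropout_pi = rep_len(dropout_pi, k),
               gg_params = gg_params, noise_sd = noise_sd,
               signal_sd = signal_sd, seed = as.integer(seed))
  if (spec$m < 3 * spec$k)
    stop("need m >= 3k (", 3 * spec$k, ") cells", call. = FALSE)
  if (any(spec$dropout_pi < 0) || any(spec$dropout_pi > 1))
    stop("dropout_pi must lie in [0, 1]", call. = FALSE)
  if (nrow(gg_params) != spec$k ||
      !all(c("alpha", "beta", "gamma") %in% names(gg_params)))
    stop("gg_params must have k rows and columns alpha, beta, gamma",
         call. = FALSE)
  if (any(as.matrix(gg_params[c("alpha", "beta", "gamma")]) <= 0))
    stop("generalized-gamma parameters must be positive", call. = FALSE)
  if (spec$noise_sd < 0) stop("noise_sd must be non-negative", call. = FALSE)
  structure(spec, class = "simulation_spec")
}

#' Simulate an expression matrix with planted cluster structure
#'
#' A pure function of its spec (seed included): identical specs give
#' identical data.
#'
#' @param spec A [simulation_spec()].
#' @return List with `x` (cells x genes matrix), `labels` (the planted
#'   [partition()]) and `spec`.
#' @export
#' @examples
#' sim <- simulate_cells(simulation_spec(m = 30, n = 50, k = 2, seed = 1))
#' table(sim$labels)
simulate_cells <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  set.seed(derive_seed(spec$seed, "simulate"))
  m <- spec$m; n <- spec$n; k <- spec$k; d <- spec$subspace_dim
  labels <- sample(rep_len(seq_len(k) - 1L, m))
  x <- matrix(0, m, n)
  for (c in seq_len(k)) {
    cells <- which(labels == c - 1L)
    mc <- length(cells)
    basis <- matrix(stats::rnorm(n * d), n, d)
    coeff <- matrix(stats::rnorm(mc * d, sd = spec$signal_sd), mc, d)
    signal <- coeff %*% t(basis) / sqrt(d)
    if (spec$noise_sd > 0)
      signal <- signal + stats::rnorm(mc * n, sd = spec$noise_sd)
    gp <- spec$gg_params[c, ]
    mags <- matrix(gp$alpha *
                     stats::rgamma(mc * n, shape = gp$beta,
                                   scale = 1)^(1 / gp$gamma), mc, n)
    keep <- matrix(stats::rbinom(mc * n, 1, 1 - spec$dropout_pi[c]), mc, n)
    x[cells, ] <- softplus(signal) * mags * keep
  }
  list(x = expression_matrix(x), labels = partition(labels), spec = spec)
}

#' A tiny deterministic block-structured fixture
#'
#' 12 cells x 30 genes in 3 clusters of 4 cells.  Each cluster expresses
#' its own block of 10 genes at high level with a deterministic
#' arithmetic pattern; off-block entries are a sparse low background.
#' Built in code (no RNG, no files) so it is bit-identical everywhere;
#' useful for exact regression tests of gene screening and clustering.
#'
#' @return List with `x` (12 x 30 matrix) and `labels` (a [partition()]).
#' @export
checkerboard_fixture <- function() {
  m <- 12L; n <- 30L; k <- 3L
  labels <- rep(0:2, each = 4)
  x <- matrix(0, m, n)
  for (i in seq_len(m)) {
    c <- labels[i]
    block <- (10 * c + 1):(10 * c + 10)
    for (j in block) x[i, j] <- 3 + (i + j) %% 3
    for (j in setdiff(seq_len(n), block))
      if ((i * j) %% 7 == 0) x[i, j] <- 0.2 + 0.05 * (j %% 3)
  }
  # guarantee every gene is expressed in at least one cell
  for (j in seq_len(n)) if (all(x[, j] == 0)) x[1, j] <- 0.1
  list(x = expression_matrix(x), labels = partition(labels))
}
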