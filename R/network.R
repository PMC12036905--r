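# Autoencoder architecture.
#
# A bias-free fully-connected chain with ReLU activations:
#   encoder  n_genes -> 256 -> 32 -> 10   (the embedding Z)
#   decoder  10 -> 32 -> 256
# followed by parallel linear heads from the 256-unit penultimate layer
# back to the gene dimension: sigmoid head for the zero probability and
# softplus heads for the positive likelihood parameters, plus a linear
# reconstruction head for Xhat.  The five chain weight matrices and the
# distribution heads enter the Frobenius regularizer; the reconstruction
# head (this package's addition, the likelihood heads being the decoder's
# published outputs) does not.  The heads are stored as one column-block
# matrix so the dominant products hit BLAS once per pass.

head_layout <- function(use_tpgg) {
  if (use_tpgg)
    list(names = c("pi", "alpha", "beta", "gamma", "xhat"),
         act = c("sigmoid", "softplus", "softplus", "softplus", "linear"))
  else
    list(names = c("pi", "mu", "theta", "xhat"),
         act = c("sigmoid", "softplus", "softplus", "linear"))
}

#' Build an untrained model
#'
#' Allocates the encoder/decoder weight matrices, the likelihood and
#' reconstruction heads, and the m x m self-expression matrix (initialized
#' to zero, diagonal permanently zero).  Weights are Glorot-normal
#' initialized from a substream of `seed`, so two builds with the same
#' arguments are identical.
#'
#' @param config A [scpedssc_config()].
#' @param n_genes Number of input genes (columns of the training matrix).
#' @param n_cells Number of cells (size of the self-expression matrix).
#' @param seed Integer seed for weight initialization.
#' @return A model-state list (class `"scpedssc_net"`).
#' @export
build_network <- function(config, n_genes, n_cells,
                          seed = config$seed) {
  stopifnot(n_cells >= 2, n_genes >= 1)
  widths <- c(n_genes, config$encoder_widths, config$decoder_widths)
  hl <- head_layout(config$use_tpgg)
  nh <- length(hl$names)
  hp <- widths[length(widths)]  # penultimate (last decoder) width

  set.seed(derive_seed(seed, "weight-init"))
  glorot <- function(fi, fo) matrix(stats::rnorm(fi * fo, sd = sqrt(2 / (fi + fo))),
                                    fi, fo)
  W <- vector("list", length(widths) - 1)
  for (l in seq_along(W)) W[[l]] <- glorot(widths[l], widths[l + 1])
  Wh <- glorot(hp, nh * n_genes)

  net <- list(
    W = W, Wh = Wh,
    b = if (config$use_bias) lapply(widths[-1], function(k) numeric(k)),
    bh = if (config$use_bias) numeric(nh * n_genes),
    M = matrix(0, n_cells, n_cells),
    widths = widths, heads = hl, n_genes = n_genes, n_cells = n_cells,
    embed_index = length(config$encoder_widths) + 1,  # H slot holding Z
    use_tpgg = config$use_tpgg, use_bias = config$use_bias
  )
  class(net) <- "scpedssc_net"
  net
}

#' @export
print.scpedssc_net <- function(x, ...) {
  cat("scpedssc autoencoder:", paste(x$widths, collapse = " -> "),
      "| heads:", paste(x$heads$names, collapse = ", "),
      sprintf("| %d cells, %d parameters\n", x$n_cells, n_parameters(x)))
  invisible(x)
}

#' Total trainable parameter count (network weights, excluding M)
#'
#' @param net A model built by [build_network()].
#' @return Integer count of weight (and bias, if enabled) entries.
#' @export
n_parameters <- function(net) {
  n <- sum(vapply(net$W, length, numeric(1))) + length(net$Wh)
  if (net$use_bias)
    n <- n + sum(vapply(net$b, length, numeric(1))) + length(net$bh)
  n
}

# Slice the column block of head `name` out of a heads-wide matrix.
head_block <- function(mat, net, name) {
  i <- match(name, net$heads$names)
  cols <- ((i - 1) * net$n_genes + 1):(i * net$n_genes)
  mat[, cols, drop = FALSE]
}

# Forward pass.  Returns all activations needed by the backward pass.
# `heads = "xhat"` computes only the reconstruction head (used by the
# warmup phase, skipping the distribution-head block products).
ae_forward <- function(net, x, heads = "all") {
  L <- length(net$W)
  H <- vector("list", L + 1)
  H[[1]] <- x
  for (l in seq_len(L)) {
    pre <- H[[l]] %*% net$W[[l]]
    if (net$use_bias) pre <- sweep(pre, 2, net$b[[l]], "+")
    # ReLU between layers; the embedding output itself is linear so the
    # bottleneck does not lose half its directions to dead units
    H[[l + 1]] <- if (l + 1 == net$embed_index) pre else pmax(pre, 0)
  }
  Hp <- H[[L + 1]]
  if (identical(heads, "xhat")) {
    i <- match("xhat", net$heads$names)
    cols <- ((i - 1) * net$n_genes + 1):(i * net$n_genes)
    pre_h <- Hp %*% net$Wh[, cols, drop = FALSE]
    if (net$use_bias) pre_h <- sweep(pre_h, 2, net$bh[cols], "+")
    return(list(H = H, Z = H[[net$embed_index]], Hp = Hp,
                heads = list(xhat = pre_h), xhat_cols = cols))
  }
  pre_h <- Hp %*% net$Wh
  if (net$use_bias) pre_h <- sweep(pre_h, 2, net$bh, "+")

  out <- list()
  for (i in seq_along(net$heads$names)) {
    blk <- head_block(pre_h, net, net$heads$names[i])
    out[[net$heads$names[i]]] <- switch(net$heads$act[i],
      sigmoid = sigmoid(blk),
      softplus = softplus(blk),
      linear = blk)
  }
  list(H = H, Z = H[[net$embed_index]], Hp = Hp, pre_h = pre_h,
       heads = out)
}

# TPGG mean (1 - pi) * alpha * Gamma(beta + 1/gamma) / Gamma(beta); used
# for reconstruction when xhat_from_tpgg_mean is set.
tpgg_mean <- function(heads) {
  with(heads, (1 - pi) * alpha * exp(lgamma(beta + 1 / gamma) - lgamma(beta)))
}

reconstruction <- function(net, fwd, config) {
  if (config$xhat_from_tpgg_mean && net$use_tpgg) tpgg_mean(fwd$heads)
  else fwd$heads$xhat
}
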