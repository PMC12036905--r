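# Run configuration.
#
# Defaults are the published operating point of the method: T = 2000 retained
# genes, loss weights lambda1 = 0.2, lambda2 = 1.0, lambda3 = 0.5, encoder
# widths 256/32/10 mirrored by the decoder, learning rate 0.001 and a KNN
# graph with K = 10.  Training-schedule settings (optimizer epochs) are this
# package's own choices; see the methods vignette.

#' Construct a run configuration
#'
#' @param t_genes Number of genes retained by Laplacian-score selection
#'   (the method's `T`).  Pipelines cap it at the number of available
#'   genes.
#' @param lambda1,lambda2,lambda3 Non-negative weights of the
#'   reconstruction, self-expression and sparsity losses.
#' @param lr Adam learning rate.
#' @param encoder_widths Integer widths of the three encoder layers
#'   (input -> 256 -> 32 -> 10 by default); the last entry is the
#'   embedding dimension.
#' @param decoder_widths Integer widths of the decoder layers after the
#'   embedding (10 -> 32 -> 256 by default; the parameter heads map the
#'   last width back to the gene dimension).
#' @param knn_k Neighbor count of the spectral-clustering KNN graph.
#' @param seed Master seed; every stochastic component derives a named
#'   substream from it via [derive_seed()].
#' @param epochs_warmup,epochs_pretrain,epochs_joint Epoch counts of the
#'   three training phases: reconstruction-only warmup (the likelihood
#'   gradient is orders of magnitude larger than the scaled
#'   reconstruction gradient, so the embedding needs a dedicated warmup
#'   to form before the likelihood takes over), reconstruction +
#'   likelihood pretraining, then the full joint objective including the
#'   self-expression matrix.
#' @param use_laplace_preprocess If `FALSE` (the "DP" ablation), replace
#'   Laplacian-score gene screening with conventional preprocessing:
#'   library-size normalization, log1p, top-T genes by variance.
#' @param use_tpgg If `FALSE` (the "TP" ablation), replace the two-part
#'   generalized gamma likelihood with a zero-inflated negative binomial
#'   head of the same layout (dropout/mean/dispersion).
#' @param use_enhancement If `FALSE` (the "ESM" ablation), build the
#'   similarity matrix directly from the self-expression matrix without
#'   second-order proximity enhancement.
#' @param weight_decay_scale Coefficient on the summed squared Frobenius
#'   norms of the trainable weight matrices in the likelihood loss (the
#'   printed form of the loss carries coefficient 1).
#' @param recon_block_scale Scale applied to the weighted sum of the three
#'   autoencoder losses before adding the likelihood loss (the combined
#'   objective divides that block by 10).
#' @param score_direction `"high"` retains genes with the largest harmonic
#'   mean of the four Laplacian scores (the method's stated rule);
#'   `"low"` retains the smallest (the classic Laplacian-score
#'   convention).
#' @param graph_axis `"cells"` builds the four similarity graphs over
#'   cells and scores genes with the Laplacian score (default);
#'   `"genes"` builds gene-gene graphs and scores genes by weighted node
#'   degree instead.
#' @param svd_mode How the similarity matrix is normalized through its
#'   SVD before the KNN graph: `"gram"` (default) builds the max-norm
#'   scaled absolute Gram matrix of the row-L2-normalized spectral
#'   coordinates `U S^(1/2)`; `"sym"` is the literal
#'   column-normalize-and-symmetrize reading (degrades clustering; kept
#'   for comparison); `"none"` skips the step.  See [svd_normalize()].
#' @param weighted_adjacency Keep similarity weights on the KNN graph
#'   instead of binary edges.
#' @param use_bias Add bias vectors to all layers (the forward rule is
#'   bias-free by default).
#' @param xhat_from_tpgg_mean Reconstruct `X` from the TPGG mean
#'   `(1-pi) * alpha * Gamma(beta + 1/gamma)/Gamma(beta)` instead of a
#'   dedicated linear head.
#' @param kmeans_nstart Number of random k-means restarts.
#' @param zero_tol Magnitude below which an expression entry is treated as
#'   an exact zero by the hurdle likelihood.
#' @return A classed list of settings.
#' @export
#' @examples
#' cfg <- scpedssc_config(knn_k = 15)
#' cfg$lambda1
scpedssc_config <- function(t_genes = 2000,
                            lambda1 = 0.2, lambda2 = 1.0, lambda3 = 0.5,
                            lr = 0.001,
                            encoder_widths = c(256L, 32L, 10L),
                            decoder_widths = c(32L, 256L),
                            knn_k = 10L,
                            seed = 0L,
                            epochs_warmup = 1000L,
                            epochs_pretrain = 50L,
                            epochs_joint = 150L,
                            use_laplace_preprocess = TRUE,
                            use_tpgg = TRUE,
                            use_enhancement = TRUE,
                            weight_decay_scale = 1.0,
                            recon_block_scale = 0.1,
                            score_direction = c("high", "low"),
                            graph_axis = c("cells", "genes"),
                            svd_mode = c("gram", "sym", "none"),
                            weighted_adjacency = FALSE,
                            use_bias = FALSE,
                            xhat_from_tpgg_mean = FALSE,
                            kmeans_nstart = 20L,
                            zero_tol = 1e-12) {
  cfg <- list(
    epochs_warmup = as.integer(epochs_warmup),
    t_genes = as.integer(t_genes),
    lambda1 = lambda1, lambda2 = lambda2, lambda3 = lambda3,
    lr = lr,
    encoder_widths = as.integer(encoder_widths),
    decoder_widths = as.integer(decoder_widths),
    knn_k = as.integer(knn_k),
    seed = as.integer(seed),
    epochs_pretrain = as.integer(epochs_pretrain),
    epochs_joint = as.integer(epochs_joint),
    use_laplace_preprocess = isTRUE(use_laplace_preprocess),
    use_tpgg = isTRUE(use_tpgg),
    use_enhancement = isTRUE(use_enhancement),
    weight_decay_scale = weight_decay_scale,
    recon_block_scale = recon_block_scale,
    score_direction = match.arg(score_direction),
    graph_axis = match.arg(graph_axis),
    svd_mode = match.arg(svd_mode),
    weighted_adjacency = isTRUE(weighted_adjacency),
    use_bias = isTRUE(use_bias),
    xhat_from_tpgg_mean = isTRUE(xhat_from_tpgg_mean),
    kmeans_nstart = as.integer(kmeans_nstart),
    zero_tol = zero_tol
  )
  validate_config(cfg)
  structure(cfg, class = "scpedssc_config")
}

validate_config <- function(cfg) {
  if (cfg$t_genes <= 0) stop("t_genes must be positive", call. = FALSE)
  for (f in c("lambda1", "lambda2", "lambda3", "weight_decay_scale",
              "recon_block_scale"))
    if (cfg[[f]] < 0) stop(f, " must be non-negative", call. = FALSE)
  if (cfg$lr <= 0) stop("lr must be positive", call. = FALSE)
  if (any(cfg$encoder_widths <= 0) || any(cfg$decoder_widths <= 0))
    stop("layer widths must be positive integers", call. = FALSE)
  if (cfg$knn_k <= 0) stop("knn_k must be positive", call. = FALSE)
  if (cfg$epochs_warmup < 0 || cfg$epochs_pretrain <= 0 ||
      cfg$epochs_joint <= 0)
    stop("epoch counts must be positive (warmup may be 0)", call. = FALSE)
  invisible(cfg)
}

#' Load a run configuration from a YAML (or JSON) file
#'
#' Unset keys take the package defaults; unknown keys are an error so that
#' misspelled settings never pass silently.  An empty file yields the full
#' default configuration.
#'
#' @param path Path to a YAML/JSON mapping of configuration keys.
#' @return A [scpedssc_config()] object.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  if (!is.list(raw)) stop("config file must contain a key: value mapping",
                          call. = FALSE)
  known <- names(formals(scpedssc_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0)
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  do.call(scpedssc_config, raw)
}

#' @export
print.scpedssc_config <- function(x, ...) {
  cat("scpedssc configuration\n")
  for (nm in names(x))
    cat(sprintf("  %-22s %s\n", nm, paste(x[[nm]], collapse = " ")))
  invisible(x)
}
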