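# Training: full-batch analytic backpropagation with Adam.
#
# The self-expression matrix couples all cells, so training is full-batch
# by construction (no mini-batching of cells).  Phase 1 pretrains the
# encoder/decoder/heads on reconstruction + likelihood; phase 2 jointly
# optimizes the complete objective
#   total = (lambda1 Lrescon + lambda2 Lself + lambda3 Lspar)/10 + Ltpgg
# where Ltpgg already carries the Frobenius regularizer of the trainable
# weight matrices.  The diagonal of M is forced to zero after every step.

# Squared-Frobenius regularizer over the published trainable set: the five
# chain matrices plus the distribution heads; the auxiliary linear
# reconstruction head stays out.
reg_frob <- function(net) {
  sum(vapply(net$W, frob2, numeric(1))) + frob2(net$Wh) -
    frob2(head_block(net$Wh, net, "xhat"))
}

likelihood_nll_grad <- function(x, heads, use_tpgg, zero_tol, cache = NULL) {
  if (use_tpgg)
    tpgg_nll_grad(x, heads$pi, heads$alpha, heads$beta, heads$gamma,
                  zero_tol = zero_tol, cache = cache)
  else
    zinb_nll_grad(x, heads$pi, heads$mu, heads$theta, zero_tol = zero_tol,
                  cache = cache)
}

loss_components <- function(x, net, fwd, config, nll = NULL) {
  xhat <- reconstruction(net, fwd, config)
  # rows are cells, so the self-expression residual is Z - M Z
  rm_ <- fwd$Z - net$M %*% fwd$Z
  lik <- if (!is.null(nll)) nll
  else if (net$use_tpgg)
    -sum(tpgg_log_density(x, fwd$heads$pi, fwd$heads$alpha, fwd$heads$beta,
                          fwd$heads$gamma, zero_tol = config$zero_tol))
  else
    -sum(zinb_log_density(x, fwd$heads$pi, fwd$heads$mu, fwd$heads$theta,
                          zero_tol = config$zero_tol))
  l_rescon <- 0.5 * frob2(x - xhat)
  l_self <- 0.5 * frob2(rm_)
  l_spar <- frob2(net$M)
  l_tpgg <- lik + config$weight_decay_scale * reg_frob(net)
  total <- config$recon_block_scale *
    (config$lambda1 * l_rescon + config$lambda2 * l_self +
       config$lambda3 * l_spar) + l_tpgg
  list(l_rescon = l_rescon, l_self = l_self, l_spar = l_spar,
       l_tpgg = l_tpgg, total = total)
}

#' Evaluate all loss components at the current model state
#'
#' @param x Preprocessed cells x genes matrix the model is trained on.
#' @param net Model state from [build_network()] or [train_autoencoder()].
#' @param config The run configuration.
#' @return One-row data frame with `l_rescon`, `l_self`, `l_spar`,
#'   `l_tpgg` (likelihood + weight regularizer) and `total` (the combined
#'   objective).
#' @export
compute_losses <- function(x, net, config = scpedssc_config()) {
  if (nrow(x) != net$n_cells || ncol(x) != net$n_genes)
    stop("matrix shape (", nrow(x), " x ", ncol(x),
         ") does not match the model (", net$n_cells, " x ", net$n_genes,
         ")", call. = FALSE)
  fwd <- ae_forward(net, x)
  lc <- loss_components(x, net, fwd, config)
  if (!all(vapply(lc, is.finite, logical(1)))) {
    bad <- names(lc)[!vapply(lc, is.finite, logical(1))]
    stop("non-finite loss component(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  as.data.frame(lc)
}

# Full gradient of the training objective.  `joint = FALSE` drops the
# self-expression and sparsity terms and freezes M (pretraining phase).
ae_gradients <- function(x, net, config, joint, cache = NULL,
                         want_loss = TRUE) {
  fwd <- ae_forward(net, x)
  sc <- config$recon_block_scale
  c1 <- sc * config$lambda1
  c2 <- if (joint) sc * config$lambda2 else 0
  c3 <- if (joint) sc * config$lambda3 else 0
  wd <- config$weight_decay_scale
  heads <- fwd$heads
  hnames <- net$heads$names
  ng <- net$n_genes

  lik <- likelihood_nll_grad(x, heads, net$use_tpgg, config$zero_tol, cache)
  dpar <- lik[paste0("d", setdiff(hnames, "xhat"))]
  names(dpar) <- setdiff(hnames, "xhat")

  xhat <- reconstruction(net, fwd, config)
  dxhat <- c1 * (xhat - x)
  if (config$xhat_from_tpgg_mean && net$use_tpgg) {
    # Chain the reconstruction error through the TPGG mean
    # (1-pi) alpha Gamma(beta + 1/gamma)/Gamma(beta).
    mean_ <- tpgg_mean(heads)
    ratio <- exp(lgamma(heads$beta + 1 / heads$gamma) - lgamma(heads$beta))
    dpar$pi <- dpar$pi - dxhat * heads$alpha * ratio
    dpar$alpha <- dpar$alpha + dxhat * (1 - heads$pi) * ratio
    dpar$beta <- dpar$beta + dxhat * mean_ *
      (digamma(heads$beta + 1 / heads$gamma) - digamma(heads$beta))
    dpar$gamma <- dpar$gamma - dxhat * mean_ *
      digamma(heads$beta + 1 / heads$gamma) / heads$gamma^2
    dxhat_head <- matrix(0, nrow(x), ng)
  } else {
    dxhat_head <- dxhat
  }

  # Head-parameter gradients -> pre-activation gradients, in layout order.
  dpre_blocks <- vector("list", length(hnames))
  for (i in seq_along(hnames)) {
    nm <- hnames[i]
    if (nm == "xhat") { dpre_blocks[[i]] <- dxhat_head; next }
    blk <- head_block(fwd$pre_h, net, nm)
    act <- net$heads$act[i]
    dpre_blocks[[i]] <- if (act == "sigmoid") {
      s <- sigmoid(blk)
      dpar[[nm]] * s * (1 - s)
    } else {
      dpar[[nm]] * sigmoid(blk)  # softplus'
    }
  }
  dpre_h <- do.call(cbind, dpre_blocks)

  reg_mask_wh <- net$Wh
  reg_mask_wh[, (match("xhat", hnames) - 1) * ng + seq_len(ng)] <- 0
  gWh <- crossprod(fwd$Hp, dpre_h) + 2 * wd * reg_mask_wh
  gbh <- if (net$use_bias) colSums(dpre_h)

  L <- length(net$W)
  gW <- vector("list", L)
  gb <- if (net$use_bias) vector("list", L)
  dH <- tcrossprod(dpre_h, net$Wh)
  rm_ <- fwd$Z - net$M %*% fwd$Z
  for (l in L:1) {
    delta <- if (l + 1 == net$embed_index) dH else dH * (fwd$H[[l + 1]] > 0)
    gW[[l]] <- crossprod(fwd$H[[l]], delta) + 2 * wd * net$W[[l]]
    if (net$use_bias) gb[[l]] <- colSums(delta)
    if (l > 1) dH <- tcrossprod(delta, net$W[[l]])  # dH w.r.t. X is unused
    if (l == net$embed_index && c2 > 0)
      dH <- dH + c2 * (rm_ - crossprod(net$M, rm_))
  }

  gM <- NULL
  if (joint) {
    gM <- -c2 * tcrossprod(rm_, fwd$Z) + 2 * c3 * net$M
    diag(gM) <- 0
  }

  list(gW = gW, gWh = gWh, gb = gb, gbh = gbh, gM = gM, fwd = fwd,
       losses = if (want_loss)
         loss_components(x, net, fwd, config, nll = lik$nll))
}

# Warmup gradient: plain reconstruction loss 0.5 ||X - Xhat||_F^2 through
# the linear reconstruction head only (no likelihood, no weight decay).
# This gives the embedding a chance to form before the much larger
# likelihood gradients take over; see the methods vignette.
ae_gradients_warmup <- function(x, net) {
  fwd <- ae_forward(net, x, heads = "xhat")
  dxhat <- fwd$heads$xhat - x
  gWh <- matrix(0, nrow(net$Wh), ncol(net$Wh))
  gWh[, fwd$xhat_cols] <- crossprod(fwd$Hp, dxhat)
  gbh <- if (net$use_bias) {
    v <- numeric(length(net$bh)); v[fwd$xhat_cols] <- colSums(dxhat); v
  }
  L <- length(net$W)
  gW <- vector("list", L)
  gb <- if (net$use_bias) vector("list", L)
  dH <- tcrossprod(dxhat, net$Wh[, fwd$xhat_cols, drop = FALSE])
  for (l in L:1) {
    delta <- if (l + 1 == net$embed_index) dH else dH * (fwd$H[[l + 1]] > 0)
    gW[[l]] <- crossprod(fwd$H[[l]], delta)
    if (net$use_bias) gb[[l]] <- colSums(delta)
    if (l > 1) dH <- tcrossprod(delta, net$W[[l]])
  }
  list(gW = gW, gWh = gWh, gb = gb, gbh = gbh, gM = NULL)
}

# One Adam update for a single named parameter tensor.  The moment
# buffers live only in `state`, so the compiled kernel updates them in
# place and allocates just the returned value.
adam_update <- function(state, name, value, grad, lr, t,
                        beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  if (is.null(state$m[[name]])) {
    state$m[[name]] <- grad * 0
    state$v[[name]] <- grad * 0
  }
  .cpp_adam_step(value, grad, state$m[[name]], state$v[[name]],
                 lr, t, beta1, beta2, eps)
}

#' Train the autoencoder and learn the self-expression matrix
#'
#' Runs the three-phase full-batch Adam schedule on the preprocessed
#' expression matrix — reconstruction-only warmup, reconstruction +
#' likelihood pretraining, then the full joint objective — and returns
#' the learned self-expression matrix `M` (zero diagonal), the final
#' embedding `Z`, and the loss trace (every pretrain/joint epoch; warmup
#' epochs are logged on a thinned schedule).  Fully deterministic given
#' `config$seed`.
#'
#' @param x Preprocessed (gene-screened, L2 row-normalized) cells x genes
#'   matrix.
#' @param config A [scpedssc_config()].
#' @return List with `m_matrix`, `z`, `losses` (data frame with columns
#'   `epoch`, `phase`, the four components and `total`), and `net` (the
#'   trained model state).
#' @export
train_autoencoder <- function(x, config = scpedssc_config()) {
  m <- nrow(x)
  if (m < 3) stop("need at least 3 cells to train", call. = FALSE)
  net <- build_network(config, n_genes = ncol(x), n_cells = m,
                       seed = config$seed)
  state <- new.env(parent = emptyenv())
  state$m <- list(); state$v <- list()
  lr <- config$lr
  cache <- tpgg_cache(x, config$zero_tol)
  trace <- list()
  step <- 0

  apply_updates <- function(g, joint) {
    step <<- step + 1
    for (l in seq_along(net$W))
      net$W[[l]] <<- adam_update(state, paste0("W", l), net$W[[l]],
                                 g$gW[[l]], lr, step)
    net$Wh <<- adam_update(state, "Wh", net$Wh, g$gWh, lr, step)
    if (net$use_bias) {
      for (l in seq_along(net$b))
        net$b[[l]] <<- adam_update(state, paste0("b", l), net$b[[l]],
                                   g$gb[[l]], lr, step)
      net$bh <<- adam_update(state, "bh", net$bh, g$gbh, lr, step)
    }
    if (joint) {
      net$M <<- adam_update(state, "M", net$M, g$gM, lr, step)
      diag(net$M) <<- 0
    }
  }

  log_row <- function(epoch, phase_name, lc) {
    if (!all(vapply(lc, is.finite, logical(1)))) {
      bad <- names(lc)[!vapply(lc, is.finite, logical(1))]
      stop("training diverged during ", phase_name, " (non-finite ",
           paste(bad, collapse = ", "), ") at epoch ", epoch,
           "; last good epoch: ", epoch - 1, call. = FALSE)
    }
    trace[[length(trace) + 1]] <<- data.frame(epoch = epoch,
                                              phase = phase_name,
                                              as.data.frame(lc))
  }

  # Phase 0: reconstruction-only warmup.  Loss components are logged on a
  # thinned schedule (the full component set needs the distribution-head
  # forward pass, which the warmup otherwise skips).  Unavailable when the
  # reconstruction is itself derived from the distribution heads.
  # Loss components are logged on a thinned schedule (first epoch, every
  # fifth — every fiftieth during warmup — and the last of each phase):
  # the full component set needs forward passes the update itself does not.
  n_warm <- if (config$xhat_from_tpgg_mean) 0L else config$epochs_warmup
  for (e in seq_len(n_warm)) {
    if (e == 1 || e %% 50 == 0 || e == n_warm) {
      lc <- loss_components(x, net, ae_forward(net, x), config)
      log_row(e, "warmup", lc)
    }
    apply_updates(ae_gradients_warmup(x, net), joint = FALSE)
  }

  for (e in seq_len(config$epochs_pretrain)) {
    want <- e == 1 || e %% 5 == 0 || e == config$epochs_pretrain
    g <- ae_gradients(x, net, config, joint = FALSE, cache = cache,
                      want_loss = want)
    if (want) log_row(n_warm + e, "pretrain", g$losses)
    apply_updates(g, joint = FALSE)
  }
  for (e in seq_len(config$epochs_joint)) {
    want <- e == 1 || e %% 5 == 0 || e == config$epochs_joint
    g <- ae_gradients(x, net, config, joint = TRUE, cache = cache,
                      want_loss = want)
    if (want) log_row(n_warm + config$epochs_pretrain + e, "joint",
                      g$losses)
    apply_updates(g, joint = TRUE)
  }

  fwd <- ae_forward(net, x)
  final <- loss_components(x, net, fwd, config)
  log_row(n_warm + config$epochs_pretrain + config$epochs_joint + 1,
          "final", final)
  list(m_matrix = net$M, z = fwd$Z, losses = do.call(rbind, trace),
       net = net)
}
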