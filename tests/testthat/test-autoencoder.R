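test_that("network shapes follow the configured widths and parameter count", {
  cfg <- scpedssc_config()
  net <- build_network(cfg, n_genes = 500, n_cells = 40, seed = 1)
  # chain: 500->256->32->10->32->256, heads 256 -> 5 * 500
  want <- 500 * 256 + 256 * 32 + 32 * 10 + 10 * 32 + 32 * 256 +
    256 * 5 * 500
  expect_equal(n_parameters(net), want)
  expect_equal(dim(net$M), c(40, 40))
  expect_equal(vapply(net$W, nrow, numeric(1)), c(500, 256, 32, 10, 32))
})

test_that("weight initialization is deterministic given the seed", {
  cfg <- tiny_config()
  n1 <- build_network(cfg, 30, 10, seed = 5)
  n2 <- build_network(cfg, 30, 10, seed = 5)
  expect_identical(n1$W, n2$W)
  expect_identical(n1$Wh, n2$Wh)
  n3 <- build_network(cfg, 30, 10, seed = 6)
  expect_false(identical(n1$W[[1]], n3$W[[1]]))
})

test_that("head outputs live in their activation ranges", {
  cfg <- tiny_config()
  x <- l2_normalize_rows(random_expression(12, 30, seed = 71))
  net <- build_network(cfg, 30, 12, seed = 7)
  fwd <- scpedssc:::ae_forward(net, x)
  expect_true(all(fwd$heads$pi > 0 & fwd$heads$pi < 1))
  expect_true(all(fwd$heads$alpha > 0))
  expect_true(all(fwd$heads$beta > 0))
  expect_true(all(fwd$heads$gamma > 0))
  expect_equal(dim(fwd$Z), c(12, 4))
})

test_that("forced loss cases behave as the objective dictates", {
  cfg <- tiny_config(lambda1 = 0, lambda2 = 0, lambda3 = 0)
  x <- l2_normalize_rows(random_expression(8, 20, seed = 72))
  net <- build_network(cfg, 20, 8, seed = 8)
  # lambda = 0: total equals the likelihood loss
  lc <- compute_losses(x, net, cfg)
  expect_equal(lc$total, lc$l_tpgg)
  # M = 0: l_self = 0.5 ||Z||_F^2 and l_spar = 0
  cfg2 <- tiny_config()
  fwd <- scpedssc:::ae_forward(net, x)
  lc2 <- compute_losses(x, net, cfg2)
  expect_equal(lc2$l_self, 0.5 * sum(fwd$Z^2), tolerance = 1e-10)
  expect_equal(lc2$l_spar, 0)
})

test_that("losses match a scalar-by-scalar oracle on a tiny fixed model", {
  cfg <- scpedssc_config(encoder_widths = c(4L, 3L, 2L),
                         decoder_widths = c(3L, 4L))
  set.seed(73)
  x <- matrix(abs(rnorm(6)), 2, 3); x[2] <- 0
  net <- build_network(cfg, 3, 2, seed = 9)
  net$M <- matrix(c(0, 0.2, -0.1, 0), 2, 2)
  lc <- compute_losses(x, net, cfg)
  # scalar recomputation
  h <- x
  for (l in 1:5) {
    h <- h %*% net$W[[l]]
    if (l + 1 != net$embed_index) h <- pmax(h, 0)
    if (l + 1 == net$embed_index) z <- h
  }
  pre <- h %*% net$Wh
  pi_ <- 1 / (1 + exp(-pre[, 1:3]))
  al <- log1p(exp(-abs(pre[, 4:6]))) + pmax(pre[, 4:6], 0)
  be <- log1p(exp(-abs(pre[, 7:9]))) + pmax(pre[, 7:9], 0)
  ga <- log1p(exp(-abs(pre[, 10:12]))) + pmax(pre[, 10:12], 0)
  xh <- pre[, 13:15]
  nll <- 0
  for (i in 1:2) for (j in 1:3)
    nll <- nll - tpgg_log_density(x[i, j], pi_[i, j], al[i, j], be[i, j],
                                  ga[i, j])
  reg <- sum(unlist(lapply(net$W, function(w) sum(w^2)))) +
    sum(net$Wh[, 1:12]^2)
  r <- z - net$M %*% z
  expect_equal(lc$l_rescon, 0.5 * sum((x - xh)^2), tolerance = 1e-10)
  expect_equal(lc$l_self, 0.5 * sum(r^2), tolerance = 1e-10)
  expect_equal(lc$l_spar, sum(net$M^2), tolerance = 1e-10)
  expect_equal(lc$l_tpgg, nll + reg, tolerance = 1e-10)
  expect_equal(lc$total,
               0.1 * (0.2 * lc$l_rescon + 1.0 * lc$l_self +
                        0.5 * lc$l_spar) + lc$l_tpgg,
               tolerance = 1e-10)
})

test_that("full-objective gradients match central finite differences", {
  cfg <- scpedssc_config(encoder_widths = c(6L, 4L, 3L),
                         decoder_widths = c(4L, 6L))
  set.seed(74)
  m <- 5; n <- 8
  x <- matrix(abs(rnorm(m * n)), m, n)
  x[sample(length(x), 10)] <- 0
  net <- build_network(cfg, n, m, seed = 10)
  net$M <- matrix(rnorm(m * m, sd = 0.1), m, m); diag(net$M) <- 0
  g <- scpedssc:::ae_gradients(x, net, cfg, joint = TRUE)
  total_at <- function() {
    fwd <- scpedssc:::ae_forward(net, x)
    scpedssc:::loss_components(x, net, fwd, cfg)$total
  }
  eps <- 1e-6
  check_param <- function(get, set, want, label) {
    p <- get()
    idx <- sample(length(p), min(25, length(p)))
    for (i in idx) {
      v <- p[i]
      p[i] <- v + eps; set(p); f1 <- total_at()
      p[i] <- v - eps; set(p); f2 <- total_at()
      p[i] <- v; set(p)
      expect_equal(want[i], (f1 - f2) / (2 * eps), tolerance = 1e-4,
                   label = paste(label, "entry", i))
    }
  }
  for (l in seq_along(net$W))
    check_param(function() net$W[[l]], function(p) net$W[[l]] <<- p,
                g$gW[[l]], paste0("W", l))
  check_param(function() net$Wh, function(p) net$Wh <<- p, g$gWh, "Wh")
  gm <- g$gM
  check_param(function() net$M,
              function(p) { diag(p) <- 0; net$M <<- p }, gm, "M")
})

test_that("training is deterministic, keeps diag(M) = 0 and satisfies the loss identity", {
  cfg <- tiny_config(seed = 11)
  x <- l2_normalize_rows(random_expression(15, 25, seed = 75))
  f1 <- train_autoencoder(x, cfg)
  f2 <- train_autoencoder(x, cfg)
  expect_identical(f1$losses, f2$losses)
  expect_identical(f1$m_matrix, f2$m_matrix)
  expect_equal(unname(diag(f1$m_matrix)), rep(0, 15))
  # combined-objective accounting at every logged epoch
  with(f1$losses, expect_equal(
    total, (0.2 * l_rescon + 1.0 * l_self + 0.5 * l_spar) / 10 + l_tpgg,
    tolerance = 1e-8))
  # the loss trace covers all phases plus the final state; warmup rows are
  # logged on a thinned schedule
  expect_setequal(unique(f1$losses$phase),
                  c("warmup", "pretrain", "joint", "final"))
  # thinned logging: first epoch, every fifth, and the last of each phase
  expect_equal(sum(f1$losses$phase == "pretrain"), 4)
  expect_equal(sum(f1$losses$phase == "joint"), 6)
})

test_that("training reduces the objective on multi-subspace data", {
  ok <- 0
  for (seed in 1:3) {
    sim <- simulate_cells(simulation_spec(m = 45, n = 60, k = 3,
                                          dropout_pi = 0.3, seed = seed))
    x <- l2_normalize_rows(drop_unexpressed_genes(sim$x))
    fit <- train_autoencoder(x, tiny_config(seed = seed))
    tr <- fit$losses
    if (tail(tr$total, 1) < tr$total[1]) ok <- ok + 1
  }
  expect_gte(ok, 2)
})

test_that("the ZINB ablation trains with the same surface", {
  cfg <- tiny_config(use_tpgg = FALSE, seed = 12)
  x <- l2_normalize_rows(random_expression(10, 18, seed = 76))
  fit <- train_autoencoder(x, cfg)
  expect_equal(dim(fit$m_matrix), c(10, 10))
  expect_true(all(is.finite(fit$losses$total)))
  net <- fit$net
  expect_equal(net$heads$names, c("pi", "mu", "theta", "xhat"))
})
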