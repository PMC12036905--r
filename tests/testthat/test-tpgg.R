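test_that("generalized gamma log-density hits closed-form limits", {
  # alpha = beta = gamma = 1 is the unit exponential: log f(2) = -2
  expect_equal(gg_log_density(2, 1, 1, 1), -2)
  # gamma = 1 reduces to gamma(shape = beta, scale = alpha)
  expect_equal(gg_log_density(1.5, 2, 3, 1),
               dgamma(1.5, shape = 3, scale = 2, log = TRUE),
               tolerance = 1e-12)
  xs <- c(0.1, 0.7, 2.3, 9)
  expect_equal(gg_log_density(xs, 1.7, 0.8, 1),
               dgamma(xs, shape = 0.8, scale = 1.7, log = TRUE),
               tolerance = 1e-12)
})

test_that("generalized gamma density integrates to one", {
  set.seed(11)
  for (i in 1:10) {
    a <- runif(1, 0.3, 3); b <- runif(1, 0.3, 4); g <- runif(1, 0.4, 3)
    val <- integrate(function(x) exp(gg_log_density(x, a, b, g)),
                     0, Inf, rel.tol = 1e-9)$value
    expect_equal(val, 1, tolerance = 1e-6)
  }
})

test_that("gg_log_density rejects invalid domains", {
  expect_error(gg_log_density(-1, 1, 1, 1), "positive")
  expect_error(gg_log_density(0, 1, 1, 1), "positive")
  expect_error(gg_log_density(1, -1, 1, 1), "positive")
  expect_error(gg_log_density(1, 1, 0, 1), "positive")
})

test_that("hurdle density handles both branches and integrates to one", {
  expect_equal(tpgg_log_density(0, 0.3, 1, 1, 1), log(0.3))
  # pi floor: pi = 0 with x > 0 contributes log(1 - 1e-6), not 0
  expect_equal(tpgg_log_density(2, 0, 1, 1, 1), log1p(-1e-6) - 2,
               tolerance = 1e-9)
  set.seed(12)
  for (i in 1:5) {
    p <- runif(1, 0.05, 0.95)
    a <- runif(1, 0.5, 2); b <- runif(1, 0.5, 3); g <- runif(1, 0.5, 2)
    mass <- p + (1 - p) *
      integrate(function(x) exp(gg_log_density(x, a, b, g)), 0, Inf)$value
    expect_equal(mass, 1, tolerance = 1e-5)
  }
})

test_that("matrix NLL matches a scalar-loop oracle and counts the regularizer", {
  set.seed(13)
  x <- matrix(abs(rnorm(6)), 3, 2); x[c(1, 5)] <- 0
  pi <- matrix(runif(6, 0.1, 0.9), 3, 2)
  al <- matrix(runif(6, 0.5, 2), 3, 2)
  be <- matrix(runif(6, 0.5, 3), 3, 2)
  ga <- matrix(runif(6, 0.5, 2), 3, 2)
  oracle <- 0
  for (i in 1:3) for (j in 1:2)
    oracle <- oracle - tpgg_log_density(x[i, j], pi[i, j], al[i, j],
                                        be[i, j], ga[i, j])
  expect_equal(tpgg_nll(x, pi, al, be, ga), oracle, tolerance = 1e-12)
  w <- list(matrix(1:4, 2), matrix(0.5, 2, 3))
  expect_equal(tpgg_nll(x, pi, al, be, ga, weights = w),
               oracle + sum((1:4)^2) + 6 * 0.25, tolerance = 1e-12)
  # all-zero x with pi = 0.5 and no weights: -sum log 0.5
  x0 <- matrix(0, 4, 5)
  expect_equal(tpgg_nll(x0, 0.5, 1, 1, 1), -20 * log(0.5))
})

test_that("TPGG parameter gradients match central finite differences", {
  set.seed(14)
  x <- matrix(abs(rnorm(12)), 3, 4); x[c(2, 7, 9)] <- 0
  pi <- matrix(runif(12, 0.1, 0.9), 3, 4)
  al <- matrix(runif(12, 0.5, 2), 3, 4)
  be <- matrix(runif(12, 0.5, 3), 3, 4)
  ga <- matrix(runif(12, 0.5, 2), 3, 4)
  gr <- scpedssc:::tpgg_nll_grad(x, pi, al, be, ga)
  eps <- 1e-6
  fd <- function(mat, slot) {
    out <- mat * 0
    for (i in seq_along(mat)) {
      up <- list(pi = pi, al = al, be = be, ga = ga)
      dn <- up
      up[[slot]][i] <- up[[slot]][i] + eps
      dn[[slot]][i] <- dn[[slot]][i] - eps
      out[i] <- (tpgg_nll(x, up$pi, up$al, up$be, up$ga) -
                   tpgg_nll(x, dn$pi, dn$al, dn$be, dn$ga)) / (2 * eps)
    }
    out
  }
  expect_equal(gr$dpi, fd(pi, "pi"), tolerance = 1e-5)
  expect_equal(gr$dalpha, fd(al, "al"), tolerance = 1e-5)
  expect_equal(gr$dbeta, fd(be, "be"), tolerance = 1e-5)
  expect_equal(gr$dgamma, fd(ga, "ga"), tolerance = 1e-5)
})

test_that("ZINB log-density matches the count formula and its gradients check out", {
  # at integer x the continuous extension equals dnbinom-based ZINB
  x <- c(0, 1, 3, 7)
  pi <- 0.25; mu <- 2.5; th <- 1.7
  ref <- log(ifelse(x == 0,
                    pi + (1 - pi) * dnbinom(0, size = th, mu = mu),
                    (1 - pi) * dnbinom(x, size = th, mu = mu)))
  expect_equal(scpedssc:::zinb_log_density(x, pi, mu, th), ref,
               tolerance = 1e-10)
  set.seed(15)
  xx <- matrix(abs(rnorm(9)), 3, 3); xx[c(1, 6)] <- 0
  pim <- matrix(runif(9, .1, .9), 3, 3)
  mum <- matrix(runif(9, .5, 3), 3, 3)
  thm <- matrix(runif(9, .5, 3), 3, 3)
  gr <- scpedssc:::zinb_nll_grad(xx, pim, mum, thm)
  eps <- 1e-6
  nll <- function(p, m, t) -sum(scpedssc:::zinb_log_density(xx, p, m, t))
  for (i in seq_along(xx)) {
    for (slot in 1:3) {
      pp <- pim; mm <- mum; tt <- thm
      lst <- list(pp, mm, tt)
      lst[[slot]][i] <- lst[[slot]][i] + eps
      f1 <- nll(lst[[1]], lst[[2]], lst[[3]])
      lst[[slot]][i] <- lst[[slot]][i] - 2 * eps
      f2 <- nll(lst[[1]], lst[[2]], lst[[3]])
      want <- (f1 - f2) / (2 * eps)
      got <- switch(slot, gr$dpi[i], gr$dmu[i], gr$dtheta[i])
      expect_equal(got, want, tolerance = 1e-4)
    }
  }
})
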