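# Shared fixtures, all generated in code under fixed seeds.

random_expression <- function(m, n, seed = 1, zero_frac = 0.3) {
  set.seed(seed)
  x <- matrix(abs(rnorm(m * n)), m, n)
  x[sample(length(x), round(zero_frac * length(x)))] <- 0
  # keep every row and column expressed
  for (i in seq_len(m)) if (all(x[i, ] == 0)) x[i, 1] <- 1
  for (j in seq_len(n)) if (all(x[, j] == 0)) x[1, j] <- 1
  expression_matrix(x)
}

random_partition <- function(m, k, seed = 1) {
  set.seed(seed)
  partition(sample(k, m, replace = TRUE))
}

# A small config so tiny networks train in milliseconds.
tiny_config <- function(...) {
  scpedssc_config(encoder_widths = c(16L, 8L, 4L), decoder_widths = c(8L, 16L),
                  epochs_warmup = 10L, epochs_pretrain = 15L,
                  epochs_joint = 25L, ...)
}

# Brute-force pair counting over all unordered pairs (independent oracle).
brute_pair_counts <- function(p1, p2) {
  p1 <- as.integer(unclass(partition(p1)))
  p2 <- as.integer(unclass(partition(p2)))
  a <- b <- cc <- d <- 0
  m <- length(p1)
  for (i in seq_len(m - 1)) for (j in (i + 1):m) {
    s1 <- p1[i] == p1[j]; s2 <- p2[i] == p2[j]
    if (s1 && s2) a <- a + 1
    else if (s1 && !s2) b <- b + 1
    else if (!s1 && s2) cc <- cc + 1
    else d <- d + 1
  }
  list(a = a, b = b, c = cc, d = d)
}

# Direct contingency-table NMI oracle (scalar loops, natural log).
brute_nmi <- function(p1, p2) {
  p1 <- unclass(partition(p1)); p2 <- unclass(partition(p2))
  m <- length(p1)
  u1 <- unique(p1); u2 <- unique(p2)
  mi <- 0
  for (i in u1) for (j in u2) {
    pij <- sum(p1 == i & p2 == j) / m
    if (pij > 0) mi <- mi + pij * log(pij / (sum(p1 == i) / m * sum(p2 == j) / m))
  }
  h <- function(p) {
    s <- 0
    for (i in unique(p)) { pi_ <- sum(p == i) / length(p); s <- s - pi_ * log(pi_) }
    s
  }
  h1 <- h(p1); h2 <- h(p2)
  if (h1 + h2 == 0) return(if (all(p1 == p2)) 1 else 0)
  2 * mi / (h1 + h2)
}
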