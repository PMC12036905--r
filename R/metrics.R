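# Clustering agreement metrics: adjusted Rand index in its pair-counting
# form and normalized mutual information with arithmetic-mean ("sum")
# normalization.

#' Count concordant and discordant cell pairs of two partitions
#'
#' Over all unordered pairs of cells: `a` pairs co-clustered in both
#' partitions, `b` co-clustered only in the first, `c` only in the second,
#' `d` separated in both.  `a + b + c + d = m(m-1)/2`.
#'
#' @param p1,p2 Label vectors (or [partition()] objects) of equal length.
#' @return List with numeric components `a`, `b`, `c`, `d`.
#' @export
#' @examples
#' pair_counts(c(0, 0, 1, 1), c(0, 1, 0, 1))
pair_counts <- function(p1, p2) {
  p1 <- partition(p1); p2 <- partition(p2)
  if (length(p1) != length(p2))
    stop("partitions have different lengths: ", length(p1), " vs ",
         length(p2), call. = FALSE)
  tab <- table(unclass(p1), unclass(p2))
  n <- sum(tab)
  a <- sum(choose(tab, 2))
  same1 <- sum(choose(rowSums(tab), 2))
  same2 <- sum(choose(colSums(tab), 2))
  list(a = a, b = same1 - a, c = same2 - a,
       d = choose(n, 2) - same1 - same2 + a)
}

#' Adjusted Rand index
#'
#' Computed in the pair-counting form
#' `ARI = 2(ad - bc) / ((a+b)(b+d) + (a+c)(c+d))`, which is algebraically
#' the Hubert-Arabie adjusted Rand index.  When the denominator vanishes
#' (both partitions trivial, e.g. a single cluster each) the index is 1 by
#' convention.
#'
#' @param p1,p2 Label vectors of equal length (at least 2 cells).
#' @return A scalar, 1 for identical partitions up to relabeling.
#' @export
#' @examples
#' ari(c(0, 0, 1, 1), c(1, 1, 0, 0))
ari <- function(p1, p2) {
  pc <- pair_counts(p1, p2)
  if (length(partition(p1)) < 2)
    stop("ARI needs at least 2 cells", call. = FALSE)
  den <- (pc$a + pc$b) * (pc$b + pc$d) + (pc$a + pc$c) * (pc$c + pc$d)
  if (den == 0) return(1.0)
  2 * (pc$a * pc$d - pc$b * pc$c) / den
}

#' Normalized mutual information
#'
#' `NMI = 2 MI / (H1 + H2)` with mutual information and entropies taken
#' from the joint contingency table (natural logarithm; `0 log 0 = 0`).
#' If both partitions are single-cluster (zero total entropy) the value is
#' 1 when they are identical and 0 otherwise, by convention.
#'
#' @param p1,p2 Label vectors of equal length.
#' @return A scalar in `[0, 1]`.
#' @export
#' @examples
#' nmi(c(0, 0, 1, 1), c(0, 0, 1, 1))
nmi <- function(p1, p2) {
  p1 <- partition(p1); p2 <- partition(p2)
  if (length(p1) != length(p2))
    stop("partitions have different lengths", call. = FALSE)
  if (length(p1) == 0) stop("empty partitions", call. = FALSE)
  tab <- table(unclass(p1), unclass(p2))
  m <- sum(tab)
  pij <- tab / m
  pi_ <- rowSums(pij)
  pj_ <- colSums(pij)
  ent <- function(p) { p <- p[p > 0]; -sum(p * log(p)) }
  h1 <- ent(pi_); h2 <- ent(pj_)
  if (h1 + h2 == 0) return(if (all(unclass(p1) == unclass(p2))) 1.0 else 0.0)
  outer_p <- outer(pi_, pj_)
  pos <- pij > 0
  mi <- sum(pij[pos] * log(pij[pos] / outer_p[pos]))
  2 * mi / (h1 + h2)
}

#' Evaluate a clustering against reference labels
#'
#' @param pred,truth Label vectors of equal length.
#' @return List with components `ari` and `nmi`.
#' @export
evaluate_clustering <- function(pred, truth) {
  list(ari = ari(pred, truth), nmi = nmi(pred, truth))
}
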