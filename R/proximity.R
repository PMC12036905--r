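# Second-order proximity enhancement of the self-expression matrix and
# construction of the symmetric similarity matrix.

#' Enhance a self-expression matrix with second-order proximity
#'
#' Each off-diagonal coefficient is augmented with all length-two path
#' products through intermediary cells:
#' `Mtilde[i, j] = M[i, j] + sum_k M[i, k] * M[k, j]` for `i != j`,
#' and `Mtilde[i, i] = 0` — i.e. the off-diagonal part of `M + M^2` with a
#' zeroed diagonal.  A weak direct relationship between two cells is
#' strengthened when many intermediaries relate them both.
#'
#' @param m_matrix Square self-expression matrix with (numerically) zero
#'   diagonal.
#' @return The enhanced matrix, same shape, zero diagonal.
#' @export
#' @examples
#' m <- matrix(0, 4, 4)
#' m[1, 2] <- 0.1; m[2, 4] <- 0.1; m[1, 3] <- 0.2; m[3, 4] <- 0.2
#' enhance(m)[1, 4]  # 0.1*0.1 + 0.2*0.2 = 0.05
enhance <- function(m_matrix) {
  if (!is.matrix(m_matrix) || nrow(m_matrix) != ncol(m_matrix))
    stop("self-expression matrix must be square", call. = FALSE)
  if (any(abs(diag(m_matrix)) > 1e-8))
    stop("self-expression matrix must have a zero diagonal", call. = FALSE)
  diag(m_matrix) <- 0
  out <- m_matrix + m_matrix %*% m_matrix
  diag(out) <- 0
  out
}

#' Build the symmetric similarity matrix
#'
#' `Mhat = |Mtilde| + |Mtilde^T|`, entrywise; the result is symmetric and
#' non-negative by construction and preserves a zero diagonal.
#'
#' @param m_tilde Square (typically enhanced) self-expression matrix.
#' @return Symmetric non-negative similarity matrix.
#' @export
build_similarity <- function(m_tilde) {
  if (!is.matrix(m_tilde) || nrow(m_tilde) != ncol(m_tilde))
    stop("input must be square", call. = FALSE)
  abs(m_tilde) + abs(t(m_tilde))
}
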