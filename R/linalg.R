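# Internal linear-algebra helpers shared by the calibration and filter code.
# All pseudoinverses use the same relative singular-value cutoff so behaviour
# near rank deficiency is reproducible across modules.

#' Moore-Penrose pseudoinverse with a relative singular-value cutoff
#'
#' Singular values below `rtol * max(d)` are treated as zero.
#'
#' @param x numeric matrix.
#' @param rtol relative tolerance on singular values (default 1e-10).
#' @return the pseudoinverse of `x`.
#' @keywords internal
#' @noRd
pinv <- function(x, rtol = 1e-10) {
  x <- as.matrix(x)
  s <- svd(x)
  if (length(s$d) == 0L || s$d[1] == 0) {
    return(matrix(0, ncol(x), nrow(x)))
  }
  keep <- s$d > rtol * s$d[1]
  if (!any(keep)) {
    return(matrix(0, ncol(x), nrow(x)))
  }
  s$v[, keep, drop = FALSE] %*%
    (t(s$u[, keep, drop = FALSE]) / s$d[keep])
}

#' Numerical rank via the same singular-value cutoff as pinv()
#' @keywords internal
#' @noRd
numerical_rank <- function(x, rtol = 1e-10) {
  d <- svd(as.matrix(x), nu = 0, nv = 0)$d
  if (length(d) == 0L || d[1] == 0) return(0L)
  sum(d > rtol * d[1])
}

# Squared Frobenius norm
frob2 <- function(x) sum(x^2)

# Euclidean norm of a vector
vnorm <- function(x) sqrt(sum(x^2))
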