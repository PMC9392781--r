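#' Spherical-spline scalp interpolation operator
#'
#' Builds the linear operator that maps values measured at `from`
#' electrode positions to spherical-spline estimates at `to` positions
#' (both on the unit sphere). The kernel is the truncated Legendre series
#' g(x) = (1/4*pi) * sum_{n=1}^{N} (2n+1) / (n (n+1))^m * P_n(x)
#' with spline order `m`, truncation degree `N` and a small ridge term on
#' the diagonal for numerical stability. The operator reproduces constant
#' fields exactly (it solves the standard constrained system with a free
#' additive constant) and is linear in the data, so it can be
#' precomputed once per electrode set and applied to whole segments.
#'
#' @param from n_from x 3 matrix of unit vectors (source electrodes).
#' @param to n_to x 3 matrix of unit vectors (target positions).
#' @param m spline order (smoothness), typically 4.
#' @param terms truncation degree N of the Legendre expansion.
#' @param lambda ridge regularization added to the Gram diagonal.
#' @return An n_to x n_from matrix `L`; estimates are `L %*% values`.
#' @export
spherical_spline_operator <- function(from, to, m = 4, terms = 7,
                                      lambda = 1e-5) {
  from <- as.matrix(from); to <- as.matrix(to)
  k <- nrow(from)
  if (k < 3) stop("spherical spline needs at least 3 source electrodes",
                  call. = FALSE)
  G <- .spline_g(tcrossprod(from, from), m, terms)
  Gt <- .spline_g(tcrossprod(to, from), m, terms)
  M <- rbind(cbind(G + diag(lambda, k), rep(1, k)),
             c(rep(1, k), 0))
  Minv <- solve(M)
  (cbind(Gt, rep(1, nrow(to))) %*% Minv)[, seq_len(k), drop = FALSE]
}

# g(.) evaluated elementwise on a matrix of cosines of angular distance
.spline_g <- function(cosang, m, terms) {
  x <- cosang
  x[x > 1] <- 1
  x[x < -1] <- -1
  # Legendre P_n by the Bonnet recursion, accumulated into the series
  p_prev <- array(1, dim = dim(x))   # P_0
  p_cur <- x                         # P_1
  acc <- (2 * 1 + 1) / (1 * 2)^m * p_cur
  if (terms >= 2) {
    for (n in 2:terms) {
      p_next <- ((2 * n - 1) * x * p_cur - (n - 1) * p_prev) / n
      acc <- acc + (2 * n + 1) / (n * (n + 1))^m * p_next
      p_prev <- p_cur
      p_cur <- p_next
    }
  }
  acc / (4 * pi)
}
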