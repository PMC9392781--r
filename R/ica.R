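#' Re-reference to the common average
#'
#' Subtracts, at every sample, the mean over channels, so the channel
#' mean at each time point becomes zero. Idempotent.
#'
#' @param seg an `eeg_segment` (or an `eeg_recording`).
#' @return The input with average-referenced data.
#' @export
average_reference <- function(seg) {
  x <- seg$data
  seg$data <- sweep(x, 2, colMeans(x), "-")
  seg
}

.pinv <- function(M, tol = NULL) {
  s <- svd(M)
  if (is.null(tol)) tol <- max(dim(M)) * max(s$d) * .Machine$double.eps
  pos <- s$d > tol
  s$v[, pos, drop = FALSE] %*%
    (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}

#' Decompose a segment with extended-infomax ICA
#'
#' PCA-spheres the data to `n_comp` dimensions, then runs the
#' extended-infomax algorithm, whose per-component sub/super-Gaussian
#' switch separates both peaked sources (most EEG artifacts) and flat
#' ones (e.g. line noise). The returned unmixing matrix is the infomax
#' rotation composed with the sphering transform, so
#' `W %*% seg$data` gives the component time-series directly, and the
#' mixing matrix is its pseudo-inverse.
#'
#' Data are not mean-centred before sphering: segments arriving here are
#' high-pass filtered and average-referenced, so channel means are
#' already negligible, and skipping the centring keeps
#' `mixing %*% sources` an exact reconstruction of the input at full
#' rank.
#'
#' @param seg an `eeg_segment` (average-referenced) or any channels x
#'   samples matrix wrapped in one.
#' @param n_comp number of components. Default: channel count minus one
#'   for the average reference (when the segment is average-referenced)
#'   minus one per interpolated channel, i.e. the data's effective rank.
#' @param seed integer RNG seed (mandatory for reproducibility).
#' @param cfg a [pipeline_config()] (iteration cap, tolerance,
#'   sign-estimate subsample size).
#' @return An `ica_result`: `W` (n_ICs x n_channels unmixing), `A`
#'   (n_channels x n_ICs mixing), `S` (n_ICs x n_samples sources),
#'   `n_ICs`, `seed`, `converged`, `iterations`.
#' @export
fit_extended_infomax <- function(seg, n_comp = NULL, seed = 1L,
                                 cfg = pipeline_config()) {
  X <- seg$data
  nch <- nrow(X)
  n <- ncol(X)
  C <- tcrossprod(X) / n
  ev <- eigen(C, symmetric = TRUE)
  rank_tol <- nch * max(ev$values) * .Machine$double.eps * 100
  eff_rank <- sum(ev$values > rank_tol)
  if (is.null(n_comp)) {
    avg_ref <- max(abs(colMeans(X))) < 1e-8
    n_interp <- length(seg$interpolated_channels)
    n_comp <- nch - as.integer(avg_ref) - n_interp
    n_comp <- min(n_comp, eff_rank)
  }
  if (n_comp > eff_rank) {
    stop("rank error: n_comp = ", n_comp, " exceeds effective data rank ",
         eff_rank, call. = FALSE)
  }
  d <- ev$values[seq_len(n_comp)]
  E <- ev$vectors[, seq_len(n_comp), drop = FALSE]
  sphere <- diag(1 / sqrt(d), n_comp) %*% t(E)
  Xw <- sphere %*% X
  lrate0 <- 0.00065 / log(max(n_comp, 2))
  fit <- ext_infomax_core(Xw, max_iter = cfg$ica_max_iter,
                          tol = cfg$ica_wchange, lrate = lrate0,
                          ext_points = cfg$ica_ext_points,
                          rng_seed = as.integer(seed), extended = TRUE,
                          anneal_deg = 60, anneal_step = 0.98)
  if (!fit$converged) {
    stop("convergence error: extended infomax did not converge in ",
         fit$iterations, " iterations (weight change ",
         format(fit$wchange, digits = 3), ")", call. = FALSE)
  }
  W <- fit$W %*% sphere                       # n_comp x n_channels
  S <- W %*% X
  ord <- order(apply(S, 1, stats::var), decreasing = TRUE)
  W <- W[ord, , drop = FALSE]
  S <- S[ord, , drop = FALSE]
  A <- .pinv(W)                               # n_channels x n_comp
  structure(list(W = W, A = A, S = S, n_ICs = n_comp,
                 seed = as.integer(seed), converged = fit$converged,
                 iterations = fit$iterations,
                 channel_labels = rownames(X)),
            class = "ica_result")
}

#' @export
print.ica_result <- function(x, ...) {
  cat("<ica_result> ", x$n_ICs, " ICs x ", ncol(x$S), " samples; ",
      x$iterations, " iterations (seed ", x$seed, ")\n", sep = "")
  invisible(x)
}

#' Extract component time-series from an unmixing matrix
#'
#' Computes `S = W %*% data`: the plain product of the ICA weights with
#' the channel data. Sources are deliberately left unnormalized — their
#' amplitude carries information downstream.
#'
#' @param W unmixing matrix, n_ICs x n_channels.
#' @param seg an `eeg_segment` (or anything with a `$data` matrix).
#' @return n_ICs x n_samples source matrix.
#' @export
extract_sources <- function(W, seg) {
  if (ncol(W) != nrow(seg$data)) {
    stop("dimension error: W has ", ncol(W), " columns but the segment has ",
         nrow(seg$data), " channels", call. = FALSE)
  }
  W %*% seg$data
}
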