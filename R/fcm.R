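#' Fuzzy C-means clustering of 1D feature values
#'
#' Classical alternating-optimization FCM on scalar features (CT intensity
#' or SUV within the ROI), used to obtain the rough segmentation from which
#' the class-conditional probability models are fitted. Memberships follow
#' the standard update with exponent `2/(m-1)`; centers are the
#' membership^m-weighted means. A sample coinciding exactly with a center
#' receives membership 1 to that cluster (singularity rule). Clusters are
#' reported in ascending order of center value.
#'
#' Initialization places the k centers at evenly spaced data quantiles,
#' deterministically jittered by `seed`, so runs are reproducible per seed
#' and robust for 1D features.
#'
#' @param values Numeric vector of finite feature values (at least `k`
#'   distinct values).
#' @param k Number of clusters (>= 2).
#' @param m Fuzzifier exponent (> 1); default 2.
#' @param tol Convergence threshold on the max absolute membership change.
#' @param max_iter Iteration cap.
#' @param seed Integer seed controlling the center initialization jitter.
#' @param init_jitter Jitter amplitude as a fraction of the data range
#'   (default 1e-3); 0 places centers exactly at the quantiles.
#' @return A list of class `fmrf_fcm` with `memberships` (N x k matrix,
#'   rows summing to 1), `centers` (ascending), `iterations`, `objective`
#'   (final value of \eqn{\sum_i \sum_c u_{ic}^m (v_i - c_c)^2}) and
#'   `objective_trace` (one value per iteration, non-increasing).
#' @export
#' @examples
#' r <- fuzzy_cmeans(c(0, 0, 0, 10, 10, 10), k = 2)
#' r$centers
fuzzy_cmeans <- function(values, k = 2L, m = 2, tol = 1e-5,
                         max_iter = 300L, seed = 0L, init_jitter = 1e-3) {
  values <- as.numeric(values)
  if (anyNA(values) || any(!is.finite(values)))
    abort_fmrf("fuzzy_cmeans requires finite inputs", "fmrf_error_nonfinite")
  k <- as.integer(k)
  if (k < 2L) abort_fmrf("k must be >= 2", "fmrf_error_fcm")
  if (m <= 1) abort_fmrf("fuzzifier m must be > 1", "fmrf_error_fcm")
  if (length(unique(values)) < k)
    abort_fmrf(sprintf("need at least %d distinct values for k = %d clusters", k, k),
               "fmrf_error_too_few_distinct")

  # evenly spaced quantile init, jittered deterministically by the seed
  centers <- as.numeric(quantile(values, probs = (seq_len(k) - 0.5) / k, names = FALSE))
  rng <- diff(range(values))
  if (init_jitter > 0)
    centers <- centers + withr::with_seed(seed, runif(k, -init_jitter, init_jitter)) * rng
  if (anyDuplicated(centers)) centers <- centers + seq_len(k) * 1e-9 * max(rng, 1)

  n <- length(values)
  expo <- 2 / (m - 1)
  u <- matrix(1 / k, n, k)
  trace <- numeric(0)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    d2 <- outer(values, centers, `-`)^2
    # membership update with singularity handling (d = 0 -> membership 1)
    u_new <- 1 / (d2^(expo / 2) * rowSums(d2^(-expo / 2)))
    zero <- d2 == 0
    if (any(zero)) {
      rows <- which(rowSums(zero) > 0)
      u_new[rows, ] <- zero[rows, , drop = FALSE] / rowSums(zero[rows, , drop = FALSE])
    }
    um <- u_new^m
    centers <- colSums(um * values) / colSums(um)
    trace <- c(trace, sum(um * outer(values, centers, `-`)^2))
    delta <- max(abs(u_new - u))
    u <- u_new
    if (delta <= tol || iter >= max_iter) break
  }
  ord <- order(centers)
  structure(list(memberships = u[, ord, drop = FALSE], centers = centers[ord],
                 iterations = iter, objective = trace[length(trace)],
                 objective_trace = trace, k = k, m = m),
            class = "fmrf_fcm")
}

#' Identify the tumor-like cluster of a 2-cluster FCM result
#'
#' Within a thoracic ROI the tumor class is the high-SUV cluster on PET and
#' the high-intensity (soft tissue vs. aerated lung) cluster on CT, so for
#' both feature kinds the cluster with the larger center is returned.
#'
#' @param result An [fuzzy_cmeans()] result with `k = 2`.
#' @param feature_kind `"CT"` or `"SUV"`.
#' @return Integer cluster index (column of `result$memberships`).
#' @export
tumor_cluster_index <- function(result, feature_kind = c("CT", "SUV")) {
  feature_kind <- match.arg(feature_kind)
  stopifnot(inherits(result, "fmrf_fcm"))
  if (result$k != 2L)
    abort_fmrf("tumor_cluster_index requires a k = 2 clustering", "fmrf_error_fcm")
  which.max(result$centers)
}
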