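#' Class-conditional model parameters
#'
#' Parameters of the four per-voxel feature models used in the min/max
#' joint likelihood: `p10` (normal-tissue SUV, Gaussian), `p20`
#' (normal-tissue CT, Gaussian), `p21` (tumor CT, Gaussian) and `p11`
#' (tumor SUV, uniform on `[a, b]` in density height but supported on
#' `y >= a`). `a` is the SUV threshold separating tumor from normal
#' tissue; `b` is the maximum SUV value of the studied PET ROI.
#'
#' @param mu10,sigma10 Mean/SD of normal-tissue SUV.
#' @param mu20,sigma20 Mean/SD of normal-tissue CT.
#' @param mu21,sigma21 Mean/SD of tumor CT.
#' @param a SUV threshold for the tumor uniform density (lower bound).
#' @param b Upper bound of the tumor uniform density (`b > a`).
#' @return An object of class `fmrf_model_params`.
#' @export
model_params <- function(mu10, sigma10, mu20, sigma20, mu21, sigma21, a, b) {
  p <- structure(list(mu10 = mu10, sigma10 = sigma10, mu20 = mu20,
                      sigma20 = sigma20, mu21 = mu21, sigma21 = sigma21,
                      a = a, b = b),
                 class = "fmrf_model_params")
  for (s in c("sigma10", "sigma20", "sigma21"))
    if (!is.finite(p[[s]]) || p[[s]] <= 0)
      abort_fmrf(sprintf("%s must be > 0", s), "fmrf_error_params")
  if (!is.finite(p$a) || !is.finite(p$b) || p$b <= p$a)
    abort_fmrf("tumor SUV bounds require b > a", "fmrf_error_params")
  p
}

#' @export
print.fmrf_model_params <- function(x, ...) {
  cat(sprintf(paste0("<fmrf_model_params>\n",
                     "  p10 (normal SUV): N(%.4g, %.4g^2)\n",
                     "  p20 (normal CT):  N(%.4g, %.4g^2)\n",
                     "  p21 (tumor CT):   N(%.4g, %.4g^2)\n",
                     "  p11 (tumor SUV):  uniform, a = %.4g, b = %.4g\n"),
              x$mu10, x$sigma10, x$mu20, x$sigma20, x$mu21, x$sigma21, x$a, x$b))
  invisible(x)
}

#' Gaussian class-conditional density
#'
#' \eqn{p(y) = (2\pi\sigma^2)^{-1/2} \exp(-(y-\mu)^2 / 2\sigma^2)}, the
#' model for normal-tissue SUV (`p10`) and for CT intensity of both tumor
#' (`p21`) and normal tissue (`p20`). Vectorized over `y`.
#'
#' @param y Feature value(s).
#' @param mu Class mean.
#' @param sigma Class standard deviation (> 0).
#' @return Density value(s), exact (no flooring).
#' @export
gaussian_pdf <- function(y, mu, sigma) {
  if (!is.finite(sigma) || sigma <= 0)
    abort_fmrf("sigma must be > 0", "fmrf_error_params")
  dnorm(y, mean = mu, sd = sigma)
}

#' Uniform tumor-SUV density
#'
#' Piecewise density of SUV given tumor: 0 below the threshold `a`,
#' `1/(b - a)` at and above `a`. The density is deliberately not truncated
#' above `b`: any SUV at least `a` is equally compatible with tumor, and
#' `b` (the ROI's maximum SUV) only sets the density height.
#'
#' @param y SUV value(s).
#' @param a SUV threshold separating tumor from normal tissue.
#' @param b Upper bound (> `a`).
#' @return Density value(s).
#' @export
uniform_tumor_pdf <- function(y, a, b) {
  if (!is.finite(a) || !is.finite(b) || b <= a)
    abort_fmrf("uniform_tumor_pdf requires b > a", "fmrf_error_params")
  ifelse(y >= a, 1 / (b - a), 0)
}

#' Threshold an FCM membership map into a rough segmentation
#'
#' Voxels with tumor-cluster membership strictly greater than the threshold
#' (default 0.1) form the rough tumor mask from which model parameters are
#' estimated.
#'
#' @param memberships A `MEMBERSHIP` volume (or numeric array in \[0,1\])
#'   of tumor-cluster membership degrees on the ROI grid.
#' @param threshold Membership threshold in (0, 1); strict inequality.
#' @return A `MASK` volume.
#' @export
rough_segment <- function(memberships, threshold = 0.1) {
  if (inherits(memberships, "fmrf_volume")) {
    arr <- memberships$data; spacing <- memberships$spacing
  } else {
    arr <- memberships; spacing <- c(1, 1, 1)
  }
  if (anyNA(arr) || any(arr < 0 | arr > 1))
    abort_fmrf("memberships must lie in [0, 1]", "fmrf_error_values")
  new_volume(array(as.numeric(arr > threshold), dim(arr)), spacing, "MASK")
}

stats_or_die <- function(x, what, param) {
  if (length(x) < 2L)
    abort_fmrf(sprintf("degenerate region for %s: fewer than 2 voxels in %s", param, what),
               "fmrf_error_degenerate")
  s <- sd(x)
  if (!is.finite(s) || s <= 0)
    abort_fmrf(sprintf("degenerate region for %s: zero variance in %s", param, what),
               "fmrf_error_degenerate")
  c(mean(x), s)
}

#' Estimate model parameters from rough segmentations
#'
#' Fits the class-conditional models by moment matching on the rough
#' FCM-based masks, one mask per modality: tumor CT (`mu21`, `sigma21`)
#' from the CT rough foreground, normal CT (`mu20`, `sigma20`) from the CT
#' rough background, normal SUV (`mu10`, `sigma10`) from the SUV rough
#' background. The SUV threshold `a` is the minimum SUV over the SUV rough
#' foreground, clamped from below at `mu10 + 2*sigma10` to guard against
#' rough-segmentation leakage; `b` is the maximum SUV of the whole ROI.
#' The clamp rule is reported via `message()` when it binds.
#'
#' @param ct_roi,suv_roi CT and SUV volumes on the shared ROI grid.
#' @param ct_rough,suv_rough `MASK` volumes from [rough_segment()] of the
#'   per-modality FCM membership maps.
#' @return An [model_params()] object.
#' @export
estimate_params <- function(ct_roi, suv_roi, ct_rough, suv_rough) {
  check_same_grid(ct_roi, suv_roi)
  check_same_grid(ct_roi, ct_rough)
  check_same_grid(ct_roi, suv_rough)
  ct_fg <- ct_roi$data[ct_rough$data == 1]
  ct_bg <- ct_roi$data[ct_rough$data == 0]
  suv_fg <- suv_roi$data[suv_rough$data == 1]
  suv_bg <- suv_roi$data[suv_rough$data == 0]
  if (length(suv_fg) < 2L)
    abort_fmrf("degenerate region for a: fewer than 2 voxels in SUV rough foreground",
               "fmrf_error_degenerate")
  m21 <- stats_or_die(ct_fg, "CT rough foreground", "mu21/sigma21")
  m20 <- stats_or_die(ct_bg, "CT rough background", "mu20/sigma20")
  m10 <- stats_or_die(suv_bg, "SUV rough background", "mu10/sigma10")
  a_raw <- min(suv_fg)
  a <- max(a_raw, m10[1] + 2 * m10[2])
  if (a > a_raw)
    message(sprintf("estimate_params: SUV threshold a clamped from %.4g to mu10 + 2*sigma10 = %.4g",
                    a_raw, a))
  b <- max(suv_roi$data)
  if (b <= a)
    abort_fmrf(sprintf("degenerate region for b: ROI SUV maximum %.4g does not exceed a = %.4g", b, a),
               "fmrf_error_degenerate")
  model_params(mu10 = m10[1], sigma10 = m10[2], mu20 = m20[1], sigma20 = m20[2],
               mu21 = m21[1], sigma21 = m21[2], a = a, b = b)
}

#' Per-voxel min/max likelihood fields
#'
#' Evaluates the two arms of the joint class-conditional mixture on the
#' ROI grid: the tumor arm \eqn{A_i = \min[p_{11}(y_{i,SUV}),
#' p_{21}(y_{i,CT})]} and the normal arm \eqn{B_i = \max[p_{10}(y_{i,SUV}),
#' p_{20}(y_{i,CT})]}. In `pet_only` mode the CT terms are dropped:
#' \eqn{A_i = p_{11}(y_{i,SUV})}, \eqn{B_i = p_{10}(y_{i,SUV})}.
#'
#' @param ct_roi,suv_roi CT and SUV volumes on a shared grid.
#' @param params An [model_params()] object.
#' @param mode `"petct"` (default) or `"pet_only"`.
#' @return A list of class `fmrf_likelihood_fields` with 3D arrays `A`,
#'   `B` (non-negative, finite), plus the grid `spacing`.
#' @export
likelihood_fields <- function(ct_roi, suv_roi, params, mode = c("petct", "pet_only")) {
  mode <- match.arg(mode)
  check_same_grid(ct_roi, suv_roi)
  stopifnot(inherits(params, "fmrf_model_params"))
  p11 <- uniform_tumor_pdf(suv_roi$data, params$a, params$b)
  p10 <- gaussian_pdf(suv_roi$data, params$mu10, params$sigma10)
  if (mode == "petct") {
    p21 <- gaussian_pdf(ct_roi$data, params$mu21, params$sigma21)
    p20 <- gaussian_pdf(ct_roi$data, params$mu20, params$sigma20)
    A <- pmin(p11, p21)
    B <- pmax(p10, p20)
  } else {
    A <- p11
    B <- p10
  }
  dim(A) <- dim(suv_roi$data); dim(B) <- dim(suv_roi$data)
  structure(list(A = A, B = B, spacing = suv_roi$spacing, mode = mode),
            class = "fmrf_likelihood_fields")
}

#' Write / read model parameters as YAML
#'
#' Plain-text serialization so a run is fully reproducible and parameters
#' can be inspected or overridden by hand.
#'
#' @param params An [model_params()] object.
#' @param path File path.
#' @return `read_model_params` returns an [model_params()] object.
#' @export
write_model_params <- function(params, path) {
  stopifnot(inherits(params, "fmrf_model_params"))
  yaml::write_yaml(unclass(params), path)
  invisible(path)
}

#' @rdname write_model_params
#' @export
read_model_params <- function(path) {
  do.call(model_params, yaml::read_yaml(path))
}
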