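#' Synthetic PET/CT phantom specification
#'
#' Describes a co-registered CT + SUV phantom reproducing the hard case for
#' lung tumor segmentation: a tumor ellipsoid abutting a soft-tissue slab
#' (a chest-wall / mediastinum analogue) whose CT intensity distribution
#' matches the tumor's, while the tumor alone shows elevated SUV. Lung
#' parenchyma forms the background.
#'
#' Per-class CT intensities are Gaussian; SUV is Gaussian for the normal
#' classes and uniform on `[a_true, b_true]` for tumor voxels, matching the
#' class-conditional models the segmentation assumes, so that parameter
#' recovery is well-posed. An optional Gaussian blur of the SUV volume
#' emulates PET's coarse spatial resolution (partial-volume effect); CT is
#' left sharp.
#'
#' Spec invariants enforced at construction: tumor and confounder are
#' disjoint but share at least one face-adjacent voxel pair; the tumor and
#' confounder CT means differ by at most 0.5 pooled standard deviations;
#' `a_true` exceeds every normal-class SUV mean by at least 3 of that
#' class's standard deviations.
#'
#' @param shape Integer length-3 grid shape.
#' @param spacing Voxel spacing in mm.
#' @param tumor_center 0-based voxel coordinates of the ellipsoid center.
#' @param tumor_semiaxes Ellipsoid semi-axes in voxels.
#' @param confounder_start 0-based first voxel index along the x axis of the
#'   confounder slab; the slab is every non-tumor voxel with `i >= confounder_start`.
#' @param ct_lung,ct_tumor,ct_confounder Length-2 `(mean, sd)` of the CT
#'   intensity per class (HU-like units).
#' @param suv_lung,suv_confounder Length-2 `(mean, sd)` of SUV for the
#'   normal classes.
#' @param suv_tumor Length-2 `(a_true, b_true)` bounds of the uniform tumor
#'   SUV distribution.
#' @param suv_blur_sigma_mm Standard deviation (mm) of the isotropic
#'   Gaussian blur applied to the SUV volume only; 0 disables it.
#' @param seed Integer RNG seed; generation is bit-reproducible from it.
#' @return An object of class `fmrf_phantom_spec`.
#' @seealso [default_spec()], [generate_phantom()]
#' @export
phantom_spec <- function(shape = c(48L, 48L, 12L),
                         spacing = c(2, 2, 3),
                         tumor_center = c(22, 24, 6),
                         tumor_semiaxes = c(8, 8, 3),
                         confounder_start = 29L,
                         ct_lung = c(-700, 40),
                         ct_tumor = c(40, 15),
                         ct_confounder = c(40, 15),
                         suv_lung = c(1.0, 0.3),
                         suv_confounder = c(1.0, 0.3),
                         suv_tumor = c(2.5, 10),
                         suv_blur_sigma_mm = 0,
                         seed = 0L) {
  spec <- structure(list(
    shape = as.integer(shape), spacing = as.numeric(spacing),
    tumor_center = as.numeric(tumor_center),
    tumor_semiaxes = as.numeric(tumor_semiaxes),
    confounder_start = as.integer(confounder_start),
    ct_lung = as.numeric(ct_lung), ct_tumor = as.numeric(ct_tumor),
    ct_confounder = as.numeric(ct_confounder),
    suv_lung = as.numeric(suv_lung), suv_confounder = as.numeric(suv_confounder),
    suv_tumor = as.numeric(suv_tumor),
    suv_blur_sigma_mm = as.numeric(suv_blur_sigma_mm),
    seed = as.integer(seed)
  ), class = "fmrf_phantom_spec")
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(spec) {
  if (any(spec$shape < 4L) || any(spec$spacing <= 0))
    abort_fmrf("phantom shape/spacing invalid", "fmrf_error_phantom_spec")
  if (any(spec$tumor_semiaxes <= 0) || spec$suv_tumor[2] <= spec$suv_tumor[1])
    abort_fmrf("tumor geometry or SUV bounds invalid", "fmrf_error_phantom_spec")
  lab <- phantom_labels(spec)
  n_t <- sum(lab == 1L); n_c <- sum(lab == 2L)
  if (n_t == 0L || n_c == 0L)
    abort_fmrf("tumor or confounder region is empty", "fmrf_error_phantom_spec")
  if (adjacent_pairs(lab) == 0L)
    abort_fmrf("tumor and confounder share no face-adjacent voxel pair",
               "fmrf_error_phantom_spec")
  pooled <- sqrt((spec$ct_tumor[2]^2 + spec$ct_confounder[2]^2) / 2)
  if (abs(spec$ct_tumor[1] - spec$ct_confounder[1]) > 0.5 * pooled)
    abort_fmrf("tumor and confounder CT means are not similar (> 0.5 pooled SD apart)",
               "fmrf_error_phantom_spec")
  for (cls in list(spec$suv_lung, spec$suv_confounder)) {
    if (spec$suv_tumor[1] < cls[1] + 3 * cls[2])
      abort_fmrf("tumor SUV lower bound must exceed normal SUV mean by >= 3 SD",
                 "fmrf_error_phantom_spec")
  }
  invisible(spec)
}

# Class labels on the grid: 0 = lung, 1 = tumor ellipsoid, 2 = confounder slab.
# The slab is every non-tumor voxel at x index >= confounder_start, which
# makes tumor and confounder disjoint by construction.
phantom_labels <- function(spec) {
  n <- spec$shape
  i <- (seq_len(n[1]) - 1) - spec$tumor_center[1]
  j <- (seq_len(n[2]) - 1) - spec$tumor_center[2]
  k <- (seq_len(n[3]) - 1) - spec$tumor_center[3]
  r2 <- outer(outer((i / spec$tumor_semiaxes[1])^2,
                    (j / spec$tumor_semiaxes[2])^2, `+`),
              (k / spec$tumor_semiaxes[3])^2, `+`)
  lab <- array(0L, dim = n)
  lab[r2 <= 1] <- 1L
  slab <- array(FALSE, dim = n)
  slab[(spec$confounder_start + 1):n[1], , ] <- TRUE
  lab[slab & lab != 1L] <- 2L
  lab
}

# Number of face-adjacent (6-connectivity) tumor/confounder voxel pairs.
adjacent_pairs <- function(lab) {
  n <- dim(lab); cnt <- 0L
  for (d in 1:3) {
    if (n[d] < 2L) next
    idx_a <- lapply(n, seq_len); idx_b <- idx_a
    idx_a[[d]] <- seq_len(n[d] - 1L); idx_b[[d]] <- 2:n[d]
    a <- do.call(`[`, c(list(lab), idx_a)); b <- do.call(`[`, c(list(lab), idx_b))
    cnt <- cnt + sum((a == 1L & b == 2L) | (a == 2L & b == 1L))
  }
  cnt
}

#' Default "paper-like" phantom configuration
#'
#' Lung CT far below the tumor/confounder soft-tissue CT; tumor and
#' confounder CT distributions identical (mean 40, sd 15 HU-like units) so
#' CT alone cannot separate them; normal SUV N(1.0, 0.3); tumor SUV
#' uniform on \[2.5, 10\]; SUV blurred with a 2.5 mm Gaussian emulating
#' PET's coarse resolution. Grid 48x48x12 at 2x2x3 mm, tumor semi-axes
#' 8x8x3 voxels.
#'
#' @param seed Integer RNG seed.
#' @return An [phantom_spec()] object.
#' @export
default_spec <- function(seed = 0L) {
  phantom_spec(suv_blur_sigma_mm = 2.5, seed = seed)
}

# Separable Gaussian convolution along one array dimension with a
# kernel truncated at 3 sigma and renormalized at the edges.
conv_gauss_dim <- function(a, d, sigma) {
  if (sigma <= 0) return(a)
  dm <- dim(a)
  perm <- c(d, setdiff(1:3, d))
  ap <- aperm(a, perm)
  n <- dim(ap)[1]
  M <- matrix(ap, nrow = n)
  r <- as.integer(min(n - 1, ceiling(3 * sigma)))
  w <- stats::dnorm(seq(-r, r), sd = sigma)
  out <- matrix(0, nrow(M), ncol(M)); norm <- numeric(n)
  for (t in seq(-r, r)) {
    src <- seq.int(max(1, 1 + t), min(n, n + t))
    dst <- src - t
    wi <- w[t + r + 1L]
    out[dst, ] <- out[dst, ] + wi * M[src, , drop = FALSE]
    norm[dst] <- norm[dst] + wi
  }
  aperm(array(out / norm, dim(ap)), order(perm))
}

gaussian_blur3 <- function(a, sigma_vox) {
  for (d in 1:3) a <- conv_gauss_dim(a, d, sigma_vox[d])
  a
}

#' Generate a co-registered synthetic PET/CT phantom
#'
#' Draws CT intensities per class from the spec's Gaussians, SUV from the
#' normal-class Gaussians and the tumor uniform `[a_true, b_true]`, then
#' optionally blurs the SUV volume. The ground-truth mask is the geometric
#' tumor ellipsoid, independent of noise and blur. Bit-reproducible from
#' `spec$seed`.
#'
#' @param spec An [phantom_spec()] object.
#' @return A list with elements `ct`, `suv` (volumes), `truth` (MASK
#'   volume) and `labels` (integer array: 0 lung, 1 tumor, 2 confounder).
#' @export
#' @examples
#' ph <- generate_phantom(default_spec(1))
#' sum(ph$truth$data)  # tumor voxels
generate_phantom <- function(spec) {
  validate_phantom_spec(spec)
  lab <- phantom_labels(spec)
  withr::with_seed(spec$seed, {
    ct <- array(0, spec$shape); suv <- array(0, spec$shape)
    for (cls in 0:2) {
      p_ct <- switch(as.character(cls), "0" = spec$ct_lung,
                     "1" = spec$ct_tumor, "2" = spec$ct_confounder)
      sel <- lab == cls
      m <- sum(sel)
      ct[sel] <- if (p_ct[2] > 0) rnorm(m, p_ct[1], p_ct[2]) else rep(p_ct[1], m)
      if (cls == 1L) {
        suv[sel] <- runif(m, spec$suv_tumor[1], spec$suv_tumor[2])
      } else {
        p_suv <- if (cls == 0L) spec$suv_lung else spec$suv_confounder
        suv[sel] <- if (p_suv[2] > 0) rnorm(m, p_suv[1], p_suv[2]) else rep(p_suv[1], m)
      }
    }
  })
  if (spec$suv_blur_sigma_mm > 0)
    suv <- gaussian_blur3(suv, spec$suv_blur_sigma_mm / spec$spacing)
  list(ct = new_volume(ct, spec$spacing, "CT"),
       suv = new_volume(suv, spec$spacing, "SUV"),
       truth = new_volume(array(as.numeric(lab == 1L), spec$shape),
                          spec$spacing, "MASK"),
       labels = lab)
}

#' @export
print.fmrf_phantom_spec <- function(x, ...) {
  cat(sprintf(paste0(
    "<fmrf_phantom_spec> %s voxels @ %s mm, seed %d\n",
    "  tumor: center (%s), semi-axes (%s); confounder slab from i=%d\n",
    "  CT   lung %g+-%g, tumor %g+-%g, confounder %g+-%g\n",
    "  SUV  lung %g+-%g, confounder %g+-%g, tumor U(%g, %g), blur %g mm\n"),
    paste(x$shape, collapse = "x"), paste(x$spacing, collapse = "x"), x$seed,
    paste(x$tumor_center, collapse = ","), paste(x$tumor_semiaxes, collapse = ","),
    x$confounder_start,
    x$ct_lung[1], x$ct_lung[2], x$ct_tumor[1], x$ct_tumor[2],
    x$ct_confounder[1], x$ct_confounder[2],
    x$suv_lung[1], x$suv_lung[2], x$suv_confounder[1], x$suv_confounder[2],
    x$suv_tumor[1], x$suv_tumor[2], x$suv_blur_sigma_mm))
  invisible(x)
}
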