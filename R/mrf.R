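#' Optimization configuration for the fuzzy MRF objective
#'
#' @param alpha Gradient step size (> 0). Small values keep plain gradient
#'   descent stable; see `monotone` for the safeguard.
#' @param beta Gibbs smoothing weight (>= 0) on
#'   \eqn{\sum_i \sum_{j \in R_i} (x_i - x_j)^2}. Its gradient scales as
#'   `4 * beta * |R|` with `|R| ~ 74` neighbors in the 5x5x3 window, so
#'   the default 0.01 gives the prior an effective weight of about 3,
#'   comparable to the O(1) scale of the log-likelihood data term; much
#'   larger values erode convex tumors by curvature smoothing.
#' @param epsilon Stopping threshold on the 2-norm of the realized
#'   (post-projection) update. `NULL` (default) resolves at run time to
#'   `1e-4 * sqrt(N)` for an N-voxel ROI, making the rule scale-aware.
#' @param max_iter Iteration cap.
#' @param nbhd Neighborhood half-extents; the default `c(2, 2, 1)` is the
#'   5x5x3 window (5x5 axial, 3 across slices, matching CT's finer
#'   in-plane resolution). The center voxel is excluded; windows are
#'   truncated at the ROI boundary.
#' @param final_threshold Membership threshold `t` for the binary GTV.
#' @param log_floor Floor applied inside the logarithm (and its
#'   derivative) to guard voxels where both likelihood arms underflow.
#' @param init Membership initialization: `"likelihood_ratio"` or
#'   `"uniform_half"`.
#' @param monotone If `TRUE` (default), a step that would decrease the
#'   objective is retried with a halved step size (with a warning), so the
#'   accepted energy trace is non-decreasing.
#' @return An object of class `fmrf_optim_config`.
#' @export
optim_config <- function(alpha = 1e-3, beta = 0.01, epsilon = NULL,
                         max_iter = 5000L, nbhd = c(2L, 2L, 1L),
                         final_threshold = 0.5, log_floor = 1e-12,
                         init = c("likelihood_ratio", "uniform_half"),
                         monotone = TRUE) {
  init <- match.arg(init)
  if (!is.finite(alpha) || alpha <= 0) abort_fmrf("alpha must be > 0", "fmrf_error_config")
  if (!is.finite(beta) || beta < 0) abort_fmrf("beta must be >= 0", "fmrf_error_config")
  if (!is.null(epsilon) && (!is.finite(epsilon) || epsilon <= 0))
    abort_fmrf("epsilon must be > 0", "fmrf_error_config")
  if (any(nbhd < 0)) abort_fmrf("neighborhood half-extents must be >= 0", "fmrf_error_config")
  if (final_threshold <= 0 || final_threshold >= 1)
    abort_fmrf("final_threshold must be in (0, 1)", "fmrf_error_config")
  structure(list(alpha = alpha, beta = beta, epsilon = epsilon,
                 max_iter = as.integer(max_iter), nbhd = as.integer(nbhd),
                 final_threshold = final_threshold, log_floor = log_floor,
                 init = init, monotone = isTRUE(monotone)),
            class = "fmrf_optim_config")
}

as_membership_array <- function(x) {
  if (inherits(x, "fmrf_volume")) x <- x$data
  if (!is.array(x) || length(dim(x)) != 3L)
    abort_fmrf("membership field must be a 3D array or volume", "fmrf_error_dimensionality")
  if (anyNA(x) || any(x < 0 | x > 1))
    abort_fmrf("membership values must lie in [0, 1]", "fmrf_error_values")
  x
}

check_fields_grid <- function(x, fields) {
  if (!inherits(fields, "fmrf_likelihood_fields"))
    abort_fmrf("fields must be an fmrf_likelihood_fields object", "fmrf_error_fields")
  if (!all(dim(x) == dim(fields$A)))
    abort_fmrf("grid mismatch between membership field and likelihood fields",
               "fmrf_error_grid_mismatch")
  invisible(NULL)
}

# Sliding-window sums over the (2h+1)-box including the center,
# truncated at boundaries.
box_sum3 <- function(a, h) {
  box_sum3_cpp(as.numeric(a), as.integer(dim(a)), as.integer(h))
}

neighbor_counts <- function(shape, h) {
  box_sum3(array(1, shape), h) - 1
}

#' Fuzzy MRF objective C(x)
#'
#' \deqn{C(x) = \sum_i \{\ln[x_i A_i + (1-x_i) B_i]
#'   - \beta \sum_{j \in R_i} (x_i - x_j)^2\},}
#' where \eqn{A_i, B_i} are the tumor/normal arms of the min/max mixture
#' ([likelihood_fields()]) and \eqn{R_i} is the 5x5x3 neighborhood of
#' voxel i (center excluded, truncated at the ROI boundary). The mixture
#' is floored at `cfg$log_floor` inside the logarithm.
#'
#' @param x Membership field (3D array or `MEMBERSHIP` volume, values in
#'   \[0,1\]).
#' @param fields An [likelihood_fields()] object on the same grid.
#' @param cfg An [optim_config()].
#' @return The scalar objective value (to be maximized).
#' @export
energy <- function(x, fields, cfg = optim_config()) {
  x <- as_membership_array(x)
  check_fields_grid(x, fields)
  m <- x * fields$A + (1 - x) * fields$B
  data_term <- sum(log(pmax(m, cfg$log_floor)))
  if (cfg$beta > 0) {
    nbr <- neighbor_counts(dim(x), cfg$nbhd)
    t_sum <- box_sum3(x, cfg$nbhd) - x
    q_sum <- box_sum3(x^2, cfg$nbhd) - x^2
    smooth <- sum(nbr * x^2 - 2 * x * t_sum + q_sum)
  } else smooth <- 0
  data_term - cfg$beta * smooth
}

#' Gradient of the negated objective
#'
#' Returns \eqn{\Delta x_i = \partial[-C(x)]/\partial x_i =
#' -(A_i - B_i)/\max(x_i A_i + (1-x_i) B_i, \mathrm{floor})
#' + 4\beta \sum_{j \in R_i}(x_i - x_j)}. The factor 4 (not 2) arises
#' because the difference with each neighbor appears both in voxel i's own
#' energy term and in the neighbor's, and the window is symmetric under
#' reflection even when truncated at the boundary.
#'
#' @inheritParams energy
#' @return A 3D array, the descent direction for the update
#'   `x <- x - alpha * gradient`.
#' @export
gradient <- function(x, fields, cfg = optim_config()) {
  x <- as_membership_array(x)
  check_fields_grid(x, fields)
  m <- x * fields$A + (1 - x) * fields$B
  g <- -(fields$A - fields$B) / pmax(m, cfg$log_floor)
  if (cfg$beta > 0) {
    nbr <- neighbor_counts(dim(x), cfg$nbhd)
    t_sum <- box_sum3(x, cfg$nbhd) - x
    g <- g + 4 * cfg$beta * (nbr * x - t_sum)
  }
  g
}

#' Initialize the membership field
#'
#' `uniform_half` sets every voxel to 0.5; `likelihood_ratio` sets
#' \eqn{x_i = A_i / (A_i + B_i)} (0.5 where \eqn{A_i + B_i} is at or below
#' the log floor), a data-driven start close to the voxelwise optimum of
#' the data term.
#'
#' @param fields An [likelihood_fields()] object.
#' @param mode `"likelihood_ratio"` or `"uniform_half"`.
#' @param log_floor Underflow guard for the denominator.
#' @return A `MEMBERSHIP` volume.
#' @export
initialize_membership <- function(fields, mode = c("likelihood_ratio", "uniform_half"),
                                  log_floor = 1e-12) {
  mode <- match.arg(mode)
  if (mode == "uniform_half") {
    x <- array(0.5, dim(fields$A))
  } else {
    s <- fields$A + fields$B
    x <- ifelse(s <= log_floor, 0.5, fields$A / s)
    dim(x) <- dim(fields$A)
  }
  new_volume(x, fields$spacing, "MEMBERSHIP")
}

#' Projected gradient ascent on the fuzzy MRF objective
#'
#' Iterates `x <- clip(x - alpha * gradient, 0, 1)` until the 2-norm of
#' the realized post-projection change is at most `epsilon` or `max_iter`
#' is reached. With `cfg$monotone` (default) a step that would decrease
#' the objective is retried at half the step size, so the accepted energy
#' trace is non-decreasing; a warning reports the first halving.
#'
#' @param x0 Initial membership field (3D array or `MEMBERSHIP` volume).
#' @param fields An [likelihood_fields()] object on the same grid.
#' @param cfg An [optim_config()].
#' @return A list with `x_hat` (`MEMBERSHIP` volume), `trace` (data frame:
#'   iteration, energy, step_norm, alpha; iteration 0 is the initial
#'   state) and `converged`.
#' @export
optimize_membership <- function(x0, fields, cfg = optim_config()) {
  x <- as_membership_array(x0)
  check_fields_grid(x, fields)
  eps <- if (is.null(cfg$epsilon)) 1e-4 * sqrt(length(x)) else cfg$epsilon
  alpha <- cfg$alpha
  e_cur <- energy(x, fields, cfg)
  if (!is.finite(e_cur))
    abort_fmrf("non-finite objective at the initial point", "fmrf_error_nonfinite")
  iters <- integer(cfg$max_iter + 1L)
  energies <- numeric(cfg$max_iter + 1L)
  steps <- numeric(cfg$max_iter + 1L)
  alphas <- numeric(cfg$max_iter + 1L)
  energies[1] <- e_cur; steps[1] <- NA_real_; alphas[1] <- alpha
  n_rec <- 1L
  warned <- FALSE
  converged <- FALSE
  for (it in seq_len(cfg$max_iter)) {
    g <- gradient(x, fields, cfg)
    accept <- TRUE
    repeat {
      x_new <- pmin(pmax(x - alpha * g, 0), 1)
      step_norm <- sqrt(sum((x_new - x)^2))
      e_new <- energy(x_new, fields, cfg)
      if (!is.finite(e_new))
        abort_fmrf("non-finite objective encountered during descent (bad alpha or degenerate fields)",
                   "fmrf_error_nonfinite")
      if (!cfg$monotone || e_new >= e_cur) break
      if (step_norm <= eps) {
        # a sub-epsilon step that would lower the objective: stop here
        accept <- FALSE
        break
      }
      if (!warned) {
        warning("objective decreased; halving step size alpha", call. = FALSE)
        warned <- TRUE
      }
      alpha <- alpha / 2
    }
    if (accept) {
      x <- x_new; e_cur <- e_new
    } else {
      step_norm <- 0; e_new <- e_cur
    }
    n_rec <- n_rec + 1L
    iters[n_rec] <- it; energies[n_rec] <- e_new; steps[n_rec] <- step_norm
    alphas[n_rec] <- alpha
    if (step_norm <= eps) { converged <- TRUE; break }
  }
  trace <- data.frame(iteration = c(0L, iters[2:n_rec]),
                      energy = energies[1:n_rec],
                      step_norm = steps[1:n_rec],
                      alpha = alphas[1:n_rec])
  list(x_hat = new_volume(x, fields$spacing, "MEMBERSHIP"),
       trace = trace, converged = converged)
}

#' Threshold the membership field into a binary GTV
#'
#' @param x Membership field (3D array or `MEMBERSHIP` volume).
#' @param t Threshold in (0, 1); voxels with `x >= t` become tumor.
#' @return A `MASK` volume.
#' @export
threshold_membership <- function(x, t = 0.5) {
  spacing <- if (inherits(x, "fmrf_volume")) x$spacing else c(1, 1, 1)
  x <- as_membership_array(x)
  if (t <= 0 || t >= 1) abort_fmrf("threshold t must be in (0, 1)", "fmrf_error_config")
  new_volume(array(as.numeric(x >= t), dim(x)), spacing, "MASK")
}

#' End-to-end fuzzy MRF segmentation of a PET/CT region of interest
#'
#' Runs the full pipeline on co-registered CT and SUV ROI volumes: fuzzy
#' C-means per modality, rough segmentation at the membership threshold,
#' moment-matching parameter estimation, min/max likelihood fields,
#' membership initialization, projected gradient ascent, and final
#' thresholding. Errors raised by a stage carry the stage name.
#'
#' @param ct_roi,suv_roi CT and SUV volumes on a shared grid (the
#'   manually selected region containing the tumor).
#' @param cfg An [optim_config()].
#' @param mode `"petct"` fuses both modalities through the min/max
#'   mixture; `"pet_only"` drops the CT terms (the PET-only fuzzy MRF
#'   variant).
#' @param rough_threshold Membership threshold of the rough segmentation
#'   (strict `>`; default 0.1).
#' @param fcm_seed Seed for the FCM center initialization.
#' @return A list of class `fmrf_segmentation`: `mask` (binary GTV on the
#'   ROI grid), `x_hat` (converged membership volume), `params`
#'   ([model_params()]), `trace` (optimizer trace), `converged`, `mode`,
#'   `cfg`, and the per-modality `fcm` results and `rough` masks.
#' @export
#' @examples
#' ph <- generate_phantom(default_spec(1))
#' seg <- segment(ph$ct, ph$suv, cfg = optim_config(max_iter = 200L))
#' dsc(seg$mask, ph$truth)
segment <- function(ct_roi, suv_roi, cfg = optim_config(),
                    mode = c("petct", "pet_only"),
                    rough_threshold = 0.1, fcm_seed = 0L) {
  mode <- match.arg(mode)
  with_stage("io", check_same_grid(ct_roi, suv_roi))
  fcm_ct <- with_stage("fcm", fuzzy_cmeans(as.numeric(ct_roi$data), k = 2L, seed = fcm_seed))
  fcm_suv <- with_stage("fcm", fuzzy_cmeans(as.numeric(suv_roi$data), k = 2L, seed = fcm_seed))
  shape <- dim(ct_roi$data)
  memb_ct <- array(fcm_ct$memberships[, tumor_cluster_index(fcm_ct, "CT")], shape)
  memb_suv <- array(fcm_suv$memberships[, tumor_cluster_index(fcm_suv, "SUV")], shape)
  rough_ct <- with_stage("rough_segment", {
    v <- new_volume(memb_ct, ct_roi$spacing, "MEMBERSHIP")
    rough_segment(v, rough_threshold)
  })
  rough_suv <- with_stage("rough_segment", {
    v <- new_volume(memb_suv, suv_roi$spacing, "MEMBERSHIP")
    rough_segment(v, rough_threshold)
  })
  params <- with_stage("estimate_params",
                       estimate_params(ct_roi, suv_roi, rough_ct, rough_suv))
  fields <- with_stage("likelihood_fields",
                       likelihood_fields(ct_roi, suv_roi, params, mode))
  x0 <- with_stage("initialize", initialize_membership(fields, cfg$init, cfg$log_floor))
  opt <- with_stage("optimize", optimize_membership(x0, fields, cfg))
  mask <- with_stage("threshold",
                     threshold_membership(opt$x_hat, cfg$final_threshold))
  structure(list(mask = mask, x_hat = opt$x_hat, params = params,
                 trace = opt$trace, converged = opt$converged, mode = mode,
                 cfg = cfg,
                 fcm = list(ct = fcm_ct, suv = fcm_suv),
                 rough = list(ct = rough_ct, suv = rough_suv)),
            class = "fmrf_segmentation")
}

#' @export
print.fmrf_segmentation <- function(x, ...) {
  cat(sprintf("<fmrf_segmentation> mode %s, %d iterations (%s), GTV %d voxels\n",
              x$mode, max(x$trace$iteration),
              if (x$converged) "converged" else "max_iter reached",
              sum(x$mask$data)))
  print(x$params)
  invisible(x)
}
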