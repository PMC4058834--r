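test_that("energy matches the brute-force double-loop oracle", {
  # hand-sized 2x2x2 toy
  inst <- random_instance(c(2, 2, 2), seed = 101, beta = 0.1)
  f <- make_fields(inst$A, inst$B)
  cfg <- optim_config(beta = 0.1)
  expect_equal(energy(inst$x, f, cfg),
               brute_energy(inst$x, inst$A, inst$B, 0.1), tolerance = 1e-12)
  # larger random instances, several betas and window shapes
  for (s in 1:4) {
    inst <- random_instance(c(5, 4, 3), seed = 200 + s)
    beta <- c(0, 0.01, 0.1, 1)[s]
    h <- list(c(2, 2, 1), c(1, 1, 1), c(2, 2, 1), c(0, 1, 1))[[s]]
    cfg <- optim_config(beta = beta, nbhd = h)
    expect_equal(energy(inst$x, make_fields(inst$A, inst$B), cfg),
                 brute_energy(inst$x, inst$A, inst$B, beta, h),
                 tolerance = 1e-10)
  }
})

test_that("energy special cases: single voxel and constant fields", {
  f <- make_fields(array(1, c(1, 1, 1)), array(0, c(1, 1, 1)))
  expect_equal(energy(array(1, c(1, 1, 1)), f, optim_config(beta = 5)), 0)
  # constant membership: the smoothness term vanishes exactly
  inst <- random_instance(c(4, 4, 2), seed = 7)
  f2 <- make_fields(inst$A, inst$B)
  xc <- array(0.3, c(4, 4, 2))
  e_smooth <- energy(xc, f2, optim_config(beta = 2))
  e_data <- sum(log(0.3 * inst$A + 0.7 * inst$B))
  expect_equal(e_smooth, e_data, tolerance = 1e-12)
})

test_that("analytic gradient matches finite differences of the brute energy", {
  inst <- random_instance(c(3, 3, 3), seed = 55, beta = 0.1)
  cfg <- optim_config(beta = 0.1)
  g <- gradient(inst$x, make_fields(inst$A, inst$B), cfg)
  hstep <- 1e-6
  for (v in seq_len(27)) {
    xp <- inst$x; xp[v] <- xp[v] + hstep
    xm <- inst$x; xm[v] <- xm[v] - hstep
    fd <- (brute_energy(xp, inst$A, inst$B, 0.1) -
             brute_energy(xm, inst$A, inst$B, 0.1)) / (2 * hstep)
    # gradient() returns the descent direction for -C
    expect_lt(abs(g[v] + fd), 1e-4 * max(1, abs(fd)))
  }
})

test_that("gradient special cases", {
  inst <- random_instance(c(4, 3, 2), seed = 70)
  cfg <- optim_config(beta = 0.5)
  # constant field: smoothness part identically zero
  xc <- array(0.4, c(4, 3, 2))
  g <- gradient(xc, make_fields(inst$A, inst$B), cfg)
  g0 <- -(inst$A - inst$B) / (0.4 * inst$A + 0.6 * inst$B)
  expect_equal(g, g0, tolerance = 1e-12)
  # A == B: data part zero, gradient is purely the smoothness term
  f_eq <- make_fields(inst$A, inst$A)
  g2 <- gradient(inst$x, f_eq, cfg)
  nbr <- fuzzymrf:::neighbor_counts(dim(inst$x), cfg$nbhd)
  t_sum <- fuzzymrf:::box_sum3(inst$x, cfg$nbhd) - inst$x
  expect_equal(g2, 4 * 0.5 * (nbr * inst$x - t_sum), tolerance = 1e-12)
})

test_that("optimizer: fixed point, 1-voxel sign analysis, projection safety", {
  # single voxel with A > B at x0 = 1 is a fixed point
  f <- make_fields(array(0.8, c(1, 1, 1)), array(0.2, c(1, 1, 1)))
  r <- optimize_membership(array(1, c(1, 1, 1)), f, optim_config())
  expect_true(r$converged)
  expect_equal(max(r$trace$iteration), 1)
  expect_equal(as.numeric(r$x_hat$data), 1)
  # beta = 0: the 1-voxel data term is monotone in x
  cfg0 <- optim_config(alpha = 0.05, beta = 0, epsilon = 1e-10, max_iter = 10000)
  up <- optimize_membership(array(0.5, c(1, 1, 1)), f, cfg0)
  expect_equal(as.numeric(up$x_hat$data), 1, tolerance = 1e-6)
  f_dn <- make_fields(array(0.2, c(1, 1, 1)), array(0.8, c(1, 1, 1)))
  dn <- optimize_membership(array(0.5, c(1, 1, 1)), f_dn, cfg0)
  expect_equal(as.numeric(dn$x_hat$data), 0, tolerance = 1e-6)
  # 1-D grid-search cross-check of the 1-voxel objective maximizer
  grid <- seq(0, 1, 1e-3)
  best <- grid[which.max(log(grid * 0.2 + (1 - grid) * 0.8))]
  expect_equal(as.numeric(dn$x_hat$data), best, tolerance = 1e-3)
  # projection: iterates stay in [0,1] even with a violent step size
  inst <- random_instance(c(4, 4, 2), seed = 3)
  big <- optim_config(alpha = 5, beta = 0.1, max_iter = 50, monotone = FALSE)
  rb <- optimize_membership(inst$x, make_fields(inst$A, inst$B), big)
  expect_true(all(rb$x_hat$data >= 0 & rb$x_hat$data <= 1))
})

test_that("converged objective matches the coordinate grid-search oracle", {
  inst <- random_instance(c(4, 4, 2), seed = 11, beta = 0.1)
  oracle <- grid_search_oracle(inst$A, inst$B, 0.1)
  cfg <- optim_config(alpha = 1e-3, beta = 0.1, epsilon = 1e-9, max_iter = 50000)
  r <- suppressWarnings(
    optimize_membership(initialize_membership(make_fields(inst$A, inst$B)),
                        make_fields(inst$A, inst$B), cfg))
  ours <- brute_energy(r$x_hat$data, inst$A, inst$B, 0.1)
  expect_gte(ours, oracle$objective - 1e-6)
  # agreement with the grid maximizer is limited by the 0.05 grid pitch
  expect_lt(max(abs(r$x_hat$data - oracle$x)), 0.1)
})

test_that("smoothness of the converged field is non-increasing in beta", {
  ph <- generate_phantom(default_spec(5))
  pairsum <- function(x, h = c(2, 2, 1)) {
    nbr <- fuzzymrf:::neighbor_counts(dim(x), h)
    t_sum <- fuzzymrf:::box_sum3(x, h) - x
    q_sum <- fuzzymrf:::box_sum3(x^2, h) - x^2
    sum(nbr * x^2 - 2 * x * t_sum + q_sum)
  }
  vals <- vapply(c(0.01, 0.1, 1), function(b) {
    seg <- segment(ph$ct, ph$suv, cfg = optim_config(beta = b))
    pairsum(seg$x_hat$data)
  }, numeric(1))
  b0 <- segment(ph$ct, ph$suv, cfg = optim_config(beta = 0))
  vals <- c(pairsum(b0$x_hat$data), vals)
  expect_true(all(diff(vals) <= 1e-6 * max(vals)))
})

test_that("initialize_membership and threshold_membership follow their definitions", {
  A <- array(c(0, 0.5, 0.3, 0), c(2, 2, 1))
  B <- array(c(0.2, 0.5, 0, 0), c(2, 2, 1))
  f <- make_fields(A, B)
  x <- initialize_membership(f, "likelihood_ratio")
  expect_equal(as.numeric(x$data), c(0, 0.5, 1, 0.5))  # A=B=0 falls back to 0.5
  expect_true(all(initialize_membership(f, "uniform_half")$data == 0.5))
  m <- threshold_membership(array(c(0.2, 0.5, 0.9, 0), c(2, 2, 1)), 0.5)
  expect_equal(as.numeric(m$data), c(0, 1, 1, 0))  # >= convention at t
  expect_true(all(threshold_membership(array(1, c(2, 2, 1)), 0.5)$data == 1))
  expect_true(all(threshold_membership(array(0, c(2, 2, 1)), 0.5)$data == 0))
})

test_that("segment runs end-to-end and stage errors carry their stage", {
  ph <- generate_phantom(default_spec(6))
  seg <- segment(ph$ct, ph$suv)
  expect_s3_class(seg, "fmrf_segmentation")
  expect_gt(dsc(seg$mask, ph$truth), 0.9)
  expect_true(all(seg$x_hat$data >= 0 & seg$x_hat$data <= 1))
  # energy trace of the accepted iterations never decreases
  expect_true(all(diff(seg$trace$energy) >= 0))
  # a constant SUV volume cannot be clustered: error labeled with its stage
  flat <- new_volume(array(1, dim(ph$suv$data)), ph$suv$spacing, "SUV")
  err <- expect_error(segment(ph$ct, flat), class = "fmrf_stage_error")
  expect_match(conditionMessage(err), "\\[stage fcm\\]")
  expect_error(segment(ph$ct, extract_roi(ph$suv, roi_box(c(0, 0, 0), c(10, 10, 4)))),
               class = "fmrf_error_grid_mismatch")
})

test_that("pet_only GTV is larger than the fused petct GTV on blurred phantoms", {
  ph <- generate_phantom(default_spec(12))
  pc <- segment(ph$ct, ph$suv, mode = "petct")
  po <- segment(ph$ct, ph$suv, mode = "pet_only")
  expect_gt(sum(po$mask$data), sum(pc$mask$data))
})
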