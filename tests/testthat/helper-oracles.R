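# Independent brute-force oracles for the MRF objective, kept deliberately
# separate from the package's separable box-sum implementation.

# C(x) by direct double loop over voxels and their (2h+1)-window neighbors.
brute_energy <- function(x, A, B, beta, h = c(2, 2, 1), log_floor = 1e-12) {
  n <- dim(x)
  e <- 0
  for (i in seq_len(n[1])) for (j in seq_len(n[2])) for (k in seq_len(n[3])) {
    m <- x[i, j, k] * A[i, j, k] + (1 - x[i, j, k]) * B[i, j, k]
    sm <- 0
    for (di in -h[1]:h[1]) for (dj in -h[2]:h[2]) for (dk in -h[3]:h[3]) {
      if (di == 0 && dj == 0 && dk == 0) next
      ii <- i + di; jj <- j + dj; kk <- k + dk
      if (ii < 1 || ii > n[1] || jj < 1 || jj > n[2] || kk < 1 || kk > n[3]) next
      sm <- sm + (x[i, j, k] - x[ii, jj, kk])^2
    }
    e <- e + log(max(m, log_floor)) - beta * sm
  }
  e
}

# Iterated coordinate-wise grid search over memberships {0, 0.05, ..., 1}.
# For a single coordinate the terms of C(x) involving x_v are its own data
# term and the pair differences with each neighbor, each of which appears
# twice in the double sum (once in v's neighborhood term, once in the
# neighbor's), hence the factor 2 here.
grid_search_oracle <- function(A, B, beta, h = c(2, 2, 1), log_floor = 1e-12,
                               grid = seq(0, 1, by = 0.05), max_sweeps = 200) {
  n <- dim(A)
  x <- array(0.5, n)
  nbrs <- function(i, j, k) {
    out <- numeric(0)
    for (di in -h[1]:h[1]) for (dj in -h[2]:h[2]) for (dk in -h[3]:h[3]) {
      if (di == 0 && dj == 0 && dk == 0) next
      ii <- i + di; jj <- j + dj; kk <- k + dk
      if (ii < 1 || ii > n[1] || jj < 1 || jj > n[2] || kk < 1 || kk > n[3]) next
      out <- c(out, x[ii, jj, kk])
    }
    out
  }
  for (sweep in seq_len(max_sweeps)) {
    changed <- FALSE
    for (i in seq_len(n[1])) for (j in seq_len(n[2])) for (k in seq_len(n[3])) {
      nb <- nbrs(i, j, k)
      score <- log(pmax(grid * A[i, j, k] + (1 - grid) * B[i, j, k], log_floor)) -
        2 * beta * vapply(grid, function(c) sum((c - nb)^2), numeric(1))
      best <- grid[which.max(score)]
      if (best != x[i, j, k]) { x[i, j, k] <- best; changed <- TRUE }
    }
    if (!changed) break
  }
  list(x = x, objective = brute_energy(x, A, B, beta, h, log_floor))
}

# Random likelihood-field instance away from the log floor and the clip
# boundary, for gradient / optimizer oracles.
random_instance <- function(shape, seed, beta = 0.1) {
  withr::with_seed(seed, {
    n <- prod(shape)
    list(A = array(runif(n, 0.05, 1.5), shape),
         B = array(runif(n, 0.05, 1.5), shape),
         x = array(runif(n, 0.05, 0.95), shape),
         beta = beta)
  })
}

make_fields <- function(A, B, spacing = c(1, 1, 1), mode = "petct") {
  structure(list(A = A, B = B, spacing = spacing, mode = mode),
            class = "fmrf_likelihood_fields")
}

rand_volume <- function(shape, modality = "CT", spacing = c(1, 1, 1.5)) {
  data <- switch(modality,
                 MASK = array(sample(c(0, 1), prod(shape), replace = TRUE), shape),
                 MEMBERSHIP = array(runif(prod(shape)), shape),
                 array(rnorm(prod(shape), 0, 100), shape))
  new_volume(data, spacing = spacing, modality = modality)
}
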