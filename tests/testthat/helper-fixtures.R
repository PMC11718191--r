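# Shared fixtures and independent oracles.

# Scalar mass balance, written independently of the package internals.
oracle_balance <- function(F, total, bmax, kd, n_ratio) {
  F * (1 + sum(n_ratio)) + sum(bmax * F / (kd + F)) - total
}

# Exhaustive grid oracle for the free concentration (default 1e6 points).
oracle_grid_free <- function(total, bmax, kd, n_ratio, n = 1e6) {
  if (total == 0) return(0)
  grid <- seq(0, total, length.out = n)
  bound_sat <- 0
  for (j in seq_along(bmax)) bound_sat <- bound_sat +
      bmax[j] * grid / (kd[j] + grid)
  resid <- abs(grid * (1 + sum(n_ratio)) + bound_sat - total)
  grid[which.min(resid)]
}

# High-precision root by stats::uniroot (independent of the bisection
# implementation under test).
oracle_uniroot_free <- function(total, bmax, kd, n_ratio) {
  if (total == 0) return(0)
  stats::uniroot(oracle_balance, c(0, total), total = total, bmax = bmax,
                 kd = kd, n_ratio = n_ratio, tol = 1e-14)$root
}

# Random valid serum composition under a local RNG.
random_composition <- function() {
  n_sat <- sample(0:3, 1)
  n_non <- sample(0:2, 1)
  sat <- lapply(seq_len(n_sat), function(i)
    saturable_site(paste0("site", i), runif(1, 0, 1000),
                   runif(1, 0.5, 200)))
  non <- lapply(seq_len(n_non), function(i)
    nonsaturable_term(paste0("ns", i), runif(1, 0, 5)))
  serum_composition(runif(1, 0, 500), sat, non)
}

# Pinned reference set used across modules.
ref_total <- 200
ref_bmax <- 336.8
ref_kd <- 10
ref_albumin <- 1.74
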