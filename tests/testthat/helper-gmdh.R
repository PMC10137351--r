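# Shared test helpers.

# Independent least-squares oracle: solve the 6x6 normal equations directly.
# Deliberately a different code path from the package's SVD solver.
oracle_quad_fit <- function(x_i, x_j, y) {
  A <- cbind(1, x_i, x_j, x_i^2, x_j^2, x_i * x_j)
  unname(drop(solve(crossprod(A), crossprod(A, y))))
}

# Random full-rank two-feature design with a quadratic target plus noise.
random_design <- function(n = 30L) {
  list(xi = runif(n, -1, 2), xj = runif(n, -1, 2))
}

# Small detector grid for fast end-to-end runs (330 rows, all voltages).
small_grid <- function() {
  grid_spec(polar_angles_deg = 0,
            tangent_angles_deg = seq(0, 20, by = 2),
            distances_mm = c(250, 500, 750, 1000, 1250),
            voltages_kv = c(40, 60, 80, 100, 120, 140))
}

noiseless_params <- function() surrogate_params(noise_sigma = 0)
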