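# Independent oracles used to cross-check the package implementations.

# Literal sequential evaluation of the dual-threshold contact rules.
oracle_states <- function(sums, lower = 2, upper = 5) {
  st <- character(length(sums))
  st[1] <- "on_ground"
  for (i in seq_along(sums)[-1]) {
    st[i] <- if (st[i - 1] == "on_ground") {
      if (sums[i] < lower) "off_ground" else "on_ground"
    } else {
      if (sums[i] > upper) "on_ground" else "off_ground"
    }
  }
  st
}

# Normal-equations least squares, independent of stats::lm.
oracle_ols <- function(X, y) as.vector(solve(t(X) %*% X, t(X) %*% y))

# 1-D grid search minimising sum((r - b1 u)^2).
oracle_grid_b1 <- function(r, u, lo = 0, hi = 3, step = 1e-4) {
  grid <- seq(lo, hi, by = step)
  sse <- vapply(grid, function(b) sum((r - b * u)^2), numeric(1))
  grid[which.min(sse)]
}

# Textbook two-pass adjusted R^2.
oracle_adj_r2 <- function(y, yhat, p) {
  n <- length(y)
  ss_res <- sum((y - yhat)^2)
  ss_tot <- sum((y - mean(y))^2)
  1 - (ss_res / (n - p - 1)) / (ss_tot / (n - 1))
}

# Reference coefficient values used as generating ground truth in tests.
ref_vals <- function(sex) {
  cf <- reference_coefficients(sex)
  c(gamma = cf$gamma, b0 = cf$b0, b1 = cf$b1, p0 = cf$p0)
}
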