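# Independent oracles used across the suite.

# All permutations of 1..n as a matrix (n! rows); brute-force ground truth
# for cycle counting.
all_perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_perms(n - 1)
  out <- NULL
  for (pos in seq_len(n)) {
    block <- cbind(sub[, seq_len(pos - 1), drop = FALSE], n,
                   sub[, seq(pos, n - 1)[seq_len(n - pos)], drop = FALSE])
    out <- rbind(out, block)
  }
  out
}

# Number of cycles of one permutation (vector p with p[i] = image of i).
cycle_count <- function(p) {
  seen <- logical(length(p))
  k <- 0L
  for (i in seq_along(p)) {
    if (!seen[i]) {
      k <- k + 1L
      j <- i
      while (!seen[j]) { seen[j] <- TRUE; j <- p[j] }
    }
  }
  k
}

# Brute-force unsigned Stirling numbers s(n, k) for all k, by enumerating
# every permutation of n elements and tallying cycle counts.
stirling_brute <- function(n) {
  tab <- table(factor(apply(all_perms(n), 1, cycle_count), levels = 1:n))
  as.numeric(tab)
}

# Total-variation distance between two pmfs on a shared support.
tv_dist <- function(p, q) 0.5 * sum(abs(p - q))

# Grid-normalized probability masses for a log density on an arbitrary
# (possibly unevenly spaced) grid: trapezoid-style cell weights so the
# result approximates the continuous density regardless of grid layout.
grid_masses <- function(grid, log_dens) {
  lp <- log_dens(grid)
  w <- diff(grid)
  w <- c(w[1], (w[-1] + w[-length(w)]) / 2, w[length(w)])
  p <- exp(lp - max(lp)) * w
  p / sum(p)
}

# Kolmogorov-Smirnov distance between draws and a grid-normalized density:
# `log_dens` evaluated on `grid` (fine, covering the support mass).
ks_to_grid <- function(draws, grid, log_dens) {
  p <- grid_masses(grid, log_dens)
  cdf <- stats::approxfun(grid, cumsum(p), yleft = 0, yright = 1)
  n <- length(draws)
  max(abs(cdf(sort(draws)) - (seq_len(n) - 0.5) / n))
}

# Median of a grid-normalized density.
grid_median <- function(grid, log_dens) {
  p <- grid_masses(grid, log_dens)
  grid[which.min(abs(cumsum(p) - 0.5))]
}

# Small neutral test fixture: one metacommunity with the given shape.
make_neutral_matrix <- function(theta = 20, m = 0.1, J = c(400, 400),
                                seed = 1) {
  set.seed(seed)
  simulate_neutral_metacommunity(theta, immigration_from_m(m, J), J)
}

# Reduced-length chain settings used throughout the suite; the default
# 50,000-sweep protocol is exercised separately.
test_chain <- function(seed = 1, n = 4000L, burn = 2000L, thin = 10L) {
  chain_settings(n, burn, thin, seed = seed)
}
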