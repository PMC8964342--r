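# Log-space unsigned Stirling numbers of the first kind, the Antoniak
# species-count distribution, and CRP table-count sampling. These are the
# combinatorial primitives behind the biodiversity-number conditional and
# the ancestral-count updates of the multi-site neutral sampler.

# Triangular table of log s(n, k), grown monotonically and cached for the
# process. Row n is a numeric vector of length n + 1 indexed by k = 0..n.
.stirling_cache <- new.env(parent = emptyenv())

.log_add <- function(a, b) {
  # log(exp(a) + exp(b)), elementwise, -Inf safe
  m <- pmax(a, b)
  out <- m + log1p(exp(pmin(a, b) - m))
  out[is.infinite(m) & m < 0] <- -Inf
  out
}

.stirling_rows <- function(max_n) {
  rows <- .stirling_cache$rows
  if (is.null(rows)) rows <- list(`0` = 0) # row 0: log s(0,0) = 0
  have <- length(rows) - 1L
  if (max_n > have) {
    for (n in (have + 1L):max_n) {
      prev <- rows[[n]] # row n - 1, length n
      # s(n, k) = s(n-1, k-1) + (n-1) s(n-1, k), k = 0..n
      row <- .log_add(c(-Inf, prev), log(n - 1) + c(prev, -Inf))
      rows[[n + 1L]] <- row
    }
    .stirling_cache$rows <- rows
  }
  rows
}

#' Log unsigned Stirling numbers of the first kind
#'
#' Computes \eqn{\log s(n, k)} where \eqn{s(n, k)} counts permutations of
#' \eqn{n} elements with exactly \eqn{k} cycles, by the additive recurrence
#' \eqn{s(n,k) = s(n-1,k-1) + (n-1)\,s(n-1,k)} carried out entirely in log
#' space (linear-space evaluation overflows near \eqn{n \approx 170}).
#' The triangle is built lazily up to the largest \eqn{n} requested and
#' cached for the process; callers must not rely on mutating it.
#'
#' @param n,k Non-negative integers (vectorized over `k`).
#' @return `log s(n, k)`; `-Inf` where `s(n, k) = 0` (e.g. `k = 0`, `n >= 1`
#'   or `k > n`).
#' @examples
#' exp(log_stirling1(3, 2)) # 3 permutations of 3 elements with 2 cycles
#' @export
log_stirling1 <- function(n, k) {
  if (length(n) != 1L || n < 0 || n != round(n)) {
    stop("`n` must be a single non-negative integer")
  }
  if (any(k < 0) || any(k != round(k))) {
    stop("`k` must be non-negative integers")
  }
  rows <- .stirling_rows(as.integer(n))
  row <- rows[[n + 1L]]
  out <- rep(-Inf, length(k))
  ok <- k <= n
  out[ok] <- row[k[ok] + 1L]
  out
}

#' Antoniak distribution of the number of distinct types
#'
#' Probability mass function of the number of species \eqn{S} observed after
#' \eqn{N} draws from a Dirichlet process with concentration \eqn{\theta}:
#' \deqn{P(S \mid \theta, N) = s(N, S)\,\theta^S\,
#'   \Gamma(\theta)/\Gamma(\theta + N),}
#' with \eqn{s(N, S)} the unsigned Stirling number of the first kind.
#' Evaluated in log space; the result is checked to sum to 1 within 1e-10.
#'
#' @param theta Positive concentration parameter.
#' @param n_draws Number of draws (\eqn{N \ge 1}).
#' @return Numeric probability vector over \eqn{S = 1, \dots, N}.
#' @export
antoniak_pmf <- function(theta, n_draws) {
  if (!is.numeric(theta) || length(theta) != 1L || theta <= 0) {
    stop("`theta` must be a single positive number")
  }
  if (n_draws < 1 || n_draws != round(n_draws)) {
    stop("`n_draws` must be a positive integer")
  }
  k <- seq_len(n_draws)
  lp <- log_stirling1(n_draws, k) + k * log(theta) + lgamma(theta) -
    lgamma(theta + n_draws)
  p <- exp(lp - max(lp))
  p <- p / sum(p)
  raw_total <- sum(exp(lp))
  if (abs(raw_total - 1) > 1e-10) {
    stop(sprintf("Antoniak pmf failed normalization check (sum = %.3e)",
                 raw_total))
  }
  p
}

#' Sample a Chinese-restaurant-process table count
#'
#' Sequential CRP simulation: customer \eqn{i} opens a new table with
#' probability \eqn{c/(c + i - 1)}. The table count after `n_customers`
#' customers follows the Antoniak distribution with concentration
#' `concentration`, which is how ancestral counts are drawn without dense
#' Stirling tables ([antoniak_pmf()] remains the small-\eqn{n} oracle).
#'
#' @param n_customers Non-negative integer number of draws.
#' @param concentration Positive DP concentration.
#' @return Integer table count; 0 iff `n_customers = 0`.
#' @export
sample_crp_tables <- function(n_customers, concentration) {
  if (n_customers < 0 || n_customers != round(n_customers)) {
    stop("`n_customers` must be a non-negative integer")
  }
  if (!is.numeric(concentration) || concentration <= 0) {
    stop("`concentration` must be positive")
  }
  crp_tables_cpp(as.integer(n_customers), concentration)
}

#' Expected CRP table count
#'
#' \eqn{E[T] = \sum_{i=1}^{n} c/(c + i - 1) =
#' c\{\psi(c + n) - \psi(c)\}}; used to initialize ancestral counts.
#'
#' @inheritParams sample_crp_tables
#' @return Expected number of tables.
#' @export
expected_crp_tables <- function(n_customers, concentration) {
  if (any(n_customers < 0)) stop("`n_customers` must be non-negative")
  if (any(concentration <= 0)) stop("`concentration` must be positive")
  concentration * (digamma(concentration + n_customers) -
                     digamma(concentration))
}
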