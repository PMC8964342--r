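# Four-step Gibbs sampler for the HDP-approximated multi-site neutral
# model. Each sweep draws, in order: (a) the fundamental biodiversity
# number theta given the species count S and grand ancestor total T;
# (b) the metacommunity relative frequencies beta (Dirichlet, with an
# explicit unrepresented-mass component); (c) the per-site immigration
# rates I_i; (d) the ancestral counts T_ij (Antoniak via CRP simulation).
# The theta and I_i conditionals are non-standard 1-D densities and are
# drawn by slice sampling in log-parameter space.

#' Chain settings for the neutral-model Gibbs sampler
#'
#' Defaults follow the standard protocol for this sampler: 50,000 sweeps
#' with the first 25,000 discarded as burn-in, posterior summaries taken as
#' medians with 2.5%/97.5% credible limits over the retained sweeps, and
#' every 10th post-burn-in sweep stored (2,500 parameter sets) for reuse by
#' the Monte Carlo neutrality test.
#'
#' @param n_iterations Total Gibbs sweeps.
#' @param n_burnin Sweeps discarded as burn-in (`< n_iterations`).
#' @param thinning Store every `thinning`-th post-burn-in sweep.
#' @param seed Integer seed; every draw of the chain flows from it.
#' @param priors A [prior_spec()].
#' @return A `chain_settings` list; `n_stored` gives the implied number of
#'   stored parameter sets.
#' @export
chain_settings <- function(n_iterations = 50000L, n_burnin = 25000L,
                           thinning = 10L, seed = 1L,
                           priors = prior_spec()) {
  if (n_burnin >= n_iterations) stop("`n_burnin` must be below `n_iterations`")
  if (thinning < 1) stop("`thinning` must be at least 1")
  stopifnot(inherits(priors, "prior_spec"))
  structure(list(n_iterations = as.integer(n_iterations),
                 n_burnin = as.integer(n_burnin),
                 thinning = as.integer(thinning),
                 seed = as.integer(seed), priors = priors,
                 n_stored = (as.integer(n_iterations) -
                               as.integer(n_burnin)) %/% as.integer(thinning)),
            class = "chain_settings")
}

#' Draw the fundamental biodiversity number from its full conditional
#'
#' Samples \eqn{\theta} from the density proportional to
#' \eqn{\theta^S \Gamma(\theta)/\Gamma(\theta + T)\,
#' \mathrm{Gamma}(\theta \mid \alpha, \zeta)} (the Stirling factor
#' \eqn{s(T, S)} is constant in \eqn{\theta} and dropped), via slice
#' sampling in \eqn{\log\theta}. With `n_updates` large the returned value
#' is effectively an independent draw; inside the Gibbs sweep a single
#' update per sweep is used.
#'
#' @param S Observed taxon count (\eqn{1 \le S \le T}).
#' @param T_total Grand ancestor total \eqn{T}.
#' @param prior A [prior_spec()].
#' @param init Starting value (defaults to `S`).
#' @param n_updates Number of internal slice updates.
#' @return A positive draw of \eqn{\theta}.
#' @export
sample_theta <- function(S, T_total, prior = prior_spec(), init = S,
                         n_updates = 25L) {
  if (S < 1 || S > T_total) stop("require 1 <= S <= T_total")
  slice_theta_cpp(init, S, T_total, prior$theta_shape, prior$theta_rate,
                  as.integer(n_updates))
}

#' Draw the metacommunity relative frequencies
#'
#' \eqn{(\beta_1, \dots, \beta_S, \beta_u) \sim
#' \mathrm{Dir}(T_{\cdot 1}, \dots, T_{\cdot S}, \theta)}: a Dirichlet draw
#' over the observed taxa's ancestor totals with the biodiversity number as
#' the concentration of the unrepresented mass.
#'
#' @param T_per_taxon Vector of per-taxon ancestor totals (at least one
#'   positive).
#' @param theta Positive biodiversity number.
#' @return Numeric vector of length `length(T_per_taxon) + 1` summing to 1;
#'   the last entry is the unrepresented mass \eqn{\beta_u}.
#' @export
sample_beta <- function(T_per_taxon, theta) {
  if (any(T_per_taxon < 0) || all(T_per_taxon == 0)) {
    stop("ancestor totals must be non-negative with at least one positive")
  }
  if (theta <= 0) stop("`theta` must be positive")
  g <- c(rgamma(length(T_per_taxon), shape = T_per_taxon, rate = 1),
         rgamma(1, shape = theta, rate = 1))
  g <- pmax(g, 1e-300)
  g / sum(g)
}

#' Draw a site immigration rate from its full conditional
#'
#' Samples \eqn{I_i} from the density proportional to
#' \eqn{\Gamma(I)/\Gamma(J_i + I)\, I^{T_i}\,
#' \mathrm{Gamma}(I \mid \eta, \nu)} by slice sampling in \eqn{\log I}.
#'
#' @param T_i Site ancestor total (\eqn{1 \le T_i \le J_i}).
#' @param J_i Site read total.
#' @param prior A [prior_spec()].
#' @param init Starting value.
#' @param n_updates Number of internal slice updates.
#' @return A positive draw of \eqn{I_i}.
#' @export
sample_immigration <- function(T_i, J_i, prior = prior_spec(), init = 10,
                               n_updates = 25L) {
  if (T_i < 1 || T_i > J_i) stop("require 1 <= T_i <= J_i")
  slice_immig_cpp(init, T_i, J_i, prior$immig_shape, prior$immig_rate,
                  as.integer(n_updates))
}

#' Draw an ancestral count
#'
#' \eqn{T_{ij}} given \eqn{x_{ij}} reads follows the Antoniak distribution
#' with concentration \eqn{I_i \beta_j}, realized by sequential CRP
#' simulation (O(x) per draw, no Stirling tables).
#'
#' @param x_ij Non-negative read count.
#' @param I_i Site immigration rate.
#' @param beta_j Metacommunity frequency of the taxon (positive when
#'   `x_ij > 0`).
#' @return Integer ancestor count in `[1, x_ij]` (0 iff `x_ij = 0`).
#' @export
sample_ancestors <- function(x_ij, I_i, beta_j) {
  if (x_ij == 0) return(0L)
  conc <- I_i * beta_j
  if (!is.finite(conc) || conc <= 0) {
    stop("`I_i * beta_j` must be positive when `x_ij` > 0")
  }
  crp_tables_cpp(as.integer(x_ij), conc)
}

#' Fit the multi-site neutral model by Gibbs sampling
#'
#' Runs the four-step sampler on a community matrix and summarizes the
#' posterior. Initialization: `beta` from pooled observed relative
#' abundances with unrepresented mass \eqn{1/(1 + \sum_i J_i)}; all
#' \eqn{I_i = 10}; \eqn{T_{ij}} at the expected CRP table count given
#' \eqn{x_{ij}} and \eqn{I_i\beta_j}, rounded and clamped to
#' \eqn{[1, x_{ij}]}. Summaries are medians and 2.5%/97.5% quantiles over
#' all post-burn-in sweeps; every `thinning`-th post-burn-in sweep is
#' stored in full (`theta`, `I`, `beta`) for the neutrality test.
#'
#' The single migration probability reported per metacommunity (`m_pooled`)
#' is the median across post-burn-in sweeps of the across-site mean of
#' \eqn{m_i = I_i/(I_i + J_i - 1)}; the `M_value` is the across-site mean
#' of the per-site median immigration rate ("average median of the
#' individuals migrated per generation"). Per-site summaries are also
#' returned. `L0` is the median over stored parameter sets of the observed
#' Dirichlet-multinomial log-likelihood under each set.
#'
#' @param X A [community_matrix()].
#' @param settings A [chain_settings()].
#' @return An object of class `msn_fit`: posterior summaries, the stored
#'   parameter sets (`$trace`), settings echo and the final ancestral
#'   counts.
#' @examples
#' X <- community_matrix(rbind(c(30, 5, 2), c(20, 9, 1)))
#' fit <- fit_msn(X, chain_settings(2000, 1000, 10, seed = 1))
#' fit$theta_median
#' @export
fit_msn <- function(X, settings = chain_settings()) {
  stopifnot(inherits(X, "community_matrix"), inherits(settings,
                                                      "chain_settings"))
  x <- as.matrix(X)
  M <- nrow(x); S <- ncol(x)
  J <- rowSums(x)
  set.seed(settings$seed)

  # initialization (deterministic given X)
  beta_u0 <- 1 / (1 + sum(J))
  beta0 <- c(colSums(x) / sum(J) * (1 - beta_u0), beta_u0)
  I0 <- rep(10, M)
  T0 <- matrix(0L, M, S)
  for (i in seq_len(M)) {
    pos <- x[i, ] > 0
    expT <- expected_crp_tables(x[i, pos], 10 * beta0[seq_len(S)][pos])
    T0[i, pos] <- pmin(pmax(1L, as.integer(round(expT))), x[i, pos])
  }

  pr <- settings$priors
  raw <- gibbs_msn_cpp(x, settings$n_iterations, settings$n_burnin,
                       settings$thinning, pr$theta_shape, pr$theta_rate,
                       pr$immig_shape, pr$immig_rate,
                       theta0 = S, I0 = I0, beta0 = beta0, T0 = T0)

  theta_post <- raw$theta_post
  I_post <- raw$I_post
  m_post <- sweep(I_post, 2, J - 1, function(I, d) I / (I + d))
  qs <- function(v) unname(quantile(v, c(0.025, 0.5, 0.975)))
  tq <- qs(theta_post)
  m_site <- apply(m_post, 2, qs)
  I_site_median <- apply(I_post, 2, median)
  m_pool <- qs(rowMeans(m_post))

  trace <- list(theta = raw$theta_stored, I = raw$I_stored,
                beta = raw$beta_stored)
  L0_sets <- vapply(seq_along(trace$theta), function(t) {
    metacommunity_log_likelihood(x, trace$I[t, ],
                                 trace$beta[t, seq_len(S)])
  }, numeric(1))

  structure(list(
    theta_median = tq[2], theta_lo = tq[1], theta_hi = tq[3],
    m_site_median = m_site[2, ], m_site_lo = m_site[1, ],
    m_site_hi = m_site[3, ],
    m_pooled = m_pool[2], m_pooled_lo = m_pool[1], m_pooled_hi = m_pool[3],
    M_value = mean(I_site_median), I_site_median = I_site_median,
    L0 = median(L0_sets), L0_sets = L0_sets,
    trace = trace, site_totals = J, n_sites = M, n_taxa = S,
    counts = x, T_final = raw$T_final, settings = settings), class = "msn_fit")
}

#' @export
print.msn_fit <- function(x, ...) {
  cat(sprintf(paste0(
    "Multi-site neutral model fit (%d sites, %d taxa)\n",
    "  theta  %.3f  [%.3f, %.3f]\n",
    "  m      %.4f  [%.4f, %.4f]  (pooled across %d sites)\n",
    "  M-value %.3f   L0 %.3f\n",
    "  chain: %d sweeps, %d burn-in, %d stored sets\n"),
    x$n_sites, x$n_taxa, x$theta_median, x$theta_lo, x$theta_hi,
    x$m_pooled, x$m_pooled_lo, x$m_pooled_hi, x$n_sites,
    x$M_value, x$L0, x$settings$n_iterations, x$settings$n_burnin,
    length(x$trace$theta)))
  invisible(x)
}
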