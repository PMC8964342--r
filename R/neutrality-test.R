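# Monte Carlo goodness-of-fit tests of neutrality. For each stored
# parameter set of a fit, one replicate metacommunity is simulated at the
# observed read depths, its log-likelihood is evaluated under the
# parameter set that generated it, and the observed likelihood L0 is
# evaluated under the same stored set; the pseudo-P value is the fraction
# of replicates whose likelihood falls at or below the observed one
# (ties count as below). P > 0.05 means the data are indistinguishable
# from the neutral prediction.

.STICK_EPS <- 1e-8

# one Polya-urn row per site; robust to single-atom base measures
.urn_rows <- function(J, I, atoms) {
  K <- length(atoms)
  counts <- matrix(0L, length(J), K)
  for (i in seq_along(J)) {
    counts[i, ] <- polya_urn_cpp(as.integer(J[i]), I[i], atoms, numeric(0))
  }
  counts
}

#' Simulate a neutral metacommunity (full model)
#'
#' Draws metacommunity frequencies by stick breaking at `theta` (truncated
#' when the residual stick falls below 1e-8), then assembles each site by a
#' Polya-urn realization of \eqn{DP(I_i, \beta)} with exactly `J[i]` reads.
#'
#' @param theta Positive biodiversity number.
#' @param I Vector of per-site immigration rates.
#' @param J Vector of per-site read depths (same length as `I`).
#' @return A [community_matrix()]; row totals equal `J` exactly.
#' @export
simulate_neutral_metacommunity <- function(theta, I, J) {
  if (length(I) != length(J)) stop("`I` and `J` lengths differ")
  if (theta <= 0 || any(I <= 0) || any(J < 1)) {
    stop("all parameters must be positive")
  }
  atoms <- stick_break_cpp(theta, .STICK_EPS)
  counts <- .urn_rows(J, I, atoms)
  suppressMessages(community_matrix(counts))
}

#' Simulate neutral local communities around a fixed metacommunity
#'
#' Holds the metacommunity frequencies fixed at a fitted draw (the
#' unrepresented mass `beta_u` is re-broken into sticks at `theta`) and
#' simulates each site by Polya urn — the local-level null in which only
#' the local communities are required to assemble neutrally.
#'
#' @param beta Fitted frequencies of the observed taxa (may sum to < 1).
#' @param theta Biodiversity number used to re-break the leftover mass.
#' @param I,J Per-site immigration rates and read depths.
#' @return A [community_matrix()]; columns beyond `length(beta)` labelled
#'   `new1, new2, ...` are re-broken-mass taxa that received reads.
#' @export
simulate_neutral_local <- function(beta, theta, I, J) {
  if (length(I) != length(J)) stop("`I` and `J` lengths differ")
  if (any(beta < 0) || sum(beta) > 1 + 1e-9) stop("invalid `beta`")
  if (theta <= 0 || any(I <= 0) || any(J < 1)) {
    stop("all parameters must be positive")
  }
  rest <- max(0, 1 - sum(beta))
  atoms <- c(beta, if (rest > .STICK_EPS)
    rest * stick_break_cpp(theta, .STICK_EPS) else rest)
  keep <- atoms > 0
  labs <- c(paste0("taxon", seq_along(beta)),
            paste0("new", seq_len(length(atoms) - length(beta))))
  counts <- .urn_rows(J, I, atoms[keep])
  colnames(counts) <- labs[keep]
  suppressMessages(community_matrix(counts))
}

#' Pseudo-P value from simulated likelihoods
#'
#' \eqn{P = N_{below}/N} where \eqn{N_{below}} counts simulated
#' log-likelihoods at or below the observed `L0` (ties count as below,
#' conservative toward non-rejection). The complement \eqn{1 - P} is also
#' reported, mirroring the sign-adjustment bookkeeping used when comparing
#' against legacy program output.
#'
#' @param L0 Observed log-likelihood.
#' @param L_sim Non-empty vector of finite simulated log-likelihoods.
#' @return List with `n_below`, `n_total`, `pseudo_P`, `pseudo_P_complement`,
#'   `L_sim_median` and the `verdict` (`"neutral-compatible"` iff
#'   `pseudo_P > 0.05`).
#' @export
pseudo_p <- function(L0, L_sim) {
  if (length(L_sim) == 0 || any(!is.finite(L_sim)) || !is.finite(L0)) {
    stop("`L0` and `L_sim` must be finite and `L_sim` non-empty")
  }
  n_below <- sum(L_sim <= L0)
  p <- n_below / length(L_sim)
  list(n_below = n_below, n_total = length(L_sim), pseudo_P = p,
       pseudo_P_complement = 1 - p, L_sim_median = median(L_sim),
       verdict = if (p > 0.05) "neutral-compatible" else "non-neutral")
}

#' Monte Carlo neutrality test from a fitted chain
#'
#' For each stored parameter set of `fit`, simulates one replicate at the
#' observed read depths — at the metacommunity level a fresh stick-broken
#' metacommunity at \eqn{\theta_t} (full neutral model), at the local level
#' the stored \eqn{\beta_t} held fixed — evaluates the replicate's
#' log-likelihood under its generating parameter set and the observed
#' matrix's likelihood under the stored set, and aggregates the per-set
#' indicators \eqn{L_{sim} \le L_0} into the pseudo-P value. With
#' `fixed_L0 = TRUE` the observed likelihood is instead fixed at its median
#' across stored sets before comparison.
#'
#' @param X The [community_matrix()] the chain was fitted to.
#' @param fit An [fit_msn()] object for `X`.
#' @param level `"metacommunity"` or `"local"`.
#' @param fixed_L0 Use a single fixed observed likelihood instead of the
#'   per-set construction.
#' @return A `neutrality_test` list: `level`, `L0`, `L_sim_median`,
#'   `n_below`, `n_total`, `pseudo_P`, `pseudo_P_complement`, `verdict`.
#' @export
run_neutrality_test <- function(X, fit, level = c("metacommunity", "local"),
                                fixed_L0 = FALSE) {
  level <- match.arg(level)
  stopifnot(inherits(fit, "msn_fit"))
  x <- as.matrix(X)
  if (!isTRUE(all.equal(unname(rowSums(x)), unname(fit$site_totals)))) {
    stop("read depths of `X` do not match the fitted trace")
  }
  M <- nrow(x); S <- ncol(x); J <- rowSums(x)
  tr <- fit$trace
  n_sets <- length(tr$theta)
  L_sim <- numeric(n_sets)
  L_obs <- fit$L0_sets

  lcoef <- sum(lgamma(J + 1)) # shared multinomial-coefficient depth term
  for (t in seq_len(n_sets)) {
    th <- tr$theta[t]; It <- tr$I[t, ]
    if (level == "metacommunity") {
      atoms <- stick_break_cpp(th, .STICK_EPS)
    } else {
      bu <- tr$beta[t, S + 1]
      atoms <- c(tr$beta[t, seq_len(S)],
                 if (bu > .STICK_EPS) bu * stick_break_cpp(th, .STICK_EPS)
                 else bu)
    }
    ll <- lcoef
    for (i in seq_len(M)) {
      cnt <- polya_urn_cpp(as.integer(J[i]), It[i], atoms, numeric(0))
      pos <- cnt > 0L
      a <- It[i] * atoms[pos] / sum(atoms)
      ll <- ll - sum(lgamma(cnt[pos] + 1)) + lgamma(It[i]) -
        lgamma(It[i] + J[i]) + sum(lgamma(a + cnt[pos]) - lgamma(a))
    }
    L_sim[t] <- ll
  }

  if (fixed_L0) {
    res <- pseudo_p(median(L_obs), L_sim)
  } else {
    n_below <- sum(L_sim <= L_obs)
    p <- n_below / n_sets
    res <- list(n_below = n_below, n_total = n_sets, pseudo_P = p,
                pseudo_P_complement = 1 - p, L_sim_median = median(L_sim),
                verdict = if (p > 0.05) "neutral-compatible" else
                  "non-neutral")
  }
  structure(c(list(level = level, L0 = median(L_obs)), res),
            class = "neutrality_test")
}

#' @export
print.neutrality_test <- function(x, ...) {
  cat(sprintf(paste0("Neutrality test (%s level)\n",
                     "  L0 %.3f   median simulated L %.3f\n",
                     "  pseudo-P = %d/%d = %.4f  -> %s\n"),
              x$level, x$L0, x$L_sim_median, x$n_below, x$n_total,
              x$pseudo_P, x$verdict))
  invisible(x)
}
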