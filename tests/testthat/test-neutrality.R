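test_that("neutral metacommunity simulation honours depths and limits", {
  set.seed(21)
  J <- c(120, 345, 67)
  X <- simulate_neutral_metacommunity(10, c(5, 5, 5), J)
  expect_identical(unname(rowSums(as.matrix(X))), J)
  # stick-breaking limit: tiny theta gives near-total monodominance
  shares <- replicate(60, {
    Xs <- simulate_neutral_metacommunity(0.001, c(10, 10), c(250, 250))
    max(colSums(as.matrix(Xs))) / sum(Xs)
  })
  expect_gt(median(shares), 0.99)
  expect_error(simulate_neutral_metacommunity(-1, 1, 10), "positive")
})

test_that("observed richness matches the Ewens expectation when sites
           sample the metacommunity directly", {
  # at very large I a site is an iid sample of the stick-broken
  # metacommunity, so E[richness] = sum_i theta/(theta + i - 1)
  theta <- 20; J <- 500
  ewens <- sum(theta / (theta + 0:(J - 1)))
  set.seed(8)
  rich <- replicate(150, ncol(simulate_neutral_metacommunity(theta, 1e7, J)))
  expect_lt(abs(mean(rich) - ewens) / ewens, 0.05)
})

test_that("local-community simulation approaches its two I limits", {
  beta <- c(0.35, 0.25, 0.2, 0.15, 0.05)
  set.seed(5)
  X <- simulate_neutral_local(beta, theta = 5, I = rep(1e6, 2),
                              J = rep(10000, 2))
  comp <- as.matrix(X)[, paste0("taxon", 1:5)] / 10000
  expect_lt(max(0.5 * rowSums(abs(sweep(comp, 2, beta)))), 0.05)
  expect_equal(unname(rowSums(as.matrix(X))), c(10000, 10000))
  # I -> 0: near-monodominant sites
  shares <- replicate(40, {
    Xs <- simulate_neutral_local(beta, 5, I = 0.01, J = 300)
    max(Xs) / 300
  })
  expect_gt(median(shares), 0.95)
})

test_that("pseudo-P counts ties as below and hits its extremes", {
  expect_identical(pseudo_p(-10, c(-5, -4, -3))$pseudo_P, 0)
  expect_identical(pseudo_p(-1, c(-5, -4, -3))$pseudo_P, 1)
  L <- seq(-100, -1, length.out = 2500)
  r <- pseudo_p(median(L), L)
  expect_identical(r$n_below, 1250L + 0L) # ceiling(n/2) with ties below
  expect_equal(r$pseudo_P + r$pseudo_P_complement, 1)
  expect_identical(pseudo_p(0, c(0, 0, -1))$n_below, 3L)
  expect_identical(pseudo_p(-2, c(-1, -3))$verdict, "neutral-compatible")
  expect_identical(pseudo_p(-2, rep(-1, 100))$verdict, "non-neutral")
  expect_error(pseudo_p(NaN, c(-1)), "finite")
  expect_error(pseudo_p(-1, c(-1, Inf)), "finite")
})

test_that("pseudo-P is invariant to taxon relabeling", {
  X <- make_neutral_matrix(theta = 10, m = 0.1, J = c(250, 250), seed = 3)
  fit <- fit_msn(X, test_chain(seed = 4, n = 1200L, burn = 600L, thin = 20L))
  set.seed(42)
  perm <- sample(ncol(X))
  Xp <- community_matrix(as.matrix(X)[, perm, drop = FALSE])
  S <- ncol(X)
  fitp <- fit
  fitp$trace$beta <- fit$trace$beta[, c(perm, S + 1), drop = FALSE]
  fitp$counts <- as.matrix(Xp)
  fitp$L0_sets <- vapply(seq_along(fit$trace$theta), function(t) {
    metacommunity_log_likelihood(Xp, fit$trace$I[t, ],
                                 fitp$trace$beta[t, seq_len(S)])
  }, numeric(1))
  # relabeling leaves every likelihood, hence the pseudo-P, unchanged
  expect_equal(fitp$L0_sets, fit$L0_sets, tolerance = 1e-10)
  set.seed(99)
  t1 <- run_neutrality_test(X, fit, "metacommunity")
  set.seed(99)
  t2 <- run_neutrality_test(Xp, fitp, "metacommunity")
  expect_identical(t1$n_below, t2$n_below)
  expect_equal(t1$pseudo_P, t2$pseudo_P)
})

test_that("pseudo-P is approximately uniform under a known-parameter null", {
  # H0 with parameters known (not estimated): simulate data and reference
  # sets from the same fixed (beta, I); the pseudo-P of each dataset
  # against its reference distribution should be uniform
  set.seed(77)
  beta <- as.numeric(msneutral:::stick_break_cpp(8, 1e-6))
  I <- c(20, 20); J <- c(150, 150)
  loglik <- function(cnt) {
    sum(vapply(1:2, function(i) {
      site_log_likelihood(cnt[i, ], I[i], beta / sum(beta))
    }, numeric(1)))
  }
  sim <- function() {
    t(vapply(1:2, function(i) {
      msneutral:::polya_urn_cpp(J[i], I[i], beta, numeric(0))
    }, integer(length(beta))))
  }
  L_ref <- replicate(150, loglik(sim()))
  ps <- replicate(200, pseudo_p(loglik(sim()), L_ref)$pseudo_P)
  dec <- seq(0.1, 0.9, by = 0.1)
  emp <- vapply(dec, function(q) mean(ps <= q), numeric(1))
  expect_lt(max(abs(emp - dec)), 0.1)
})

test_that("fit-then-test keeps verdicts consistent across levels on
           neutral data", {
  agree <- 0
  for (r in 1:5) {
    set.seed(400 + r)
    J <- rep(600, 2)
    X <- simulate_neutral_metacommunity(20, immigration_from_m(0.08, J), J)
    fit <- fit_msn(X, test_chain(seed = 500 + r, n = 2000L, burn = 1000L))
    tm <- run_neutrality_test(X, fit, "metacommunity")
    tl <- run_neutrality_test(X, fit, "local")
    agree <- agree + (tm$verdict == tl$verdict)
    expect_identical(tm$n_total, fit$settings$n_stored)
  }
  expect_gte(agree, 4)
})

test_that("depth mismatches between matrix and trace are rejected", {
  X <- make_neutral_matrix(theta = 10, m = 0.1, J = c(200, 200), seed = 6)
  fit <- fit_msn(X, test_chain(seed = 1, n = 600L, burn = 300L, thin = 30L))
  Y <- make_neutral_matrix(theta = 10, m = 0.1, J = c(150, 200), seed = 7)
  expect_error(run_neutrality_test(Y, fit), "depths")
})

test_that("the fixed-L0 variant agrees with the per-set construction on
           clearly neutral data", {
  set.seed(31)
  J <- rep(500, 2)
  X <- simulate_neutral_metacommunity(15, immigration_from_m(0.1, J), J)
  fit <- fit_msn(X, test_chain(seed = 9, n = 2000L, burn = 1000L))
  set.seed(1); a <- run_neutrality_test(X, fit, "metacommunity")
  set.seed(1); b <- run_neutrality_test(X, fit, "metacommunity",
                                        fixed_L0 = TRUE)
  expect_identical(a$verdict, "neutral-compatible")
  expect_identical(b$verdict, "neutral-compatible")
})
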