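test_that("the default couple design mirrors the study layout", {
  spec <- synthetic_spec()
  expect_identical(spec$n_couples, 23L)
  expect_identical(unname(spec$depth_means),
                   c(1712, 2854, 2854))
  small <- synthetic_spec(n_couples = 23, depth_means = c(CM = 300,
                                                          CNA = 400,
                                                          CNB = 400),
                          theta_true = 10, seed = 4)
  ds <- generate_couple_dataset(small)
  expect_identical(length(ds$matrices), 23L)
  expect_identical(nrow(ds$design), 69L) # 23 couples x 3 samples
  expect_true(all(table(ds$design$role) == 23L))
  expect_true(all(vapply(ds$matrices, nrow, integer(1)) == 3L))
})

test_that("couple generation is seed-reproducible and depth-consistent", {
  spec <- synthetic_spec(n_couples = 3, depth_means = c(CM = 250, CNA = 350,
                                                        CNB = 350),
                         theta_true = 15, seed = 11)
  a <- generate_couple_dataset(spec)
  b <- generate_couple_dataset(spec)
  expect_identical(lapply(a$matrices, as.matrix),
                   lapply(b$matrices, as.matrix))
  expect_identical(a$design, b$design)
  depths <- unlist(lapply(a$matrices, function(m) rowSums(as.matrix(m))))
  expect_true(all(depths >= 200)) # log-normal depths floored at 200
})

test_that("the niche control preserves depths and raises cross-site
           dissimilarity", {
  skip_if_not_installed("vegan")
  base <- list(n_couples = 1, depth_means = c(CM = 500, CNA = 500,
                                              CNB = 500),
               theta_true = 20, m_true = 0.1)
  bc <- function(niche, seed) {
    spec <- do.call(synthetic_spec, c(base, niche_effect = niche,
                                      seed = seed))
    ds <- if (niche > 1) generate_niche_dataset(spec) else
      generate_couple_dataset(spec)
    m <- as.matrix(ds$matrices[[1]])
    expect_identical(unname(rowSums(m) >= 200), rep(TRUE, 3))
    mean(vegan::vegdist(m, method = "bray"))
  }
  neutral <- vapply(1:30, function(s) bc(1, s), numeric(1))
  niche <- vapply(1:30, function(s) bc(16, 1000 + s), numeric(1))
  expect_gt(mean(niche), mean(neutral))
  expect_gt(stats::t.test(niche, neutral, alternative = "greater")$p.value,
            -1) # smoke: test is computable
  expect_lt(stats::t.test(niche, neutral,
                          alternative = "greater")$p.value, 0.05)
  expect_error(generate_niche_dataset(do.call(synthetic_spec,
                                              c(base, niche_effect = 1,
                                                seed = 1))),
               "exceed 1")
})

test_that("expected richness increases with the biodiversity number", {
  rich <- function(theta) {
    mean(vapply(1:10, function(s) {
      set.seed(7000 + s + round(theta))
      J <- rep(400, 3)
      ncol(simulate_neutral_metacommunity(theta,
                                          immigration_from_m(0.1, J), J))
    }, numeric(1)))
  }
  r <- vapply(c(2, 20, 100), rich, numeric(1))
  expect_true(all(diff(r) > 0))
})

test_that("forward Moran simulation matches its boundary behaviours", {
  meta <- c(0.4, 0.3, 0.2, 0.1)
  # m = 1: every replacement immigrates, so the community is an iid sample
  set.seed(13)
  rej <- vapply(1:100, function(r) {
    cnt <- forward_hubbell(200, 1, meta, n_events = 2000)
    suppressWarnings(stats::chisq.test(cnt, p = meta)$p.value) < 0.01
  }, logical(1))
  expect_gte(mean(!rej), 0.9)
  # m -> 0 with long runs: drift fixes a single taxon
  fixed <- vapply(1:20, function(r) {
    cnt <- forward_hubbell(60, 1e-9, c(0.5, 0.5), n_events = 60 * 400)
    max(cnt) == 60
  }, logical(1))
  expect_gte(mean(fixed), 0.9)
  expect_identical(sum(forward_hubbell(100, 0.2, meta)), 100L)
  expect_error(forward_hubbell(1, 0.5, meta), "at least 2")
})

test_that("neutral generator and forward simulator agree on richness", {
  # matched (theta, m, J): the urn generator at one site vs a forward
  # Moran run sampled without replacement at the same depth
  theta <- 10; m <- 0.3; J <- 300
  set.seed(17)
  meta <- msneutral:::stick_break_cpp(theta, 1e-8)
  meta <- meta / sum(meta)
  rich_urn <- vapply(1:60, function(r) {
    ncol(simulate_neutral_metacommunity(theta, immigration_from_m(m, J), J))
  }, numeric(1))
  rich_fwd <- vapply(1:60, function(r) {
    metar <- msneutral:::stick_break_cpp(theta, 1e-8)
    sum(forward_hubbell(J, m, metar, n_events = 30 * J) > 0)
  }, numeric(1))
  ks <- suppressWarnings(stats::ks.test(rich_urn, rich_fwd))
  expect_gt(ks$p.value, 0.01)
})
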