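test_that("m <-> I transforms are exact inverses and order preserving", {
  expect_equal(immigration_from_m(0.5, 2), 1)
  expect_equal(immigration_from_m(0.05, 2500), 2499 * 0.05 / 0.95)
  expect_equal(m_from_immigration(1, 2), 0.5)
  expect_equal(m_from_immigration(131.526315789, 2500), 0.05,
               tolerance = 1e-9)
  m <- c(0.001, 0.151, 0.5, 0.93)
  expect_equal(m_from_immigration(immigration_from_m(m, 2500), 2500), m,
               tolerance = 1e-12)
  expect_true(all(diff(immigration_from_m(m, 2500)) > 0))
  expect_error(immigration_from_m(1, 10), "strictly")
  expect_error(immigration_from_m(0, 10), "strictly")
  expect_error(m_from_immigration(-2, 10), "positive")
})

test_that("theta follows from the speciation probability", {
  expect_equal(theta_from_speciation(0.5, 3), 2)
  expect_equal(theta_from_speciation(0.01, 10001), 0.01 / 0.99 * 10000)
  expect_error(theta_from_speciation(1, 10), "strictly")
})

test_that("site likelihood reproduces Polya-urn enumeration", {
  # a single draw has probability equal to the metacommunity frequency
  expect_equal(site_log_likelihood(c(1, 0), 7.3, c(0.4, 0.6)), log(0.4))
  # J = 2, I = 1, beta = (1/2, 1/2): urn enumeration over the 3 outcomes
  expect_equal(site_log_likelihood(c(2, 0), 1, c(0.5, 0.5)), log(0.375))
  expect_equal(site_log_likelihood(c(1, 1), 1, c(0.5, 0.5)), log(0.25))
  expect_equal(site_log_likelihood(c(0, 2), 1, c(0.5, 0.5)), log(0.375))
  # impossible observation, distinct from a precondition violation
  expect_identical(site_log_likelihood(c(1, 1), 1, c(1, 0)), -Inf)
  expect_error(site_log_likelihood(c(1, 0), -1, c(0.5, 0.5)), "positive")
  expect_error(site_log_likelihood(c(1, 0), 1, c(0.9, 0.9)), "mass")
})

test_that("Dirichlet-multinomial normalizes over all count vectors", {
  for (S in 2:3) {
    beta <- if (S == 2) c(0.3, 0.7) else c(0.2, 0.3, 0.5)
    for (J in c(2, 4)) {
      grids <- do.call(expand.grid, rep(list(0:J), S))
      grids <- grids[rowSums(grids) == J, , drop = FALSE]
      for (I in c(0.1, 1, 10)) {
        tot <- sum(apply(grids, 1, function(x) {
          exp(site_log_likelihood(as.numeric(x), I, beta))
        }))
        expect_equal(tot, 1, tolerance = 1e-10)
      }
    }
  }
})

test_that("large immigration recovers the multinomial limit", {
  x <- c(5, 2, 1)
  beta <- c(0.6, 0.3, 0.1)
  mn <- lgamma(sum(x) + 1) - sum(lgamma(x + 1)) + sum(x * log(beta))
  expect_equal(site_log_likelihood(x, 1e6, beta), mn, tolerance = 1e-4)
})

test_that("likelihood is finite and continuous in I on (0, Inf)", {
  x <- c(12, 3, 0, 1)
  beta <- c(0.5, 0.3, 0.1, 0.1)
  Is <- 10^seq(-3, 5, length.out = 60)
  ll <- vapply(Is, function(I) site_log_likelihood(x, I, beta), numeric(1))
  expect_true(all(is.finite(ll)))
  expect_lt(max(abs(diff(ll))), 10) # no jumps along a smooth grid
})

test_that("metacommunity likelihood is additive and order invariant", {
  X <- community_matrix(rbind(c(2, 0), c(0, 2)))
  I <- c(1, 1)
  beta <- c(0.5, 0.5)
  expect_equal(metacommunity_log_likelihood(X, I, beta), 2 * log(0.375))
  Xp <- community_matrix(X[2:1, ])
  expect_equal(metacommunity_log_likelihood(Xp, I, beta),
               metacommunity_log_likelihood(X, I, beta))
  # single site (plain matrix input): equals the site likelihood
  expect_equal(metacommunity_log_likelihood(rbind(c(2, 0)), 1, beta),
               site_log_likelihood(c(2, 0), 1, beta))
})

test_that("community matrices validate counts and drop empty taxa", {
  expect_message(X <- community_matrix(rbind(c(1, 0, 3), c(2, 0, 1))),
                 "all-zero")
  expect_identical(ncol(X), 2L)
  expect_identical(unname(attr(X, "site_totals")), c(4, 3))
  expect_error(community_matrix(rbind(c(1, 0), c(0, 0))), "positive read")
  expect_error(community_matrix(rbind(c(1.5, 1))), "integers")
  expect_error(community_matrix(rbind(c(-1, 2))), "integers")
})

test_that("OTU tables round-trip through the tab-separated format", {
  X <- make_neutral_matrix(theta = 10, m = 0.2, J = c(150, 150), seed = 5)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_otu_table(X, path)
  # on disk: taxa as rows, first column taxon_id, header = sample ids
  hdr <- readLines(path, n = 1)
  expect_match(hdr, "^taxon_id\t")
  Y <- read_otu_table(path)
  expect_identical(unclass(as.matrix(Y)), unclass(as.matrix(X)))
  # transposed layout via the flag
  path2 <- withr::local_tempfile(fileext = ".tsv")
  df <- data.frame(sample_id = rownames(X), as.matrix(X),
                   check.names = FALSE)
  write.table(df, path2, sep = "\t", quote = FALSE, row.names = FALSE)
  Z <- read_otu_table(path2, samples_as_rows = TRUE)
  expect_identical(unclass(as.matrix(Z)), unclass(as.matrix(X)))
  # non-integer cells are an error
  path3 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("taxon_id\ts1\ts2", "t1\t1.5\t2", "t2\t1\t1"), path3)
  expect_error(read_otu_table(path3), "non-integer")
})

test_that("BIOM-style JSON tables are ingested", {
  skip_if_not_installed("biomformat")
  X <- make_neutral_matrix(theta = 5, m = 0.3, J = c(80, 80), seed = 9)
  b <- biomformat::make_biom(t(as.matrix(X))) # biom stores taxa x samples
  path <- withr::local_tempfile(fileext = ".biom")
  biomformat::write_biom(b, path)
  Y <- read_biom_table(path)
  expect_equal(unname(as.matrix(Y)), unname(as.matrix(X)))
})
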