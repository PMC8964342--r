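# Core data types of the multi-site neutral model, the m <-> I and
# nu <-> theta parameter transforms, and the Dirichlet-multinomial
# observation likelihood that defines L_0 and every simulated-likelihood
# comparison in the neutrality tests.

#' Community matrix of site-by-taxon counts
#'
#' Validated container for one metacommunity instance: an integer abundance
#' matrix `x[i, j]` of `M` sites by `S` observed taxa. Taxon columns that
#' are all-zero are dropped (with a message) so that every observed taxon
#' has at least one read somewhere; every site must have a positive read
#' total.
#'
#' @param counts Integer matrix, sites in rows, taxa in columns.
#' @param site_ids,taxon_ids Optional label vectors; default to existing
#'   dimnames or generated labels.
#' @return An object of class `community_matrix`: the integer matrix with
#'   dimnames set and attribute `site_totals`.
#' @export
community_matrix <- function(counts, site_ids = NULL, taxon_ids = NULL) {
  counts <- as.matrix(counts)
  if (any(!is.finite(counts)) || any(counts < 0) ||
      any(counts != round(counts))) {
    stop("counts must be non-negative integers")
  }
  storage.mode(counts) <- "integer"
  if (is.null(site_ids)) {
    site_ids <- rownames(counts) %||% paste0("site", seq_len(nrow(counts)))
  }
  if (is.null(taxon_ids)) {
    taxon_ids <- colnames(counts) %||% paste0("taxon", seq_len(ncol(counts)))
  }
  dimnames(counts) <- list(site_ids, taxon_ids)
  empty <- colSums(counts) == 0L
  if (any(empty)) {
    message(sum(empty), " all-zero taxon column(s) dropped")
    counts <- counts[, !empty, drop = FALSE]
  }
  if (ncol(counts) == 0L) stop("no taxon has a positive count")
  totals <- rowSums(counts)
  if (any(totals == 0L)) {
    stop("every site must have a positive read total; offending site(s): ",
         paste(rownames(counts)[totals == 0L], collapse = ", "))
  }
  structure(counts, site_totals = totals, class = c("community_matrix",
                                                    "matrix", "array"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
as.matrix.community_matrix <- function(x, ...) {
  attr(x, "site_totals") <- NULL
  class(x) <- NULL
  x
}

#' @export
print.community_matrix <- function(x, ...) {
  cat(sprintf("community_matrix: %d site(s) x %d taxa, read depths %s\n",
              nrow(x), ncol(x),
              paste(attr(x, "site_totals"), collapse = ", ")))
  invisible(x)
}

#' Gamma prior specification for the Gibbs sampler
#'
#' Shape/rate constants of the Gamma priors on the fundamental biodiversity
#' number \eqn{\theta} and the per-site immigration rates \eqn{I_i}. The
#' defaults are Gamma(0.1, 0.001) on both: both parameters live on scales
#' of tens to hundreds at realistic read depths, where an exponential rate
#' of even 0.1 is strongly informative (it shrinks estimates — and the
#' implied migration probability — markedly downward), so the default rate
#' is kept three orders of magnitude smaller.
#'
#' @param theta_shape,theta_rate Prior on \eqn{\theta}.
#' @param immig_shape,immig_rate Prior on each \eqn{I_i}.
#' @return A `prior_spec` list.
#' @export
prior_spec <- function(theta_shape = 0.1, theta_rate = 0.001,
                       immig_shape = 0.1, immig_rate = 0.001) {
  vals <- c(theta_shape, theta_rate, immig_shape, immig_rate)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all prior constants must be strictly positive")
  }
  structure(list(theta_shape = theta_shape, theta_rate = theta_rate,
                 immig_shape = immig_shape, immig_rate = immig_rate),
            class = "prior_spec")
}

#' Convert a migration probability to an immigration rate
#'
#' \eqn{I = (N - 1)\, m / (1 - m)}: the scaled coupling of a local
#' community of size `n_local` to the metacommunity. The sample read total
#' \eqn{J_i} stands in for the unobservable local community size.
#'
#' @param m Migration probability in (0, 1).
#' @param n_local Local community (sample) size, at least 2.
#' @return Immigration rate \eqn{I > 0}; strictly increasing in `m`.
#' @export
immigration_from_m <- function(m, n_local) {
  if (any(m <= 0) || any(m >= 1)) stop("`m` must lie strictly in (0, 1)")
  if (any(n_local < 2)) stop("`n_local` must be at least 2")
  (n_local - 1) * m / (1 - m)
}

#' Convert an immigration rate to a migration probability
#'
#' Inverse of [immigration_from_m()]: \eqn{m = I / (I + N - 1)}.
#'
#' @param I Positive immigration rate.
#' @param n_local Local community (sample) size, at least 2.
#' @return Migration probability in (0, 1).
#' @export
m_from_immigration <- function(I, n_local) {
  if (any(I <= 0)) stop("`I` must be positive")
  if (any(n_local < 2)) stop("`n_local` must be at least 2")
  I / (I + n_local - 1)
}

#' Fundamental biodiversity number from a speciation probability
#'
#' \eqn{\theta = \nu/(1 - \nu)\,(N - 1)} for speciation probability
#' \eqn{\nu} in a metacommunity of \eqn{N} individuals.
#'
#' @param nu Speciation probability in (0, 1).
#' @param n_meta Metacommunity size, at least 2.
#' @return \eqn{\theta > 0}.
#' @export
theta_from_speciation <- function(nu, n_meta) {
  if (any(nu <= 0) || any(nu >= 1)) stop("`nu` must lie strictly in (0, 1)")
  if (any(n_meta < 2)) stop("`n_meta` must be at least 2")
  nu / (1 - nu) * (n_meta - 1)
}

#' Dirichlet-multinomial log-likelihood of one site
#'
#' Marginalizing the Dirichlet-process site composition
#' \eqn{\pi_i \sim DP(I, \beta)} out of the multinomial observation model
#' gives the Dirichlet-multinomial likelihood
#' \deqn{\log \binom{J}{x_1 \cdots x_S} + \log\Gamma(I) - \log\Gamma(I + J)
#'  + \sum_j \{\log\Gamma(I\beta_j + x_j) - \log\Gamma(I\beta_j)\}.}
#' `beta` holds the metacommunity relative frequencies of the taxa in
#' `x_row` and may sum to less than 1: the remaining (unrepresented) mass
#' carries a zero count and contributes nothing, while the total
#' concentration is always `I` times the full unit mass. A positive count
#' on a zero-frequency taxon yields `-Inf` (an impossible observation, not
#' an error).
#'
#' @param x_row Non-negative integer count vector with positive total.
#' @param I Positive immigration rate of the site.
#' @param beta Non-negative frequency vector, same length as `x_row`,
#'   summing to at most 1.
#' @return Log-likelihood (finite, or `-Inf` for impossible observations).
#' @export
site_log_likelihood <- function(x_row, I, beta) {
  if (length(beta) != length(x_row)) stop("`beta` and `x_row` lengths differ")
  if (any(x_row < 0) || any(x_row != round(x_row))) {
    stop("counts must be non-negative integers")
  }
  if (!is.finite(I) || I <= 0) stop("`I` must be positive and finite")
  if (any(beta < 0) || sum(beta) > 1 + 1e-9) {
    stop("`beta` must be non-negative with total mass at most 1")
  }
  J <- sum(x_row)
  if (J < 1) stop("site read total must be positive")
  pos <- x_row > 0
  if (any(beta[pos] == 0)) return(-Inf)
  a <- I * beta[pos]
  lgamma(J + 1) - sum(lgamma(x_row[pos] + 1)) +
    lgamma(I) - lgamma(I + J) +
    sum(lgamma(a + x_row[pos]) - lgamma(a))
}

#' Metacommunity log-likelihood
#'
#' Sum of [site_log_likelihood()] over the sites of a community matrix;
#' this is the quantity reported as the observed likelihood \eqn{L_0} and
#' recomputed for every simulated replicate in the neutrality tests.
#'
#' @param X A [community_matrix()] (or plain count matrix).
#' @param I Vector of per-site immigration rates (length `nrow(X)`).
#' @param beta Metacommunity frequencies of the columns of `X`.
#' @return Total log-likelihood.
#' @export
metacommunity_log_likelihood <- function(X, I, beta) {
  X <- as.matrix(X)
  if (length(I) != nrow(X)) stop("one immigration rate per site required")
  sum(vapply(seq_len(nrow(X)),
             function(i) site_log_likelihood(X[i, ], I[i], beta),
             numeric(1)))
}

# ---- OTU table I/O --------------------------------------------------------

#' Read an OTU count table
#'
#' Tab-separated text with taxa as rows and samples as columns, first
#' column the taxon ID and header row the sample IDs (the common QIIME
#' export layout). Set `samples_as_rows = TRUE` when the table is stored
#' transposed. All cells must parse as non-negative integers.
#'
#' @param path File path.
#' @param samples_as_rows Logical; is the table already samples x taxa?
#' @return A [community_matrix()] (sites/samples in rows).
#' @export
read_otu_table <- function(path, samples_as_rows = FALSE) {
  tab <- read.delim(path, header = TRUE, row.names = 1, sep = "\t",
                    check.names = FALSE)
  mat <- as.matrix(tab)
  if (!is.numeric(mat) || any(mat != round(mat))) {
    stop("OTU table contains non-integer cells")
  }
  if (!samples_as_rows) mat <- t(mat)
  community_matrix(mat)
}

#' Write an OTU count table
#'
#' Inverse of [read_otu_table()]: taxa as rows, samples as columns,
#' tab-separated, first column `taxon_id`.
#'
#' @param X A [community_matrix()] or count matrix (sites in rows).
#' @param path Output file path.
#' @export
write_otu_table <- function(X, path) {
  mat <- t(as.matrix(X))
  df <- data.frame(taxon_id = rownames(mat), mat, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a BIOM-format (JSON) OTU table
#'
#' Ingests the JSON flavour of the BIOM format via the `biomformat`
#' package and returns the sample-by-taxon community matrix.
#'
#' @param path Path to a BIOM JSON file.
#' @return A [community_matrix()] (samples in rows).
#' @export
read_biom_table <- function(path) {
  if (!requireNamespace("biomformat", quietly = TRUE)) {
    stop("the `biomformat` package is required to read BIOM files")
  }
  b <- biomformat::read_biom(path)
  mat <- as.matrix(biomformat::biom_data(b)) # taxa x samples
  if (any(mat != round(mat))) stop("BIOM table contains non-integer cells")
  community_matrix(t(mat))
}
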