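# Generators standing in for the study's couple-level OTU tables (23
# couples, one semen and two vaginal samples each, with no public
# accession): neutral metacommunities shaped like the couple design, a
# niche-structured (selection-weighted) control for power checks, and a
# forward-in-time Moran simulator used to validate the Dirichlet-process
# approximation of the local dynamics.

#' Specification of a synthetic couple dataset
#'
#' Defaults mirror the study design: 23 couples, three sites per couple
#' (CM = semen, CNA = vaginal before intercourse, CNB = vaginal after),
#' mean read depths 1,712 (CM) and 2,854 (CNA/CNB). Depths are drawn as
#' rounded log-normals around the role means with coefficient of variation
#' `depth_cv`, floored at 200. `theta_true` and `m_true` set the neutral
#' parameters (`m_true` may be a single value or named per role);
#' `niche_effect = 1` is the neutral null, values above 1 multiply the
#' per-read acceptance weight of a random half of each site's taxa.
#'
#' @param n_couples Number of couples.
#' @param depth_means Named mean read depths per role.
#' @param depth_cv Coefficient of variation of the log-normal depths.
#' @param theta_true Biodiversity number of each couple's metacommunity.
#' @param m_true Migration probability (scalar or named per role).
#' @param niche_effect Selection strength, `>= 1`; 1 = neutral.
#' @param seed Integer seed.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_couples = 23L,
                           depth_means = c(CM = 1712, CNA = 2854,
                                           CNB = 2854),
                           depth_cv = 0.3, theta_true = 50, m_true = 0.05,
                           niche_effect = 1, seed = 1L) {
  roles <- c("CM", "CNA", "CNB")
  stopifnot(all(roles %in% names(depth_means)), all(depth_means > 0),
            theta_true > 0, all(m_true > 0), all(m_true < 1),
            niche_effect >= 1, n_couples >= 1)
  if (length(m_true) == 1L) m_true <- setNames(rep(m_true, 3), roles)
  stopifnot(all(roles %in% names(m_true)))
  structure(list(n_couples = as.integer(n_couples), roles = roles,
                 depth_means = depth_means[roles], depth_cv = depth_cv,
                 theta_true = theta_true, m_true = m_true[roles],
                 niche_effect = niche_effect, seed = as.integer(seed)),
            class = "synthetic_spec")
}

.draw_depth <- function(mean_depth, cv) {
  sdlog <- sqrt(log1p(cv^2))
  d <- round(exp(rnorm(1, log(mean_depth) - sdlog^2 / 2, sdlog)))
  max(200, d)
}

.simulate_couple <- function(spec) {
  atoms <- stick_break_cpp(spec$theta_true, 1e-8)
  K <- length(atoms)
  counts <- matrix(0L, 3, K,
                   dimnames = list(spec$roles, paste0("T", seq_len(K))))
  for (r in spec$roles) {
    J <- .draw_depth(spec$depth_means[[r]], spec$depth_cv)
    I <- immigration_from_m(spec$m_true[[r]], J)
    w <- numeric(0)
    if (spec$niche_effect > 1) {
      w <- rep(1, K)
      w[sample.int(K, K %/% 2)] <- spec$niche_effect
    }
    counts[r, ] <- polya_urn_cpp(J, I, atoms, w)
  }
  counts
}

#' Generate a synthetic couple dataset
#'
#' For each couple draws one metacommunity by stick breaking at
#' `theta_true` and assembles the three sites (CM, CNA, CNB) by Polya urn
#' at the immigration rate implied by `m_true` and the site's drawn depth.
#' With `niche_effect = 1` each couple is exactly a draw from
#' [simulate_neutral_metacommunity()]; larger values add site-specific
#' selection. Fully reproducible from `spec$seed`.
#'
#' @param spec A [synthetic_spec()].
#' @return List with `$matrices` (one [community_matrix()] per couple,
#'   sites in rows) and `$design` (data frame: `sample_id`, `couple_id`,
#'   `role`).
#' @export
generate_couple_dataset <- function(spec = synthetic_spec()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  ids <- sprintf("C%02d", seq_len(spec$n_couples))
  mats <- vector("list", spec$n_couples)
  names(mats) <- ids
  design <- NULL
  for (c in seq_along(ids)) {
    counts <- .simulate_couple(spec)
    rownames(counts) <- paste0(ids[c], "_", spec$roles)
    mats[[c]] <- suppressMessages(community_matrix(counts))
    design <- rbind(design,
                    data.frame(sample_id = rownames(counts),
                               couple_id = ids[c], role = spec$roles))
  }
  list(matrices = mats, design = design, spec = spec)
}

#' Generate a niche-structured (non-neutral) control dataset
#'
#' As [generate_couple_dataset()] but requires `niche_effect > 1`: at each
#' site a random half of the metacommunity's taxa have their per-read
#' acceptance weight multiplied by `niche_effect`, i.e. site-specific
#' filtering of the urn draws with depth held fixed. The neutral model is
#' nested at `niche_effect = 1`.
#'
#' @param spec A [synthetic_spec()] with `niche_effect > 1`.
#' @inherit generate_couple_dataset return
#' @export
generate_niche_dataset <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (spec$niche_effect <= 1) {
    stop("`spec$niche_effect` must exceed 1 for the niche control")
  }
  generate_couple_dataset(spec)
}

#' Forward Moran simulation of a local neutral community
#'
#' Zero-sum death/replacement dynamic: at each event a random individual
#' dies and is replaced by a metacommunity immigrant with probability `m`
#' or by the offspring of a randomly chosen surviving local individual
#' otherwise. This is the process whose stationary composition the
#' Dirichlet-process approximation (immigration rate
#' \eqn{I = (N-1)m/(1-m)}) describes; the package's validation suite
#' compares the two.
#'
#' @param N Local community size (`>= 2`).
#' @param m Migration probability in (0, 1].
#' @param metacommunity_sad Relative abundances of the source pool.
#' @param n_events Number of death events (default `50 * N`, ample for
#'   stationarity at moderate `m`).
#' @return Integer count vector over the metacommunity taxa, summing to
#'   `N`.
#' @export
forward_hubbell <- function(N, m, metacommunity_sad, n_events = 50 * N) {
  forward_hubbell_cpp(as.integer(N), m, metacommunity_sad,
                      as.integer(n_events))
}
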