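# Orchestration of the couple-level transmission analysis: grouping each
# couple's samples into the four metacommunity settings (CM+CNA+CNB and
# the three pairs), fitting and testing every setting x couple, tabulating
# summary tables (observed likelihood, theta, m, M-value, simulated
# likelihoods, pseudo-P at both levels, passing rates), and rank-based
# cross-setting comparisons of m and theta.

.SETTINGS <- list("CM+CNA+CNB" = c("CM", "CNA", "CNB"),
                  "CM+CNA" = c("CM", "CNA"),
                  "CM+CNB" = c("CM", "CNB"),
                  "CNA+CNB" = c("CNA", "CNB"))

#' Build the four metacommunity groupings from a couple design
#'
#' Each couple contributes one metacommunity per setting: the full
#' three-site grouping CM+CNA+CNB and the pairwise combinations CM+CNA,
#' CM+CNB and CNA+CNB. Couples missing a role are excluded from the
#' settings that need it, with a warning.
#'
#' @param design Data frame with columns `sample_id`, `couple_id`, `role`
#'   (roles among CM, CNA, CNB; at most one sample per couple and role).
#' @return Named list of settings; each a named list mapping couple IDs to
#'   the sample IDs of the grouping's sites.
#' @export
build_groupings <- function(design) {
  stopifnot(all(c("sample_id", "couple_id", "role") %in% names(design)))
  if (!all(design$role %in% c("CM", "CNA", "CNB"))) {
    stop("roles must be among CM, CNA, CNB")
  }
  if (anyDuplicated(design$sample_id)) stop("duplicated sample_ids")
  if (anyDuplicated(design[, c("couple_id", "role")])) {
    stop("a couple may have at most one sample per role")
  }
  couples <- unique(design$couple_id)
  out <- lapply(.SETTINGS, function(roles) {
    g <- lapply(couples, function(cid) {
      sub <- design[design$couple_id == cid & design$role %in% roles, ]
      if (nrow(sub) < length(roles)) return(NULL)
      sub$sample_id[match(roles, sub$role)]
    })
    names(g) <- couples
    keep <- !vapply(g, is.null, logical(1))
    if (any(!keep)) {
      warning(sprintf("%d couple(s) missing a role excluded from %s",
                      sum(!keep), paste(roles, collapse = "+")),
              call. = FALSE)
    }
    g[keep]
  })
  out
}

.align_couple_sites <- function(matrices, design, sample_ids) {
  # rows of the couple's matrix for the requested samples, taxa aligned by
  # label union; taxa absent in all requested sites dropped
  cid <- unique(design$couple_id[match(sample_ids, design$sample_id)])
  stopifnot(length(cid) == 1L)
  mat <- as.matrix(matrices[[cid]])
  rows <- mat[sample_ids, , drop = FALSE]
  suppressMessages(community_matrix(rows))
}

#' Run the full couple-level neutral-model analysis
#'
#' For every setting and couple: aligns the grouping's sites, fits the
#' multi-site neutral model ([fit_msn()]) and runs the neutrality test at
#' both levels ([run_neutrality_test()]), assembling one summary table per
#' setting with columns `ID`, `L_0`, `theta`, `m`, `M_value`, `L_M`,
#' `N_M`, `N`, `P_M`, `L_L`, `N_L`, `P_L`, plus column means and
#' metacommunity/local passing rates (percentage of couples with P >
#' 0.05). Per-(couple, setting) chains are seeded deterministically from
#' `master_seed` as `master_seed + 1009 * couple_index + 101 *
#' setting_index`, so a rerun reproduces every cell. Couples whose fit
#' fails are recorded in `$failures` and excluded from means.
#'
#' @param matrices Named list of per-couple [community_matrix()] objects
#'   (couple ID -> sites-in-rows matrix), as from
#'   [generate_couple_dataset()].
#' @param design The couple design data frame.
#' @param settings A [chain_settings()]; its seed is ignored in favour of
#'   the derived per-cell seeds.
#' @param master_seed Integer master seed.
#' @return List with `$summaries` (one data frame per setting),
#'   `$passing_rates`, `$comparisons` (from [compare_settings()]) and
#'   `$failures`.
#' @export
run_full_analysis <- function(matrices, design, settings = chain_settings(),
                              master_seed = 1L) {
  groups <- suppressWarnings(build_groupings(design))
  summaries <- list()
  failures <- list()
  for (s in seq_along(groups)) {
    sname <- names(groups)[s]
    rows <- NULL
    for (k in seq_along(groups[[s]])) {
      cid <- names(groups[[s]])[k]
      cell_seed <- (master_seed + 1009L * k + 101L * s) %% .Machine$integer.max
      res <- tryCatch({
        X <- .align_couple_sites(matrices, design, groups[[s]][[k]])
        st <- settings
        st$seed <- as.integer(cell_seed)
        fit <- fit_msn(X, st)
        tm <- run_neutrality_test(X, fit, "metacommunity")
        tl <- run_neutrality_test(X, fit, "local")
        data.frame(ID = cid, L_0 = fit$L0, theta = fit$theta_median,
                   m = fit$m_pooled, M_value = fit$M_value,
                   L_M = tm$L_sim_median, N_M = tm$n_below, N = tm$n_total,
                   P_M = tm$pseudo_P, L_L = tl$L_sim_median,
                   N_L = tl$n_below, P_L = tl$pseudo_P)
      }, error = function(e) e)
      if (inherits(res, "error")) {
        failures[[paste(sname, cid, sep = ":")]] <- conditionMessage(res)
      } else {
        rows <- rbind(rows, res)
      }
    }
    summaries[[sname]] <- rows
  }
  passing <- t(vapply(summaries, function(df) {
    if (is.null(df)) return(c(meta = NA_real_, local = NA_real_))
    c(meta = 100 * mean(df$P_M > 0.05, na.rm = TRUE),
      local = 100 * mean(df$P_L > 0.05, na.rm = TRUE))
  }, numeric(2)))
  list(summaries = summaries, passing_rates = passing,
       comparisons = compare_settings(summaries), failures = failures)
}

#' Append a mean row to a setting summary table
#'
#' Unweighted arithmetic means over couples of every numeric column,
#' computed over finite entries only.
#'
#' @param df A per-setting summary data frame from [run_full_analysis()].
#' @return The table with a final `Mean` row.
#' @export
summary_with_mean <- function(df) {
  num <- vapply(df, is.numeric, logical(1))
  mean_row <- df[1, ]
  mean_row$ID <- "Mean"
  for (j in names(df)[num]) {
    mean_row[[j]] <- mean(df[[j]][is.finite(df[[j]])])
  }
  rbind(df, mean_row)
}

#' Cross-setting comparisons of m and theta
#'
#' For each of the six pairs of metacommunity settings, a Wilcoxon
#' rank-based test on the per-couple migration probability `m` and on the
#' per-couple biodiversity number `theta`. The paired signed-rank version
#' (pairing by couple) is the default since every setting is measured on
#' the same couples; `paired = FALSE` gives the rank-sum variant. Raw
#' p-values are reported with a significance flag at 0.05, plus
#' Benjamini-Hochberg-adjusted values (per tested quantity) as a clearly
#' separate column. Comparing a setting with itself (all paired
#' differences zero) returns p = 1 with a warning.
#'
#' @param summaries Named list of per-setting summary data frames (columns
#'   `ID`, `m`, `theta`), as produced by [run_full_analysis()].
#' @param paired Use the paired signed-rank test (default) or unpaired
#'   rank-sum.
#' @return Data frame with one row per setting pair and per quantity:
#'   `setting_a`, `setting_b`, `quantity`, `p_value`, `significant`,
#'   `p_BH`, `n_pairs`.
#' @export
compare_settings <- function(summaries, paired = TRUE) {
  summaries <- summaries[!vapply(summaries, is.null, logical(1))]
  if (length(summaries) < 2) stop("need at least two settings to compare")
  small <- vapply(summaries, nrow, integer(1)) < 6L
  if (any(small)) {
    warning("settings with fewer than 6 couples: ",
            paste(names(summaries)[small], collapse = ", "), call. = FALSE)
  }
  pairs <- utils::combn(names(summaries), 2, simplify = FALSE)
  out <- NULL
  for (pr in pairs) {
    a <- summaries[[pr[1]]]; b <- summaries[[pr[2]]]
    for (qty in c("m", "theta")) {
      if (paired) {
        common <- intersect(a$ID, b$ID)
        dropped <- length(union(a$ID, b$ID)) - length(common)
        if (dropped > 0) {
          message(dropped, " unpaired couple(s) dropped for ",
                  pr[1], " vs ", pr[2])
        }
        va <- a[[qty]][match(common, a$ID)]
        vb <- b[[qty]][match(common, b$ID)]
        n_pairs <- length(common)
        if (all(va == vb)) {
          warning("all paired differences are zero for ", qty, " in ",
                  pr[1], " vs ", pr[2], "; p set to 1", call. = FALSE)
          p <- 1
        } else {
          p <- suppressWarnings(wilcox.test(va, vb, paired = TRUE)$p.value)
        }
      } else {
        n_pairs <- min(nrow(a), nrow(b))
        p <- suppressWarnings(wilcox.test(a[[qty]], b[[qty]])$p.value)
      }
      out <- rbind(out, data.frame(setting_a = pr[1], setting_b = pr[2],
                                   quantity = qty, p_value = p,
                                   significant = is.finite(p) & p < 0.05,
                                   n_pairs = n_pairs))
    }
  }
  out$p_BH <- NA_real_
  for (qty in c("m", "theta")) {
    idx <- out$quantity == qty
    out$p_BH[idx] <- p.adjust(out$p_value[idx], method = "BH")
  }
  out
}
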