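#' Malthusian growth rate
#'
#' Per-day exponential growth rate `m = ln(n1/n0) / t` estimated from a
#' start and end density. A final count of zero is censored at the
#' detection limit before taking the log (a plate count cannot
#' distinguish absence from below-detection); censored entries are
#' flagged in the `"censored"` attribute.
#'
#' @param n0 Starting density (> 0), cfu/mL.
#' @param n1 Final density (>= 0), cfu/mL.
#' @param t Assay duration in days (> 0, default 7).
#' @param detection_limit Replacement value for zero final counts
#'   (default 1 cfu/mL).
#' @return Numeric vector of growth rates (day^-1) with a logical
#'   `"censored"` attribute.
#' @export
#' @examples
#' malthusian(1e5, 1e7, 7) # ln(100)/7 ~ 0.658
malthusian <- function(n0, n1, t = 7, detection_limit = 1) {
  if (any(!is.finite(n0)) || any(n0 <= 0)) {
    stop("starting density n0 must be positive", call. = FALSE)
  }
  if (any(!is.finite(n1)) || any(n1 < 0)) {
    stop("final density n1 must be >= 0", call. = FALSE)
  }
  if (any(t <= 0)) stop("assay time t must be positive", call. = FALSE)
  censored <- n1 == 0
  n1[censored] <- detection_limit
  structure(log(n1 / n0) / t, censored = censored)
}

#' Relative invader growth rate
#'
#' The invasion-from-rare fitness statistic: the ratio of Malthusian
#' parameters `m_focal : m_community`, where the community rate is
#' computed from the total (summed) density change of all resident
#' populations combined. A ratio above 1 means the rare invader outgrew
#' the resident community (negative frequency dependence). When the
#' resident total does not increase (`m_community <= 0`) the ratio is
#' uninterpretable and is returned as `NA` with a warning.
#'
#' @param n0_focal,n1_focal Invader start/final densities (cfu/mL).
#' @param n0_residents,n1_residents Per-resident start/final densities
#'   (numeric vectors, summed before the log).
#' @param t Assay duration in days (default 7).
#' @param detection_limit Censoring value for zero final counts.
#' @return Single numeric ratio (or `NA` when undefined).
#' @export
#' @examples
#' relative_invader_growth(1e3, 1e6, 1e5, 1e7) # ln(1000)/ln(100) = 1.5
relative_invader_growth <- function(n0_focal, n1_focal, n0_residents,
                                    n1_residents, t = 7, detection_limit = 1) {
  if (length(n0_residents) != length(n1_residents)) {
    stop("resident density vectors must have equal length", call. = FALSE)
  }
  if (length(n0_residents) == 0) stop("residents must be nonempty", call. = FALSE)
  m_focal <- as.numeric(malthusian(n0_focal, n1_focal, t, detection_limit))
  m_community <- as.numeric(malthusian(sum(n0_residents), sum(n1_residents),
                                       t, detection_limit))
  if (m_community <= 0) {
    warning("resident community did not grow (m_community <= 0); ",
            "relative invader growth rate undefined", call. = FALSE)
    return(NA_real_)
  }
  m_focal / m_community
}

#' One-sample test of invasion
#'
#' Two-sided one-sample t-test of the replicate relative invader growth
#' rates against the null hypothesis that their mean equals
#' `null_value` (1: invader and residents grow equally fast).
#' Zero-variance replicate sets are flagged degenerate with an
#' undefined p-value rather than a division by zero.
#'
#' @param ratios Numeric vector of replicate ratios (>= 2 finite values).
#' @param null_value Null mean (default 1).
#' @return List with `mean`, `t`, `df`, `p`, `n` and `degenerate`.
#' @export
test_invasion <- function(ratios, null_value = 1) {
  ratios <- ratios[is.finite(ratios)]
  n <- length(ratios)
  if (n < 2) stop("at least two finite replicate ratios are required",
                  call. = FALSE)
  if (sd(ratios) == 0) {
    return(list(mean = mean(ratios), t = NA_real_, df = n - 1L, p = NA_real_,
                n = n, degenerate = TRUE))
  }
  ht <- t.test(ratios, mu = null_value, alternative = "two.sided")
  list(mean = unname(ht$estimate), t = unname(ht$statistic),
       df = unname(ht$parameter), p = ht$p.value, n = n, degenerate = FALSE)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up false discovery rate correction of a vector of p-values,
#' applied jointly across all tests of a family (here: all 75 invasion
#' treatments together). Validates the input range and delegates to the
#' standard step-up implementation.
#'
#' @param p_values Numeric vector with values in `[0, 1]` (`NA` allowed).
#' @return Adjusted p-values in the input order.
#' @export
adjust_fdr <- function(p_values) {
  ok <- is.na(p_values) | (p_values >= 0 & p_values <= 1)
  if (!all(ok)) stop("p-values must lie in [0, 1]", call. = FALSE)
  p.adjust(p_values, method = "BH")
}

#' Per-treatment invasion statistics
#'
#' Computes the full invasion-from-rare analysis from a long-format
#' invasion table: per-replicate relative invader growth rates, a
#' one-sample t-test per treatment against a mean of 1, and joint FDR
#' correction across treatments. Replicates whose resident community
#' declined are excluded with a warning.
#'
#' @param invasion Data frame with columns `focal`, `residents`,
#'   `replicate`, `species`, `n0`, `n1`, `t` (one row per species per
#'   replicate culture), as produced by [generate_study_datasets()].
#' @param alpha Significance level applied to the FDR-adjusted p-values
#'   (default 0.05).
#' @param detection_limit Censoring value for zero final counts.
#' @return Data frame with one row per treatment: `focal`, `residents`,
#'   `diversity`, `n`, `mean_ratio`, `t`, `df`, `p`, `p_adj`, `invades`.
#' @export
invasion_stats <- function(invasion, alpha = 0.05, detection_limit = 1) {
  needed <- c("focal", "residents", "replicate", "species", "n0", "n1", "t")
  if (!all(needed %in% names(invasion))) {
    stop("invasion table must have columns: ", paste(needed, collapse = ", "),
         call. = FALSE)
  }
  key <- interaction(invasion$focal, invasion$residents, drop = TRUE)
  res <- lapply(split(invasion, key), function(tr) {
    focal <- tr$focal[1]
    ratios <- vapply(split(tr, tr$replicate), function(rep) {
      f <- rep[rep$species == focal, ]
      r <- rep[rep$species != focal, ]
      if (nrow(f) != 1 || nrow(r) == 0) {
        stop("treatment ", focal, " vs ", tr$residents[1],
             ": missing focal or resident densities", call. = FALSE)
      }
      suppressWarnings(
        relative_invader_growth(f$n0, f$n1, r$n0, r$n1, t = f$t,
                                detection_limit = detection_limit))
    }, numeric(1))
    n_undef <- sum(!is.finite(ratios))
    if (n_undef > 0) {
      warning("treatment ", focal, " vs ", tr$residents[1], ": ", n_undef,
              " replicate(s) with undefined ratio excluded", call. = FALSE)
    }
    ht <- test_invasion(ratios[is.finite(ratios)])
    data.frame(focal = focal, residents = tr$residents[1],
               diversity = length(split_composition(tr$residents[1])),
               n = ht$n, mean_ratio = ht$mean, t = ht$t, df = ht$df, p = ht$p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out <- out[order(out$focal, out$diversity, out$residents), ]
  out$p_adj <- adjust_fdr(out$p)
  out$invades <- !is.na(out$p_adj) & out$p_adj < alpha & out$mean_ratio > 1
  rownames(out) <- NULL
  out
}

#' Summarise an invasion analysis
#'
#' Coexistence summary over per-treatment invasion statistics: how many
#' treatments show significant invasion from rare (mean ratio above 1
#' and adjusted p below `alpha`), the range of mean relative invader
#' growth rates, and a per-diversity-level breakdown.
#'
#' @param stats Per-treatment data frame from [invasion_stats()] (one
#'   row per treatment).
#' @param alpha Significance level (default 0.05).
#' @return List with `n_treatments`, `n_invading`, `fraction_invading`,
#'   `min_mean_ratio`, `max_mean_ratio` and `by_diversity`.
#' @export
summarize_invasion <- function(stats, alpha = 0.05) {
  if (is.null(stats) || nrow(stats) == 0) {
    stop("no invasion statistics supplied", call. = FALSE)
  }
  if (anyDuplicated(stats[, c("focal", "residents")])) {
    stop("duplicate treatments in invasion statistics", call. = FALSE)
  }
  invades <- !is.na(stats$p_adj) & stats$p_adj < alpha & stats$mean_ratio > 1
  by_div <- aggregate(invades, list(diversity = stats$diversity),
                      function(x) c(n = length(x), invading = sum(x)))
  by_div <- data.frame(diversity = by_div$diversity,
                       n = by_div$x[, "n"], invading = by_div$x[, "invading"])
  list(n_treatments = nrow(stats),
       n_invading = sum(invades),
       fraction_invading = mean(invades),
       min_mean_ratio = min(stats$mean_ratio),
       max_mean_ratio = max(stats$mean_ratio),
       by_diversity = by_div)
}
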