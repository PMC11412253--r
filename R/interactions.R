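#' Pairwise interaction from co-culture
#'
#' The effect of a partner species on a focal species, `w_focal|partner`:
#' the focal's abundance in pair culture relative to its abundance in
#' monoculture. Per replicate and week, the pair-culture density is
#' divided by the week-matched monoculture mean; `w` is the mean of
#' those ratios over the analysis weeks (~9 replicate ratios at 3
#' replicates x 3 weeks). `w > 1` indicates facilitation, `w < 1`
#' competition, and `w = 0` competitive exclusion. Week-1 records are
#' excluded because cultures have not yet equilibrated.
#'
#' @param records Long-format persistence table with columns
#'   `composition`, `species`, `week`, `replicate`, `density`.
#' @param focal,partner Species labels.
#' @param weeks Weeks to include (default 2:4).
#' @return One-row data frame: `focal`, `partner`, `w`, `n`.
#' @export
pairwise_w <- function(records, focal, partner, weeks = 2:4) {
  ratios <- w_ratios(records, focal, c(focal, partner), weeks)
  data.frame(focal = focal, partner = partner, w = mean(ratios),
             n = length(ratios), stringsAsFactors = FALSE)
}

# per-replicate ratios of focal density in `members` culture to the
# week-matched monoculture mean of the focal
w_ratios <- function(records, focal, members, weeks) {
  needed <- c("composition", "species", "week", "replicate", "density")
  if (!all(needed %in% names(records))) {
    stop("persistence table must have columns: ",
         paste(needed, collapse = ", "), call. = FALSE)
  }
  mono <- records[records$composition == focal & records$species == focal &
                    records$week %in% weeks, ]
  if (nrow(mono) == 0) {
    stop("no monoculture reference for ", focal, call. = FALSE)
  }
  mono_mean <- tapply(mono$density, mono$week, mean)
  if (any(mono_mean == 0)) {
    stop("monoculture mean density of ", focal, " is zero", call. = FALSE)
  }
  id <- composition_id(members)
  cc <- records[records$composition == id & records$species == focal &
                  records$week %in% weeks, ]
  if (nrow(cc) == 0) {
    stop("no records for ", focal, " in composition ", id, call. = FALSE)
  }
  ref <- mono_mean[as.character(cc$week)]
  if (anyNA(ref)) stop("monoculture reference missing for some weeks",
                       call. = FALSE)
  unname(cc$density / ref)
}

#' All directed pairwise interactions
#'
#' [pairwise_w()] for every ordered species pair in the pool (20
#' estimates for five species).
#'
#' @inheritParams pairwise_w
#' @param pool Species labels (default: all species in `records`).
#' @return Data frame with columns `focal`, `partner`, `w`, `n`.
#' @export
pairwise_matrix <- function(records, pool = NULL, weeks = 2:4) {
  if (is.null(pool)) pool <- sort(unique(records$species))
  pairs <- enumerate_ordered_pairs(pool)
  out <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(i) {
    pairwise_w(records, pairs$focal[i], pairs$partner[i], weeks)
  }))
  rownames(out) <- NULL
  out
}

#' Multiplicative prediction from pairwise interactions
#'
#' The predicted joint effect of a partner set on the focal species
#' under purely pairwise (multiplicative) composition:
#' `w_hat = prod_j w_focal|j`.
#'
#' @param pairwise Data frame of pairwise estimates (`focal`, `partner`,
#'   `w`), e.g. from [pairwise_matrix()].
#' @param focal Focal species label.
#' @param partners Character vector of partner labels.
#' @return Single numeric predicted `w`.
#' @export
predicted_w <- function(pairwise, focal, partners) {
  if (length(partners) == 0) stop("partners must be nonempty", call. = FALSE)
  w <- vapply(partners, function(p) {
    row <- pairwise[pairwise$focal == focal & pairwise$partner == p, "w"]
    if (length(row) != 1) {
      stop("missing pairwise estimate for ", focal, " | ", p, call. = FALSE)
    }
    row
  }, numeric(1))
  prod(w)
}

#' Classify an indirect (higher-order) interaction
#'
#' Compares the observed multi-species effect on a focal species,
#' `w_obs`, with the multiplicative pairwise prediction `w_pred`. The
#' deviation is `d = w_obs - w_pred`. When the deviation pushes the
#' effect further from neutrality in the predicted direction
#' (`sign(d) == sign(w_pred - 1)`) the interaction is synergistic; when
#' it pulls back toward neutrality it is buffering; `d = 0` is additive.
#' The sign-adjusted statistic `ii_adj` flips the deviation for
#' predicted-negative interactions (`w_pred < 1`) so that synergistic
#' values are always positive and buffering values negative. A neutral
#' prediction (`w_pred = 1`) with a nonzero deviation has no defined
#' direction and is flagged indeterminate.
#'
#' @param w_obs Observed `w` (>= 0), vectorised.
#' @param w_pred Predicted `w` (>= 0), vectorised.
#' @return Data frame with columns `w_obs`, `w_pred`, `deviation`,
#'   `prediction_dir` (`"negative"`, `"positive"`, `"neutral"`),
#'   `class` (`"synergistic"`, `"buffering"`, `"additive"`,
#'   `"indeterminate"`) and `ii_adj`.
#' @export
#' @examples
#' indirect_interaction(w_obs = 0.10, w_pred = 0.25) # synergistic, +0.15
indirect_interaction <- function(w_obs, w_pred) {
  if (any(w_obs < 0) || any(w_pred < 0)) {
    stop("w values must be >= 0", call. = FALSE)
  }
  k <- max(length(w_obs), length(w_pred))
  w_obs <- rep_len(w_obs, k)
  w_pred <- rep_len(w_pred, k)
  d <- w_obs - w_pred
  dir <- ifelse(w_pred < 1, "negative", ifelse(w_pred > 1, "positive", "neutral"))
  cls <- ifelse(d == 0, "additive",
         ifelse(dir == "neutral", "indeterminate",
         ifelse(sign(d) == sign(w_pred - 1), "synergistic", "buffering")))
  ii_adj <- ifelse(w_pred < 1, -d, d)
  ii_adj[cls == "indeterminate"] <- NA_real_
  data.frame(w_obs = w_obs, w_pred = w_pred, deviation = d,
             prediction_dir = dir, class = cls, ii_adj = ii_adj,
             stringsAsFactors = FALSE)
}

#' Indirect interactions for every multi-species combination
#'
#' For each focal-by-partners combination with at least two partners
#' (55 for five species), computes the observed effect `w_obs` from the
#' persistence records, the multiplicative pairwise prediction `w_pred`,
#' and the classified indirect interaction. Predictions always use the
#' pairwise estimates only (no recursive rescaling at higher diversity).
#'
#' @inheritParams pairwise_matrix
#' @param pairwise Optional precomputed [pairwise_matrix()]; computed
#'   from `records` when `NULL`.
#' @return Data frame with one row per combination: `focal`, `partners`,
#'   `diversity`, `w_obs`, `w_pred`, `deviation`, `prediction_dir`,
#'   `class`, `ii_adj`.
#' @export
indirect_table <- function(records, pool = NULL, weeks = 2:4, pairwise = NULL) {
  if (is.null(pool)) pool <- sort(unique(records$species))
  if (is.null(pairwise)) pairwise <- pairwise_matrix(records, pool, weeks)
  design <- enumerate_indirect_design(pool)
  rows <- lapply(seq_len(nrow(design)), function(i) {
    focal <- design$focal[i]
    partners <- split_composition(design$partners[i])
    w_obs <- mean(w_ratios(records, focal, c(focal, partners), weeks))
    w_pred <- predicted_w(pairwise, focal, partners)
    cbind(data.frame(focal = focal, partners = design$partners[i],
                     diversity = design$diversity[i], stringsAsFactors = FALSE),
          indirect_interaction(w_obs, w_pred))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Interaction strength vs indirect-interaction type
#'
#' One-way ANOVA asking whether the strength of the expected pairwise
#' interaction (`w_pred`, the response) differs between synergistic and
#' buffering indirect interactions, restricted to predicted-negative
#' interactions (`w_pred < 1`), where both classes are well populated.
#'
#' @param indirects Data frame from [indirect_table()] (or with columns
#'   `w_pred`, `prediction_dir`, `class`).
#' @return List with `F`, `df1`, `df2`, `p` and the fitted group means.
#' @export
interaction_strength_anova <- function(indirects) {
  d <- indirects[indirects$prediction_dir == "negative" &
                   indirects$class %in% c("synergistic", "buffering"), ]
  counts <- table(factor(d$class, levels = c("buffering", "synergistic")))
  if (any(counts < 2)) {
    stop("need at least two observations in each class ",
         "(buffering, synergistic); got ",
         paste(counts, collapse = " and "), call. = FALSE)
  }
  fit <- lm(w_pred ~ class, data = d)
  tab <- anova(fit)
  list(F = tab$`F value`[1], df1 = tab$Df[1], df2 = tab$Df[2],
       p = tab$`Pr(>F)`[1],
       group_means = tapply(d$w_pred, d$class, mean))
}

#' Supernatant growth rate
#'
#' Per-day growth rate in the spent-media assay, `ln(N1/N0) / t` with
#' `t = 2` days. A negative rate is floored at 0.001 (flagged in the
#' `"floored"` attribute) so that downstream relative-growth ratios stay
#' positive.
#'
#' @param n0 Starting density (> 0), cfu/mL.
#' @param n1 Final density (> 0), cfu/mL.
#' @param t Assay duration in days (default 2).
#' @param floor Replacement for negative rates (default 0.001).
#' @return Numeric vector of growth rates with a logical `"floored"`
#'   attribute.
#' @export
supernatant_growth <- function(n0, n1, t = 2, floor = 0.001) {
  if (any(!is.finite(n0)) || any(n0 <= 0)) {
    stop("starting density n0 must be positive", call. = FALSE)
  }
  g <- log(n1 / n0) / t
  floored <- g < 0
  g[floored] <- floor
  structure(g, floored = floored)
}

#' Relative supernatant growth
#'
#' Growth rate in a supernatant divided by the growth rate in fresh
#' medium: above 1 the supernatant promotes growth, below 1 it inhibits.
#' A non-positive fresh-media rate leaves the ratio undefined (`NA`,
#' with a warning).
#'
#' @param g_sup Growth rate in supernatant (day^-1).
#' @param g_fresh Growth rate in fresh medium (day^-1).
#' @return Numeric vector of relative growth values.
#' @export
relative_supernatant_growth <- function(g_sup, g_fresh) {
  k <- max(length(g_sup), length(g_fresh))
  g_sup <- rep_len(as.numeric(g_sup), k)
  g_fresh <- rep_len(as.numeric(g_fresh), k)
  out <- ifelse(g_fresh > 0, g_sup / g_fresh, NA_real_)
  if (anyNA(out)) {
    warning("fresh-media growth rate <= 0; relative growth undefined",
            call. = FALSE)
  }
  out
}

#' Relative growth table from a supernatant assay
#'
#' Turns the long-format supernatant table into one relative-growth
#' value per focal-source combination: technical replicates are
#' collapsed by median, growth rates are computed (negative rates
#' floored), and each source's rate is divided by the focal's
#' fresh-media rate.
#'
#' @param supernatant Data frame with columns `focal`, `source`,
#'   `replicate`, `n0`, `n1`, `t` (source `"fresh"` is the baseline).
#' @return Data frame with columns `focal`, `source`, `value`, `kind`
#'   (`"intraspecific"` when source == focal, else `"interspecific"`).
#' @export
supernatant_relative_growth <- function(supernatant) {
  needed <- c("focal", "source", "replicate", "n0", "n1", "t")
  if (!all(needed %in% names(supernatant))) {
    stop("supernatant table must have columns: ",
         paste(needed, collapse = ", "), call. = FALSE)
  }
  rows <- list()
  for (f in unique(supernatant$focal)) {
    sub <- supernatant[supernatant$focal == f, ]
    g_by_source <- vapply(split(sub, sub$source), function(d) {
      median(as.numeric(supernatant_growth(d$n0, d$n1, d$t[1])))
    }, numeric(1))
    if (!"fresh" %in% names(g_by_source)) {
      stop("no fresh-media baseline for ", f, call. = FALSE)
    }
    src <- setdiff(names(g_by_source), "fresh")
    rows[[f]] <- data.frame(
      focal = f, source = src,
      value = relative_supernatant_growth(g_by_source[src],
                                          g_by_source[["fresh"]]),
      kind = ifelse(src == f, "intraspecific", "interspecific"),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Intraspecific vs interspecific supernatant effects
#'
#' Per focal species, compares growth in its own supernatant
#' (intraspecific competition) with the mean growth across other
#' species' supernatants (interspecific), with a 95% t-based confidence
#' interval on the interspecific mean. Coexistence is expected when
#' intraspecific competition is the stronger of the two (ratio below 1).
#'
#' @param values Data frame from [supernatant_relative_growth()].
#' @return Data frame with one row per focal species: `intra`,
#'   `inter_mean`, `inter_ci_low`, `inter_ci_high`, `n_inter`, `ratio`
#'   (intra / inter mean). CI columns are `NA` when only one
#'   interspecific value exists.
#' @export
summarize_intra_vs_inter <- function(values) {
  rows <- lapply(split(values, values$focal), function(d) {
    intra <- d$value[d$kind == "intraspecific"]
    if (length(intra) != 1) {
      stop("need exactly one intraspecific value per focal species",
           call. = FALSE)
    }
    inter <- d$value[d$kind == "interspecific"]
    if (length(inter) == 0) {
      stop("need at least one interspecific value per focal species",
           call. = FALSE)
    }
    m <- mean(inter)
    if (length(inter) >= 2) {
      half <- qt(0.975, length(inter) - 1) * sd(inter) / sqrt(length(inter))
      ci <- c(m - half, m + half)
    } else {
      ci <- c(NA_real_, NA_real_)
    }
    data.frame(focal = d$focal[1], intra = intra, inter_mean = m,
               inter_ci_low = ci[1], inter_ci_high = ci[2],
               n_inter = length(inter), ratio = intra / m,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
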