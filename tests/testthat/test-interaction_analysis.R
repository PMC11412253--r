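# small handmade persistence table: monoculture of "f" plus co-cultures
persist_fixture <- function() {
  rbind(
    # monoculture of f, week 2: mean 8e5
    data.frame(composition = "f", species = "f", week = 2,
               replicate = 1:3, density = c(7e5, 8e5, 9e5)),
    # pair culture f+g, week 2
    data.frame(composition = "f;g", species = "f", week = 2,
               replicate = 1:3, density = c(2e5, 4e5, 6e5)),
    data.frame(composition = "f;g", species = "g", week = 2,
               replicate = 1:3, density = c(1e6, 1e6, 1e6)),
    # pair culture f+h: f excluded
    data.frame(composition = "f;h", species = "f", week = 2,
               replicate = 1:3, density = c(0, 0, 0)),
    data.frame(composition = "f;h", species = "h", week = 2,
               replicate = 1:3, density = c(2e6, 2e6, 2e6)),
    # triple culture
    data.frame(composition = "f;g;h", species = "f", week = 2,
               replicate = 1:3, density = c(1e5, 1e5, 1e5))
  )
}

test_that("pairwise w is the mean per-replicate ratio to the week-matched monoculture", {
  rec <- persist_fixture()
  pw <- pairwise_w(rec, "f", "g", weeks = 2)
  expect_equal(pw$w, mean(c(2e5, 4e5, 6e5) / 8e5)) # 0.5
  expect_equal(pw$n, 3)
  # competitive exclusion scores exactly zero
  expect_equal(pairwise_w(rec, "f", "h", weeks = 2)$w, 0)
  # equal densities give w = 1
  same <- rec
  same$density[same$composition == "f;g" & same$species == "f"] <- 8e5
  expect_equal(pairwise_w(same, "f", "g", weeks = 2)$w, 1)
})

test_that("pairwise w is invariant to rescaling all densities", {
  rec <- persist_fixture()
  scaled <- rec
  scaled$density <- scaled$density * 37.5
  expect_equal(pairwise_w(scaled, "f", "g", weeks = 2)$w,
               pairwise_w(rec, "f", "g", weeks = 2)$w)
})

test_that("missing or empty monoculture reference is an error", {
  rec <- persist_fixture()
  expect_error(pairwise_w(rec, "g", "f", weeks = 2), "monoculture")
  zero <- rec
  zero$density[zero$composition == "f"] <- 0
  expect_error(pairwise_w(zero, "f", "g", weeks = 2), "zero")
})

test_that("multiplicative prediction is the product of pairwise estimates", {
  pw <- data.frame(focal = "f", partner = c("g", "h", "k"),
                   w = c(0.5, 0.5, 0))
  expect_equal(predicted_w(pw, "f", "g"), 0.5)
  expect_equal(predicted_w(pw, "f", c("g", "h")), 0.25)
  expect_equal(predicted_w(pw, "f", c("g", "h", "k")), 0)
  expect_error(predicted_w(pw, "f", c("g", "zz")), "missing pairwise")
  expect_error(predicted_w(pw, "f", character(0)), "nonempty")
})

test_that("prediction is permutation-invariant and multiplicative over disjoint sets", {
  set.seed(4)
  pool <- paste0("p", 1:6)
  pw <- data.frame(focal = "f", partner = pool, w = runif(6, 0, 2))
  for (i in 1:20) {
    k <- sample(2:6, 1)
    s <- sample(pool, k)
    expect_equal(predicted_w(pw, "f", s), predicted_w(pw, "f", rev(s)))
    if (k >= 4) {
      cut <- sample(1:(k - 1), 1)
      expect_equal(predicted_w(pw, "f", s),
                   predicted_w(pw, "f", s[1:cut]) *
                     predicted_w(pw, "f", s[-(1:cut)]))
    }
  }
})

test_that("indirect interactions classify by the resolved sign convention", {
  expect_equal(indirect_interaction(0.25, 0.25)$class, "additive")
  expect_equal(indirect_interaction(0.25, 0.25)$ii_adj, 0)

  syn_neg <- indirect_interaction(w_obs = 0.10, w_pred = 0.25)
  expect_equal(syn_neg$class, "synergistic")
  expect_equal(syn_neg$ii_adj, 0.15)

  buf_neg <- indirect_interaction(w_obs = 0.60, w_pred = 0.25)
  expect_equal(buf_neg$class, "buffering")
  expect_equal(buf_neg$ii_adj, -0.35)

  syn_pos <- indirect_interaction(w_obs = 2.0, w_pred = 1.5)
  expect_equal(syn_pos$class, "synergistic")
  expect_equal(syn_pos$ii_adj, 0.5)

  buf_pos <- indirect_interaction(w_obs = 1.1, w_pred = 1.5)
  expect_equal(buf_pos$class, "buffering")
  expect_equal(buf_pos$ii_adj, -0.4)

  neut <- indirect_interaction(w_obs = 1.3, w_pred = 1)
  expect_equal(neut$class, "indeterminate")
  expect_true(is.na(neut$ii_adj))
  expect_equal(indirect_interaction(1, 1)$class, "additive")

  expect_error(indirect_interaction(-0.1, 0.5), ">= 0")
})

test_that("every grid point gets exactly one class with matching ii_adj sign", {
  grid <- expand.grid(w_pred = seq(0.05, 2, by = 0.05),
                      w_obs = seq(0.05, 2, by = 0.05))
  res <- indirect_interaction(grid$w_obs, grid$w_pred)
  expect_true(all(res$class %in% c("synergistic", "buffering", "additive",
                                   "indeterminate")))
  # independent sign-case table: synergism = deviation away from 1 in the
  # predicted direction
  expected <- ifelse(res$w_obs == res$w_pred, "additive",
              ifelse(res$w_pred == 1, "indeterminate",
              ifelse(res$w_pred < 1,
                     ifelse(res$w_obs < res$w_pred, "synergistic", "buffering"),
                     ifelse(res$w_obs > res$w_pred, "synergistic", "buffering"))))
  expect_equal(res$class, expected)
  defined <- res$class %in% c("synergistic", "buffering")
  expect_true(all(res$ii_adj[res$class == "synergistic"] > 0))
  expect_true(all(res$ii_adj[res$class == "buffering"] < 0))
  expect_true(all(res$ii_adj[res$class == "additive"] == 0))
  expect_equal(res$ii_adj[res$class == "additive"],
               rep(0, sum(res$class == "additive")))
  # deviation magnitude is preserved by the sign flip
  expect_equal(abs(res$ii_adj[defined]), abs(res$deviation[defined]))
})

test_that("indirect table covers the full design with pairwise-only predictions", {
  rec <- persist_fixture()
  # add monocultures for g, h and the remaining pair so predictions exist
  rec <- rbind(rec,
    data.frame(composition = "g", species = "g", week = 2,
               replicate = 1:3, density = 1.2e6),
    data.frame(composition = "h", species = "h", week = 2,
               replicate = 1:3, density = 2.5e6),
    data.frame(composition = "f;g", species = "g", week = 2,
               replicate = 1:3, density = 1.2e6),
    data.frame(composition = "f;h", species = "h", week = 2,
               replicate = 1:3, density = 2.5e6),
    data.frame(composition = "g;h", species = c("g", "h"), week = 2,
               replicate = rep(1:3, each = 2), density = rep(c(1.2e6, 2.5e6), 3)),
    data.frame(composition = "f;g;h", species = c("g", "h"), week = 2,
               replicate = rep(1:3, each = 2), density = rep(c(1.2e6, 2.5e6), 3))
  )
  ind <- indirect_table(rec, pool = c("f", "g", "h"), weeks = 2)
  expect_equal(nrow(ind), 3)
  frow <- ind[ind$focal == "f", ]
  # w_f|g = 0.5, w_f|h = 0 -> prediction 0; observed 1e5/8e5 = 0.125
  expect_equal(frow$w_pred, 0)
  expect_equal(frow$w_obs, 0.125)
  expect_equal(frow$class, "buffering")
})

test_that("interaction-strength ANOVA matches the hand-computed F", {
  ind <- data.frame(
    w_pred = c(0.2, 0.3, 0.6, 0.7),
    prediction_dir = "negative",
    class = c("synergistic", "synergistic", "buffering", "buffering"))
  out <- interaction_strength_anova(ind)
  # between-SS 0.16, within-SS 0.01 on (1, 2) df -> F = 32
  expect_equal(out$F, 32)
  expect_equal(c(out$df1, out$df2), c(1, 2))

  equal_means <- data.frame(w_pred = c(0.2, 0.4, 0.2, 0.4),
                            prediction_dir = "negative",
                            class = rep(c("synergistic", "buffering"), each = 2))
  eq <- interaction_strength_anova(equal_means)
  expect_equal(eq$F, 0)
  expect_equal(eq$p, 1)

  one_class <- data.frame(w_pred = c(0.2, 0.3), prediction_dir = "negative",
                          class = "synergistic")
  expect_error(interaction_strength_anova(one_class), "each class")
})

test_that("supernatant growth rate floors negative values at 0.001", {
  g <- supernatant_growth(1e5, 1e5 * exp(2))
  expect_equal(as.numeric(g), 1)
  expect_false(attr(g, "floored"))

  dec <- supernatant_growth(1e5, 5e4)
  expect_equal(as.numeric(dec), 0.001)
  expect_true(attr(dec, "floored"))

  flat <- supernatant_growth(1e5, 1e5)
  expect_equal(as.numeric(flat), 0) # zero is not negative: no floor
  expect_false(attr(flat, "floored"))

  expect_error(supernatant_growth(0, 1e5), "positive")
})

test_that("relative supernatant growth divides by the fresh-media rate", {
  expect_equal(relative_supernatant_growth(1, 1), 1)
  expect_equal(relative_supernatant_growth(0.5, 1), 0.5)
  expect_warning(out <- relative_supernatant_growth(0.5, 0), "undefined")
  expect_true(is.na(out))
})

test_that("supernatant table collapses technical replicates by median", {
  sup <- rbind(
    data.frame(focal = "f", source = "fresh", replicate = 1:3,
               n0 = 1e5, n1 = 1e5 * exp(2 * c(0.9, 1.0, 1.4)), t = 2),
    data.frame(focal = "f", source = "f", replicate = 1:3,
               n0 = 1e5, n1 = 1e5 * exp(2 * c(0.1, 0.2, 0.3)), t = 2),
    data.frame(focal = "f", source = "g", replicate = 1:3,
               n0 = 1e5, n1 = 1e5 * exp(2 * c(0.5, 0.6, 2.0)), t = 2))
  rel <- supernatant_relative_growth(sup)
  expect_equal(nrow(rel), 2)
  expect_equal(rel$value[rel$source == "f"], 0.2 / 1.0)
  expect_equal(rel$value[rel$source == "g"], 0.6 / 1.0)
  expect_equal(rel$kind[rel$source == "f"], "intraspecific")
})

test_that("intra vs inter summary gives the t-based confidence interval", {
  vals <- data.frame(
    focal = "f",
    source = c("f", "a", "b", "c", "d"),
    value = c(0.5, 0.8, 1.0, 1.2, 1.0),
    kind = c("intraspecific", rep("interspecific", 4)))
  s <- summarize_intra_vs_inter(vals)
  expect_equal(s$inter_mean, 1)
  half <- qt(0.975, 3) * sd(c(0.8, 1.0, 1.2, 1.0)) / 2
  expect_equal(s$inter_ci_high - s$inter_mean, half)
  expect_equal(round(half, 2), 0.26)
  expect_equal(s$ratio, 0.5)

  one <- vals[1:2, ]
  s1 <- summarize_intra_vs_inter(one)
  expect_true(is.na(s1$inter_ci_low))

  all_equal <- vals; all_equal$value <- 1
  expect_equal(summarize_intra_vs_inter(all_equal)$ratio, 1)

  expect_error(summarize_intra_vs_inter(vals[-1, ]), "intraspecific")
})
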