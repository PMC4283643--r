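# independent brute-force sums-of-squares oracle for the one-way
# within-subject decomposition (scalar loops, no matrix shortcuts)
one_way_oracle_F <- function(y) {
  n <- nrow(y); k <- ncol(y)
  grand <- mean(y)
  ss_total <- 0; ss_subj <- 0; ss_reg <- 0
  for (i in 1:n) ss_subj <- ss_subj + k * (mean(y[i, ]) - grand)^2
  for (j in 1:k) ss_reg <- ss_reg + n * (mean(y[, j]) - grand)^2
  for (i in 1:n) for (j in 1:k) ss_total <- ss_total + (y[i, j] - grand)^2
  ss_err <- ss_total - ss_subj - ss_reg
  (ss_reg / (k - 1)) / (ss_err / ((k - 1) * (n - 1)))
}

test_that("one-way RM-ANOVA matches oracles and degenerate cases", {
  # identical values across regions: no region effect at all
  flat <- matrix(rep(c(1, 5, 2, 9), 3), nrow = 4)
  r <- one_way_rm_anova(rm_design(flat))
  expect_equal(r$table$F, 0)
  expect_equal(r$table$p, 1)

  # df formula
  d21 <- rm_design(matrix(rnorm(11 * 21), 11, 21))
  r21 <- one_way_rm_anova(d21)
  expect_equal(r21$table$df_num, 20L)
  expect_equal(r21$table$df_den, 200L)

  set.seed(14)
  for (rep in 1:20) {
    y <- matrix(rnorm(20), 5, 4)
    mine <- one_way_rm_anova(rm_design(y))$table$F
    expect_equal(mine, one_way_oracle_F(y), tolerance = 1e-9)
    # cross-check against stats::aov as a second, independent route
    df <- data.frame(y = as.vector(y), s = factor(rep(1:5, 4)),
                     r = factor(rep(1:4, each = 5)))
    aovF <- summary(stats::aov(y ~ r + Error(s), data = df))[[
      "Error: Within"]][[1]]["r", "F value"]
    expect_equal(mine, aovF, tolerance = 1e-9)
  }

  expect_error(rm_design(matrix(1:4, 1, 4)), "subjects")
  expect_error(rm_design(matrix(1:4, 4, 1)), "levels")
  expect_error(rm_design(matrix(c(1, NA, 3, 4), 2, 2)), "missing")
})

test_that("ANOVA decomposition and F are invariant the way they must be", {
  set.seed(15)
  y <- matrix(rnorm(7 * 5), 7, 5)
  r <- one_way_rm_anova(rm_design(y))
  expect_equal(r$ss[["total"]],
               r$ss[["subject"]] + r$ss[["region"]] + r$ss[["error"]],
               tolerance = 1e-9)
  # shift and scale invariance of F
  r_shift <- one_way_rm_anova(rm_design(y + 100))
  expect_equal(r_shift$table$F, r$table$F, tolerance = 1e-9)
  r_scale <- one_way_rm_anova(rm_design(y * 3))
  expect_equal(r_scale$table$F, r$table$F, tolerance = 1e-9)

  g <- rep(c("m", "l"), c(4, 3))
  r2 <- two_way_rm_anova(rm_design(y, g))
  expect_equal(r2$ss[["total"]],
               sum(r2$ss[c("group", "subj_within_group", "region",
                           "interaction", "error_within")]),
               tolerance = 1e-9)
})

test_that("split-plot two-way RM-ANOVA reproduces printed designs and aov", {
  set.seed(16)
  # 21 regions x 9 subjects in 2 groups -> interaction df (20, 140)
  y <- matrix(rnorm(9 * 21), 9, 21)
  g <- rep(c("medial", "lateral"), c(4, 5))
  r <- two_way_rm_anova(rm_design(y, g))
  inter <- r$table[r$table$effect == "group:region", ]
  expect_equal(inter$df_num, 20L)
  expect_equal(inter$df_den, 140L)

  # 25 within levels x 9 rats x 2 groups -> (24, 168)
  y25 <- matrix(rnorm(9 * 25), 9, 25)
  r25 <- two_way_rm_anova(rm_design(y25, g))
  inter25 <- r25$table[r25$table$effect == "group:region", ]
  expect_equal(inter25$df_num, 24L)
  expect_equal(inter25$df_den, 168L)

  # identical data in both groups: zero interaction and group effects
  same <- matrix(rnorm(4 * 6), 4, 6)
  y_same <- rbind(same, same)
  r_same <- two_way_rm_anova(rm_design(y_same, rep(c("a", "b"), each = 4)))
  expect_lt(r_same$table$F[r_same$table$effect == "group"], 1e-18)
  expect_lt(r_same$table$F[r_same$table$effect == "group:region"], 1e-18)

  # full agreement with stats::aov on random unbalanced designs
  for (rep in 1:10) {
    yy <- matrix(rnorm(9 * 5), 9, 5)
    gg <- rep(c("a", "b"), c(4, 5))
    mine <- two_way_rm_anova(rm_design(yy, gg))$table
    df <- data.frame(y = as.vector(yy), s = factor(rep(1:9, 5)),
                     r = factor(rep(1:5, each = 9)), g = factor(rep(gg, 5)))
    sm <- summary(stats::aov(y ~ g * r + Error(s), data = df))
    aov_between <- sm[["Error: s"]][[1]]
    aov_within <- sm[["Error: Within"]][[1]]
    expect_equal(mine$F[mine$effect == "group"],
                 aov_between["g", "F value"], tolerance = 1e-9)
    expect_equal(mine$F[mine$effect == "region"],
                 aov_within["r", "F value"], tolerance = 1e-9)
    expect_equal(mine$F[mine$effect == "group:region"],
                 aov_within["g:r", "F value"], tolerance = 1e-9)
  }

  expect_error(rm_design(y, rep(c("a", "b", "c"), c(1, 4, 4))), "2 subjects")
})

test_that("two-way interaction test holds its nominal type-I error", {
  set.seed(17)
  nrep <- 2000
  rejections <- 0
  for (i in seq_len(nrep)) {
    y <- matrix(rnorm(8 * 4), 8, 4)   # pure null: no group or region effect
    p <- two_way_rm_anova(rm_design(y, rep(c("a", "b"), each = 4)))$table
    if (p$p[p$effect == "group:region"] < 0.05) rejections <- rejections + 1
  }
  rate <- rejections / nrep
  ci <- 0.05 + c(-1, 1) * 1.96 * sqrt(0.05 * 0.95 / nrep)
  expect_gte(rate, ci[1])
  expect_lte(rate, ci[2])
})

test_that("Bonferroni post-hoc multiplies by the family size and caps at 1", {
  set.seed(18)
  y <- matrix(rnorm(10 * 4), 10, 4)
  y[, 1] <- y[, 1] + 3        # one clearly separated level
  d <- rm_design(y)
  ph <- bonferroni_posthoc(d, pairs = list(c(1, 2), c(1, 3), c(2, 3)))
  expect_equal(nrow(ph), 3)
  expect_equal(ph$p_adj, pmin(1, ph$p_raw * 3), tolerance = 1e-12)
  expect_true(all(ph$p_adj <= 1))
  # raw p 0.5-ish pairs cap at 1.0
  expect_true(any(ph$p_adj == 1) || all(ph$p_raw < 1 / 3))
  # adjusted p monotone in raw p within the family
  ord <- order(ph$p_raw)
  expect_true(!is.unsorted(ph$p_adj[ord]))
  # flags consistent with alpha
  expect_equal(ph$significant, ph$p_adj < d$alpha)

  all_pairs <- bonferroni_posthoc(d, "all")
  expect_equal(nrow(all_pairs), choose(4, 2))
  # paired t oracle for one pair
  tt <- t.test(y[, 1], y[, 2], paired = TRUE)
  expect_equal(all_pairs$p_raw[all_pairs$level_a == "L01" &
                                 all_pairs$level_b == "L02"],
               tt$p.value, tolerance = 1e-12)

  expect_error(bonferroni_posthoc(d, list()), "empty")
  expect_error(bonferroni_posthoc(d, list(c("L01", "nope"))), "unknown")
})

test_that("Greenhouse-Geisser correction is available but off by default", {
  set.seed(19)
  y <- matrix(rnorm(8 * 5), 8, 5)
  plain <- one_way_rm_anova(rm_design(y))
  gg <- one_way_rm_anova(rm_design(y), gg = TRUE)
  expect_false("gg_epsilon" %in% names(plain$table))
  eps <- gg$table$gg_epsilon
  expect_true(eps <= 1 && eps >= 1 / 4)
  expect_equal(gg$table$p,
               pf(gg$table$F, eps * plain$table$df_num,
                  eps * plain$table$df_den, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_equal(gg$table$F, plain$table$F) # F itself unchanged
})
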