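test_that("raw-data ANOVA agrees with brute-force sums of squares and summaries", {
  set.seed(11)
  for (rep in 1:20) {
    n <- sample(3:40, 3)
    g <- rep(c("HC", "MDD", "SCZ"), n)
    y <- stats::rnorm(sum(n), mean = rep(stats::rnorm(3), n))
    a <- anova_oneway(y, g)
    br <- anova_brute(y, g)
    expect_equal(a$F, br$F, tolerance = 1e-9)
    expect_equal(a$p, br$p, tolerance = 1e-9)
    # exact refactoring: summary path on the data's own summaries
    s <- anova_from_summary(tapply(y, g, mean), tapply(y, g, stats::sd),
                            as.vector(table(g)))
    expect_equal(a$F, s$F, tolerance = 1e-9)
    expect_equal(a$df1, s$df1)
    expect_equal(a$df2, s$df2)
  }
  # identical groups give F = 0
  y0 <- rep(c(1, 2, 3), times = 3)
  g0 <- rep(c("a", "b", "c"), each = 3)
  expect_equal(anova_oneway(rep(1, 9), g0)$F, 0)
  expect_equal(anova_from_summary(c(5, 5, 5), c(1, 1, 1), c(8, 8, 8))$F, 0)
  expect_error(anova_oneway(c(1, 2, 3), c("a", "a", "b")), "at least 2")
  expect_error(anova_from_summary(c(1, 2), c(1, 1), c(1, 1)), ">= 2")
})

test_that("ANOVA degrees of freedom are (2, N - 3) for three groups", {
  set.seed(2)
  n <- c(50, 49, 24)
  a <- anova_oneway(stats::rnorm(sum(n)), rep(letters[1:3], n))
  expect_equal(a$df1, 2)
  expect_equal(a$df2, 120)
})

test_that("BH adjustment matches the literal step-up and p.adjust", {
  expect_equal(fdr_bh(0.37), 0.37)
  expect_equal(fdr_bh(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(fdr_bh(rep(0.2, 5)), rep(0.2, 5))
  expect_error(fdr_bh(c(0.1, 1.2)), "\\[0, 1\\]")
  set.seed(4)
  for (rep in 1:50) {
    p <- stats::runif(sample(1:20, 1))
    q <- fdr_bh(p)
    expect_identical(q, bh_brute(p))
    expect_equal(q, stats::p.adjust(p, "BH"), tolerance = 1e-12)
    expect_true(all(q >= p))
  }
})

test_that("Tukey HSD matches base TukeyHSD and respects its gate", {
  set.seed(5)
  y <- stats::rnorm(60, rep(c(0, 0.5, 2), each = 20))
  g <- rep(c("HC", "MDD", "SCZ"), each = 20)
  th <- tukey_hsd(y, g, fdr_across_pairs = FALSE)
  ref <- stats::TukeyHSD(stats::aov(y ~ factor(g)))$`factor(g)`
  expect_equal(th$diff, unname(ref[, "diff"]), tolerance = 1e-9)
  expect_equal(th$p_tukey, unname(ref[, "p adj"]), tolerance = 1e-7)

  # identical groups: statistic 0, p = 1
  th0 <- tukey_hsd(rep(c(1, 1), 10), rep(c("a", "b"), 10))
  expect_equal(th0$t, 0)
  expect_equal(th0$p_tukey, 1)

  # one group shifted by 10 SD: its comparisons are overwhelming
  y10 <- c(stats::rnorm(50), stats::rnorm(49), stats::rnorm(24) + 10)
  g3 <- rep(c("HC", "MDD", "SCZ"), c(50, 49, 24))
  th10 <- tukey_hsd(y10, g3)
  expect_lt(max(th10$p_tukey[grepl("SCZ", th10$pair)]), 1e-6)

  # studentized-range adjustment never undercuts the plain two-sided t
  # p-value computed from the same pooled statistic and df
  for (pr in seq_len(nrow(th))) {
    p_plain <- 2 * stats::pt(-abs(th$t[pr]), df = 60 - 3)
    expect_gte(th$p_tukey[pr] + 1e-12, p_plain)
  }

  expect_message(gated <- tukey_hsd(y, g, anova_q = 0.5), "skipped")
  expect_equal(nrow(gated), 0)
})

test_that("the standardized GLM recovers exact coefficients and ignores units", {
  # noise-free linear data: exact recovery
  set.seed(6)
  n <- c(50, 49, 24)
  g <- rep(c("HC", "MDD", "SCZ"), n)
  vol <- stats::rnorm(123, 1000, 100)
  vol_z <- as.numeric(scale(vol))
  chi <- 0.3 * (g == "MDD") + 0.7 * vol_z * (g == "MDD") + 0.1 * vol_z
  tab <- data.frame(subject_id = seq_len(123), group = g, region = "amygdala",
                    susceptibility_ppm = chi, volume_mm3 = vol)
  fit <- suppressWarnings(glm_group_volume(tab, "amygdala"))
  sd_chi <- stats::sd(chi)
  i <- fit$term == "groupMDD:vol_z"
  expect_equal(fit$B[i], 0.7 / sd_chi, tolerance = 1e-8)
  expect_lt(max(abs(stats::residuals(attr(fit, "fit")))), 1e-8)

  # rescaling volume units leaves all standardized outputs identical
  tab$susceptibility_ppm <- chi + stats::rnorm(123, 0, 0.1)
  fit <- glm_group_volume(tab, "amygdala")
  tab2 <- tab
  tab2$volume_mm3 <- tab2$volume_mm3 / 1000
  fit2 <- glm_group_volume(tab2, "amygdala")
  expect_equal(fit$B, fit2$B, tolerance = 1e-9)
  expect_equal(fit$t, fit2$t, tolerance = 1e-9)
  expect_equal(fit$q, fit2$q, tolerance = 1e-9)

  expect_error(glm_group_volume(tab[tab$group != "SCZ", ], "amygdala"),
               "three groups")
})

test_that("ANCOVA adjusts for handedness with correct degrees of freedom", {
  set.seed(8)
  n <- c(50, 49, 24)
  g <- rep(c("HC", "MDD", "SCZ"), n)
  h <- sample(c("right", "mixed", "left"), 123, TRUE, c(0.8, 0.12, 0.08))
  y <- stats::rnorm(123) + (g == "MDD") * 0.8
  a <- ancova_handedness(y, g, h)
  expect_equal(a$df1, 2)
  expect_equal(a$df2, 123 - 5)

  # covariate independent of group and outcome: F close to the plain ANOVA
  expect_lt(abs(a$F - anova_oneway(y, g)$F) / anova_oneway(y, g)$F, 0.15)

  # outcome driven by handedness only: noise centred within every
  # group x handedness cell leaves exactly no adjusted group effect
  e <- stats::rnorm(123)
  e <- e - stats::ave(e, g, h)
  yh <- c(right = 0, mixed = 3, left = -2)[h] + e
  a2 <- ancova_handedness(yh, g, h)
  expect_lt(a2$F, 1e-10)
})

test_that("correlation screens report r, handle missingness and degeneracy", {
  tab <- data.frame(subject_id = 1:30, group = "MDD", region = "amygdala",
                    susceptibility_ppm = seq(0, 1, length.out = 30))
  tab$lin <- 2 * tab$susceptibility_ppm + 1
  tab$neg <- -tab$susceptibility_ppm
  tab$konst <- 5
  tab$holey <- c(rep(NA, 27), 1, 2, 3)
  cs <- correlation_screen(tab, "amygdala", c("lin", "neg", "konst"))
  expect_equal(cs$r, c(1, -1, NA_real_))
  expect_true(cs$flagged[3])
  cs2 <- correlation_screen(tab, "amygdala", "holey")
  expect_equal(cs2$n, 3)

  set.seed(10)
  tabn <- data.frame(subject_id = 1:10000, group = "HC", region = "x",
                     susceptibility_ppm = stats::rnorm(10000),
                     v = stats::rnorm(10000))
  expect_lt(abs(correlation_screen(tabn, "x", "v")$r), 0.05)
})

test_that("assumption checks report Shapiro-Wilk and Levene without gating", {
  set.seed(12)
  tab <- data.frame(subject_id = 1:400, group = rep(c("HC", "MDD"), each = 200),
                    region = "thalamus",
                    susceptibility_ppm = c(stats::rnorm(200, 0, 1),
                                           stats::rnorm(200, 0, 2)))
  ck <- check_assumptions(tab, "thalamus")
  expect_lt(ck$levene$p, 0.01)          # doubled SD is detected
  expect_true(all(ck$shapiro$p > 1e-4)) # both samples are Gaussian

  # degenerate constant group is flagged, not fatal
  tab$susceptibility_ppm[tab$group == "HC"] <- 1
  ck2 <- check_assumptions(tab, "thalamus")
  expect_true(ck2$shapiro$flagged[ck2$shapiro$group == "HC"])
})

test_that("Shapiro-Wilk p-values are calibrated under Gaussian sampling", {
  set.seed(13)
  ps <- replicate(400, stats::shapiro.test(stats::rnorm(50))$p.value)
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("rendered tables have the published shape and BH ordering", {
  co <- simulate_cohort(cohort_spec(seed = 21))
  res <- run_group_stats(co)
  expect_equal(nrow(res$anova), 20)
  expect_true(all(res$anova$q >= res$anova$p - 1e-12))
  expect_true(all(res$anova$df1 == 2 & res$anova$df2 == 120))

  tabs <- build_tables(co, res)
  expect_equal(nrow(tabs$susceptibility), 10)
  expect_equal(nrow(tabs$volume), 10)
  # post hoc column only populated for regions passing the gate
  gated <- res$anova$region[res$anova$measure == "susceptibility_ppm" &
                              res$anova$q < 0.05]
  has_ph <- tabs$susceptibility$region[tabs$susceptibility$posthoc != "-"]
  expect_setequal(has_ph, gated)

  # assumption reports accompany every region x measure
  expect_equal(nrow(res$assumptions), 20 * 3)
})
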