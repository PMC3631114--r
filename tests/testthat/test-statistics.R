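test_that("paired t test matches the hand formula and handles degeneracy", {
  # differences (1, 2, 3): mean 2, sd 1, n 3 -> t = 2*sqrt(3), df = 2
  x <- c(11, 22, 33); y <- c(10, 20, 30)
  r <- paired_t_test(x, y)
  expect_equal(r$statistic, 2 * sqrt(3), tolerance = 1e-12)
  expect_equal(r$statistic, 3.4641, tolerance = 1e-4)
  expect_equal(r$df, 2)

  # identical series: t = 0, p = 1
  r0 <- paired_t_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p_value, 1)

  # constant non-zero differences have zero variance: degenerate
  expect_error(paired_t_test(c(2, 3, 4), c(1, 2, 3)), "degenerate")
})

test_that("paired t p-values agree with the reference implementation", {
  for (s in 1:50) {
    set.seed(s)
    n <- sample(4:20, 1)
    x <- rnorm(n, 10, 2); y <- x + rnorm(n, 0.3, 1)
    r <- paired_t_test(x, y)
    ref <- t.test(x - y)
    expect_equal(r$p_value, ref$p.value, tolerance = 1e-10)
  }
})

test_that("two-way ANOVA handles exact null and additive structures", {
  # all cell means equal with within-cell spread: every effect SS is 0
  d <- data.frame(value = rep(c(-1, 1), 4) + 5,
                  histology = rep(c("AM", "PL"), each = 4),
                  treatment = rep(rep(c("F", "C"), each = 2), 2))
  a <- two_way_anova(d)
  expect_equal(a$sum_sq[1:3], rep(0, 3), tolerance = 1e-9)
  expect_equal(a$p_value[1:3], rep(1, 3), tolerance = 1e-6)
  # degrees of freedom partition the total
  expect_equal(sum(a$df), nrow(d) - 1)

  # perfectly additive cell means: interaction SS = 0
  eff_a <- c(AM = -2, PL = 2); eff_b <- c(F = 1, C = -1)
  d2 <- expand.grid(histology = c("AM", "PL"), treatment = c("F", "C"),
                    rep = 1:3, stringsAsFactors = FALSE)
  d2$value <- 10 + eff_a[d2$histology] + eff_b[d2$treatment]
  a2 <- two_way_anova(d2)
  expect_equal(a2$sum_sq[3], 0, tolerance = 1e-9)
  expect_gt(a2$sum_sq[1], 0)
})

test_that("Type III ANOVA matches the car oracle on unbalanced designs", {
  for (s in 1:25) {
    set.seed(s)
    # mimic the slice bookkeeping: unbalanced 12/12/16/16 plus random sizes
    ns <- if (s <= 12) c(12, 12, 16, 16) else sample(3:20, 4, replace = TRUE)
    d <- data.frame(
      value = rnorm(sum(ns), mean = rep(rnorm(4, 10, 2), ns)),
      histology = rep(c("AM", "AM", "PL", "PL"), ns),
      treatment = rep(c("F", "C", "F", "C"), ns))
    a <- two_way_anova(d)
    fit <- lm(value ~ histology * treatment, data = d,
              contrasts = list(histology = "contr.sum",
                               treatment = "contr.sum"))
    ref <- car::Anova(fit, type = 3)
    expect_equal(a$sum_sq[1:3], ref[2:4, "Sum Sq"], tolerance = 1e-8,
                 ignore_attr = TRUE)
    expect_equal(a$statistic[1:3], ref[2:4, "F value"], tolerance = 1e-8,
                 ignore_attr = TRUE)
    expect_equal(a$p_value[1:3], ref[2:4, "Pr(>F)"], tolerance = 1e-8,
                 ignore_attr = TRUE)
    expect_equal(a$sum_sq[4], ref["Residuals", "Sum Sq"], tolerance = 1e-8)
  }
})

test_that("balanced ANOVA agrees with classical aov sums of squares", {
  for (s in 1:25) {
    set.seed(100 + s)
    d <- data.frame(value = rnorm(32),
                    histology = rep(c("AM", "PL"), each = 16),
                    treatment = rep(rep(c("F", "C"), each = 8), 2))
    a <- two_way_anova(d)
    ref <- summary(aov(value ~ histology * treatment, data = d))[[1]]
    expect_equal(a$sum_sq, ref[["Sum Sq"]], tolerance = 1e-8)
    expect_equal(a$p_value[1:3], ref[["Pr(>F)"]][1:3], tolerance = 1e-8)
  }
})

test_that("swapping the factors transposes effects without changing residuals", {
  set.seed(7)
  ns <- c(5, 9, 7, 12)
  d <- data.frame(value = rnorm(sum(ns), rep(c(1, 3, 2, 5), ns)),
                  histology = rep(c("AM", "AM", "PL", "PL"), ns),
                  treatment = rep(c("F", "C", "F", "C"), ns))
  a <- two_way_anova(d, factor_a = "histology", factor_b = "treatment")
  b <- two_way_anova(d, factor_a = "treatment", factor_b = "histology")
  expect_equal(a$sum_sq[1], b$sum_sq[2], tolerance = 1e-10)
  expect_equal(a$sum_sq[2], b$sum_sq[1], tolerance = 1e-10)
  expect_equal(a$sum_sq[3], b$sum_sq[3], tolerance = 1e-10)
  expect_equal(a$sum_sq[4], b$sum_sq[4], tolerance = 1e-10)
})

test_that("empty cells are rejected with the cell named", {
  d <- data.frame(value = rnorm(6),
                  histology = c("AM", "AM", "AM", "AM", "PL", "PL"),
                  treatment = c("F", "C", "F", "C", "F", "F"))
  expect_error(two_way_anova(d), "empty cell: PL x C")
})

test_that("Tukey-Kramer matches TukeyHSD for equal n and flags known shifts", {
  for (s in 1:25) {
    set.seed(300 + s)
    d <- data.frame(value = rnorm(40),
                    histology = rep(c("AM", "PL"), each = 20),
                    treatment = rep(rep(c("F", "C"), each = 10), 2))
    tk <- tukey_posthoc(d)
    g <- interaction(d$histology, d$treatment, sep = ":")
    ref <- TukeyHSD(aov(d$value ~ g))$g
    # align pairs by absolute mean difference (orderings differ)
    expect_equal(sort(tk$p_adj), unname(sort(ref[, "p adj"])), tolerance = 1e-8)
    expect_equal(sort(abs(tk$mean_difference)), unname(sort(abs(ref[, "diff"]))),
                 tolerance = 1e-8)
  }

  # two identical groups compare with adjusted p = 1
  d0 <- data.frame(value = rep(c(1, 2, 3, 4), 4),
                   histology = rep(c("AM", "PL"), each = 8),
                   treatment = rep(rep(c("F", "C"), each = 4), 2))
  tk0 <- tukey_posthoc(d0)
  expect_true(all(tk0$p_adj > 0.999))

  # one cell shifted by 10 residual SDs: its three comparisons < 0.01
  set.seed(11)
  d1 <- data.frame(value = rnorm(40),
                   histology = rep(c("AM", "PL"), each = 20),
                   treatment = rep(rep(c("F", "C"), each = 10), 2))
  shift <- d1$histology == "AM" & d1$treatment == "F"
  d1$value[shift] <- d1$value[shift] + 10 * sd(rnorm(1000))
  tk1 <- tukey_posthoc(d1)
  involved <- grepl("AM:F", tk1$group1) | grepl("AM:F", tk1$group2)
  expect_true(all(tk1$p_adj[involved] < 0.01))
  expect_true(all(tk1$stars[involved] == "***"))
})

test_that("star notation follows the 0.05 / 0.02 / 0.01 thresholds", {
  p <- c(0.2, 0.04, 0.015, 0.005)
  expect_equal(poromech:::significance_stars(p), c("", "*", "**", "***"))
})

test_that("null type-I error is ~5% and permutation p agrees", {
  # 2000 null replicates of a balanced 2x2 with n = 8 per cell
  n_rep <- 2000
  rej <- matrix(FALSE, n_rep, 3)
  set.seed(42)
  hist_lab <- rep(c("AM", "PL"), each = 16)
  trt_lab <- rep(rep(c("F", "C"), each = 8), 2)
  for (i in seq_len(n_rep)) {
    d <- data.frame(value = rnorm(32), histology = hist_lab,
                    treatment = trt_lab)
    rej[i, ] <- two_way_anova(d)$p_value[1:3] < 0.05
  }
  rates <- colMeans(rej)
  expect_true(all(abs(rates - 0.05) <= 0.015))

  # permutation cross-check of a main-effect p on one small dataset
  set.seed(13)
  d <- data.frame(value = rnorm(24, rep(c(0, 0.9), each = 12)),
                  histology = rep(c("AM", "PL"), each = 12),
                  treatment = rep(rep(c("F", "C"), each = 6), 2))
  obs <- two_way_anova(d)
  f_obs <- obs$statistic[1]
  n_perm <- 400
  f_perm <- vapply(seq_len(n_perm), function(i) {
    dp <- d
    dp$histology <- sample(dp$histology)
    two_way_anova(dp)$statistic[1]
  }, numeric(1))
  p_perm <- (1 + sum(f_perm >= f_obs)) / (n_perm + 1)
  mc_err <- 3 * sqrt(p_perm * (1 - p_perm) / n_perm)
  expect_lt(abs(p_perm - obs$p_value[1]), mc_err + 0.02)
})
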