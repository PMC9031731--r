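test_that("pooled t from summaries reproduces published eta^2/p pairs", {
  age <- pooled_t_from_summary(ref_stats("age", "sd-aMCI"),
                               ref_stats("age", "md-aMCI"), "age")
  expect_lt(abs(age$eta_squared - 0.059), 5e-4)
  expect_lt(abs(age$p - 0.028), 5e-4)
  expect_equal(age$df, 80)
  ttau <- pooled_t_from_summary(ref_stats("csf_ttau", "sd-aMCI"),
                                ref_stats("csf_ttau", "md-aMCI"))
  expect_lt(abs(ttau$eta_squared - 0.082), 5e-4)
  expect_lt(abs(ttau$p - 0.009), 5e-4)
  # identical summaries -> t = 0, eta^2 = 0, p = 1
  s <- summary_stats(5, 1, 20)
  none <- pooled_t_from_summary(s, s)
  expect_equal(none$statistic, 0)
  expect_equal(none$eta_squared, 0)
  expect_equal(none$p, 1)
  expect_error(summary_stats(5, 1, 1), "n")
  expect_error(summary_stats(5, 0, 10), "sd")
})

test_that("summary eta^2 equals raw-data eta^2 on samples constructed to match", {
  # two-point samples with exactly the requested mean and SD
  make <- function(m, s, n) {
    x <- rep(c(-1, 1), length.out = n)
    if (n %% 2) x <- c(rep(c(-1, 1), (n - 1) / 2), 0)
    m + s * x / sd(x)
  }
  a <- make(10, 2, 20)
  b <- make(12, 3, 14)
  expect_equal(c(mean(a), sd(a), mean(b), sd(b)), c(10, 2, 12, 3))
  via_summary <- pooled_t_from_summary(summary_stats(10, 2, 20),
                                       summary_stats(12, 3, 14))
  tt <- t.test(a, b, var.equal = TRUE)
  t_raw <- unname(tt$statistic)
  expect_equal(via_summary$statistic, t_raw, tolerance = 1e-12)
  expect_equal(via_summary$eta_squared, t_raw^2 / (t_raw^2 + 32),
               tolerance = 1e-12)
})

test_that("compare_groups routes by the normality screen", {
  set.seed(40)
  co <- data.frame(group = factor(rep(c("a", "b"), c(52, 30))),
                   normal = rnorm(82),
                   heavy = rt(82, df = 1),
                   cat = factor(sample(c("x", "y"), 82, replace = TRUE)),
                   flat = 1)
  expect_equal(compare_groups(co, "normal")$test, "pooled_t")
  expect_equal(compare_groups(co, "heavy")$test, "mann_whitney")
  expect_equal(compare_groups(co, "heavy")$effect_type, "rank_eta_squared")
  expect_equal(compare_groups(co, "cat")$test, "chi_square")
  expect_error(compare_groups(co, "flat"), "constant")
  expect_error(compare_groups(co, "nope"), "not found")
})

test_that("sex split reconstructed from published percentages is null", {
  co <- data.frame(
    group = factor(rep(c("sd-aMCI", "md-aMCI"), c(52, 30)),
                   levels = c("sd-aMCI", "md-aMCI")),
    sex = c(rep(c("women", "men"), c(27, 25)),
            rep(c("women", "men"), c(16, 14))))
  cmp <- compare_groups(co, "sex")
  expect_equal(cmp$test, "chi_square")
  expect_gt(cmp$p, 0.9)
  expect_lt(cmp$eta_squared, 0.01)
})

test_that("routed test holds its nominal type-I error under the null", {
  set.seed(41)
  pvals <- vapply(1:1000, function(i) {
    co <- data.frame(group = factor(rep(c("a", "b"), c(52, 30))),
                     y = rnorm(82))
    compare_groups(co, "y")$p
  }, numeric(1))
  rate <- mean(pvals < 0.05)
  expect_gte(rate, 0.03)
  expect_lte(rate, 0.07)
  # a few Mann-Whitney routes give tied p-values; the KS distance itself is
  # unaffected, so the ties warning is suppressed
  expect_gt(suppressWarnings(ks.test(pvals, "punif")$p.value), 0.01)
})

test_that("ANCOVA adjusts the group effect for a covariate", {
  set.seed(42)
  # covariate uncorrelated with outcome: ANCOVA p ~ t-test p
  co <- data.frame(group = factor(rep(c("a", "b"), c(52, 30))),
                   age = rnorm(82, 65, 7))
  co$mmse <- 27 + 0.8 * (co$group == "a") + rnorm(82, 0, 1.8)
  an <- ancova_adjusted(co, "mmse", covariate = "age")
  tt <- compare_groups(co, "mmse")
  expect_equal(an$test, "ancova")
  expect_lt(abs(an$p - tt$p), 0.05)
  expect_true(an$eta_squared >= 0 && an$eta_squared <= 1)
  # a strong age effect plus group difference: group survives adjustment
  # at the published group means in most replicates
  hits <- vapply(1:40, function(i) {
    set.seed(100 + i)
    g <- rep(c("a", "b"), c(52, 30))
    age <- rnorm(82, ifelse(g == "a", 66.85, 63.13), 7.2)
    mmse <- 27.65 - 0.92 * (g == "b") + 0.05 * (age - 65) + rnorm(82, 0, 1.8)
    d <- data.frame(group = factor(g), age = age, mmse = mmse)
    ancova_adjusted(d, "mmse", covariate = "age")$p < 0.05
  }, logical(1))
  expect_gt(mean(hits), 0.5)
  # collinear covariate errors
  co$dup <- as.numeric(co$group == "a")
  expect_error(ancova_adjusted(co, "mmse", covariate = "dup"), "collinear")
})

test_that("ANCOVA p-values are uniform when no group effect remains", {
  set.seed(43)
  pvals <- vapply(1:400, function(i) {
    g <- rep(c("a", "b"), c(26, 15))
    age <- rnorm(41, 65, 7)
    y <- 1 + 0.1 * age + rnorm(41)
    ancova_adjusted(data.frame(group = factor(g), age = age, y = y), "y")$p
  }, numeric(1))
  expect_gt(ks.test(pvals, "punif")$p.value, 0.01)
})

test_that("correlation matrix handles mixed types with the coding contract", {
  set.seed(44)
  co <- simulate_cohort(cohort_sim_spec(seed = 44))
  R <- correlation_matrix(co, c("group", "sex", "age", "csf_ttau"))
  expect_equal(unname(diag(R)), rep(1, 4))
  expect_equal(R, t(R))
  # point-biserial group column equals Pearson on the 0/1 dummy code
  dummy <- as.numeric(co$group) - 1  # sd-aMCI = 0, md-aMCI = 1
  expect_equal(unname(R["group", "age"]), cor(dummy, co$age))
  # exactly anti-correlated pair
  co$neg_age <- -co$age
  R2 <- correlation_matrix(co, c("age", "neg_age"))
  expect_equal(unname(R2["age", "neg_age"]), -1)
  # constant column flagged, not silently zeroed
  co$const <- 1
  expect_warning(R3 <- correlation_matrix(co, c("age", "const")), "constant")
  expect_true(is.na(R3["age", "const"]))
})

test_that("point-biserial r matches the t-statistic transform r = t/sqrt(t^2+df)", {
  set.seed(45)
  co <- data.frame(group = factor(rep(c("a", "b"), c(30, 25))),
                   y = c(rnorm(30, 0), rnorm(25, 1)))
  R <- correlation_matrix(co, c("group", "y"))
  tt <- t.test(y ~ group, data = co, var.equal = TRUE)
  t <- unname(tt$statistic)
  df <- unname(tt$parameter)
  expect_equal(abs(unname(R["group", "y"])), abs(t) / sqrt(t^2 + df),
               tolerance = 1e-12)
})

test_that("group summary table has the published-table shape", {
  co <- simulate_cohort(cohort_sim_spec(seed = 46))
  tab <- group_summary_table(co, c("age", "sex", "mmse"))
  expect_equal(tab$variable, c("age", "sex", "mmse"))
  expect_true(all(c("sd.aMCI", "md.aMCI") %in% names(tab)))
  expect_true(all(tab$p >= 0 & tab$p <= 1))
})
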