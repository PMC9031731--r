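# Group comparison statistics: pooled t (also from summary statistics),
# Mann-Whitney routing, chi-square, ANCOVA, eta-squared effect sizes and the
# mixed-type predictor correlation matrix.

#' Summary statistics of one group
#'
#' @param mean,sd,n sample mean, standard deviation (> 0) and size (>= 2).
#' @return object of class `summary_stats`.
#' @export
summary_stats <- function(mean, sd, n) {
  if (!is.numeric(mean) || length(mean) != 1 || !is.finite(mean))
    abort_field("mean", "must be a finite number")
  if (!is.numeric(sd) || length(sd) != 1 || !is.finite(sd) || sd <= 0)
    abort_field("sd", "must be > 0")
  if (!is.numeric(n) || length(n) != 1 || n < 2)
    abort_field("n", "must be >= 2")
  structure(list(mean = mean, sd = sd, n = as.integer(n)),
            class = "summary_stats")
}

new_group_comparison <- function(variable, test, statistic, df, p,
                                 eta_squared, effect_type = "eta_squared",
                                 extra = list()) {
  structure(c(list(variable = variable, test = test, statistic = statistic,
                   df = df, p = p, eta_squared = eta_squared,
                   effect_type = effect_type), extra),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> %s: %s, stat = %.4g, df = %s, p = %.4g, %s = %.4g\n",
              x$variable, x$test, x$statistic,
              paste(signif(x$df, 6), collapse = "/"), x$p,
              x$effect_type, x$eta_squared))
  invisible(x)
}

#' Pooled-variance t-test and eta squared from summary statistics
#'
#' Recomputes a two-group comparison from published mean/SD/n triplets: the
#' pooled-variance Student t with `df = n_a + n_b - 2`, the two-sided p-value
#' and `eta^2 = t^2 / (t^2 + df)` (proportion of variance explained by group
#' membership; by convention 0.01 is small, 0.06 medium, 0.14 large). The
#' pooled (not Welch) variant is used because it is the one that reproduces
#' published eta^2/p pairs from these tables; see [compare_groups()] for raw
#' data.
#'
#' @param a,b [summary_stats()] for the two groups.
#' @param variable label carried into the result.
#' @return a `group_comparison`.
#' @examples
#' pooled_t_from_summary(summary_stats(66.85, 7.31, 52),
#'                       summary_stats(63.13, 7.12, 30), "age")
#' @export
pooled_t_from_summary <- function(a, b, variable = "") {
  stopifnot(inherits(a, "summary_stats"), inherits(b, "summary_stats"))
  df <- a$n + b$n - 2
  sp2 <- ((a$n - 1) * a$sd^2 + (b$n - 1) * b$sd^2) / df
  t <- (a$mean - b$mean) / sqrt(sp2 * (1 / a$n + 1 / b$n))
  p <- 2 * stats::pt(-abs(t), df)
  new_group_comparison(variable, "pooled_t", t, df, p, t^2 / (t^2 + df))
}

#' Compare one variable between two groups with routed tests
#'
#' Continuous variables are compared with the pooled-variance t-test when a
#' Shapiro-Wilk normality screen passes in both groups (at
#' `normality_alpha`), otherwise with the Mann-Whitney U-test (exact for
#' small untied samples, normal approximation with tie correction
#' otherwise). Categorical variables use the chi-square test on the 2 x 2
#' table. Effect size is eta^2 = t^2/(t^2 + df) for the t route, a
#' rank-based eta^2 ((H - 1)/(n - 2), from the Kruskal-Wallis H) for the
#' Mann-Whitney route — reported with `effect_type = "rank_eta_squared"`
#' since it is not numerically comparable to the t-based convention — and
#' phi^2 for the chi-square route.
#'
#' @param cohort data frame with a two-level `group` column (see
#'   [simulate_cohort()]).
#' @param variable column name to compare.
#' @param group name of the grouping column (default `"group"`).
#' @param normality_alpha Shapiro-Wilk screen level (default 0.05).
#' @return a `group_comparison`; its `test` field records the route taken.
#' @export
compare_groups <- function(cohort, variable, group = "group",
                           normality_alpha = 0.05) {
  if (!variable %in% names(cohort))
    abort_field("variable", sprintf("column '%s' not found", variable))
  g <- factor(cohort[[group]])
  if (nlevels(g) != 2)
    abort_field("group", "must have exactly two levels")
  x <- cohort[[variable]]
  if (is.numeric(x)) {
    if (stats::sd(x) == 0)
      stop(sprintf("variable '%s' is constant; no test possible", variable),
           call. = FALSE)
    xs <- split(x, g)
    normal <- vapply(xs, function(v) {
      length(unique(v)) > 2 && stats::shapiro.test(v)$p.value > normality_alpha
    }, logical(1))
    if (all(normal)) {
      tt <- stats::t.test(xs[[1]], xs[[2]], var.equal = TRUE)
      t <- unname(tt$statistic)
      df <- unname(tt$parameter)
      new_group_comparison(variable, "pooled_t", t, df, tt$p.value,
                           t^2 / (t^2 + df))
    } else {
      wt <- stats::wilcox.test(xs[[1]], xs[[2]])
      kw <- stats::kruskal.test(x, g)
      n <- length(x)
      eta_h <- max(0, (unname(kw$statistic) - 1) / (n - 2))
      new_group_comparison(variable, "mann_whitney", unname(wt$statistic),
                           NA_real_, wt$p.value, min(1, eta_h),
                           effect_type = "rank_eta_squared")
    }
  } else {
    tab <- table(factor(x), g)
    if (nrow(tab) < 2)
      stop(sprintf("variable '%s' is constant; no test possible", variable),
           call. = FALSE)
    ct <- suppressWarnings(stats::chisq.test(tab))
    phi2 <- unname(ct$statistic) / sum(tab)
    new_group_comparison(variable, "chi_square", unname(ct$statistic),
                         unname(ct$parameter), ct$p.value, min(1, phi2),
                         effect_type = "phi_squared")
  }
}

#' ANCOVA group comparison adjusting for one covariate
#'
#' One-way analysis of covariance: the group effect on `outcome` with
#' `covariate` entered as a linear term (fitted first, so the group F-test
#' is adjusted for it). Reports the group F statistic, its p-value and the
#' partial eta^2 `SS_group / (SS_group + SS_residual)`.
#'
#' @param cohort data frame.
#' @param outcome,covariate numeric column names.
#' @param group two-level grouping column name (default `"group"`).
#' @return a `group_comparison` with `test = "ancova"` and `df = c(1, df_res)`.
#' @export
ancova_adjusted <- function(cohort, outcome, group = "group",
                            covariate = "age") {
  for (col in c(outcome, covariate, group))
    if (!col %in% names(cohort))
      abort_field("cohort", sprintf("column '%s' not found", col))
  g <- factor(cohort[[group]])
  if (nlevels(g) != 2) abort_field("group", "must have exactly two levels")
  if (min(table(g)) < 3)
    abort_field("group", "needs >= 3 subjects per group")
  cv <- cohort[[covariate]]
  if (!is.numeric(cv) || stats::sd(cv) == 0)
    abort_field("covariate", "must be numeric and non-constant")
  fit <- stats::lm(cohort[[outcome]] ~ cv + g)
  if (anyNA(stats::coef(fit)))
    abort_field("covariate", "is collinear with the group encoding")
  an <- stats::anova(fit)
  ss_g <- an["g", "Sum Sq"]
  ss_r <- an["Residuals", "Sum Sq"]
  new_group_comparison(outcome, "ancova", an["g", "F value"],
                       c(an["g", "Df"], an["Residuals", "Df"]),
                       an["g", "Pr(>F)"], ss_g / (ss_g + ss_r),
                       effect_type = "partial_eta_squared",
                       extra = list(covariate = covariate))
}

#' Mixed-type predictor correlation matrix
#'
#' Pearson correlations between continuous variables and point-biserial
#' correlations (Pearson on a 0/1 dummy code) when a variable is binary.
#' Coding contract: the `group` column is coded first level = 0 / second
#' level = 1 (sd-aMCI = 0, md-aMCI = 1 in the default cohort) and `sex` is
#' women = 0 / men = 1. Constant columns are flagged as undefined (`NA` row
#' and column, with a warning) rather than silently set to 0.
#'
#' @param cohort data frame.
#' @param variables column names to include (default: all columns except
#'   `subject_id`).
#' @return symmetric correlation matrix with unit diagonal.
#' @export
correlation_matrix <- function(cohort, variables = NULL) {
  if (is.null(variables)) variables <- setdiff(names(cohort), "subject_id")
  missing_cols <- setdiff(variables, names(cohort))
  if (length(missing_cols))
    abort_field("variables", paste("not found:", paste(missing_cols, collapse = ", ")))
  if (nrow(cohort) < 3 || anyNA(cohort[variables]))
    abort_field("cohort", "needs >= 3 complete rows")
  num <- sapply(variables, function(v) {
    x <- cohort[[v]]
    if (is.numeric(x)) return(x)
    f <- factor(x)
    if (v == "sex") f <- factor(x, levels = c("women", "men"))
    if (nlevels(f) > 2)
      abort_field(v, "categorical variables must be binary for point-biserial coding")
    as.numeric(f) - 1
  })
  colnames(num) <- variables
  const <- apply(num, 2, stats::sd) == 0
  if (any(const))
    warning("correlation undefined for constant column(s): ",
            paste(variables[const], collapse = ", "), call. = FALSE)
  R <- suppressWarnings(stats::cor(num))
  diag(R) <- 1
  R
}

#' Published-table-shaped group summary
#'
#' For each variable: whole-cohort and per-group mean (SD) plus the routed
#' test's effect size and p-value — the layout of a clinical descriptive
#' table. Categorical variables are summarised as percentages.
#'
#' @param cohort data frame with a two-level `group` column.
#' @param variables column names to summarise.
#' @param normality_alpha passed to [compare_groups()].
#' @return data frame with one row per variable.
#' @export
group_summary_table <- function(cohort, variables,
                                normality_alpha = 0.05) {
  g <- factor(cohort$group)
  rows <- lapply(variables, function(v) {
    x <- cohort[[v]]
    cmp <- compare_groups(cohort, v, normality_alpha = normality_alpha)
    if (is.numeric(x)) {
      fmt <- function(val) sprintf("%.3g (%.3g)", mean(val), stats::sd(val))
      data.frame(variable = v, test = cmp$test,
                 whole = fmt(x),
                 group1 = fmt(x[g == levels(g)[1]]),
                 group2 = fmt(x[g == levels(g)[2]]),
                 effect_size = cmp$eta_squared, p = cmp$p,
                 stringsAsFactors = FALSE)
    } else {
      lvl <- levels(factor(x))[1]
      pct <- function(val) sprintf("%.0f%% %s", 100 * mean(val == lvl), lvl)
      data.frame(variable = v, test = cmp$test,
                 whole = pct(x),
                 group1 = pct(x[g == levels(g)[1]]),
                 group2 = pct(x[g == levels(g)[2]]),
                 effect_size = cmp$eta_squared, p = cmp$p,
                 stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  names(out)[4:5] <- make.names(levels(g))
  out
}
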