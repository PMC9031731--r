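# Synthetic two-group aMCI cohorts drawn from published summary statistics.

cohort_vars <- function() {
  c("age", "education", "mmse",
    "csf_abeta42", "csf_ttau", "csf_ptau", "csf_ng",
    "gfp_delta", "gfp_theta", "gfp_alpha", "gfp_beta",
    "gfs_delta", "gfs_theta", "gfs_alpha", "gfs_beta")
}

# Variables constrained to be positive (concentrations and spectral
# amplitudes); GFS is additionally bounded in [0, 1] but its group means sit
# ~18 SD above 0, so the positivity machinery is inert there.
positive_vars <- function() {
  setdiff(cohort_vars(), c("age", "education", "mmse"))
}

#' Published per-group summary statistics used as simulation defaults
#'
#' Mean, SD and n per variable for the single-domain (sd-aMCI, n = 52) and
#' multidomain (md-aMCI, n = 30) amnestic MCI groups and the whole cohort
#' (N = 82): demographics and MMSE, CSF biomarkers (ng/L) and the eight
#' band-level GFP/GFS qEEG measures. These printed summaries are the inputs
#' from which effect sizes are recomputed and from which synthetic cohorts
#' are drawn.
#'
#' @return data frame with columns `variable`, `group`
#'   (`"sd-aMCI"`, `"md-aMCI"`, `"whole"`), `mean`, `sd`, `n`.
#' @export
mci_reference_summaries <- function() {
  v <- cohort_vars()
  sd_m <- c(66.85, 12.18, 27.65, 673, 443, 70, 217,
            0.098, 0.054, 0.164, 0.039, 0.545, 0.549, 0.575, 0.516)
  sd_s <- c(7.31, 3.31, 1.67, 249.7, 231.9, 26.5, 80.3,
            0.048, 0.044, 0.135, 0.032, 0.022, 0.024, 0.032, 0.022)
  md_m <- c(63.13, 13.27, 26.73, 738, 317, 58, 182,
            0.109, 0.058, 0.144, 0.030, 0.558, 0.563, 0.578, 0.518)
  md_s <- c(7.12, 4.83, 2.24, 264.8, 145.9, 21.4, 60.2,
            0.056, 0.046, 0.090, 0.023, 0.030, 0.027, 0.043, 0.022)
  wh_m <- c(65.49, 12.58, 27.31, 697, 397, 66, 204,
            0.102, 0.055, 0.157, 0.036, 0.550, 0.554, 0.576, 0.516)
  wh_s <- c(7.42, 3.94, 1.94, 255.6, 212.7, 25.3, 75.1,
            0.051, 0.044, 0.120, 0.029, 0.026, 0.026, 0.036, 0.022)
  rbind(
    data.frame(variable = v, group = "sd-aMCI", mean = sd_m, sd = sd_s, n = 52),
    data.frame(variable = v, group = "md-aMCI", mean = md_m, sd = md_s, n = 30),
    data.frame(variable = v, group = "whole", mean = wh_m, sd = wh_s, n = 82)
  )
}

#' Default inter-predictor correlation matrix for cohort simulation
#'
#' A plausible shared (within-group) correlation structure among the 15
#' continuous predictors: strong coupling within the CSF tau/neurogranin
#' block, moderate coupling within the GFP and GFS band blocks, weak
#' amyloid-tau and age-tau links, and small negative links between
#' slow-band GFS and tau markers. It is a modelling choice standing in for
#' the unpublished patient-level correlations, chosen once on domain grounds
#' and validated to be symmetric positive definite.
#'
#' @return 15 x 15 correlation matrix named by variable.
#' @export
default_predictor_correlation <- function() {
  v <- cohort_vars()
  R <- diag(length(v))
  dimnames(R) <- list(v, v)
  set_r <- function(a, b, r) {
    R[a, b] <<- r
    R[b, a] <<- r
  }
  set_r("csf_ttau", "csf_ptau", 0.80)
  set_r("csf_ttau", "csf_ng", 0.65)
  set_r("csf_ptau", "csf_ng", 0.70)
  set_r("csf_abeta42", "csf_ttau", -0.20)
  set_r("csf_abeta42", "csf_ptau", -0.15)
  set_r("csf_abeta42", "csf_ng", -0.10)
  set_r("age", "csf_ttau", 0.15)
  set_r("age", "csf_ptau", 0.10)
  set_r("age", "csf_abeta42", -0.10)
  set_r("age", "mmse", -0.10)
  set_r("education", "mmse", 0.15)
  gfp <- paste0("gfp_", c("delta", "theta", "alpha", "beta"))
  gfs <- paste0("gfs_", c("delta", "theta", "alpha", "beta"))
  gfp_r <- matrix(c(1, .55, .35, .30,
                    .55, 1, .45, .35,
                    .35, .45, 1, .40,
                    .30, .35, .40, 1), 4)
  gfs_r <- matrix(c(1, .60, .40, .35,
                    .60, 1, .45, .40,
                    .40, .45, 1, .45,
                    .35, .40, .45, 1), 4)
  R[gfp, gfp] <- gfp_r
  R[gfs, gfs] <- gfs_r
  for (b in c("delta", "theta", "alpha", "beta"))
    set_r(paste0("gfp_", b), paste0("gfs_", b), 0.10)
  set_r("gfs_delta", "csf_ptau", -0.15)
  set_r("gfs_theta", "csf_ptau", -0.15)
  set_r("gfs_delta", "csf_ttau", -0.15)
  set_r("gfs_theta", "csf_ttau", -0.15)
  set_r("gfs_delta", "csf_ng", -0.10)
  set_r("gfs_theta", "csf_ng", -0.10)
  R
}

#' Specification for a synthetic two-group cohort
#'
#' Group means/SDs default to the published sd-aMCI / md-aMCI summaries
#' ([mci_reference_summaries()]); group sizes default to n = 52 and n = 30;
#' the proportion of women defaults to the published 52% and 53% (27/52 and
#' 16/30).
#'
#' @param n length-2 vector of group sizes (sd group first).
#' @param means,sds 2 x 15 matrices (groups x variables) of target means and
#'   SDs; defaults taken from the published tables.
#' @param prop_women length-2 vector of Bernoulli probabilities for sex,
#'   drawn independently of the other variables.
#' @param correlation shared 15 x 15 correlation matrix (default
#'   [default_predictor_correlation()]); must be symmetric positive
#'   semi-definite with unit diagonal.
#' @param group_labels labels for the two groups.
#' @param seed optional RNG seed.
#' @return object of class `cohort_sim_spec`.
#' @export
cohort_sim_spec <- function(n = c(52, 30), means = NULL, sds = NULL,
                            prop_women = c(27 / 52, 16 / 30),
                            correlation = default_predictor_correlation(),
                            group_labels = c("sd-aMCI", "md-aMCI"),
                            seed = NULL) {
  v <- cohort_vars()
  if (length(n) != 2 || any(n < 2))
    abort_field("n", "needs two group sizes >= 2")
  ref <- mci_reference_summaries()
  pick <- function(g, what) {
    r <- ref[ref$group == g, ]
    stats::setNames(r[[what]], r$variable)[v]
  }
  if (is.null(means))
    means <- rbind(pick("sd-aMCI", "mean"), pick("md-aMCI", "mean"))
  if (is.null(sds))
    sds <- rbind(pick("sd-aMCI", "sd"), pick("md-aMCI", "sd"))
  if (!is.matrix(means) || any(dim(means) != c(2, length(v))))
    abort_field("means", "must be a 2 x 15 groups-by-variables matrix")
  if (!is.matrix(sds) || any(dim(sds) != c(2, length(v))))
    abort_field("sds", "must be a 2 x 15 groups-by-variables matrix")
  if (any(!is.finite(sds)) || any(sds <= 0))
    abort_field("sds", "must be finite and > 0")
  colnames(means) <- colnames(sds) <- v
  rownames(means) <- rownames(sds) <- group_labels
  if (length(prop_women) != 2 || any(prop_women < 0) || any(prop_women > 1))
    abort_field("prop_women", "needs two probabilities in [0, 1]")
  if (!is.matrix(correlation) || any(dim(correlation) != length(v)))
    abort_field("correlation", "must be a 15 x 15 matrix")
  if (max(abs(correlation - t(correlation))) > 1e-10)
    abort_field("correlation", "must be symmetric")
  if (max(abs(diag(correlation) - 1)) > 1e-10)
    abort_field("correlation", "must have unit diagonal")
  ev <- eigen(correlation, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8)
    abort_field("correlation", "must be positive semi-definite")
  structure(list(n = as.integer(n), means = means, sds = sds,
                 prop_women = prop_women, correlation = correlation,
                 group_labels = group_labels, variables = v, seed = seed),
            class = "cohort_sim_spec")
}

# Parameters (mu, sigma) of a normal truncated below at 0 whose truncated
# mean and SD equal the targets. Keeps positivity without the upward mean
# bias of naive resampling and without a point mass at the bound.
match_truncnorm <- function(m, s) {
  stopifnot(m > 0, s > 0)
  if (m / s >= 8) return(list(mu = m, sigma = s, truncated = FALSE))
  moments <- function(mu, sigma) {
    a <- -mu / sigma
    lam <- stats::dnorm(a) / stats::pnorm(a, lower.tail = FALSE)
    mean_t <- mu + sigma * lam
    var_t <- sigma^2 * (1 + a * lam - lam^2)
    c(mean_t, sqrt(max(var_t, 0)))
  }
  obj <- function(p) {
    mt <- moments(p[1], exp(p[2]))
    sum(((mt - c(m, s)) / s)^2)
  }
  fit <- stats::optim(c(m, log(s)), obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-14, maxit = 5000))
  list(mu = fit$par[1], sigma = exp(fit$par[2]), truncated = TRUE)
}

# Quantile of the 0-truncated normal, used as the Gaussian-copula margin.
q_truncnorm0 <- function(p, mu, sigma) {
  pa <- stats::pnorm(0, mu, sigma)
  stats::qnorm(pa + p * (1 - pa), mu, sigma)
}

#' Simulate a two-group cohort table
#'
#' Per group, draws the 15 continuous variables from a Gaussian copula with
#' the spec's correlation matrix. Margins are plain normals with the target
#' mean/SD except for positivity-constrained variables (CSF concentrations,
#' GFP/GFS), which use a 0-truncated normal whose parameters are
#' moment-matched so the simulated mean and SD converge to the published
#' values; MMSE is clipped to its 0-30 scale range (a ceiling the real test
#' also has). Sex is drawn independently as Bernoulli(prop women). A fixed
#' seed reproduces the table exactly.
#'
#' @param spec a [cohort_sim_spec()].
#' @return data frame with `subject_id`, `group`, `sex` and the 15 numeric
#'   variables, one row per subject (sd group first).
#' @examples
#' head(simulate_cohort(cohort_sim_spec(seed = 1)))
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_sim_spec"))
  v <- spec$variables
  pos <- positive_vars()
  with_seed(spec$seed, {
    groups <- list()
    for (g in 1:2) {
      n <- spec$n[g]
      Z <- MASS::mvrnorm(n, mu = rep(0, length(v)), Sigma = spec$correlation)
      if (!is.matrix(Z)) Z <- matrix(Z, nrow = 1)
      X <- matrix(NA_real_, n, length(v), dimnames = list(NULL, v))
      for (j in seq_along(v)) {
        m <- spec$means[g, j]
        s <- spec$sds[g, j]
        if (v[j] %in% pos) {
          par <- match_truncnorm(m, s)
          X[, j] <- if (par$truncated)
            q_truncnorm0(stats::pnorm(Z[, j]), par$mu, par$sigma)
          else m + s * Z[, j]
        } else {
          X[, j] <- m + s * Z[, j]
        }
      }
      if ("mmse" %in% v) X[, "mmse"] <- pmin(pmax(X[, "mmse"], 0), 30)
      sex <- ifelse(stats::runif(n) < spec$prop_women[g], "women", "men")
      groups[[g]] <- data.frame(
        subject_id = sprintf("%s-%03d", c("sd", "md")[g], seq_len(n)),
        group = spec$group_labels[g], sex = sex, X,
        stringsAsFactors = FALSE)
    }
    out <- rbind(groups[[1]], groups[[2]])
    out$group <- factor(out$group, levels = spec$group_labels)
    out$sex <- factor(out$sex, levels = c("women", "men"))
    rownames(out) <- NULL
    out
  })
}
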