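test_that("config and fit validation catch bad inputs", {
  expect_error(rf_config(n_trees = 0), "n_trees")
  expect_error(rf_config(train_fraction = 1), "train_fraction")
  expect_error(rf_config(mtry = 0), "mtry")
  co <- separable_cohort()
  expect_error(fit_balanced_forest(co, c("signal", "nope"), "group",
                                   rf_config(10)), "not found")
  expect_error(fit_balanced_forest(co, "signal", "group",
                                   rf_config(10, mtry = 5)), "mtry")
  tiny <- co[c(1, 31:60), ]
  expect_error(fit_balanced_forest(tiny, "signal", "group", rf_config(10)),
               ">= 2 subjects")
  co$signal[1] <- NA
  expect_error(fit_balanced_forest(co, "signal", "group", rf_config(10)),
               "missing")
})

test_that("per-tree draws are balanced 50/50 and sized by the minority class", {
  co <- simulate_cohort(cohort_sim_spec(seed = 50))
  m <- fit_balanced_forest(co, c("age", "mmse"), "group",
                           rf_config(n_trees = 25, mtry = 1, seed = 51))
  expect_equal(m$n_draw, c(21, 21))  # floor(0.7 * 30) per class
  y01 <- as.numeric(co$group) - 1
  for (t in 1:25) {
    train <- setdiff(seq_len(82), m$oob[[t]])
    expect_equal(length(train), 42)
    expect_equal(sum(y01[train]), 21)  # exactly half from each class
  }
})

test_that("fits are deterministic given seed, config and data", {
  co <- separable_cohort()
  cfg <- rf_config(n_trees = 50, mtry = 2, seed = 52)
  r1 <- oob_report(fit_balanced_forest(co, c("signal", "other", "noise"),
                                       "group", cfg))
  r2 <- oob_report(fit_balanced_forest(co, c("signal", "other", "noise"),
                                       "group", cfg))
  expect_identical(r1$oob_error, r2$oob_error)
  expect_identical(r1$votes, r2$votes)
})

test_that("separable classes give near-zero OOB error", {
  co <- separable_cohort()
  m <- fit_balanced_forest(co, c("signal", "other", "noise"), "group",
                           rf_config(n_trees = 300, mtry = 2, seed = 53))
  rep <- oob_report(m)
  expect_lt(rep$oob_error, 5)
  expect_equal(length(rep$never_oob), 0)
  # per-class errors average (weighted by class size) to the overall error
  seen <- !is.na(rep$predicted)
  w <- table(co$group[seen])
  expect_equal(unname(sum(rep$per_class_error * w) / sum(w)),
               rep$oob_error, tolerance = 1e-9)
  # vote fractions sum to 1 per subject
  expect_equal(unname(rowSums(rep$votes)), rep(1, nrow(co)))
})

test_that("label-permuted data sits at the 50% chance level", {
  co <- separable_cohort(n_per = 41)
  errs <- vapply(1:3, function(i) {
    set.seed(60 + i)
    co$gperm <- sample(co$group)
    m <- fit_balanced_forest(co, c("signal", "other", "noise"), "gperm",
                             rf_config(n_trees = 300, mtry = 2,
                                       seed = 70 + i))
    oob_report(m)$oob_error
  }, numeric(1))
  # binomial SE for one 82-subject OOB estimate is 100*sqrt(.25/82) = 5.5
  se <- 100 * sqrt(0.25 / 82) / sqrt(3)
  expect_lt(abs(mean(errs) - 50), 3 * se)
})

test_that("vote ties break to class 0 and are flagged", {
  co <- separable_cohort()
  m <- fit_balanced_forest(co, c("signal", "other", "noise"), "group",
                           rf_config(n_trees = 20, mtry = 2, seed = 54))
  # force an exact tie on one subject by editing the vote bookkeeping path:
  # a subject OOB in 2 trees with opposing votes
  rep <- oob_report(m)
  if (length(rep$tie_subjects)) {
    expect_true(all(rep$predicted[rep$tie_subjects] == 0))
  }
  # constructed check on the tie rule itself: equal votes -> class 0
  votes <- c(`a` = 5, `b` = 5)
  expect_equal(as.integer(votes[2] > votes[1]), 0L)
})

test_that("agrees with an independent forest implementation on easy data", {
  skip_if_not_installed("randomForest")
  co <- separable_cohort(n_per = 40)
  mine <- oob_report(fit_balanced_forest(
    co, c("signal", "other", "noise"), "group",
    rf_config(n_trees = 300, mtry = 2, seed = 55)))$oob_error
  set.seed(55)
  rf <- randomForest::randomForest(group ~ signal + other + noise, data = co,
                                   ntree = 300, mtry = 2)
  theirs <- 100 * mean(rf$predicted != co$group)
  expect_lt(abs(mine - theirs), 5)
})

test_that("permutation importance isolates informative predictors", {
  co <- separable_cohort(n_per = 35)
  m <- fit_balanced_forest(co, c("signal", "other", "noise"), "group",
                           rf_config(n_trees = 200, mtry = 2, seed = 56))
  imp <- permutation_importance(m, seed = 57)
  expect_equal(imp$predictor[1], "signal")
  expect_gt(imp$importance[1], 0.3)
  # pure-noise predictors rank at the bottom with ~0 importance
  expect_true(all(abs(imp$importance[imp$predictor != "signal"]) < 0.02))
  expect_setequal(imp$predictor[2:3], c("other", "noise"))
})

test_that("duplicating an informative predictor splits its credit", {
  co <- separable_cohort(n_per = 35)
  co$signal2 <- co$signal + rnorm(70, 0, 0.01)
  single <- fit_balanced_forest(co, c("signal", "other", "noise"), "group",
                                rf_config(n_trees = 200, mtry = 2, seed = 58))
  dup <- fit_balanced_forest(co, c("signal", "signal2", "other", "noise"),
                             "group",
                             rf_config(n_trees = 200, mtry = 2, seed = 58))
  imp_single <- permutation_importance(single, seed = 59)
  imp_dup <- permutation_importance(dup, seed = 59)
  top_single <- imp_single$importance[imp_single$predictor == "signal"]
  sig_dup <- imp_dup$importance[imp_dup$predictor %in% c("signal", "signal2")]
  expect_true(all(sig_dup < top_single))
  expect_lt(abs(oob_report(dup)$oob_error - oob_report(single)$oob_error), 5)
})

test_that("vote fractions stabilize as trees are added", {
  co <- separable_cohort(n_per = 20)
  co$signal <- co$signal + rnorm(40, 0, 0.6)  # make it non-trivial
  vote_for_subject1 <- function(n_trees, seed) {
    m <- fit_balanced_forest(co, c("signal", "other", "noise"), "group",
                             rf_config(n_trees = n_trees, mtry = 2,
                                       seed = seed))
    oob_report(m)$votes[1, 2]
  }
  few <- vapply(1:6, function(s) vote_for_subject1(5, 500 + s), numeric(1))
  many <- vapply(1:6, function(s) vote_for_subject1(200, 600 + s), numeric(1))
  expect_gt(var(few), var(many))
})
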