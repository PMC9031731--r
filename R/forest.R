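# Class-balanced random forest for two-group classification.
#
# The subsampling scheme mirrors the published model: each tree is trained
# on an equal-count draw from both classes — floor(train_fraction x minority
# n) subjects per class, WITHOUT replacement (a 70/30 split per tree rather
# than classic bootstrap bagging) — and evaluated on the subjects it never
# saw. Trees are unpruned CART (Gini impurity, `mtry` predictors sampled at
# each split). OOB bookkeeping, the tie rule and permutation importance are
# implemented here so their contracts are explicit.

#' Random forest configuration
#'
#' Defaults follow the published model: 5,000 trees, 3 predictors tested per
#' split (kept at 3 even though sqrt(16) would round to 4 — the stated value
#' wins; pass `mtry = "sqrt"` for the rule), each tree trained on 70% of the
#' data with the two classes drawn 50/50, nodes split until pure or below
#' `min_node_size`.
#'
#' @param n_trees number of trees (default 5000).
#' @param mtry predictors sampled per split (default 3), or `"sqrt"` for
#'   `floor(sqrt(p))` resolved at fit time.
#' @param train_fraction per-tree training fraction of the minority class
#'   (default 0.70), drawn without replacement from EACH class.
#' @param class_balance draw equal counts from both classes (default TRUE).
#'   With `FALSE`, `train_fraction` of each class is drawn (stratified but
#'   unbalanced).
#' @param min_node_size minimum node size to attempt a split on (default 1:
#'   nodes are split until pure, every node keeps >= 1 observation).
#' @param seed RNG seed for reproducible fits.
#' @return object of class `rf_config`.
#' @export
rf_config <- function(n_trees = 5000, mtry = 3, train_fraction = 0.70,
                      class_balance = TRUE, min_node_size = 1, seed = NULL) {
  if (!is.numeric(n_trees) || n_trees < 1)
    abort_field("n_trees", "must be >= 1")
  if (!(identical(mtry, "sqrt") || (is.numeric(mtry) && mtry >= 1)))
    abort_field("mtry", "must be >= 1 or \"sqrt\"")
  if (!is.numeric(train_fraction) || train_fraction <= 0 || train_fraction >= 1)
    abort_field("train_fraction", "must be in (0, 1)")
  if (!is.numeric(min_node_size) || min_node_size < 1)
    abort_field("min_node_size", "must be >= 1")
  structure(list(n_trees = as.integer(n_trees), mtry = mtry,
                 train_fraction = train_fraction,
                 class_balance = isTRUE(class_balance),
                 min_node_size = as.integer(min_node_size), seed = seed),
            class = "rf_config")
}

# Grow one unpruned CART tree on rows `rows` of X (numeric matrix) with 0/1
# labels y01. Returns a node matrix with columns:
#   var, split, left, right, pred  (var = 0 marks a terminal node).
grow_cart <- function(X, y01, rows, mtry, min_node_size) {
  p <- ncol(X)
  nodes <- matrix(0, nrow = 2 * length(rows) + 1, ncol = 5,
                  dimnames = list(NULL, c("var", "split", "left", "right", "pred")))
  n_nodes <- 0L
  new_node <- function() {
    n_nodes <<- n_nodes + 1L
    if (n_nodes > nrow(nodes))
      nodes <<- rbind(nodes, matrix(0, nrow(nodes), 5))
    n_nodes
  }
  majority <- function(y) as.numeric(sum(y) * 2 > length(y))  # tie -> class 0
  build <- function(r) {
    id <- new_node()
    y <- y01[r]
    n <- length(r)
    if (n <= min_node_size || all(y == y[1])) {
      nodes[id, "pred"] <<- majority(y)
      return(id)
    }
    vars <- if (mtry >= p) seq_len(p) else sample.int(p, mtry)
    best <- list(cost = Inf)
    tot1 <- sum(y)
    for (j in vars) {
      v <- X[r, j]
      o <- order(v)
      vs <- v[o]
      cuts <- which(diff(vs) > 0)
      if (!length(cuts)) next
      c1 <- cumsum(y[o])[cuts]
      nl <- cuts
      nr <- n - nl
      n1r <- tot1 - c1
      cost <- 2 * c1 * (nl - c1) / nl + 2 * n1r * (nr - n1r) / nr
      i <- which.min(cost)
      if (cost[i] < best$cost) {
        best <- list(cost = cost[i], var = j,
                     split = (vs[cuts[i]] + vs[cuts[i] + 1]) / 2)
      }
    }
    if (!is.finite(best$cost)) {  # sampled predictors all constant here
      nodes[id, "pred"] <<- majority(y)
      return(id)
    }
    go_left <- X[r, best$var] <= best$split
    left_id <- build(r[go_left])
    right_id <- build(r[!go_left])
    nodes[id, ] <<- c(best$var, best$split, left_id, right_id, NA)
    id
  }
  build(rows)
  nodes[seq_len(n_nodes), , drop = FALSE]
}

# Predict 0/1 classes for rows `rows` of X with one grown tree.
predict_cart <- function(tree, X, rows) {
  node <- rep(1L, length(rows))
  repeat {
    v <- tree[node, "var"]
    active <- v > 0
    if (!any(active)) break
    idx <- which(active)
    go_left <- X[cbind(rows[idx], v[idx])] <= tree[node[idx], "split"]
    node[idx] <- ifelse(go_left, tree[node[idx], "left"],
                        tree[node[idx], "right"])
  }
  tree[node, "pred"]
}

#' Fit a class-balanced random forest
#'
#' @param cohort data frame holding predictors and the outcome.
#' @param predictors character vector of predictor column names; two-level
#'   factors are dummy-coded 0/1 (first level = 0), all others must be
#'   numeric and complete.
#' @param outcome name of the binary outcome column; its first factor level
#'   is "class 0" (sd-aMCI in the default cohort) and wins vote ties.
#' @param cfg an [rf_config()].
#' @return object of class `balanced_rf` holding the trees, per-tree
#'   out-of-sample row indices, the design matrix and labels.
#' @seealso [oob_report()], [permutation_importance()]
#' @export
fit_balanced_forest <- function(cohort, predictors, outcome,
                                cfg = rf_config()) {
  stopifnot(inherits(cfg, "rf_config"))
  missing_cols <- setdiff(c(predictors, outcome), names(cohort))
  if (length(missing_cols))
    abort_field("predictors", paste("not found:", paste(missing_cols, collapse = ", ")))
  y <- factor(cohort[[outcome]])
  if (nlevels(y) != 2)
    abort_field("outcome", "must be binary")
  if (min(table(y)) < 2)
    abort_field("outcome", "each class needs >= 2 subjects")
  X <- sapply(predictors, function(v) {
    x <- cohort[[v]]
    if (is.numeric(x)) return(x)
    f <- factor(x)
    if (v == "sex" && all(levels(f) %in% c("women", "men")))
      f <- factor(x, levels = c("women", "men"))
    if (nlevels(f) != 2)
      abort_field(v, "non-numeric predictors must be binary")
    as.numeric(f) - 1
  })
  colnames(X) <- predictors
  if (anyNA(X) || anyNA(y))
    abort_field("predictors", "must be complete (no missing values)")
  p <- ncol(X)
  mtry <- if (identical(cfg$mtry, "sqrt")) max(1L, floor(sqrt(p)))
          else as.integer(cfg$mtry)
  if (mtry > p)
    abort_field("mtry", sprintf("exceeds the %d available predictors", p))
  idx_by_class <- split(seq_along(y), y)
  n_min <- min(lengths(idx_by_class))
  n_draw <- if (cfg$class_balance)
    rep(floor(cfg$train_fraction * n_min), 2)
  else
    floor(cfg$train_fraction * lengths(idx_by_class))
  if (any(n_draw < 1))
    abort_field("train_fraction", "yields an empty per-class draw")
  y01 <- as.numeric(y) - 1
  n <- length(y)
  with_seed(cfg$seed, {
    trees <- vector("list", cfg$n_trees)
    oob <- vector("list", cfg$n_trees)
    for (t in seq_len(cfg$n_trees)) {
      train <- c(sample(idx_by_class[[1]], n_draw[1]),
                 sample(idx_by_class[[2]], n_draw[2]))
      trees[[t]] <- grow_cart(X, y01, train, mtry, cfg$min_node_size)
      oob[[t]] <- setdiff(seq_len(n), train)
    }
    structure(list(trees = trees, oob = oob, X = X, y = y, y01 = y01,
                   classes = levels(y), predictors = predictors,
                   mtry = mtry, n_draw = n_draw, cfg = cfg),
              class = "balanced_rf")
  })
}

#' @export
print.balanced_rf <- function(x, ...) {
  cat(sprintf("<balanced_rf> %d trees, mtry %d, %s per class per tree, %d predictors, classes %s/%s\n",
              length(x$trees), x$mtry, paste(x$n_draw, collapse = "+"),
              ncol(x$X), x$classes[1], x$classes[2]))
  invisible(x)
}

#' Out-of-bag classification report
#'
#' Each subject is classified by the majority vote of the trees for which it
#' was out-of-sample; vote ties go to class 0 (the first outcome level) and
#' are flagged. Reports the out-of-bag estimated error rate (OOB-EER, in
#' percent), per-class errors, per-subject vote fractions, and any subject
#' that was never out-of-sample (counted as missing, never silently
#' dropped).
#'
#' @param model a [fit_balanced_forest()] fit.
#' @return object of class `rf_report` with fields `oob_error` (%),
#'   `per_class_error` (named %, per true class), `confusion`, `votes`
#'   (n x 2 matrix of vote fractions), `predicted`, `tie_subjects` and
#'   `never_oob`.
#' @export
oob_report <- function(model) {
  stopifnot(inherits(model, "balanced_rf"))
  n <- length(model$y01)
  votes <- matrix(0, n, 2, dimnames = list(NULL, model$classes))
  for (t in seq_along(model$trees)) {
    o <- model$oob[[t]]
    if (!length(o)) next
    pred <- predict_cart(model$trees[[t]], model$X, o)
    votes[cbind(o, pred + 1)] <- votes[cbind(o, pred + 1)] + 1
  }
  n_votes <- rowSums(votes)
  never <- which(n_votes == 0)
  frac <- votes
  frac[n_votes > 0, ] <- votes[n_votes > 0, ] / n_votes[n_votes > 0]
  predicted <- rep(NA_integer_, n)
  seen <- n_votes > 0
  predicted[seen] <- as.integer(votes[seen, 2] > votes[seen, 1])  # tie -> 0
  ties <- which(seen & votes[, 1] == votes[, 2])
  wrong <- predicted != model$y01
  oob_error <- 100 * mean(wrong[seen])
  per_class <- vapply(0:1, function(cl) {
    sel <- seen & model$y01 == cl
    if (!any(sel)) return(NA_real_)
    100 * mean(wrong[sel])
  }, numeric(1))
  names(per_class) <- model$classes
  confusion <- table(truth = model$y[seen],
                     predicted = factor(model$classes[predicted[seen] + 1],
                                        levels = model$classes))
  structure(list(oob_error = oob_error, per_class_error = per_class,
                 confusion = confusion, votes = frac, predicted = predicted,
                 tie_subjects = ties, never_oob = never,
                 n_trees = length(model$trees)), class = "rf_report")
}

#' @export
print.rf_report <- function(x, ...) {
  cat(sprintf("<rf_report> OOB error %.1f%% (%d trees)\n", x$oob_error,
              x$n_trees))
  cat(sprintf("  per-class error: %s\n",
              paste(sprintf("%s %.1f%%", names(x$per_class_error),
                            x$per_class_error), collapse = ", ")))
  if (length(x$tie_subjects))
    cat(sprintf("  %d tied vote(s) broken to class %s\n",
                length(x$tie_subjects), names(x$per_class_error)[1]))
  if (length(x$never_oob))
    cat(sprintf("  %d subject(s) never out-of-sample\n", length(x$never_oob)))
  invisible(x)
}

#' Permutation variable importance (mean decrease in accuracy)
#'
#' For every predictor and tree: permute the predictor's values among that
#' tree's out-of-sample subjects, re-predict, and record the drop in
#' out-of-sample accuracy; the importance is the mean drop across trees
#' (raw accuracy fraction, not rescaled). Irrelevant predictors score ~0.
#'
#' @param model a [fit_balanced_forest()] fit.
#' @param seed RNG seed for the permutations (default: derived from the
#'   fit's seed when one was set).
#' @return data frame `(predictor, importance, rank)` sorted by decreasing
#'   importance.
#' @export
permutation_importance <- function(model, seed = NULL) {
  stopifnot(inherits(model, "balanced_rf"))
  if (is.null(seed) && !is.null(model$cfg$seed))
    seed <- child_seed(model$cfg$seed, 1)
  p <- ncol(model$X)
  with_seed(seed, {
    drop_sum <- numeric(p)
    n_used <- 0L
    for (t in seq_along(model$trees)) {
      o <- model$oob[[t]]
      if (length(o) < 2) next
      n_used <- n_used + 1L
      tree <- model$trees[[t]]
      base_acc <- mean(predict_cart(tree, model$X, o) == model$y01[o])
      for (j in seq_len(p)) {
        Xp <- model$X[o, , drop = FALSE]
        Xp[, j] <- Xp[sample.int(length(o)), j]
        perm_acc <- mean(predict_cart(tree, Xp, seq_along(o)) == model$y01[o])
        drop_sum[j] <- drop_sum[j] + (base_acc - perm_acc)
      }
    }
    imp <- drop_sum / n_used
    out <- data.frame(predictor = model$predictors, importance = imp)
    out <- out[order(-out$importance), ]
    out$rank <- seq_len(nrow(out))
    rownames(out) <- NULL
    out
  })
}
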