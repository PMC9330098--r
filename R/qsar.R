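# Ensemble random-forest QSAR. The classifier is a bag of forests: each
# member is trained on an independent seeded 90% row sample of the training
# set, and the ensemble predicts the majority class (strictly more than 50%
# of member votes = active). Hyperparameters (tree count and feature-block
# combination) are chosen by seeded stratified cross-validation.

#' Assemble the QSAR feature matrix from blocks
#'
#' Binds the physchem, Morgan-fingerprint and residue-contact blocks into a
#' single matrix, recording block membership per column. Block column order
#' is frozen; missing values are an error.
#'
#' @param features list from [compute_features()] (uses `physchem`, `morgan`).
#' @param plifs binary residue-contact matrix (columns = residues), or `NULL`.
#' @param residues residue columns to use (default [key_residues()]).
#' @param blocks which blocks to include.
#' @return numeric matrix with attribute `block` (character per column).
#' @export
assemble_feature_matrix <- function(features, plifs = NULL,
                                    residues = key_residues(),
                                    blocks = c("physchem", "morgan",
                                               "residue_contacts")) {
  parts <- list(); tags <- character(0)
  if ("physchem" %in% blocks) {
    parts$physchem <- features$physchem
    tags <- c(tags, rep("physchem", ncol(features$physchem)))
  }
  if ("morgan" %in% blocks) {
    parts$morgan <- features$morgan
    tags <- c(tags, rep("morgan", ncol(features$morgan)))
  }
  if ("residue_contacts" %in% blocks) {
    if (is.null(plifs)) stop("residue_contacts block requested without PLIFs")
    if (!all(residues %in% colnames(plifs)))
      stop("residue columns missing from PLIF matrix")
    parts$residue_contacts <- plifs[, residues, drop = FALSE]
    tags <- c(tags, rep("residue_contacts", length(residues)))
  }
  x <- do.call(cbind, parts)
  if (anyNA(x)) stop("feature matrix contains missing values")
  attr(x, "block") <- tags
  x
}

#' Random train/test split
#'
#' `floor(test_fraction * n)` rows go to the test set; the split is plain
#' random sampling, reproducible under `seed`.
#'
#' @param labels class labels (each class must have >= 2 members).
#' @param test_fraction fraction assigned to the test set (default 0.3).
#' @param seed integer seed.
#' @return list with integer index vectors `train` and `test`.
#' @export
split_train_test <- function(labels, test_fraction = 0.3, seed = 1) {
  n <- length(labels)
  if (any(table(labels) < 2)) stop("each class needs at least 2 records")
  if (length(unique(labels)) < 2) stop("both classes must be present")
  n_test <- floor(test_fraction * n)
  test <- if (n_test > 0) sort(with_seed(seed, sample.int(n, n_test))) else integer(0)
  list(train = setdiff(seq_len(n), test), test = test)
}

#' Stratified cross-validation folds
#'
#' @param labels class labels.
#' @param k number of folds.
#' @param seed integer seed.
#' @return integer fold assignment per row.
#' @export
make_cv_folds <- function(labels, k = 10, seed = 1) {
  if (any(table(labels) < k))
    stop("a class has fewer members than folds; stratification impossible")
  folds <- integer(length(labels))
  with_seed(seed, for (cl in unique(labels)) {
    idx <- sample(which(labels == cl))
    folds[idx] <- rep_len(seq_len(k), length(idx))
  })
  folds
}

rf_fit <- function(x, y, num_trees, seed) {
  ranger::ranger(x = x, y = factor(y, levels = c("inactive", "active")),
                 num.trees = num_trees, seed = seed, num.threads = 1)
}

rf_predict <- function(fit, x) {
  # fixed predict seed: ranger breaks tied tree votes randomly otherwise
  as.character(predict(fit, data = x, num.threads = 1,
                       seed = 1L)$predictions)
}

#' Enumerate feature-block combinations
#'
#' All non-empty subsets of the available blocks, ordered by size then
#' lexicographically (7 combinations for the three standard blocks).
#'
#' @param blocks character vector of block names.
#' @return list of character vectors.
#' @export
enumerate_block_combos <- function(blocks = c("physchem", "morgan",
                                              "residue_contacts")) {
  enumerate_signatures(blocks, 1, length(blocks))
}

#' Grid search over tree counts and feature blocks
#'
#' Evaluates every (tree count, block combination) pair by seeded stratified
#' k-fold cross-validation accuracy and returns the argmax; ties prefer
#' fewer trees, then fewer feature columns, then lexicographic block names.
#'
#' @param x feature matrix from [assemble_feature_matrix()].
#' @param y class labels.
#' @param trees_grid tree counts to try (default 100-1000 step 100).
#' @param block_combos list of block combinations (default all non-empty).
#' @param cv_folds number of CV folds (default 10).
#' @param seed integer seed.
#' @return list: `n_trees`, `blocks`, `cv_accuracy_mean`, `cv_accuracy_sd`,
#'   and the full `grid` data.frame.
#' @export
optimize_hyperparameters <- function(x, y,
                                     trees_grid = seq(100, 1000, by = 100),
                                     block_combos = NULL,
                                     cv_folds = 10, seed = 1) {
  tags <- attr(x, "block")
  if (is.null(tags)) stop("x must carry a block attribute")
  if (is.null(block_combos))
    block_combos <- enumerate_block_combos(unique(tags))
  folds <- make_cv_folds(y, cv_folds, seed)
  fit_seeds <- derive_seeds(seed + 1L,
                            length(trees_grid) * length(block_combos) * cv_folds)
  grid <- list(); s <- 0L
  for (combo in block_combos) for (nt in trees_grid) {
    cols <- tags %in% combo
    acc <- vapply(seq_len(cv_folds), function(f) {
      s <<- s + 1L
      fit <- rf_fit(x[folds != f, cols, drop = FALSE], y[folds != f],
                    nt, fit_seeds[s])
      mean(rf_predict(fit, x[folds == f, cols, drop = FALSE]) == y[folds == f])
    }, numeric(1))
    grid[[length(grid) + 1L]] <- data.frame(
      n_trees = nt, blocks = paste(sort(combo), collapse = "+"),
      n_features = sum(cols), cv_accuracy_mean = mean(acc),
      cv_accuracy_sd = sd(acc), stringsAsFactors = FALSE)
  }
  grid <- do.call(rbind, grid)
  ord <- order(-grid$cv_accuracy_mean, grid$n_trees, grid$n_features,
               grid$blocks)
  best <- grid[ord[1], ]
  list(n_trees = best$n_trees,
       blocks = strsplit(best$blocks, "+", fixed = TRUE)[[1]],
       cv_accuracy_mean = best$cv_accuracy_mean,
       cv_accuracy_sd = best$cv_accuracy_sd,
       grid = grid)
}

#' Train the random-forest ensemble
#'
#' `n_members` forests, each trained on an independent seeded
#' `bag_fraction` row sample drawn without replacement.
#'
#' @param x feature matrix (training rows).
#' @param y class labels.
#' @param n_trees trees per member (default 700).
#' @param n_members ensemble size (default 100).
#' @param bag_fraction fraction of training rows per member (default 0.9).
#' @param seed integer seed.
#' @param replace bag with replacement instead (default `FALSE`).
#' @return object of class `rf_ensemble`.
#' @export
train_ensemble <- function(x, y, n_trees = 700, n_members = 100,
                           bag_fraction = 0.9, seed = 1, replace = FALSE) {
  n <- nrow(x)
  bag_n <- floor(bag_fraction * n)
  seeds <- derive_seeds(seed, 2L * n_members)
  members <- vector("list", n_members)
  for (m in seq_len(n_members)) {
    rows <- with_seed(seeds[m], sample.int(n, bag_n, replace = replace))
    if (any(table(y[rows]) < 2) || length(unique(y[rows])) < 2)
      stop("bag contains fewer than 2 rows of a class; enlarge the training set")
    members[[m]] <- rf_fit(x[rows, , drop = FALSE], y[rows], n_trees,
                           seeds[n_members + m])
  }
  structure(list(members = members, n_trees = n_trees,
                 n_members = n_members, bag_fraction = bag_fraction,
                 feature_names = colnames(x), blocks = attr(x, "block"),
                 seed = seed),
            class = "rf_ensemble")
}

#' @export
print.rf_ensemble <- function(x, ...) {
  cat(sprintf("<rf_ensemble> %d members x %d trees, bag %.0f%%, %d features\n",
              x$n_members, x$n_trees, 100 * x$bag_fraction,
              length(x$feature_names)))
  invisible(x)
}

#' Majority-vote ensemble prediction
#'
#' The predicted class is active iff strictly more than 50% of the members
#' vote active; an exact 50% tie is inactive.
#'
#' @param model an `rf_ensemble`.
#' @param x feature matrix with the training columns.
#' @return data.frame: `compound_id`, `vote_fraction_active`,
#'   `predicted_label`.
#' @export
predict_majority <- function(model, x) {
  if (!identical(colnames(x), model$feature_names))
    stop("feature columns do not match the trained ensemble")
  votes <- vapply(model$members, function(m) rf_predict(m, x) == "active",
                  logical(nrow(x)))
  if (nrow(x) == 1L) votes <- matrix(votes, nrow = 1L)
  vf <- rowMeans(votes)
  data.frame(compound_id = rownames(x) %||% as.character(seq_len(nrow(x))),
             vote_fraction_active = vf,
             predicted_label = ifelse(vf > 0.5, "active", "inactive"),
             stringsAsFactors = FALSE)
}

#' Classification performance metrics
#'
#' Precision for actives = true actives / predicted actives; accuracy =
#' (true actives + true inactives) / all predictions. Precision is `NA`
#' (undefined), never 0, when a class is never predicted.
#'
#' @param predicted predicted labels.
#' @param truth true labels.
#' @return list of class `qsar_metrics`.
#' @export
evaluate_predictions <- function(predicted, truth) {
  stopifnot(length(predicted) == length(truth))
  pa <- sum(predicted == "active"); pi_ <- sum(predicted == "inactive")
  ta <- sum(predicted == "active" & truth == "active")
  ti <- sum(predicted == "inactive" & truth == "inactive")
  structure(list(true_actives = ta, true_inactives = ti,
                 predicted_actives = pa, predicted_inactives = pi_,
                 precision_active = if (pa > 0) ta / pa else NA_real_,
                 precision_inactive = if (pi_ > 0) ti / pi_ else NA_real_,
                 accuracy = (ta + ti) / length(truth)),
            class = "qsar_metrics")
}

#' @export
print.qsar_metrics <- function(x, ...) {
  cat(sprintf(
    "<qsar_metrics> accuracy %.3f | precision(active) %s (%d/%d) | precision(inactive) %s\n",
    x$accuracy,
    ifelse(is.na(x$precision_active), "NA", sprintf("%.3f", x$precision_active)),
    x$true_actives, x$predicted_actives,
    ifelse(is.na(x$precision_inactive), "NA", sprintf("%.3f", x$precision_inactive))))
  invisible(x)
}

#' Out-of-fold correctness of a single forest
#'
#' Cross-validated per-row prediction correctness on the training set,
#' needed by the reliability-density applicability domain.
#'
#' @param x training feature matrix.
#' @param y labels.
#' @param cv_folds folds (default 10).
#' @param n_trees trees (default 700).
#' @param seed integer seed.
#' @return logical vector per training row.
#' @export
cv_correctness <- function(x, y, cv_folds = 10, n_trees = 700, seed = 1) {
  folds <- make_cv_folds(y, cv_folds, seed)
  seeds <- derive_seeds(seed + 7L, cv_folds)
  correct <- logical(length(y))
  for (f in seq_len(cv_folds)) {
    fit <- rf_fit(x[folds != f, , drop = FALSE], y[folds != f],
                  n_trees, seeds[f])
    correct[folds == f] <-
      rf_predict(fit, x[folds == f, , drop = FALSE]) == y[folds == f]
  }
  correct
}
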