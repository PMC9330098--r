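# splits, hyperparameter grid, ensemble voting, metrics, applicability domain

make_xy <- function(n = 40, p = 6, seed = 1, separable = TRUE) {
  set.seed(seed)
  y <- rep(c("active", "inactive"), length.out = n)
  x <- matrix(rnorm(n * p), n, p)
  if (separable) x[, 1] <- x[, 1] + ifelse(y == "active", 3, -3)
  colnames(x) <- paste0("f", 1:p)
  rownames(x) <- paste0("r", 1:n)
  attr(x, "block") <- rep(c("physchem", "morgan"), length.out = p)
  list(x = x, y = y)
}

test_that("train/test split follows the floor rule and is seed-reproducible", {
  labels <- rep(c("active", "inactive"), each = 312)
  sp <- split_train_test(labels, 0.3, seed = 11)
  expect_length(sp$train, 437)
  expect_length(sp$test, 187)
  expect_identical(sort(c(sp$train, sp$test)), 1:624)
  expect_identical(sp, split_train_test(labels, 0.3, seed = 11))
  expect_length(split_train_test(labels, 0, seed = 1)$train, 624)
  expect_error(split_train_test(rep("active", 10)), "class")
})

test_that("stratified folds keep both classes in every fold", {
  labels <- rep(c("active", "inactive"), c(30, 26))
  folds <- make_cv_folds(labels, 5, seed = 2)
  for (f in 1:5)
    expect_identical(sort(unique(labels[folds == f])),
                     c("active", "inactive"))
  expect_error(make_cv_folds(rep(c("active", "inactive"), c(3, 30)), 5),
               "fewer")
})

test_that("grid search evaluates trees x block-combinations and is deterministic", {
  expect_length(enumerate_block_combos(), 7)
  d <- make_xy(n = 30)
  opt <- optimize_hyperparameters(d$x, d$y, trees_grid = c(20, 40),
                                  cv_folds = 3, seed = 4)
  expect_identical(nrow(opt$grid), 2L * 3L)   # 2 tree counts x 3 combos
  expect_gte(opt$cv_accuracy_mean, max(table(d$y)) / length(d$y))
  opt2 <- optimize_hyperparameters(d$x, d$y, trees_grid = c(20, 40),
                                   cv_folds = 3, seed = 4)
  expect_identical(opt$n_trees, opt2$n_trees)
  expect_identical(opt$blocks, opt2$blocks)
  # the default grid over three blocks spans 70 configurations
  d3 <- make_xy(n = 24, p = 6)
  attr(d3$x, "block") <- rep(c("physchem", "morgan", "residue_contacts"), 2)
  opt3 <- optimize_hyperparameters(d3$x, d3$y, cv_folds = 2, seed = 1)
  expect_identical(nrow(opt3$grid),
                   length(seq(100, 1000, by = 100)) * 7L)
})

test_that("ensemble votes match a brute-force member count and respect ties", {
  d <- make_xy(n = 30, separable = FALSE)
  model <- train_ensemble(d$x, d$y, n_trees = 50, n_members = 4, seed = 9)
  expect_length(model$members, 4)
  q <- make_xy(n = 16, seed = 99, separable = FALSE)$x
  pred <- predict_majority(model, q)
  member_votes <- sapply(model$members, function(m)
    as.character(predict(m, data = q, num.threads = 1,
                         seed = 1L)$predictions))
  vf <- rowMeans(member_votes == "active")
  expect_equal(pred$vote_fraction_active, unname(vf))
  expect_identical(pred$predicted_label,
                   unname(ifelse(vf > 0.5, "active", "inactive")))
  # exact 50-50 ties (if present) must be inactive
  if (any(vf == 0.5))
    expect_true(all(pred$predicted_label[vf == 0.5] == "inactive"))
  # member order is irrelevant; a single-member ensemble equals its member
  perm <- model; perm$members <- rev(perm$members)
  expect_equal(predict_majority(perm, q)$vote_fraction_active,
               pred$vote_fraction_active)
  one <- train_ensemble(d$x, d$y, n_trees = 50, n_members = 1, seed = 9)
  single <- as.character(predict(one$members[[1]], data = q,
                                 num.threads = 1, seed = 1L)$predictions)
  expect_identical(predict_majority(one, q)$predicted_label, unname(single))
  # reproducibility and column contract
  again <- train_ensemble(d$x, d$y, n_trees = 50, n_members = 4, seed = 9)
  expect_equal(predict_majority(again, q)$vote_fraction_active,
               pred$vote_fraction_active)
  expect_error(predict_majority(model, q[, c(2:6, 1)]), "columns")
})

test_that("performance metrics follow the precision/accuracy definitions", {
  pred <- c(rep("active", 10), rep("inactive", 10))
  truth <- c(rep("active", 9), rep("inactive", 11))
  m <- evaluate_predictions(pred, truth)
  expect_equal(m$precision_active, 0.9)
  expect_equal(m$accuracy, 19 / 20)
  perfect <- evaluate_predictions(truth, truth)
  expect_equal(perfect$accuracy, 1)
  none <- evaluate_predictions(rep("inactive", 5), rep("active", 5))
  expect_true(is.na(none$precision_active))
  for (i in 1:100) {
    set.seed(i)
    n <- sample(5:50, 1)
    p <- sample(c("active", "inactive"), n, replace = TRUE)
    t <- sample(c("active", "inactive"), n, replace = TRUE)
    got <- evaluate_predictions(p, t)
    want <- oracle_confusion(p, t)
    expect_equal(got$precision_active, want$precision_active)
    expect_equal(got$accuracy, want$accuracy)
  }
})

test_that("reliability is a kernel sum over correct neighbors", {
  set.seed(5)
  train <- matrix(rbinom(20 * 16, 1, 0.3), 20, 16)
  correct <- rep(TRUE, 20)
  queries <- rbind(train[1, ], 1 - train[1, ])
  rel <- rdn_reliability(train, correct, queries, bandwidth = 0.25)
  expect_gte(rel[1], rel[2])
  expect_identical(rdn_reliability(train, correct,
                                   matrix(0L, 1, 16))[1], 0)
  expect_error(rdn_reliability(train[0, ], logical(0), queries), "empty")
  # brute-force double-loop kernel sum
  h <- 0.25
  for (i in 1:30) {
    set.seed(i)
    tr <- matrix(rbinom(12 * 10, 1, 0.4), 12, 10)
    ok <- runif(12) < 0.7
    q <- matrix(rbinom(3 * 10, 1, 0.4), 3, 10)
    want <- vapply(1:3, function(k) {
      s <- 0
      for (j in 1:12) {
        inter <- sum(q[k, ] & tr[j, ]); uni <- sum(q[k, ] | tr[j, ])
        sim <- if (uni > 0) inter / uni else 0
        if (sim > 0 && ok[j]) s <- s + exp(-(1 - sim)^2 / (2 * h^2))
      }
      s
    }, numeric(1))
    expect_equal(rdn_reliability(tr, ok, q, h), want)
    # a new identical, correctly-predicted neighbor never lowers any score
    grown <- rdn_reliability(rbind(tr, q[1, ]), c(ok, TRUE), q, h)
    expect_true(all(grown >= rdn_reliability(tr, ok, q, h) - 1e-12))
  }
})

test_that("AD curve coverage shrinks monotonically with the cutoff", {
  preds <- data.frame(predicted_label = rep(c("active", "inactive"), 10),
                      reliability = seq(0, 1, length.out = 20))
  labels <- rep(c("active", "inactive"), 10)
  curve <- ad_curve(preds, labels, c(0, 0.3, 0.6, 0.9))
  expect_equal(curve$coverage[1], 1)
  expect_true(all(diff(curve$coverage) <= 0))
  expect_error(ad_curve(preds, labels, numeric(0)), "empty")
})
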