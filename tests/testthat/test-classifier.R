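make_toy <- function(n_groups = 10, poses = 3, seed = 1) {
  set.seed(seed)
  groups <- rep(sprintf("g%02d", seq_len(n_groups)), each = poses)
  labels <- rep(rep(c("agonist", "antagonist"), length.out = n_groups), each = poses)
  x <- matrix(rnorm(length(groups) * 4), ncol = 4)
  x[, 1] <- x[, 1] + 3 * (labels == "agonist")  # separable-ish
  list(x = x, labels = labels, groups = groups)
}

test_that("grouped folds never split a group and balance labels", {
  toy <- make_toy(10, 3)
  f <- grouped_stratified_folds(toy$labels, toy$groups, k = 5, seed = 1)
  expect_equal(sort(unique(f)), 1:5)
  # each group wholly inside one fold
  expect_true(all(tapply(f, toy$groups, function(v) length(unique(v))) == 1))
  # 10 equal groups over 5 folds: exactly 2 groups per fold, labels balanced
  expect_true(all(table(f) == 6))
  expect_true(all(table(f, toy$labels) == 3))
})

test_that("a dominant group occupies one fold and the no-split property holds", {
  groups <- c(rep("big", 30), rep(sprintf("s%d", 1:6), each = 5))
  labels <- c(rep("agonist", 30), rep(c("agonist", "antagonist"), 15))
  f <- grouped_stratified_folds(labels, groups, k = 5, seed = 2)
  expect_length(unique(f[groups == "big"]), 1L)
  expect_true(all(tapply(f, groups, function(v) length(unique(v))) == 1))
})

test_that("fewer groups than folds is an error", {
  expect_error(grouped_stratified_folds(c("agonist", "antagonist"),
                                        c("a", "b"), k = 5), "fewer groups")
})

test_that("stratification stays within the achievable (group-size) bound over random instances", {
  set.seed(7)
  for (rep in 1:100) {
    ng <- sample(6:15, 1)
    sizes <- sample(1:6, ng, replace = TRUE)
    glab <- sample(c("agonist", "antagonist"), ng, replace = TRUE)
    if (length(unique(glab)) < 2) glab[1:2] <- c("agonist", "antagonist")
    groups <- rep(sprintf("g%d", seq_len(ng)), sizes)
    labels <- rep(glab, sizes)
    k <- sample(2:4, 1)
    if (ng < k) next
    f <- grouped_stratified_folds(labels, groups, k = k, seed = rep)
    expect_true(all(tapply(f, groups, function(v) length(unique(v))) == 1))
    # per-fold positive counts deviate from the target by at most the
    # largest single-group class count (one group move's worth)
    pos_t <- sum(labels == "agonist") / k
    per_fold_pos <- vapply(1:k, function(ff) sum(labels[f == ff] == "agonist"), 0)
    bound <- max(tapply(labels == "agonist", groups, sum))
    expect_true(all(abs(per_fold_pos - pos_t) <= bound + 1e-9))
  }
})

test_that("greedy fold balance is close to the exhaustive optimum on tiny instances", {
  set.seed(21)
  for (rep in 1:20) {
    ng <- sample(4:7, 1); k <- 2
    sizes <- sample(1:4, ng, replace = TRUE)
    glab <- sample(c("agonist", "antagonist"), ng, replace = TRUE)
    if (length(unique(glab)) < 2) glab[1:2] <- c("agonist", "antagonist")
    groups <- rep(sprintf("g%d", seq_len(ng)), sizes)
    labels <- rep(glab, sizes)
    f <- grouped_stratified_folds(labels, groups, k = k, seed = rep)
    pos_t <- sum(labels == "agonist") / k
    dev_of <- function(assign_g) {
      ff <- assign_g[match(groups, sprintf("g%d", seq_len(ng)))]
      max(abs(vapply(1:k, function(j) sum(labels[ff == j] == "agonist"), 0) - pos_t))
    }
    # exhaustive search over all 2^ng group assignments
    best <- Inf
    for (code in 0:(2^ng - 1)) {
      a <- bitwAnd(bitwShiftR(code, seq_len(ng) - 1), 1) + 1
      if (length(unique(a)) < k) next
      best <- min(best, dev_of(a))
    }
    gf <- vapply(sprintf("g%d", seq_len(ng)), function(g) f[groups == g][1], 0L)
    got <- dev_of(gf)
    bound <- max(tapply(labels == "agonist", groups, sum))
    expect_lte(got, best + bound)
  }
})

test_that("training is deterministic, separable data fits, single class errors", {
  toy <- make_toy(10, 3)
  m1 <- train_rf(toy$x, toy$labels, trees = 100, seed = 3)
  m2 <- train_rf(toy$x, toy$labels, trees = 100, seed = 3)
  expect_identical(predict(m1, toy$x), predict(m2, toy$x))
  # linearly separable toy set: perfect training accuracy
  sep <- evaluate(predict(m1, toy$x, class = "agonist"), toy$labels)
  expect_equal(sep$accuracy, 1)
  expect_error(train_rf(toy$x, rep("agonist", nrow(toy$x))), "per class")
})

test_that("metrics match the closed-form confusion arithmetic", {
  # TP=3, FP=1, FN=1, TN=5
  scores <- c(rep(0.9, 3), rep(0.1, 1), 0.8, rep(0.2, 5))
  labels <- c(rep("agonist", 4), rep("antagonist", 6))
  m <- evaluate(scores, labels)
  expect_equal(m$precision, 0.75)
  expect_equal(m$recall, 0.75)
  expect_equal(m$f1, 0.75)
  expect_equal(m$accuracy, 0.8)
  # perfect ranking of 4 samples
  expect_equal(roc_auc(c(0.9, 0.8, 0.2, 0.1), c(TRUE, TRUE, FALSE, FALSE)), 1)
})

test_that("metrics agree with brute-force oracles on random prediction vectors", {
  set.seed(11)
  for (rep in 1:200) {
    n <- sample(10:60, 1)
    labels <- sample(c("agonist", "antagonist"), n, replace = TRUE)
    if (length(unique(labels)) < 2) labels[1:2] <- c("agonist", "antagonist")
    scores <- round(runif(n), 2)   # ties included
    m <- suppressWarnings(evaluate(scores, labels))
    o <- oracle_metrics(scores, labels)
    expect_equal(unlist(m[c("precision", "recall", "f1", "accuracy")]),
                 o, ignore_attr = TRUE)
    expect_equal(m$auc, oracle_auc(scores, labels))
    # F1 is the harmonic mean of precision and recall
    if (m$precision + m$recall > 0)
      expect_equal(m$f1, 2 / (1 / max(m$precision, 1e-12) + 1 / max(m$recall, 1e-12)),
                   tolerance = 1e-9)
  }
})

test_that("AUC of random scores converges to 0.5 and single-class labels error", {
  set.seed(5)
  labels <- rep(c("agonist", "antagonist"), 500)
  auc <- roc_auc(runif(1000), labels)
  expect_lt(abs(auc - 0.5), 0.05)
  expect_error(evaluate(runif(4), rep("agonist", 4)), "single class")
})

test_that("zero-denominator metrics warn and report 0", {
  # nothing predicted positive: precision has a zero denominator
  w <- capture_warnings(
    m <- evaluate(c(0.1, 0.2, 0.3, 0.4),
                  c("antagonist", "antagonist", "antagonist", "agonist")))
  expect_true(any(grepl("precision", w)))
  expect_equal(m$precision, 0)
  expect_equal(m$f1, 0)
})

test_that("grouped CV reports folds without leakage and sane metrics", {
  toy <- make_toy(12, 4, seed = 6)
  cv <- cross_validate(toy$x, toy$labels, toy$groups, k = 4, trees = 60, seed = 2)
  expect_equal(nrow(cv$per_fold), 4L)
  expect_true(all(unlist(cv$per_fold[, -1]) >= 0 & unlist(cv$per_fold[, -1]) <= 1))
  for (ff in 1:4) {
    tr <- unique(toy$groups[cv$folds != ff])
    te <- unique(toy$groups[cv$folds == ff])
    expect_length(intersect(tr, te), 0L)
  }
})

test_that("molecule probability is the mean over poses", {
  toy <- make_toy(10, 3)
  m <- train_rf(toy$x, toy$labels, trees = 80, seed = 4)
  pp <- predict(m, toy$x, class = "antagonist")
  for (g in unique(toy$groups)[1:4]) {
    rows <- toy$groups == g
    expect_equal(predict_molecule_probability(m, toy$x[rows, , drop = FALSE]),
                 mean(pp[rows]))
  }
  # single pose: that pose's probability
  expect_equal(predict_molecule_probability(m, toy$x[1, , drop = FALSE]), pp[1])
  expect_error(predict_molecule_probability(m, toy$x[0, , drop = FALSE]), "no poses")
  expect_error(predict(m, toy$x[, 1:2]), "mismatch")
})

test_that("the probability filter is boundary-inclusive and order-preserving", {
  expect_equal(filter_by_probability(c(0.83, 0.84, 0.95)), c(0.84, 0.95))
  expect_length(filter_by_probability(c(0.1, 0.2)), 0L)
  expect_equal(filter_by_probability(c(0.3, 0.1), threshold = 0), c(0.3, 0.1))
  df <- data.frame(id = 1:3, probability = c(0.9, 0.5, 0.84))
  expect_equal(filter_by_probability(df)$id, c(1L, 3L))
  expect_error(filter_by_probability(c(1.2)), "\\[0, 1\\]")
})
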