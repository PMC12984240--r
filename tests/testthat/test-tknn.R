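test_that("the default parameter bag enumerates 120 combinations", {
  bag <- knn_parameter_bag()
  expect_equal(nrow(bag), 120L)
  expect_equal(length(unique(bag$k)), 10L)
  expect_equal(length(unique(bag$distance)), 4L)
  expect_equal(length(unique(bag$weighting)), 3L)
  expect_false(anyDuplicated(bag) > 0)
})

test_that("kNN prediction follows the distance and tie rules", {
  # exact training point at zero distance
  X <- matrix(c(0, 0, 1, 1, 5, 5), ncol = 2, byrow = TRUE)
  y <- c("a", "b", "c")
  expect_equal(knn_predict(X, y, X[2, , drop = FALSE], k = 1), "b")

  # 1-D cityblock example: neighbors of 1.6 among {0,1,2,3,4} are 1, 2, 3
  X1 <- matrix(0:4, ncol = 1)
  y1 <- c("A", "A", "B", "B", "B")
  expect_equal(knn_predict(X1, y1, matrix(1.6), k = 3,
                           distance = "cityblock"), "B")

  # cosine is scale invariant in the test vector
  set.seed(31)
  Xt <- matrix(rnorm(40), 10, 4)
  yt <- rep(c("p", "q"), 5)
  te <- matrix(rnorm(8), 2, 4)
  expect_equal(knn_predict(Xt, yt, te, k = 3, distance = "cosine"),
               knn_predict(Xt, yt, 10 * te, k = 3, distance = "cosine"))

  # vote ties break toward the smallest label
  Xe <- matrix(c(0, 2), ncol = 1)
  expect_equal(knn_predict(Xe, c("z", "a"), matrix(1), k = 2), "a")

  expect_error(knn_predict(X1, y1, matrix(1), k = 9), "parameter error")
})

test_that("kNN agrees with brute-force enumeration across the bag", {
  set.seed(17)
  train <- matrix(rnorm(30 * 5), 30, 5)
  ytr <- sample(c("good", "bad"), 30, replace = TRUE)
  test <- matrix(rnorm(6 * 5), 6, 5)
  bag <- knn_parameter_bag(k = c(1, 3, 7))
  for (ci in seq_len(nrow(bag))) {
    got <- knn_predict(train, ytr, test, bag$k[ci], bag$distance[ci],
                       bag$weighting[ci])
    want <- vapply(seq_len(nrow(test)), function(i)
      brute_force_knn(train, ytr, test[i, ], bag$k[ci], bag$distance[ci],
                      bag$weighting[ci]), character(1))
    expect_equal(got, want,
                 label = sprintf("combo %d (%s/%s/k=%d)", ci,
                                 bag$distance[ci], bag$weighting[ci], bag$k[ci]))
  }
})

test_that("spearman distance treats constant vectors as uncorrelated", {
  train <- rbind(c(1, 1, 1), c(1, 2, 3))
  D <- tensorcsbp:::pairwise_distances(matrix(c(3, 2, 1), 1), train, "spearman")
  expect_equal(D[1, 1], 1)       # constant vector: correlation defined as 0
  expect_equal(D[1, 2], 2)       # perfectly anti-correlated
})

test_that("cross-validated outcomes cover the bag with sane accuracies", {
  set.seed(23)
  n <- 40
  y <- rep(c("a", "b"), each = n / 2)
  X <- matrix(rnorm(n * 3), n, 3) + ifelse(y == "a", 0, 6)
  cv <- crossval_outcomes(X, y, folds = 5, seed = 1)
  expect_equal(ncol(cv$outP), 120L)
  expect_true(all(cv$acc >= 0 & cv$acc <= 1))
  expect_true(any(cv$acc == 1))                  # separable clusters
  expect_equal(length(cv$fold), n)
  # deterministic given the seed; every class reaches every fold
  cv2 <- crossval_outcomes(X, y, folds = 5, seed = 1)
  expect_identical(cv2$outP, cv$outP)
  expect_true(all(table(y, cv$fold) > 0))
  expect_error(crossval_outcomes(X[1:3, ], c("a", "a", "b"), folds = 2),
               "fewer than 2")
})

test_that("iterative majority voting takes per-sample modes", {
  out <- cbind(c(1L, 1L, 2L), c(1L, 2L, 2L), c(2L, 1L, 2L))
  imv <- iterative_majority_voting(out, y_code = c(1L, 1L, 2L), nlev = 2L)
  expect_equal(ncol(imv$outV), 1L)
  expect_equal(imv$outV[, 1], c(1L, 1L, 2L))     # (1,1,2)->1, (1,2,1)->1, ...
  expect_equal(imv$acc, 1)
  # unanimity: identical outcomes vote to themselves
  same <- matrix(rep(c(1L, 2L, 1L), 5), ncol = 5)
  imv2 <- iterative_majority_voting(same, c(1L, 2L, 1L), 2L)
  expect_true(all(imv2$outV == c(1L, 2L, 1L)))
  expect_error(iterative_majority_voting(out[, 1:2], c(1L, 1L, 2L), 2L),
               "parameter error")
})

test_that("tkNN produces 2 NP - 2 outcomes and greedily selects the max", {
  set.seed(29)
  y <- rep(c("a", "b"), each = 15)
  X <- matrix(rnorm(30 * 4), 30, 4) + ifelse(y == "a", 0, 2)
  fit <- tknn(X, y, folds = 5, seed = 2)
  expect_equal(length(fit$accP), 120L)
  expect_equal(length(fit$accV), 118L)
  expect_equal(fit$final$accuracy, max(c(fit$accP, fit$accV)))
  expect_gte(fit$final$accuracy, max(fit$accP))
  expect_equal(fit$final$index, greedy_final(c(fit$accP, fit$accV)))
  # a smaller bag still yields 2 NP - 2 outcomes
  small <- tknn(X, y, bag = knn_parameter_bag(k = 1:2,
                                              distances = "euclidean"),
                folds = 5, seed = 2)
  expect_equal(length(small$accP) + length(small$accV), 2 * 6 - 2)
  expect_error(greedy_final(numeric(0)), "no outcomes")
})

test_that("confusion metrics match direct formula evaluation", {
  # confusion TP=50 FN=10 FP=5 TN=35 with positive class "pos"
  y <- c(rep("pos", 60), rep("neg", 40))
  yhat <- c(rep("pos", 50), rep("neg", 10), rep("pos", 5), rep("neg", 35))
  m <- confusion_metrics(y, yhat, positive = "pos")
  expect_equal(m$accuracy, 0.85)
  expect_equal(m$sensitivity, 50 / 60, tolerance = 1e-4)
  expect_equal(m$specificity, 0.875)
  expect_equal(m$precision, 50 / 55, tolerance = 1e-4)
  expect_equal(m$f1, 0.8696, tolerance = 1e-4)
  expect_equal(m$gmean, 0.8539, tolerance = 1e-4)
  expect_false(m$degenerate)

  perfect <- confusion_metrics(c(1, 2, 1), c(1, 2, 1))
  for (nm in c("accuracy", "sensitivity", "specificity", "precision",
               "f1", "gmean"))
    expect_equal(perfect[[nm]], 1)

  # all-one-class prediction on balanced labels collapses specificity
  deg <- confusion_metrics(rep(c("a", "b"), 10), rep("a", 20), positive = "a")
  expect_equal(deg$accuracy, 0.5)
  expect_equal(deg$specificity, 0)
  # from the other class's viewpoint precision is 0/0: flagged as 0
  expect_warning(
    deg2 <- confusion_metrics(rep(c("a", "b"), 10), rep("a", 20),
                              positive = "b"))
  expect_equal(deg2$precision, 0)
  expect_true(deg2$degenerate)
  expect_error(confusion_metrics(character(0), character(0)),
               "parameter error")
})
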