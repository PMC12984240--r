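# The worked two-channel signal used throughout: rows alternate between the
# channels so the center-symmetric differences flip sign window by window.
worked_signal <- matrix(c(1, 0, 0, 1, 2, 0, 0, 2, 3, 0, 0, 3, 4, 0, 0, 4, 5, 0),
                        ncol = 2, byrow = TRUE)

test_that("windowing yields L - 7 step-1 windows and rejects short input", {
  expect_length(make_windows(matrix(rnorm(8 * 3), 8, 3)), 1L)
  w <- make_windows(matrix(1:9, ncol = 1))
  expect_length(w, 2L)
  expect_equal(as.vector(w[[1]]), 1:8)
  expect_equal(as.vector(w[[2]]), 2:9)
  expect_length(make_windows(matrix(rnorm(3840 * 2), ncol = 2)), 3833L)
  expect_error(make_windows(matrix(1:7, ncol = 1)), "at least 8")
})

test_that("center-symmetric differences match the defining formula", {
  w <- make_windows(worked_signal[1:8, ])[[1]]
  D <- center_symmetric_differences(w)
  expect_equal(unname(D),
               matrix(c(1, -4, -4, 1, 2, -3, -3, 2), ncol = 2, byrow = TRUE))

  # all-equal window: zero differences
  expect_equal(unname(center_symmetric_differences(matrix(5, 8, 3))),
               matrix(0, 4, 3))

  # time reversal negates every difference vector
  set.seed(7)
  win <- matrix(rnorm(8 * 4), 8, 4)
  expect_equal(center_symmetric_differences(win[8:1, ]),
               -center_symmetric_differences(win))
})

test_that("rank transform sorts descending with smallest-index ties", {
  expect_equal(rank_transform(c(1, -4)), c(1L, 2L))
  expect_equal(rank_transform(c(-3, 2)), c(2L, 1L))
  expect_equal(rank_transform(rep(0, 5)), 1:5)
  expect_equal(rank_transform(c(2, 5, 5, 1)), c(2L, 3L, 1L, 4L))
  expect_error(rank_transform(c(1, NaN)), "invalid value")
})

test_that("transformed signals match the hand-traced worked example", {
  ts <- build_transformed_signals(worked_signal)
  expect_equal(ts$T[[1]], c(1L, 2L, 2L, 1L))
  expect_equal(ts$T[[2]], c(2L, 1L, 1L, 2L))
  expect_equal(ts$T[[3]], c(1L, 2L, 2L, 1L))
  expect_equal(ts$T[[4]], c(2L, 1L, 1L, 2L))

  const <- build_transformed_signals(matrix(3, 10, 2))
  for (k in 1:4) expect_equal(const$T[[k]], rep(c(1L, 2L), 3))
})

test_that("every Nc-block of a transformed signal is a permutation", {
  set.seed(11)
  for (rep in 1:5) {
    Nc <- sample(2:5, 1)
    L <- sample(8:24, 1)
    ts <- build_transformed_signals(matrix(rnorm(L * Nc), L, Nc))
    for (k in 1:4) {
      blocks <- matrix(ts$T[[k]], nrow = Nc)
      expect_equal(ncol(blocks), L - 7L)
      expect_true(all(apply(blocks, 2, function(b) identical(sort(b), 1:Nc))))
    }
  }
})

test_that("transition matrices count adjacent pairs with conserved totals", {
  expect_equal(transition_matrix(c(1, 2, 2, 1), 2),
               matrix(c(0, 1, 1, 1), 2, byrow = TRUE))
  expect_equal(transition_matrix(c(1, 2, 1, 2, 1, 2), 2),
               matrix(c(0, 3, 2, 0), 2, byrow = TRUE))
  expect_equal(transition_matrix(3, 4), matrix(0L, 4, 4))
  expect_error(transition_matrix(c(1, 5, 2), 4), "position 2")

  set.seed(3)
  s <- sample(1:6, 200, replace = TRUE)
  expect_equal(sum(transition_matrix(s, 6)), 199)
})

test_that("feature vectors have length 4 Nc^2 and match the worked flatten", {
  expect_length(extract_features(matrix(rnorm(20 * 32), 20, 32)), 4096L)
  expect_length(extract_features(matrix(rnorm(20 * 14), 20, 14)), 784L)
  expect_equal(extract_features(worked_signal),
               c(0, 1, 1, 1, 1, 1, 1, 0, 0, 1, 1, 1, 1, 1, 1, 0))
})

test_that("features are invariant under positive scaling and global offset", {
  set.seed(21)
  for (rep in 1:5) {
    sig <- matrix(rnorm(40 * 4), 40, 4)
    ff <- extract_features(sig)
    expect_equal(extract_features(3.7 * sig + 100), ff)
    expect_equal(extract_features(0.02 * sig - 5), ff)
  }
})

test_that("extract_features matches the literal brute-force oracle", {
  set.seed(5)
  for (rep in 1:25) {
    Nc <- sample(2:4, 1)
    L <- sample(8:30, 1)
    sig <- matrix(rnorm(L * Nc), L, Nc)
    expect_equal(extract_features(sig), brute_force_features(sig))
  }
})

test_that("feature matrices stack per-segment vectors deterministically", {
  set.seed(13)
  seg <- matrix(rnorm(20 * 14), 20, 14)
  X <- extract_feature_matrix(list(seg, seg, matrix(rnorm(20 * 14), 20, 14)))
  expect_equal(dim(X), c(3L, 784L))
  expect_equal(X[1, ], X[2, ])
  # each row sums to 4 * (Nc * (L - 7) - 1)
  expect_true(all(rowSums(X) == 4 * (14 * 13 - 1)))
  expect_error(extract_feature_matrix(list(seg, matrix(1:14, 1, 14))),
               "segment 2")
})

test_that("feature matrix CSV round trip preserves values and header", {
  X <- extract_feature_matrix(list(matrix(rnorm(24), 12, 2)))
  p <- withr::local_tempfile(fileext = ".csv")
  write_feature_matrix(X, p)
  back <- read_feature_matrix(p)
  expect_equal(unname(back), unname(X))
  expect_equal(colnames(back)[1:2], c("f1", "f2"))
})
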