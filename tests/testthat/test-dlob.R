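dlob_file <- system.file("extdata", "dlob_sentence.txt", package = "tensorcsbp")
hemi_file <- system.file("extdata", "hemispheric_sentence.txt",
                         package = "tensorcsbp")

test_that("feature indices decode to channel pairs on one shared grid", {
  expect_equal(unname(feature_index_to_channels(1, 32)), cbind(1L, 1L))
  expect_equal(unname(feature_index_to_channels(34, 32)), cbind(2L, 2L))
  expect_equal(unname(feature_index_to_channels(1025, 32)), cbind(1L, 1L))
  # the four transition matrices collapse onto the same channel grid
  set.seed(41)
  f <- sample(32^2, 20)
  base <- feature_index_to_channels(f, 32)
  for (m in 1:3)
    expect_equal(feature_index_to_channels(f + m * 32^2, 32), base)
  expect_error(feature_index_to_channels(4 * 32^2 + 1, 32), "domain error")
  expect_error(feature_index_to_channels(0, 32), "domain error")
})

test_that("the montage-derived LUT follows 10-20 naming conventions", {
  lut <- default_channel_lut(c("Fp1", "AF4", "F7", "FC2", "Cz", "T7", "TP10",
                               "CP5", "P8", "POz", "O1", "Oz", "A2"))
  expect_equal(unname(lut),
               c("FL", "FR", "FL", "FR", "Cz", "TL", "TR",
                 "CL", "PR", "Pz", "OL", "Oz", "AR"))
  expect_error(default_channel_lut("XX"), "supply a LUT")
})

test_that("symbol sequences pair the row and column channel of each feature", {
  lut <- c("FL", "FR", "Cz", "Pz")
  # feature 2 of a 4-channel grid is channel pair (1, 2)
  expect_equal(generate_symbol_sequence(2, lut, 4), c("FL", "FR"))
  expect_equal(generate_symbol_sequence(1, lut, 4), c("FL", "FL"))
  expect_equal(generate_symbol_sequence(integer(0), lut, 4), character(0))
  seq <- generate_symbol_sequence(c(5, 16, 33), lut, 4)
  expect_length(seq, 6L)
  expect_error(generate_symbol_sequence(1, lut[1:2], 4), "LUT covers")
})

test_that("sequence generation and tokenization are mutually inverse", {
  set.seed(43)
  lut <- default_channel_lut(c("F3", "F4", "C3", "C4", "P3", "P4", "O1", "O2"))
  inS <- sample(4 * 64, 50)
  seq <- generate_symbol_sequence(inS, lut, 8)
  expect_equal(tokenize_sentence(paste(seq, collapse = "")), seq)
})

test_that("tokenization validates structure and reports offsets", {
  expect_equal(tokenize_sentence("FLFRPz"), c("FL", "FR", "Pz"))
  expect_error(tokenize_sentence("FLF"), "odd")
  expect_error(tokenize_sentence("FLXX"), "offset 3")
})

test_that("hemispheric sequences take second letters, length preserved", {
  expect_equal(hemispheric_sequence(c("FL", "FR", "Pz")), c("L", "R", "z"))
  expect_equal(hemispheric_sequence(rep("Fz", 5)), rep("z", 5))
})

test_that("histograms and transition matrices satisfy their totals", {
  seq <- c("FL", "FL", "FR")
  h <- sequence_histogram(seq)
  expect_equal(sum(h), 3L)
  expect_equal(unname(h[c("FL", "FR")]), c(2L, 1L), ignore_attr = TRUE)
  expect_equal(unname(h["Oz"]), 0L, ignore_attr = TRUE)
  expect_equal(sum(sequence_histogram(character(0))), 0L)

  tm <- sequence_transition_matrix(seq)
  expect_equal(tm["FL", "FL"], 1L)
  expect_equal(tm["FL", "FR"], 1L)
  expect_equal(sum(tm), 2L)
  expect_error(sequence_transition_matrix(c("FL", "QQ")), "domain error")

  # marginals differ from the histogram by at most one (end effects)
  set.seed(47)
  s <- sample(dlob_symbols(), 300, replace = TRUE)
  tm2 <- sequence_transition_matrix(s)
  h2 <- sequence_histogram(s)
  expect_true(all(abs(rowSums(tm2) - as.integer(h2)) <= 1))
  expect_true(all(abs(colSums(tm2) - as.integer(h2)) <= 1))
  expect_equal(sum(tm2), 299L)
})

test_that("entropy and complexity behave on canonical inputs", {
  expect_equal(shannon_entropy(c("R", "R", "L", "L")), 1)
  expect_equal(shannon_entropy(rep("FL", 9)), 0)
  expect_error(shannon_entropy(character(0)), "parameter error")
  uniform <- rep(dlob_symbols()[1:8], 10)
  expect_equal(complexity_ratio(uniform, 8), 1)
  expect_error(complexity_ratio("FL", 1), "parameter error")
  # entropy bounded by log2 of distinct symbols, equality iff uniform
  set.seed(53)
  s <- sample(c("L", "R", "z"), 100, replace = TRUE, prob = c(0.6, 0.3, 0.1))
  expect_lt(shannon_entropy(s), log2(3))
})

test_that("the published region sentence reproduces its summary statistics", {
  toks <- tokenize_sentence(readLines(dlob_file, warn = FALSE))
  expect_length(toks, 1212L)
  expect_equal(length(unique(toks)), 14L)
  h <- sequence_histogram(toks)
  expect_equal(unname(h["FL"]), 188L, ignore_attr = TRUE)
  expect_equal(unname(h["FR"]), 193L, ignore_attr = TRUE)
  expect_equal(shannon_entropy(toks), 3.5675, tolerance = 1e-4)
  expect_equal(complexity_ratio(toks, 14), 0.9370, tolerance = 5e-4)
  expect_equal(sequence_transition_matrix(toks)["FR", "FR"], 51L)

  hemi <- hemispheric_sequence(toks)
  expect_equal(paste(hemi, collapse = ""),
               readLines(hemi_file, warn = FALSE))
  hh <- sequence_histogram(hemi)
  expect_equal(as.integer(hh[c("R", "L", "z")]), c(531L, 501L, 180L))
  expect_equal(complexity_ratio(hemi, 3), 0.9193, tolerance = 5e-4)
})
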