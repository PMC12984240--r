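#' Overlapping eight-sample windows
#'
#' Splits an `L x Nc` signal into `W = L - 7` overlapping windows, each
#' holding eight consecutive sample rows; the step between windows is one
#' sample. Window `w` covers rows `w .. w+7`.
#'
#' @param signal Numeric `L x Nc` matrix (time by channels), `L >= 8`.
#' @return A list of `W` matrices, each `8 x Nc`.
#' @export
make_windows <- function(signal) {
  signal <- as_signal_matrix(signal)
  L <- nrow(signal)
  if (L < 8L)
    stop(sprintf("input too short: %d rows, at least 8 samples are required", L))
  lapply(seq_len(L - 7L), function(w) signal[w:(w + 7L), , drop = FALSE])
}

# Accept an eeg_recording or a plain matrix.
as_signal_matrix <- function(signal) {
  if (inherits(signal, "eeg_recording")) signal <- signal$samples
  signal <- as.matrix(signal)
  if (!is.numeric(signal)) stop("signal must be a numeric matrix")
  signal
}

#' Center-symmetric differences of an eight-sample window
#'
#' For an eight-row window with rows `V1..V8`, returns the four
#' center-symmetric difference vectors `Dk = Vk - V(9-k)` for `k = 1..4`,
#' elementwise per channel. Differencing symmetric positions contrasts the
#' two halves of the window at lags 7, 5, 3 and 1, so reversing the window
#' in time negates every `Dk`.
#'
#' @param win An `8 x Nc` matrix (one window from [make_windows()]).
#' @return A `4 x Nc` matrix whose row `k` is `Dk`.
#' @export
center_symmetric_differences <- function(win) {
  win <- as.matrix(win)
  if (nrow(win) != 8L) stop("a window must have exactly 8 rows")
  win[1:4, , drop = FALSE] - win[8:5, , drop = FALSE]
}

#' Descending-rank channel transformation
#'
#' Returns the 1-based channel indices of a difference vector sorted by
#' descending value; ties are broken toward the smaller channel index
#' (stable descending sort), so a constant vector maps to `1..Nc`.
#'
#' @param d Numeric vector of per-channel differences (finite values).
#' @return Integer permutation of `1..length(d)`.
#' @export
#' @examples
#' rank_transform(c(1, -4))   # 1 2
#' rank_transform(c(-3, 2))   # 2 1
rank_transform <- function(d) {
  if (anyNA(d) || any(!is.finite(d)))
    stop("invalid value: difference vector contains NaN/NA/Inf")
  order(-d, seq_along(d))
}

#' Transformed rank signals of a multichannel signal
#'
#' Applies the window / center-symmetric difference / descending-rank steps
#' over every window of the signal and concatenates the rank blocks in time
#' order: `Tk` is the length `Nc * (L - 7)` integer sequence whose `w`-th
#' block of `Nc` entries is the descending-rank permutation of `Dk` in window
#' `w`. Every block is a permutation of `1..Nc`, which makes the transform
#' invariant under positive scaling and global offset of the signal.
#'
#' @param signal Numeric `L x Nc` matrix or [eeg_recording], `L >= 8`.
#' @return List with `T` (list of 4 integer sequences), `Nc` and `W = L - 7`.
#' @export
build_transformed_signals <- function(signal) {
  signal <- as_signal_matrix(signal)
  L <- nrow(signal)
  Nc <- ncol(signal)
  if (L < 8L)
    stop(sprintf("input too short: %d rows, at least 8 samples are required", L))
  if (anyNA(signal) || any(!is.finite(signal)))
    stop("invalid value: signal contains NaN/NA/Inf")
  W <- L - 7L
  T <- vector("list", 4L)
  idx <- seq_len(Nc)
  for (k in 1:4) {
    # D_k over all windows at once: rows w .. w+W-1 at offsets k-1 and 8-k
    Dk <- signal[k:(k + W - 1L), , drop = FALSE] -
      signal[(9L - k):(8L - k + W), , drop = FALSE]
    ranks <- vapply(seq_len(W), function(w) order(-Dk[w, ], idx), integer(Nc))
    T[[k]] <- as.vector(ranks)      # column-stacked = window-by-window blocks
  }
  list(T = T, Nc = Nc, W = W)
}

#' Transition count matrix of an integer sequence
#'
#' Counts adjacent ordered pairs: starting from the all-zero `Nc x Nc`
#' matrix, each consecutive pair `(seq[a], seq[a+1])` increments entry
#' `(seq[a], seq[a+1])`. Adjacency runs across the full sequence, so counts
#' span window boundaries when the input is a concatenated rank signal.
#'
#' @param seq Integer sequence with entries in `1..Nc`, length at least 1.
#' @param Nc Alphabet size (number of channels).
#' @return `Nc x Nc` matrix of non-negative integer counts summing to
#'   `length(seq) - 1`.
#' @export
#' @examples
#' transition_matrix(c(1, 2, 2, 1), 2)   # rbind(c(0,1), c(1,1))
transition_matrix <- function(seq, Nc) {
  seq <- as.integer(seq)
  if (length(seq) < 1L) stop("sequence must have length at least 1")
  bad <- which(is.na(seq) | seq < 1L | seq > Nc)
  if (length(bad) > 0L)
    stop(sprintf("domain error: symbol out of 1..%d at position %d", Nc, bad[1L]))
  if (length(seq) == 1L) return(matrix(0L, Nc, Nc))
  a <- seq[-length(seq)]
  b <- seq[-1L]
  counts <- tabulate((a - 1L) * Nc + b, nbins = Nc * Nc)
  matrix(counts, Nc, Nc, byrow = TRUE)
}

#' TensorCSBP feature vector of one segment
#'
#' The full extractor: builds the four transformed rank signals, counts each
#' one's transition matrix, flattens each matrix row-major (entry `(w, u)` at
#' position `(w-1) * Nc + u`) and concatenates the four flattenings. The
#' result has length `4 * Nc^2` (4096 for a 32-channel montage, 784 for 14
#' channels) and consists of raw integer counts; any normalization is left to
#' the selection stage.
#'
#' @param signal Numeric `L x Nc` matrix or [eeg_recording], `L >= 8`.
#' @return Integer feature vector of length `4 * Nc^2`.
#' @export
extract_features <- function(signal) {
  ts <- build_transformed_signals(signal)
  unlist(lapply(ts$T, function(s) as.vector(t(transition_matrix(s, ts$Nc)))),
         use.names = FALSE)
}

#' TensorCSBP feature matrix of a segment set
#'
#' Applies [extract_features()] to every segment, in order. Row `s` of the
#' result is the feature vector of segment `s`.
#'
#' @param segments A [segment_set] or plain list of matrices/recordings.
#' @return `Ns x 4*Nc^2` numeric matrix with columns named `f1..f4Nc2`.
#' @export
extract_feature_matrix <- function(segments) {
  segs <- if (inherits(segments, "segment_set")) segments$segments else segments
  if (length(segs) == 0L) stop("no segments to extract features from")
  rows <- vector("list", length(segs))
  for (s in seq_along(segs)) {
    rows[[s]] <- tryCatch(extract_features(segs[[s]]),
                          error = function(e)
                            stop(sprintf("segment %d: %s", s, conditionMessage(e)),
                                 call. = FALSE))
  }
  X <- do.call(rbind, rows)
  colnames(X) <- paste0("f", seq_len(ncol(X)))
  X
}

#' Write / read a feature matrix as CSV
#'
#' Plain-text interchange for feature matrices: a header row of feature
#' indices `f1..f4Nc2`, one row per segment.
#'
#' @param X Feature matrix (rows = segments).
#' @param path File path.
#' @return `path` invisibly (write) or the feature matrix (read).
#' @export
write_feature_matrix <- function(X, path) {
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  utils::write.csv(X, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(path) {
  as.matrix(utils::read.csv(path, check.names = FALSE))
}
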