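#' The Directed Lobish symbol alphabet
#'
#' The 16 two-character brain-region symbols: first letter the lobe
#' (F frontal, T temporal, C central, P parietal, O occipital, A auditory),
#' second letter the hemisphere (L left, R right, z midline). A given
#' montage typically reaches only a subset (14 symbols for a 32-channel
#' frontal-through-occipital cap, which has no auditory electrodes and no
#' midline temporal/auditory sites).
#'
#' @return Character vector of the 16 symbols.
#' @export
dlob_symbols <- function() {
  c("FL", "FR", "Fz", "TL", "TR", "CL", "CR", "Cz",
    "PL", "PR", "Pz", "OL", "OR", "Oz", "AL", "AR")
}

hemisphere_symbols <- function() c("L", "R", "z")

# lobe-prefix table, longest prefixes first so FC/FT/TP/CP/PO resolve before
# their single-letter parents
lobe_prefixes <- c(Fp = "F", AF = "F", FC = "F", FT = "F", F = "F",
                   TP = "T", T = "T", CP = "C", C = "C",
                   PO = "P", P = "P", O = "O", A = "A")

#' Build a channel-to-symbol look-up table from 10-20 names
#'
#' Maps each montage label to a Directed Lobish symbol by convention: the
#' lobe comes from the leading letters (Fp/AF/F/FC/FT to F, T/TP to T,
#' C/CP to C, P/PO to P, O to O, A to A) and the hemisphere from the digit
#' parity (odd = left, even = right) or a trailing "z" (midline). The
#' FC/FT/CP/PO boundary assignments are a convention; supply an explicit
#' table where a different anatomical assignment is wanted.
#'
#' @param channel_names Character vector of 10-20 montage labels.
#' @return Named character vector: one symbol per channel, names are the
#'   channel labels.
#' @export
#' @examples
#' default_channel_lut(c("Fp1", "F4", "Cz", "PO10", "T7"))
default_channel_lut <- function(channel_names) {
  sym <- vapply(channel_names, function(ch) {
    hit <- NA_character_
    for (p in names(lobe_prefixes)) {
      if (startsWith(ch, p)) { hit <- lobe_prefixes[[p]]; break }
    }
    if (is.na(hit))
      stop(sprintf("cannot infer a lobe for channel '%s'; supply a LUT", ch))
    tail1 <- substring(ch, nchar(ch))
    hemi <- if (tail1 %in% c("z", "Z")) {
      "z"
    } else {
      digits <- regmatches(ch, regexpr("[0-9]+$", ch))
      if (length(digits) == 0L)
        stop(sprintf("cannot infer a hemisphere for channel '%s'; supply a LUT",
                     ch))
      if (as.integer(digits) %% 2L == 1L) "L" else "R"
    }
    paste0(hit, hemi)
  }, character(1L))
  bad <- setdiff(sym, dlob_symbols())
  if (length(bad) > 0L)
    stop(sprintf("derived symbol(s) outside the alphabet: %s",
                 paste(bad, collapse = ", ")))
  names(sym) <- channel_names
  sym
}

#' Read a channel-to-symbol table from a delimited file
#'
#' Two whitespace/comma/tab-separated columns: channel name, symbol.
#' Symbols are validated against the 16-symbol alphabet.
#'
#' @param path Path to the table.
#' @return Named character vector (names = channels, values = symbols).
#' @export
read_channel_lut <- function(path) {
  tab <- utils::read.table(path, header = FALSE, sep = "",
                           stringsAsFactors = FALSE,
                           col.names = c("channel", "symbol"))
  if (ncol(tab) != 2L) stop("LUT file must have two columns: channel, symbol")
  bad <- setdiff(tab$symbol, dlob_symbols())
  if (length(bad) > 0L)
    stop(sprintf("LUT contains symbols outside the alphabet: %s",
                 paste(bad, collapse = ", ")))
  stats::setNames(tab$symbol, tab$channel)
}

#' Decode a feature index into its channel pair
#'
#' The feature vector concatenates four row-major flattened `Nc x Nc`
#' transition matrices, so index `f` decodes to
#' `row = (floor((f - 1) / Nc) mod Nc) + 1` and `col = ((f - 1) mod Nc) + 1`;
#' the `mod Nc` collapses the four matrices onto one channel grid, so
#' `f`, `f + Nc^2`, `f + 2 Nc^2` and `f + 3 Nc^2` all decode to the same
#' pair.
#'
#' @param f Integer feature index (or vector of indices), `1 <= f <= 4 Nc^2`.
#' @param Nc Channel count.
#' @return Integer matrix with columns `row` and `col`, one row per index.
#' @export
#' @examples
#' feature_index_to_channels(34, 32)     # channel pair (2, 2)
#' feature_index_to_channels(1025, 32)   # wraps back to (1, 1)
feature_index_to_channels <- function(f, Nc) {
  f <- as.integer(f)
  if (any(is.na(f) | f < 1L | f > 4L * Nc^2))
    stop(sprintf("domain error: feature index out of 1..%d", 4L * Nc^2))
  cbind(row = ((f - 1L) %/% Nc) %% Nc + 1L,
        col = (f - 1L) %% Nc + 1L)
}

#' Directed Lobish sequence of a selected-feature set
#'
#' For each selected feature index (in order), decodes the channel pair and
#' appends the symbol of the row channel then the symbol of the column
#' channel, giving a sequence of length `2 * length(inS)`.
#'
#' @param inS Selected feature indices (1-based, in selection order).
#' @param lut Channel look-up table: character vector of symbols in channel
#'   order, or named by channel name (see [default_channel_lut()]); must
#'   cover all `Nc` channels.
#' @param Nc Channel count.
#' @return Character vector of two-character symbols.
#' @export
generate_symbol_sequence <- function(inS, lut, Nc) {
  if (length(inS) == 0L) return(character(0L))
  if (length(lut) < Nc)
    stop(sprintf("LUT covers %d channels but Nc = %d", length(lut), Nc))
  ch <- feature_index_to_channels(inS, Nc)
  as.vector(rbind(lut[ch[, "row"]], lut[ch[, "col"]]))
}

#' Tokenize a concatenated symbol sentence
#'
#' Splits a string of concatenated two-character Directed Lobish symbols
#' into its token sequence, validating every chunk against the alphabet.
#'
#' @param text The concatenated symbol string.
#' @return Character vector of symbols.
#' @export
#' @examples
#' tokenize_sentence("FLFRPz")
tokenize_sentence <- function(text) {
  text <- trimws(text)
  n <- nchar(text)
  if (n == 0L) return(character(0L))
  if (n %% 2L != 0L)
    stop(sprintf("parse error: sentence length %d is odd", n))
  toks <- substring(text, seq(1L, n, 2L), seq(2L, n, 2L))
  bad <- which(!toks %in% dlob_symbols())
  if (length(bad) > 0L)
    stop(sprintf("parse error: invalid symbol '%s' at offset %d",
                 toks[bad[1L]], 2L * (bad[1L] - 1L) + 1L))
  toks
}

#' Hemispheric sequence of a symbol sequence
#'
#' The second character of each symbol (L, R or z), order and length
#' preserved; summarizes lateralization.
#'
#' @param seq Character vector of two-character symbols.
#' @return Character vector over `{L, R, z}`.
#' @export
hemispheric_sequence <- function(seq) {
  substring(seq, 2L, 2L)
}

infer_alphabet <- function(seq) {
  if (length(seq) == 0L) return(dlob_symbols())
  if (all(nchar(seq) == 1L)) hemisphere_symbols() else dlob_symbols()
}

#' Symbol histogram of a sequence
#'
#' Occurrence counts per symbol; absent alphabet symbols are reported as 0,
#' and the counts sum to the sequence length.
#'
#' @param seq Symbol (or character) sequence.
#' @param alphabet Symbols to tabulate over; default: the full Directed
#'   Lobish alphabet for two-character sequences, `{L, R, z}` for
#'   single-character ones.
#' @return Named integer vector of counts.
#' @export
sequence_histogram <- function(seq, alphabet = infer_alphabet(seq)) {
  table(factor(seq, levels = alphabet))
}

#' Transition count matrix of a symbol sequence
#'
#' Counts consecutive ordered symbol pairs over the whole sequence (the
#' connectome matrix: entry `(a, b)` counts transitions `a -> b`); the total
#' equals the sequence length minus one.
#'
#' @inheritParams sequence_histogram
#' @return Square integer count matrix with alphabet dimnames.
#' @export
sequence_transition_matrix <- function(seq, alphabet = infer_alphabet(seq)) {
  bad <- which(!seq %in% alphabet)
  if (length(bad) > 0L)
    stop(sprintf("domain error: symbol '%s' at position %d is outside the alphabet",
                 seq[bad[1L]], bad[1L]))
  n <- length(alphabet)
  tm <- matrix(0L, n, n, dimnames = list(alphabet, alphabet))
  if (length(seq) >= 2L) {
    a <- match(seq[-length(seq)], alphabet)
    b <- match(seq[-1L], alphabet)
    counts <- tabulate((a - 1L) * n + b, nbins = n * n)
    tm <- matrix(counts, n, n, byrow = TRUE, dimnames = list(alphabet, alphabet))
  }
  tm
}

#' Shannon entropy of a symbol sequence
#'
#' `H = -sum p_s log2(p_s)` over the symbols with nonzero count, with
#' `p_s = count / length`; in bits.
#'
#' @param seq Non-empty symbol sequence.
#' @return Entropy in bits.
#' @export
#' @examples
#' shannon_entropy(c("R", "R", "L", "L"))   # 1 bit
shannon_entropy <- function(seq) {
  if (length(seq) == 0L) stop("parameter error: empty sequence")
  p <- as.numeric(table(seq)) / length(seq)
  -sum(p * log2(p))
}

#' Entropy-based complexity ratio
#'
#' Shannon entropy divided by its maximum `log2(alphabet_size)`; the
#' denominator uses the number of symbols the montage can actually produce
#' (the utilized alphabet), not the full 16-symbol alphabet.
#'
#' @param seq Non-empty symbol sequence.
#' @param alphabet_size Utilized alphabet size, at least 2; default: the
#'   number of distinct symbols in `seq`.
#' @return Ratio in `[0, 1]`.
#' @export
complexity_ratio <- function(seq, alphabet_size = length(unique(seq))) {
  if (alphabet_size < 2L)
    stop("parameter error: alphabet_size must be at least 2")
  shannon_entropy(seq) / log2(alphabet_size)
}

#' Full Directed Lobish explainability report
#'
#' Builds the complete symbolic summary of a symbol sequence: the
#' hemispheric sequence, both histograms, both transition (connectome)
#' matrices, entropies and complexity ratios. The complexity denominators
#' default to the utilized alphabet sizes (distinct symbols present in each
#' sequence).
#'
#' @param seq Character vector of two-character symbols (e.g. from
#'   [generate_symbol_sequence()] or [tokenize_sentence()]).
#' @param dlob_alphabet_size Denominator alphabet size for the symbol
#'   sequence; default: distinct symbols present.
#' @param hemi_alphabet_size Denominator for the hemispheric sequence;
#'   default: distinct hemisphere letters present.
#' @return Object of class `dlob_report`.
#' @export
dlob_report <- function(seq,
                        dlob_alphabet_size = max(2L, length(unique(seq))),
                        hemi_alphabet_size = NULL) {
  if (length(seq) == 0L) stop("parameter error: empty sequence")
  hemi <- hemispheric_sequence(seq)
  if (is.null(hemi_alphabet_size))
    hemi_alphabet_size <- max(2L, length(unique(hemi)))
  structure(list(
    sequence = seq,
    hemispheric = hemi,
    length = length(seq),
    symbol_histogram = sequence_histogram(seq, dlob_symbols()),
    hemispheric_histogram = sequence_histogram(hemi, hemisphere_symbols()),
    symbol_transitions = sequence_transition_matrix(seq, dlob_symbols()),
    hemispheric_transitions = sequence_transition_matrix(hemi,
                                                         hemisphere_symbols()),
    entropy = shannon_entropy(seq),
    hemispheric_entropy = shannon_entropy(hemi),
    complexity = complexity_ratio(seq, dlob_alphabet_size),
    hemispheric_complexity = complexity_ratio(hemi, hemi_alphabet_size),
    dlob_alphabet_size = dlob_alphabet_size,
    hemi_alphabet_size = hemi_alphabet_size,
    # occurrence counts per hemisphere letter; consecutive-pair counts of
    # left/right cross-talk are reported separately from the transition matrix
    cross_hemispheric = c(
      LR = unname(sequence_transition_matrix(hemi,
                                             hemisphere_symbols())["L", "R"]),
      RL = unname(sequence_transition_matrix(hemi,
                                             hemisphere_symbols())["R", "L"]))
  ), class = "dlob_report")
}

#' @export
print.dlob_report <- function(x, ...) {
  cat(sprintf("<dlob_report> %d symbols, %d utilized (%d hemispheric)\n",
              x$length, x$dlob_alphabet_size, x$hemi_alphabet_size))
  cat(sprintf("  entropy       %.4f bits, complexity %.4f\n",
              x$entropy, x$complexity))
  cat(sprintf("  hemispheric   %.4f bits, complexity %.4f\n",
              x$hemispheric_entropy, x$hemispheric_complexity))
  nz <- x$symbol_histogram[x$symbol_histogram > 0]
  cat("  histogram:", paste(sprintf("%s=%d", names(nz), as.integer(nz)),
                            collapse = " "), "\n")
  invisible(x)
}

#' Export an explainability report to JSON / CSV
#'
#' Writes the report's histograms, entropies and complexities as JSON and,
#' optionally, the two transition matrices as CSV alongside it.
#'
#' @param report A `dlob_report`.
#' @param path Output JSON path.
#' @param transitions_csv Also write `<path>_symbol.csv` and
#'   `<path>_hemispheric.csv` transition matrices (default TRUE).
#' @return `path`, invisibly.
#' @export
write_dlob_report <- function(report, path, transitions_csv = TRUE) {
  stopifnot(inherits(report, "dlob_report"))
  jsonlite::write_json(list(
    length = report$length,
    sentence = paste(report$sequence, collapse = ""),
    symbol_histogram = as.list(report$symbol_histogram),
    hemispheric_histogram = as.list(report$hemispheric_histogram),
    entropy = report$entropy,
    hemispheric_entropy = report$hemispheric_entropy,
    complexity = report$complexity,
    hemispheric_complexity = report$hemispheric_complexity,
    dlob_alphabet_size = report$dlob_alphabet_size,
    hemi_alphabet_size = report$hemi_alphabet_size,
    cross_hemispheric = as.list(report$cross_hemispheric)
  ), path, auto_unbox = TRUE, digits = NA)
  if (transitions_csv) {
    base <- sub("\\.json$", "", path)
    utils::write.csv(report$symbol_transitions,
                     paste0(base, "_symbol_transitions.csv"))
    utils::write.csv(report$hemispheric_transitions,
                     paste0(base, "_hemispheric_transitions.csv"))
  }
  invisible(path)
}
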