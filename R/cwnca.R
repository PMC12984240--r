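#' Per-sample min-max normalization
#'
#' Maps each row `d` of the feature matrix to
#' `(X[d, ] - min(X[d, ])) / (max(X[d, ]) - min(X[d, ]) + eps)`, so every
#' sample is rescaled by its own range. The small `eps` guards the division:
#' a constant row maps to all zeros. Note this is per sample-row, not the
#' conventional per-feature-column scaling; it normalizes each segment's
#' transition-count profile before features are compared across segments.
#'
#' @param X Numeric `Ns x F` matrix with finite entries.
#' @param eps Small positive guard added to the denominator (default 1e-12).
#' @return Matrix of the same shape with entries in `[0, 1)`.
#' @export
rowwise_minmax_normalize <- function(X, eps = 1e-12) {
  X <- as.matrix(X)
  if (anyNA(X) || any(!is.finite(X))) stop("X must have finite entries")
  rmin <- apply(X, 1L, min)
  rmax <- apply(X, 1L, max)
  (X - rmin) / (rmax - rmin + eps)
}

#' Neighborhood component analysis feature weights
#'
#' Learns one non-negative weight per feature by maximizing the
#' leave-one-out stochastic-neighbor objective. Sample distances are
#' weighted city-block distances with squared weights,
#' `d(i, j) = sum_f w_f^2 |x_if - x_jf|`; the probability that sample `i`
#' picks `j` as its neighbor is `p_ij = exp(-d_ij) / sum_{k != i} exp(-d_ik)`,
#' and the objective is the expected leave-one-out accuracy
#' `sum_i sum_{j: y_j = y_i} p_ij` minus an L2 penalty `lambda * sum w_f^2`.
#' Optimization is deterministic: all weights start at 1 and an adaptive-step
#' gradient ascent runs for at most `max_iter` iterations (the step grows
#' after an accepted move and is halved on rejection). The returned weights
#' are the squared coordinates, hence non-negative; with `max_iter = 0` the
#' initial weights are returned unchanged.
#'
#' @param X Numeric `Ns x F` matrix (typically row-normalized features).
#' @param y Class labels, at least two classes.
#' @param lambda L2 regularization strength; default `1 / nrow(X)`.
#' @param max_iter Iteration cap for the gradient ascent (default 100).
#' @param tol Stop when the objective improves by less than this (default 1e-8).
#' @return Numeric vector of `F` non-negative feature weights.
#' @export
nca_weights <- function(X, y, lambda = 1 / nrow(X), max_iter = 100L,
                        tol = 1e-8) {
  X <- as.matrix(X)
  Ns <- nrow(X)
  F_ <- ncol(X)
  if (Ns < 2L) stop("at least two samples are required")
  y <- as.character(y)
  if (length(y) != Ns) stop("'y' must have one label per row of X")
  if (length(unique(y)) < 2L)
    stop("degenerate labels: at least two classes are required")
  v <- rep(1, F_)
  if (max_iter <= 0L) return(v^2)

  # Pairwise per-feature absolute differences, one column per feature.
  A <- matrix(0, Ns * Ns, F_)
  for (f in seq_len(F_)) A[, f] <- abs(rep(X[, f], times = Ns) -
                                         rep(X[, f], each = Ns))
  same <- outer(y, y, "==")
  diag(same) <- FALSE

  objective_parts <- function(v) {
    d <- matrix(A %*% (v^2), Ns, Ns)          # d[j, i] layout (j varies fastest)
    diag(d) <- Inf
    # column-wise softmax of -d: p[j, i] = p_{i j}
    dmin <- apply(d, 2L, min)
    E <- exp(-(sweep(d, 2L, dmin)))
    E[!is.finite(E)] <- 0
    P <- sweep(E, 2L, colSums(E), "/")
    pi_i <- colSums(P * t(same))
    list(P = P, pi = pi_i,
         obj = sum(pi_i) - lambda * sum(v^2))
  }

  grad <- function(v, parts) {
    # coef[j, i] = p_i * p_ij - [y_i = y_j] p_ij  (maximize => ascend)
    coef <- sweep(parts$P, 2L, parts$pi, "*") - parts$P * t(same)
    g_inner <- as.vector(crossprod(A, as.vector(coef)))
    2 * v * g_inner - 2 * lambda * v
  }

  parts <- objective_parts(v)
  step <- 1
  for (it in seq_len(max_iter)) {
    g <- grad(v, parts)
    improved <- FALSE
    for (half in seq_len(30L)) {
      v_new <- v + step * g
      parts_new <- objective_parts(v_new)
      if (parts_new$obj > parts$obj) {
        improved <- TRUE
        break
      }
      step <- step / 2
    }
    if (!improved) break
    delta <- parts_new$obj - parts$obj
    v <- v_new
    parts <- parts_new
    step <- step * 1.2
    if (delta < tol) break
  }
  v^2
}

#' Cumulative-weight feature count
#'
#' Given non-negative weights and their descending order, returns the
#' smallest `m` such that the `m` largest weights hold at least `th` of the
#' total weight mass. With `th = 1` and strictly positive weights this is
#' the full feature count.
#'
#' @param wt Non-negative weights with positive sum.
#' @param ord Permutation ordering `wt` descending (default: stable
#'   descending order with ties toward the smaller index).
#' @param th Threshold in `(0, 1]` on the cumulative weight fraction.
#' @return Integer `of`, the selected feature count.
#' @export
#' @examples
#' cumulative_weight_count(c(0.7, 0.2, 0.1), th = 0.85)   # 2
cumulative_weight_count <- function(wt, ord = order(-wt, seq_along(wt)),
                                    th = 0.9999) {
  if (any(wt < 0)) stop("weights must be non-negative")
  total <- sum(wt)
  if (total <= 0) stop("degenerate weights: total weight mass is zero")
  if (th <= 0 || th > 1) stop("'th' must be in (0, 1]")
  frac <- cumsum(wt[ord]) / total
  hit <- which(frac >= th - 1e-12)
  if (length(hit) == 0L) length(wt) else hit[1L]
}

#' CWNCA feature selection
#'
#' The full selector: per-sample min-max normalization, NCA feature
#' weighting, stable descending ordering of the weights, cumulative-weight
#' choice of the feature count at threshold `th`, and materialization of the
#' selected columns. `inS` refers to the original column indices of `X`
#' (selection happens after row normalization, which leaves column positions
#' unchanged); `SX` holds the normalized values of the selected columns, as
#' the selection stage feeds the classifier normalized features.
#'
#' @param X Numeric `Ns x F` feature matrix (raw counts).
#' @param y Class labels.
#' @param th Cumulative-weight threshold in `(0, 1]`; default 0.9999.
#' @param eps Normalization guard, see [rowwise_minmax_normalize()].
#' @param ... Passed to [nca_weights()] (`lambda`, `max_iter`, `tol`).
#' @return Object of class `cwnca_selection`: list with `weights`, `order`,
#'   `of`, `inS`, `SX`, `th`.
#' @export
select_features <- function(X, y, th = 0.9999, eps = 1e-12, ...) {
  X <- as.matrix(X)
  Xn <- rowwise_minmax_normalize(X, eps = eps)
  wt <- nca_weights(Xn, y, ...)
  ord <- order(-wt, seq_along(wt))
  of <- cumulative_weight_count(wt, ord, th)
  inS <- ord[seq_len(of)]
  structure(list(weights = wt, order = ord, of = of, inS = inS,
                 SX = Xn[, inS, drop = FALSE], th = th),
            class = "cwnca_selection")
}

#' @export
print.cwnca_selection <- function(x, ...) {
  cat(sprintf("<cwnca_selection> %d of %d features at th = %g\n",
              x$of, length(x$weights), x$th))
  cat("top indices:", utils::head(x$inS, 10L),
      if (x$of > 10L) "..." else "", "\n")
  invisible(x)
}

#' Serialize a selection result to JSON
#'
#' Writes weights, ordering, the selected count and indices, and the
#' threshold, for the explainability stage and for audit.
#'
#' @param sel A `cwnca_selection` object.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_selection_json <- function(sel, path) {
  stopifnot(inherits(sel, "cwnca_selection"))
  jsonlite::write_json(
    list(th = sel$th, of = sel$of, inS = sel$inS,
         weights = sel$weights, order = sel$order),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
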