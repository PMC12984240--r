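#' Parameter bag for the kNN sweep
#'
#' Enumerates every combination of neighbor count, distance and vote
#' weighting used by the self-organizing kNN ensemble. With the defaults
#' (k = 1..10, four distances, three weightings) the bag holds
#' `NP = 120` combinations. Enumeration order is k outermost, then
#' distance, then weighting; this order breaks ties among equally accurate
#' outcomes deterministically.
#'
#' @param k Integer neighbor counts (default `1:10`).
#' @param distances Distance names among `"euclidean"`, `"spearman"`,
#'   `"cityblock"`, `"cosine"`.
#' @param weightings Vote weighting schemes among `"inverse"`,
#'   `"squared-inverse"`, `"equal"`.
#' @return Data frame with columns `k`, `distance`, `weighting`; one row per
#'   combination.
#' @export
knn_parameter_bag <- function(k = 1:10,
                              distances = c("euclidean", "spearman",
                                            "cityblock", "cosine"),
                              weightings = c("inverse", "squared-inverse",
                                             "equal")) {
  distances <- match.arg(distances, several.ok = TRUE)
  weightings <- match.arg(weightings, several.ok = TRUE)
  g <- expand.grid(weighting = weightings, distance = distances, k = k,
                   stringsAsFactors = FALSE)
  data.frame(k = g$k, distance = g$distance, weighting = g$weighting,
             stringsAsFactors = FALSE)
}

# Cross-distance matrix (rows = test samples, cols = train samples).
# spearman: 1 - rank correlation between the two feature vectors; a
# zero-variance vector has correlation defined as 0 (distance 1).
# cosine: 1 - cosine similarity; a zero vector has similarity 0.
pairwise_distances <- function(test_X, train_X,
                               distance = c("euclidean", "spearman",
                                            "cityblock", "cosine")) {
  distance <- match.arg(distance)
  A <- as.matrix(test_X)
  B <- as.matrix(train_X)
  if (ncol(A) != ncol(B)) stop("feature dimensions differ")
  switch(distance,
    euclidean = {
      d2 <- outer(rowSums(A^2), rep(1, nrow(B))) +
        outer(rep(1, nrow(A)), rowSums(B^2)) - 2 * tcrossprod(A, B)
      sqrt(pmax(d2, 0))
    },
    cityblock = {
      t(vapply(seq_len(nrow(A)),
               function(i) colSums(abs(t(B) - A[i, ])),
               numeric(nrow(B))))
    },
    cosine = {
      na <- sqrt(rowSums(A^2))
      nb <- sqrt(rowSums(B^2))
      S <- tcrossprod(A, B) / outer(pmax(na, .Machine$double.xmin),
                                    pmax(nb, .Machine$double.xmin))
      S[na == 0, ] <- 0
      if (any(nb == 0)) S[, nb == 0] <- 0
      1 - S
    },
    spearman = {
      Ra <- t(apply(A, 1L, rank))
      Rb <- t(apply(B, 1L, rank))
      if (ncol(A) == 1L) return(matrix(1, nrow(A), nrow(B)))
      Ca <- Ra - rowMeans(Ra)
      Cb <- Rb - rowMeans(Rb)
      da <- sqrt(rowSums(Ca^2))
      db <- sqrt(rowSums(Cb^2))
      S <- tcrossprod(Ca, Cb) / outer(pmax(da, .Machine$double.xmin),
                                      pmax(db, .Machine$double.xmin))
      S[da == 0, ] <- 0
      if (any(db == 0)) S[, db == 0] <- 0
      1 - S
    })
}

# Shared label coding: sorted unique levels; ties always break toward the
# first (smallest) level.
label_levels <- function(y) {
  if (is.factor(y)) levels(y) else as.character(sort(unique(y)))
}

vote_weights <- function(d, weighting, delta = 1e-12) {
  switch(weighting,
         equal = rep(1, length(d)),
         inverse = 1 / (d + delta),
         `squared-inverse` = 1 / (d + delta)^2,
         stop(sprintf("unknown weighting '%s'", weighting)))
}

# Predict from precomputed neighbor orderings: ord/ds are n_test x n_train
# (train indices sorted by increasing distance, earlier index first on ties).
predict_from_neighbors <- function(ord, ds, y_code, k, weighting, nlev,
                                   delta = 1e-12) {
  n <- nrow(ord)
  out <- integer(n)
  for (i in seq_len(n)) {
    nb <- ord[i, seq_len(k)]
    w <- vote_weights(ds[i, seq_len(k)], weighting, delta)
    tall <- numeric(nlev)
    cls <- y_code[nb]
    for (j in seq_len(k)) tall[cls[j]] <- tall[cls[j]] + w[j]
    out[i] <- which.max(tall)          # ties toward the smallest label
  }
  out
}

#' Weighted k-nearest-neighbor prediction
#'
#' Predicts test labels by (optionally distance-weighted) voting among the
#' `k` nearest training samples. Distance ties are broken toward the earlier
#' training index, vote ties toward the smallest label value.
#'
#' @param train_X,train_y Training feature matrix and labels.
#' @param test_X Test feature matrix.
#' @param k Neighbor count, at most `nrow(train_X)`.
#' @param distance One of `"euclidean"`, `"spearman"`, `"cityblock"`,
#'   `"cosine"`.
#' @param weighting One of `"inverse"`, `"squared-inverse"`, `"equal"`.
#' @param delta Guard added to distances in inverse weights (default 1e-12).
#' @return Character vector of predicted labels.
#' @export
knn_predict <- function(train_X, train_y, test_X, k,
                        distance = "euclidean", weighting = "equal",
                        delta = 1e-12) {
  train_X <- as.matrix(train_X)
  test_X <- as.matrix(test_X)
  if (k > nrow(train_X))
    stop(sprintf("parameter error: k = %d exceeds training size %d",
                 k, nrow(train_X)))
  lev <- label_levels(train_y)
  y_code <- match(as.character(train_y), lev)
  D <- pairwise_distances(test_X, train_X, distance)
  ord <- t(apply(D, 1L, function(d) order(d, seq_along(d))))
  ds <- t(vapply(seq_len(nrow(D)), function(i) D[i, ord[i, ]],
                 numeric(ncol(D))))
  if (nrow(test_X) == 1L) { ord <- matrix(ord, 1L); ds <- matrix(ds, 1L) }
  lev[predict_from_neighbors(ord, ds, y_code, k, weighting, length(lev),
                             delta)]
}

# Evaluate an expression under a fixed RNG state without disturbing the
# caller's stream.
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Stratified fold assignment: within each class, indices are shuffled and
# dealt round-robin, so every class reaches every training split whenever it
# has at least two members.
stratified_folds <- function(y, folds, seed) {
  y <- as.character(y)
  counts <- table(y)
  if (any(counts < 2L))
    stop(sprintf("folding error: class '%s' has fewer than 2 samples",
                 names(counts)[counts < 2L][1L]))
  fold <- integer(length(y))
  with_local_seed(seed, {
    for (cl in names(counts)) {
      idx <- which(y == cl)
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- rep_len(seq_len(folds), length(idx))
    }
  })
  fold
}

#' Out-of-fold outcomes for every parameter combination
#'
#' Runs stratified k-fold cross-validation once and produces, for each of
#' the `NP` parameter combinations in the bag, one full-length out-of-fold
#' prediction vector (each sample predicted by the model trained on the
#' other folds) together with its accuracy against the labels. Distance
#' matrices are computed once per fold and distance and reused across the
#' k / weighting grid.
#'
#' @param SX Feature matrix (`Ns x of`).
#' @param y Labels.
#' @param bag Parameter bag from [knn_parameter_bag()].
#' @param folds Fold count, at least 2 (default 10).
#' @param seed Integer seed for the stratified shuffle.
#' @param delta Distance guard for inverse weights.
#' @return List with `outP` (`Ns x NP` matrix of predicted level codes),
#'   `acc` (length `NP`), `levels`, `fold` (fold assignment).
#' @export
crossval_outcomes <- function(SX, y, bag = knn_parameter_bag(), folds = 10L,
                              seed = 1L, delta = 1e-12) {
  SX <- as.matrix(SX)
  Ns <- nrow(SX)
  if (folds < 2L) stop("parameter error: at least 2 folds are required")
  lev <- label_levels(y)
  y_code <- match(as.character(y), lev)
  NP <- nrow(bag)
  max_k <- max(bag$k)
  fold <- stratified_folds(y, folds, seed)
  outP <- matrix(0L, Ns, NP)
  for (f in sort(unique(fold))) {
    te <- which(fold == f)
    tr <- which(fold != f)
    if (length(unique(y_code[tr])) < length(lev))
      stop("folding error: a class is absent from a training split")
    if (max_k > length(tr))
      stop(sprintf("parameter error: k = %d exceeds training size %d",
                   max_k, length(tr)))
    for (dist_name in unique(bag$distance)) {
      D <- pairwise_distances(SX[te, , drop = FALSE], SX[tr, , drop = FALSE],
                              dist_name)
      ord <- t(apply(D, 1L, function(d) order(d, seq_along(d))))
      if (length(te) == 1L) ord <- matrix(ord, 1L)
      ds <- t(vapply(seq_len(nrow(D)), function(i) D[i, ord[i, ]],
                     numeric(ncol(D))))
      if (length(te) == 1L) ds <- matrix(ds, 1L)
      for (ci in which(bag$distance == dist_name)) {
        outP[te, ci] <- predict_from_neighbors(ord, ds, y_code[tr], bag$k[ci],
                                               bag$weighting[ci], length(lev),
                                               delta)
      }
    }
  }
  acc <- colMeans(outP == y_code)
  list(outP = outP, acc = acc, levels = lev, fold = fold)
}

#' Iterative majority voting over sorted outcomes
#'
#' Given outcome vectors sorted by descending accuracy, voted outcome
#' `i - 2` (for `i = 3..NP`) is the per-sample mode of the top `i` outcomes;
#' mode ties break toward the smallest label.
#'
#' @param sorted_out `Ns x NP` matrix of level codes, columns in descending
#'   accuracy order.
#' @param y_code Integer label codes (length `Ns`).
#' @param nlev Number of label levels.
#' @return List with `outV` (`Ns x (NP - 2)` matrix) and `acc`
#'   (length `NP - 2`).
#' @export
iterative_majority_voting <- function(sorted_out, y_code, nlev) {
  NP <- ncol(sorted_out)
  if (NP < 3L) stop("parameter error: at least 3 outcomes are required")
  Ns <- nrow(sorted_out)
  counts <- matrix(0L, Ns, nlev)
  add <- function(counts, col) {
    counts[cbind(seq_len(Ns), col)] <- counts[cbind(seq_len(Ns), col)] + 1L
    counts
  }
  counts <- add(add(counts, sorted_out[, 1L]), sorted_out[, 2L])
  outV <- matrix(0L, Ns, NP - 2L)
  acc <- numeric(NP - 2L)
  for (i in 3:NP) {
    counts <- add(counts, sorted_out[, i])
    outV[, i - 2L] <- max.col(counts, ties.method = "first")
    acc[i - 2L] <- mean(outV[, i - 2L] == y_code)
  }
  list(outV = outV, acc = acc)
}

#' Greedy selection of the best outcome
#'
#' Returns the index of the maximal accuracy; ties break toward the smallest
#' index (parametric outcomes come before voted ones, earlier parameter
#' combinations first).
#'
#' @param acc Vector of accuracies over all outcomes.
#' @return Integer index of the winning outcome.
#' @export
greedy_final <- function(acc) {
  if (length(acc) == 0L) stop("no outcomes to select from")
  which.max(acc)
}

#' Self-organizing kNN ensemble (tkNN)
#'
#' The full classifier: the parameter sweep produces `NP` out-of-fold
#' outcome vectors, the outcomes are sorted by descending accuracy,
#' iterative majority voting adds `NP - 2` voted outcomes, and the single
#' best of all `2 NP - 2` outcomes is selected greedily. Note the sorting
#' and greedy selection consult the labels over cross-validated predictions;
#' the selection is therefore optimistically biased by design, and the
#' reported final accuracy is the selected outcome's out-of-fold accuracy.
#'
#' @inheritParams crossval_outcomes
#' @return Object of class `tknn_result`: `outP`, `accP`, `idacc`, `outV`,
#'   `accV`, `final` (list with `index`, `type`, `outcome`, `accuracy`),
#'   `levels`, `bag`, `fold`.
#' @export
tknn <- function(SX, y, bag = knn_parameter_bag(), folds = 10L, seed = 1L,
                 delta = 1e-12) {
  cv <- crossval_outcomes(SX, y, bag, folds, seed, delta)
  NP <- nrow(bag)
  y_code <- match(as.character(y), cv$levels)
  idacc <- order(-cv$acc, seq_len(NP))
  imv <- iterative_majority_voting(cv$outP[, idacc, drop = FALSE], y_code,
                                   length(cv$levels))
  acc_all <- c(cv$acc, imv$acc)
  idmax <- greedy_final(acc_all)
  if (idmax <= NP) {
    final <- list(index = idmax, type = "parametric",
                  outcome = cv$levels[cv$outP[, idmax]],
                  accuracy = acc_all[idmax],
                  parameters = bag[idmax, ])
  } else {
    final <- list(index = idmax, type = "voted",
                  outcome = cv$levels[imv$outV[, idmax - NP]],
                  accuracy = acc_all[idmax],
                  n_voters = idmax - NP + 2L)
  }
  structure(list(outP = cv$outP, accP = cv$acc, idacc = idacc,
                 outV = imv$outV, accV = imv$acc, final = final,
                 levels = cv$levels, bag = bag, fold = cv$fold),
            class = "tknn_result")
}

#' @export
print.tknn_result <- function(x, ...) {
  NP <- length(x$accP)
  cat(sprintf("<tknn_result> %d outcomes (%d parametric + %d voted)\n",
              NP + length(x$accV), NP, length(x$accV)))
  cat(sprintf("final: %s outcome #%d, accuracy %.4f\n",
              x$final$type, x$final$index, x$final$accuracy))
  invisible(x)
}

#' Confusion-matrix metric suite
#'
#' Computes accuracy, sensitivity, specificity, precision, F1-score and
#' geometric mean from the confusion matrix. Binary problems use the stated
#' positive class; multiclass metrics are macro-averaged one-vs-rest.
#' A ratio with zero denominator is reported as 0 and flagged (with a
#' warning).
#'
#' @param y True labels.
#' @param yhat Predicted labels (same length).
#' @param positive Positive class for binary problems; defaults to the first
#'   sorted level.
#' @return Object of class `metric_report`: the six metrics, the confusion
#'   matrix, and a `degenerate` flag.
#' @export
confusion_metrics <- function(y, yhat, positive = NULL) {
  y <- as.character(y)
  yhat <- as.character(yhat)
  if (length(y) == 0L) stop("parameter error: empty input")
  if (length(y) != length(yhat)) stop("'y' and 'yhat' lengths differ")
  lev <- sort(unique(c(y, yhat)))
  cm <- table(factor(y, lev), factor(yhat, lev), dnn = c("truth", "predicted"))
  degenerate <- FALSE
  ratio <- function(num, den) {
    if (den == 0) { degenerate <<- TRUE; 0 } else num / den
  }
  per_class <- function(cl) {
    tp <- sum(y == cl & yhat == cl)
    fn <- sum(y == cl & yhat != cl)
    fp <- sum(y != cl & yhat == cl)
    tn <- sum(y != cl & yhat != cl)
    sens <- ratio(tp, tp + fn)
    spec <- ratio(tn, tn + fp)
    prec <- ratio(tp, tp + fp)
    f1 <- ratio(2 * prec * sens, prec + sens)
    c(sensitivity = sens, specificity = spec, precision = prec, f1 = f1,
      gmean = sqrt(sens * spec))
  }
  if (length(lev) <= 2L) {
    if (is.null(positive)) positive <- lev[1L]
    m <- per_class(positive)
  } else {
    m <- rowMeans(vapply(lev, per_class, numeric(5L)))
  }
  if (degenerate)
    warning("a metric had a zero denominator and was reported as 0")
  structure(list(accuracy = mean(y == yhat),
                 sensitivity = unname(m["sensitivity"]),
                 specificity = unname(m["specificity"]),
                 precision = unname(m["precision"]),
                 f1 = unname(m["f1"]),
                 gmean = unname(m["gmean"]),
                 confusion = cm, degenerate = degenerate),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat("<metric_report>\n")
  for (nm in c("accuracy", "sensitivity", "specificity", "precision",
               "f1", "gmean"))
    cat(sprintf("  %-12s %.4f\n", nm, x[[nm]]))
  print(x$confusion)
  invisible(x)
}
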