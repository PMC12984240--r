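# Independent brute-force oracles, written as literal loops over the method
# definitions. They share no code with the package implementation.

# Literal window-by-window feature extractor: eight overlapping vectors,
# center-symmetric differences, descending rank with smallest-index ties,
# transition counting over the concatenated sequences, row-major flatten.
brute_force_features <- function(signal) {
  L <- nrow(signal)
  Nc <- ncol(signal)
  stopifnot(L >= 8)
  T <- list(integer(0), integer(0), integer(0), integer(0))
  for (i in 0:(L - 8)) {
    V <- lapply(1:8, function(j) signal[i + j, ])
    for (k in 1:4) {
      D <- V[[k]] - V[[9 - k]]
      # descending rank by repeated maximum, earlier channel on ties
      remaining <- seq_len(Nc)
      perm <- integer(0)
      vals <- D
      while (length(remaining) > 0) {
        best <- remaining[which.max(vals[remaining])]
        perm <- c(perm, best)
        remaining <- setdiff(remaining, best)
      }
      T[[k]] <- c(T[[k]], perm)
    }
  }
  FF <- numeric(0)
  for (k in 1:4) {
    TM <- matrix(0, Nc, Nc)
    s <- T[[k]]
    for (a in seq_len(length(s) - 1)) TM[s[a], s[a + 1]] <- TM[s[a], s[a + 1]] + 1
    for (w in seq_len(Nc)) for (u in seq_len(Nc)) FF <- c(FF, TM[w, u])
  }
  FF
}

# Brute-force kNN by full distance enumeration (base R distance formulas).
brute_force_knn <- function(train_X, train_y, test_x, k, distance, weighting,
                            delta = 1e-12) {
  d <- apply(train_X, 1, function(tr) {
    switch(distance,
      euclidean = sqrt(sum((tr - test_x)^2)),
      cityblock = sum(abs(tr - test_x)),
      cosine = {
        den <- sqrt(sum(tr^2)) * sqrt(sum(test_x^2))
        if (den == 0) 1 else 1 - sum(tr * test_x) / den
      },
      spearman = {
        r1 <- rank(tr); r2 <- rank(test_x)
        if (stats::sd(r1) == 0 || stats::sd(r2) == 0) 1
        else 1 - stats::cor(r1, r2)
      })
  })
  ord <- order(d, seq_along(d))[seq_len(k)]
  w <- switch(weighting,
              equal = rep(1, k),
              inverse = 1 / (d[ord] + delta),
              `squared-inverse` = 1 / (d[ord] + delta)^2)
  lev <- sort(unique(as.character(train_y)))
  tally <- sapply(lev, function(cl) sum(w[as.character(train_y)[ord] == cl]))
  lev[which.max(tally)]
}

# NCA leave-one-out objective for a given weight vector (weights enter
# squared, city-block distance, softmax neighbor probabilities).
nca_objective <- function(X, y, w, lambda = 0) {
  Ns <- nrow(X)
  total <- 0
  for (i in seq_len(Ns)) {
    d <- sapply(seq_len(Ns), function(j) sum(w^2 * abs(X[i, ] - X[j, ])))
    e <- exp(-(d - min(d[-i])))
    e[i] <- 0
    p <- e / sum(e)
    total <- total + sum(p[y == y[i] & seq_len(Ns) != i])
  }
  total - lambda * sum(w^2)
}
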