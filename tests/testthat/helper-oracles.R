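# Brute-force oracles: direct double loops over pairwise distances and
# scatter sums, independent of the vectorized implementations they check.

euclid <- function(a, b) sqrt(sum((a - b)^2))

oracle_silhouette <- function(X, lab) {
  X <- as.matrix(X); n <- nrow(X)
  s <- numeric(n)
  for (i in seq_len(n)) {
    same <- setdiff(which(lab == lab[i]), i)
    if (!length(same)) { s[i] <- 0; next }
    a <- mean(vapply(same, function(j) euclid(X[i, ], X[j, ]), numeric(1)))
    b <- Inf
    for (g in setdiff(unique(lab), lab[i])) {
      mem <- which(lab == g)
      b <- min(b, mean(vapply(mem, function(j) euclid(X[i, ], X[j, ]), numeric(1))))
    }
    s[i] <- if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }
  mean(s)
}

oracle_davies_bouldin <- function(X, lab) {
  X <- as.matrix(X)
  lev <- sort(unique(lab))
  cent <- lapply(lev, function(g) colMeans(X[lab == g, , drop = FALSE]))
  disp <- vapply(seq_along(lev), function(j) {
    mem <- which(lab == lev[j])
    mean(vapply(mem, function(i) euclid(X[i, ], cent[[j]]), numeric(1)))
  }, numeric(1))
  total <- 0
  for (i in seq_along(lev)) {
    worst <- -Inf
    for (j in seq_along(lev)) {
      if (i == j) next
      worst <- max(worst, (disp[i] + disp[j]) / euclid(cent[[i]], cent[[j]]))
    }
    total <- total + worst
  }
  total / length(lev)
}

oracle_calinski_harabasz <- function(X, lab) {
  X <- as.matrix(X)
  lev <- sort(unique(lab))
  n <- nrow(X); k <- length(lev)
  grand <- colMeans(X)
  sb <- 0; sw <- 0
  for (g in lev) {
    mem <- which(lab == g)
    cen <- colMeans(X[mem, , drop = FALSE])
    sb <- sb + length(mem) * sum((cen - grand)^2)
    for (i in mem) sw <- sw + sum((X[i, ] - cen)^2)
  }
  (sb / (k - 1)) / (sw / (n - k))
}

oracle_kappa <- function(m) {
  m <- as.matrix(m); n <- sum(m)
  po <- 0
  for (i in seq_len(nrow(m))) po <- po + m[i, i]
  po <- po / n
  pe <- 0
  for (i in seq_len(nrow(m))) {
    ri <- sum(m[i, ]); ci <- sum(m[, i])
    pe <- pe + ri * ci
  }
  pe <- pe / n^2
  (po - pe) / (1 - pe)
}

# random labelled instance with every cluster non-empty
random_instance <- function(n, d, k) {
  lab <- c(seq_len(k), sample.int(k, n - k, replace = TRUE))
  X <- matrix(stats::rnorm(n * d, sd = 2), n, d) +
    2 * matrix(lab, n, d) # mild separation so indices are well-defined
  list(X = X, lab = lab)
}
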