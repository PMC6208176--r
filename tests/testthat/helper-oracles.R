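# Independent brute-force oracles, deliberately written as plain loops so
# they share no code with the package implementations they check.

# route one sample through a tree without assign_locality(); returns the
# leaf's position (left-to-right) and the feature nodes seen on the way
oracle_route <- function(node, x, feats = integer(0), counter = NULL) {
  if (is.null(counter)) {
    counter <- new.env()
    counter$leaf <- 0L
  }
  if (node$kind == "leaf") {
    counter$leaf <- counter$leaf + 1L
    return(list(leaf = counter$leaf, features = feats, hit = TRUE))
  }
  if (node$kind == "feature") {
    return(oracle_route(node$child, x, c(feats, node$feature), counter))
  }
  # split: walk both branches to keep leaf numbering, but only one "hits"
  go_left <- x[node$feature] <= node$threshold
  l <- oracle_route(node$left, x, c(feats), counter)
  r <- oracle_route(node$right, x, c(feats), counter)
  if (go_left) l else r
}

# Eq.-1-style score by exhaustive O(n^2) neighbor search
oracle_score <- function(tree, X, y, k) {
  n <- nrow(X)
  routes <- lapply(seq_len(n), function(i) {
    env <- new.env()
    env$leaf <- 0L
    walk <- function(node, x, feats) {
      if (node$kind == "leaf") {
        env$leaf <- env$leaf + 1L
        return(list(leaf = env$leaf, features = feats))
      }
      if (node$kind == "feature") return(walk(node$child, x, c(feats, node$feature)))
      left <- walk(node$left, x, feats)
      keep <- if (x[node$feature] <= node$threshold) left else NULL
      right <- walk(node$right, x, feats)
      if (is.null(keep)) right else keep
    }
    walk(tree$root, X[i, ], integer(0))
  })
  leaf_of <- vapply(routes, `[[`, 0L, "leaf")
  total <- 0
  for (i in seq_len(n)) {
    same <- setdiff(which(leaf_of == leaf_of[i]), i)
    if (length(same) == 0) next
    feats <- routes[[i]]$features
    if (length(feats) == 0) feats <- seq_len(ncol(X))
    d <- numeric(length(same))
    for (s in seq_along(same)) {
      d[s] <- sqrt(sum((X[i, feats] - X[same[s], feats])^2))
    }
    kx <- min(k, length(same))
    nbr <- same[order(d, same)][seq_len(kx)]
    total <- total + sum(y[nbr] == y[i]) / kx
  }
  total / n
}

# sample-entropy template counts by explicit loops (Chebyshev distance)
oracle_sampen <- function(x, m, r_abs) {
  n <- length(x)
  N <- n - m
  A <- 0
  B <- 0
  for (i in seq_len(N - 1)) {
    for (j in (i + 1):N) {
      dm <- max(abs(x[i:(i + m - 1)] - x[j:(j + m - 1)]))
      if (dm <= r_abs) {
        B <- B + 1
        if (max(dm, abs(x[i + m] - x[j + m])) <= r_abs) A <- A + 1
      }
    }
  }
  c(A = A, B = B)
}

# diagonal-line statistics of a recurrence matrix by explicit diagonal scans
oracle_rqa <- function(R, l_min) {
  n <- nrow(R)
  off <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) if (i != j && R[i, j] == 1) off <- off + 1
  RR <- if (n > 1) off / (n * (n - 1)) else 0
  lens <- integer(0)
  for (k in seq_len(n - 1)) {
    for (side in c("up", "lo")) {
      run <- 0L
      for (t in seq_len(n - k)) {
        v <- if (side == "up") R[t, t + k] else R[t + k, t]
        if (v == 1) {
          run <- run + 1L
        } else {
          if (run > 0) lens <- c(lens, run)
          run <- 0L
        }
      }
      if (run > 0) lens <- c(lens, run)
    }
  }
  lens <- lens[lens >= l_min]
  if (length(lens) == 0 || off == 0) return(c(RR = RR, DET = 0, L = 0, ENT = 0))
  p <- as.numeric(table(lens)) / length(lens)
  c(RR = RR, DET = min(1, sum(lens) / off), L = mean(lens),
    ENT = -sum(p * log(p)))
}

# leave-one-out 1-nearest-neighbor accuracy over chosen feature columns
oracle_loo_1nn <- function(X, y) {
  n <- nrow(X)
  hits <- 0
  for (i in seq_len(n)) {
    d <- rep(Inf, n)
    for (j in seq_len(n)) {
      if (j != i) d[j] <- sqrt(sum((X[i, ] - X[j, ])^2))
    }
    hits <- hits + (y[which.min(d)] == y[i])
  }
  hits / n
}

# random feature tree for oracle comparisons
random_tree <- function(n_features, depth = 3, p_split = 0.4, p_feat = 0.4) {
  build <- function(d, used) {
    if (d >= depth) return(ft_leaf())
    u <- runif(1)
    free <- setdiff(seq_len(n_features), used)
    if (u < p_split) {
      j <- sample(rep(seq_len(n_features), 2), 1)
      ft_split(j, rnorm(1, 0, 0.5), build(d + 1, used), build(d + 1, used))
    } else if (u < p_split + p_feat && length(free) > 0) {
      j <- sample(rep(free, 2), 1)
      ft_feature(j, build(d + 1, c(used, j)))
    } else {
      ft_leaf()
    }
  }
  feature_tree(build(0, integer(0)), n_features)
}
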