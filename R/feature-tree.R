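#' Feature-tree node constructors
#'
#' A feature tree is a univariate binary decision tree augmented with
#' single-child *feature nodes*: a feature node attributes its feature to
#' every locality below it, a split node routes samples on a threshold
#' (`<=` goes left), and each leaf is a *locality* owning the feature nodes
#' on its root path.
#'
#' @param feature Feature index (column of the training matrix).
#' @param child,left,right Child nodes.
#' @param threshold Split threshold.
#' @param locality Optional locality id (assigned by [feature_tree()]).
#' @return A node list with a `kind` field.
#' @export
ft_leaf <- function(locality = NA_integer_) {
  list(kind = "leaf", locality = locality)
}

#' @rdname ft_leaf
#' @export
ft_feature <- function(feature, child) {
  list(kind = "feature", feature = as.integer(feature), child = child)
}

#' @rdname ft_leaf
#' @export
ft_split <- function(feature, threshold, left, right) {
  list(kind = "split", feature = as.integer(feature), threshold = threshold,
       left = left, right = right)
}

#' Assemble and validate a feature tree
#'
#' Assigns locality ids to leaves in left-to-right order and checks the
#' structural invariants: feature nodes have exactly one child, and no
#' root-to-leaf path repeats a feature index as a feature node.
#'
#' @param root Root node built from [ft_leaf()], [ft_feature()],
#'   [ft_split()].
#' @param n_features Number of features in the training space.
#' @return A `feature_tree` object.
#' @export
feature_tree <- function(root, n_features) {
  counter <- new.env()
  counter$id <- 0L
  label <- function(node, path_feats) {
    switch(node$kind,
      leaf = {
        counter$id <- counter$id + 1L
        node$locality <- counter$id
        node
      },
      feature = {
        if (node$feature %in% path_feats) {
          stop("feature ", node$feature, " repeated as feature node on a path",
               call. = FALSE)
        }
        if (node$feature < 1 || node$feature > n_features) {
          stop("feature index out of range", call. = FALSE)
        }
        node$child <- label(node$child, c(path_feats, node$feature))
        node
      },
      split = {
        node$left <- label(node$left, path_feats)
        node$right <- label(node$right, path_feats)
        node
      },
      stop("unknown node kind: ", node$kind, call. = FALSE)
    )
  }
  structure(
    list(root = label(root, integer(0)), n_features = as.integer(n_features),
         n_localities = counter$id),
    class = "feature_tree"
  )
}

#' @export
print.feature_tree <- function(x, ...) {
  cat("<feature_tree> ", x$n_localities, " localities over ", x$n_features,
      " features\n", sep = "")
  invisible(x)
}

#' Route a sample through a feature tree
#'
#' Walks the sample from the root to a unique leaf: split nodes route left
#' iff the feature value is `<= threshold`; feature nodes are accumulated
#' into the locality's feature subset.
#'
#' @param tree A [feature_tree()].
#' @param x Numeric feature vector (length `tree$n_features`).
#' @return List with `locality` (leaf id) and `features` (feature-node
#'   indices on the path; possibly empty).
#' @export
assign_locality <- function(tree, x) {
  node <- tree$root
  feats <- integer(0)
  repeat {
    if (node$kind == "leaf") return(list(locality = node$locality, features = feats))
    if (node$kind == "feature") {
      feats <- c(feats, node$feature)
      node <- node$child
    } else {
      node <- if (x[node$feature] <= node$threshold) node$left else node$right
    }
  }
}

# route all rows of X: locality id per row + per-locality feature subsets
tree_partition <- function(tree, X) {
  loc <- integer(nrow(X))
  feats <- vector("list", tree$n_localities)
  for (i in seq_len(nrow(X))) {
    a <- assign_locality(tree, X[i, ])
    loc[i] <- a$locality
    feats[[a$locality]] <- a$features
  }
  # localities with no routed sample still need their subsets
  walk <- function(node, path) {
    if (node$kind == "leaf") {
      feats[[node$locality]] <<- path
    } else if (node$kind == "feature") {
      walk(node$child, c(path, node$feature))
    } else {
      walk(node$left, path)
      walk(node$right, path)
    }
  }
  walk(tree$root, integer(0))
  list(locality = loc, features = feats)
}

#' Score a feature tree on a labeled training set
#'
#' The locality-wise k-nearest-neighbor label agreement: for every training
#' sample, the fraction of its k nearest neighbors *within its locality*
#' (Euclidean distance over the locality's feature subset; an empty subset
#' falls back to all features) that share its label, averaged over the
#' training set. Localities with fewer than `k` other members use all they
#' have; single-sample localities contribute 0.
#'
#' @param tree A [feature_tree()].
#' @param X Numeric samples x features matrix.
#' @param y Label vector (length `nrow(X)`).
#' @param k Neighbor count.
#' @return Scalar in `[0, 1]`.
#' @export
score_tree <- function(tree, X, y, k = 5) {
  stopifnot(nrow(X) >= 1, length(y) == nrow(X), k >= 1)
  part <- tree_partition(tree, X)
  ycode <- match(y, unique(y))
  total <- 0
  for (l in seq_len(tree$n_localities)) {
    idx <- which(part$locality == l)
    if (length(idx) < 2) next
    feats <- part$features[[l]]
    if (length(feats) == 0) feats <- seq_len(ncol(X))
    total <- total + knn_agreement(X[idx, feats, drop = FALSE],
                                   ycode[idx], as.integer(k))
  }
  total / nrow(X)
}

# candidate split thresholds: midpoints between consecutive sorted unique
# values, thinned to at most `n_grid` quantile positions
threshold_grid <- function(v, n_grid = 9) {
  u <- sort(unique(v))
  if (length(u) < 2) return(numeric(0))
  mids <- (u[-1] + u[-length(u)]) / 2
  if (length(mids) > n_grid) {
    mids <- unname(quantile(mids, probs = seq_len(n_grid) / (n_grid + 1), type = 1))
  }
  unique(mids)
}

#' Monte-Carlo feature-tree search
#'
#' Grows feature trees by sequential action choices — add a feature node
#' `f_i`, a split node `s_i` (threshold drawn from midpoints of the chosen
#' feature's sorted values), or terminate `T` — using an epsilon-greedy
#' bandit over per-state action values estimated from rollout scores
#' ([score_tree()]). After a warm-up, half the rollouts refine the incumbent
#' best tree by local mutations, and the final tree is polished by a
#' deterministic greedy pass (in two-locality mode also by an exact rebuild
#' over candidate splits, since the two-leaf score is separable). The
#' single-leaf tree is always evaluated first, so the returned best tree
#' never scores below it. Deterministic given the seed.
#'
#' @param X Numeric samples x features matrix.
#' @param y Label vector.
#' @param k Neighbor count for the score.
#' @param budget Number of rollouts.
#' @param max_depth Maximum path length in nodes.
#' @param seed Integer seed.
#' @param epsilon Exploration rate.
#' @param require_split If `TRUE`, restrict the search to trees with exactly
#'   two leaves (one split node plus feature nodes) — the two-locality mode.
#' @return An `ft_search` object: best `tree`, its `score`, the single-leaf
#'   `baseline`, and per-feature rollout statistics (`feature_weights`,
#'   `feature_counts`).
#' @export
search_feature_tree <- function(X, y, k = 5, budget = 500, max_depth = 4,
                                seed = 1, epsilon = 0.2, require_split = FALSE) {
  stopifnot(budget >= 1, is.matrix(X))
  nf <- ncol(X)
  set.seed(as.integer(seed))
  grids <- lapply(seq_len(nf), function(j) threshold_grid(X[, j]))
  splittable <- which(lengths(grids) > 0)
  if (require_split && (length(splittable) == 0 || max_depth < 1)) {
    stop("no splittable feature available for two-locality search", call. = FALSE)
  }

  baseline_tree <- feature_tree(ft_leaf(), nf)
  baseline <- score_tree(baseline_tree, X, y, k)
  best <- if (require_split) NULL else baseline_tree
  best_score <- if (require_split) -Inf else baseline

  qtab <- new.env(parent = emptyenv())
  q_get <- function(state) {
    if (is.null(qtab[[state]])) qtab[[state]] <- list(sum = numeric(0), n = numeric(0))
    qtab[[state]]
  }
  choose <- function(state, acts) {
    if (length(acts) == 1) return(acts)
    if (runif(1) < epsilon) return(sample(acts, 1))
    e <- q_get(state)
    means <- vapply(acts, function(a) {
      i <- match(a, names(e$sum))
      if (is.na(i)) Inf else e$sum[i] / e$n[i] # untried actions are optimistic
    }, 0)
    top <- acts[means == max(means)]
    if (length(top) == 1) top else sample(top, 1)
  }

  w <- numeric(nf)
  cnt <- numeric(nf)
  warmup <- ceiling(budget / 5)
  for (roll in seq_len(budget)) {
    # after a warm-up of fresh rollouts, half the budget refines the
    # incumbent best tree by local mutations
    if (roll > warmup && !is.null(best) && runif(1) < 0.5) {
      cand <- mutate_tree(best, grids, max_depth, require_split, nf)
      if (!is.null(cand)) {
        sc <- score_tree(cand, X, y, k)
        used_feats <- unique(tree_feature_nodes(cand$root))
        if (length(used_feats)) {
          w[used_feats] <- w[used_feats] + max(0, sc - baseline)
          cnt[used_feats] <- cnt[used_feats] + 1
        }
        if (sc > best_score) {
          best_score <- sc
          best <- cand
        }
      }
      next
    }
    visited <- character(0)
    taken <- character(0)
    grow <- function(state, depth, used) {
      pre_split <- require_split && !grepl("s", state, fixed = TRUE)
      free <- setdiff(seq_len(nf), used)
      acts <- character(0)
      if (!pre_split && (depth >= max_depth || TRUE)) acts <- "T"
      if (depth < max_depth) {
        if (length(free)) acts <- c(acts, paste0("f", free))
        acts <- c(acts, paste0("s", splittable))
      } else if (pre_split) {
        acts <- paste0("s", splittable) # must still place the one split
      }
      if (pre_split) acts <- setdiff(acts, "T")
      a <- choose(state, acts)
      visited <<- c(visited, state)
      taken <<- c(taken, a)
      if (a == "T") return(ft_leaf())
      j <- as.integer(substring(a, 2))
      if (startsWith(a, "f")) {
        return(ft_feature(j, grow(paste0(state, "|", a), depth + 1L, c(used, j))))
      }
      g <- grids[[j]]
      thr <- g[sample.int(length(g), 1)]
      if (require_split) {
        # one split only: branches may add feature nodes, then terminate
        left <- grow_chain(paste0(state, "|", a, "L"), depth + 1L, c(used))
        right <- grow_chain(paste0(state, "|", a, "R"), depth + 1L, c(used))
        return(ft_split(j, thr, left, right))
      }
      ft_split(j, thr,
               grow(paste0(state, "|", a, "L"), depth + 1L, used),
               grow(paste0(state, "|", a, "R"), depth + 1L, used))
    }
    grow_chain <- function(state, depth, used) {
      free <- setdiff(seq_len(nf), used)
      acts <- "T"
      if (depth < max_depth && length(free)) acts <- c(acts, paste0("f", free))
      a <- choose(state, acts)
      visited <<- c(visited, state)
      taken <<- c(taken, a)
      if (a == "T") return(ft_leaf())
      j <- as.integer(substring(a, 2))
      ft_feature(j, grow_chain(paste0(state, "|", a), depth + 1L, c(used, j)))
    }
    tree <- feature_tree(grow("root", 0L, integer(0)), nf)
    sc <- score_tree(tree, X, y, k)
    for (i in seq_along(visited)) {
      e <- q_get(visited[i])
      pos <- match(taken[i], names(e$sum))
      if (is.na(pos)) {
        e$sum <- c(e$sum, stats::setNames(sc, taken[i]))
        e$n <- c(e$n, stats::setNames(1, taken[i]))
      } else {
        e$sum[pos] <- e$sum[pos] + sc
        e$n[pos] <- e$n[pos] + 1
      }
      qtab[[visited[i]]] <- e
    }
    used_feats <- unique(unlist(tree_feature_nodes(tree$root)))
    if (length(used_feats)) {
      w[used_feats] <- w[used_feats] + max(0, sc - baseline)
      cnt[used_feats] <- cnt[used_feats] + 1
    }
    if (sc > best_score) {
      best_score <- sc
      best <- tree
    }
  }
  if (is.null(best)) stop("no valid two-locality tree found", call. = FALSE)
  ref <- refine_tree(best, best_score, X, y, k, grids, max_depth)
  best <- ref$tree
  best_score <- ref$score
  if (require_split) {
    cand_features <- unique(c(split_feature_at(best$root, 1L),
                              order(-w)[seq_len(min(5L, nf))]))
    rb <- rebuild_two_locality(X, y, k, cand_features, grids, max_depth)
    if (!is.null(rb) && rb$score > best_score) {
      ref <- refine_tree(rb$tree, rb$score, X, y, k, grids, max_depth)
      best <- ref$tree
      best_score <- ref$score
    }
  }
  final_feats <- unique(tree_feature_nodes(best$root))
  if (length(final_feats)) {
    w[final_feats] <- w[final_feats] + max(0, best_score - baseline) * warmup
    cnt[final_feats] <- cnt[final_feats] + warmup
  }
  structure(
    list(tree = best, score = best_score, baseline = baseline,
         feature_weights = w, feature_counts = cnt, budget = budget, k = k),
    class = "ft_search"
  )
}

# Deterministic greedy polish of the best rollout tree: retune each split
# threshold over its grid, try dropping or relocating each feature node, and
# greedily add best-gain feature nodes at the leaves; repeat until no move
# improves the score (or the sweep cap is hit).
refine_tree <- function(tree, score, X, y, k, grids, max_depth, max_sweeps = 10) {
  nf <- tree$n_features
  try_tree <- function(root) {
    cand <- tryCatch(feature_tree(root, nf), error = function(e) NULL)
    if (is.null(cand)) return(NULL)
    list(tree = cand, score = score_tree(cand, X, y, k))
  }
  for (sweep in seq_len(max_sweeps)) {
    improved <- FALSE
    # retune split thresholds
    n_split <- count_nodes(tree$root, function(n, d, u) n$kind == "split")
    for (si in seq_len(n_split)) {
      for (thr in grids[[split_feature_at(tree$root, si)]]) {
        counter <- new.env(); counter$i <- 0L
        root2 <- transform_node(
          tree$root, function(n, d, u) n$kind == "split", si,
          function(n, d, u) { n$threshold <- thr; n },
          counter, 0L, integer(0)
        )
        cand <- try_tree(root2)
        if (!is.null(cand) && cand$score > score + 1e-12) {
          tree <- cand$tree; score <- cand$score; improved <- TRUE
        }
      }
    }
    # drop each feature node
    n_fn <- count_nodes(tree$root, function(n, d, u) n$kind == "feature")
    for (fi in seq_len(n_fn)) {
      counter <- new.env(); counter$i <- 0L
      root2 <- transform_node(
        tree$root, function(n, d, u) n$kind == "feature", fi,
        function(n, d, u) n$child, counter, 0L, integer(0)
      )
      cand <- try_tree(root2)
      if (!is.null(cand) && cand$score > score + 1e-12) {
        tree <- cand$tree; score <- cand$score; improved <- TRUE
        break
      }
    }
    # greedy feature-node additions at each leaf
    repeat {
      n_leaf <- count_nodes(tree$root, function(n, d, u)
        n$kind == "leaf" && d < max_depth)
      gain <- NULL
      for (li in seq_len(n_leaf)) {
        for (j in seq_len(nf)) {
          counter <- new.env(); counter$i <- 0L
          root2 <- transform_node(
            tree$root,
            function(n, d, u) n$kind == "leaf" && d < max_depth, li,
            function(n, d, u) if (j %in% u) n else ft_feature(j, ft_leaf()),
            counter, 0L, integer(0)
          )
          cand <- try_tree(root2)
          if (!is.null(cand) && cand$score > score + 1e-12 &&
              (is.null(gain) || cand$score > gain$score)) {
            gain <- cand
          }
        }
      }
      if (is.null(gain)) break
      tree <- gain$tree
      score <- gain$score
      improved <- TRUE
    }
    if (!improved) break
  }
  list(tree = tree, score = score)
}

# summed k-NN label agreement of one locality over a feature subset
# (empty subset = all features, matching score_tree)
locality_agreement <- function(X, y, idx, feats, k) {
  if (length(idx) < 2) return(0)
  if (length(feats) == 0) feats <- seq_len(ncol(X))
  knn_agreement(X[idx, feats, drop = FALSE], match(y, unique(y))[idx],
                as.integer(k))
}

# Direct optimizer for two-leaf trees: for each candidate split feature
# (and its threshold grid), partition the samples and greedily forward-select
# each side's feature subset; the locality scores are separable, so the
# combined score is exact. Used to polish the Monte-Carlo result in
# two-locality mode.
rebuild_two_locality <- function(X, y, k, cand_features, grids, max_depth) {
  nf <- ncol(X)
  n <- nrow(X)
  best <- NULL
  greedy_side <- function(idx) {
    S <- integer(0)
    sc <- locality_agreement(X, y, idx, S, k)
    while (length(S) < max_depth - 1L) {
      gains <- vapply(setdiff(seq_len(nf), S), function(j)
        locality_agreement(X, y, idx, c(S, j), k), 0)
      cand <- setdiff(seq_len(nf), S)
      if (max(gains) <= sc + 1e-12) break
      S <- c(S, cand[which.max(gains)])
      sc <- max(gains)
    }
    list(S = S, sc = sc)
  }
  for (j in cand_features) {
    g <- grids[[j]]
    if (length(g) == 0) next
    if (length(g) > 5) g <- g[round(seq(1, length(g), length.out = 5))]
    for (thr in g) {
      left_idx <- which(X[, j] <= thr)
      right_idx <- which(X[, j] > thr)
      L <- greedy_side(left_idx)
      R <- greedy_side(right_idx)
      total <- (L$sc + R$sc) / n
      if (is.null(best) || total > best$score) {
        chain <- function(S) Reduce(function(acc, f) ft_feature(f, acc),
                                    rev(S), ft_leaf())
        best <- list(
          tree = feature_tree(ft_split(j, thr, chain(L$S), chain(R$S)), nf),
          score = total
        )
      }
    }
  }
  best
}

# feature index of the si-th split node (depth-first order)
split_feature_at <- function(node, target) {
  counter <- new.env(); counter$i <- 0L
  out <- new.env()
  transform_node(node, function(n, d, u) n$kind == "split", target,
                 function(n, d, u) { out$j <- n$feature; n },
                 counter, 0L, integer(0))
  out$j
}

# --- elite mutation moves -------------------------------------------------
# Local refinements of the incumbent best tree; together with the fresh
# epsilon-greedy rollouts they form the Monte-Carlo search policy. Every
# mutation preserves the structural invariants (single-child feature nodes,
# no repeated feature node on a path, exactly one split in two-leaf mode).

# rebuild the tree applying `fn` at the `target`-th node satisfying `pred`
# (depth-first); counter carried in an environment
transform_node <- function(node, pred, target, fn, counter, depth, used) {
  if (pred(node, depth, used)) {
    counter$i <- counter$i + 1L
    if (counter$i == target) return(fn(node, depth, used))
  }
  switch(node$kind,
    leaf = node,
    feature = {
      node$child <- transform_node(node$child, pred, target, fn, counter,
                                   depth + 1L, c(used, node$feature))
      node
    },
    split = {
      node$left <- transform_node(node$left, pred, target, fn, counter,
                                  depth + 1L, used)
      node$right <- transform_node(node$right, pred, target, fn, counter,
                                   depth + 1L, used)
      node
    }
  )
}

count_nodes <- function(node, pred, depth = 0L, used = integer(0)) {
  n <- as.integer(pred(node, depth, used))
  switch(node$kind,
    leaf = n,
    feature = n + count_nodes(node$child, pred, depth + 1L, c(used, node$feature)),
    split = n + count_nodes(node$left, pred, depth + 1L, used) +
      count_nodes(node$right, pred, depth + 1L, used)
  )
}

mutate_tree <- function(tree, grids, max_depth, require_split, nf) {
  root <- tree$root
  moves <- c("add_feat", "move_feat", "drop_feat", "retune_split", "reroll_split")
  probs <- c(0.3, 0.2, 0.1, 0.2, 0.2)
  if (!require_split) {
    moves <- c(moves, "add_split", "prune")
    probs <- c(probs * 0.8, 0.1, 0.1)
  }
  move <- sample(moves, 1, prob = probs)
  splittable <- which(lengths(grids) > 0)
  apply_move <- function(pred, fn) {
    n <- count_nodes(root, pred)
    if (n == 0) return(NULL)
    counter <- new.env()
    counter$i <- 0L
    transform_node(root, pred, sample.int(n, 1), fn, counter, 0L, integer(0))
  }
  out <- switch(move,
    add_feat = apply_move(
      function(node, depth, used) node$kind == "leaf" && depth < max_depth &&
        length(setdiff(seq_len(nf), used)) > 0,
      function(node, depth, used) {
        ft_feature(sample(rep(setdiff(seq_len(nf), used), 2), 1), ft_leaf())
      }
    ),
    drop_feat = apply_move(
      function(node, depth, used) node$kind == "feature",
      function(node, depth, used) node$child
    ),
    move_feat = {
      n_fn <- count_nodes(root, function(node, depth, used) node$kind == "feature")
      if (n_fn == 0) NULL else {
        moved <- new.env()
        counter <- new.env()
        counter$i <- 0L
        spliced <- transform_node(
          root, function(node, depth, used) node$kind == "feature",
          sample.int(n_fn, 1),
          function(node, depth, used) {
            moved$feature <- node$feature
            node$child
          },
          counter, 0L, integer(0)
        )
        n_leaf <- count_nodes(spliced, function(node, depth, used)
          node$kind == "leaf" && depth < max_depth && !(moved$feature %in% used))
        if (n_leaf == 0) NULL else {
          counter$i <- 0L
          transform_node(
            spliced, function(node, depth, used)
              node$kind == "leaf" && depth < max_depth && !(moved$feature %in% used),
            sample.int(n_leaf, 1),
            function(node, depth, used) ft_feature(moved$feature, ft_leaf()),
            counter, 0L, integer(0)
          )
        }
      }
    },
    retune_split = apply_move(
      function(node, depth, used) node$kind == "split",
      function(node, depth, used) {
        g <- grids[[node$feature]]
        node$threshold <- g[sample.int(length(g), 1)]
        node
      }
    ),
    reroll_split = apply_move(
      function(node, depth, used) node$kind == "split",
      function(node, depth, used) {
        j <- sample(rep(splittable, 2), 1)
        g <- grids[[j]]
        ft_split(j, g[sample.int(length(g), 1)], node$left, node$right)
      }
    ),
    add_split = apply_move(
      function(node, depth, used) node$kind == "leaf" && depth < max_depth,
      function(node, depth, used) {
        j <- sample(rep(splittable, 2), 1)
        g <- grids[[j]]
        ft_split(j, g[sample.int(length(g), 1)], ft_leaf(), ft_leaf())
      }
    ),
    prune = apply_move(
      function(node, depth, used) node$kind != "leaf" && depth > 0,
      function(node, depth, used) ft_leaf()
    )
  )
  if (is.null(out)) NULL else feature_tree(out, nf)
}

# feature-node indices used anywhere in a tree
tree_feature_nodes <- function(node) {
  switch(node$kind,
    leaf = integer(0),
    feature = c(node$feature, tree_feature_nodes(node$child)),
    split = c(tree_feature_nodes(node$left), tree_feature_nodes(node$right))
  )
}

#' @export
print.ft_search <- function(x, ...) {
  cat("<ft_search> best score ", round(x$score, 4), " (single-leaf ",
      round(x$baseline, 4), ") after ", x$budget, " rollouts\n", sep = "")
  invisible(x)
}

#' Arousal and valence feature subsets by two-locality search
#'
#' Runs two independent two-leaf feature-tree searches — one scored against
#' binarized arousal labels, one against binarized valence labels — and
#' returns, for each axis, the `n_keep` features ranked by rollout selection
#' frequency weighted by score gain over the single-leaf baseline.
#'
#' @param tbl A feature table (see [extract_features()]) carrying `arousal`
#'   and `valence` rating columns.
#' @param k,budget,max_depth,epsilon Passed to [search_feature_tree()].
#' @param n_keep Features kept per axis (default 10).
#' @param cutoff Rating cutoff binarizing arousal/valence.
#' @param seed Integer seed.
#' @return A `locality_subsets` list with character vectors `arousal` and
#'   `valence` of feature column names, plus the two `ft_search` results.
#' @export
two_locality_subsets <- function(tbl, k = 5, budget = 500, max_depth = 4,
                                 n_keep = 10, cutoff = 5, seed = 1,
                                 epsilon = 0.2) {
  cols <- feature_columns(tbl)
  X <- scale(as.matrix(tbl[, cols]))
  X[is.nan(X)] <- 0 # constant columns carry no information
  if (length(cols) < n_keep) {
    warning("fewer than n_keep = ", n_keep, " features available; returning all",
            call. = FALSE)
  }
  labels <- list(
    arousal = ifelse(tbl$arousal > cutoff, "high", "low"),
    valence = ifelse(tbl$valence > cutoff, "high", "low")
  )
  searches <- purrr::imap(labels, function(y, axis) {
    search_feature_tree(X, y, k = k, budget = budget, max_depth = max_depth,
                        seed = as.integer(seed) + match(axis, names(labels)) - 1L,
                        epsilon = epsilon, require_split = TRUE)
  })
  subsets <- purrr::map(searches, function(s) {
    ord <- order(-s$feature_weights, -s$feature_counts, seq_along(cols))
    cols[ord[seq_len(min(n_keep, length(cols)))]]
  })
  structure(
    list(arousal = subsets$arousal, valence = subsets$valence,
         searches = searches),
    class = "locality_subsets"
  )
}

#' @export
print.locality_subsets <- function(x, ...) {
  cat("<locality_subsets>\n  arousal: ", paste(x$arousal, collapse = ", "),
      "\n  valence: ", paste(x$valence, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Serialize a feature tree to JSON
#'
#' @param tree A [feature_tree()].
#' @param path Optional file path; if `NULL` the JSON string is returned.
#' @return JSON string (invisibly when written to file).
#' @export
tree_to_json <- function(tree, path = NULL) {
  js <- jsonlite::toJSON(list(n_features = tree$n_features, root = tree$root),
                         auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' @rdname tree_to_json
#' @param json JSON string or file path to read.
#' @export
tree_from_json <- function(json) {
  obj <- jsonlite::fromJSON(json, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  fix <- function(node) {
    switch(node$kind,
      leaf = ft_leaf(node$locality),
      feature = ft_feature(node$feature, fix(node$child)),
      split = ft_split(node$feature, node$threshold, fix(node$left), fix(node$right))
    )
  }
  feature_tree(fix(obj$root), obj$n_features)
}
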