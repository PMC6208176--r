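#' Mass functions over the emotion frame
#'
#' A basic belief assignment over the nonempty subsets of the frame of
#' discernment (by default the four quadrants `Q1..Q4`). Hypotheses are named
#' by comma-joined sorted member labels (e.g. `"Q1"`, `"Q1,Q3"`). The
#' constructor enforces the belief-function conditions: no mass on the empty
#' set, nonnegative masses, total mass 1 (within 1e-9).
#'
#' @param mass Named numeric vector of focal-element masses.
#' @param frame Character vector of singleton class labels.
#' @return A `mass_function` object.
#' @export
mass_function <- function(mass, frame = quarter_levels()) {
  stopifnot(length(mass) >= 1, !is.null(names(mass)))
  members <- strsplit(names(mass), ",", fixed = TRUE)
  if (any(lengths(members) == 0)) stop("mass on the empty set", call. = FALSE)
  if (!all(unlist(members) %in% frame)) stop("hypothesis outside the frame", call. = FALSE)
  names(mass) <- vapply(members, function(m) paste(sort(unique(m)), collapse = ","), "")
  mass <- tapply(mass, names(mass), sum)
  mass <- stats::setNames(as.numeric(mass), names(mass))
  if (any(mass < -1e-12)) stop("negative mass", call. = FALSE)
  mass[mass < 0] <- 0
  if (abs(sum(mass) - 1) > 1e-9) stop("masses must sum to 1", call. = FALSE)
  structure(mass[mass > 0], frame = frame, class = "mass_function")
}

#' @export
print.mass_function <- function(x, ...) {
  cat("<mass_function> over {", paste(attr(x, "frame"), collapse = ","), "}\n", sep = "")
  print(unclass(x))
  invisible(x)
}

#' Vacuous mass function
#'
#' All mass on the whole frame: total ignorance, the neutral element of
#' Dempster's rule.
#'
#' @param frame Singleton class labels.
#' @return A [mass_function()].
#' @export
vacuous_mass <- function(frame = quarter_levels()) {
  mass_function(stats::setNames(1, paste(sort(frame), collapse = ",")), frame)
}

#' Softmax conversion of posterior scores to a singleton mass function
#'
#' `m({s_j}) = exp(R_j) / sum_c exp(R_c)` (max-subtracted for overflow
#' safety); all mass lands on singletons, so the belief-function conditions
#' hold exactly. Shift-invariant in `R`.
#'
#' @param R Numeric per-class score vector (e.g. classifier posteriors).
#' @param frame Class labels, one per element of `R`.
#' @return A [mass_function()].
#' @export
softmax_mass <- function(R, frame = quarter_levels()) {
  stopifnot(length(R) == length(frame), all(is.finite(R)))
  e <- exp(R - max(R))
  mass_function(stats::setNames(e / sum(e), frame), frame)
}

#' Combine two mass functions by Dempster's rule
#'
#' `m(S) = sum_{S1 cap S2 = S} m1(S1) m2(S2) / (1 - K)` with conflict
#' `K = sum_{S1 cap S2 = empty} m1(S1) m2(S2)`. Total conflict (`K = 1`) is
#' an error.
#'
#' @param m1,m2 [mass_function()]s over the same frame.
#' @return List with `mass` (the combined [mass_function()]) and `conflict`
#'   (the scalar K).
#' @export
dempster_combine <- function(m1, m2) {
  stopifnot(inherits(m1, "mass_function"), inherits(m2, "mass_function"))
  frame <- attr(m1, "frame")
  stopifnot(identical(frame, attr(m2, "frame")))
  acc <- new.env(parent = emptyenv())
  K <- 0
  for (a in names(m1)) {
    sa <- strsplit(a, ",", fixed = TRUE)[[1]]
    for (b in names(m2)) {
      sb <- strsplit(b, ",", fixed = TRUE)[[1]]
      inter <- intersect(sa, sb)
      p <- unclass(m1)[[a]] * unclass(m2)[[b]]
      if (length(inter) == 0) {
        K <- K + p
      } else {
        key <- paste(sort(inter), collapse = ",")
        acc[[key]] <- (if (is.null(acc[[key]])) 0 else acc[[key]]) + p
      }
    }
  }
  if (1 - K <= 1e-12) stop("total conflict: sources fully contradict", call. = FALSE)
  keys <- ls(acc)
  vals <- vapply(keys, function(k) acc[[k]], 0) / (1 - K)
  list(mass = mass_function(stats::setNames(vals, keys), frame), conflict = K)
}

#' Belief of a hypothesis
#'
#' Sum of the masses of all nonempty subsets of `hypothesis`; for a
#' singleton this equals its own mass.
#'
#' @param m A [mass_function()].
#' @param hypothesis Character vector of member classes.
#' @return Scalar belief.
#' @export
belief <- function(m, hypothesis) {
  tot <- 0
  for (a in names(m)) {
    sa <- strsplit(a, ",", fixed = TRUE)[[1]]
    if (all(sa %in% hypothesis)) tot <- tot + unclass(m)[[a]]
  }
  tot
}

#' Decide a class by maximum singleton belief
#'
#' Returns the class with the largest `Bel({q})` (equal to its singleton
#' mass). Ties go to the lowest class index, with a message.
#'
#' @param m A [mass_function()].
#' @return Single class label.
#' @export
decide <- function(m) {
  frame <- attr(m, "frame")
  bel <- vapply(frame, function(q) belief(m, q), 0)
  top <- which(bel == max(bel))
  if (length(top) > 1) message("belief tie between ", paste(frame[top], collapse = ", "),
                               "; choosing ", frame[top[1]])
  frame[top[1]]
}

#' Class prototypes in standardized feature space
#'
#' Per-class mean vectors of the z-scored training features, used by the
#' distance-based relabeling.
#'
#' @param X Numeric samples x features matrix (already standardized).
#' @param y Class labels.
#' @return Classes x features matrix of means.
#' @export
class_prototypes <- function(X, y) {
  classes <- sort(unique(y))
  t(vapply(classes, function(cl) colMeans(X[y == cl, , drop = FALSE]),
           numeric(ncol(X))))
}

#' Distance-based relabeling of a training sample
#'
#' Membership of each class is the normalized inverse Euclidean distance to
#' its prototype, `(1/d_q) / sum_p (1/d_p)` (zero distance gives full
#' membership). The target hypothesis is every class whose membership
#' reaches `threshold`; if none does, the argmax class. Samples near several
#' prototypes thus receive composite (set-valued) targets, carrying their
#' label ambiguity into training.
#'
#' @param x Numeric feature vector.
#' @param prototypes Matrix from [class_prototypes()].
#' @param threshold Membership threshold in (0, 1).
#' @return List with `target` (character vector of classes) and `membership`
#'   (named numeric vector).
#' @export
relabel <- function(x, prototypes, threshold = 0.4) {
  stopifnot(threshold > 0, threshold < 1)
  d <- sqrt(rowSums(sweep(prototypes, 2, x)^2))
  if (any(d == 0)) {
    w <- stats::setNames(as.numeric(d == 0) / sum(d == 0), rownames(prototypes))
  } else {
    w <- stats::setNames((1 / d) / sum(1 / d), rownames(prototypes))
  }
  target <- names(w)[w >= threshold]
  if (length(target) == 0) target <- names(w)[which.max(w)]
  list(target = target, membership = w)
}

#' Train the two-subset Dempster-Shafer fusion classifier
#'
#' Fits two independent single-hidden-layer perceptrons — one on the arousal
#' feature subset, one on the valence subset — after distance-based
#' relabeling in each subset's standardized space. Composite relabeled
#' targets contribute a uniform distribution over their member classes
#' (implemented as weighted row expansion, which is equivalent under the
#' cross-entropy loss). Test-time posteriors are softmax-normalized into
#' singleton mass functions, combined by Dempster's rule, and decided by
#' maximum belief.
#'
#' @param tbl Training feature table with a `quarter` label column.
#' @param subsets A `locality_subsets` (or list with `arousal`/`valence`
#'   character vectors of feature column names).
#' @param membership_threshold Relabeling threshold.
#' @param hidden Hidden-layer size.
#' @param maxit Maximum training epochs.
#' @param decay Weight decay.
#' @param seed Integer seed for weight initialization.
#' @return A `dst_model` object with `predict`, [tidy()] and [glance()]
#'   methods.
#' @export
fit_dst <- function(tbl, subsets, membership_threshold = 0.4, hidden = 20,
                    maxit = 500, decay = 1e-4, seed = 1) {
  stopifnot(all(c(subsets$arousal, subsets$valence) %in% names(tbl)))
  frame <- quarter_levels()
  y <- factor(tbl$quarter, levels = frame)
  set.seed(as.integer(seed))
  learners <- purrr::map(list(arousal = subsets$arousal, valence = subsets$valence),
                         function(cols) {
    X <- as.matrix(tbl[, cols])
    ctr <- colMeans(X)
    scl <- apply(X, 2, sd)
    scl[scl == 0] <- 1
    Z <- scale(X, ctr, scl)
    proto <- class_prototypes(Z, as.character(y))
    rl <- apply(Z, 1, relabel, prototypes = proto,
                threshold = membership_threshold)
    # weighted row expansion: a composite target {Q1,Q3} becomes two rows
    # with weight 1/2 each
    rows <- integer(0)
    tgt <- character(0)
    wts <- numeric(0)
    for (i in seq_along(rl)) {
      tg <- rl[[i]]$target
      rows <- c(rows, rep(i, length(tg)))
      tgt <- c(tgt, tg)
      wts <- c(wts, rep(1 / length(tg), length(tg)))
    }
    Yx <- nnet::class.ind(factor(tgt, levels = frame))
    net <- nnet::nnet(Z[rows, , drop = FALSE], Yx, weights = wts, size = hidden,
                      softmax = TRUE, maxit = maxit, decay = decay,
                      trace = FALSE, MaxNWts = 5000)
    if (net$convergence != 0 && net$value / sum(wts) > 0.1) {
      warning("MLP did not converge within ", maxit, " epochs (final loss ",
              signif(net$value, 4), ")", call. = FALSE)
    }
    n_composite <- sum(vapply(rl, function(r) length(r$target) > 1, TRUE))
    list(net = net, cols = cols, center = ctr, scale = scl,
         prototypes = proto, n_composite = n_composite)
  })
  structure(
    list(learners = learners, frame = frame,
         params = list(membership_threshold = membership_threshold,
                       hidden = hidden, maxit = maxit, decay = decay,
                       seed = seed)),
    class = "dst_model"
  )
}

# per-learner posterior matrix for new data
learner_posteriors <- function(learner, tbl) {
  Z <- scale(as.matrix(tbl[, learner$cols]), learner$center, learner$scale)
  p <- predict(learner$net, Z)
  if (is.null(dim(p))) p <- matrix(p, nrow = 1, dimnames = list(NULL, names(p)))
  p
}

#' Predict emotion quadrants with a fitted fusion model
#'
#' @param object A `dst_model`.
#' @param newdata Feature table containing the model's feature columns.
#' @param ... Unused.
#' @return Tibble with the fused decision (`.pred`), the per-learner
#'   decisions, the fused singleton masses and the conflict `K` per sample.
#' @export
predict.dst_model <- function(object, newdata, ...) {
  posts <- purrr::map(object$learners, learner_posteriors, tbl = newdata)
  frame <- object$frame
  purrr::map_dfr(seq_len(nrow(newdata)), function(i) {
    m1 <- softmax_mass(posts[[1]][i, frame], frame)
    m2 <- softmax_mass(posts[[2]][i, frame], frame)
    fused <- dempster_combine(m1, m2)
    masses <- vapply(frame, function(q) belief(fused$mass, q), 0)
    out <- tibble::tibble(
      .pred = decide(fused$mass),
      .pred_arousal = decide(m1),
      .pred_valence = decide(m2),
      conflict = fused$conflict
    )
    out[paste0("mass_", frame)] <- as.list(masses)
    out
  })
}

#' @rdname fit_dst
#' @param x A `dst_model`.
#' @param ... Unused.
#' @export
tidy.dst_model <- function(x, ...) {
  purrr::imap_dfr(x$learners, function(l, axis) {
    tibble::tibble(learner = axis, feature = l$cols)
  })
}

#' @rdname fit_dst
#' @export
glance.dst_model <- function(x, ...) {
  tibble::tibble(
    n_features_arousal = length(x$learners$arousal$cols),
    n_features_valence = length(x$learners$valence$cols),
    n_composite_arousal = x$learners$arousal$n_composite,
    n_composite_valence = x$learners$valence$n_composite,
    hidden = x$params$hidden
  )
}

#' @export
print.dst_model <- function(x, ...) {
  cat("<dst_model> two MLPs (", x$params$hidden, " hidden units) fused by ",
      "Dempster's rule\n", sep = "")
  invisible(x)
}
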