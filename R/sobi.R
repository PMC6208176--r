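#' Second-order blind identification (SOBI)
#'
#' Separates a multichannel signal into uncorrelated sources by whitening
#' followed by orthogonal joint diagonalization (Jacobi rotations) of a set of
#' time-lagged covariance matrices. Rank-deficient inputs are handled by
#' dropping near-zero whitening eigenvalues, so fewer components than channels
#' may be returned (with a warning).
#'
#' @param x Numeric channels x samples matrix.
#' @param lags Integer sample lags whose covariances are jointly
#'   diagonalized; default `1:min(100, n_samples/4)`.
#' @param tol Convergence tolerance on the Jacobi rotation sines.
#' @param max_sweeps Maximum number of Jacobi sweeps.
#' @return A `bss_result`: list with `mixing` (channels x components),
#'   `sources` (components x samples), `method`, and the off-diagonal energy
#'   recorded after each sweep (`off_diag`).
#' @export
#' @examples
#' t <- seq(0, 4, length.out = 512)
#' s <- rbind(sin(2 * pi * 5 * t), sin(2 * pi * 11 * t))
#' x <- matrix(c(1, 0.6, 0.4, 1), 2) %*% s
#' res <- sobi(x)
#' abs(cor(res$sources[1, ], s[1, ]))
sobi <- function(x, lags = NULL, tol = 1e-8, max_sweeps = 200) {
  stopifnot(is.matrix(x), nrow(x) >= 2)
  n_ch <- nrow(x)
  n <- ncol(x)
  if (is.null(lags)) lags <- seq_len(max(1L, min(100L, floor(n / 4))))
  lags <- as.integer(lags)
  if (n <= max(lags) + 1L) stop("signal too short for requested lags", call. = FALSE)

  xc <- x - rowMeans(x)
  C0 <- tcrossprod(xc) / n
  eg <- eigen(C0, symmetric = TRUE)
  keep <- eg$values > max(eg$values) * 1e-10
  r <- sum(keep)
  if (r < n_ch) {
    warning("rank-deficient covariance: returning ", r, " components", call. = FALSE)
  }
  d <- eg$values[keep]
  E <- eg$vectors[, keep, drop = FALSE]
  z <- (t(E) / sqrt(d)) %*% xc # whitened data, r x n

  mats <- lapply(lags, function(l) {
    Cl <- z[, seq_len(n - l), drop = FALSE] %*% t(z[, (l + 1):n, drop = FALSE]) / (n - l)
    (Cl + t(Cl)) / 2
  })
  jd <- joint_diagonalize(mats, tol = tol, max_sweeps = max_sweeps)
  V <- jd$V

  sources <- t(V) %*% z
  mixing <- E %*% (sqrt(d) * V) # unwhitening: E diag(sqrt(d)) V

  # sign convention: largest-magnitude mixing weight of each component positive
  for (k in seq_len(ncol(mixing))) {
    j <- which.max(abs(mixing[, k]))
    if (mixing[j, k] < 0) {
      mixing[, k] <- -mixing[, k]
      sources[k, ] <- -sources[k, ]
    }
  }
  rownames(mixing) <- rownames(x)
  structure(
    list(mixing = mixing, sources = sources, method = "sobi",
         off_diag = jd$off_diag, sweeps = jd$sweeps),
    class = "bss_result"
  )
}

#' @export
print.bss_result <- function(x, ...) {
  cat("<bss_result> ", x$method, ": ", ncol(x$mixing), " components, ",
      ncol(x$sources), " samples (", x$sweeps, " sweeps)\n", sep = "")
  invisible(x)
}

# Orthogonal joint approximate diagonalization of symmetric matrices by
# Jacobi rotations (pairwise angles chosen from the dominant eigenvector of
# the 2x2 Grammian of [App-Aqq, Apq+Aqp] across matrices).
joint_diagonalize <- function(mats, tol = 1e-8, max_sweeps = 200) {
  r <- nrow(mats[[1]])
  V <- diag(r)
  off_energy <- function(ms) sum(vapply(ms, function(A) sum(A^2) - sum(diag(A)^2), 0))
  off_diag <- off_energy(mats)
  sweeps <- 0L
  if (r < 2) return(list(V = V, off_diag = off_diag, sweeps = 0L))
  repeat {
    sweeps <- sweeps + 1L
    max_s <- 0
    for (p in 1:(r - 1)) {
      for (q in (p + 1):r) {
        G <- matrix(0, 2, 2)
        for (A in mats) {
          h <- c(A[p, p] - A[q, q], A[p, q] + A[q, p])
          G <- G + tcrossprod(h)
        }
        ev <- eigen(G, symmetric = TRUE)
        ang <- ev$vectors[, 1]
        if (ang[1] < 0) ang <- -ang
        rr <- sqrt(sum(ang^2))
        c_ <- sqrt((ang[1] + rr) / (2 * rr))
        s_ <- ang[2] / (2 * rr * c_)
        if (abs(s_) > tol) {
          max_s <- max(max_s, abs(s_))
          R <- diag(r)
          R[p, p] <- c_; R[q, q] <- c_
          R[p, q] <- -s_; R[q, p] <- s_
          mats <- lapply(mats, function(A) crossprod(R, A %*% R))
          V <- V %*% R
        }
      }
    }
    off_diag <- c(off_diag, off_energy(mats))
    if (max_s <= tol || sweeps >= max_sweeps) break
  }
  list(V = V, off_diag = off_diag, sweeps = sweeps)
}

#' Per-channel neural activity of a source decomposition
#'
#' Summarizes how strongly each channel expresses the separated components:
#' `activity(c) = sum_k |mixing[c, k]| * sd(source_k)` — each component's
#' scalp weight magnitude, energy-weighted. Nonnegative, and invariant to the
#' sign indeterminacy of blind source separation.
#'
#' @param bss A `bss_result` from [sobi()].
#' @return Numeric vector, one value per channel.
#' @export
component_activity <- function(bss) {
  stopifnot(inherits(bss, "bss_result"))
  energy <- apply(bss$sources, 1, sd)
  as.numeric(abs(bss$mixing) %*% energy)
}

#' Class-average activity maps, normalized over the whole dataset
#'
#' Averages per-epoch channel-activity vectors within each emotion class,
#' then min-max normalizes the pooled class-mean values to `[-1, 1]` (the
#' pooled minimum maps to -1 and the pooled maximum to +1, so classes remain
#' comparable).
#'
#' @param activity Numeric epochs x channels matrix of per-epoch activity
#'   vectors (e.g. rows of [component_activity()] outputs).
#' @param class_labels Character vector of epoch class labels (length
#'   `nrow(activity)`).
#' @param channel_labels Optional channel names.
#' @return An `activity_map` tibble with columns `class`, `channel`,
#'   `channel_label`, `activity` and attribute `n_trials_averaged`.
#' @export
average_and_normalize <- function(activity, class_labels, channel_labels = NULL) {
  stopifnot(is.matrix(activity), nrow(activity) == length(class_labels), nrow(activity) >= 1)
  if (is.null(channel_labels)) channel_labels <- default_channel_labels(ncol(activity))
  stopifnot(length(channel_labels) == ncol(activity))
  classes <- sort(unique(class_labels))
  means <- t(vapply(classes, function(cl) {
    colMeans(activity[class_labels == cl, , drop = FALSE])
  }, numeric(ncol(activity))))
  lo <- min(means)
  hi <- max(means)
  norm <- if (hi > lo) 2 * (means - lo) / (hi - lo) - 1 else means * 0
  out <- tibble::tibble(
    class = rep(classes, each = ncol(activity)),
    channel = rep(seq_len(ncol(activity)), times = length(classes)),
    channel_label = rep(channel_labels, times = length(classes)),
    activity = as.numeric(t(norm))
  )
  attr(out, "n_trials_averaged") <- as.integer(table(class_labels)[classes])
  class(out) <- c("activity_map", class(out))
  out
}

#' Compute per-epoch activity vectors for an epoch set
#'
#' Runs [sobi()] on every epoch and stacks the [component_activity()] vectors.
#'
#' @param eset An `eeg_epoch_set`.
#' @param lags Passed to [sobi()].
#' @return Epochs x channels numeric matrix.
#' @export
epoch_activity <- function(eset, lags = NULL) {
  stopifnot(inherits(eset, "eeg_epoch_set"))
  t(vapply(eset$epochs, function(e) component_activity(sobi(e$data, lags = lags)),
           numeric(nrow(eset$epochs[[1]]$data))))
}

#' @rdname average_and_normalize
#' @param object An `activity_map`.
#' @param ... Unused.
#' @export
autoplot.activity_map <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(
    x = stats::reorder(.data$channel_label, .data$channel),
    y = .data$activity, fill = .data$activity
  )) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::facet_wrap(~class) +
    ggplot2::scale_fill_gradient2(low = "steelblue", high = "firebrick") +
    ggplot2::labs(x = "channel", y = "normalized activity") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}
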