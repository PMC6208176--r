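#' Delay embedding of a scalar series
#'
#' Reconstructs a phase-space trajectory: row `i` is
#' `(x[i], x[i+tau], ..., x[i+(m-1)tau])`.
#'
#' @param x Numeric series.
#' @param m Embedding dimension.
#' @param tau Delay in samples.
#' @return Numeric `(length(x) - (m-1)*tau) x m` matrix with attributes `m`
#'   and `tau`.
#' @export
delay_embed <- function(x, m, tau) {
  stopifnot(m >= 1, tau >= 1)
  n_points <- length(x) - (m - 1) * tau
  if (n_points <= 0) stop("series too short for this (m, tau)", call. = FALSE)
  traj <- vapply(seq_len(m), function(k) x[(1 + (k - 1) * tau):((k - 1) * tau + n_points)],
                 numeric(n_points))
  traj <- matrix(traj, nrow = n_points)
  attr(traj, "m") <- m
  attr(traj, "tau") <- tau
  traj
}

# First zero crossing of the autocorrelation function, a standard delay
# choice; capped so the embedding keeps at least `min_points` points.
acf_delay <- function(x, m, min_points = 100) {
  max_tau <- max(1L, floor((length(x) - min_points) / max(1L, m - 1L)))
  a <- acf(x, lag.max = min(length(x) - 1L, 4L * max_tau), plot = FALSE)$acf[-1]
  tau <- which(a <= 0)[1]
  if (is.na(tau)) tau <- length(a)
  max(1L, min(as.integer(tau), max_tau))
}

#' Correlation dimension (Grassberger-Procaccia)
#'
#' Slope of `log C(r)` versus `log r` over a scaling region, where `C(r)` is
#' the fraction of trajectory-point pairs closer than `r` (Euclidean), pairs
#' closer in time than the Theiler window excluded.
#'
#' @param ps Trajectory matrix (points x dimension), e.g. from
#'   [delay_embed()].
#' @param radii Optional radii; default a geometric grid between the 1st and
#'   10th percentile of the pairwise distances.
#' @param theiler Theiler window in trajectory-index units (default 0).
#' @return Scalar dimension estimate; 0 for a degenerate (constant) series.
#' @export
correlation_dimension <- function(ps, radii = NULL, theiler = 0) {
  X <- as.matrix(ps)
  n <- nrow(X)
  stopifnot(n >= 100)
  D <- as.matrix(dist(X))
  keep <- abs(row(D) - col(D)) > theiler
  d <- D[keep & upper.tri(D)]
  if (length(d) == 0 || max(d) == 0) return(0)
  if (is.null(radii)) {
    lo <- quantile(d[d > 0], 0.01)
    hi <- quantile(d, 0.1)
    if (hi <= lo) return(0)
    radii <- exp(seq(log(lo), log(hi), length.out = 10))
  }
  C <- vapply(radii, function(r) mean(d <= r), 0)
  use <- C > 0 & C < 1
  if (sum(use) < 2) return(0)
  unname(coef(lm(log(C[use]) ~ log(radii[use])))[2])
}

#' Higuchi fractal dimension
#'
#' Curve-length regression estimate; between 1 (smooth curve) and 2
#' (space-filling, e.g. white noise) for bounded series.
#'
#' @param x Numeric series.
#' @param k_max Maximum curve-reconstruction interval.
#' @return Scalar fractal dimension.
#' @export
higuchi_fd <- function(x, k_max = 10) {
  n <- length(x)
  stopifnot(n > 2 * k_max)
  Lk <- vapply(seq_len(k_max), function(k) {
    mean(vapply(seq_len(k), function(m0) {
      idx <- seq(m0, n, by = k)
      if (length(idx) < 2) return(NA_real_)
      norm <- (n - 1) / (floor((n - m0) / k) * k)
      sum(abs(diff(x[idx]))) * norm / k
    }, 0), na.rm = TRUE)
  }, 0)
  fit <- lm(log(Lk) ~ log(seq_len(k_max)))
  unname(-coef(fit)[2])
}

#' Largest Lyapunov exponent (Rosenstein method)
#'
#' Tracks the mean log divergence of nearest-neighbor trajectory pairs over
#' time and fits the slope of the initial (pre-saturation) linear region.
#'
#' @param ps Trajectory matrix (points x dimension).
#' @param fs Sampling rate of the underlying series in Hz; the returned
#'   exponent is per second (`fs = 1` gives per-sample/per-step units).
#' @param theiler Temporal exclusion window for the neighbor search; default
#'   the embedding window `m * tau` when `ps` carries those attributes, else
#'   10.
#' @param n_steps Number of divergence steps tracked.
#' @return Scalar exponent (1/s).
#' @export
largest_lyapunov <- function(ps, fs = 1, theiler = NULL, n_steps = 30) {
  X <- as.matrix(ps)
  n <- nrow(X)
  stopifnot(n >= 50)
  if (is.null(theiler)) {
    m <- attr(ps, "m"); tau <- attr(ps, "tau")
    theiler <- if (!is.null(m) && !is.null(tau)) m * tau else 10L
  }
  D <- as.matrix(dist(X))
  diag(D) <- Inf
  D[abs(row(D) - col(D)) <= theiler] <- Inf
  nn <- apply(D, 1, which.min)
  n_steps <- min(n_steps, n - 2L)
  y <- vapply(seq_len(n_steps), function(j) {
    i <- which(seq_len(n) + j <= n & nn + j <= n)
    if (length(i) == 0) return(NA_real_)
    dj <- sqrt(rowSums((X[i + j, , drop = FALSE] - X[nn[i] + j, , drop = FALSE])^2))
    dj <- dj[dj > 0]
    if (length(dj) == 0) return(NA_real_)
    mean(log(dj))
  }, 0)
  steps <- which(!is.na(y))
  if (length(steps) < 3) return(0)
  # fit the initial linear region, before divergence saturates at the
  # attractor scale: keep the leading consecutive steps below 70% of the
  # total rise of the divergence curve
  y1 <- y[steps[1]]
  rng <- max(y[steps]) - y1
  if (rng < 0.1) {
    run <- steps # flat curve: no divergence to saturate
  } else {
    lin <- steps[y[steps] <= y1 + 0.7 * rng]
    run <- lin[cumsum(c(TRUE, diff(lin) != 1L)) == 1L]
    if (length(run) < 3) run <- head(steps, 3)
  }
  slope <- unname(coef(lm(y[run] ~ run))[2])
  slope * fs
}

#' Sample entropy
#'
#' `-ln(A/B)` with `A` the number of `(m+1)`-template Chebyshev matches and
#' `B` the number of `m`-template matches within tolerance `r * sd(x)`,
#' self-matches excluded. Needs on the order of 4000 samples for stable
#' estimates in production use; shorter series are accepted.
#'
#' @param x Numeric series.
#' @param m Template length (default 2).
#' @param r Tolerance as a fraction of the series standard deviation
#'   (default 0.2).
#' @return Scalar entropy (nats). A constant series gives 0; if no
#'   `m`-template matches exist 0 is returned, and if only the
#'   `(m+1)`-matches are absent the conservative upper estimate `log(B)` is
#'   returned.
#' @export
sample_entropy <- function(x, m = 2, r = 0.2) {
  stopifnot(length(x) > m + 2, r > 0)
  s <- sd(x)
  if (s == 0) return(0)
  counts <- sampen_counts(as.numeric(x), as.integer(m), r * s)
  A <- counts[1]; B <- counts[2]
  if (B == 0) return(0)
  if (A == 0) return(log(B))
  -log(A / B)
}

#' Recurrence matrix of a trajectory
#'
#' @param ps Trajectory matrix (points x dimension).
#' @param eps Recurrence radius: `R[i, j] = 1` iff the Euclidean distance
#'   between points i and j is at most `eps`. Symmetric with unit diagonal.
#' @return Binary integer matrix.
#' @export
recurrence_matrix <- function(ps, eps) {
  X <- as.matrix(ps)
  D <- as.matrix(dist(X))
  R <- (D <= eps) * 1L
  storage.mode(R) <- "integer"
  R
}

# lengths of diagonal recurrence lines (both triangles, main diagonal
# excluded) via run-length encoding of each off-diagonal
diag_line_lengths <- function(R) {
  n <- nrow(R)
  out <- integer(0)
  for (k in seq_len(n - 1)) {
    for (v in list(R[cbind(1:(n - k), (1 + k):n)], R[cbind((1 + k):n, 1:(n - k))])) {
      r <- rle(v)
      out <- c(out, r$lengths[r$values == 1L])
    }
  }
  out
}

#' Recurrence quantification measures
#'
#' Computes the four standard diagonal-line statistics of a recurrence
#' matrix: recurrence rate `RR` (off-diagonal density), determinism `DET`
#' (fraction of off-diagonal recurrence points lying on diagonal lines of
#' length at least `l_min`), mean diagonal line length `L`, and the Shannon
#' entropy `ENT` (natural log) of the line-length histogram. The main
#' diagonal (line of identity) is excluded throughout. With no qualifying
#' lines, `DET = L = ENT = 0`.
#'
#' @param R Symmetric binary recurrence matrix.
#' @param l_min Minimum diagonal line length (at least 2).
#' @return Named numeric vector `c(RR, DET, L, ENT)`.
#' @export
rqa <- function(R, l_min = 2) {
  stopifnot(is.matrix(R), nrow(R) == ncol(R), l_min >= 2)
  n <- nrow(R)
  off_points <- sum(R) - sum(diag(R))
  RR <- if (n > 1) off_points / (n * (n - 1)) else 0
  lens <- diag_line_lengths(R)
  lens <- lens[lens >= l_min]
  if (length(lens) == 0 || off_points == 0) {
    return(c(RR = RR, DET = 0, L = 0, ENT = 0))
  }
  DET <- min(1, sum(lens) / off_points)
  L <- mean(lens)
  p <- table(lens) / length(lens)
  ENT <- -sum(p * log(p))
  c(RR = RR, DET = DET, L = L, ENT = unname(ENT))
}

#' Differential entropy under a Gaussian assumption
#'
#' Closed form `0.5 * ln(2 * pi * e * sigma^2)` with `sigma^2` the unbiased
#' sample variance.
#'
#' @param x Numeric series.
#' @return Scalar entropy in nats.
#' @export
differential_entropy <- function(x) {
  0.5 * log(2 * pi * exp(1) * var(x))
}

#' Feature-extraction parameters
#'
#' Conventions for the nine nonlinear features. Phase-space statistics
#' (correlation dimension, Lyapunov exponent, recurrence measures) are
#' computed on an evenly decimated trajectory of at most `max_points` points
#' so epochs of any length cost the same; sample entropy, fractal dimension
#' and differential entropy use the full series.
#'
#' @param m Embedding dimension.
#' @param tau Delay in samples, or `NULL` for the first autocorrelation zero
#'   crossing per channel.
#' @param max_points Trajectory points kept for pairwise-distance statistics.
#' @param k_max Higuchi maximum interval.
#' @param sampen_m,sampen_r Sample-entropy template length and tolerance
#'   fraction.
#' @param rr_target Recurrence radius is chosen per epoch to fix the
#'   recurrence rate near this value, making DET/L/ENT comparable across
#'   epochs.
#' @param l_min Minimum diagonal line length.
#' @return Named list of parameters.
#' @export
feature_params <- function(m = 10, tau = NULL, max_points = 500, k_max = 10,
                           sampen_m = 2, sampen_r = 0.2, rr_target = 0.02,
                           l_min = 2) {
  list(m = m, tau = tau, max_points = max_points, k_max = k_max,
       sampen_m = sampen_m, sampen_r = sampen_r, rr_target = rr_target,
       l_min = l_min)
}

feature_abbrevs <- function() c("CD", "FD", "LLE", "SpEn", "RR", "DET", "L", "ENT", "DeEn")

# the nine features for one channel of one epoch
channel_features <- function(x, fs, params) {
  m <- params$m
  tau <- if (is.null(params$tau)) acf_delay(x, m) else params$tau
  traj <- delay_embed(x, m, tau)
  stride <- max(1L, floor(nrow(traj) / params$max_points))
  idx <- seq(1L, nrow(traj), by = stride)
  Xd <- traj[idx, , drop = FALSE]
  theiler_ds <- max(1L, ceiling(m * tau / stride))
  D <- as.matrix(dist(Xd))
  nd <- nrow(Xd)
  offd <- D[upper.tri(D)]

  cd <- correlation_dimension_from_dist(D, theiler_ds)
  fd <- higuchi_fd(x, params$k_max)
  ps_attr <- Xd
  attr(ps_attr, "m") <- m
  attr(ps_attr, "tau") <- max(1L, round(tau / stride))
  lle <- largest_lyapunov(ps_attr, fs = fs / stride, theiler = theiler_ds)
  spen <- sample_entropy(x, params$sampen_m, params$sampen_r)
  eps <- quantile(offd, params$rr_target)
  rq <- rqa((D <= eps) * 1L, params$l_min)
  deen <- differential_entropy(x)
  c(CD = cd, FD = fd, LLE = lle, SpEn = spen,
    RR = unname(rq["RR"]), DET = unname(rq["DET"]), L = unname(rq["L"]),
    ENT = unname(rq["ENT"]), DeEn = deen)
}

# correlation dimension given a precomputed distance matrix
correlation_dimension_from_dist <- function(D, theiler) {
  keep <- abs(row(D) - col(D)) > theiler
  d <- D[keep & upper.tri(D)]
  if (length(d) == 0 || max(d) == 0) return(0)
  lo <- quantile(d[d > 0], 0.01)
  hi <- quantile(d, 0.1)
  if (hi <= lo) return(0)
  radii <- exp(seq(log(lo), log(hi), length.out = 10))
  C <- vapply(radii, function(r) mean(d <= r), 0)
  use <- C > 0 & C < 1
  if (sum(use) < 2) return(0)
  unname(coef(lm(log(C[use]) ~ log(radii[use])))[2])
}

#' Extract the nine nonlinear features per selected channel
#'
#' Produces one row per epoch with columns `"<channel>_<abbrev>"` for each
#' selected channel and feature (CD, FD, LLE, SpEn, RR, DET, L, ENT, DeEn),
#' plus the `trial_id`, `quarter`, `arousal` and `valence` labels.
#' Deterministic given the parameters; any non-finite feature raises an
#' error naming the epoch, channel and feature.
#'
#' @param eset An `eeg_epoch_set`.
#' @param channels A [channel_set()] of channels to extract from.
#' @param params A [feature_params()] list.
#' @return A `feature_table` tibble.
#' @export
extract_features <- function(eset, channels, params = feature_params()) {
  stopifnot(inherits(eset, "eeg_epoch_set"), inherits(channels, "channel_set"))
  rows <- purrr::map_dfr(eset$epochs, function(e) {
    vals <- purrr::map(seq_along(channels$indices), function(ci) {
      ch <- channels$indices[ci]
      f <- channel_features(e$data[ch, ], e$fs, params)
      bad <- !is.finite(f)
      if (any(bad)) {
        stop("non-finite feature ", names(f)[bad][1], " for epoch ", e$trial_id,
             ", channel ", channels$labels[ci], call. = FALSE)
      }
      stats::setNames(f, paste0(channels$labels[ci], "_", names(f)))
    })
    tibble::as_tibble_row(c(
      list(trial_id = e$trial_id, quarter = e$quarter,
           arousal = e$arousal, valence = e$valence),
      as.list(unlist(vals))
    ))
  })
  class(rows) <- c("feature_table", class(rows))
  rows
}

#' Columns of a feature table that hold features (not labels)
#'
#' @param tbl A feature table.
#' @return Character vector of feature column names.
#' @export
feature_columns <- function(tbl) {
  setdiff(names(tbl), c("trial_id", "quarter", "arousal", "valence", "label"))
}
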