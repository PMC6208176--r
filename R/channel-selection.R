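#' Channel sets
#'
#' A `channel_set` holds strictly increasing channel indices, their montage
#' labels and the emotion class (or `"intersection"`) it belongs to.
#'
#' @param indices Integer channel indices (1-based).
#' @param labels Corresponding channel names.
#' @param class_label Quadrant label or `"intersection"`.
#' @return A `channel_set` object.
#' @export
channel_set <- function(indices, labels, class_label) {
  ord <- order(indices)
  structure(
    list(indices = as.integer(indices[ord]), labels = labels[ord],
         class_label = class_label),
    class = "channel_set"
  )
}

#' @export
print.channel_set <- function(x, ...) {
  cat("<channel_set> [", x$class_label, "] ",
      paste(x$labels, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Select emotional channels by activity thresholding
#'
#' Channels whose absolute normalized activity exceeds the threshold are
#' "emotional channels" for that class. Both strongly active and strongly
#' inactive channels carry information, hence the absolute value; comparison
#' is strict (`>`), so values exactly at the threshold are excluded.
#'
#' @param map An `activity_map` (from [average_and_normalize()]) restricted
#'   to, or filtered for, one class; if it holds several classes, pass
#'   `class` to pick one.
#' @param threshold Scalar in (0, 1).
#' @param class Optional class label to filter `map` by.
#' @return A [channel_set()].
#' @export
select_emotional_channels <- function(map, threshold, class = NULL) {
  if (threshold <= 0 || threshold >= 1) {
    stop("threshold must lie strictly inside (0, 1)", call. = FALSE)
  }
  tbl <- tibble::as_tibble(map)
  if (!is.null(class)) tbl <- dplyr::filter(tbl, .data$class == !!class)
  if (length(unique(tbl$class)) != 1) {
    stop("map must contain exactly one class (use the `class` argument)", call. = FALSE)
  }
  hit <- abs(tbl$activity) > threshold
  if (!any(hit)) {
    warning("no channel exceeds threshold ", threshold, " for class ",
            tbl$class[1], call. = FALSE)
  }
  channel_set(tbl$channel[hit], tbl$channel_label[hit], tbl$class[1])
}

#' Intersect per-class channel sets
#'
#' Keeps only channels common to all supplied sets — channels informative for
#' every emotion class.
#'
#' @param sets List of [channel_set()]s over the same channel space.
#' @return A [channel_set()] with `class_label = "intersection"`.
#' @export
intersect_channels <- function(sets) {
  stopifnot(length(sets) >= 1, all(vapply(sets, inherits, TRUE, "channel_set")))
  idx <- Reduce(intersect, lapply(sets, `[[`, "indices"))
  if (length(idx) == 0) {
    stop("empty channel intersection: decrease the activity threshold", call. = FALSE)
  }
  all_idx <- sets[[1]]$indices
  all_lab <- sets[[1]]$labels
  channel_set(idx, all_lab[match(idx, all_idx)], "intersection")
}

#' Tune the activity threshold against a downstream score
#'
#' Evaluates each candidate threshold by building the four per-class channel
#' sets, intersecting them, and scoring the intersection with a user-supplied
#' scorer (typically a cross-validated classification accuracy). Candidates
#' whose intersection is empty are skipped. The best-scoring candidate wins;
#' ties go to the smallest threshold (more channels retained).
#'
#' @param map An `activity_map` holding all four classes.
#' @param candidates Numeric candidate thresholds in (0, 1); default
#'   `seq(0.1, 0.9, by = 0.1)`.
#' @param scorer Function taking a [channel_set()] and returning a scalar
#'   score (larger is better).
#' @return The selected threshold (with the winning channel set and the score
#'   table attached as attributes `channels` and `scores`).
#' @export
tune_threshold <- function(map, candidates = seq(0.1, 0.9, by = 0.1), scorer) {
  stopifnot(length(candidates) >= 1)
  classes <- unique(tibble::as_tibble(map)$class)
  rows <- purrr::map(sort(candidates), function(th) {
    sets <- tryCatch(
      lapply(classes, function(cl)
        suppressWarnings(select_emotional_channels(map, th, class = cl))),
      error = function(e) NULL
    )
    inter <- tryCatch(intersect_channels(sets), error = function(e) NULL)
    if (is.null(inter)) return(NULL)
    tibble::tibble(threshold = th, n_channels = length(inter$indices),
                   score = scorer(inter), channels = list(inter))
  })
  scores <- dplyr::bind_rows(rows)
  if (nrow(scores) == 0) {
    stop("all candidate thresholds give an empty channel intersection", call. = FALSE)
  }
  best <- scores[which.max(scores$score), ] # which.max: first max = smallest threshold
  out <- best$threshold
  attr(out, "channels") <- best$channels[[1]]
  attr(out, "scores") <- dplyr::select(scores, -"channels")
  out
}
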