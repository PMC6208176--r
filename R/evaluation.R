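#' Confusion matrix of quadrant decisions
#'
#' Rows are decisions, columns are targets, in class order `Q1..Q4`.
#'
#' @param decisions,targets Character vectors of predicted and true classes.
#' @param levels Class order.
#' @return An `emotion_confusion` integer matrix.
#' @export
confusion <- function(decisions, targets, levels = quarter_levels()) {
  stopifnot(length(decisions) == length(targets))
  cm <- table(factor(decisions, levels = levels), factor(targets, levels = levels))
  m <- matrix(as.integer(cm), nrow = length(levels),
              dimnames = list(decision = levels, target = levels))
  structure(m, class = c("emotion_confusion", "matrix"))
}

#' Column-normalized confidence matrix
#'
#' Each cell is the percentage of that target class's samples receiving the
#' row's decision: `100 * counts[d, t] / column_total[t]`. Columns sum to 100
#' (empty target classes give zero columns).
#'
#' @param cm An [confusion()] matrix.
#' @return Numeric 4x4 percentage matrix.
#' @export
confidence <- function(cm) {
  totals <- colSums(cm)
  out <- sweep(unclass(cm) * 100, 2, pmax(totals, 1), "/")
  out[, totals == 0] <- 0
  out
}

#' Correct classification rate
#'
#' Trace of the confusion matrix divided by the grand total.
#'
#' @param cm An [confusion()] matrix.
#' @return Scalar in `[0, 1]`.
#' @export
ccr <- function(cm) {
  sum(diag(unclass(cm))) / sum(cm)
}

#' @export
print.emotion_confusion <- function(x, ...) {
  cat("<emotion_confusion> CCR = ", round(ccr(x), 4), "\n", sep = "")
  print(unclass(x))
  invisible(x)
}

#' @rdname confusion
#' @param x An `emotion_confusion`.
#' @param ... Unused.
#' @export
tidy.emotion_confusion <- function(x, ...) {
  conf <- confidence(x)
  tibble::as_tibble(as.table(unclass(x)), .name_repair = ~c("decision", "target", "n")) |>
    dplyr::mutate(confidence = as.numeric(conf[cbind(.data$decision, .data$target)]))
}

#' @rdname confusion
#' @param object An `emotion_confusion`.
#' @export
autoplot.emotion_confusion <- function(object, ...) {
  tidy(object) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$target, y = .data$decision,
                                 fill = .data$confidence)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(
      label = sprintf("%d\n%.2f%%", .data$n, .data$confidence)
    ), size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "seagreen") +
    ggplot2::scale_y_discrete(limits = rev) +
    ggplot2::labs(title = sprintf("CCR = %.4f", ccr(object))) +
    ggplot2::theme_minimal()
}

#' Stratified fold assignment
#'
#' @param labels Class labels.
#' @param k Fold count.
#' @param seed Integer seed.
#' @return Integer fold id per sample; folds partition the data with
#'   per-class sizes differing by at most 1.
#' @export
cv_folds <- function(labels, k = 10, seed = 1) {
  set.seed(as.integer(seed))
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- sample(which(labels == cl))
    if (length(idx) < k) {
      warning("class ", cl, " has fewer than ", k, " samples; folds adjusted",
              call. = FALSE)
    }
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Pipeline configuration for cross-validation
#'
#' Collects every tunable stage parameter: SOBI lags, the activity threshold
#' (stepped down by 0.1, with a warning, if it yields an empty channel
#' intersection in a training fold), feature-extraction parameters, the
#' feature-tree search settings, the relabeling threshold and MLP settings.
#'
#' @param channel_threshold Activity threshold in (0, 1).
#' @param lags SOBI lags (`NULL` for the default).
#' @param features A [feature_params()] list.
#' @param tree_k,tree_budget,tree_max_depth,n_keep Feature-tree search
#'   settings.
#' @param membership_threshold,hidden,maxit,decay MLP/relabeling settings.
#' @param cutoff Arousal/valence binarization cutoff.
#' @return Named list.
#' @export
pipeline_config <- function(channel_threshold = 0.5, lags = NULL,
                            features = feature_params(),
                            tree_k = 5, tree_budget = 500, tree_max_depth = 4,
                            n_keep = 10, membership_threshold = 0.4,
                            hidden = 20, maxit = 500, decay = 1e-4, cutoff = 5) {
  list(channel_threshold = channel_threshold, lags = lags, features = features,
       tree_k = tree_k, tree_budget = tree_budget,
       tree_max_depth = tree_max_depth, n_keep = n_keep,
       membership_threshold = membership_threshold, hidden = hidden,
       maxit = maxit, decay = decay, cutoff = cutoff)
}

# per-class channel sets -> intersection, stepping the threshold down if empty
select_common_channels <- function(map, threshold, channel_labels) {
  th <- threshold
  repeat {
    sets <- lapply(unique(tibble::as_tibble(map)$class), function(cl)
      suppressWarnings(select_emotional_channels(map, th, class = cl)))
    inter <- tryCatch(intersect_channels(sets), error = function(e) NULL)
    if (!is.null(inter)) {
      if (th < threshold) {
        warning("activity threshold stepped down to ", th,
                " to keep the channel intersection nonempty", call. = FALSE)
      }
      return(inter)
    }
    th <- th - 0.1
    if (th <= 0) stop("no threshold yields a nonempty channel intersection",
                      call. = FALSE)
  }
}

#' Cross-validate the full emotion-recognition pipeline
#'
#' Runs stratified k-fold cross-validation with every supervised stage refit
#' inside each training fold: class-average activity maps and channel
#' selection, the two-locality feature-subset search, prototypes/relabeling
#' and the two MLPs. Per-epoch source separation and feature extraction are
#' computed once up front — they are label-free, so no information leaks
#' across folds. Counts are pooled over folds.
#'
#' @param eset An `eeg_epoch_set`.
#' @param config A [pipeline_config()].
#' @param k Fold count (default 10).
#' @param seed Integer seed.
#' @return An `emotion_cv` object: pooled `confusion`, pooled `ccr`, fused
#'   and single-learner accuracies, and the per-sample `predictions` tibble.
#' @export
cross_validate <- function(eset, config = pipeline_config(), k = 10, seed = 1) {
  stopifnot(inherits(eset, "eeg_epoch_set"))
  n_ch <- nrow(eset$epochs[[1]]$data)
  labels <- eset$epochs[[1]]$channel_labels
  activity <- epoch_activity(eset, lags = config$lags)
  all_channels <- channel_set(seq_len(n_ch), labels, "all")
  features <- extract_features(eset, all_channels, config$features)
  quarter <- features$quarter
  fold <- cv_folds(quarter, k = k, seed = seed)

  preds <- purrr::map_dfr(seq_len(k), function(f) {
    tr <- which(fold != f)
    te <- which(fold == f)
    if (length(te) == 0) return(NULL)
    map <- average_and_normalize(activity[tr, , drop = FALSE], quarter[tr],
                                 channel_labels = labels)
    chans <- select_common_channels(map, config$channel_threshold, labels)
    cols <- as.vector(outer(chans$labels, feature_abbrevs(), paste, sep = "_"))
    tbl_tr <- features[tr, c("trial_id", "quarter", "arousal", "valence", cols)]
    tbl_te <- features[te, c("trial_id", "quarter", "arousal", "valence", cols)]
    subsets <- two_locality_subsets(
      tbl_tr, k = config$tree_k, budget = config$tree_budget,
      max_depth = config$tree_max_depth, n_keep = config$n_keep,
      cutoff = config$cutoff, seed = seed + f
    )
    model <- fit_dst(tbl_tr, subsets,
                     membership_threshold = config$membership_threshold,
                     hidden = config$hidden, maxit = config$maxit,
                     decay = config$decay, seed = seed + f)
    dplyr::bind_cols(
      tibble::tibble(fold = f, trial_id = tbl_te$trial_id, quarter = tbl_te$quarter),
      predict(model, tbl_te)
    )
  })

  cm <- confusion(preds$.pred, preds$quarter)
  structure(
    list(
      confusion = cm, ccr = ccr(cm),
      fused_accuracy = mean(preds$.pred == preds$quarter),
      arousal_accuracy = mean(preds$.pred_arousal == preds$quarter),
      valence_accuracy = mean(preds$.pred_valence == preds$quarter),
      mean_conflict = mean(preds$conflict),
      predictions = preds, k = k, seed = seed
    ),
    class = "emotion_cv"
  )
}

#' @export
print.emotion_cv <- function(x, ...) {
  cat("<emotion_cv> ", x$k, "-fold, pooled CCR = ", round(x$ccr, 4),
      " (arousal-subset MLP ", round(x$arousal_accuracy, 4),
      ", valence-subset MLP ", round(x$valence_accuracy, 4), ")\n", sep = "")
  invisible(x)
}

#' @rdname cross_validate
#' @param x An `emotion_cv`.
#' @param ... Unused.
#' @export
tidy.emotion_cv <- function(x, ...) {
  x$predictions |>
    dplyr::group_by(.data$fold) |>
    dplyr::summarise(
      n = dplyr::n(),
      accuracy = mean(.data$.pred == .data$quarter),
      mean_conflict = mean(.data$conflict),
      .groups = "drop"
    )
}

#' @rdname cross_validate
#' @export
glance.emotion_cv <- function(x, ...) {
  tibble::tibble(
    k = x$k, n = nrow(x$predictions), ccr = x$ccr,
    fused_accuracy = x$fused_accuracy,
    arousal_accuracy = x$arousal_accuracy,
    valence_accuracy = x$valence_accuracy,
    mean_conflict = x$mean_conflict
  )
}

#' Markdown report of confusion and confidence matrices
#'
#' Renders the pooled confusion matrix in the count-over-percentage layout
#' used to report quadrant classification results.
#'
#' @param cm An [confusion()] matrix.
#' @return Character vector of Markdown lines.
#' @export
confusion_report <- function(cm) {
  conf <- confidence(cm)
  lv <- rownames(cm)
  lines <- c(
    paste0("| Decision \\ Target | ", paste(lv, collapse = " | "), " |"),
    paste0("|---", strrep("|---", length(lv)), "|")
  )
  for (d in lv) {
    cells <- vapply(lv, function(t)
      sprintf("%d<br>%.2f%%", cm[d, t], conf[d, t]), "")
    lines <- c(lines, paste0("| ", d, " | ", paste(cells, collapse = " | "), " |"))
  }
  c(lines, "", sprintf("CCR = %.4f", ccr(cm)))
}
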