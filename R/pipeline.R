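#' Write and read epoch sets on disk
#'
#' Epochs are stored as one CSV matrix per trial (channels x samples, no
#' header) plus a `manifest.json` carrying trial ids, ratings, quadrant
#' labels, sampling rate and channel labels.
#'
#' @param eset An `eeg_epoch_set`.
#' @param dir Directory to create/read.
#' @return `write_epochs` the directory (invisibly); `read_epochs` an
#'   `eeg_epoch_set`.
#' @export
write_epochs <- function(eset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- purrr::map(eset$epochs, function(e) {
    utils::write.table(e$data, file.path(dir, paste0(e$trial_id, ".csv")),
                       sep = ",", row.names = FALSE, col.names = FALSE)
    list(trial_id = e$trial_id, arousal = e$arousal, valence = e$valence,
         quarter = e$quarter, fs = e$fs)
  })
  jsonlite::write_json(
    list(channel_labels = eset$epochs[[1]]$channel_labels, trials = manifest),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}

#' @rdname write_epochs
#' @export
read_epochs <- function(dir) {
  mf <- file.path(dir, "manifest.json")
  if (!file.exists(mf)) stop("no manifest.json in ", dir,
                             ": run the 'simulate' stage first", call. = FALSE)
  man <- jsonlite::fromJSON(mf, simplifyDataFrame = FALSE)
  labels <- unlist(man$channel_labels)
  epochs <- purrr::map(man$trials, function(tr) {
    X <- as.matrix(utils::read.table(file.path(dir, paste0(tr$trial_id, ".csv")),
                                     sep = ","))
    dimnames(X) <- list(labels, NULL)
    structure(
      list(data = X, fs = tr$fs, channel_labels = labels,
           trial_id = tr$trial_id, arousal = tr$arousal, valence = tr$valence,
           quarter = tr$quarter),
      class = "eeg_epoch"
    )
  })
  new_epoch_set(epochs)
}

#' Load a pipeline configuration from YAML (or defaults)
#'
#' The YAML may hold `sim` (arguments of [sim_config()] except
#' `class_channel_map`, which defaults per channel count), `pipeline`
#' (arguments of [pipeline_config()]), and `cv` (`k`). Missing entries fall
#' back to the package defaults.
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @return Nested configuration list.
#' @export
read_pipeline_config <- function(path = NULL) {
  cfg <- list(sim = list(), pipeline = list(), cv = list(k = 10))
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    cfg <- utils::modifyList(cfg, user)
  }
  cfg
}

stage_log <- function(out_dir, stage, config, seed, extra = list()) {
  jsonlite::write_json(
    c(list(stage = stage, seed = seed, config_hash = rlang::hash(config),
           timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")), extra),
    file.path(out_dir, paste0(stage, "_log.json")), auto_unbox = TRUE, digits = NA
  )
}

require_artifact <- function(path, stage) {
  if (!file.exists(path)) {
    stop("missing artifact ", path, ": run the '", stage, "' stage first",
         call. = FALSE)
  }
  path
}

#' Run one pipeline stage
#'
#' Stages: `simulate`, `select-channels`, `extract-features`,
#' `select-features`, `train`, `predict`, `evaluate`, and `all` (the full
#' sequence). Each stage reads its predecessors' artifacts from `out_dir`,
#' writes its own, and logs its parameters, seed and configuration hash.
#'
#' @param stage Stage name.
#' @param config Configuration list from [read_pipeline_config()].
#' @param out_dir Artifact directory.
#' @param seed Integer seed threaded through every stochastic stage.
#' @return The stage's main artifact, invisibly.
#' @export
run_stage <- function(stage, config = read_pipeline_config(), out_dir = "emofuse_out",
                      seed = 1) {
  stages <- c("simulate", "select-channels", "extract-features",
              "select-features", "train", "predict", "evaluate")
  if (identical(stage, "all")) {
    out <- NULL
    for (s in stages) out <- run_stage(s, config, out_dir, seed)
    return(invisible(out))
  }
  if (!stage %in% stages) {
    stop("unknown stage '", stage, "'; use one of: ",
         paste(c(stages, "all"), collapse = ", "), call. = FALSE)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  pconf <- do.call(pipeline_config, config$pipeline %||% list())
  result <- switch(stage,
    "simulate" = {
      sim_args <- utils::modifyList(list(seed = seed), config$sim %||% list())
      cfg <- do.call(sim_config, sim_args)
      eset <- generate_epochs(cfg)
      write_epochs(eset, file.path(out_dir, "epochs"))
      eset
    },
    "select-channels" = {
      eset <- read_epochs(file.path(out_dir, "epochs"))
      labels <- eset$epochs[[1]]$channel_labels
      activity <- epoch_activity(eset, lags = pconf$lags)
      map <- average_and_normalize(activity, eset$manifest$quarter,
                                   channel_labels = labels)
      write.csv(map, file.path(out_dir, "activity_map.csv"), row.names = FALSE)
      inter <- select_common_channels(map, pconf$channel_threshold, labels)
      sets <- lapply(unique(map$class), function(cl)
        suppressWarnings(select_emotional_channels(map, pconf$channel_threshold,
                                                   class = cl)))
      jsonlite::write_json(
        list(threshold = pconf$channel_threshold,
             per_class = lapply(sets, unclass), intersection = unclass(inter)),
        file.path(out_dir, "channels.json"), auto_unbox = TRUE, digits = NA
      )
      inter
    },
    "extract-features" = {
      eset <- read_epochs(file.path(out_dir, "epochs"))
      ch <- jsonlite::fromJSON(require_artifact(file.path(out_dir, "channels.json"),
                                                "select-channels"))
      chans <- channel_set(ch$intersection$indices, ch$intersection$labels,
                           "intersection")
      tbl <- extract_features(eset, chans, pconf$features)
      write.csv(tbl, file.path(out_dir, "features.csv"), row.names = FALSE)
      jsonlite::write_json(pconf$features, file.path(out_dir, "feature_params.json"),
                           auto_unbox = TRUE, digits = NA, null = "null")
      tbl
    },
    "select-features" = {
      tbl <- read_feature_table(out_dir)
      subsets <- two_locality_subsets(tbl, k = pconf$tree_k,
                                      budget = pconf$tree_budget,
                                      max_depth = pconf$tree_max_depth,
                                      n_keep = pconf$n_keep,
                                      cutoff = pconf$cutoff, seed = seed)
      jsonlite::write_json(
        list(arousal = subsets$arousal, valence = subsets$valence,
             arousal_score = subsets$searches$arousal$score,
             valence_score = subsets$searches$valence$score),
        file.path(out_dir, "subsets.json"), auto_unbox = TRUE, digits = NA
      )
      subsets
    },
    "train" = {
      tbl <- read_feature_table(out_dir)
      ss <- jsonlite::fromJSON(require_artifact(file.path(out_dir, "subsets.json"),
                                                "select-features"))
      model <- fit_dst(tbl, list(arousal = ss$arousal, valence = ss$valence),
                       membership_threshold = pconf$membership_threshold,
                       hidden = pconf$hidden, maxit = pconf$maxit,
                       decay = pconf$decay, seed = seed)
      save_model(model, file.path(out_dir, "model.json"))
      model
    },
    "predict" = {
      tbl <- read_feature_table(out_dir)
      model <- load_model(require_artifact(file.path(out_dir, "model.json"), "train"))
      preds <- dplyr::bind_cols(tibble::tibble(trial_id = tbl$trial_id),
                                predict(model, tbl))
      write.csv(preds, file.path(out_dir, "predictions.csv"), row.names = FALSE)
      preds
    },
    "evaluate" = {
      eset <- read_epochs(file.path(out_dir, "epochs"))
      cv <- cross_validate(eset, pconf, k = config$cv$k %||% 10, seed = seed)
      write.csv(unclass(cv$confusion), file.path(out_dir, "confusion.csv"))
      writeLines(confusion_report(cv$confusion), file.path(out_dir, "report.md"))
      jsonlite::write_json(as.list(glance(cv)), file.path(out_dir, "metrics.json"),
                           auto_unbox = TRUE, digits = NA)
      cv
    }
  )
  stage_log(out_dir, stage, config, seed)
  invisible(result)
}

read_feature_table <- function(out_dir) {
  path <- require_artifact(file.path(out_dir, "features.csv"), "extract-features")
  tbl <- tibble::as_tibble(read.csv(path, check.names = FALSE))
  class(tbl) <- c("feature_table", class(tbl))
  tbl
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Persist and restore a fitted fusion model
#'
#' The bundle is a single JSON file: metadata, feature subsets, prototypes,
#' scalers, and the raw MLP weight vectors. `load_model` rebuilds the model
#' with a weight-based forward pass, so predictions match the original
#' object.
#'
#' @param model A `dst_model`.
#' @param path JSON file path.
#' @return `save_model` the path invisibly; `load_model` a `dst_model`.
#' @export
save_model <- function(model, path) {
  learners <- purrr::map(model$learners, function(l) {
    list(cols = l$cols, center = l$center, scale = l$scale,
         prototypes = list(values = as.numeric(l$prototypes),
                           classes = rownames(l$prototypes)),
         wts = l$net$wts, size = l$net$n)
  })
  jsonlite::write_json(
    list(format = "emofuse-dst-bundle", version = 1L, frame = model$frame,
         params = model$params, learners = learners),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  learners <- purrr::map(obj$learners, function(l) {
    proto <- matrix(l$prototypes$values, nrow = length(l$prototypes$classes),
                    dimnames = list(l$prototypes$classes, l$cols))
    list(cols = l$cols, center = stats::setNames(l$center, l$cols),
         scale = stats::setNames(l$scale, l$cols), prototypes = proto,
         net = structure(list(wts = l$wts, n = l$size, frame = obj$frame),
                         class = "emofuse_net"))
  })
  structure(list(learners = learners, frame = obj$frame, params = obj$params),
            class = "dst_model")
}

# forward pass through a saved single-hidden-layer softmax net using the
# nnet weight layout: per hidden unit (bias, inputs), then per output
# (bias, hidden)
#' @export
predict.emofuse_net <- function(object, newdata, ...) {
  n <- object$n # c(inputs, hidden, outputs)
  p <- n[1]; h <- n[2]; K <- n[3]
  W1 <- matrix(object$wts[seq_len(h * (p + 1))], nrow = h, byrow = TRUE)
  W2 <- matrix(object$wts[h * (p + 1) + seq_len(K * (h + 1))], nrow = K, byrow = TRUE)
  H <- 1 / (1 + exp(-(cbind(1, newdata) %*% t(W1))))
  O <- cbind(1, H) %*% t(W2)
  E <- exp(O - apply(O, 1, max))
  P <- E / rowSums(E)
  colnames(P) <- object$frame
  P
}
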