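#' Declare a zero-shot recognition experiment
#'
#' A configuration names the data source (an annotated event log, an already
#' parsed/segmented input, or a synthetic scenario), the embedding source,
#' the disjoint seen and unseen label sets, and the network settings. The
#' seen/unseen disjointness rule is validated here, before any computation.
#'
#' @param seen,unseen Character vectors of activity labels; must be disjoint
#'   and non-empty. May be omitted when `scenario` is given (the scenario
#'   defines them).
#' @param events A parsed event tibble, or a path to a CASAS-dialect log.
#' @param scenario A `zs_scenario` from [make_congruent_scenario()] for
#'   fully synthetic runs.
#' @param embeddings An [embedding_table()] or a path to a word2vec text
#'   file; defaults to the scenario's toy embeddings for synthetic runs.
#' @param network Named list of overrides for [network_config()] (e.g.
#'   `list(epochs = 100)`).
#' @param scale Standardize feature columns with training-data parameters.
#' @param seed Experiment seed (also the default network seed).
#' @param out_dir Optional directory to write report artifacts into.
#' @return A validated `scenario_config` object.
#' @export
scenario_config <- function(seen = NULL, unseen = NULL,
                            events = NULL, scenario = NULL,
                            embeddings = NULL,
                            network = list(),
                            scale = TRUE,
                            seed = 1L,
                            out_dir = NULL) {
  if (is.null(scenario) && is.null(events)) {
    abort("supply a data source: `events` or `scenario`.", class = "adlzero_validation")
  }
  if (!is.null(scenario)) {
    stopifnot(inherits(scenario, "zs_scenario"))
    seen <- seen %||% scenario$seen_profiles$labels
    unseen <- unseen %||% scenario$unseen_profiles$labels
  }
  if (is.null(seen) || is.null(unseen) ||
      length(seen) == 0 || length(unseen) == 0) {
    abort("both `seen` and `unseen` label sets are required and non-empty.",
          class = "adlzero_validation")
  }
  overlap <- intersect(seen, unseen)
  if (length(overlap) > 0) {
    abort(sprintf("seen and unseen classes must be disjoint; overlap: %s.",
                  paste(overlap, collapse = ", ")),
          class = "adlzero_validation")
  }
  structure(list(seen = seen, unseen = unseen, events = events,
                 scenario = scenario, embeddings = embeddings,
                 network = network, scale = isTRUE(scale),
                 seed = as.integer(seed), out_dir = out_dir),
            class = "scenario_config")
}

resolve_embeddings <- function(config) {
  emb <- config$embeddings
  if (is.null(emb)) {
    if (is.null(config$scenario)) {
      abort("an embedding source is required for real event logs.",
            class = "adlzero_validation")
    }
    return(make_toy_embeddings(config$scenario)$table)
  }
  if (inherits(emb, "embedding_table")) return(emb)
  read_word2vec(emb)
}

#' Run the full zero-shot pipeline
#'
#' Executes parse -> segment -> featurize (vocabulary and scaler fitted on
#' seen data only) -> build and train the network -> zero-shot prediction ->
#' evaluation, logging instance/class counts at each stage. Two runs with
#' the same configuration and seed produce identical reports.
#'
#' @param config A [scenario_config()].
#' @param quiet Suppress stage messages.
#' @return An object of class `zs_report`: the confusion matrix, per-class
#'   metrics, per-instance predictions, the trained network and scaler, the
#'   seen/unseen correlation matrices (pearson on feature centroids, cosine
#'   on prototypes) and a reproducibility manifest. Artifacts are written to
#'   `config$out_dir` when set.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "scenario_config"))
  say <- function(...) if (!quiet) message(sprintf(...))

  # --- stage: data -----------------------------------------------------
  if (!is.null(config$scenario)) {
    streams <- generate_scenario_streams(config$scenario)
    train_events <- streams$train$events
    test_events <- streams$test$events
    train_instances <- segment_activity_instances(train_events)
    test_instances <- segment_activity_instances(test_events)
  } else {
    events <- config$events
    if (is.character(events)) events <- read_casas_events(events)
    instances <- segment_activity_instances(events)
    train_instances <- instances[instances$label %in% config$seen, ]
    test_instances <- instances[instances$label %in% config$unseen, ]
  }
  if (nrow(train_instances) == 0) {
    abort("data stage: no training instances with a seen label.")
  }
  if (nrow(test_instances) == 0) {
    abort("data stage: no zero-shot instances with an unseen label.")
  }
  say("data: %d training instances (%d seen classes), %d zero-shot instances (%d unseen classes)",
      nrow(train_instances), length(unique(train_instances$label)),
      nrow(test_instances), length(unique(test_instances$label)))

  # --- stage: features (vocabulary and scaler from seen data only) -----
  vocabulary <- build_sensor_vocabulary(train_instances)
  train_raw <- build_feature_matrix(train_instances, vocabulary)
  test_raw <- build_feature_matrix(test_instances, vocabulary)
  scaler <- NULL
  train_features <- train_raw
  test_features <- test_raw
  if (config$scale) {
    scaler <- fit_feature_scaler(train_raw)
    train_features <- scale_features(train_raw, scaler)
    test_features <- scale_features(test_raw, scaler)
  }
  say("features: %d sensors in vocabulary", length(vocabulary))

  # --- stage: semantic space ------------------------------------------
  table <- resolve_embeddings(config)
  seen_proto <- label_prototypes(config$seen, table)
  unseen_proto <- label_prototypes(config$unseen, table)
  say("semantic space: dimension %d", table$dim)

  # --- stage: model ----------------------------------------------------
  net_args <- utils::modifyList(
    list(input_dim = length(vocabulary), embedding_dim = table$dim,
         seed = config$seed),
    config$network)
  network <- build_network(do.call(network_config, net_args), seen_proto)
  network <- zs_train(network, train_features)
  say("model: trained %d epochs, seen-class accuracy %.3f",
      network$config$epochs, network$final_accuracy)

  # --- stage: zero-shot prediction and evaluation ---------------------
  preds <- predict_zero_shot(network, test_features, unseen_proto)
  results <- dplyr::bind_cols(
    test_features[, c("instance_id", "label")], preds)
  cm <- confusion_matrix(results, class_order = sort(config$unseen))
  metrics <- class_metrics(cm, round_to = 2)
  say("evaluation: zero-shot accuracy %.3f",
      sum(diag(cm$table)) / sum(cm$table))

  centroids <- dplyr::bind_rows(train_raw, test_raw) |>
    dplyr::select(-"instance_id") |>
    dplyr::group_by(.data$label) |>
    dplyr::summarise(dplyr::across(dplyr::everything(), mean), .groups = "drop")
  correlations <- list(
    features = correlation_matrix(centroids, method = "pearson"),
    prototypes = correlation_matrix(
      rbind(seen_proto$vectors, unseen_proto$vectors), method = "cosine")
  )

  manifest <- list(
    package = "adlzero",
    seed = config$seed,
    config_hash = rlang::hash(config[setdiff(names(config), "out_dir")]),
    n_train = nrow(train_instances),
    n_test = nrow(test_instances),
    seen = config$seen,
    unseen = config$unseen,
    n_sensors = length(vocabulary)
  )

  report <- structure(list(
    confusion = cm,
    metrics = metrics,
    predictions = results,
    network = network,
    scaler = scaler,
    vocabulary = vocabulary,
    correlations = correlations,
    manifest = manifest
  ), class = "zs_report")

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(report$confusion$table,
                       file.path(config$out_dir, "confusion.tsv"),
                       sep = "\t", quote = FALSE, col.names = NA)
    write_class_metrics(metrics, file.path(config$out_dir, "metrics.tsv"))
    utils::write.table(results, file.path(config$out_dir, "predictions.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    write_zs_checkpoint(network, file.path(config$out_dir, "checkpoint.json"),
                        scaler = scaler)
  }
  report
}

#' @export
print.zs_report <- function(x, ...) {
  cat("<zero-shot evaluation report>\n")
  print(x$confusion)
  cat("\nPer-class metrics:\n")
  print(as.data.frame(x$metrics[, c("class", "n_classified", "n_truth",
                                    "accuracy", "precision", "recall",
                                    "f_measure")]))
  invisible(x)
}

#' @method glance zs_report
#' @export
glance.zs_report <- function(x, ...) {
  tibble::tibble(
    n_test = sum(x$confusion$table),
    zero_shot_accuracy = sum(diag(x$confusion$table)) / sum(x$confusion$table),
    n_unseen_classes = length(x$confusion$labels),
    seen_train_accuracy = x$network$final_accuracy
  )
}
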