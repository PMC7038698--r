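#' Build the sensor vocabulary defining feature-column order
#'
#' The vocabulary is the sorted set of sensor ids that produced at least one
#' categorical (binary-state) event across the supplied instances. It fixes
#' the column order of every feature matrix built from it, so it must be
#' built once, on training instances only, and then reused unchanged at test
#' time. Numeric environmental sensors (temperature, light, ...) are excluded
#' unless `include_numeric = TRUE`, in which case they are counted through
#' change-point binarization (see [count_activations()]).
#'
#' @param instances Instance tibble from [segment_activity_instances()].
#' @param include_numeric Also admit sensors that only report numeric values.
#' @return A sorted character vector of sensor ids.
#' @export
build_sensor_vocabulary <- function(instances, include_numeric = FALSE) {
  stopifnot(nrow(instances) >= 1)
  events <- dplyr::bind_rows(instances$events)
  ids <- unique(events$sensor_id[events$message_type == "categorical"])
  if (include_numeric) {
    ids <- union(ids, unique(events$sensor_id[events$message_type == "numeric"]))
  }
  if (length(ids) == 0) {
    abort(paste0(
      "no binary (ON/OFF/OPEN/CLOSE) sensors found in these instances; ",
      "if the data only has numeric sensors, set `include_numeric = TRUE` ",
      "and choose a `numeric_threshold` for change-point binarization."))
  }
  sort(ids)
}

#' Count activation events per sensor for one activity instance
#'
#' An activation is an `ON` or `OPEN` message; `OFF`/`CLOSE` transitions and
#' sensors absent from the instance contribute zero, and sensors outside the
#' vocabulary are ignored. When `numeric_threshold` is supplied, a numeric
#' sensor in the vocabulary is additionally counted as activated each time
#' its reading changes by more than the threshold relative to its previous
#' reading within the instance.
#'
#' @param instance_events Event tibble of a single instance.
#' @param vocabulary Sensor vocabulary from [build_sensor_vocabulary()].
#' @param numeric_threshold Absolute change in a numeric reading that counts
#'   as an activation; `NULL` (default) ignores numeric events entirely.
#' @return A named integer vector of length `length(vocabulary)`.
#' @export
count_activations <- function(instance_events, vocabulary,
                              numeric_threshold = NULL) {
  stopifnot(length(vocabulary) >= 1)
  counts <- setNames(integer(length(vocabulary)), vocabulary)
  on <- instance_events$message_type == "categorical" &
    toupper(instance_events$message) %in% c("ON", "OPEN")
  tab <- table(factor(instance_events$sensor_id[on], levels = vocabulary))
  counts[] <- as.integer(tab)
  if (!is.null(numeric_threshold)) {
    num <- instance_events[instance_events$message_type == "numeric" &
                             instance_events$sensor_id %in% vocabulary, ]
    if (nrow(num) > 0) {
      jumps <- tapply(num$value, num$sensor_id, function(v) {
        sum(abs(diff(v)) > numeric_threshold)
      })
      counts[names(jumps)] <- counts[names(jumps)] + as.integer(jumps)
    }
  }
  counts
}

#' Build the per-instance activation-count feature matrix
#'
#' Row i holds the activation counts of instance i over the vocabulary — the
#' m x n count matrix at the heart of the method, with m instances and n
#' sensors. Raw counts are non-negative integers; when a fitted scaler is
#' supplied the columns are standardized with parameters estimated on
#' training data only (see [fit_feature_scaler()]), which guards against
#' train/test leakage.
#'
#' @param instances Instance tibble from [segment_activity_instances()].
#' @param vocabulary Sensor vocabulary (fixed on training data).
#' @param scaler Optional fitted scaler from [fit_feature_scaler()].
#' @inheritParams count_activations
#' @return A tibble with `instance_id`, `label`, then one numeric column per
#'   vocabulary sensor, in vocabulary order.
#' @export
build_feature_matrix <- function(instances, vocabulary, scaler = NULL,
                                 numeric_threshold = NULL) {
  stopifnot(length(vocabulary) >= 1)
  counts <- t(vapply(
    instances$events,
    count_activations,
    integer(length(vocabulary)),
    vocabulary = vocabulary,
    numeric_threshold = numeric_threshold
  ))
  out <- tibble::as_tibble(as.data.frame(counts))
  names(out) <- vocabulary
  out <- dplyr::bind_cols(
    tibble::tibble(instance_id = instances$instance_id, label = instances$label),
    out
  )
  if (!is.null(scaler)) {
    out <- scale_features(out, scaler)
  }
  out
}

#' Fit a per-column standardizer on a training feature matrix
#'
#' @param features Feature tibble from [build_feature_matrix()] (unscaled,
#'   training data).
#' @return An object of class `feature_scaler` holding per-sensor means and
#'   standard deviations. Constant columns get unit scale so they map to 0
#'   rather than NaN.
#' @export
fit_feature_scaler <- function(features) {
  x <- feature_values(features)
  mu <- colMeans(x)
  sigma <- apply(x, 2, sd)
  sigma[!is.finite(sigma) | sigma == 0] <- 1
  structure(list(mean = mu, sd = sigma, sensors = colnames(x)),
            class = "feature_scaler")
}

#' Apply a fitted standardizer to a feature matrix
#'
#' @param features Feature tibble from [build_feature_matrix()].
#' @param scaler Fitted scaler from [fit_feature_scaler()].
#' @return The feature tibble with sensor columns centered and scaled by the
#'   scaler's (training-data) parameters.
#' @export
scale_features <- function(features, scaler) {
  stopifnot(inherits(scaler, "feature_scaler"))
  sensors <- feature_sensors(features)
  if (!identical(sensors, scaler$sensors)) {
    abort("scaler was fitted on a different sensor vocabulary than `features`.")
  }
  for (s in sensors) {
    features[[s]] <- (features[[s]] - scaler$mean[[s]]) / scaler$sd[[s]]
  }
  features
}

#' Extract the numeric value matrix from a feature tibble
#'
#' @param features Feature tibble from [build_feature_matrix()].
#' @return A numeric matrix (instances x sensors).
#' @export
feature_values <- function(features) {
  sensors <- feature_sensors(features)
  as.matrix(features[, sensors, drop = FALSE])
}

feature_sensors <- function(features) {
  setdiff(names(features), c("instance_id", "label"))
}

#' Write / read a feature matrix as delimited text
#'
#' Tab-separated with a header naming the sensors and a label column; raw
#' integer counts round-trip bit-exactly.
#'
#' @param features Feature tibble.
#' @param path File path.
#' @return `write_feature_matrix()` returns `features` invisibly;
#'   `read_feature_matrix()` returns the feature tibble.
#' @export
write_feature_matrix <- function(features, path) {
  utils::write.table(features, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(features)
}

#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(path) {
  tibble::as_tibble(utils::read.table(path, sep = "\t", header = TRUE,
                                      check.names = FALSE,
                                      stringsAsFactors = FALSE))
}
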