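# Synthetic smart-home streams with the statistical structure the method
# assumes: each activity class has a per-sensor Poisson activation profile,
# each unseen class is a convex mixture of seen classes, and the toy
# embedding geometry mirrors the same mixture — the congruence that makes
# zero-shot transfer work (and, when broken, fail).

#' Per-class activation-rate profiles
#'
#' @param rates Numeric matrix of expected activation counts per instance;
#'   rows are activity classes (row names = labels), columns are sensors
#'   (column names = sensor ids). All rates finite and non-negative, each
#'   class with at least one positive rate.
#' @param n_instances Integer vector (recycled) of instances to generate per
#'   class.
#' @return An object of class `activity_profiles`.
#' @export
activity_profiles <- function(rates, n_instances) {
  stopifnot(is.matrix(rates), !is.null(rownames(rates)), !is.null(colnames(rates)),
            all(is.finite(rates)), all(rates >= 0))
  if (any(rowSums(rates) == 0)) {
    abort("every class needs at least one positive activation rate.")
  }
  n_instances <- rep_len(as.integer(n_instances), nrow(rates))
  structure(list(labels = rownames(rates),
                 sensors = colnames(rates),
                 rates = rates,
                 n_instances = setNames(n_instances, rownames(rates))),
            class = "activity_profiles")
}

#' Generate an annotated CASAS-dialect event stream
#'
#' Draws, for every instance, per-sensor activation counts from a Poisson
#' law at the class profile's rate; each ON is paired with a later OFF, all
#' timestamps are strictly increasing on a centisecond grid, and every
#' instance is wrapped in begin/end annotation events (carried by OFF
#' boundary events, which contribute nothing to the counts). The output
#' parses losslessly through [parse_casas_events()] and, featurized, returns
#' exactly the drawn counts.
#'
#' @param profiles An [activity_profiles()] object.
#' @param seed Integer seed; the same seed yields a byte-identical log.
#' @param start Start time of the stream (POSIXct, UTC).
#' @param shuffle_rates When `TRUE`, each instance keeps its label but draws
#'   its counts from the profile of a uniformly random class — the
#'   incongruent control in which features carry no information about the
#'   label.
#' @param include_numeric_sensor Also emit a numeric temperature reading
#'   (sensor `T101`) inside each instance, exercising the numeric-exclusion
#'   rule downstream.
#' @return A list: `lines` (the CASAS-dialect log), `events` (its parsed
#'   tibble) and `truth` (tibble of `instance_id`, `label`, `rate_label` —
#'   the class whose rates were used — and a `counts` list column of drawn
#'   per-sensor counts).
#' @export
generate_stream <- function(profiles, seed,
                            start = as.POSIXct("2024-03-01 08:00:00", tz = "UTC"),
                            shuffle_rates = FALSE,
                            include_numeric_sensor = FALSE) {
  stopifnot(inherits(profiles, "activity_profiles"))
  plan_labels <- rep(profiles$labels, times = profiles$n_instances)
  if (length(plan_labels) == 0) {
    return(list(lines = character(0), events = empty_events(),
                truth = tibble::tibble(instance_id = integer(),
                                       label = character(),
                                       rate_label = character(),
                                       counts = list())))
  }
  withr::with_seed(seed, {
    plan_labels <- sample(plan_labels)
    rate_labels <- if (shuffle_rates) {
      sample(profiles$labels, length(plan_labels), replace = TRUE)
    } else plan_labels
    cs <- 0L  # centiseconds since `start`
    lines <- character(0)
    truth_counts <- vector("list", length(plan_labels))
    stamp <- function(cs) {
      t <- start + cs %/% 100
      sprintf("%s.%02d", format(t, "%Y-%m-%d %H:%M:%S", tz = "UTC"), cs %% 100)
    }
    boundary_sensor <- profiles$sensors[1]
    for (i in seq_along(plan_labels)) {
      rates <- profiles$rates[rate_labels[i], ]
      counts <- rpois(length(rates), rates)
      names(counts) <- profiles$sensors
      truth_counts[[i]] <- counts
      activations <- rep(profiles$sensors, times = counts)
      if (length(activations) > 1) activations <- sample(activations)
      cs <- cs + sample(50:300, 1)
      inst <- sprintf("%s %s OFF %s begin", stamp(cs), boundary_sensor,
                      plan_labels[i])
      if (include_numeric_sensor) {
        cs <- cs + sample(50:300, 1)
        inst <- c(inst, sprintf("%s T101 %.1f", stamp(cs), runif(1, 18, 26)))
      }
      for (s in activations) {
        cs <- cs + sample(50:300, 1)
        inst <- c(inst, sprintf("%s %s %s", stamp(cs), s,
                                if (startsWith(s, "D")) "OPEN" else "ON"))
        cs <- cs + sample(50:300, 1)
        inst <- c(inst, sprintf("%s %s %s", stamp(cs), s,
                                if (startsWith(s, "D")) "CLOSE" else "OFF"))
      }
      cs <- cs + sample(50:300, 1)
      inst <- c(inst, sprintf("%s %s OFF %s end", stamp(cs), boundary_sensor,
                              plan_labels[i]))
      cs <- cs + 6000L  # one-minute gap between instances
      lines <- c(lines, inst)
    }
    list(lines = lines,
         events = parse_casas_events(lines),
         truth = tibble::tibble(instance_id = seq_along(plan_labels),
                                label = plan_labels,
                                rate_label = rate_labels,
                                counts = truth_counts))
  })
}

default_seen_labels <- function(k) {
  pool <- c("cook", "wash", "sleep", "read", "bathe",
            "dress", "phone", "watch", "relax", "work")
  if (k <= length(pool)) pool[seq_len(k)] else c(pool, paste0("seen", seq_len(k - length(pool))))
}

default_unseen_labels <- function(k) {
  pool <- c("toilet", "hygiene", "lunch", "breakfast", "dinner", "snack")
  if (k <= length(pool)) pool[seq_len(k)] else c(pool, paste0("unseen", seq_len(k - length(pool))))
}

#' Construct a congruent zero-shot scenario
#'
#' Seen classes get disjoint dominant sensor blocks (rate = `separation`)
#' over a low background rate, so their count profiles are well separated.
#' Each unseen class is tied to a convex mixture of seen classes (by default
#' an equal mix of two consecutive seen classes), and its feature profile
#' uses the SAME mixture of the seen rate profiles as its toy prototype uses
#' of the seen prototypes. That congruence is exactly what lets the trained
#' network place unseen instances near the right prototype; setting
#' `incongruent = TRUE` severs it (test instances draw their counts from a
#' random class profile), which must drive accuracy to the 1/K chance floor.
#'
#' @param K_seen Number of seen (training) classes, at least 2.
#' @param K_unseen Number of unseen (zero-shot) classes, at least 1.
#' @param n_sensors Number of binary sensors, at least `K_seen`.
#' @param separation Dominant-block activation rate (expected ON count per
#'   instance); the background rate is 0.2.
#' @param n_train_per_class Training instances per seen class.
#' @param n_test Total zero-shot test instances, split as evenly as possible
#'   across unseen classes.
#' @param embedding_dim Toy semantic dimension, at least `K_seen`.
#' @param noise Isotropic noise scale added to unseen prototypes.
#' @param seed Scenario seed.
#' @param incongruent Build the negative control (see above).
#' @return An object of class `zs_scenario` bundling the seen and unseen
#'   [activity_profiles()], the mixing matrix (rows sum to 1), and the
#'   embedding geometry parameters.
#' @export
make_congruent_scenario <- function(K_seen = 5, K_unseen = 3, n_sensors = 30,
                                    separation = 6,
                                    n_train_per_class = 40,
                                    n_test = 200,
                                    embedding_dim = 16,
                                    noise = 0.05,
                                    seed = 1L,
                                    incongruent = FALSE) {
  stopifnot(K_seen >= 2, K_unseen >= 1)
  if (n_sensors < K_seen) abort("need at least one sensor per seen class.")
  if (embedding_dim < K_seen) {
    abort("embedding_dim must be at least the number of seen classes.")
  }
  seen_labels <- default_seen_labels(K_seen)
  unseen_labels <- default_unseen_labels(K_unseen)
  sensors <- sprintf("M%03d", seq_len(n_sensors))

  block <- floor(n_sensors / K_seen)
  seen_rates <- matrix(0.2, K_seen, n_sensors,
                       dimnames = list(seen_labels, sensors))
  for (k in seq_len(K_seen)) {
    cols <- ((k - 1) * block + 1):(k * block)
    seen_rates[k, cols] <- separation
  }

  mixing <- matrix(0, K_unseen, K_seen,
                   dimnames = list(unseen_labels, seen_labels))
  for (j in seq_len(K_unseen)) {
    a <- ((j - 1) %% K_seen) + 1
    b <- (j %% K_seen) + 1
    mixing[j, c(a, b)] <- 0.5
  }
  unseen_rates <- mixing %*% seen_rates

  n_test_per <- rep(n_test %/% K_unseen, K_unseen) +
    c(rep(1, n_test %% K_unseen), rep(0, K_unseen - n_test %% K_unseen))

  structure(list(
    seen_profiles = activity_profiles(seen_rates, n_train_per_class),
    unseen_profiles = activity_profiles(unseen_rates, n_test_per),
    mixing = mixing,
    embedding_dim = as.integer(embedding_dim),
    noise = noise,
    seed = as.integer(seed),
    incongruent = isTRUE(incongruent)
  ), class = "zs_scenario")
}

#' @export
print.zs_scenario <- function(x, ...) {
  cat(sprintf(
    "<zs_scenario: %d seen / %d unseen classes, %d sensors, dim %d%s>\n",
    length(x$seen_profiles$labels), length(x$unseen_profiles$labels),
    length(x$seen_profiles$sensors), x$embedding_dim,
    if (x$incongruent) ", INCONGRUENT control" else ""))
  invisible(x)
}

#' Build a toy embedding table realizing a scenario's semantic geometry
#'
#' Seen prototypes are mutually orthogonal unit vectors (a seeded random
#' orthonormal frame); each unseen prototype is the scenario's mixing-matrix
#' combination of the seen prototypes plus seeded isotropic noise,
#' re-normalized to unit length. Extra filler tokens (random unit vectors)
#' are included so distractor experiments have a vocabulary to draw from.
#'
#' @param scenario A `zs_scenario` from [make_congruent_scenario()].
#' @param n_extra_tokens Filler tokens added to the table.
#' @return A list: `table` (an [embedding_table()] containing every class
#'   label plus the filler tokens), `seen` and `unseen`
#'   (`class_prototypes`).
#' @export
make_toy_embeddings <- function(scenario, n_extra_tokens = 20) {
  stopifnot(inherits(scenario, "zs_scenario"))
  d <- scenario$embedding_dim
  ks <- length(scenario$seen_profiles$labels)
  ku <- length(scenario$unseen_profiles$labels)
  if (d < ks) abort("embedding dimension smaller than the number of seen classes.")
  withr::with_seed(scenario$seed, {
    q <- qr.Q(qr(matrix(rnorm(d * ks), d, ks)))   # orthonormal columns
    seen_vec <- t(q)
    rownames(seen_vec) <- scenario$seen_profiles$labels
    raw <- scenario$mixing %*% seen_vec +
      scenario$noise * matrix(rnorm(ku * d), ku, d) / sqrt(d)
    unseen_vec <- raw / sqrt(rowSums(raw^2))
    rownames(unseen_vec) <- scenario$unseen_profiles$labels
    extra <- matrix(rnorm(n_extra_tokens * d), n_extra_tokens, d)
    extra <- extra / sqrt(rowSums(extra^2))
    rownames(extra) <- sprintf("word%02d", seq_len(n_extra_tokens))
    list(table = embedding_table(rbind(seen_vec, unseen_vec, extra)),
         seen = as_class_prototypes(seen_vec),
         unseen = as_class_prototypes(unseen_vec))
  })
}

#' Generate the training and zero-shot event streams of a scenario
#'
#' @param scenario A `zs_scenario`.
#' @return A list with `train` and `test` streams (see [generate_stream()]);
#'   the test stream honours the scenario's `incongruent` flag.
#' @export
generate_scenario_streams <- function(scenario) {
  stopifnot(inherits(scenario, "zs_scenario"))
  # test stream starts a day after the training stream so the two segments
  # concatenate into one chronologically valid log
  list(
    train = generate_stream(scenario$seen_profiles, seed = scenario$seed + 1L),
    test = generate_stream(scenario$unseen_profiles, seed = scenario$seed + 2L,
                           start = as.POSIXct("2024-03-02 08:00:00", tz = "UTC"),
                           shuffle_rates = scenario$incongruent)
  )
}
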