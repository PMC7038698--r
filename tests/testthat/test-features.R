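segmented <- function(lines) segment_activity_instances(parse_casas_events(lines))

test_that("vocabulary is the sorted set of binary sensors", {
  inst <- segmented(c(
    event_line("10:00:00.00", "M002", "ON", "A begin"),
    event_line("10:00:01.00", "M001", "ON"),
    event_line("10:00:02.00", "M002", "OFF", "A end")
  ))
  expect_equal(build_sensor_vocabulary(inst), c("M001", "M002"))
})

test_that("numeric-only sensors are excluded unless binarization is requested", {
  inst <- segmented(c(
    event_line("10:00:00.00", "M003", "ON", "A begin"),
    event_line("10:00:01.00", "D001", "OPEN"),
    event_line("10:00:02.00", "T101", "21.5"),
    event_line("10:00:03.00", "M003", "OFF", "A end")
  ))
  expect_equal(build_sensor_vocabulary(inst), c("D001", "M003"))
  expect_equal(build_sensor_vocabulary(inst, include_numeric = TRUE),
               c("D001", "M003", "T101"))

  numeric_only <- segmented(c(
    event_line("10:00:00.00", "T101", "20.0", "A begin"),
    event_line("10:00:01.00", "T101", "25.0", "A end")
  ))
  expect_error(build_sensor_vocabulary(numeric_only), "include_numeric")
})

test_that("activation counting follows the ON/OPEN rule", {
  inst <- segmented(c(
    event_line("10:00:00.00", "M001", "ON", "A begin"),
    event_line("10:00:01.00", "M001", "OFF"),
    event_line("10:00:02.00", "M001", "ON"),
    event_line("10:00:03.00", "M002", "ON"),
    event_line("10:00:04.00", "M099", "ON"),        # out of vocabulary
    event_line("10:00:05.00", "M001", "OFF", "A end")
  ))
  counts <- count_activations(inst$events[[1]], c("M001", "M002"))
  expect_equal(counts, c(M001 = 2L, M002 = 1L))
  # empty instance
  expect_equal(count_activations(inst$events[[1]][0, ], c("M001", "M002")),
               c(M001 = 0L, M002 = 0L))
})

test_that("numeric binarization counts threshold-exceeding changes", {
  inst <- segmented(c(
    event_line("10:00:00.00", "M001", "ON", "A begin"),
    event_line("10:00:01.00", "T101", "20.0"),
    event_line("10:00:02.00", "T101", "20.3"),
    event_line("10:00:03.00", "T101", "23.0"),
    event_line("10:00:04.00", "M001", "OFF", "A end")
  ))
  counts <- count_activations(inst$events[[1]], c("M001", "T101"),
                              numeric_threshold = 1)
  expect_equal(counts, c(M001 = 1L, T101 = 1L))
})

test_that("counting equals the brute-force tally on random fixtures", {
  set.seed(5)
  vocab <- c("D001", "M001", "M002")
  for (rep in 1:10) {
    ev <- parse_casas_events(random_stream_lines(k = 1, sensors = vocab))
    inst <- segment_activity_instances(ev)
    expect_equal(count_activations(inst$events[[1]], vocab),
                 brute_force_counts(inst$events[[1]], vocab))
  }
})

test_that("feature rows equal per-instance counts and conserve activations", {
  set.seed(6)
  inst <- segmented(random_stream_lines(k = 5))
  vocab <- build_sensor_vocabulary(inst)
  feats <- build_feature_matrix(inst, vocab)
  expect_equal(names(feats), c("instance_id", "label", vocab))
  x <- feature_values(feats)
  for (i in seq_len(nrow(inst))) {
    cnt <- count_activations(inst$events[[i]], vocab)
    expect_equal(unname(x[i, ]), unname(as.numeric(cnt)))
    n_activations <- sum(inst$events[[i]]$sensor_id %in% vocab &
                           toupper(inst$events[[i]]$message) %in% c("ON", "OPEN"))
    expect_equal(sum(x[i, ]), n_activations)
  }
})

test_that("counting is invariant to event order within an instance", {
  set.seed(7)
  inst <- segmented(random_stream_lines(k = 1))
  vocab <- build_sensor_vocabulary(inst)
  shuffled <- inst$events[[1]][sample(nrow(inst$events[[1]])), ]
  expect_equal(count_activations(shuffled, vocab),
               count_activations(inst$events[[1]], vocab))
})

test_that("standardization gives zero-mean unit-variance training columns", {
  set.seed(8)
  inst <- segmented(random_stream_lines(k = 8))
  vocab <- build_sensor_vocabulary(inst)
  raw <- build_feature_matrix(inst, vocab)
  scaler <- fit_feature_scaler(raw)
  scaled <- build_feature_matrix(inst, vocab, scaler = scaler)
  x <- feature_values(scaled)
  for (j in seq_len(ncol(x))) {
    if (scaler$sd[j] != 1 || scaler$mean[j] != 0) {
      expect_lt(abs(mean(x[, j])), 1e-9)
      expect_lt(abs(stats::var(x[, j]) - 1), 1e-9)
    }
  }
})

test_that("test-time featurization leaves vocabulary and scaler untouched", {
  set.seed(9)
  train <- segmented(random_stream_lines(k = 5))
  test <- segmented(random_stream_lines(k = 3, sensors = c("M001", "M007")))
  vocab <- build_sensor_vocabulary(train)
  scaler <- fit_feature_scaler(build_feature_matrix(train, vocab))
  vocab_before <- vocab
  scaler_before <- scaler
  feats <- build_feature_matrix(test, vocab, scaler = scaler)
  expect_identical(vocab, vocab_before)
  expect_identical(scaler, scaler_before)
  expect_equal(feature_sensors <- setdiff(names(feats), c("instance_id", "label")),
               vocab)
  # a scaler fitted elsewhere cannot be applied to a different vocabulary
  other <- build_feature_matrix(test, build_sensor_vocabulary(test))
  expect_error(scale_features(other, scaler), "different sensor vocabulary")
})

test_that("unscaled feature matrices round-trip through delimited text", {
  set.seed(10)
  inst <- segmented(random_stream_lines(k = 4))
  vocab <- build_sensor_vocabulary(inst)
  feats <- build_feature_matrix(inst, vocab)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_feature_matrix(feats, path)
  expect_equal(read_feature_matrix(path), feats)
})
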