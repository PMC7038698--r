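test_that("confusion tallies match truth/prediction pairs", {
  df <- tibble::tibble(label = c("a", "a", "b"), .pred_label = c("a", "a", "b"))
  cm <- confusion_matrix(df)
  expect_equal(unname(diag(cm$table)), c(2L, 1L))
  expect_equal(sum(cm$table) - sum(diag(cm$table)), 0L)

  set.seed(41)
  labs <- letters[1:4]
  df <- tibble::tibble(label = sample(labs, 50, replace = TRUE),
                       .pred_label = sample(labs, 50, replace = TRUE))
  cm <- confusion_matrix(df, class_order = labs)
  for (i in labs) for (j in labs) {
    expect_equal(cm$table[i, j], sum(df$label == i & df$.pred_label == j))
  }
  expect_equal(unname(rowSums(cm$table)),
               unname(table(factor(df$label, labs))[labs]), ignore_attr = TRUE)

  expect_error(confusion_matrix(df, class_order = letters[1:3]), "not in")
})

test_that("a label sequence rebuilt from the HH101 scenario-1 tally reproduces it", {
  ref <- reference_confusion("hh101", 1)
  seqs <- tidyr::uncount(tidy(ref), weights = .data$Freq)
  df <- tibble::tibble(label = seqs$truth, .pred_label = seqs$predicted)
  cm <- confusion_matrix(df, class_order = ref$labels)
  expect_identical(cm$table, ref$table)
})

test_that("one-vs-rest metrics reproduce the published per-class columns", {
  m1 <- class_metrics(reference_confusion("hh101", 1), round_to = 2)
  expect_equal(m1$accuracy, c(98.87, 83.2, 84.33))
  expect_equal(m1$f_measure, c(0.96, 0.6, 0.88))
  expect_equal(m1$n_classified, c(91L, 176L, 352L))
  expect_equal(m1$n_truth, c(84L, 86L, 449L))

  m2 <- class_metrics(reference_confusion("hh101", 2), round_to = 2)
  expect_equal(m2$accuracy, c(97.84, 100, 97.84))
  expect_equal(m2$f_measure, c(0.87, 1, 0.99))

  m3 <- class_metrics(reference_confusion("hh125", 2), round_to = 2)
  expect_equal(m3$accuracy, c(100, 97.93, 97.93))
  expect_equal(m3$f_measure, c(1, 0.25, 0.99))

  expect_error(reference_confusion("hh125", 1), "inconsistent")
})

test_that("a perfect diagonal matrix scores perfectly", {
  cm <- as_zs_confusion(diag(c(5, 3, 2)) |>
                          (\(m) {dimnames(m) <- list(letters[1:3], letters[1:3]); m})())
  m <- class_metrics(cm)
  expect_equal(m$accuracy, rep(100, 3))
  expect_equal(m$precision, rep(1, 3))
  expect_equal(m$recall, rep(1, 3))
  expect_equal(m$f_measure, rep(1, 3))
})

test_that("metrics match a brute-force one-vs-rest computation and its invariants", {
  set.seed(42)
  for (rep in 1:10) {
    k <- sample(3:5, 1)
    m <- matrix(rpois(k * k, 8), k, k,
                dimnames = list(letters[1:k], letters[1:k]))
    cm <- as_zs_confusion(m)
    got <- class_metrics(cm)
    for (kk in seq_len(k)) {
      want <- brute_force_ovr(m, kk)
      expect_equal(got$tp[kk], want$tp)
      expect_equal(got$tn[kk], want$tn)
      expect_equal(got$accuracy[kk], want$accuracy)
      expect_equal(got$precision[kk], want$precision)
      expect_equal(got$recall[kk], want$recall)
      expect_equal(got$f_measure[kk], want$f_measure)
      # TP + TN + FP + FN covers every instance, for every class
      expect_equal(got$tp[kk] + got$tn[kk] + got$fp[kk] + got$fn[kk], sum(m))
      # F is symmetric in precision and recall
      p <- want$precision; r <- want$recall
      swapped <- if (p + r == 0) 0 else 2 * r * p / (r + p)
      expect_equal(got$f_measure[kk], swapped)
    }
    # micro accuracy is invariant to a class permutation
    perm <- sample(k)
    cm_p <- as_zs_confusion(m[perm, perm])
    expect_equal(sum(diag(cm_p$table)) / sum(cm_p$table),
                 sum(diag(m)) / sum(m))
  }
})

test_that("correlation matrices follow the chosen formula", {
  expect_equal(correlation_matrix(rbind(a = c(1, 2, 3),
                                        b = c(1, 2, 3)))$matrix["a", "b"], 1)
  expect_equal(correlation_matrix(rbind(a = c(1, 2, 3),
                                        b = -c(1, 2, 3)))$matrix["a", "b"], -1)
  set.seed(43)
  x <- matrix(rnorm(3 * 7), 3, 7, dimnames = list(c("p", "q", "r"), NULL))
  got <- correlation_matrix(x)$matrix
  for (i in 1:3) for (j in 1:3) {
    num <- sum((x[i, ] - mean(x[i, ])) * (x[j, ] - mean(x[j, ])))
    den <- sqrt(sum((x[i, ] - mean(x[i, ]))^2) * sum((x[j, ] - mean(x[j, ]))^2))
    expect_equal(got[i, j], num / den, tolerance = 1e-12)
  }
  expect_equal(got, t(got))

  cosg <- correlation_matrix(x, method = "cosine")$matrix
  expect_equal(cosg[1, 2], cosine_similarity(x[1, ], x[2, ]))

  expect_error(correlation_matrix(rbind(a = c(1, 1, 1), b = c(1, 2, 3))),
               "constant")
})

test_that("distractor evaluation is a no-op at zero distractors", {
  fx_scn <- make_congruent_scenario(K_seen = 3, K_unseen = 2, n_sensors = 9,
                                    embedding_dim = 6, n_train_per_class = 30,
                                    n_test = 40, seed = 44)
  emb <- make_toy_embeddings(fx_scn)
  streams <- generate_scenario_streams(fx_scn)
  vocab <- build_sensor_vocabulary(segment_activity_instances(streams$train$events))
  raw <- build_feature_matrix(segment_activity_instances(streams$train$events), vocab)
  scaler <- fit_feature_scaler(raw)
  train <- scale_features(raw, scaler)
  test <- scale_features(
    build_feature_matrix(segment_activity_instances(streams$test$events), vocab),
    scaler)
  net <- zs_train(build_network(tiny_config(length(vocab), fx_scn$embedding_dim),
                                emb$seen), train)

  plain <- mean(predict_zero_shot(net, test, emb$unseen)$.pred_label ==
                  test$label)
  res <- evaluate_with_distractors(net, test, emb$unseen, emb$table,
                                   n_distractors = c(0L, 5L), mode = "random",
                                   seed = 4)
  expect_equal(res$accuracy[res$n_distractors == 0], plain)
  expect_error(evaluate_with_distractors(net, test, emb$unseen, emb$table,
                                         n_distractors = 10000L),
               "available")

  # distractors orthogonal to every embedding the network emits cannot win
  emb_mat <- zs_embed(net, test[1:4, ])
  q <- qr.Q(qr(t(emb_mat)), complete = TRUE)
  ortho_vec <- q[, ncol(q)]
  expect_lt(max(abs(emb_mat %*% ortho_vec)), 1e-8)
  dist <- as_class_prototypes(matrix(ortho_vec, 1,
                                     dimnames = list("decoy", NULL)))
  with_decoy <- evaluate_with_distractors(net, test[1:4, ], emb$unseen,
                                          distractors = dist)
  base4 <- mean(predict_zero_shot(net, test[1:4, ], emb$unseen)$.pred_label ==
                  test$label[1:4])
  expect_equal(with_decoy$accuracy, base4)

  # a duplicate of a true prototype under a smaller label wins by tie-break
  dup_label <- "aaa"
  true1 <- emb$unseen$labels[1]
  dup <- as_class_prototypes(matrix(emb$unseen$vectors[1, ], 1,
                                    dimnames = list(dup_label, NULL)))
  with_dup <- evaluate_with_distractors(net, test, emb$unseen,
                                        distractors = dup)
  preds <- predict_zero_shot(net, test, emb$unseen)
  expected <- mean(ifelse(preds$.pred_label == true1, dup_label,
                          preds$.pred_label) == test$label)
  expect_equal(with_dup$accuracy, expected)

  # knn mode returns one accuracy per requested size
  res_knn <- evaluate_with_distractors(net, test, emb$unseen, emb$table,
                                       n_distractors = c(1L, 3L), mode = "knn")
  expect_equal(nrow(res_knn), 2)
  expect_true(all(res_knn$accuracy >= 0 & res_knn$accuracy <= 1))
})
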