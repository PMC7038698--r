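# A tiny, fully synthetic setting used across these tests.
tiny_scenario_fixture <- function(K_seen = 3, seed = 31) {
  scn <- make_congruent_scenario(K_seen = K_seen, K_unseen = 2,
                                 n_sensors = 9, embedding_dim = 6,
                                 n_train_per_class = 30, n_test = 60,
                                 seed = seed)
  emb <- make_toy_embeddings(scn)
  streams <- generate_scenario_streams(scn)
  train_inst <- segment_activity_instances(streams$train$events)
  test_inst <- segment_activity_instances(streams$test$events)
  vocab <- build_sensor_vocabulary(train_inst)
  raw <- build_feature_matrix(train_inst, vocab)
  scaler <- fit_feature_scaler(raw)
  list(
    scn = scn, emb = emb, vocab = vocab, scaler = scaler,
    train = scale_features(raw, scaler),
    test = scale_features(build_feature_matrix(test_inst, vocab), scaler)
  )
}

test_that("the frozen output layer has the promised shape and content", {
  set.seed(32)
  v <- matrix(rnorm(5 * 300), 5, 300,
              dimnames = list(paste0("c", 1:5), NULL))
  protos <- as_class_prototypes(v)
  net <- build_network(network_config(input_dim = 10), protos)
  expect_equal(dim(net$W_out), c(300L, 5L))
  expect_equal(net$W_out, t(protos$unit))
  expect_error(build_network(network_config(input_dim = 10, embedding_dim = 20),
                             protos), "dimension")
  expect_error(build_network(network_config(input_dim = 10),
                             as_class_prototypes(v[1, , drop = FALSE])),
               "at least two")
})

test_that("the forward pass equals a hand-computed SELU/matmul/softmax chain", {
  protos <- as_class_prototypes(rbind(a = c(1, 0, 0), b = c(0, 1, 1)))
  cfg <- network_config(input_dim = 2, embedding_dim = 3, hidden1 = 2,
                        batch_norm = FALSE)
  net <- build_network(cfg, protos)
  net$params$W1 <- matrix(c(0.5, -0.2, 0.1, 0.3), 2, 2)
  net$params$b1 <- c(0.05, -0.1)
  net$params$W2 <- matrix(c(0.2, -0.4, 0.6, 0.1, -0.3, 0.5), 2, 3)
  net$params$b2 <- c(0, 0.1, -0.2)
  x <- c(1, -2)

  scale <- 1.0507009873554805
  alpha <- 1.6732632423543772
  selu1 <- function(t) if (t > 0) scale * t else scale * alpha * (exp(t) - 1)
  a1 <- c(x[1] * 0.5 + x[2] * -0.2 + 0.05, x[1] * 0.1 + x[2] * 0.3 - 0.1)
  h1 <- vapply(a1, selu1, numeric(1))
  a2 <- c(h1[1] * 0.2 + h1[2] * -0.4 + 0,
          h1[1] * 0.6 + h1[2] * 0.1 + 0.1,
          h1[1] * -0.3 + h1[2] * 0.5 - 0.2)
  h2 <- vapply(a2, selu1, numeric(1))
  w <- t(protos$unit)
  logits <- c(sum(h2 * w[, 1]), sum(h2 * w[, 2]))
  probs <- exp(logits) / sum(exp(logits))

  expect_equal(as.numeric(zs_embed(net, matrix(x, 1))), h2, tolerance = 1e-9)
  expect_equal(as.numeric(predict(net, matrix(x, 1), type = "prob")), probs,
               tolerance = 1e-9)
})

test_that("softmax rows sum to one for arbitrary inputs", {
  fx <- tiny_scenario_fixture()
  cfg <- tiny_config(length(fx$vocab), fx$scn$embedding_dim)
  net <- build_network(cfg, fx$emb$seen)
  probs <- predict(net, fx$train, type = "prob")
  expect_equal(unname(rowSums(probs)), rep(1, nrow(probs)), tolerance = 1e-6)
  net <- zs_train(net, fx$train)
  probs <- predict(net, fx$test, type = "prob")
  expect_equal(unname(rowSums(probs)), rep(1, nrow(probs)), tolerance = 1e-6)
})

test_that("training learns well-separated classes and never touches W", {
  fx <- tiny_scenario_fixture()
  cfg <- network_config(length(fx$vocab), embedding_dim = fx$scn$embedding_dim,
                        hidden1 = 16L, epochs = 60L, seed = 3L)
  net <- build_network(cfg, fx$emb$seen)
  w_before <- net$W_out
  trained <- zs_train(net, fx$train)
  expect_identical(trained$W_out, w_before)
  expect_gte(trained$final_accuracy, 0.95)
  expect_lt(tail(trained$history$loss, 1), trained$history$loss[1])
})

test_that("labels outside the seen classes are rejected as leakage", {
  fx <- tiny_scenario_fixture()
  net <- build_network(tiny_config(length(fx$vocab), fx$scn$embedding_dim),
                       fx$emb$seen)
  poisoned <- fx$train
  poisoned$label[1] <- fx$scn$unseen_profiles$labels[1]
  expect_error(zs_train(net, poisoned), "leakage")
})

test_that("training and inference are deterministic given the seed", {
  fx <- tiny_scenario_fixture()
  cfg <- tiny_config(length(fx$vocab), fx$scn$embedding_dim, seed = 9L)
  a <- zs_train(build_network(cfg, fx$emb$seen), fx$train)
  b <- zs_train(build_network(cfg, fx$emb$seen), fx$train)
  expect_identical(a$params, b$params)
  expect_identical(a$bn, b$bn)
  expect_identical(predict_zero_shot(a, fx$test, fx$emb$unseen),
                   predict_zero_shot(b, fx$test, fx$emb$unseen))
  expect_identical(zs_embed(a, fx$test), zs_embed(a, fx$test))
})

test_that("zero-shot prediction is the embed-then-match composition", {
  fx <- tiny_scenario_fixture()
  net <- zs_train(build_network(tiny_config(length(fx$vocab),
                                            fx$scn$embedding_dim),
                                fx$emb$seen), fx$train)
  preds <- predict_zero_shot(net, fx$test, fx$emb$unseen)
  emb <- zs_embed(net, fx$test)
  for (i in seq_len(nrow(emb))) {
    hit <- nearest_prototype(emb[i, ], fx$emb$unseen)
    expect_equal(preds$.pred_label[i], hit$label)
    expect_equal(preds$similarity[i], hit$similarity)
  }
  expect_error(predict_zero_shot(net, fx$test, fx$emb$seen), "overlap")
})

test_that("an embedding equal to a prototype is matched to it exactly", {
  protos <- as_class_prototypes(rbind(x = c(1, 0, 0, 0), y = c(0, 1, 0, 0)))
  hit <- nearest_prototype(c(0, 1, 0, 0), protos)
  expect_equal(hit$label, "y")
  expect_equal(hit$similarity, 1)
})

test_that("class-independent features score at the chance floor", {
  set.seed(33)
  fx <- tiny_scenario_fixture()
  net <- zs_train(build_network(tiny_config(length(fx$vocab),
                                            fx$scn$embedding_dim),
                                fx$emb$seen), fx$train)
  k <- 4
  protos <- as_class_prototypes(
    matrix(diag(fx$scn$embedding_dim)[1:k, ], k,
           dimnames = list(paste0("u", 1:k), NULL)))
  n <- 400
  noise <- matrix(rnorm(n * length(fx$vocab)), n)
  truth <- sample(protos$labels, n, replace = TRUE)
  emb <- zs_embed(net, noise)
  preds <- vapply(seq_len(n),
                  function(i) nearest_prototype(emb[i, ], protos)$label,
                  character(1))
  acc <- mean(preds == truth)
  band <- stats::qbinom(c(0.005, 0.995), n, 1 / k) / n
  expect_gte(acc, band[1])
  expect_lte(acc, band[2])
})

test_that("the prototype-regression loss variant also trains", {
  fx <- tiny_scenario_fixture()
  cfg <- network_config(length(fx$vocab), embedding_dim = fx$scn$embedding_dim,
                        hidden1 = 16L, epochs = 60L, loss = "prototype")
  net <- zs_train(build_network(cfg, fx$emb$seen), fx$train)
  expect_lt(tail(net$history$loss, 1), net$history$loss[1])
  expect_gte(net$final_accuracy, 0.9)
})

test_that("checkpoints restore predictions bit-for-bit", {
  fx <- tiny_scenario_fixture()
  net <- zs_train(build_network(tiny_config(length(fx$vocab),
                                            fx$scn$embedding_dim),
                                fx$emb$seen), fx$train)
  path <- withr::local_tempfile(fileext = ".json")
  write_zs_checkpoint(net, path, scaler = fx$scaler)
  back <- read_zs_checkpoint(path)
  expect_identical(predict(back$network, fx$test, type = "prob"),
                   predict(net, fx$test, type = "prob"))
  expect_identical(zs_embed(back$network, fx$test), zs_embed(net, fx$test))
  expect_equal(back$scaler, fx$scaler)
})
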