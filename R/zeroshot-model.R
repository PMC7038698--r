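# Shallow network with a frozen semantic output layer.
#
# Architecture: input(n) -> dense 128 (SELU) [-> batch norm]
#                        -> dense 300 (SELU) [-> batch norm]
#                        -> fixed matrix multiply by W (L x K_seen, columns =
#                           L2-normalized seen-class word vectors) -> softmax.
# The 300-unit activation is the network's image in word-vector space; W is
# never updated, so training shapes that image to align with the seen
# prototypes, and unseen classes are read off by cosine matching.

SELU_ALPHA <- 1.6732632423543772
SELU_SCALE <- 1.0507009873554805
BN_EPS <- 1e-5
BN_MOMENTUM <- 0.9

selu <- function(x) SELU_SCALE * ifelse(x > 0, x, SELU_ALPHA * (exp(x) - 1))
selu_grad <- function(x) SELU_SCALE * ifelse(x > 0, 1, SELU_ALPHA * exp(x))

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

#' Configuration of the zero-shot network
#'
#' Defaults follow the reference architecture: two SELU hidden layers of 128
#' and 300 units (the second matching the embedding dimension L), softmax
#' cross-entropy over the seen classes, Adam, and batch normalization after
#' each hidden layer. The published work selected optimizer hyperparameters
#' by grid search without reporting them; the defaults here (learning rate
#' 1e-3, batch size 32, 200 epochs) are conventional Adam settings, and
#' [grid_search_config()] explores alternatives.
#'
#' @param input_dim Number of sensors n (feature-vector length).
#' @param embedding_dim Semantic dimension L; the second hidden layer has
#'   exactly this many units.
#' @param hidden1 Units in the first hidden layer.
#' @param learning_rate,batch_size,epochs Adam optimizer settings.
#' @param batch_norm Apply batch normalization after each hidden layer.
#' @param loss `"softmax"` for cross-entropy through the frozen layer
#'   (default), or `"prototype"` for direct least-squares regression of the
#'   300-unit activation onto the class prototype.
#' @param class_weights Weight the loss by inverse class frequency (off by
#'   default; activity counts in real homes are strongly imbalanced).
#' @param seed Integer seed; fixes initialization and batch shuffling so
#'   training is reproducible.
#' @return A `network_config` list.
#' @export
network_config <- function(input_dim,
                           embedding_dim = 300L,
                           hidden1 = 128L,
                           learning_rate = 1e-3,
                           batch_size = 32L,
                           epochs = 200L,
                           batch_norm = TRUE,
                           loss = c("softmax", "prototype"),
                           class_weights = FALSE,
                           seed = 1L) {
  loss <- match.arg(loss)
  stopifnot(input_dim >= 1, embedding_dim >= 1, hidden1 >= 1,
            epochs >= 1, batch_size >= 1, learning_rate > 0)
  structure(list(
    input_dim = as.integer(input_dim),
    embedding_dim = as.integer(embedding_dim),
    hidden1 = as.integer(hidden1),
    hidden2 = as.integer(embedding_dim),
    learning_rate = learning_rate,
    batch_size = as.integer(batch_size),
    epochs = as.integer(epochs),
    batch_norm = isTRUE(batch_norm),
    loss = loss,
    class_weights = isTRUE(class_weights),
    seed = as.integer(seed)
  ), class = "network_config")
}

#' Build an untrained zero-shot network
#'
#' The output layer is a fixed matrix multiplication by `W` (L x K_seen)
#' whose columns are the L2-normalized seen-class prototypes; it is excluded
#' from training, so logits stay proportional to the cosine between the
#' 300-unit activation and each seen prototype. Hidden weights use seeded
#' Lecun-normal initialization (the variance-preserving choice for SELU).
#'
#' @param config A [network_config()]; `embedding_dim` must equal the
#'   prototype dimension.
#' @param seen_prototypes A `class_prototypes` object with at least two
#'   classes.
#' @return An object of class `zeroshot_network`.
#' @export
build_network <- function(config, seen_prototypes) {
  stopifnot(inherits(config, "network_config"),
            inherits(seen_prototypes, "class_prototypes"))
  if (length(seen_prototypes$labels) < 2) {
    abort("need at least two seen classes.")
  }
  if (ncol(seen_prototypes$vectors) != config$embedding_dim) {
    abort(sprintf("prototype dimension %d does not match embedding_dim %d.",
                  ncol(seen_prototypes$vectors), config$embedding_dim))
  }
  n <- config$input_dim
  h1 <- config$hidden1
  h2 <- config$hidden2
  params <- withr::with_seed(config$seed, list(
    W1 = matrix(rnorm(n * h1, sd = sqrt(1 / n)), n, h1),
    b1 = numeric(h1),
    W2 = matrix(rnorm(h1 * h2, sd = sqrt(1 / h1)), h1, h2),
    b2 = numeric(h2),
    gamma1 = rep(1, h1), beta1 = numeric(h1),
    gamma2 = rep(1, h2), beta2 = numeric(h2)
  ))
  structure(list(
    config = config,
    params = params,
    bn = list(mean1 = numeric(h1), var1 = rep(1, h1),
              mean2 = numeric(h2), var2 = rep(1, h2)),
    W_out = t(seen_prototypes$unit),          # L x K_seen, frozen
    seen_labels = seen_prototypes$labels,
    trained = FALSE,
    history = NULL,
    final_accuracy = NA_real_
  ), class = "zeroshot_network")
}

#' @export
print.zeroshot_network <- function(x, ...) {
  cat(sprintf(
    "<zeroshot_network: %d -> %d (SELU) -> %d (SELU) -> frozen W [%d x %d] -> softmax>\n",
    x$config$input_dim, x$config$hidden1, x$config$hidden2,
    nrow(x$W_out), ncol(x$W_out)))
  cat(sprintf("  seen classes: %s\n", paste(x$seen_labels, collapse = ", ")))
  cat(sprintf("  trained: %s\n", x$trained))
  invisible(x)
}

as_input_matrix <- function(network, x) {
  if (is.data.frame(x)) x <- feature_values(x)
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (ncol(x) != network$config$input_dim) {
    abort(sprintf("input has %d columns; network expects %d.",
                  ncol(x), network$config$input_dim))
  }
  unname(as.matrix(x))
}

bn_infer <- function(z, gamma, beta, mean, var) {
  xhat <- sweep(sweep(z, 2, mean, "-"), 2, sqrt(var + BN_EPS), "/")
  sweep(sweep(xhat, 2, gamma, "*"), 2, beta, "+")
}

# Inference-mode forward pass (batch norm uses running statistics).
forward_infer <- function(network, X) {
  p <- network$params
  cfg <- network$config
  a1 <- sweep(X %*% p$W1, 2, p$b1, "+")
  z1 <- selu(a1)
  h1 <- if (cfg$batch_norm) {
    bn_infer(z1, p$gamma1, p$beta1, network$bn$mean1, network$bn$var1)
  } else z1
  a2 <- sweep(h1 %*% p$W2, 2, p$b2, "+")
  z2 <- selu(a2)
  h2 <- if (cfg$batch_norm) {
    bn_infer(z2, p$gamma2, p$beta2, network$bn$mean2, network$bn$var2)
  } else z2
  logits <- h2 %*% network$W_out
  list(h2 = h2, logits = logits, probs = softmax_rows(logits))
}

bn_train_forward <- function(z, gamma, beta) {
  m <- nrow(z)
  mu <- colMeans(z)
  v <- colMeans(sweep(z, 2, mu, "-")^2)   # population variance
  invstd <- 1 / sqrt(v + BN_EPS)
  xhat <- sweep(sweep(z, 2, mu, "-"), 2, invstd, "*")
  out <- sweep(sweep(xhat, 2, gamma, "*"), 2, beta, "+")
  list(out = out, xhat = xhat, invstd = invstd, mu = mu, var = v)
}

bn_backward <- function(dout, cache, gamma) {
  m <- nrow(dout)
  dgamma <- colSums(dout * cache$xhat)
  dbeta <- colSums(dout)
  dxhat <- sweep(dout, 2, gamma, "*")
  sum_dxhat <- colSums(dxhat)
  sum_dxhat_xhat <- colSums(dxhat * cache$xhat)
  dz <- sweep(m * dxhat, 2, sum_dxhat, "-")
  dz <- dz - sweep(cache$xhat, 2, sum_dxhat_xhat, "*")
  dz <- sweep(dz, 2, cache$invstd / m, "*")
  list(dz = dz, dgamma = dgamma, dbeta = dbeta)
}

adam_step <- function(params, grads, state, lr) {
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  state$t <- state$t + 1
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- b1 * state$m[[nm]] + (1 - b1) * g
    state$v[[nm]] <- b2 * state$v[[nm]] + (1 - b2) * g^2
    mhat <- state$m[[nm]] / (1 - b1^state$t)
    vhat <- state$v[[nm]] / (1 - b2^state$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

#' Train the network on seen-class activity instances
#'
#' Minimizes categorical cross-entropy of the softmax over seen classes (or
#' squared error to the class prototype under `loss = "prototype"`) with
#' Adam, in shuffled mini-batches, all randomness governed by the config
#' seed. Every row label must belong to the network's seen classes — an
#' outside label means zero-shot classes leaked into training and is an
#' error. The frozen output matrix is untouched by construction.
#'
#' @param network An untrained (or previously trained) [build_network()]
#'   object.
#' @param features Feature tibble from [build_feature_matrix()] (scaled), or
#'   a numeric matrix plus `labels`.
#' @param labels Optional explicit label vector overriding
#'   `features$label`.
#' @return The trained network, with a `history` tibble (`epoch`, `loss`)
#'   and `final_accuracy` (seen-class training accuracy) filled in.
#' @export
zs_train <- function(network, features, labels = NULL) {
  stopifnot(inherits(network, "zeroshot_network"))
  labels <- labels %||% features$label
  if (is.null(labels)) abort("no labels: supply a `label` column or `labels`.")
  X <- as_input_matrix(network, features)
  if (length(labels) != nrow(X)) abort("labels and feature rows differ in length.")
  unknown <- setdiff(unique(labels), network$seen_labels)
  if (length(unknown) > 0) {
    abort(sprintf("label(s) outside the seen classes (zero-shot leakage?): %s.",
                  paste(unknown, collapse = ", ")))
  }
  cfg <- network$config
  k <- length(network$seen_labels)
  yi <- match(labels, network$seen_labels)
  Y <- matrix(0, nrow(X), k)
  Y[cbind(seq_len(nrow(X)), yi)] <- 1
  wts <- rep(1, nrow(X))
  if (cfg$class_weights) {
    freq <- tabulate(yi, nbins = k)
    wts <- (nrow(X) / (k * freq))[yi]
  }
  proto_t <- t(network$W_out)                 # K x L, unit prototypes

  p <- network$params
  bn <- network$bn
  trainable <- names(p)
  if (!cfg$batch_norm) trainable <- c("W1", "b1", "W2", "b2")
  state <- list(t = 0,
                m = lapply(p[trainable], function(z) z * 0),
                v = lapply(p[trainable], function(z) z * 0))
  losses <- numeric(cfg$epochs)

  run <- withr::with_seed(cfg$seed + 1L, {
    for (epoch in seq_len(cfg$epochs)) {
      idx <- sample.int(nrow(X))
      batch_starts <- seq(1, nrow(X), by = cfg$batch_size)
      epoch_loss <- 0
      for (s in batch_starts) {
        rows <- idx[s:min(s + cfg$batch_size - 1, nrow(X))]
        xb <- X[rows, , drop = FALSE]
        yb <- Y[rows, , drop = FALSE]
        wb <- wts[rows]
        wsum <- sum(wb)
        b <- length(rows)

        a1 <- sweep(xb %*% p$W1, 2, p$b1, "+")
        z1 <- selu(a1)
        if (cfg$batch_norm) {
          c1 <- bn_train_forward(z1, p$gamma1, p$beta1)
          h1 <- c1$out
          bn$mean1 <- BN_MOMENTUM * bn$mean1 + (1 - BN_MOMENTUM) * c1$mu
          bn$var1 <- BN_MOMENTUM * bn$var1 + (1 - BN_MOMENTUM) * c1$var
        } else h1 <- z1
        a2 <- sweep(h1 %*% p$W2, 2, p$b2, "+")
        z2 <- selu(a2)
        if (cfg$batch_norm) {
          c2 <- bn_train_forward(z2, p$gamma2, p$beta2)
          h2 <- c2$out
          bn$mean2 <- BN_MOMENTUM * bn$mean2 + (1 - BN_MOMENTUM) * c2$mu
          bn$var2 <- BN_MOMENTUM * bn$var2 + (1 - BN_MOMENTUM) * c2$var
        } else h2 <- z2

        if (cfg$loss == "softmax") {
          logits <- h2 %*% network$W_out
          probs <- softmax_rows(logits)
          loss_b <- -sum(wb * log(pmax(probs[yb == 1], 1e-12))) / wsum
          dlogits <- (probs - yb) * (wb / wsum)
          dh2 <- dlogits %*% t(network$W_out)
        } else {
          target <- proto_t[yi[rows], , drop = FALSE]
          diffm <- h2 - target
          loss_b <- sum(wb * rowSums(diffm^2)) / wsum
          dh2 <- 2 * diffm * (wb / wsum)
        }
        epoch_loss <- epoch_loss + loss_b * b

        grads <- list()
        if (cfg$batch_norm) {
          bk2 <- bn_backward(dh2, c2, p$gamma2)
          dz2 <- bk2$dz
          grads$gamma2 <- bk2$dgamma; grads$beta2 <- bk2$dbeta
        } else dz2 <- dh2
        da2 <- dz2 * selu_grad(a2)
        grads$W2 <- t(h1) %*% da2
        grads$b2 <- colSums(da2)
        dh1 <- da2 %*% t(p$W2)
        if (cfg$batch_norm) {
          bk1 <- bn_backward(dh1, c1, p$gamma1)
          dz1 <- bk1$dz
          grads$gamma1 <- bk1$dgamma; grads$beta1 <- bk1$dbeta
        } else dz1 <- dh1
        da1 <- dz1 * selu_grad(a1)
        grads$W1 <- t(xb) %*% da1
        grads$b1 <- colSums(da1)

        upd <- adam_step(p, grads, state, cfg$learning_rate)
        p <- upd$params
        state <- upd$state
      }
      losses[epoch] <- epoch_loss / nrow(X)
    }
    list(params = p, bn = bn, losses = losses)
  })

  network$params <- run$params
  network$bn <- run$bn
  network$trained <- TRUE
  network$history <- tibble::tibble(epoch = seq_len(cfg$epochs),
                                    loss = run$losses)
  preds <- network$seen_labels[
    max.col(forward_infer(network, X)$probs, ties.method = "first")]
  network$final_accuracy <- mean(preds == labels)
  network
}

#' Map feature vectors into the semantic word-vector space
#'
#' Returns the activation of the 300-unit layer — the representation the
#' frozen output layer multiplies — for each input row. Inference is
#' deterministic (batch normalization uses its running statistics).
#'
#' @param network A `zeroshot_network`.
#' @param features Feature tibble or numeric matrix with `input_dim`
#'   columns, scaled the same way as the training data.
#' @return A numeric matrix (rows x L).
#' @export
zs_embed <- function(network, features) {
  stopifnot(inherits(network, "zeroshot_network"))
  X <- as_input_matrix(network, features)
  forward_infer(network, X)$h2
}

#' Predict labels of previously unseen activities
#'
#' Each row is embedded into the semantic space with [zs_embed()] and
#' assigned the unseen prototype of maximal cosine similarity — by
#' construction identical to composing the two operations yourself.
#'
#' @param network A trained `zeroshot_network`.
#' @param features Feature tibble or matrix of zero-shot instances.
#' @param unseen_prototypes `class_prototypes` for the candidate unseen
#'   classes; their labels must be disjoint from the network's seen classes.
#' @return A tibble with one row per input: `.pred_label` and `similarity`.
#' @export
predict_zero_shot <- function(network, features, unseen_prototypes) {
  stopifnot(inherits(network, "zeroshot_network"),
            inherits(unseen_prototypes, "class_prototypes"))
  if (length(unseen_prototypes$labels) == 0) abort("no unseen prototypes.")
  overlap <- intersect(unseen_prototypes$labels, network$seen_labels)
  if (length(overlap) > 0) {
    abort(sprintf("unseen classes overlap the seen classes: %s.",
                  paste(overlap, collapse = ", ")))
  }
  E <- zs_embed(network, features)
  res <- purrr::map(seq_len(nrow(E)),
                    ~nearest_prototype(E[.x, ], unseen_prototypes))
  out <- dplyr::bind_rows(res)
  names(out) <- c(".pred_label", "similarity")
  out
}

#' Softmax prediction over the seen classes
#'
#' @param object A trained `zeroshot_network`.
#' @param features Feature tibble or matrix.
#' @param type `"class"` for hard labels, `"prob"` for the softmax matrix.
#' @param ... Unused.
#' @return A character vector of seen-class labels, or a probability matrix
#'   with one column per seen class.
#' @export
predict.zeroshot_network <- function(object, features,
                                     type = c("class", "prob"), ...) {
  type <- match.arg(type)
  X <- as_input_matrix(object, features)
  probs <- forward_infer(object, X)$probs
  colnames(probs) <- object$seen_labels
  if (type == "prob") return(probs)
  object$seen_labels[max.col(probs, ties.method = "first")]
}

#' @method tidy zeroshot_network
#' @export
tidy.zeroshot_network <- function(x, ...) {
  if (is.null(x$history)) {
    return(tibble::tibble(epoch = integer(), loss = double()))
  }
  x$history
}

#' @method glance zeroshot_network
#' @export
glance.zeroshot_network <- function(x, ...) {
  n_par <- sum(vapply(x$params, length, integer(1)))
  tibble::tibble(
    input_dim = x$config$input_dim,
    n_seen_classes = length(x$seen_labels),
    embedding_dim = x$config$embedding_dim,
    n_trainable_params = n_par,
    epochs = x$config$epochs,
    final_loss = if (is.null(x$history)) NA_real_ else tail(x$history$loss, 1),
    train_accuracy = x$final_accuracy
  )
}

#' Persist / restore a trained network as a JSON checkpoint
#'
#' Stores the config, all layer parameters, batch-norm running statistics,
#' the frozen output matrix, label order and (optionally) a feature scaler
#' at full floating-point precision, so a reloaded network reproduces
#' predictions bit-for-bit.
#'
#' @param network A `zeroshot_network`.
#' @param path File path for the JSON checkpoint.
#' @param scaler Optional [fit_feature_scaler()] object stored alongside.
#' @return `write_zs_checkpoint()` returns `network` invisibly;
#'   `read_zs_checkpoint()` returns a list with `network` and `scaler`.
#' @export
write_zs_checkpoint <- function(network, path, scaler = NULL) {
  stopifnot(inherits(network, "zeroshot_network"))
  payload <- list(
    config = unclass(network$config),
    params = network$params,
    bn = network$bn,
    W_out = network$W_out,
    seen_labels = network$seen_labels,
    trained = network$trained,
    final_accuracy = network$final_accuracy,
    history = network$history,
    scaler = if (!is.null(scaler)) unclass(scaler)
  )
  jsonlite::write_json(payload, path, digits = I(17), auto_unbox = TRUE,
                       null = "null")
  invisible(network)
}

#' @rdname write_zs_checkpoint
#' @export
read_zs_checkpoint <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- do.call(network_config, raw$config[
    c("input_dim", "embedding_dim", "hidden1", "learning_rate", "batch_size",
      "epochs", "batch_norm", "loss", "class_weights", "seed")])
  net <- structure(list(
    config = cfg,
    params = list(
      W1 = matrix(raw$params$W1, cfg$input_dim, cfg$hidden1),
      b1 = as.numeric(raw$params$b1),
      W2 = matrix(raw$params$W2, cfg$hidden1, cfg$hidden2),
      b2 = as.numeric(raw$params$b2),
      gamma1 = as.numeric(raw$params$gamma1),
      beta1 = as.numeric(raw$params$beta1),
      gamma2 = as.numeric(raw$params$gamma2),
      beta2 = as.numeric(raw$params$beta2)
    ),
    bn = lapply(raw$bn, as.numeric),
    W_out = matrix(raw$W_out, cfg$embedding_dim, length(raw$seen_labels)),
    seen_labels = as.character(raw$seen_labels),
    trained = isTRUE(raw$trained),
    history = if (!is.null(raw$history)) tibble::as_tibble(raw$history),
    final_accuracy = raw$final_accuracy %||% NA_real_
  ), class = "zeroshot_network")
  scaler <- NULL
  if (!is.null(raw$scaler)) {
    scaler <- structure(list(
      mean = setNames(as.numeric(raw$scaler$mean), raw$scaler$sensors),
      sd = setNames(as.numeric(raw$scaler$sd), raw$scaler$sensors),
      sensors = as.character(raw$scaler$sensors)
    ), class = "feature_scaler")
  }
  list(network = net, scaler = scaler)
}

#' Small grid search over optimizer settings
#'
#' Trains one network per grid point on the supplied seen-class data and
#' ranks them by final training loss (or accuracy). Mirrors the practice of
#' selecting optimizer hyperparameters by grid search when none are known a
#' priori.
#'
#' @param features Scaled training feature tibble with a `label` column.
#' @param seen_prototypes `class_prototypes` of the seen classes.
#' @param learning_rates,batch_sizes,epochs Vectors of candidate settings.
#' @param metric Ranking criterion.
#' @param ... Further arguments passed to [network_config()].
#' @return A tibble, one row per grid point, sorted best-first, with the
#'   fitted network in a list column.
#' @export
grid_search_config <- function(features, seen_prototypes,
                               learning_rates = c(1e-2, 1e-3),
                               batch_sizes = c(16L, 32L),
                               epochs = 100L,
                               metric = c("loss", "accuracy"),
                               ...) {
  metric <- match.arg(metric)
  grid <- tidyr::expand_grid(learning_rate = learning_rates,
                             batch_size = batch_sizes,
                             epochs = epochs)
  fits <- purrr::pmap(grid, function(learning_rate, batch_size, epochs) {
    cfg <- network_config(
      input_dim = length(feature_sensors(features)),
      embedding_dim = ncol(seen_prototypes$vectors),
      learning_rate = learning_rate, batch_size = batch_size,
      epochs = epochs, ...)
    zs_train(build_network(cfg, seen_prototypes), features)
  })
  out <- dplyr::mutate(
    grid,
    final_loss = purrr::map_dbl(fits, ~tail(.x$history$loss, 1)),
    train_accuracy = purrr::map_dbl(fits, "final_accuracy"),
    network = fits
  )
  if (metric == "loss") {
    dplyr::arrange(out, .data$final_loss)
  } else {
    dplyr::arrange(out, dplyr::desc(.data$train_accuracy))
  }
}
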