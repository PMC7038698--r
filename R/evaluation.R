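#' Confusion matrix with rows as truth, columns as predictions
#'
#' @param data A data frame holding one row per evaluated instance.
#' @param truth,estimate Columns of `data` with the true and predicted
#'   labels (tidy-eval; defaults `label` and `.pred_label`).
#' @param class_order Optional character vector fixing the label order; by
#'   default the sorted union of observed labels. Labels outside
#'   `class_order` are an error.
#' @return An object of class `zs_confusion`: the K x K integer `table`
#'   (rows = truth, columns = predicted) plus the label order.
#' @export
confusion_matrix <- function(data, truth = label, estimate = .pred_label,
                             class_order = NULL) {
  t_vec <- as.character(dplyr::pull(data, {{ truth }}))
  p_vec <- as.character(dplyr::pull(data, {{ estimate }}))
  if (length(t_vec) != length(p_vec)) {
    abort("truth and estimate differ in length.")
  }
  class_order <- class_order %||% sort(unique(c(t_vec, p_vec)))
  bad <- setdiff(unique(c(t_vec, p_vec)), class_order)
  if (length(bad) > 0) {
    abort(sprintf("label(s) not in `class_order`: %s.",
                  paste(bad, collapse = ", ")))
  }
  tab <- table(factor(t_vec, levels = class_order),
               factor(p_vec, levels = class_order))
  m <- matrix(as.integer(tab), nrow = length(class_order),
              dimnames = list(truth = class_order, predicted = class_order))
  new_zs_confusion(m)
}

new_zs_confusion <- function(m) {
  structure(list(table = m, labels = rownames(m)), class = "zs_confusion")
}

#' Construct a confusion object from an already-tallied matrix
#'
#' Useful for re-analysing published confusion tables.
#'
#' @param m Square numeric matrix of non-negative counts; rows are truth,
#'   columns are predictions, dimnames give the labels (row names win).
#' @return A `zs_confusion` object.
#' @export
as_zs_confusion <- function(m) {
  stopifnot(is.matrix(m), nrow(m) == ncol(m), all(m >= 0))
  labels <- rownames(m) %||% colnames(m)
  if (is.null(labels)) abort("matrix must carry class labels as dimnames.")
  storage.mode(m) <- "integer"
  dimnames(m) <- list(truth = labels, predicted = labels)
  new_zs_confusion(m)
}

#' @export
print.zs_confusion <- function(x, ...) {
  cat(sprintf("<confusion matrix: %d classes, %d instances (rows = truth)>\n",
              length(x$labels), sum(x$table)))
  print(x$table)
  invisible(x)
}

#' @method tidy zs_confusion
#' @export
tidy.zs_confusion <- function(x, ...) {
  tibble::as_tibble(as.data.frame(as.table(x$table), stringsAsFactors = FALSE))
}

#' @method glance zs_confusion
#' @export
glance.zs_confusion <- function(x, ...) {
  tot <- sum(x$table)
  tibble::tibble(
    n_classes = length(x$labels),
    n_instances = tot,
    accuracy = sum(diag(x$table)) / tot
  )
}

#' One-vs-rest performance metrics per class
#'
#' For each class k: TP is the diagonal entry, FP the rest of its column
#' (instances classified as k but not k), FN the rest of its row, TN the
#' remainder, and
#' \deqn{Accuracy = (TP+TN)/(TP+TN+FP+FN) \times 100}
#' \deqn{Precision = TP/(TP+FP), \quad Recall = TP/(TP+FN)}
#' \deqn{F_1 = 2 \cdot Precision \cdot Recall / (Precision + Recall)}
#' with the 0/0 convention that precision, recall and F1 are 0 when their
#' denominator is 0. `n_classified` (column sum) and `n_truth` (row sum)
#' reproduce the N(Classified)/N(Truth) accounting of per-class report
#' tables.
#'
#' @param cm A `zs_confusion` object.
#' @param round_to Decimal places for reporting (accuracy in percent and the
#'   three ratio metrics alike); `NULL` (default) leaves values unrounded.
#' @return A tibble with one row per class: `class`, `tp`, `tn`, `fp`, `fn`,
#'   `n_classified`, `n_truth`, `accuracy` (percent), `precision`, `recall`,
#'   `f_measure`.
#' @export
class_metrics <- function(cm, round_to = NULL) {
  stopifnot(inherits(cm, "zs_confusion"))
  m <- cm$table
  total <- sum(m)
  if (total == 0) abort("empty confusion matrix.")
  tp <- diag(m)
  fp <- colSums(m) - tp
  fn <- rowSums(m) - tp
  tn <- total - tp - fp - fn
  safe_div <- function(num, den) ifelse(den == 0, 0, num / den)
  precision <- safe_div(tp, tp + fp)
  recall <- safe_div(tp, tp + fn)
  f1 <- safe_div(2 * precision * recall, precision + recall)
  acc <- (tp + tn) / total * 100
  if (!is.null(round_to)) {
    acc <- round(acc, round_to)
    precision <- round(precision, round_to)
    recall <- round(recall, round_to)
    f1 <- round(f1, round_to)
  }
  tibble::tibble(
    class = cm$labels,
    tp = as.integer(tp), tn = as.integer(tn),
    fp = as.integer(fp), fn = as.integer(fn),
    n_classified = as.integer(colSums(m)),
    n_truth = as.integer(rowSums(m)),
    accuracy = unname(acc),
    precision = unname(precision),
    recall = unname(recall),
    f_measure = unname(f1)
  )
}

#' Export per-class metrics in report-table layout
#'
#' @param metrics Tibble from [class_metrics()].
#' @param path File path for a tab-separated table (class, N classified,
#'   N truth, accuracy, precision, recall, F-measure).
#' @return `metrics`, invisibly.
#' @export
write_class_metrics <- function(metrics, path) {
  out <- metrics[, c("class", "n_classified", "n_truth", "accuracy",
                     "precision", "recall", "f_measure")]
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(metrics)
}

#' Pairwise correlation / cosine matrix of labeled vectors
#'
#' Computes the correlation structure among activity classes — either of
#' their feature centroids or of their semantic prototypes — used to reason
#' about when knowledge transfers from seen to unseen classes.
#'
#' @param data A data frame with a label column and numeric columns (one row
#'   per class vector), or a numeric matrix with row names.
#' @param method `"pearson"` or `"cosine"`.
#' @param label_col Name of the label column when `data` is a data frame.
#' @return A `zs_correlation` object: the symmetric K x K coefficient matrix
#'   with unit diagonal.
#' @export
correlation_matrix <- function(data, method = c("pearson", "cosine"),
                               label_col = "label") {
  method <- match.arg(method)
  if (is.data.frame(data)) {
    labels <- as.character(data[[label_col]])
    x <- as.matrix(data[, setdiff(names(data), c(label_col, "instance_id")),
                        drop = FALSE])
  } else {
    x <- as.matrix(data)
    labels <- rownames(x)
  }
  if (is.null(labels) || nrow(x) < 2) {
    abort("need at least two labeled vectors.")
  }
  if (method == "pearson") {
    if (any(apply(x, 1, sd) == 0)) {
      abort("pearson correlation is undefined for a constant vector.")
    }
    r <- cor(t(x))
  } else {
    norms <- sqrt(rowSums(x^2))
    if (any(norms == 0)) abort("cosine is undefined for a zero vector.")
    r <- (x / norms) %*% t(x / norms)
  }
  dimnames(r) <- list(labels, labels)
  diag(r) <- 1
  structure(list(matrix = r, method = method), class = "zs_correlation")
}

#' @export
print.zs_correlation <- function(x, ...) {
  cat(sprintf("<%s correlation matrix: %d classes>\n", x$method,
              nrow(x$matrix)))
  print(round(x$matrix, 3))
  invisible(x)
}

#' @method tidy zs_correlation
#' @export
tidy.zs_correlation <- function(x, ...) {
  df <- as.data.frame(as.table(x$matrix), stringsAsFactors = FALSE)
  names(df) <- c("class_a", "class_b", "coefficient")
  tibble::as_tibble(df)
}

#' Zero-shot accuracy under an enlarged candidate vocabulary
#'
#' Stress-tests semantic discrimination by adding distractor prototypes —
#' candidate labels that are incorrect by construction — to the unseen set
#' before nearest-prototype matching. `mode = "random"` samples tokens
#' uniformly from the embedding table; `mode = "knn"` takes, for each true
#' unseen prototype, its nearest table tokens (the much harder setting).
#' Tokens that tokenize-match any true label are never used as distractors.
#'
#' @param network A trained `zeroshot_network`.
#' @param features Zero-shot feature tibble with a `label` column (truth).
#' @param unseen_prototypes `class_prototypes` of the true unseen classes.
#' @param table [embedding_table()] providing the distractor vocabulary
#'   (not needed when `distractors` is given).
#' @param n_distractors Integer vector: candidate-set enlargements to
#'   evaluate; 0 reproduces the plain evaluation.
#' @param mode `"random"` or `"knn"`.
#' @param seed Seed for random sampling.
#' @param distractors Optional explicit `class_prototypes` to use as the
#'   distractor pool instead of drawing from `table`.
#' @return A tibble with `n_distractors`, `mode` and `accuracy` per setting.
#' @export
evaluate_with_distractors <- function(network, features, unseen_prototypes,
                                      table = NULL,
                                      n_distractors = c(0L, 5L, 10L),
                                      mode = c("random", "knn"),
                                      seed = 1L,
                                      distractors = NULL) {
  mode <- match.arg(mode)
  truth <- features$label
  if (is.null(truth)) abort("`features` must carry a `label` column (truth).")
  E <- zs_embed(network, features)

  accuracy_with <- function(extra) {
    if (is.null(extra)) {
      cand <- unseen_prototypes
    } else {
      overlap <- intersect(rownames(extra), unseen_prototypes$labels)
      if (length(overlap) > 0) {
        abort(sprintf("distractor label(s) collide with true labels: %s.",
                      paste(overlap, collapse = ", ")))
      }
      cand <- as_class_prototypes(rbind(unseen_prototypes$vectors, extra))
    }
    preds <- vapply(seq_len(nrow(E)),
                    function(i) nearest_prototype(E[i, ], cand)$label,
                    character(1))
    mean(preds == truth)
  }

  if (!is.null(distractors)) {
    stopifnot(inherits(distractors, "class_prototypes"))
    return(tibble::tibble(
      n_distractors = length(distractors$labels),
      mode = "explicit",
      accuracy = accuracy_with(distractors$vectors)))
  }

  stopifnot(inherits(table, "embedding_table"))
  true_tokens <- unique(unlist(lapply(unseen_prototypes$labels, tokenize_label)))
  pool_tokens <- setdiff(rownames(table$vectors), true_tokens)

  pick <- function(k) {
    if (k == 0) return(NULL)
    if (mode == "random") {
      if (k > length(pool_tokens)) {
        abort(sprintf("asked for %d distractors but only %d tokens available.",
                      k, length(pool_tokens)))
      }
      toks <- withr::with_seed(seed, sample(pool_tokens, k))
      table$vectors[toks, , drop = FALSE]
    } else {
      if (k > length(pool_tokens)) {
        abort(sprintf("asked for %d neighbors but only %d tokens available.",
                      k, length(pool_tokens)))
      }
      pool_unit <- table$vectors[pool_tokens, , drop = FALSE]
      pool_unit <- pool_unit / sqrt(rowSums(pool_unit^2))
      toks <- unique(unlist(lapply(seq_along(unseen_prototypes$labels),
        function(i) {
          u <- unseen_prototypes$unit[i, ]
          sims <- as.numeric(pool_unit %*% u)
          pool_tokens[order(-sims, pool_tokens)[seq_len(k)]]
        })))
      table$vectors[toks, , drop = FALSE]
    }
  }

  purrr::map_dfr(as.integer(n_distractors), function(k) {
    tibble::tibble(n_distractors = k, mode = mode,
                   accuracy = accuracy_with(pick(k)))
  })
}
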