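#' Embedding tables in the word2vec text format
#'
#' An embedding table maps case-normalized tokens to real vectors of a common
#' dimension L (300 for the published Google-News model). The text format is
#' a header line `"count dim"` followed by one `"token v1 ... vdim"` line per
#' token.
#'
#' @param vectors A numeric matrix with one row per token; row names are the
#'   tokens (lowercased on construction).
#' @return An object of class `embedding_table`.
#' @export
embedding_table <- function(vectors) {
  stopifnot(is.matrix(vectors), !is.null(rownames(vectors)))
  rownames(vectors) <- tolower(rownames(vectors))
  if (anyDuplicated(rownames(vectors))) {
    abort("embedding tokens must be unique after case normalization.")
  }
  structure(list(vectors = vectors, dim = ncol(vectors)),
            class = "embedding_table")
}

#' @export
print.embedding_table <- function(x, ...) {
  cat(sprintf("<embedding_table: %d tokens, dimension %d>\n",
              nrow(x$vectors), x$dim))
  invisible(x)
}

#' @export
dim.embedding_table <- function(x) dim(x$vectors)

#' Read a word2vec text-format embedding file
#'
#' @param path Path to a word2vec text file.
#' @return An [embedding_table()].
#' @export
read_word2vec <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 1) abort("empty word2vec file.")
  header <- as.integer(strsplit(trimws(lines[1]), "[[:space:]]+")[[1]])
  if (length(header) != 2 || anyNA(header)) {
    abort("word2vec header must be two integers: 'count dim'.")
  }
  count <- header[1]
  l <- header[2]
  body <- lines[-1]
  body <- body[nzchar(trimws(body))]
  if (length(body) != count) {
    abort(sprintf("word2vec header promises %d tokens but file has %d lines.",
                  count, length(body)))
  }
  parts <- strsplit(trimws(body), "[[:space:]]+")
  tokens <- vapply(parts, `[[`, character(1), 1)
  bad <- which(lengths(parts) != l + 1)
  if (length(bad) > 0) {
    abort(sprintf("token '%s' has %d values, expected %d.",
                  tokens[bad[1]], lengths(parts)[bad[1]] - 1, l))
  }
  vecs <- matrix(as.numeric(unlist(lapply(parts, `[`, -1))),
                 nrow = count, ncol = l, byrow = TRUE)
  if (anyNA(vecs)) {
    abort(sprintf("token '%s' has a non-numeric vector entry.",
                  tokens[which(rowSums(is.na(vecs)) > 0)[1]]))
  }
  rownames(vecs) <- tokens
  embedding_table(vecs)
}

#' Write an embedding table in word2vec text format
#'
#' @param table An [embedding_table()].
#' @param path File path.
#' @return `table`, invisibly.
#' @export
write_word2vec <- function(table, path) {
  stopifnot(inherits(table, "embedding_table"))
  v <- table$vectors
  lines <- c(
    sprintf("%d %d", nrow(v), ncol(v)),
    vapply(seq_len(nrow(v)), function(i) {
      paste(rownames(v)[i], paste(sprintf("%.8g", v[i, ]), collapse = " "))
    }, character(1))
  )
  writeLines(lines, path)
  invisible(table)
}

#' Split an activity label into embedding tokens
#'
#' Labels in smart-home datasets mix conventions — `"Wash Dinner Dishes"`,
#' `"CookBreakfast"`, `"personal_hygiene"` — while word embeddings hold
#' single lowercase words. Splits on spaces, underscores and camel-case
#' boundaries, then lowercases.
#'
#' @param label Activity label.
#' @return Character vector of tokens.
#' @export
tokenize_label <- function(label) {
  x <- gsub("([[:lower:]])([[:upper:]])", "\\1 \\2", label)
  x <- gsub("[_[:space:]]+", " ", x)
  tokens <- tolower(strsplit(trimws(x), " ")[[1]])
  tokens[nzchar(tokens)]
}

#' Vectorize activity labels as semantic class prototypes
#'
#' Each label's prototype is the arithmetic mean of its tokens' embedding
#' vectors; tokens missing from the table are skipped with a warning as long
#' as at least one token is found, otherwise an error lists the attempted
#' tokens.
#'
#' @param labels Character vector of activity labels.
#' @param table An [embedding_table()].
#' @return An object of class `class_prototypes`: a list with `labels`, the
#'   raw prototype matrix `vectors` (labels x L) and its row-wise
#'   L2-normalized copy `unit`.
#' @export
label_prototypes <- function(labels, table) {
  stopifnot(inherits(table, "embedding_table"), length(labels) >= 1)
  if (anyDuplicated(labels)) abort("prototype labels must be unique.")
  vecs <- t(vapply(labels, function(lab) {
    tokens <- tokenize_label(lab)
    found <- tokens[tokens %in% rownames(table$vectors)]
    if (length(found) == 0) {
      abort(sprintf("no embedding found for label '%s' (tried tokens: %s).",
                    lab, paste(tokens, collapse = ", ")))
    }
    missing <- setdiff(tokens, found)
    if (length(missing) > 0) {
      warn(sprintf("label '%s': token(s) %s not in the embedding table; skipped.",
                   lab, paste(missing, collapse = ", ")))
    }
    colMeans(table$vectors[found, , drop = FALSE])
  }, numeric(table$dim)))
  rownames(vecs) <- labels
  as_class_prototypes(vecs)
}

#' Construct class prototypes directly from a labeled vector matrix
#'
#' @param vectors Numeric matrix, one row per class, row names are labels.
#' @return A `class_prototypes` object.
#' @export
as_class_prototypes <- function(vectors) {
  stopifnot(is.matrix(vectors), !is.null(rownames(vectors)))
  norms <- sqrt(rowSums(vectors^2))
  if (any(norms == 0)) {
    abort(sprintf("prototype '%s' is the zero vector.",
                  rownames(vectors)[which(norms == 0)[1]]))
  }
  structure(list(labels = rownames(vectors),
                 vectors = vectors,
                 unit = vectors / norms),
            class = "class_prototypes")
}

#' @export
print.class_prototypes <- function(x, ...) {
  cat(sprintf("<class_prototypes: %d classes, dimension %d>\n  %s\n",
              length(x$labels), ncol(x$vectors),
              paste(x$labels, collapse = ", ")))
  invisible(x)
}

#' Cosine similarity between two vectors
#'
#' `dot(x, y) / (||x|| * ||y||)`, in `[-1, 1]`. This is the quantity that
#' drives nearest-prototype matching; note that despite being written as a
#' "distance" in some treatments it is a similarity — larger means closer.
#'
#' @param x,y Nonzero numeric vectors of equal length.
#' @return A number in `[-1, 1]`.
#' @export
cosine_similarity <- function(x, y) {
  stopifnot(length(x) == length(y))
  nx <- sqrt(sum(x^2))
  ny <- sqrt(sum(y^2))
  if (nx == 0 || ny == 0) abort("cosine similarity is undefined for a zero vector.")
  sum(x * y) / (nx * ny)
}

#' Nearest semantic class prototype of a query vector
#'
#' Returns the prototype maximizing cosine similarity to the query; exact
#' ties are broken by the lexicographically smallest label so matching is
#' deterministic.
#'
#' @param query Nonzero numeric vector of the prototype dimension.
#' @param prototypes A `class_prototypes` object.
#' @return A one-row tibble with `label` and `similarity`.
#' @export
nearest_prototype <- function(query, prototypes) {
  stopifnot(inherits(prototypes, "class_prototypes"))
  if (length(prototypes$labels) == 0) abort("no prototypes supplied.")
  if (length(query) != ncol(prototypes$vectors)) {
    abort("query dimension does not match the prototypes.")
  }
  nq <- sqrt(sum(query^2))
  if (nq == 0) abort("cosine similarity is undefined for a zero query vector.")
  sims <- as.numeric(prototypes$unit %*% (query / nq))
  best <- order(-sims, prototypes$labels)[1]
  tibble::tibble(label = prototypes$labels[best], similarity = sims[best])
}
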