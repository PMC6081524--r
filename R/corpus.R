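#' Bag-of-words corpus container
#'
#' A corpus is an M x V sparse matrix of nonnegative integer term counts
#' together with its vocabulary (column order = term order) and document
#' identifiers. Rows must be non-empty: a document with no surviving tokens
#' is not a document.
#'
#' @param counts an M x V matrix coercible to [Matrix::dgCMatrix-class] with
#'   nonnegative integer entries.
#' @param terms character vector of V unique terms, one per column.
#' @param doc_ids character vector of M document identifiers; defaults to
#'   `"d1" ... "dM"`.
#' @return an object of class `swarmlda_corpus` with elements `counts`,
#'   `terms`, `doc_ids`.
#' @export
corpus <- function(counts, terms, doc_ids = NULL) {
  counts <- methods::as(methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                                                "dMatrix"), "generalMatrix"), "CsparseMatrix")
  x <- counts@x
  if (any(x < 0) || any(x != round(x))) {
    stop_fmt("corpus counts must be nonnegative integers")
  }
  terms <- as.character(terms)
  if (anyDuplicated(terms)) stop_fmt("vocabulary terms must be unique")
  if (ncol(counts) != length(terms)) {
    stop_fmt("matrix has %d columns but vocabulary has %d terms",
             ncol(counts), length(terms))
  }
  if (nrow(counts) == 0L) stop_fmt("corpus must contain at least one document")
  if (any(Matrix::rowSums(counts) == 0)) {
    stop_fmt("corpus contains all-zero rows (empty documents)")
  }
  if (is.null(doc_ids)) doc_ids <- paste0("d", seq_len(nrow(counts)))
  doc_ids <- as.character(doc_ids)
  if (length(doc_ids) != nrow(counts)) {
    stop_fmt("doc_ids length %d does not match %d documents",
             length(doc_ids), nrow(counts))
  }
  structure(list(counts = counts, terms = terms, doc_ids = doc_ids),
            class = "swarmlda_corpus")
}

#' @export
print.swarmlda_corpus <- function(x, ...) {
  cat(sprintf("<swarmlda_corpus> %d documents, %d terms, %d tokens\n",
              nrow(x$counts), ncol(x$counts), sum(x$counts)))
  invisible(x)
}

#' @rdname corpus
#' @param x object to test.
#' @export
is_corpus <- function(x) inherits(x, "swarmlda_corpus")

#' Labelled corpus
#'
#' Attaches per-document class ids (0-based integers, as stored on disk) to a
#' corpus. Classification stages require labels; unsupervised stages ignore
#' them.
#'
#' @param corpus a [corpus()].
#' @param labels integer vector of per-document class ids, or `NULL`.
#' @return an object of class `swarmlda_labeled_corpus`.
#' @export
labeled_corpus <- function(corpus, labels = NULL) {
  if (!is_corpus(corpus)) stop_fmt("'corpus' must be a swarmlda_corpus")
  if (!is.null(labels)) {
    labels <- as.integer(labels)
    if (length(labels) != nrow(corpus$counts)) {
      stop_fmt("labels length %d does not match %d documents",
               length(labels), nrow(corpus$counts))
    }
    if (anyNA(labels)) stop_fmt("labels must not contain NA")
  }
  structure(list(corpus = corpus, labels = labels),
            class = "swarmlda_labeled_corpus")
}

#' @export
print.swarmlda_labeled_corpus <- function(x, ...) {
  print(x$corpus)
  if (is.null(x$labels)) cat("  unlabelled\n")
  else cat(sprintf("  %d classes\n", length(unique(x$labels))))
  invisible(x)
}

#' Read a sparse corpus from disk
#'
#' The matrix is MatrixMarket coordinate integer format (1-based on disk,
#' 0-based semantics in memory follow R's own indexing); the vocabulary is
#' one UTF-8 term per line, in column order; labels, when present, are a
#' two-column tab-separated file of `doc_id<TAB>class`.
#'
#' @param matrix_path path to the `.mtx` counts file.
#' @param vocab_path path to the vocabulary file.
#' @param labels_path optional path to the labels TSV.
#' @return a [labeled_corpus()]; `labels` is `NULL` when no labels file is
#'   given.
#' @export
read_corpus <- function(matrix_path, vocab_path, labels_path = NULL) {
  m <- Matrix::readMM(matrix_path)
  terms <- readLines(vocab_path, encoding = "UTF-8")
  terms <- terms[nzchar(terms)]
  labels <- NULL
  doc_ids <- NULL
  if (!is.null(labels_path)) {
    lab <- utils::read.table(labels_path, sep = "\t", header = FALSE,
                             col.names = c("doc_id", "class"),
                             colClasses = c("character", "integer"))
    if (nrow(lab) != nrow(m)) {
      stop_fmt("labels file has %d rows but matrix has %d documents",
               nrow(lab), nrow(m))
    }
    labels <- lab$class
    doc_ids <- lab$doc_id
  }
  labeled_corpus(corpus(m, terms, doc_ids), labels)
}

#' Write a sparse corpus to disk
#'
#' Inverse of [read_corpus()]; the round trip is lossless on counts, terms
#' and labels. The matrix header is `coordinate integer general`.
#'
#' @param lc a [labeled_corpus()] (a bare [corpus()] is accepted).
#' @param matrix_path,vocab_path,labels_path output paths; `labels_path` is
#'   ignored when the corpus is unlabelled.
#' @return invisibly, the paths written.
#' @export
write_corpus <- function(lc, matrix_path, vocab_path, labels_path = NULL) {
  if (is_corpus(lc)) lc <- labeled_corpus(lc)
  if (!inherits(lc, "swarmlda_labeled_corpus")) {
    stop_fmt("'lc' must be a swarmlda corpus")
  }
  cc <- lc$corpus
  tm <- methods::as(cc$counts, "TsparseMatrix")
  con <- file(matrix_path, "w")
  on.exit(close(con), add = TRUE)
  writeLines(c("%%MatrixMarket matrix coordinate integer general",
               sprintf("%d %d %d", nrow(tm), ncol(tm), length(tm@x))), con)
  if (length(tm@x)) {
    writeLines(sprintf("%d %d %d", tm@i + 1L, tm@j + 1L, as.integer(tm@x)), con)
  }
  writeLines(cc$terms, vocab_path, useBytes = TRUE)
  written <- c(matrix_path, vocab_path)
  if (!is.null(lc$labels) && !is.null(labels_path)) {
    utils::write.table(data.frame(doc_id = cc$doc_ids, class = lc$labels),
                       labels_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    written <- c(written, labels_path)
  }
  invisible(written)
}

#' Tokenize raw text lines into a corpus
#'
#' A deliberately minimal tokenizer: lowercase, split on anything that is not
#' a letter or digit, drop empty tokens. Terms whose total collection
#' frequency falls below `min_term_count` are removed; documents emptied by
#' the filter are dropped with a warning so that no all-zero row survives.
#'
#' @param text_lines character vector, one document per line.
#' @param min_term_count minimum total occurrences for a term to be kept.
#' @return a [corpus()]; `doc_ids` are `"d<i>"` with `i` the original line
#'   number, so dropped lines are visible.
#' @export
tokenize_to_corpus <- function(text_lines, min_term_count = 1L) {
  min_term_count <- assert_scalar_int(min_term_count, "min_term_count", min = 1)
  if (length(text_lines) == 0L) stop_fmt("no input lines")
  toks <- strsplit(tolower(text_lines), "[^[:alnum:]]+")
  toks <- lapply(toks, function(t) t[nzchar(t)])
  all_tokens <- unlist(toks, use.names = FALSE)
  if (length(all_tokens) == 0L) stop_fmt("all documents are empty")
  freq <- table(all_tokens)
  keep_terms <- sort(names(freq)[freq >= min_term_count])
  if (length(keep_terms) == 0L) {
    stop_fmt("no term reaches min_term_count = %d", min_term_count)
  }
  toks <- lapply(toks, function(t) t[t %in% keep_terms])
  keep_docs <- which(lengths(toks) > 0L)
  if (length(keep_docs) == 0L) stop_fmt("all documents empty after term filtering")
  if (length(keep_docs) < length(toks)) {
    warn_fmt("dropping %d document(s) emptied by the min_term_count filter",
             length(toks) - length(keep_docs))
  }
  di <- rep.int(seq_along(keep_docs), lengths(toks[keep_docs]))
  wi <- match(unlist(toks[keep_docs], use.names = FALSE), keep_terms)
  m <- Matrix::sparseMatrix(i = di, j = wi, x = 1,
                            dims = c(length(keep_docs), length(keep_terms)))
  corpus(m, keep_terms, doc_ids = paste0("d", keep_docs))
}

# Flatten a corpus to parallel 0-based (doc, word) token vectors for the
# sampler. Token order is row-major over the sparse structure; within a
# (doc, term) cell tokens are contiguous. Order is deterministic.
corpus_tokens <- function(cc) {
  tm <- methods::as(cc$counts, "TsparseMatrix")
  ord <- order(tm@i, tm@j)
  reps <- as.integer(tm@x[ord])
  list(doc = rep.int(tm@i[ord], reps), word = rep.int(tm@j[ord], reps))
}
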