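# Text preprocessing: cleaning/tokenization, TF-IDF vocabulary truncation,
# corpus splitting and integer encoding. Brings raw text (or the synthetic
# generator's output) into the encoded form the trainer consumes.

#' Default English stopword list
#'
#' A fixed, packaged list (119 common English function words). Pinning one
#' list keeps the pipeline reproducible; pass your own list to
#' [clean_and_tokenize()] to override.
#'
#' @return Character vector of stopwords.
#' @export
default_stopwords <- function() {
  path <- system.file("extdata", "stopwords_en.txt", package = "curribatch",
                      mustWork = TRUE)
  readLines(path, encoding = "UTF-8")
}

#' Clean and tokenize raw text
#'
#' Lowercases, replaces punctuation characters with spaces, splits on
#' whitespace, and removes digit-only tokens and stopwords. The operation is
#' idempotent: re-tokenizing the space-joined output changes nothing.
#'
#' @param raw_text A character string (vectors are processed element-wise
#'   and concatenated).
#' @param stopwords Character vector of stopwords; defaults to the packaged
#'   list.
#' @return Character vector of tokens (possibly empty).
#' @export
#' @examples
#' clean_and_tokenize("Chest pain, 2 days", stopwords = c("days"))
clean_and_tokenize <- function(raw_text, stopwords = default_stopwords()) {
  if (length(raw_text) == 0L) return(character(0))
  txt <- tolower(paste(raw_text, collapse = " "))
  txt <- gsub("[[:punct:]]+", " ", txt)
  toks <- strsplit(trimws(txt), "[[:space:]]+")[[1]]
  toks <- toks[nzchar(toks)]
  toks <- toks[!grepl("^[0-9]+$", toks)]
  toks[!(toks %in% stopwords)]
}

#' Build a TF-IDF-truncated vocabulary
#'
#' Scores every token of the corpus at the corpus level as
#' `score(t) = tf(t) * log(N / df(t))`, where `tf` is the total count of `t`
#' across all documents, `df` the number of documents containing it and `N`
#' the number of documents (natural log, no smoothing). The `top_k` tokens
#' by score are retained; ties are broken by total frequency, then
#' lexicographically, so the ranking is deterministic and independent of
#' document order. A token occurring in every document has IDF 0 and ranks
#' last.
#'
#' @param corpus A `labeled_corpus`.
#' @param top_k Number of tokens to retain (default 10000).
#' @return A `vocabulary`: list with `tokens` (retained, rank order), `ids`
#'   (named integer map, contiguous from 1), `unk_id`
#'   (`retained_size + 1`, reserved for out-of-vocabulary tokens) and
#'   `retained_size`.
#' @export
build_vocabulary <- function(corpus, top_k = 10000L) {
  stopifnot(inherits(corpus, "labeled_corpus"))
  assert_count(top_k, "top_k", min = 1L)
  if (length(corpus$examples) == 0L) stop("corpus is empty", call. = FALSE)
  n_docs <- length(corpus$examples)
  all_tok <- unlist(lapply(corpus$examples, `[[`, "tokens"), use.names = FALSE)
  tf_tab <- table(all_tok)
  df_tab <- table(unlist(lapply(corpus$examples,
                                function(e) unique(e$tokens)), use.names = FALSE))
  tokens <- names(tf_tab)
  tf_v <- as.numeric(tf_tab)
  df_v <- as.numeric(df_tab[tokens])
  score <- tf_v * log(n_docs / df_v)
  ord <- order(-score, -tf_v, tokens, method = "radix")
  keep <- utils::head(ord, min(as.integer(top_k), length(tokens)))
  kept <- tokens[keep]
  ids <- seq_along(kept)
  names(ids) <- kept
  structure(list(tokens = kept,
                 ids = ids,
                 unk_id = length(kept) + 1L,
                 retained_size = length(kept),
                 scores = score[keep]),
            class = "vocabulary")
}

#' @export
print.vocabulary <- function(x, ...) {
  cat(sprintf("<vocabulary> %d tokens (+1 unknown id = %d)\n",
              x$retained_size, x$unk_id))
  invisible(x)
}

#' Save / load a vocabulary as two-column TSV (token, id)
#'
#' @param vocab A `vocabulary`.
#' @param path File path.
#' @export
write_vocabulary <- function(vocab, path) {
  stopifnot(inherits(vocab, "vocabulary"))
  utils::write.table(data.frame(token = vocab$tokens, id = vocab$ids),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_vocabulary
#' @export
read_vocabulary <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = c("character", "integer"))
  ids <- df$id
  names(ids) <- df$token
  structure(list(tokens = df$token, ids = ids,
                 unk_id = nrow(df) + 1L, retained_size = nrow(df),
                 scores = NULL),
            class = "vocabulary")
}

#' Split a corpus into train/validation/test
#'
#' Shuffles the corpus with the given seed and partitions it. Validation and
#' test sizes are the floors of their ratio shares; the remainder goes to
#' the training split, which therefore is always the largest under the
#' conventional 7:1:2 ratios.
#'
#' @param corpus A `labeled_corpus` with at least 3 examples.
#' @param ratios Numeric length-3 `(train, val, test)` summing to 1 (within
#'   1e-9). Default `c(0.7, 0.1, 0.2)`.
#' @param seed Integer seed for the shuffle.
#' @return Named list of three `labeled_corpus` objects (`train`, `val`,
#'   `test`) sharing the parent's label catalog and vocabulary; pairwise
#'   disjoint with union equal to the corpus.
#' @export
split_corpus <- function(corpus, ratios = c(0.7, 0.1, 0.2), seed = 1L) {
  stopifnot(inherits(corpus, "labeled_corpus"))
  if (length(ratios) != 3L || any(ratios < 0) || abs(sum(ratios) - 1) > 1e-9) {
    stop("`ratios` must be three non-negative numbers summing to 1", call. = FALSE)
  }
  n <- length(corpus$examples)
  if (n < 3L) stop("corpus must have at least 3 examples to split", call. = FALSE)
  set.seed(fork_seed(seed, "split"))
  perm <- sample.int(n)
  n_val <- floor(n * ratios[2])
  n_test <- floor(n * ratios[3])
  n_train <- n - n_val - n_test
  idx <- list(train = perm[seq_len(n_train)],
              val = perm[n_train + seq_len(n_val)],
              test = perm[n_train + n_val + seq_len(n_test)])
  lapply(idx, function(i) {
    new_labeled_corpus(corpus$examples[i], corpus$label_catalog, corpus$vocabulary)
  })
}

#' Encode a corpus against a vocabulary
#'
#' Maps tokens to integer ids (out-of-vocabulary tokens to the reserved
#' unknown id) and label sets to multi-hot rows over the full label catalog.
#'
#' @param corpus A `labeled_corpus`; every example must have a non-empty
#'   label set (an empty one is a validation error naming the document).
#' @param vocab A `vocabulary` from [build_vocabulary()].
#' @return An `encoded_corpus`: list with `doc_ids`, `token_ids` (list of
#'   integer vectors), `label_matrix` (examples x catalog 0/1 matrix with
#'   dimnames), `label_catalog`, `vocab`.
#' @export
encode_corpus <- function(corpus, vocab) {
  stopifnot(inherits(corpus, "labeled_corpus"), inherits(vocab, "vocabulary"))
  catalog <- corpus$label_catalog
  n <- length(corpus$examples)
  dids <- vapply(corpus$examples, `[[`, "", "doc_id")
  token_ids <- vector("list", n)
  label_matrix <- matrix(0L, nrow = n, ncol = length(catalog),
                         dimnames = list(dids, catalog))
  for (i in seq_len(n)) {
    e <- corpus$examples[[i]]
    if (length(e$labels) == 0L) {
      stop(sprintf("example '%s' has an empty label set", e$doc_id), call. = FALSE)
    }
    m <- vocab$ids[e$tokens]
    m[is.na(m)] <- vocab$unk_id
    token_ids[[i]] <- unname(m)
    j <- match(e$labels, catalog)
    if (anyNA(j)) {
      stop(sprintf("example '%s' carries labels missing from the catalog", e$doc_id),
           call. = FALSE)
    }
    label_matrix[i, j] <- 1L
  }
  structure(list(doc_ids = dids, token_ids = token_ids,
                 label_matrix = label_matrix,
                 label_catalog = catalog, vocab = vocab),
            class = "encoded_corpus")
}

#' @export
print.encoded_corpus <- function(x, ...) {
  cat(sprintf("<encoded_corpus> %d examples, %d labels, vocab %d (+unk)\n",
              length(x$doc_ids), length(x$label_catalog), x$vocab$retained_size))
  invisible(x)
}
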