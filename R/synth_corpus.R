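# Synthetic long-tailed multi-label corpora.
#
# Real ICD-coded discharge-summary corpora are access-restricted, so the
# package ships a generator that reproduces their statistical shape: a large
# label catalog with power-law (Zipf) label frequencies, a handful of labels
# per document, and documents whose tokens carry a learnable label signal.
# The generator is first-class, seeded and fully reproducible; every
# downstream module (samplers, divergence diagnostics, trainer, metrics) is
# exercised against it.

#' Zipf label-frequency distribution
#'
#' Returns the rank-frequency distribution `P(rank r) = r^-s / H(L, s)` over
#' `n_labels` labels, where `H` is the generalized harmonic normalizer. An
#' exponent of 0 gives the uniform distribution; larger exponents concentrate
#' mass on the head labels, emulating the severe label imbalance of clinical
#' coding data.
#'
#' @param n_labels Number of labels `L` (>= 1).
#' @param zipf_exponent Skew `s >= 0`; 0 is uniform.
#' @param seed Ignored; the distribution is a closed form. Accepted so the
#'   operation slots into seeded pipelines uniformly.
#' @return Named numeric vector of length `n_labels` summing to 1,
#'   non-increasing in rank; names are the label identifiers.
#' @export
#' @examples
#' sample_label_frequencies(3, 0)    # uniform: 1/3 each
#' sample_label_frequencies(3, 1)    # 6/11, 3/11, 2/11
sample_label_frequencies <- function(n_labels, zipf_exponent = 1.2, seed = NULL) {
  assert_count(n_labels, "n_labels", min = 1L)
  if (!is.numeric(zipf_exponent) || length(zipf_exponent) != 1L || zipf_exponent < 0) {
    stop("`zipf_exponent` must be a single number >= 0", call. = FALSE)
  }
  w <- seq_len(n_labels)^(-zipf_exponent)
  p <- w / sum(w)
  names(p) <- label_ids(n_labels)
  p
}

label_ids <- function(L) sprintf("c%04d", seq_len(L))
doc_ids_for <- function(n) sprintf("d%06d", seq_len(n))
token_ids_for <- function(V) sprintf("w%05d", seq_len(V))

#' Configuration for the synthetic corpus generator
#'
#' Defaults describe the desk-scale study corpus used throughout the
#' package's own experiments: 2,000 documents over a 200-label catalog with
#' Zipf exponent 1.2. Labels per example average 3 (clipped to 1..8), which
#' keeps the fraction of the catalog touched by one document comparable to
#' full-scale clinical coding data (about 11 codes out of ~7,000) when the
#' catalog is scaled down; documents are 100-300 tokens over a 5,000-token
#' vocabulary. `signal_strength` is the probability that a token is drawn
#' from a label-specific token block rather than the shared background, i.e.
#' how learnable the labels are.
#'
#' @param n_examples Number of documents.
#' @param n_labels Size of the label catalog `L`.
#' @param zipf_exponent Label-frequency skew (see
#'   [sample_label_frequencies()]).
#' @param mean_labels_per_example Mean of the (truncated) Poisson label-count
#'   distribution.
#' @param min_labels_per_example,max_labels_per_example Clip bounds for the
#'   label count; the minimum must be >= 1 (every document carries at least
#'   one code).
#' @param vocab_size Token vocabulary size; roughly half is partitioned into
#'   per-label signal blocks, the rest is background.
#' @param doc_length_range Integer `(min, max)` token counts per document.
#' @param signal_strength Probability in `[0, 1]` that a token is
#'   label-conditional.
#' @param seed Integer seed; identical configs generate identical corpora.
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_examples = 2000L,
                         n_labels = 200L,
                         zipf_exponent = 1.2,
                         mean_labels_per_example = 3,
                         max_labels_per_example = 8L,
                         min_labels_per_example = 1L,
                         vocab_size = 5000L,
                         doc_length_range = c(100L, 300L),
                         signal_strength = 0.7,
                         seed = 1L) {
  assert_count(n_examples, "n_examples", min = 0L)
  assert_count(n_labels, "n_labels", min = 1L)
  assert_count(max_labels_per_example, "max_labels_per_example", min = 1L)
  assert_count(min_labels_per_example, "min_labels_per_example", min = 1L)
  assert_count(vocab_size, "vocab_size", min = 2L)
  assert_prob(signal_strength, "signal_strength")
  if (zipf_exponent < 0) stop("`zipf_exponent` must be >= 0", call. = FALSE)
  if (!(min_labels_per_example <= mean_labels_per_example &&
        mean_labels_per_example <= max_labels_per_example)) {
    stop("need min_labels_per_example <= mean_labels_per_example <= max_labels_per_example",
         call. = FALSE)
  }
  if (length(doc_length_range) != 2L || doc_length_range[1] < 1 ||
      doc_length_range[1] > doc_length_range[2]) {
    stop("`doc_length_range` must be (min, max) with 1 <= min <= max", call. = FALSE)
  }
  if (vocab_size < n_labels + 1L) {
    stop("`vocab_size` must exceed `n_labels`: each label needs a signal token plus background",
         call. = FALSE)
  }
  structure(list(
    n_examples = as.integer(n_examples),
    n_labels = as.integer(n_labels),
    zipf_exponent = zipf_exponent,
    mean_labels_per_example = mean_labels_per_example,
    max_labels_per_example = as.integer(max_labels_per_example),
    min_labels_per_example = as.integer(min_labels_per_example),
    vocab_size = as.integer(vocab_size),
    doc_length_range = as.integer(doc_length_range),
    signal_strength = signal_strength,
    seed = as.integer(seed)
  ), class = "synth_config")
}

new_labeled_corpus <- function(examples, label_catalog, vocabulary) {
  stopifnot(is.list(examples), is.character(label_catalog), is.character(vocabulary))
  structure(list(examples = examples,
                 label_catalog = label_catalog,
                 vocabulary = vocabulary),
            class = "labeled_corpus")
}

#' Construct a labeled corpus from examples
#'
#' Validates the corpus invariants: unique document ids, non-empty token and
#' label lists, and every label present in the catalog.
#'
#' @param examples List of examples, each a list with `doc_id` (string),
#'   `tokens` (character vector) and `labels` (character vector).
#' @param label_catalog Ordered character vector of all label identifiers;
#'   defaults to the sorted labels observed in `examples`.
#' @param vocabulary Ordered character vector of tokens; defaults to the
#'   sorted tokens observed.
#' @return A `labeled_corpus`.
#' @export
labeled_corpus <- function(examples,
                           label_catalog = NULL,
                           vocabulary = NULL) {
  ids <- vapply(examples, function(e) as.character(e$doc_id), "")
  if (anyDuplicated(ids)) stop("doc_ids must be unique", call. = FALSE)
  for (e in examples) {
    if (length(e$labels) == 0L) {
      stop(sprintf("example '%s' has an empty label set", e$doc_id), call. = FALSE)
    }
    if (length(e$tokens) == 0L) {
      stop(sprintf("example '%s' has no tokens", e$doc_id), call. = FALSE)
    }
  }
  obs_labels <- sort(unique(unlist(lapply(examples, `[[`, "labels"), use.names = FALSE)))
  label_catalog <- label_catalog %||% obs_labels
  if (!all(obs_labels %in% label_catalog)) {
    stop("examples carry labels missing from `label_catalog`", call. = FALSE)
  }
  vocabulary <- vocabulary %||%
    sort(unique(unlist(lapply(examples, `[[`, "tokens"), use.names = FALSE)))
  new_labeled_corpus(examples, label_catalog, vocabulary)
}

#' Generate a synthetic long-tailed multi-label corpus
#'
#' Each document draws its label count from a Poisson distribution with the
#' configured mean, clipped to the configured bounds, then draws that many
#' distinct labels (no duplicate codes on one document) with probability
#' proportional to the Zipf label frequencies. Tokens are a mixture: with
#' probability `signal_strength` a token comes from the token block of one of
#' the document's labels (chosen uniformly among them), otherwise from the
#' shared background block. Disjoint per-label blocks guarantee that a small
#' linear or convolutional classifier can recover the labels from the text.
#'
#' @param config A [synth_config()].
#' @return A `labeled_corpus` whose `label_catalog` covers all
#'   `config$n_labels` labels (including any that happened to never be
#'   drawn) and whose `vocabulary` is the full generator vocabulary. The
#'   generating config is attached as attribute `"config"`.
#' @export
#' @examples
#' corp <- generate_corpus(synth_config(n_examples = 50, n_labels = 20,
#'                                      vocab_size = 200, seed = 7))
#' corpus_stats(corp)
generate_corpus <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  L <- config$n_labels
  V <- config$vocab_size
  if (config$n_examples == 0L) {
    warning("generating an empty corpus (n_examples = 0)", call. = FALSE)
    corp <- new_labeled_corpus(list(), label_ids(L), token_ids_for(V))
    attr(corp, "config") <- config
    return(corp)
  }
  set.seed(fork_seed(config$seed, "synth"))
  p <- sample_label_frequencies(L, config$zipf_exponent)
  vocab <- token_ids_for(V)
  # Per-label signal blocks: up to half the vocabulary, at least 1 token per
  # label; the remainder is background.
  spl <- max(1L, (V %/% 2L) %/% L)
  n_signal <- spl * L
  n_bg <- V - n_signal
  n <- config$n_examples
  k <- stats::rpois(n, config$mean_labels_per_example)
  k <- pmin(pmax(k, config$min_labels_per_example),
            min(config$max_labels_per_example, L))
  lens <- sample(config$doc_length_range[1]:config$doc_length_range[2], n, replace = TRUE)
  examples <- vector("list", n)
  dids <- doc_ids_for(n)
  for (i in seq_len(n)) {
    labs <- sort(sample.int(L, k[i], prob = p))
    len <- lens[i]
    is_sig <- stats::runif(len) < config$signal_strength
    tok <- integer(len)
    nsig <- sum(is_sig)
    if (nsig > 0L) {
      which_lab <- labs[sample.int(length(labs), nsig, replace = TRUE)]
      tok[is_sig] <- (which_lab - 1L) * spl + sample.int(spl, nsig, replace = TRUE)
    }
    if (nsig < len) {
      tok[!is_sig] <- if (n_bg > 0L) n_signal + sample.int(n_bg, len - nsig, replace = TRUE)
                      else sample.int(n_signal, len - nsig, replace = TRUE)
    }
    examples[[i]] <- list(doc_id = dids[i],
                          tokens = vocab[tok],
                          labels = label_ids(L)[labs])
  }
  corp <- new_labeled_corpus(examples, label_ids(L), vocab)
  attr(corp, "config") <- config
  corp
}

#' Summary statistics of a labeled corpus
#'
#' Exact counts and means of words and labels per example, in the layout
#' customarily used to describe coded clinical corpora.
#'
#' @param corpus A `labeled_corpus`.
#' @return A `corpus_stats` list with `n_examples`, `n_unique_labels`, and
#'   `avg/max/min_words_per_example`, `avg/max/min_labels_per_example`.
#'   An empty corpus yields all-zero statistics.
#' @export
corpus_stats <- function(corpus) {
  stopifnot(inherits(corpus, "labeled_corpus"))
  n <- length(corpus$examples)
  if (n == 0L) {
    out <- list(n_examples = 0L, n_unique_labels = 0L,
                avg_words_per_example = 0, max_words_per_example = 0L,
                min_words_per_example = 0L,
                avg_labels_per_example = 0, max_labels_per_example = 0L,
                min_labels_per_example = 0L)
    return(structure(out, class = "corpus_stats"))
  }
  nw <- vapply(corpus$examples, function(e) length(e$tokens), 0L)
  nl <- vapply(corpus$examples, function(e) length(e$labels), 0L)
  out <- list(
    n_examples = n,
    n_unique_labels = length(unique(unlist(lapply(corpus$examples, `[[`, "labels"),
                                           use.names = FALSE))),
    avg_words_per_example = mean(nw),
    max_words_per_example = max(nw),
    min_words_per_example = min(nw),
    avg_labels_per_example = mean(nl),
    max_labels_per_example = max(nl),
    min_labels_per_example = min(nl)
  )
  structure(out, class = "corpus_stats")
}

#' @export
print.corpus_stats <- function(x, ...) {
  cat("Corpus statistics\n")
  cat(sprintf("  examples: %d   unique labels: %d\n", x$n_examples, x$n_unique_labels))
  cat(sprintf("  words  per example: avg %.2f (min %d, max %d)\n",
              x$avg_words_per_example, x$min_words_per_example, x$max_words_per_example))
  cat(sprintf("  labels per example: avg %.2f (min %d, max %d)\n",
              x$avg_labels_per_example, x$min_labels_per_example, x$max_labels_per_example))
  invisible(x)
}

#' @export
print.labeled_corpus <- function(x, ...) {
  cat(sprintf("<labeled_corpus> %d examples, %d labels, %d vocabulary tokens\n",
              length(x$examples), length(x$label_catalog), length(x$vocabulary)))
  invisible(x)
}

#' Write / read a corpus as JSON-lines
#'
#' One example per line with fields `doc_id`, `tokens`, `labels` (UTF-8).
#' The catalog and vocabulary are not serialized; on reading they default to
#' the sorted labels/tokens observed in the file, or can be supplied.
#'
#' @param corpus A `labeled_corpus`.
#' @param path File path.
#' @return `write_corpus` returns `path` invisibly; `read_corpus` returns a
#'   `labeled_corpus`.
#' @export
write_corpus <- function(corpus, path) {
  stopifnot(inherits(corpus, "labeled_corpus"))
  lines <- vapply(corpus$examples, function(e) {
    jsonlite::toJSON(list(doc_id = jsonlite::unbox(e$doc_id),
                          tokens = e$tokens, labels = e$labels))
  }, "")
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_corpus
#' @param label_catalog,vocabulary Optional explicit catalog/vocabulary
#'   (labels or tokens absent from the file are otherwise lost).
#' @export
read_corpus <- function(path, label_catalog = NULL, vocabulary = NULL) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  examples <- lapply(lines, function(ln) {
    x <- jsonlite::fromJSON(ln)
    list(doc_id = x$doc_id, tokens = as.character(x$tokens),
         labels = as.character(x$labels))
  })
  labeled_corpus(examples, label_catalog = label_catalog, vocabulary = vocabulary)
}

#' Write corpus statistics as TSV
#'
#' @param stats A `corpus_stats` object.
#' @param path File path.
#' @export
write_stats_tsv <- function(stats, path) {
  stopifnot(inherits(stats, "corpus_stats"))
  df <- data.frame(statistic = names(unclass(stats)),
                   value = unlist(unclass(stats), use.names = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
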