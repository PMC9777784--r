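# Batch-set construction: the heart of the curriculum batching strategy.
#
# Three samplers build batch sets with three different pooled label
# exposures from the same training corpus:
#   SDD  - plain shuffling: a seeded permutation chunked by a sliding window;
#          batches partition the corpus, so local batch statistics fluctuate
#          around the global ones.
#   UDD  - stratified sampling with replacement (SSR): each batch draws M
#          labels uniformly over the training label set, then one example
#          uniformly from each drawn label's stratum; rare codes are seen as
#          often as common ones.
#   IDD  - probability sampling with replacement (PSR): labels are drawn
#          from the empirical label distribution instead, matching each
#          batch's label exposure to the global distribution.
# A curriculum schedule then sequences the three batch sets from easy
# (UDD) to hard (IDD) across training epochs.

BATCHSET_KINDS <- c("UDD", "SDD", "IDD")

#' Empirical label distribution of a corpus
#'
#' Each example contributes each of its labels once;
#' `P(l) = incidences(l) / total incidences`. Labels in the catalog that
#' never occur get probability 0.
#'
#' @param x A `labeled_corpus`, an `encoded_corpus`, or a list of character
#'   label sets.
#' @param label_catalog Catalog to index the distribution by; defaults to
#'   the object's own catalog (required for a bare list of label sets).
#' @return Named numeric vector over the catalog, non-negative, summing
#'   to 1.
#' @export
#' @examples
#' corp <- labeled_corpus(list(
#'   list(doc_id = "a", tokens = "t", labels = "x"),
#'   list(doc_id = "b", tokens = "t", labels = c("x", "y"))))
#' label_distribution(corp) # x: 2/3, y: 1/3
label_distribution <- function(x, label_catalog = NULL) {
  sets <- label_sets_of(x)
  label_catalog <- label_catalog %||% catalog_of(x)
  if (is.null(label_catalog)) {
    label_catalog <- sort(unique(unlist(sets, use.names = FALSE)))
  }
  all_labs <- unlist(sets, use.names = FALSE)
  if (length(all_labs) == 0L) stop("no label incidences to form a distribution",
                                   call. = FALSE)
  counts <- table(factor(all_labs, levels = label_catalog))
  p <- as.numeric(counts) / length(all_labs)
  names(p) <- label_catalog
  p
}

label_sets_of <- function(x) {
  if (inherits(x, "labeled_corpus")) {
    lapply(x$examples, `[[`, "labels")
  } else if (inherits(x, "encoded_corpus")) {
    apply(x$label_matrix, 1L, function(r) x$label_catalog[r > 0], simplify = FALSE)
  } else if (is.list(x)) {
    x
  } else {
    stop("cannot extract label sets from this object", call. = FALSE)
  }
}

catalog_of <- function(x) {
  if (inherits(x, "labeled_corpus") || inherits(x, "encoded_corpus")) x$label_catalog
  else NULL
}

new_batch_set <- function(kind, batches, batch_size, seed, source,
                          drawn_labels = NULL) {
  kind <- match.arg(kind, BATCHSET_KINDS)
  structure(list(kind = kind, batches = batches,
                 batch_size = as.integer(batch_size), seed = as.integer(seed),
                 source_corpus_id = source, drawn_labels = drawn_labels),
            class = "batch_set")
}

#' @export
print.batch_set <- function(x, ...) {
  cat(sprintf("<batch_set> kind %s: %d batches of size %d (seed %d)\n",
              x$kind, length(x$batches), x$batch_size, x$seed))
  invisible(x)
}

# Map label -> integer indices of training examples carrying it.
label_strata <- function(corpus) {
  sets <- label_sets_of(corpus)
  n_per <- lengths(sets)
  split(rep(seq_along(sets), n_per), unlist(sets, use.names = FALSE))
}

corpus_doc_ids <- function(corpus) {
  if (inherits(corpus, "encoded_corpus")) corpus$doc_ids
  else vapply(corpus$examples, `[[`, "", "doc_id")
}

#' Shuffle batching (SDD batch set)
#'
#' Randomly permutes the training corpus and chunks it with a sliding
#' window of size `M` into `K = ceiling(|D| / M)` batches; every example
#' appears exactly once, the last batch may be short.
#'
#' @param corpus Training corpus (`labeled_corpus` or `encoded_corpus`).
#' @param M Batch size (>= 1). If `M > |D|` a single batch of size `|D|` is
#'   returned with a warning.
#' @param seed Integer seed.
#' @return A `batch_set` of kind `"SDD"`; batches hold document ids.
#' @export
shuffle_batchset <- function(corpus, M, seed = 1L) {
  assert_count(M, "M", min = 1L)
  dids <- corpus_doc_ids(corpus)
  n <- length(dids)
  if (n == 0L) stop("corpus is empty", call. = FALSE)
  if (M > n) {
    warning(sprintf("batch size M = %d exceeds |D| = %d; returning one batch", M, n),
            call. = FALSE)
    M <- n
  }
  set.seed(fork_seed(seed, "sdd"))
  perm <- sample.int(n)
  K <- ceiling(n / M)
  batches <- lapply(seq_len(K), function(b) {
    dids[perm[((b - 1L) * M + 1L):min(b * M, n)]]
  })
  new_batch_set("SDD", batches, M, seed, corpus_id_any(corpus))
}

corpus_id_any <- function(corpus) {
  if (inherits(corpus, "labeled_corpus")) corpus_id(corpus)
  else sprintf("encoded-n%d-L%d", length(corpus$doc_ids), length(corpus$label_catalog))
}

#' Stratified sampling with replacement (UDD batch set)
#'
#' Each batch draws `M` labels uniformly at random (with replacement) from
#' the set of labels that occur in the training corpus, then one example
#' uniformly with replacement from each drawn label's stratum (the examples
#' whose label set contains it). `N` batches are drawn,
#' `N = ceiling(|D| / M)` by default, so that one pass over the batch set
#' costs the same as one shuffled epoch. Duplicate examples within a batch
#' are permitted (sampling is with replacement).
#'
#' @param corpus Training corpus.
#' @param M Batch size (number of label draws per batch).
#' @param N Number of batches; default `ceiling(|D| / M)`.
#' @param seed Integer seed.
#' @return A `batch_set` of kind `"UDD"`; the label draws behind each batch
#'   are kept in `$drawn_labels` so the sampler's marginal can be audited.
#' @export
ssr_batchset <- function(corpus, M, N = NULL, seed = 1L) {
  sample_batchset(corpus, M, N, seed, kind = "UDD")
}

#' Probability sampling with replacement (IDD batch set)
#'
#' Identical to [ssr_batchset()] except that the `M` labels of each batch
#' are drawn i.i.d. from the empirical label distribution of the training
#' corpus (via [label_distribution()]) rather than uniformly, so each
#' batch's label exposure tracks the global distribution.
#'
#' @inheritParams ssr_batchset
#' @param N_prime Number of batches; default `ceiling(|D| / M)`.
#' @return A `batch_set` of kind `"IDD"`.
#' @export
psr_batchset <- function(corpus, M, N_prime = NULL, seed = 1L) {
  sample_batchset(corpus, M, N_prime, seed, kind = "IDD")
}

sample_batchset <- function(corpus, M, N, seed, kind) {
  assert_count(M, "M", min = 1L)
  dids <- corpus_doc_ids(corpus)
  n <- length(dids)
  if (n == 0L) stop("corpus is empty", call. = FALSE)
  strata <- label_strata(corpus)
  if (length(strata) == 0L) stop("corpus has no labels", call. = FALSE)
  if (is.null(N)) N <- ceiling(n / M) else assert_count(N, "N", min = 1L)
  set.seed(fork_seed(seed, tolower(kind)))
  present <- names(strata)
  prob <- NULL
  if (kind == "IDD") {
    p <- label_distribution(corpus)
    prob <- p[present]
  }
  batches <- vector("list", N)
  drawn_all <- vector("list", N)
  for (b in seq_len(N)) {
    drawn <- if (is.null(prob)) sample(present, M, replace = TRUE)
             else sample(present, M, replace = TRUE, prob = prob)
    within <- vapply(drawn, function(l) {
      s <- strata[[l]]
      s[sample.int(length(s), 1L)]
    }, 0L, USE.NAMES = FALSE)
    batches[[b]] <- dids[within]
    drawn_all[[b]] <- drawn
  }
  new_batch_set(kind, batches, M, seed, corpus_id_any(corpus),
                drawn_labels = drawn_all)
}

#' Build the three batch sets at once
#'
#' Convenience wrapper producing the UDD, SDD and IDD batch sets from one
#' corpus, batch size and root seed (each sampler gets its own forked
#' stream).
#'
#' @inheritParams ssr_batchset
#' @return Named list `list(UDD = , SDD = , IDD = )` of `batch_set`s.
#' @export
build_batchsets <- function(corpus, M, seed = 1L) {
  list(UDD = ssr_batchset(corpus, M, seed = seed),
       SDD = shuffle_batchset(corpus, M, seed = seed),
       IDD = psr_batchset(corpus, M, seed = seed))
}

#' Pooled label distribution of a batch set
#'
#' The label distribution of all examples of all batches pooled together
#' (an example drawn twice counts twice).
#'
#' @param batchset A `batch_set`.
#' @param corpus The corpus it was drawn from.
#' @return Named numeric vector over the corpus catalog.
#' @export
pooled_label_distribution <- function(batchset, corpus) {
  stopifnot(inherits(batchset, "batch_set"))
  sets <- label_sets_of(corpus)
  names(sets) <- corpus_doc_ids(corpus)
  pooled <- unlist(batchset$batches, use.names = FALSE)
  missing <- setdiff(pooled, names(sets))
  if (length(missing)) {
    stop("batch set references documents absent from the corpus", call. = FALSE)
  }
  label_distribution(sets[pooled], label_catalog = catalog_of(corpus))
}

#' Curriculum schedule over batch-set kinds
#'
#' An ordered list of phases, each a batch-set kind with an epoch count.
#' The default is the easy-to-hard curriculum UDD (50) -> SDD (50) ->
#' IDD (50), 150 epochs in total; arbitrary phase lists express the
#' ablations (shuffle only, UDD+SDD, ...).
#'
#' @param phases Either a specification string like `"udd:50,sdd:50,idd:50"`
#'   or a list of `list(kind, epochs)` pairs. Kinds are case-insensitive.
#' @return A `curriculum_schedule`: data.frame with columns `kind`,
#'   `epochs`, and attribute `total_epochs`.
#' @export
#' @examples
#' build_schedule()                  # the default 150-epoch curriculum
#' build_schedule("sdd:150")         # plain-shuffle baseline
#' build_schedule(list(list("UDD", 10), list("SDD", 10), list("IDD", 10)))
build_schedule <- function(phases = "udd:50,sdd:50,idd:50") {
  if (is.character(phases)) {
    stopifnot(length(phases) == 1L)
    parts <- strsplit(trimws(phases), ",")[[1]]
    phases <- lapply(parts, function(p) {
      kv <- strsplit(trimws(p), ":")[[1]]
      if (length(kv) != 2L) stop(sprintf("cannot parse phase '%s'", p), call. = FALSE)
      list(kv[1], as.numeric(kv[2]))
    })
  }
  if (length(phases) == 0L) stop("schedule must have at least one phase", call. = FALSE)
  kind <- vapply(phases, function(p) toupper(as.character(p[[1]])), "")
  epochs <- vapply(phases, function(p) as.numeric(p[[2]]), 0)
  if (!all(kind %in% BATCHSET_KINDS)) {
    stop("phase kinds must be among UDD, SDD, IDD", call. = FALSE)
  }
  if (any(is.na(epochs)) || any(epochs < 1) || any(epochs != floor(epochs))) {
    stop("phase epoch counts must be integers >= 1", call. = FALSE)
  }
  out <- data.frame(kind = kind, epochs = as.integer(epochs),
                    stringsAsFactors = FALSE)
  class(out) <- c("curriculum_schedule", "data.frame")
  attr(out, "total_epochs") <- sum(out$epochs)
  out
}

#' @export
print.curriculum_schedule <- function(x, ...) {
  cat(sprintf("<curriculum_schedule> %d phases, %d epochs: %s\n",
              nrow(x), attr(x, "total_epochs"),
              paste(sprintf("%s(%d)", x$kind, x$epochs), collapse = " -> ")))
  invisible(x)
}

#' Total epochs of a schedule
#' @param schedule A `curriculum_schedule`.
#' @return Integer epoch count.
#' @export
total_epochs <- function(schedule) attr(schedule, "total_epochs")

#' Batch-set kind scheduled for a given epoch
#'
#' Epochs are indexed from 0; under the default schedule epoch 0 is UDD,
#' the switch to SDD happens at epoch 50 and to IDD at epoch 100.
#'
#' @param schedule A `curriculum_schedule`.
#' @param epoch Epoch index, `0 <= epoch < total_epochs(schedule)`.
#' @return One of `"UDD"`, `"SDD"`, `"IDD"`.
#' @export
batchset_for_epoch <- function(schedule, epoch) {
  stopifnot(inherits(schedule, "curriculum_schedule"))
  if (!is.numeric(epoch) || length(epoch) != 1L || is.na(epoch) ||
      epoch < 0 || epoch >= attr(schedule, "total_epochs")) {
    stop(sprintf("epoch must satisfy 0 <= epoch < %d", attr(schedule, "total_epochs")),
         call. = FALSE)
  }
  cum <- cumsum(schedule$epochs)
  schedule$kind[which(epoch < cum)[1]]
}

#' First epoch of each phase after the first
#'
#' The epochs at which the curriculum switches batch sets (e.g. 50 and 100
#' under the default schedule); useful for locating phase-transition loss
#' spikes.
#'
#' @param schedule A `curriculum_schedule`.
#' @return Integer vector (possibly empty).
#' @export
phase_switch_epochs <- function(schedule) {
  stopifnot(inherits(schedule, "curriculum_schedule"))
  cs <- cumsum(schedule$epochs)
  if (nrow(schedule) < 2L) integer(0) else cs[-length(cs)]
}

#' Write / read a batch set as JSON-lines
#'
#' One batch per line with fields `kind`, `index`, `doc_ids`.
#'
#' @param batchset A `batch_set`.
#' @param path File path.
#' @export
write_batchset <- function(batchset, path) {
  stopifnot(inherits(batchset, "batch_set"))
  lines <- vapply(seq_along(batchset$batches), function(i) {
    jsonlite::toJSON(list(kind = jsonlite::unbox(batchset$kind),
                          index = jsonlite::unbox(i),
                          doc_ids = batchset$batches[[i]]))
  }, "")
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_batchset
#' @export
read_batchset <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  recs <- lapply(lines, jsonlite::fromJSON)
  kind <- recs[[1]]$kind
  batches <- lapply(recs, function(r) as.character(r$doc_ids))
  new_batch_set(kind, batches, max(lengths(batches)), 0L, "file")
}
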