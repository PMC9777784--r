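# Batch-set difficulty diagnostics.
#
# A batch set is "harder" for the model the closer its per-batch label
# distributions are to the global training distribution (nothing is
# rebalanced for it) and "easier" the more uniform its label exposure. The
# distance between batch-level label distributions and the global one is
# quantified with the Kullback-Leibler divergence and the Jensen-Shannon
# distance. For the three samplers the expected ordering on long-tailed
# corpora is UDD > SDD > IDD under both measures.

#' Kullback-Leibler divergence between label distributions
#'
#' `KL(p || q) = sum p(l) * ln(p(l) / q(l))` in nats. Both arguments are
#' additively smoothed by `epsilon` and renormalized before the sum, which
#' keeps the divergence finite when a batch set misses rare labels
#' entirely. With `epsilon = 0`, a label with `q(l) = 0 < p(l)` makes the
#' divergence `Inf` (returned, not an error), and terms with `p(l) = 0`
#' contribute 0.
#'
#' @param p,q Numeric probability vectors over the same label catalog.
#' @param epsilon Additive smoothing, `>= 0` (default `1e-10`).
#' @return Non-negative real (possibly `Inf`); 0 iff `p == q` at
#'   `epsilon = 0`.
#' @export
#' @examples
#' kl_divergence(c(1, 0), c(0.5, 0.5), epsilon = 0) # log(2)
kl_divergence <- function(p, q, epsilon = 1e-10) {
  check_dist_pair(p, q)
  if (epsilon < 0) stop("`epsilon` must be >= 0", call. = FALSE)
  if (epsilon > 0) {
    p <- p + epsilon; p <- p / sum(p)
    q <- q + epsilon; q <- q / sum(q)
  }
  pos <- p > 0
  if (any(q[pos] == 0)) return(Inf)
  sum(p[pos] * log(p[pos] / q[pos]))
}

#' Jensen-Shannon distance between label distributions
#'
#' The metric square root of the Jensen-Shannon divergence,
#' `sqrt(KL(p || m)/2 + KL(q || m)/2)` with `m = (p + q)/2` and natural
#' logs. Symmetric, and bounded above by `sqrt(ln 2)` (attained by disjoint
#' point masses). No smoothing is needed: `m > 0` wherever `p` or `q` is.
#'
#' @param p,q Numeric probability vectors over the same label catalog.
#' @return Non-negative real in `[0, sqrt(ln 2)]`.
#' @export
#' @examples
#' js_distance(c(1, 0), c(0, 1)) # sqrt(log(2))
js_distance <- function(p, q) {
  check_dist_pair(p, q)
  m <- (p + q) / 2
  sqrt(max(0, kl_divergence(p, m, epsilon = 0) / 2 +
              kl_divergence(q, m, epsilon = 0) / 2))
}

check_dist_pair <- function(p, q) {
  if (length(p) != length(q)) {
    stop("`p` and `q` must be over the same label catalog", call. = FALSE)
  }
  if (!is.null(names(p)) && !is.null(names(q)) && !identical(names(p), names(q))) {
    stop("`p` and `q` have mismatched label catalogs", call. = FALSE)
  }
  if (any(p < 0) || any(q < 0)) stop("probabilities must be non-negative", call. = FALSE)
  invisible(TRUE)
}

#' Batch-set learning-difficulty report
#'
#' Compares the label distribution of each batch set against the global
#' label distribution of the training corpus with both KLD (direction
#' `KL(batch set || corpus)`) and the Jensen-Shannon distance.
#'
#' By default (`aggregate = "per_batch"`) the divergence is computed per
#' batch — each batch's label distribution against the global one — and
#' averaged over batches. This captures the batch-level distribution
#' mismatch that actually drives minibatch gradient noise: a shuffled batch
#' set partitions the corpus, so its *pooled* distribution is exactly the
#' global one, yet its individual batches still fluctuate around it.
#' `aggregate = "pooled"` compares the pooled distribution of the whole
#' batch set instead (useful to verify marginal correctness of the
#' samplers: it is 0 for SDD and converges to 0 for IDD).
#'
#' @param batchsets A list of `batch_set`s (e.g. from [build_batchsets()]).
#' @param corpus The training corpus they were drawn from.
#' @param epsilon Additive smoothing for the KLD (default `1e-10`).
#' @param aggregate `"per_batch"` (default) or `"pooled"`.
#' @param direction `"batch_vs_corpus"` (default) or `"corpus_vs_batch"`,
#'   the KL orientation.
#' @return A `difficulty_report` data.frame with one row per batch set:
#'   `kind`, `kld` (nats), `jsd`, `n_batches`, plus attributes `epsilon`,
#'   `aggregate` and `reference` (corpus id).
#' @export
difficulty_report <- function(batchsets, corpus, epsilon = 1e-10,
                              aggregate = c("per_batch", "pooled"),
                              direction = c("batch_vs_corpus", "corpus_vs_batch")) {
  aggregate <- match.arg(aggregate)
  direction <- match.arg(direction)
  if (inherits(batchsets, "batch_set")) batchsets <- list(batchsets)
  sets <- label_sets_of(corpus)
  names(sets) <- corpus_doc_ids(corpus)
  catalog <- catalog_of(corpus)
  q <- label_distribution(corpus)
  rows <- lapply(batchsets, function(bs) {
    stopifnot(inherits(bs, "batch_set"))
    bad <- setdiff(unlist(bs$batches, use.names = FALSE), names(sets))
    if (length(bad)) stop("batch set references documents absent from the corpus",
                          call. = FALSE)
    one <- function(p) {
      kld <- if (direction == "batch_vs_corpus") kl_divergence(p, q, epsilon)
             else kl_divergence(q, p, epsilon)
      c(kld = kld, jsd = js_distance(p, q))
    }
    if (aggregate == "pooled") {
      v <- one(label_distribution(sets[unlist(bs$batches, use.names = FALSE)],
                                  label_catalog = catalog))
    } else {
      per <- vapply(bs$batches, function(b) {
        one(label_distribution(sets[b], label_catalog = catalog))
      }, c(kld = 0, jsd = 0))
      v <- rowMeans(per)
    }
    data.frame(kind = bs$kind, kld = v[["kld"]], jsd = v[["jsd"]],
               n_batches = length(bs$batches), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("difficulty_report", "data.frame")
  attr(out, "epsilon") <- epsilon
  attr(out, "aggregate") <- aggregate
  attr(out, "direction") <- direction
  attr(out, "reference") <- corpus_id_any(corpus)
  out
}

#' Write a difficulty report as TSV
#'
#' @param report A `difficulty_report`.
#' @param path File path.
#' @export
write_difficulty_tsv <- function(report, path) {
  stopifnot(inherits(report, "difficulty_report"))
  utils::write.table(as.data.frame(report), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
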