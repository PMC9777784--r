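# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Derive a reproducible child seed from a root seed
#'
#' All stochastic stages of the package (corpus generation, splitting, the
#' three batch-set samplers, parameter initialization) draw their seeds from
#' one root seed through this function, so that a single integer pins down an
#' entire experiment while the stages remain statistically decoupled.
#'
#' @param seed Integer root seed.
#' @param label Character tag naming the consumer (e.g. `"ssr"`, `"split"`).
#' @return An integer in `[0, 2^31 - 2]`, a deterministic function of
#'   `seed` and `label`.
#' @export
#' @examples
#' fork_seed(1L, "ssr")
#' fork_seed(1L, "psr") # differs from the "ssr" stream
fork_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(label))
  # 64-bit-safe multiplicative mix kept in double precision; all intermediates
  # stay below 2^53 so the arithmetic is exact.
  h <- 0
  for (k in utf8ToInt(label)) h <- (h * 131 + k) %% 2147483647
  as.integer((abs(seed) %% 2147483647 * 48271 + h * 69621 + 11) %% 2147483647)
}

assert_count <- function(x, name, min = 0L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != floor(x)) {
    stop(sprintf("`%s` must be a single integer >= %d", name, min), call. = FALSE)
  }
  invisible(as.integer(x))
}

assert_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    stop(sprintf("`%s` must be a single number in [0, 1]", name), call. = FALSE)
  }
  invisible(as.numeric(x))
}

# Stable identity string for a corpus, used to check that batch sets,
# difficulty reports and runs refer to the same data.
corpus_id <- function(corpus) {
  n <- length(corpus$examples)
  ids <- vapply(corpus$examples, `[[`, "", "doc_id")
  sprintf("corpus-n%d-L%d-%s", n, length(corpus$label_catalog),
          substr(paste0(c(utils::head(ids, 3), utils::tail(ids, 3)), collapse = "+"), 1, 60))
}
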