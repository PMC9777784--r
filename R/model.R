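# Reference multi-label text classifier: a small convolutional network
# (embedding -> parallel convolutions of widths 2/3/4 -> max-over-time
# pooling -> linear layer to one logit per label), written directly in
# matrix algebra with an explicit backward pass. The trainer treats the
# model through a narrow contract (init / forward / backward), so other
# architectures can be substituted.

#' Specification of the reference convolutional classifier
#'
#' @param vocab_size Number of retained vocabulary tokens (the embedding
#'   table additionally holds a padding row and an unknown-token row).
#' @param n_labels Output dimension = size of the label catalog.
#' @param embedding_dim Embedding width (default 16).
#' @param filter_widths Convolution window widths (default `c(2, 3, 4)`).
#' @param n_filters Filters per width (default 16).
#' @param max_doc_len Documents are truncated/padded to this many tokens
#'   (default 100).
#' @return A `model_spec` list.
#' @export
model_spec <- function(vocab_size, n_labels, embedding_dim = 16L,
                       filter_widths = c(2L, 3L, 4L), n_filters = 16L,
                       max_doc_len = 100L) {
  assert_count(vocab_size, "vocab_size", min = 1L)
  assert_count(n_labels, "n_labels", min = 1L)
  assert_count(embedding_dim, "embedding_dim", min = 1L)
  assert_count(n_filters, "n_filters", min = 1L)
  assert_count(max_doc_len, "max_doc_len", min = max(filter_widths))
  filter_widths <- as.integer(filter_widths)
  if (any(filter_widths < 1L)) stop("filter widths must be >= 1", call. = FALSE)
  structure(list(vocab_size = as.integer(vocab_size),
                 n_labels = as.integer(n_labels),
                 embedding_dim = as.integer(embedding_dim),
                 filter_widths = filter_widths,
                 n_filters = as.integer(n_filters),
                 max_doc_len = as.integer(max_doc_len)),
            class = "model_spec")
}

#' Number of trainable parameters of a spec
#'
#' Embedding `(V + 2) x d` (padding + unknown rows included), per width a
#' `(w d) x F` kernel and `F` biases, and the `(n_widths F) x L` output
#' layer with `L` biases.
#'
#' @param spec A `model_spec`.
#' @return Integer parameter count.
#' @export
n_params <- function(spec) {
  stopifnot(inherits(spec, "model_spec"))
  d <- spec$embedding_dim; FF <- spec$n_filters; L <- spec$n_labels
  emb <- (spec$vocab_size + 2L) * d
  conv <- sum(spec$filter_widths * d * FF + FF)
  out <- length(spec$filter_widths) * FF * L + L
  as.integer(emb + conv + out)
}

#' Seeded uniform parameter initialization
#'
#' All weights are drawn i.i.d. uniform on `[-0.05, 0.05]`; the padding
#' embedding row starts at zero (it still trains). The same seed always
#' yields the same parameters.
#'
#' @param spec A `model_spec`.
#' @param seed Integer seed.
#' @return A named list of parameter matrices/vectors (class
#'   `model_params`).
#' @export
init_params <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "model_spec"))
  set.seed(fork_seed(seed, "init"))
  d <- spec$embedding_dim; FF <- spec$n_filters
  r <- function(n) stats::runif(n, -0.05, 0.05)
  emb <- matrix(r((spec$vocab_size + 2L) * d), ncol = d)
  emb[1L, ] <- 0  # padding row (token id 0)
  params <- list(emb = emb)
  for (w in spec$filter_widths) {
    params[[sprintf("W%d", w)]] <- matrix(r(w * d * FF), ncol = FF)
    params[[sprintf("b%d", w)]] <- r(FF)
  }
  nh <- length(spec$filter_widths) * FF
  params$W_out <- matrix(r(nh * spec$n_labels), ncol = spec$n_labels)
  params$b_out <- r(spec$n_labels)
  structure(params, class = "model_params", spec = spec)
}

# Token-id sequences -> B x T id matrix, truncating and right-padding with
# id 0 (the padding row of the embedding table).
pad_token_ids <- function(token_ids, max_doc_len) {
  B <- length(token_ids)
  out <- matrix(0L, nrow = B, ncol = max_doc_len)
  for (i in seq_len(B)) {
    t <- token_ids[[i]]
    k <- min(length(t), max_doc_len)
    if (k > 0L) out[i, seq_len(k)] <- t[seq_len(k)]
  }
  out
}

# Forward pass over one padded id matrix. Returns logits and, optionally,
# the intermediate quantities the backward pass needs.
cnn_forward <- function(params, spec, ids_mat, keep_cache = FALSE) {
  B <- nrow(ids_mat); T <- ncol(ids_mat)
  d <- spec$embedding_dim; FF <- spec$n_filters
  row_ix <- as.vector(t(ids_mat)) + 1L           # doc-major (doc1 t1..T, ...)
  X <- params$emb[row_ix, , drop = FALSE]        # (B*T) x d
  pooled_all <- vector("list", length(spec$filter_widths))
  cache_w <- if (keep_cache) vector("list", length(spec$filter_widths)) else NULL
  for (wi in seq_along(spec$filter_widths)) {
    w <- spec$filter_widths[wi]
    P <- T - w + 1L
    base <- rep((seq_len(B) - 1L) * T, each = P) + rep(seq_len(P), times = B)
    U <- do.call(cbind, lapply(0:(w - 1L), function(k) X[base + k, , drop = FALSE]))
    Z <- U %*% params[[sprintf("W%d", w)]]
    Z <- Z + rep(params[[sprintf("b%d", w)]], each = nrow(Z))
    H <- pmax(Z, 0)
    pooled <- matrix(-Inf, B, FF)
    amax <- matrix(1L, B, FF)
    off <- (seq_len(B) - 1L) * P
    for (p in seq_len(P)) {
      Hp <- H[p + off, , drop = FALSE]
      upd <- Hp > pooled
      pooled[upd] <- Hp[upd]
      amax[upd] <- p
    }
    pooled_all[[wi]] <- pooled
    if (keep_cache) cache_w[[wi]] <- list(U = U, base = base, P = P,
                                          pooled = pooled, amax = amax)
  }
  h <- do.call(cbind, pooled_all)                # B x (n_widths*F)
  logits <- h %*% params$W_out
  logits <- logits + rep(params$b_out, each = B)
  if (!keep_cache) return(list(logits = logits))
  list(logits = logits, h = h, row_ix = row_ix, B = B, T = T,
       cache_w = cache_w, X_rows = nrow(X))
}

# Backward pass: gradient of the scalar loss w.r.t. every parameter, given
# d loss / d logits. Max-pool routes gradient to the argmax window; the
# ReLU derivative is taken as 0 where the pooled activation is 0.
cnn_backward <- function(params, spec, fwd, dlogits) {
  B <- fwd$B; T <- fwd$T
  d <- spec$embedding_dim; FF <- spec$n_filters
  grads <- list()
  grads$W_out <- crossprod(fwd$h, dlogits)
  grads$b_out <- colSums(dlogits)
  dh <- dlogits %*% t(params$W_out)              # B x (n_widths*F)
  dX <- matrix(0, fwd$X_rows, d)
  for (wi in seq_along(spec$filter_widths)) {
    w <- spec$filter_widths[wi]
    cw <- fwd$cache_w[[wi]]
    P <- cw$P
    dpool <- dh[, (wi - 1L) * FF + seq_len(FF), drop = FALSE]
    dpool[cw$pooled <= 0] <- 0
    nH <- B * P
    dH <- matrix(0, nH, FF)
    rows <- cw$amax + (seq_len(B) - 1L) * P      # B x F matrix of row indices
    li <- as.vector(rows) + rep((seq_len(FF) - 1L) * nH, each = B)
    dH[li] <- as.vector(dpool)
    Wn <- sprintf("W%d", w)
    grads[[Wn]] <- crossprod(cw$U, dH)
    grads[[sprintf("b%d", w)]] <- colSums(dH)
    dU <- dH %*% t(params[[Wn]])                 # (B*P) x (w*d)
    for (k in 0:(w - 1L)) {
      dX[cw$base + k, ] <- dX[cw$base + k, ] + dU[, k * d + seq_len(d), drop = FALSE]
    }
  }
  rs <- rowsum(dX, fwd$row_ix)
  demb <- matrix(0, nrow(params$emb), d)
  demb[as.integer(rownames(rs)), ] <- rs
  grads$emb <- demb
  grads
}

#' Sigmoid binary cross-entropy on logits
#'
#' The numerically stable mean element-wise loss
#' `mean( max(x, 0) - x y + log(1 + exp(-|x|)) )`, equal to
#' `-mean( y log sigma(x) + (1 - y) log(1 - sigma(x)) )` — the standard
#' multi-label objective, one independent sigmoid per label.
#'
#' @param logits Numeric matrix/vector of raw scores.
#' @param targets Binary matrix/vector of the same shape.
#' @return Non-negative scalar.
#' @export
#' @examples
#' bce_loss(0, 1) # log(2)
bce_loss <- function(logits, targets) {
  if (!all(dim(as.matrix(logits)) == dim(as.matrix(targets)))) {
    stop("`logits` and `targets` must have identical shapes", call. = FALSE)
  }
  if (!all(targets %in% c(0, 1))) stop("`targets` must be 0/1", call. = FALSE)
  x <- as.numeric(logits); y <- as.numeric(targets)
  mean(pmax(x, 0) - x * y + log1p(exp(-abs(x))))
}

#' Predicted label scores for encoded examples
#'
#' Runs the forward pass in chunks and returns per-example per-label
#' sigmoid scores in (0, 1). Deterministic given the parameters.
#'
#' @param params `model_params` (or a `train_state`, whose selected
#'   parameters are used).
#' @param data An `encoded_corpus`.
#' @param spec The `model_spec`; defaults to the one attached to `params`.
#' @param chunk Examples per forward pass (default 256).
#' @return Numeric matrix examples x labels with dimnames.
#' @export
predict_scores <- function(params, data, spec = NULL, chunk = 256L) {
  if (inherits(params, "train_state")) {
    spec <- spec %||% params$spec
    params <- params$best_params %||% params$params
  }
  spec <- spec %||% attr(params, "spec")
  stopifnot(inherits(spec, "model_spec"), inherits(data, "encoded_corpus"))
  if (length(data$label_catalog) != spec$n_labels) {
    stop("label catalog size does not match the model's output dimension",
         call. = FALSE)
  }
  n <- length(data$doc_ids)
  out <- matrix(NA_real_, n, spec$n_labels,
                dimnames = list(data$doc_ids, data$label_catalog))
  for (start in seq(1L, n, by = chunk)) {
    idx <- start:min(start + chunk - 1L, n)
    ids_mat <- pad_token_ids(data$token_ids[idx], spec$max_doc_len)
    logits <- cnn_forward(params, spec, ids_mat)$logits
    out[idx, ] <- 1 / (1 + exp(-logits))
  }
  out
}

#' Threshold scores into binary label decisions
#'
#' A label is predicted positive when its score is greater than or equal
#' to the threshold; raising the threshold never increases the number of
#' positives.
#'
#' @param scores Score matrix from [predict_scores()].
#' @param threshold Decision threshold in (0, 1), default 0.5.
#' @return Binary integer matrix of the same shape.
#' @export
predict_labels <- function(scores, threshold = 0.5) {
  if (threshold <= 0 || threshold >= 1) stop("`threshold` must be in (0, 1)",
                                             call. = FALSE)
  m <- (scores >= threshold) + 0L
  dimnames(m) <- dimnames(scores)
  m
}
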