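# Minibatch gradient descent driven by a curriculum schedule. Each epoch
# iterates every batch of the batch set scheduled for that epoch, computes
# the mean sigmoid cross-entropy over the batch, and updates the
# parameters with Adam using the average gradient over the batch's
# examples. Batch sets are built offline once and reused across the epochs
# of a phase.

#' Training configuration
#'
#' Defaults follow common practice for this task family: Adam with
#' learning rate 0.008, decision threshold 0.5, and the 150-epoch
#' easy-to-hard curriculum (UDD 50 / SDD 50 / IDD 50). The total epoch
#' count is the schedule's.
#'
#' @param batch_size Batch size `M` the batch sets were built with.
#' @param learning_rate Adam step size (default 0.008).
#' @param schedule A `curriculum_schedule` (default [build_schedule()]), or
#'   `NULL` for a zero-epoch run (parameters returned untouched).
#' @param seed Integer root seed (initialization forks from it).
#' @param prediction_threshold Decision threshold in (0, 1) used for
#'   validation-time model selection and downstream evaluation.
#' @param beta1,beta2,adam_eps Adam moment decay rates and stabilizer.
#' @param select_best `"micro_f1"` keeps the parameters of the epoch with
#'   the best validation micro-F1 (when a validation set is supplied);
#'   `"final"` keeps the last epoch's.
#' @return A `train_config` list.
#' @export
train_config <- function(batch_size,
                         learning_rate = 0.008,
                         schedule = build_schedule(),
                         seed = 1L,
                         prediction_threshold = 0.5,
                         beta1 = 0.9, beta2 = 0.999, adam_eps = 1e-8,
                         select_best = c("micro_f1", "final")) {
  assert_count(batch_size, "batch_size", min = 1L)
  if (learning_rate <= 0) stop("`learning_rate` must be > 0", call. = FALSE)
  if (prediction_threshold <= 0 || prediction_threshold >= 1) {
    stop("`prediction_threshold` must be in (0, 1)", call. = FALSE)
  }
  if (!is.null(schedule)) stopifnot(inherits(schedule, "curriculum_schedule"))
  structure(list(batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 schedule = schedule,
                 total_epochs = if (is.null(schedule)) 0L else total_epochs(schedule),
                 seed = as.integer(seed),
                 prediction_threshold = prediction_threshold,
                 beta1 = beta1, beta2 = beta2, adam_eps = adam_eps,
                 select_best = match.arg(select_best)),
            class = "train_config")
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, cfg) {
  state$t <- state$t + 1L
  c1 <- 1 - cfg$beta1^state$t
  c2 <- 1 - cfg$beta2^state$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- cfg$beta1 * state$m[[nm]] + (1 - cfg$beta1) * g
    state$v[[nm]] <- cfg$beta2 * state$v[[nm]] + (1 - cfg$beta2) * g * g
    params[[nm]] <- params[[nm]] -
      cfg$learning_rate * (state$m[[nm]] / c1) /
      (sqrt(state$v[[nm]] / c2) + cfg$adam_eps)
  }
  list(params = params, state = state)
}

#' Train the classifier under a curriculum of batch sets
#'
#' For each epoch the schedule selects one of the offline-built batch
#' sets; every batch of that set is visited once, the mean loss over the
#' batch is recorded, and the parameters are updated by Adam with the
#' batch-averaged gradient. The whole run is deterministic given the
#' corpus, batch sets, spec and seed.
#'
#' @param train_data `encoded_corpus` of the training split.
#' @param batchsets Named list of `batch_set`s covering at least every kind
#'   the schedule references (e.g. from [build_batchsets()]); a schedule
#'   kind with no batch set is an error.
#' @param spec A `model_spec` whose output dimension matches the catalog.
#' @param config A `train_config`.
#' @param val_data Optional `encoded_corpus` used to track validation
#'   micro-F1 per epoch and select the best parameters.
#' @return A `train_state`: `params` (final), `best_params` (per
#'   `config$select_best`), `best_epoch`, `loss_history` (data.frame
#'   `epoch`, `phase`, `mean_loss`), `switch_epochs`, `val_history`,
#'   `spec`, `config`.
#' @export
train_classifier <- function(train_data, batchsets, spec, config,
                             val_data = NULL) {
  stopifnot(inherits(train_data, "encoded_corpus"),
            inherits(spec, "model_spec"),
            inherits(config, "train_config"))
  if (spec$n_labels != length(train_data$label_catalog)) {
    stop("model output dimension must equal the label catalog size", call. = FALSE)
  }
  params <- init_params(spec, config$seed)
  E <- config$total_epochs
  empty_hist <- data.frame(epoch = integer(0), phase = character(0),
                           mean_loss = numeric(0))
  if (E == 0L) {
    return(structure(list(params = params, best_params = params,
                          best_epoch = NA_integer_,
                          loss_history = empty_hist,
                          switch_epochs = integer(0),
                          val_history = NULL,
                          spec = spec, config = config),
                     class = "train_state"))
  }
  needed <- unique(config$schedule$kind)
  missing_kinds <- setdiff(needed, names(batchsets))
  if (length(missing_kinds)) {
    stop(sprintf("schedule needs batch set(s) %s but they were not provided",
                 paste(missing_kinds, collapse = ", ")), call. = FALSE)
  }
  # Resolve document ids to row indices once per batch set.
  batch_idx <- lapply(batchsets[needed], function(bs) {
    lapply(bs$batches, function(b) {
      i <- match(b, train_data$doc_ids)
      if (anyNA(i)) stop("batch set references documents absent from the training split",
                         call. = FALSE)
      i
    })
  })
  ids_all <- pad_token_ids(train_data$token_ids, spec$max_doc_len)
  Y_all <- train_data$label_matrix
  L <- spec$n_labels
  adam <- adam_init(params)
  losses <- numeric(E)
  phases <- character(E)
  val_hist <- if (is.null(val_data)) NULL else numeric(E)
  best_f1 <- -Inf
  best_params <- params
  best_epoch <- NA_integer_
  for (epoch in 0:(E - 1L)) {
    kind <- batchset_for_epoch(config$schedule, epoch)
    idx_list <- batch_idx[[kind]]
    batch_losses <- numeric(length(idx_list))
    for (bi in seq_along(idx_list)) {
      idx <- idx_list[[bi]]
      ids_mat <- ids_all[idx, , drop = FALSE]
      Y <- Y_all[idx, , drop = FALSE]
      fwd <- cnn_forward(params, spec, ids_mat, keep_cache = TRUE)
      x <- fwd$logits
      batch_losses[bi] <- mean(pmax(x, 0) - x * Y + log1p(exp(-abs(x))))
      sig <- 1 / (1 + exp(-x))
      dlogits <- (sig - Y) / (nrow(Y) * L)
      grads <- cnn_backward(params, spec, fwd, dlogits)
      upd <- adam_step(params, grads, adam, config)
      params <- upd$params
      adam <- upd$state
    }
    if (!all(is.finite(batch_losses))) {
      stop(sprintf("non-finite training loss at epoch %d", epoch), call. = FALSE)
    }
    losses[epoch + 1L] <- mean(batch_losses)
    phases[epoch + 1L] <- kind
    if (!is.null(val_data)) {
      scores <- predict_scores(params, val_data, spec)
      pred <- predict_labels(scores, config$prediction_threshold)
      f1 <- micro_metrics(pred, val_data$label_matrix)$f1
      val_hist[epoch + 1L] <- f1
      if (config$select_best == "micro_f1" && f1 > best_f1) {
        best_f1 <- f1
        best_params <- params
        best_epoch <- epoch
      }
    }
  }
  if (is.null(val_data) || config$select_best == "final") {
    best_params <- params
    best_epoch <- E - 1L
  }
  structure(list(params = params, best_params = best_params,
                 best_epoch = best_epoch,
                 loss_history = data.frame(epoch = 0:(E - 1L), phase = phases,
                                           mean_loss = losses),
                 switch_epochs = phase_switch_epochs(config$schedule),
                 val_history = val_hist,
                 spec = spec, config = config),
            class = "train_state")
}

#' @export
print.train_state <- function(x, ...) {
  E <- nrow(x$loss_history)
  cat(sprintf("<train_state> %d epochs", E))
  if (E > 0) {
    cat(sprintf(", loss %.4f -> %.4f", x$loss_history$mean_loss[1],
                x$loss_history$mean_loss[E]))
  }
  if (!is.na(x$best_epoch)) cat(sprintf(", selected epoch %d", x$best_epoch))
  cat("\n")
  invisible(x)
}

#' Write the per-epoch loss history as TSV
#'
#' Columns `epoch`, `phase`, `mean_loss`.
#'
#' @param state A `train_state`.
#' @param path File path.
#' @export
write_loss_history_tsv <- function(state, path) {
  stopifnot(inherits(state, "train_state"))
  utils::write.table(state$loss_history, path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
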