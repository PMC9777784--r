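# The package's reference desk-scale studies. Two synthetic corpora are
# used throughout the documentation and tests:
#
#  * the sampler-study corpus (the package defaults: 2,000 documents over
#    200 labels, Zipf 1.2) for the sampling-law and batch-difficulty
#    diagnostics, and
#  * the training-study corpus defined here (2,000 documents over 50
#    labels, Zipf 1.8) for the curriculum-versus-shuffle training
#    comparison.
#
# The training study deliberately operates in the under-converged regime:
# at full scale, curriculum batching matters while the model is still far
# from convergence (150 epochs of deep-model training never saturate on
# ~7,000 ICD codes), so the desk-scale analogue pairs a 30-epoch budget
# with a step size (0.0025) at which those 30 epochs do not saturate the
# small reference network. At the full-scale default step size of 0.008
# the reference model converges within a few epochs and every batching
# strategy reaches the same optimum, which emulates nothing.

#' Conditions of the bundled curriculum training study
#'
#' Returns the fixed corpus, model and optimization settings of the
#' package's desk-scale training study: a long-tailed 50-label corpus with
#' severely rare tail codes (Zipf exponent 1.8, ~2 labels per document),
#' the reference convolutional classifier, a 30-epoch budget split 10/10/10
#' across the curriculum phases, and a long-tail threshold of 30 training
#' documents (covering roughly three quarters of the catalog, as the
#' conventional threshold of 219 does on full-scale ICD-9 data).
#'
#' @return A list with elements `synth` (arguments for [synth_config()]
#'   minus the seed), `batch_size`, `model` (arguments for [model_spec()]
#'   minus sizes), `learning_rate`, `gamma`, `curriculum` and `baseline`
#'   schedule strings.
#' @export
training_study_config <- function() {
  list(
    synth = list(n_examples = 2000L, n_labels = 50L, zipf_exponent = 1.8,
                 mean_labels_per_example = 2, max_labels_per_example = 5L,
                 min_labels_per_example = 1L, vocab_size = 1000L,
                 doc_length_range = c(60L, 120L), signal_strength = 0.8),
    batch_size = 100L,
    model = list(embedding_dim = 32L, filter_widths = c(2L, 3L, 4L),
                 n_filters = 32L, max_doc_len = 80L),
    learning_rate = 0.0025,
    gamma = 30,
    curriculum = "udd:10,sdd:10,idd:10",
    baseline = "sdd:30"
  )
}

#' Run one arm of the training study
#'
#' Generates the training-study corpus for `seed`, splits 7:1:2, builds
#' the vocabulary and the three batch sets, trains the reference
#' classifier under `schedule`, and evaluates micro/macro and long-tailed
#' metrics on the test split with the final-epoch parameters.
#'
#' @param seed Integer seed; all stages fork from it.
#' @param schedule Schedule string, e.g. `"udd:10,sdd:10,idd:10"`.
#' @param study Conditions, defaults to [training_study_config()].
#' @return List with `macro_f1`, `micro_f1`, `lt_recall`, `lt_precision`,
#'   `report`, `longtail`, `loss_history`, `switch_epochs`.
#' @export
run_training_arm <- function(seed, schedule, study = training_study_config()) {
  sc <- do.call(synth_config, c(study$synth, list(seed = fork_seed(seed, "study-corpus"))))
  corpus <- generate_corpus(sc)
  splits <- split_corpus(corpus, seed = fork_seed(seed, "study-split"))
  vocab <- build_vocabulary(splits$train, top_k = study$synth$vocab_size)
  enc <- lapply(splits, encode_corpus, vocab = vocab)
  bs <- build_batchsets(enc$train, study$batch_size,
                        seed = fork_seed(seed, "study-batches"))
  spec <- do.call(model_spec,
                  c(list(vocab_size = vocab$retained_size,
                         n_labels = length(corpus$label_catalog)),
                    study$model))
  tc <- train_config(study$batch_size, learning_rate = study$learning_rate,
                     schedule = build_schedule(schedule),
                     seed = fork_seed(seed, "study-train"),
                     select_best = "final")
  state <- train_classifier(enc$train, bs, spec, tc)
  pred <- predict_labels(predict_scores(state, enc$test),
                         tc$prediction_threshold)
  report <- micro_macro_report(pred, enc$test$label_matrix)
  lt <- longtail_metrics(pred, enc$test$label_matrix,
                         label_frequencies(enc$train), gamma = study$gamma)
  list(macro_f1 = report$f1_macro, micro_f1 = report$f1_micro,
       lt_recall = lt$recall, lt_precision = lt$precision,
       report = report, longtail = lt,
       loss_history = state$loss_history,
       switch_epochs = state$switch_epochs)
}

#' Loss change at each phase switch
#'
#' For each curriculum phase after the first, the difference between the
#' mean training loss at the phase's first epoch and the mean loss at the
#' last epoch of the preceding phase (positive = the switch raised the
#' loss).
#'
#' @param loss_history Data frame from a `train_state` (`epoch`, `phase`,
#'   `mean_loss`).
#' @return Data frame with `switch_epoch`, `loss_before`, `loss_after`,
#'   `rise`.
#' @export
phase_switch_deltas <- function(loss_history) {
  sw <- which(loss_history$phase[-1] != loss_history$phase[-nrow(loss_history)])
  if (length(sw) == 0L) {
    return(data.frame(switch_epoch = integer(0), loss_before = numeric(0),
                      loss_after = numeric(0), rise = numeric(0)))
  }
  data.frame(switch_epoch = loss_history$epoch[sw + 1L],
             loss_before = loss_history$mean_loss[sw],
             loss_after = loss_history$mean_loss[sw + 1L],
             rise = loss_history$mean_loss[sw + 1L] - loss_history$mean_loss[sw])
}
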