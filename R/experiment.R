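# End-to-end experiment orchestration: simulate -> preprocess ->
# make-batches -> diagnose -> train -> evaluate, from one nested config,
# with every stage seeded from a single root seed and all artifacts
# written to a run directory. Rerunning an identical config reproduces
# every file bit for bit.

#' Default experiment configuration
#'
#' A nested list mirroring the pipeline stages. The defaults run the full
#' 150-epoch curriculum on the default synthetic corpus; tests and quick
#' studies shrink the schedule and corpus.
#'
#' @param seed Root seed propagated (via [fork_seed()]) to every stage.
#' @return Nested configuration list.
#' @export
default_run_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    synth = list(n_examples = 2000L, n_labels = 200L, zipf_exponent = 1.2,
                 mean_labels_per_example = 3, max_labels_per_example = 8L,
                 min_labels_per_example = 1L, vocab_size = 5000L,
                 doc_length_range = c(100L, 300L), signal_strength = 0.7),
    split = list(ratios = c(0.7, 0.1, 0.2)),
    vocab = list(top_k = 10000L),
    batching = list(batch_size = 100L),
    schedule = "udd:50,sdd:50,idd:50",
    train = list(learning_rate = 0.008, prediction_threshold = 0.5,
                 model = list(embedding_dim = 16L, filter_widths = c(2L, 3L, 4L),
                              n_filters = 16L, max_doc_len = 100L)),
    longtail = list(gamma = 219)
  )
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(override[[nm]]) && is.list(base[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

#' Read an experiment configuration from YAML
#'
#' Unspecified fields fall back to [default_run_config()].
#'
#' @param path YAML file path.
#' @return Nested configuration list.
#' @export
read_run_config <- function(path) {
  merge_config(default_run_config(), yaml::read_yaml(path))
}

#' Run one end-to-end experiment
#'
#' Generates (or loads) the corpus, splits and encodes it, builds the
#' three batch sets offline, writes the batch-set difficulty report,
#' trains the reference classifier under the configured schedule with
#' validation-based model selection, and evaluates micro/macro and
#' long-tailed metrics on the test split. All artifacts and a manifest
#' capturing every parameter, seed and file checksum are written to
#' `output_dir`. If a stage fails, a `FAILED` marker file naming it is
#' left in the directory.
#'
#' @param config Nested config list (see [default_run_config()]) or a path
#'   to a YAML file.
#' @param output_dir Run directory (created if needed).
#' @param quiet Suppress per-stage progress messages.
#' @return Invisibly, a list with the `train_state`, test `report`,
#'   `longtail` metrics, `difficulty` report and the manifest.
#' @export
run_experiment <- function(config, output_dir, quiet = FALSE) {
  if (is.character(config)) config <- read_run_config(config)
  config <- merge_config(default_run_config(), config)
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  marker <- file.path(output_dir, "FAILED")
  if (file.exists(marker)) unlink(marker)
  stage <- function(name, expr) {
    if (!quiet) message(sprintf("[%s] seed=%d", name, config$seed))
    tryCatch(force(expr), error = function(e) {
      writeLines(sprintf("stage: %s\nerror: %s", name, conditionMessage(e)), marker)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)), call. = FALSE)
    })
  }
  root <- config$seed

  corpus <- stage("simulate", {
    sc <- do.call(synth_config, c(config$synth, list(seed = fork_seed(root, "corpus"))))
    corp <- generate_corpus(sc)
    write_corpus(corp, file.path(output_dir, "corpus.jsonl"))
    write_stats_tsv(corpus_stats(corp), file.path(output_dir, "corpus_stats.tsv"))
    corp
  })

  pre <- stage("preprocess", {
    splits <- split_corpus(corpus, config$split$ratios, seed = fork_seed(root, "split"))
    vocab <- build_vocabulary(splits$train, top_k = config$vocab$top_k)
    write_vocabulary(vocab, file.path(output_dir, "vocabulary.tsv"))
    for (nm in names(splits)) {
      write_corpus(splits[[nm]], file.path(output_dir, sprintf("%s.jsonl", nm)))
    }
    list(enc = lapply(splits, encode_corpus, vocab = vocab), vocab = vocab)
  })

  batchsets <- stage("make-batches", {
    bs <- build_batchsets(pre$enc$train, config$batching$batch_size,
                          seed = fork_seed(root, "batchsets"))
    for (nm in names(bs)) {
      write_batchset(bs[[nm]], file.path(output_dir,
                                         sprintf("batchset_%s.jsonl", tolower(nm))))
    }
    bs
  })

  difficulty <- stage("diagnose", {
    rep <- difficulty_report(batchsets, pre$enc$train)
    write_difficulty_tsv(rep, file.path(output_dir, "difficulty.tsv"))
    rep
  })

  state <- stage("train", {
    spec <- do.call(model_spec,
                    c(list(vocab_size = pre$vocab$retained_size,
                           n_labels = length(corpus$label_catalog)),
                      config$train$model))
    tc <- train_config(batch_size = config$batching$batch_size,
                       learning_rate = config$train$learning_rate,
                       schedule = build_schedule(config$schedule),
                       seed = fork_seed(root, "train"),
                       prediction_threshold = config$train$prediction_threshold)
    st <- train_classifier(pre$enc$train, batchsets, spec, tc,
                           val_data = pre$enc$val)
    write_loss_history_tsv(st, file.path(output_dir, "loss_history.tsv"))
    st
  })

  eval_out <- stage("evaluate", {
    scores <- predict_scores(state, pre$enc$test)
    pred <- predict_labels(scores, config$train$prediction_threshold)
    report <- micro_macro_report(pred, pre$enc$test$label_matrix)
    lt <- longtail_metrics(pred, pre$enc$test$label_matrix,
                           label_frequencies(pre$enc$train),
                           gamma = config$longtail$gamma)
    write_metrics_tsv(report, file.path(output_dir, "metrics.tsv"),
                      run = config$schedule, longtail = lt)
    list(report = report, longtail = lt)
  })

  manifest <- stage("manifest", {
    files <- sort(setdiff(list.files(output_dir), c("manifest.json", "FAILED")))
    man <- list(package = "curribatch",
                version = as.character(utils::packageVersion("curribatch")),
                seed = root,
                config = config,
                corpus_id = corpus_id(corpus),
                files = as.list(tools::md5sum(file.path(output_dir, files))))
    names(man$files) <- files
    jsonlite::write_json(man, file.path(output_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    man
  })

  invisible(list(state = state, report = eval_out$report,
                 longtail = eval_out$longtail,
                 difficulty = difficulty, manifest = manifest))
}

#' Compare completed runs side by side
#'
#' Aligns the metric rows of two or more run directories produced by
#' [run_experiment()] on the same corpus (verified by checksum), e.g. a
#' plain-shuffle baseline against the full curriculum, or the ablation
#' trio, and appends the across-run mean.
#'
#' @param run_dirs Character vector of at least two run directories.
#' @return A data.frame: one row per run (columns `dir`, `run` =
#'   schedule, the metric columns) plus a final `mean` row.
#' @export
compare_runs <- function(run_dirs) {
  if (length(run_dirs) < 2L) stop("need at least two runs to compare", call. = FALSE)
  mans <- lapply(run_dirs, function(d) {
    jsonlite::fromJSON(file.path(d, "manifest.json"), simplifyVector = TRUE)
  })
  corpora <- vapply(mans, function(m) m$files[["corpus.jsonl"]], "")
  if (length(unique(corpora)) != 1L) {
    stop("runs were not produced on the same corpus", call. = FALSE)
  }
  rows <- lapply(seq_along(run_dirs), function(i) {
    df <- utils::read.table(file.path(run_dirs[i], "metrics.tsv"),
                            sep = "\t", header = TRUE)
    cbind(dir = run_dirs[i], df)
  })
  out <- do.call(rbind, rows)
  num <- vapply(out, is.numeric, TRUE)
  mean_row <- out[1, ]
  mean_row$dir <- "(mean)"
  mean_row$run <- "(mean)"
  mean_row[num] <- lapply(out[num], mean)
  rbind(out, mean_row)
}
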