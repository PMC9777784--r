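tiny_spec <- function() {
  model_spec(vocab_size = 10, n_labels = 5, embedding_dim = 4,
             filter_widths = c(2, 3), n_filters = 2, max_doc_len = 6)
}

test_that("initialization is seeded and the parameter count is exact", {
  spec <- tiny_spec()
  # hand count: embedding (10+2)*4 = 48; conv (2*4*2+2)+(3*4*2+2) = 44;
  # output 2*2*5+5 = 25
  expect_equal(n_params(spec), 48 + 44 + 25)
  p1 <- init_params(spec, seed = 3)
  expect_equal(sum(vapply(p1, length, 0L)), n_params(spec))
  expect_identical(p1, init_params(spec, seed = 3))
  expect_false(identical(p1, init_params(spec, seed = 4)))
  expect_true(all(unlist(p1) >= -0.05 & unlist(p1) <= 0.05))
  expect_equal(unname(p1$emb[1, ]), rep(0, 4)) # padding row
})

test_that("binary cross-entropy matches hand-computed values", {
  expect_equal(bce_loss(0, 1), log(2), tolerance = 1e-12)
  expect_lt(bce_loss(20, 1), 1e-8)
  logits <- rbind(c(0, 2), c(-1, 1))
  targets <- rbind(c(1, 0), c(0, 1))
  # direct (unstable) formula as the scalar-arithmetic oracle
  sig <- 1 / (1 + exp(-logits))
  direct <- -mean(targets * log(sig) + (1 - targets) * log(1 - sig))
  expect_equal(bce_loss(logits, targets), direct, tolerance = 1e-12)
  expect_error(bce_loss(matrix(0, 2, 2), matrix(0, 2, 3)), "shape")
  expect_error(bce_loss(0, 0.5), "0/1")
})

test_that("analytic gradients agree with finite differences", {
  spec <- tiny_spec()
  params <- init_params(spec, seed = 7)
  set.seed(8)
  ids <- matrix(sample(0:11, 18, replace = TRUE), nrow = 3) # 3 docs, T = 6
  Y <- matrix(rbinom(15, 1, 0.4), nrow = 3)
  loss_at <- function(pp) {
    x <- curribatch:::cnn_forward(pp, spec, ids)$logits
    mean(pmax(x, 0) - x * Y + log1p(exp(-abs(x))))
  }
  fwd <- curribatch:::cnn_forward(params, spec, ids, keep_cache = TRUE)
  sig <- 1 / (1 + exp(-fwd$logits))
  grads <- curribatch:::cnn_backward(params, spec, fwd,
                                     (sig - Y) / (nrow(Y) * spec$n_labels))
  eps <- 1e-6
  set.seed(9)
  for (nm in names(grads)) {
    coords <- sample(length(params[[nm]]), min(6, length(params[[nm]])))
    for (k in coords) {
      up <- params; up[[nm]][k] <- up[[nm]][k] + eps
      dn <- params; dn[[nm]][k] <- dn[[nm]][k] - eps
      num <- (loss_at(up) - loss_at(dn)) / (2 * eps)
      expect_equal(grads[[nm]][k], num, tolerance = 1e-4,
                   label = sprintf("grad %s[%d]", nm, k))
    }
  }
})

test_that("prediction applies the >= threshold and is monotone", {
  spec <- tiny_spec()
  params <- init_params(spec, seed = 1)
  # all-zero parameters give sigmoid(0) = 0.5 everywhere
  zero <- lapply(params, function(p) p * 0)
  attr(zero, "spec") <- spec
  enc <- structure(list(doc_ids = c("a", "b"),
                        token_ids = list(c(1L, 2L), c(3L, 4L, 5L)),
                        label_matrix = matrix(0L, 2, 5),
                        label_catalog = paste0("l", 1:5)),
                   class = "encoded_corpus")
  sc <- predict_scores(zero, enc, spec)
  expect_true(all(sc == 0.5))
  expect_true(all(predict_labels(sc, 0.5) == 1L)) # boundary is positive
  sc2 <- predict_scores(params, enc, spec)
  n_pos <- vapply(c(0.3, 0.5, 0.7), function(th) sum(predict_labels(sc2, th)), 0)
  expect_true(all(diff(n_pos) <= 0))
  expect_error(predict_labels(sc2, 0), "threshold")
  bad <- structure(list(doc_ids = "a", token_ids = list(1L),
                        label_matrix = matrix(0L, 1, 3),
                        label_catalog = paste0("l", 1:3)),
                   class = "encoded_corpus")
  expect_error(predict_scores(params, bad, spec), "output dimension")
})

make_training_fixture <- function(seed = 17) {
  cfg <- synth_config(n_examples = 120, n_labels = 6,
                      mean_labels_per_example = 1, max_labels_per_example = 2,
                      vocab_size = 60, doc_length_range = c(8, 14),
                      signal_strength = 1, seed = seed)
  corp <- generate_corpus(cfg)
  vocab <- build_vocabulary(corp, top_k = 60)
  enc <- encode_corpus(corp, vocab)
  spec <- model_spec(vocab$retained_size, 6, embedding_dim = 8,
                     n_filters = 4, max_doc_len = 14)
  list(enc = enc, spec = spec, bs = build_batchsets(enc, 30, seed = seed))
}

test_that("a zero-epoch run returns the initial parameters untouched", {
  fx <- make_training_fixture()
  cfg <- train_config(30, schedule = NULL, seed = 5)
  st <- train_classifier(fx$enc, fx$bs, fx$spec, cfg)
  expect_identical(st$params, init_params(fx$spec, 5))
  expect_equal(nrow(st$loss_history), 0)
})

test_that("training reduces the loss on a separable corpus and is seeded", {
  fx <- make_training_fixture()
  cfg <- train_config(30, schedule = build_schedule("sdd:4"), seed = 5)
  st <- train_classifier(fx$enc, fx$bs, fx$spec, cfg)
  expect_equal(nrow(st$loss_history), 4)
  expect_true(all(is.finite(st$loss_history$mean_loss)))
  expect_lt(st$loss_history$mean_loss[4], st$loss_history$mean_loss[1])
  st2 <- train_classifier(fx$enc, fx$bs, fx$spec, cfg)
  expect_identical(st$loss_history, st2$loss_history)
  expect_identical(st$params, st2$params)
  cfg2 <- train_config(30, schedule = build_schedule("sdd:4"), seed = 6)
  st3 <- train_classifier(fx$enc, fx$bs, fx$spec, cfg2)
  expect_false(identical(st$loss_history$mean_loss, st3$loss_history$mean_loss))
})

test_that("the schedule's phases are recorded and missing kinds error", {
  fx <- make_training_fixture()
  cfg <- train_config(30, schedule = build_schedule("udd:1,sdd:1,idd:1"),
                      seed = 2)
  st <- train_classifier(fx$enc, fx$bs, fx$spec, cfg)
  expect_equal(st$loss_history$phase, c("UDD", "SDD", "IDD"))
  expect_equal(st$switch_epochs, c(1, 2))
  expect_error(train_classifier(fx$enc, fx$bs["SDD"], fx$spec, cfg),
               "batch set")
})

test_that("validation tracking selects the best epoch by micro-F1", {
  fx <- make_training_fixture()
  val <- make_training_fixture(seed = 18)$enc
  cfg <- train_config(30, schedule = build_schedule("sdd:3"), seed = 2)
  st <- train_classifier(fx$enc, fx$bs, fx$spec, cfg, val_data = val)
  expect_length(st$val_history, 3)
  expect_equal(st$best_epoch, which.max(st$val_history) - 1L)
})
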