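test_that("cleaning removes punctuation, numbers and stopwords", {
  expect_identical(clean_and_tokenize("", c("a")), character(0))
  expect_identical(clean_and_tokenize("chest pain, 2 days", stopwords = "days"),
                   c("chest", "pain"))
  expect_identical(clean_and_tokenize("12, 34 ... 5!"), character(0))
  expect_identical(clean_and_tokenize("Chest PAIN"), c("chest", "pain"))
  # digit/punctuation mixes reduce to digits and are dropped; mixed
  # alphanumerics are kept
  expect_identical(clean_and_tokenize("2.5 10mg", stopwords = character(0)),
                   "10mg")
})

test_that("cleaning is idempotent", {
  texts <- c("Pt c/o chest pain, 2 days; EKG wnl.",
             "Hx: DM2, HTN -- 40% EF?!",
             "afebrile,   stable")
  for (tx in texts) {
    once <- clean_and_tokenize(tx)
    twice <- clean_and_tokenize(paste(once, collapse = " "))
    expect_identical(twice, once)
  }
})

test_that("vocabulary ranking matches a hand-computed TF-IDF oracle", {
  corp <- labeled_corpus(list(
    list(doc_id = "d1", tokens = c("a", "a", "b", "c"), labels = "l1"),
    list(doc_id = "d2", tokens = c("b", "d", "d", "d"), labels = "l2")
  ))
  # by hand (N = 2, natural log):
  #  a: tf 2, df 1 -> 2*log(2) = 1.386
  #  b: tf 2, df 2 -> 2*log(1) = 0
  #  c: tf 1, df 1 -> log(2)   = 0.693
  #  d: tf 3, df 1 -> 3*log(2) = 2.079
  vocab <- build_vocabulary(corp, top_k = 10)
  expect_identical(vocab$tokens, c("d", "a", "c", "b"))
  expect_equal(unname(vocab$scores), c(3, 2, 1, 0) * log(2) * c(1, 1, 1, 0),
               tolerance = 1e-12)
  expect_equal(vocab$retained_size, 4)
  expect_equal(vocab$unk_id, 5)
  # a token present in every document scores 0 and ranks last
  expect_identical(vocab$tokens[4], "b")
  # truncation keeps the top scorers
  expect_identical(build_vocabulary(corp, top_k = 2)$tokens, c("d", "a"))
  expect_error(build_vocabulary(corp, top_k = 0), "top_k")
})

test_that("vocabulary ranking is invariant to document order", {
  corp <- generate_corpus(synth_config(n_examples = 40, n_labels = 5,
                                       vocab_size = 60,
                                       doc_length_range = c(5, 15), seed = 8))
  rev_corp <- labeled_corpus(rev(corp$examples), corp$label_catalog,
                             corp$vocabulary)
  expect_identical(build_vocabulary(corp, 30)$tokens,
                   build_vocabulary(rev_corp, 30)$tokens)
})

test_that("splits are seeded partitions with floor-rounded shares", {
  corp <- generate_corpus(synth_config(n_examples = 10, n_labels = 3,
                                       vocab_size = 20,
                                       doc_length_range = c(2, 4), seed = 1))
  sp <- split_corpus(corp, c(0.7, 0.1, 0.2), seed = 4)
  expect_equal(vapply(sp, function(s) length(s$examples), 0L),
               c(train = 7L, val = 1L, test = 2L))
  ids <- lapply(sp, function(s) vapply(s$examples, `[[`, "", "doc_id"))
  expect_setequal(unlist(ids), vapply(corp$examples, `[[`, "", "doc_id"))
  expect_length(intersect(ids$train, ids$val), 0)
  expect_length(intersect(ids$train, ids$test), 0)
  expect_identical(split_corpus(corp, c(0.7, 0.1, 0.2), seed = 4), sp)
  expect_false(identical(split_corpus(corp, c(0.7, 0.1, 0.2), seed = 5), sp))
  # sizes always sum to n for awkward ratios and sizes
  for (n in c(3, 5, 23)) {
    cc <- generate_corpus(synth_config(n_examples = n, n_labels = 3,
                                       vocab_size = 20,
                                       doc_length_range = c(2, 3), seed = n))
    ss <- split_corpus(cc, c(0.5, 0.25, 0.25), seed = 1)
    expect_equal(sum(vapply(ss, function(s) length(s$examples), 0L)), n)
  }
  expect_error(split_corpus(corp, c(0.5, 0.5, 0.5)), "summing to 1")
  expect_error(split_corpus(labeled_corpus(corp$examples[1:2])), "at least 3")
})

test_that("encoding produces multi-hot labels and maps unknown tokens", {
  corp <- labeled_corpus(list(
    list(doc_id = "d1", tokens = c("x", "zzz"), labels = "l3"),
    list(doc_id = "d2", tokens = c("x", "y"), labels = c("l1", "l3"))
  ), label_catalog = c("l1", "l2", "l3"))
  vocab <- build_vocabulary(labeled_corpus(list(
    list(doc_id = "v1", tokens = c("x", "y"), labels = "l1"))), top_k = 5)
  enc <- encode_corpus(corp, vocab)
  expect_equal(unname(enc$label_matrix["d1", ]), c(0L, 0L, 1L))
  expect_equal(unname(enc$label_matrix["d2", ]), c(1L, 0L, 1L))
  expect_true(vocab$unk_id %in% enc$token_ids[[1]])   # zzz -> unknown id
  expect_false(vocab$unk_id %in% enc$token_ids[[2]])  # all in vocab
  # vocabulary TSV round-trip preserves the id map
  path <- withr::local_tempfile(fileext = ".tsv")
  write_vocabulary(vocab, path)
  back <- read_vocabulary(path)
  expect_identical(back$ids, vocab$ids)
})
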