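test_that("label distribution counts each example's labels once", {
  corp <- labeled_corpus(list(
    list(doc_id = "d1", tokens = "t", labels = "a"),
    list(doc_id = "d2", tokens = "t", labels = c("a", "b"))
  ))
  p <- label_distribution(corp)
  expect_equal(unname(p), c(2 / 3, 1 / 3))
  expect_equal(sum(p), 1)
  one <- labeled_corpus(list(list(doc_id = "d", tokens = "t", labels = "a")))
  expect_equal(unname(label_distribution(one)), 1)
  # zero probability for catalog labels never observed
  p2 <- label_distribution(corp, label_catalog = c("a", "b", "c"))
  expect_equal(unname(p2["c"]), 0)
})

test_that("shuffle batching is a seeded permutation partition", {
  corp <- generate_corpus(synth_config(n_examples = 10, n_labels = 3,
                                       vocab_size = 20,
                                       doc_length_range = c(2, 3), seed = 1))
  bs <- shuffle_batchset(corp, M = 3, seed = 2)
  expect_equal(bs$kind, "SDD")
  expect_equal(lengths(bs$batches), c(3L, 3L, 3L, 1L))
  expect_setequal(unlist(bs$batches), vapply(corp$examples, `[[`, "", "doc_id"))
  expect_identical(shuffle_batchset(corp, 3, seed = 2)$batches, bs$batches)
  expect_false(identical(shuffle_batchset(corp, 3, seed = 3)$batches, bs$batches))
  # K = ceiling(n / M) across awkward sizes
  for (cf in list(c(386, 10, 39), c(100, 100, 1), c(101, 100, 2))) {
    cc <- single_label_corpus(cf[1], c("a", "b"), seed = cf[1])
    expect_length(shuffle_batchset(cc, cf[2], seed = 1)$batches, cf[3])
  }
  expect_warning(big <- shuffle_batchset(corp, 99, seed = 1), "exceeds")
  expect_equal(lengths(big$batches), 10L)
})

test_that("stratified sampling draws labels uniformly", {
  corp <- single_label_corpus(200, c("a", "b", "c", "d"), seed = 3)
  bs <- ssr_batchset(corp, M = 100, N = 100, seed = 11)
  expect_equal(bs$kind, "UDD")
  expect_length(bs$batches, 100)
  expect_true(all(lengths(bs$batches) == 100))
  draws <- table(factor(unlist(bs$drawn_labels), levels = c("a", "b", "c", "d")))
  expect_true(multinomial_within_3sigma(as.numeric(draws), rep(0.25, 4)))
  # every drawn example's label set contains the drawn label
  sets <- lapply(corp$examples, `[[`, "labels")
  names(sets) <- vapply(corp$examples, `[[`, "", "doc_id")
  for (b in 1:5) {
    ok <- mapply(function(did, l) l %in% sets[[did]],
                 bs$batches[[b]], bs$drawn_labels[[b]])
    expect_true(all(ok))
  }
})

test_that("single-stratum SSR reduces to draws from the whole corpus", {
  corp <- labeled_corpus(lapply(1:7, function(i) {
    list(doc_id = sprintf("d%d", i), tokens = "t", labels = "only")
  }))
  bs <- ssr_batchset(corp, M = 4, seed = 5)
  expect_length(bs$batches, ceiling(7 / 4))
  expect_true(all(unlist(bs$batches) %in% sprintf("d%d", 1:7)))
  expect_true(all(unlist(bs$drawn_labels) == "only"))
})

test_that("probability sampling follows the empirical label distribution", {
  # two labels with a 0.9 / 0.1 split, one batch of 1000 draws
  labs <- c(rep("h", 900), rep("t", 100))
  corp <- labeled_corpus(lapply(seq_along(labs), function(i) {
    list(doc_id = sprintf("d%04d", i), tokens = "t", labels = labs[i])
  }))
  bs <- psr_batchset(corp, M = 1000, N_prime = 1, seed = 7)
  expect_equal(bs$kind, "IDD")
  n_h <- sum(unlist(bs$drawn_labels) == "h")
  expect_lt(abs(n_h - 900), 3 * sqrt(1000 * 0.9 * 0.1))
  # draw frequencies over a larger batch set converge to the corpus
  # distribution on a skewed catalog
  corp2 <- single_label_corpus(500, letters[1:10], seed = 9)
  q <- label_distribution(corp2)
  bs2 <- psr_batchset(corp2, M = 100, N_prime = 200, seed = 13)
  draws <- table(factor(unlist(bs2$drawn_labels), levels = names(q)))
  expect_true(multinomial_within_3sigma(as.numeric(draws), unname(q)))
})

test_that("samplers are reproducible and validate inputs", {
  corp <- generate_corpus(synth_config(n_examples = 50, n_labels = 8,
                                       vocab_size = 40,
                                       doc_length_range = c(2, 4), seed = 2))
  expect_identical(ssr_batchset(corp, 10, seed = 21)$batches,
                   ssr_batchset(corp, 10, seed = 21)$batches)
  expect_identical(psr_batchset(corp, 10, seed = 21)$batches,
                   psr_batchset(corp, 10, seed = 21)$batches)
  # UDD and IDD use different forked streams from the same root seed
  expect_false(identical(ssr_batchset(corp, 10, seed = 21)$batches,
                         psr_batchset(corp, 10, seed = 21)$batches))
  expect_error(ssr_batchset(corp, 0), "M")
  # batch-set JSONL round-trip
  bs <- ssr_batchset(corp, 10, seed = 21)
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_batchset(bs, path)
  back <- read_batchset(path)
  expect_identical(back$batches, bs$batches)
  expect_equal(back$kind, "UDD")
})

test_that("curriculum schedules map epochs to phases", {
  sch <- build_schedule()
  expect_equal(total_epochs(sch), 150)
  expect_equal(batchset_for_epoch(sch, 0), "UDD")
  expect_equal(batchset_for_epoch(sch, 49), "UDD")
  expect_equal(batchset_for_epoch(sch, 50), "SDD")
  expect_equal(batchset_for_epoch(sch, 100), "IDD")
  expect_equal(batchset_for_epoch(sch, 149), "IDD")
  expect_equal(phase_switch_epochs(sch), c(50, 100))
  expect_error(batchset_for_epoch(sch, 150), "epoch")
  expect_error(batchset_for_epoch(sch, -1), "epoch")

  base <- build_schedule("sdd:150")
  expect_equal(total_epochs(base), 150)
  expect_equal(unique(base$kind), "SDD")
  expect_equal(phase_switch_epochs(base), integer(0))

  abl <- build_schedule(list(list("UDD", 50), list("SDD", 100)))
  expect_equal(abl$kind, c("UDD", "SDD"))
  expect_error(build_schedule(list()), "at least one phase")
  expect_error(build_schedule("udd:0"), "epoch counts")
  expect_error(build_schedule("xdd:5"), "kinds")
})
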