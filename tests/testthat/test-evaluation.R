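mk_doc <- function(id, tags) sig_document(id, strrep("x", 60), tags)
mk_tag <- function(label, s, e) tag_instance(label, s, e)

test_that("exact span/label scoring counts matches, misses and spurious tags", {
  ref <- list(mk_doc("a", list(mk_tag("TAKE", 0, 2), mk_tag("FREQ", 5, 9))))
  hyp_same <- ref
  rep <- score_spans(ref, hyp_same)
  expect_equal(rep$overall$f, 1.0)
  expect_true(all(rep$per_label$f == 1.0))

  hyp_empty <- list(mk_doc("a", list()))
  rep <- score_spans(ref, hyp_empty)
  expect_equal(rep$overall$precision, 1.0)  # nothing spurious
  expect_equal(rep$overall$recall, 0.0)
  expect_equal(rep$overall$f, 0.0)

  hyp_half <- list(mk_doc("a", list(mk_tag("TAKE", 0, 2),
                                    mk_tag("ROUTE", 20, 24))))
  rep <- score_spans(ref, hyp_half)
  expect_equal(rep$overall$precision, 0.5)
  expect_equal(rep$overall$recall, 0.5)
  expect_equal(rep$overall$f, 0.5)

  # same span, wrong label is both a miss and a false alarm
  hyp_lab <- list(mk_doc("a", list(mk_tag("DISPENSE", 0, 2),
                                   mk_tag("FREQ", 5, 9))))
  rep <- score_spans(ref, hyp_lab)
  expect_equal(rep$overall$tp, 1)
  expect_equal(rep$overall$fp, 1)
  expect_equal(rep$overall$fn, 1)

  expect_error(score_spans(ref, list(mk_doc("b", list()))), "doc_id")
})

test_that("micro counts tie out to the tag totals", {
  gen <- generate_corpus(generator_config(n_documents = 50, seed = 3))
  m <- train_tagger(gen$documents[1:40], epochs = 5)
  hyp <- tag_corpus(m, gen$documents[41:50])
  ref <- gen$documents[41:50]
  rep <- score_spans(ref, hyp)
  expect_equal(rep$overall$tp + rep$overall$fn,
               sum(vapply(ref, function(d) length(d$tags), integer(1))))
  expect_equal(rep$overall$tp + rep$overall$fp,
               sum(vapply(hyp, function(d) length(d$tags), integer(1))))
})

test_that("pairwise agreement is 1 on itself, 0 on disjoint sets, and F-symmetric", {
  a <- list(mk_doc("a", list(mk_tag("TAKE", 0, 2), mk_tag("FREQ", 5, 9))),
            mk_doc("b", list(mk_tag("ROUTE", 3, 7))))
  expect_equal(pairwise_agreement(a, a)$overall$f, 1.0)

  b_disjoint <- list(mk_doc("a", list(mk_tag("TAKE", 10, 12))),
                     mk_doc("b", list()))
  expect_equal(pairwise_agreement(a, b_disjoint)$overall$f, 0.0)

  set.seed(8)
  for (k in 1:5) {
    gen <- generate_corpus(generator_config(n_documents = 15, seed = 60 + k))
    drop_some <- lapply(gen$documents, function(d) {
      keep <- runif(length(d$tags)) < 0.7
      d$tags <- d$tags[keep]
      d
    })
    ab <- pairwise_agreement(gen$documents, drop_some)
    ba <- pairwise_agreement(drop_some, gen$documents)
    expect_equal(ab$overall$f, ba$overall$f)
    expect_equal(ab$overall$precision, ba$overall$recall)
  }
})

test_that("self-agreement is perfect for every label present", {
  gen <- generate_corpus(generator_config(n_documents = 40, seed = 19))
  rep <- pairwise_agreement(gen$documents, gen$documents)
  expect_true(all(rep$per_label$f == 1.0))
  expect_equal(rep$overall$f, 1.0)
})

test_that("attribute accuracy counts only non-null gold values on gold spans", {
  gold <- list(sig_document("g", "take 2 tablets weekly", list(
    tag_instance("TAKE", 5, 6, list(amount = 2)),
    tag_instance("FREQ", 15, 21,
                 list(times_per = 1, every = 1, unit = "week")))))
  pred_same <- gold
  rep <- attribute_accuracy(gold, pred_same)
  expect_true(all(rep$accuracy == 1.0))
  # to_times_per is all-null in gold, hence absent from the report
  expect_false("to_times_per" %in% rep$attribute)

  pred_wrong <- gold
  pred_wrong[[1]]$tags[[2]]$attributes$unit <- "day"
  rep <- attribute_accuracy(gold, pred_wrong)
  expect_equal(rep$accuracy[rep$attribute == "unit"], 0.0)

  # 7:3 majority baseline scores exactly 0.7
  gold10 <- list(sig_document("m", strrep("u ", 40), lapply(0:9, function(i)
    tag_instance("DURATION_UNIT", i * 2, i * 2 + 1,
                 list(unit = if (i < 7) "day" else "week")))))
  pred10 <- gold10
  for (i in 1:10) pred10[[1]]$tags[[i]]$attributes$unit <- "day"
  rep <- attribute_accuracy(gold10, pred10)
  expect_equal(rep$accuracy, 0.7)

  stray <- gold
  stray[[1]]$tags[[1]]$start <- 0
  expect_error(attribute_accuracy(gold, stray), "absent from gold")
})

test_that("corpus splitting is deterministic, disjoint and exhaustive", {
  corpus <- as.list(letters[1:10])
  sp <- split_corpus(corpus, 0.8, seed = 5)
  expect_length(sp$train, 8)
  expect_length(sp$test, 2)
  expect_setequal(c(unlist(sp$train), unlist(sp$test)), letters[1:10])
  expect_identical(split_corpus(corpus, 0.8, seed = 5), sp)
  expect_false(identical(split_corpus(corpus, 0.8, seed = 6), sp))

  big <- as.list(seq_len(1746))
  sp <- split_corpus(big, 0.8, seed = 1)
  expect_length(sp$train, 1397)
  expect_length(sp$test, 349)
  expect_error(split_corpus(list(), 0.8, 1), "empty")
})
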