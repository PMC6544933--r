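test_that("generation is deterministic given the seed", {
  a <- generate_corpus(generator_config(n_documents = 5, seed = 17))
  b <- generate_corpus(generator_config(n_documents = 5, seed = 17))
  expect_identical(lapply(a$documents, rxsig:::doc_to_list),
                   lapply(b$documents, rxsig:::doc_to_list))
  expect_identical(a$records, b$records)
  c_ <- generate_corpus(generator_config(n_documents = 5, seed = 18))
  expect_false(identical(lapply(a$documents, rxsig:::doc_to_list),
                         lapply(c_$documents, rxsig:::doc_to_list)))
})

test_that("every generated document validates with zero violations", {
  sc <- sig_schema()
  gen <- generate_corpus(generator_config(
    n_documents = 80, seed = 21,
    noise = list(misspell_prob = 0.1, abbrev_prob = 0.5,
                 number_word_prob = 0.5)))
  for (doc in gen$documents) {
    rep <- validate_document(doc, sc)
    expect_equal(nrow(rep$violations), 0, info = doc$doc_id)
    expect_equal(doc$source, "synthetic")
  }
})

test_that("empirical tag counts track the configured frequency profile", {
  cfg <- generator_config(n_documents = 2000, seed = 17)
  gen <- generate_corpus(cfg)
  counts <- table(unlist(lapply(gen$documents, function(d)
    vapply(d$tags, `[[`, character(1), "label"))))
  expected <- expected_tag_counts(cfg)
  observed <- vapply(names(expected), function(l)
    if (l %in% names(counts)) as.numeric(counts[[l]]) else 0, numeric(1))
  # goodness of fit over all non-tiny cells (binomial variance < Poisson,
  # so the chi-square reference is conservative)
  big <- expected >= 20
  x2 <- sum((observed[big] - expected[big])^2 / expected[big])
  expect_gt(stats::pchisq(x2, df = sum(big), lower.tail = FALSE), 1e-3)
  # hard +/-20% band where it is wide relative to sampling noise
  for (label in names(expected)[expected >= 200]) {
    expect_gt(observed[[label]], 0.8 * expected[[label]],
              label = paste(label, "count"))
    expect_lt(observed[[label]], 1.2 * expected[[label]],
              label = paste(label, "count"))
  }
  # the catch-all INSTRUCTION dominates; FREQ and TIMING lead the rest
  ord <- sort(counts, decreasing = TRUE)
  expect_equal(names(ord)[1], "INSTRUCTION")
  expect_setequal(names(ord)[2:3], c("FREQ", "TIMING"))
})

test_that("rare labels are represented so low-frequency tags stay trainable", {
  gen <- generate_corpus(generator_config(n_documents = 2000, seed = 17))
  labels <- unique(unlist(lapply(gen$documents, function(d)
    vapply(d$tags, `[[`, character(1), "label"))))
  expect_setequal(labels, names(sig_schema()$labels))
})

test_that("gold FREQ attributes are recoverable from the other half of the corpus", {
  gen <- generate_corpus(generator_config(n_documents = 400, seed = 17))
  sp <- split_corpus(gen$documents, 0.5, seed = 17)
  harvest <- function(docs) {
    ctxs <- list(); maps <- list()
    for (doc in docs) for (t in doc$tags) if (t$label == "FREQ") {
      ctxs[[length(ctxs) + 1L]] <- span_context(doc$text, t$start, t$end)
      maps[[length(maps) + 1L]] <- t$attributes
    }
    list(ctxs = ctxs, maps = maps)
  }
  tr <- harvest(sp$train); te <- harvest(sp$test)
  model <- fit_freq_normalizer(tr$ctxs, tr$maps, method = "hybrid", seed = 1)
  pred_units <- vapply(te$ctxs, function(cx)
    normalize_freq(cx, model)$unit %||% "<none>", character(1))
  gold_units <- vapply(te$maps, `[[`, character(1), "unit")
  expect_gte(mean(pred_units == gold_units), 0.95)
})

test_that("noise switches behave as configured", {
  clean <- generate_corpus(generator_config(
    n_documents = 60, seed = 9,
    noise = list(misspell_prob = 0, abbrev_prob = 0, number_word_prob = 0)))
  txt <- vapply(clean$documents, `[[`, character(1), "text")
  # digits only: no number words appear
  expect_false(any(grepl("\\b(one|two|three|four|five|twice)\\b", txt)))
  # no clinical abbreviations
  expect_false(any(grepl("b\\.i\\.d|t\\.i\\.d|q\\.d|\\bprn\\b", txt)))
  # misspell-free: every DOSEFORM surface folds to its gold value
  for (doc in clean$documents) for (t in doc$tags)
    if (t$label == "DOSEFORM") {
      surf <- substr(doc$text, t$start + 1, t$end)
      expect_equal(rxsig:::fold_unit(surf), t$attributes$form)
    }
})

test_that("discrepancy-free corpora produce agreeing record pairs", {
  gen <- generate_corpus(generator_config(n_documents = 50, seed = 33,
                                          discrepancy_rate = 0))
  expect_equal(nrow(gen$perturbations), 0)
  res <- compare_records(gen$records, gen$documents)
  expect_equal(nrow(res$findings), 0)
})
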