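test_that("edit distance matches the recursive oracle", {
  expect_equal(edit_distance("a", "a"), 0L)
  expect_equal(edit_distance("kitten", "sitting"), 3L)
  expect_equal(edit_distance("", "abc"), 3L)

  alphabet <- c("a", "b", "e", "l", "t")
  short <- strings_up_to(alphabet, 3)           # exhaustive, lengths 0-3
  pairs <- expand.grid(a = short, b = short, stringsAsFactors = FALSE)
  got <- as.integer(utils::adist(short, short))
  want <- mapply(oracle_lev, pairs$a, pairs$b)
  expect_equal(got, as.integer(want))

  long <- strings_up_to(alphabet, 6)            # seeded sample, lengths 0-6
  set.seed(99)
  ia <- sample(long, 400, replace = TRUE)
  ib <- sample(long, 400, replace = TRUE)
  expect_equal(edit_distance(ia, ib),
               as.integer(mapply(oracle_lev, ia, ib)))
})

test_that("snap returns the nearest valid numeric value, ties to the smaller", {
  for (v in c(0, 0.4, 1, 7.2, 13, 13.5, 14, 20, 22.5, 37.5, 52.5, 100)) {
    s <- snap_valid_numeric(v)
    allowed <- c(1:12, 15, 30, 45, 60)
    expect_true(s %in% allowed)
    expect_true(all(abs(s - v) <= abs(allowed - v)))
  }
  expect_equal(snap_valid_numeric(13.5), 12)   # equidistant: smaller wins
  expect_equal(snap_valid_numeric(37.5), 30)
})

test_that("baseline predictor is the training majority and needs data", {
  p <- fit_attribute_predictor(c("x", "x", "x", "y", "y", "z", "w"),
                               c("day", "day", "day", "day", "day",
                                 "hour", "hour"), method = "baseline")
  expect_equal(unname(predict(p, "anything")), "day")
  p1 <- fit_attribute_predictor("s", "mg", method = "baseline")
  expect_equal(unname(predict(p1, "q")), "mg")
  expect_error(fit_attribute_predictor(character(), character(),
                                       method = "baseline"), "no non-null")
})

test_that("literal match looks up, falls back to allowed values, then majority", {
  p <- fit_attribute_predictor(
    c("tabs", "tabs", "tabs", "caps"),
    c("tablet", "tablet", "tablet", "capsule"),
    method = "literal",
    allowed_values = c("tablet", "capsule", "week"))
  expect_equal(unname(predict(p, "tabs")), "tablet")
  expect_equal(unname(predict(p, "TABS")), "tablet")      # case-folded key
  expect_equal(unname(predict(p, "week")), "week")        # allowed-value hit
  expect_equal(unname(predict(p, "zzz")), "tablet")       # double miss
})

test_that("levenshtein fallback agrees with literal on seen spans and resolves near misses", {
  spans <- c("tabs", "tabs", "caps")
  vals <- c("tablet", "tablet", "capsule")
  lit <- fit_attribute_predictor(spans, vals, method = "literal",
                                 allowed_values = c("tablet", "capsule"))
  lev <- fit_attribute_predictor(spans, vals, method = "levenshtein",
                                 allowed_values = c("tablet", "capsule"))
  for (s in spans) expect_equal(predict(lev, s), predict(lit, s))
  expect_equal(unname(predict(lev, "tablts")), "tablet")
  # equidistant between equal-frequency values -> lexicographically smaller
  tie <- fit_attribute_predictor(c("aa", "bb"), c("abx", "aby"),
                                 method = "levenshtein",
                                 allowed_values = c("abx", "aby"))
  expect_equal(unname(predict(tie, "ab")), "abx")
})

test_that("maxent classifier separates simple classes and degrades gracefully", {
  spans <- c("every 2 hours", "after 3 hours", "2 times daily",
             "3 times weekly", "hours apart", "daily dose")
  vals <- c("hour", "hour", "day", "week", "hour", "day")
  p <- fit_attribute_predictor(spans, vals, method = "classifier", seed = 4)
  expect_equal(unname(predict(p, spans)), vals)   # linearly separable

  single <- fit_attribute_predictor(c("a", "b"), c("mg", "mg"),
                                    method = "classifier")
  expect_equal(unname(predict(single, "anything")), "mg")

  refill <- fit_attribute_predictor(c("no refills", "refill ok"),
                                    c(FALSE, TRUE), method = "classifier",
                                    seed = 4)
  expect_identical(unname(predict(refill, c("no refills", "refill ok"))),
                   c(FALSE, TRUE))
})

test_that("FREQ normalization distinguishes counts from intervals and fills ranges", {
  m <- normalize_freq("2-3 times per day")
  expect_equal(m$times_per, 2)
  expect_equal(m$to_times_per, 3)
  expect_equal(m$every, 1)
  expect_null(m$to_every)
  expect_equal(m$unit, "day")

  m <- normalize_freq("every 4-6 hours")
  expect_equal(m$every, 4)
  expect_equal(m$to_every, 6)
  expect_equal(m$times_per, 1)
  expect_equal(m$unit, "hour")

  a <- normalize_freq("every three days")
  b <- normalize_freq("three times per day")
  expect_equal(a$every, 3); expect_equal(a$times_per, 1)
  expect_equal(b$times_per, 3); expect_equal(b$every, 1)
  expect_equal(a$unit, "day"); expect_equal(b$unit, "day")

  # digit-free idioms resolve through the lexicon
  expect_equal(normalize_freq("twice a day")$times_per, 2)
  expect_equal(normalize_freq("once daily")$times_per, 1)
  expect_equal(normalize_freq("b.i.d.")$times_per, 2)
  expect_equal(normalize_freq("t.i.d.")$unit, "day")
  expect_equal(normalize_freq("every other day")$every, 2)
})

test_that("FREQ baseline emits the default numeric values with the majority unit", {
  ctxs <- lapply(c("twice a day", "3 times a day", "every 6 hours"),
                 span_context)
  maps <- list(list(times_per = 2, every = 1, unit = "day"),
               list(times_per = 3, every = 1, unit = "day"),
               list(times_per = 1, every = 6, unit = "hour"))
  base <- fit_freq_normalizer(ctxs, maps, method = "baseline")
  m <- base |> (\(b) normalize_freq("anything at all", b))()
  expect_equal(m$times_per, 1)
  expect_equal(m$every, 1)
  expect_null(m$to_times_per)
  expect_null(m$to_every)
  expect_equal(m$unit, "day")
})

test_that("TIMING normalization maps offsets, direction and event", {
  m <- normalize_timing("1 hour after meals")
  expect_equal(m$offset, 1)
  expect_equal(m$offset_unit, "hour")
  expect_equal(m$direction, "after")
  expect_equal(m$event, "meals")

  m <- normalize_timing("before meals")
  expect_equal(m$direction, "before")
  expect_equal(m$event, "meals")
  expect_null(m$offset)

  m <- normalize_timing("at bedtime")
  expect_equal(m$event, "bedtime")
  expect_null(m$direction)

  expect_equal(normalize_timing("with meals")$direction, "other")
  expect_equal(normalize_timing("30 minutes before breakfast")$offset, 30)
})

test_that("numeric mapping honors the normalized/unnormalized switch", {
  expect_equal(map_numeric("three", "normalized")$value, 3)
  expect_equal(map_numeric("three", "unnormalized")$value, "three")
  rng <- map_numeric("2-3", "normalized")
  expect_equal(rng$value, 2)
  expect_equal(rng$to_value, 3)
  expect_warning(v <- map_numeric("tablets", "normalized"), "no number")
  expect_null(v$value)
})

test_that("every predictor output validates against the schema", {
  sc <- sig_schema()
  gen <- generate_corpus(generator_config(n_documents = 120, seed = 13))
  sp <- split_corpus(gen$documents, 0.5, seed = 1)
  for (method in c("baseline", "literal", "levenshtein", "classifier")) {
    models <- fit_attribute_models(sp$train, sc, choice_method = method,
                                   boolean_method = if (method == "classifier")
                                     "classifier" else "baseline",
                                   seed = 2)
    normed <- lapply(sp$test[1:20], normalize_document, schema = sc,
                     models = models)
    for (doc in normed) {
      rep <- validate_document(doc, sc)
      expect_equal(nrow(rep$violations), 0,
                   info = paste(method, doc$doc_id))
    }
  }
})
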