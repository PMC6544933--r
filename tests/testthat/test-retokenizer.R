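test_that("number expressions map to the expected canonical values", {
  one <- find_number_expressions("take three tablets")
  expect_equal(nrow(one), 1)
  expect_equal(one$value, 3)

  half <- find_number_expressions("one and a half")
  expect_equal(nrow(half), 1)
  expect_equal(half$value, 1.5)
  expect_equal(half$surface, "one and a half")

  expect_equal(nrow(find_number_expressions("")), 0)
  expect_equal(nrow(find_number_expressions("no numbers here at all")), 0)

  rng <- find_number_expressions("2-3 times")
  expect_equal(rng$value, c(2, 3))

  expect_equal(find_number_expressions("2 1/2 tablets")$value, 2.5)
  expect_equal(find_number_expressions("1/2 tablet")$value, 0.5)
  expect_equal(find_number_expressions("1.5 tablets")$value, 1.5)
  expect_equal(find_number_expressions("twenty-one")$value, 21)
  expect_equal(find_number_expressions("a hundred")$value, 100)
  expect_equal(find_number_expressions("two and a quarter")$value, 2.25)

  # surfaces always equal the covered text
  x <- "take two and a half tablets every 4-6 hours"
  ns <- find_number_expressions(x)
  expect_equal(ns$surface, substring(x, ns$start + 1, ns$end))
})

test_that("ordinals carry a value but are flagged and never rewritten", {
  ns <- find_number_expressions("every third day")
  expect_equal(ns$value, 3)
  expect_true(ns$ordinal)
  expect_equal(canonicalize_numbers("every third day")$text,
               "every third day")
})

test_that("word-number parser agrees with the table-driven oracle on 0-100", {
  phrases <- oracle_number_words()
  for (v in 0:100) {
    ns <- find_number_expressions(phrases[v + 1])
    expect_equal(nrow(ns), 1, info = phrases[v + 1])
    expect_equal(ns$value, v, info = phrases[v + 1])
  }
})

test_that("canonicalization rewrites numbers and nothing else", {
  expect_equal(canonicalize_numbers("take three tablets")$text,
               "take 3 tablets")
  expect_equal(canonicalize_numbers("4")$text, "4")
  expect_equal(canonicalize_numbers("one and a half")$text, "1.5")
  expect_equal(canonicalize_numbers("")$text, "")
  expect_equal(canonicalize_numbers("take two to three tablets")$text,
               "take 2 to 3 tablets")
})

test_that("canonicalization is idempotent on generated sigs", {
  gen <- generate_corpus(generator_config(n_documents = 40, seed = 23))
  for (doc in gen$documents) {
    once <- canonicalize_numbers(doc$text)$text
    expect_identical(canonicalize_numbers(once)$text, once)
  }
})

test_that("offset map round trip returns a containing span", {
  gen <- generate_corpus(generator_config(
    n_documents = 30, seed = 41,
    noise = list(number_word_prob = 0.8)))
  for (doc in gen$documents) {
    nt <- canonicalize_numbers(doc$text)
    for (t in doc$tags) {
      m <- span_to_normalized(nt, t$start, t$end)
      back <- span_to_original(nt, m[1], m[2])
      expect_lte(back[1], t$start)
      expect_gte(back[2], t$end)
    }
  }
  # positions outside replaced regions map bijectively
  nt <- canonicalize_numbers("take three tablets daily")
  expect_equal(span_to_normalized(nt, 0, 4), c(0, 4))     # "take"
  expect_equal(span_to_normalized(nt, 11, 18), c(7, 14))  # "tablets"
  expect_equal(span_to_original(nt, 7, 14), c(11, 18))
})

test_that("canonical decimal rendering is minimal", {
  expect_equal(rxsig:::format_decimal(c(3, 1.5, 0.5, 2.25, 100)),
               c("3", "1.5", "0.5", "2.25", "100"))
})
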