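test_that("tokenizer splits punctuation and tiles the non-whitespace text", {
  expect_equal(sig_tokenize("take 2-3 times")$surface,
               c("take", "2", "-", "3", "times"))
  expect_equal(nrow(sig_tokenize("")), 0)
  expect_equal(sig_tokenize("p.o.")$surface, c("p", ".", "o", "."))
  toks <- sig_tokenize("take 1.5 tablets (800 mg)")
  expect_equal(paste(toks$surface, collapse = ""),
               gsub("[[:space:]]", "", "take 1.5 tablets (800 mg)"))
  # offsets exact
  txt <- "use 2 drops in left eye"
  toks <- sig_tokenize(txt)
  expect_equal(toks$surface, substring(txt, toks$start + 1, toks$end))
})

test_that("feature extraction emits exactly the documented families", {
  toks <- sig_tokenize("Take 2 tablets")
  f <- token_features(toks, 3)
  expect_true(all(c("pre1=t", "pre2=ta", "pre3=tab",
                    "suf1=s", "suf2=ts", "suf3=ets") %in% f))
  expect_true("w=tablets" %in% f)
  expect_true(all(c("w-1=2", "w-2=Take", "w-3=<S>", "w1=<E>") %in% f))
  expect_false("cap" %in% f)
  expect_true("dig" %in% token_features(toks, 2))
  expect_true("cap" %in% token_features(toks, 1))
  expect_true("pcap" %in% token_features(toks, 2))
  # boundary placeholders at position 1
  f1 <- token_features(toks, 1)
  expect_true(all(c("w-1=<S>", "w-2=<S>", "w-3=<S>") %in% f1))
})

test_that("BIO encoding inverts through run conversion for token-aligned spans", {
  gen <- generate_corpus(generator_config(n_documents = 25, seed = 7))
  for (doc in gen$documents) {
    toks <- sig_tokenize(doc$text)
    labels <- encode_bio(toks, doc$tags)
    back <- decode_bio(toks, labels)
    orig <- lapply(doc$tags, function(t) t[c("label", "start", "end")])
    got <- lapply(back, function(t) t[c("label", "start", "end")])
    key <- function(l) paste(vapply(l, function(t)
      paste(t$label, t$start, t$end), character(1)), collapse = ";")
    ord <- function(l) l[order(vapply(l, `[[`, numeric(1), "start"))]
    expect_equal(key(ord(got)), key(ord(orig)), info = doc$doc_id)
  }
  # stray I- opens a new run
  toks <- sig_tokenize("a b")
  tags <- decode_bio(toks, c("I-TAKE", "I-FREQ"))
  expect_equal(vapply(tags, `[[`, character(1), "label"), c("TAKE", "FREQ"))
})

test_that("training is deterministic and the label inventory follows the corpus", {
  docs <- lapply(1:30, function(i)
    sig_document(paste0("d", i), "take 2 tablets",
                 list(tag_instance("TAKE", 5, 6, list(amount = 2)))))
  m <- train_tagger(docs, epochs = 3)
  expect_setequal(m$labels, c("O", "B-TAKE"))
  m2 <- train_tagger(docs, epochs = 3)
  probe <- "take 3 tablets"
  expect_identical(tag_sig(m, probe), tag_sig(m2, probe))
  expect_error(train_tagger(list()), "empty")
})

test_that("trained model decodes template-generated sigs with high fidelity", {
  gen <- generate_corpus(generator_config(n_documents = 150, seed = 29))
  m <- train_tagger(gen$documents, epochs = 10)
  expect_true("B-FREQ" %in% m$labels)
  pred <- tag_corpus(m, gen$documents)
  rep <- score_spans(gen$documents, pred)
  expect_gte(rep$overall$f, 0.95)
})

test_that("decode-time bias has the two limit behaviors and shifts the tradeoff", {
  gen <- generate_corpus(generator_config(n_documents = 120, seed = 31))
  m <- train_tagger(gen$documents, epochs = 6)
  text <- gen$documents[[1]]$text
  expect_length(tag_sig(m, text, bias = 1e6), 0)
  flood <- tag_sig(m, text, bias = -1e6)
  toks <- sig_tokenize(text)
  covered <- vapply(seq_len(nrow(toks)), function(i)
    any(vapply(flood, function(t)
      t$start <= toks$start[i] && toks$end[i] <= t$end, logical(1))),
    logical(1))
  expect_true(all(covered))
  # tag counts never increase with the bias
  counts <- vapply(c(-3, 0, 3), function(b)
    sum(vapply(gen$documents, function(d)
      length(tag_sig(m, d$text, b)), integer(1))), numeric(1))
  expect_true(all(diff(counts) <= 0))
})
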