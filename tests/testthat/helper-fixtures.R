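# Shared fixtures, built once per test run and cached. The benchmark
# corpus (1000 documents, seed 17) and the models trained on its training
# half are reused by several files to keep the suite fast.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

bench_corpus <- function() {
  fixture("bench", function() {
    gen <- generate_corpus(generator_config(n_documents = 1000, seed = 17))
    split <- split_corpus(gen$documents, 0.8, seed = 17)
    c(gen, list(train = split$train, test = split$test))
  })
}

bench_tagger <- function() {
  fixture("tagger", function()
    train_tagger(bench_corpus()$train, epochs = 10, seed = 17))
}

bench_attr_models <- function(method = "classifier") {
  fixture(paste0("attrs_", method), function()
    fit_attribute_models(bench_corpus()$train, sig_schema(),
                         choice_method = method, freq_method = "hybrid",
                         seed = 17))
}

# A tiny hand-made annotated document reused across files: the classic
# ibuprofen sig with a deliberate structured-field contradiction (the
# record says take 1, the text says take 2).
ibuprofen_doc <- function() {
  text <- "take 2 tablets three times a day as needed for pain"
  sig_document("247", text, list(
    tag_instance("TAKE", 5, 6, list(amount = 2)),
    tag_instance("DOSEFORM", 7, 14, list(form = "tablet")),
    tag_instance("FREQ", 15, 32,
                 list(times_per = 3, every = 1, unit = "day")),
    tag_instance("PRN", 33, 42),
    tag_instance("INDICATION", 47, 51)))
}

ibuprofen_record <- function() {
  data.frame(id = "247", medication = "IBUPROFEN", route = "PO", dose = 600,
             dose_units = "MG", strength = "600MG", take = 1,
             form = "Tablet", frequency = "TID", prn = "1",
             prn_reason = "Pain", duration = NA_real_, duration_units = "",
             dispense_quantity = 90, dispense_quantity_units = "Tablet(s)",
             directions = "take 2 tablets three times a day as needed for pain",
             stringsAsFactors = FALSE)
}

# Pooled accuracy of one prediction method over the unit-choice labels (or
# any label/attribute selection) on gold spans.
pooled_accuracy <- function(report, labels, attribute) {
  df <- report[report$label %in% labels & report$attribute == attribute, ,
               drop = FALSE]
  sum(df$correct) / sum(df$total)
}
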