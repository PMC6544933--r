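# rxsig

Free-text prescription directions ("sigs" — *take 2 tablets three times a
day as needed for pain*) carry the regimen information that downstream
systems need in structured form: dose, frequency, route, duration,
as-needed status. `rxsig` is an R toolkit for turning sigs into structured,
normalized medication-regimen annotations and for auditing them against
pharmacist-entered structured fields. It is aimed at clinical-NLP
researchers and pharmacy-informatics engineers who need a complete,
inspectable pipeline rather than a black box.

The package provides:

* **A 19-label annotation schema** for medication regimens — DISPENSE,
  DISPENSE_UNIT, MEDICATION, TAKE, STRENGTH, STRENGTH_UNIT, DOSEAMOUNT,
  DOSEAMOUNT_UNIT, DOSEFORM, DURATION, DURATION_UNIT, FREQ, TIMING, PRN,
  INDICATION, ROUTE, REFILL, SUB_STATUS, INSTRUCTION — each with typed,
  validated attributes (numeric, choice, boolean, free text). Frequency is
  fully range-capable: *every 4–6 hours* is
  `{every: 4, to_every: 6, unit: hour, times_per: 1}`, and the schema
  preserves the semantic difference between *every three days*
  (`every = 3`) and *three times per day* (`times_per = 3`).
* **A numeric retokenizer** mapping English number expressions to canonical
  decimals (*three* → 3, *one and a half* → 1.5) with a bidirectional
  character-offset map, so standoff annotations survive normalization.
* **A sequence tagger** (linear-chain model over BIO-encoded labels,
  averaged structured perceptron with Viterbi decoding) using prefix/suffix
  n-grams, capitalization, digit and windowed surface features, plus a
  signed decode-time **bias** trading precision against recall: positive
  values suppress low-margin spans, negative values pull more tokens into
  tags.
* **Attribute normalization** by five methods — majority baseline, literal
  span matching, Levenshtein fallback, maximum-entropy classification
  (bag-of-words + bigrams + number-expression count), and the hybrid
  FREQ/TIMING normalizers that classify the categorical attributes and map
  numbers left-to-right from the retokenized span.
* **Evaluation**: exact span+label precision/recall/F per label and
  micro-averaged, pairwise inter-annotator agreement by F-measure,
  attribute accuracy on gold spans, and deterministic corpus splits.
* **A seeded synthetic sig generator** emitting short direction strings
  with gold annotations, realistic clinical abbreviations (TID, p.o., prn),
  number words, optional misspellings, and paired structured prescription
  records with a controllable, logged contradiction rate.
* **Interchange**: standoff JSON / JSONL corpora, delimited prescription
  record tables, inline XML for human inspection, and FHIR-Dosage-shaped
  JSON export.
* **Discrepancy detection** comparing text-derived normalized values
  against structured record fields (Take, Frequency codes, Route, Duration,
  Dispense, PRN, Form), reporting mismatches and one-sided omissions.

## Worked example

```r
library(rxsig)
sc <- sig_schema()

# 1000 synthetic sigs with gold annotations; 80/20 split
gen   <- generate_corpus(generator_config(n_documents = 1000, seed = 17))
split <- split_corpus(gen$documents, 0.8, seed = 17)

model <- train_tagger(split$train, epochs = 10, seed = 17)
pred  <- tag_corpus(model, split$test)
rep   <- score_spans(split$test, pred)
sprintf("P=%.3f R=%.3f F=%.3f",
        rep$overall$precision, rep$overall$recall, rep$overall$f)
#> "P=1.000 R=1.000 F=1.000"

sig  <- "take 2 tablets three times a day as needed for pain"
doc  <- normalize_document(sig_document("demo", sig, tag_sig(model, sig)), sc)
cat(export_inline_xml(doc))
#> take <TAKE amount="2">2</TAKE> <DOSEFORM form="tablet">tablets</DOSEFORM>
#> <FREQ times_per="3" every="1" unit="day">three times a day</FREQ>
#> <PRN>as needed</PRN> for <INDICATION>pain</INDICATION>

jsonlite::toJSON(unclass(to_fhir_dosage(doc)), auto_unbox = TRUE)
#> {"doseQuantity":{"value":2,"unit":"tablet"},
#>  "frequency":3,"period":1,"periodUnit":"day",
#>  "asNeeded":true,"asNeededReason":"pain"}
```

The tagger reads the sig, assigns labeled spans; the normalizers fill each
tag's attributes (the quantity *2*, the form *tablet*, the count-type
frequency *3 per 1 day*, the as-needed flag and its reason); the FHIR
export maps those attributes onto the Dosage fields
(`frequency`/`period`/`periodUnit`, `doseQuantity`, `asNeeded`). On the
clean templated test set the span model is at ceiling; real prescription
text is harder — see the vignette for what the synthetic benchmark does
and does not show.

A command-line wrapper covering the same pipeline
(`generate`, `train`, `tag`, `normalize`, `eval`, `agree`, `export-fhir`,
`check`) is installed at `inst/cli/rxsig`:

```sh
Rscript inst/cli/rxsig generate --n 1000 --seed 17 --out corpus.jsonl --records records.csv
Rscript inst/cli/rxsig train --in corpus.jsonl --out model.rds --seed 17
Rscript inst/cli/rxsig tag --model model.rds --text "take 2 tablets twice a day"
```

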