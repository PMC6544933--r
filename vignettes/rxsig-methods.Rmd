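---
title: "Models and methods behind rxsig"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind rxsig}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rxsig)
```

`rxsig` structures free-text prescription directions along three layers:
*where* regimen concepts are mentioned (spans), *what kind* of concept each
mention is (one of 19 labels), and *what it means* (typed attributes with
normalized values). This vignette explains each model in the pipeline, the
parameters that matter, the numerical conventions, and what the bundled
synthetic benchmark does and does not demonstrate.

## The annotation model

A tag is a character span (0-based, half-open, counted in code points —
the unambiguous standard for standoff annotation) plus a label and an
attribute map. Attributes are typed:

* **numeric** — non-negative decimals stored losslessly (*one and a half*
  must normalize to 1.5, so integers-only storage is not an option). Range
  expressions fill a value pair, e.g. DURATION `num`/`to_num` for
  *7-10 days*.
* **choice** — values from a fixed list. Time units
  (minute/hour/day/week/month/other), laterality (left/right/both) and
  TIMING's direction/event lists are fixed in the schema; the dosing-unit,
  dose-form and route lists are deployment vocabulary and ship as editable
  configuration with curated defaults, so a site can substitute its own
  guideline lists without touching code.
* **boolean** — REFILL.refill and SUB_STATUS.subst.
* **free text** — MEDICATION.name and INSTRUCTION.note, defaulting to the
  span text.

An unstated attribute is `NULL`, never a sentinel value; serialization
omits nulls. Frequency semantics deserve emphasis: a *count* phrase
(*three times per day*) sets `times_per` with `every = 1`, an *interval*
phrase (*every three days*) sets `every` with `times_per = 1`, and ranges
(*2-3 times per day*, *every 4-6 hours*) fill the `to_*` companions. This
is what makes the representation mappable onto FHIR Dosage's
`frequency`/`frequencyMax`/`period`/`periodMax`/`periodUnit` block.

Validation never throws: `validate_tag()` returns a list of violations so
that corpus audits can aggregate them. Two different labels may share a
span (a token can plausibly be both a quantity and a strength); same-label
overlap is reported as a warning, not an error, since annotation tools
disagree on whether it is ever legitimate.

## Numeric retokenization

`find_number_expressions()` scans left-to-right with longest-match over a
small grammar: digit literals and decimals, fractions (`1/2`, `2 1/2`),
additive/multiplicative number words through the hundreds (*twenty one*,
*one hundred*), and the *X and a half/quarter* idiom. Two choices are easy
to get wrong:

* **Digit ranges split.** `2-3` yields two spans (values 2 and 3), because
  downstream range attributes need both endpoints; merging would lose the
  pair.
* **Ordinals are recognized but not rewritten.** *every third day* needs
  the value 3 for the interval, but rewriting the phrase to *every 3 day*
  would corrupt it; ordinal spans carry `ordinal = TRUE` and
  `canonicalize_numbers()` leaves their surface intact. Fraction glyphs
  (½) are out of scope.

Canonical rendering is base-10, no leading zeros, at most three decimal
places, never scientific notation — determinism matters because the
literal-match attribute method keys on the rendered text. The rewrite
carries a segment-wise offset map, monotone in both directions; positions
outside replaced regions map bijectively, and a span mapped through and
back is guaranteed to contain the original. Canonicalization is idempotent
(a property the test suite checks across generated corpora).

## Span tagging

Tokenization splits on whitespace and then isolates every punctuation
character, so `2-3` becomes three tokens (range endpoints must be separate
for BIO tagging) and `p.o.` becomes four. Dotted-abbreviation identity is
recovered by features and lexicons, not by the tokenizer — keeping the
tokenizer trivial makes span offsets exact by construction.

The tagger is a linear-chain sequence model over BIO-encoded labels,
trained as an averaged structured perceptron and decoded with Viterbi
under hard BIO validity (`I-X` only continues `B-X`/`I-X`). The feature
set is deliberately small and lexical: prefix/suffix n-grams up to length
3, capitalization of the current and previous token, a contains-digit
flag, the current surface, and the surfaces at offsets ±1..±3 with
boundary placeholders. No gazetteers or drug vocabularies are used —
medication names are learned (or not) from training data alone, which is
exactly why MEDICATION is the weakest label on sparse corpora.

Training visits documents in corpus order each epoch (default 10, early
stop on a mistake-free epoch) and averages weights over all updates, so
training is deterministic given the corpus and configuration — identical
runs produce byte-identical scores. Gold spans not aligned to token
boundaries are snapped outward with a warning. Unseen features at decode
time are ignored, the standard linear-model convention.

### The precision/recall bias

Decoding takes a signed `bias` with scale constant `bias_scale` (default
1.0). The design goal is a knob whose limits are provable: at very large
positive bias no tags are emitted, at very large negative bias every token
is tagged, and intermediate values trade precision against recall.

The naive mechanism — subtracting the bias from every non-O emission
score — fails that goal in a subtle way under exact-span evaluation:
boundary tokens of a span have the thinnest margins, so a positive bias
clips span-final tokens first, turning correct spans into *wrong* spans
and lowering precision. `rxsig` therefore treats the positive side as a
**prior cost on asserting a span**: decoding runs unbiased, and each
decoded span is kept only if forcing its tokens to O would cost the
decoder more than `bias_scale * bias` in path score. Predictions shrink
monotonically, whole spans at a time, toward the empty set. The negative
side subsidizes non-O emissions uniformly, pulling additional tokens into
tags until everything is covered. Both limits hold exactly, and on the
synthetic benchmark the grid {−3, 0, +3} gives non-increasing tag counts
with precision non-decreasing in the bias.

## Attribute normalization

Each attribute is modeled independently (no cross-tag joint inference, by
design — it keeps error analysis per-attribute). The methods, from
dumbest to richest:

* **Baseline** — the most common training value; for FREQ the numeric
  defaults are `times_per = 1`, `every = 1`, ranges null.
* **Literal match** — memorize span-text → most common value (keys are
  case-folded and whitespace-collapsed). On a miss, an exact match against
  the allowed list; on a double miss (unseen *and* not an allowed value)
  the training majority, a documented totalization — the alternative,
  refusing to answer, would make the method partial for no benefit.
* **Levenshtein fallback** — identical on seen spans; unseen spans resolve
  to the allowed value at minimal edit distance (unit costs). Ties break
  by higher training frequency, then lexicographically — every tie-break
  in the package is deterministic by this two-step rule.
* **Maximum-entropy classifier** — multinomial logistic regression
  (`nnet::multinom`, weak L2 `decay = 1e-4`, 300 iterations max, seeded
  initialization) over span bag-of-words, bigrams, up to three flanking
  tokens per side, and — for FREQ/TIMING — the count of number
  expressions. Single-class training data degrades to a constant
  predictor.

FREQ's **hybrid** method fits two classifiers — the unit, and whether the
phrase is an interval or a count — and maps numbers left-to-right from the
retokenized span: count phrases fill `times_per`(,`to_times_per`),
interval phrases fill `every`(,`to_every`). The interval/count training
label is derived from gold attributes (`every > 1` or a non-null
`to_every` marks an interval). The left-to-right rule is a modeling choice
the range semantics force for two-number spans; sigs with number pairs in
reverse semantic order essentially do not occur. Digit-free idioms go
through a configurable lexicon (*once*/*twice*/*thrice*, *daily*, q.d.,
b.i.d., t.i.d., q.i.d., *every other day*, …) because after
retokenization such spans contain no digits at all. When no trained model
is supplied, the unit and phrase-type decisions fall back to the same
lexicons, which makes `normalize_freq()` usable as a deterministic rule
normalizer.

The **classifier** variant adds one classifier per numeric attribute whose
output is snapped to the valid set {1–12, 15, 30, 45, 60} (counts above
12 per unit and non-clock offsets are not legitimate regimen values;
snapping ties resolve to the smaller member). TIMING mirrors all of this
with `direction`/`event`/`offset_unit` classifiers and direct numeric
mapping of `offset`/`to_offset`. For bare event phrases (*at bedtime*)
the direction is left null rather than forced to "other": the schema's
convention is that unstated means null, and *at* asserts no ordering.
Words like *with* and *during* do assert a relation that is neither
before nor after, and map to "other".

The pure-numeric labels (DISPENSE, TAKE, STRENGTH, DOSEAMOUNT, DURATION)
support two modes: *unnormalized* (verbatim surface as the value) and
*normalized* (retokenizer output; the default), matching the two
conditions one would compare in an ablation.

## Evaluation conventions

Span scoring is exact on (start, end, label), one-to-one per document,
micro-averaged overall. Precision is defined as 1.0 when nothing spurious
was hypothesized (and recall 1.0 when nothing was missed); F is 0 when
P + R = 0. This produces the familiar P = 1.000 / R = 0.000 row shape for
labels a conservative model never predicts. Exact matching is the stricter
of the plausible conventions and the reproducible one; the match criterion
is a single point of extension if overlap matching is ever needed.

Pairwise agreement between two annotators is the same F-measure with one
side as reference — F is symmetric under the swap because precision and
recall exchange roles. Attributes are deliberately excluded from agreement
and scored separately (`attribute_accuracy()`), always on gold spans, so
span errors never compound with attribute errors; gold-null values are
excluded from denominators.

`split_corpus()` shuffles deterministically by seed and rounds
`ratio * N`; 1746 documents at 0.8 give the 1397/349 split used as the
reference configuration.

## The synthetic corpus

Real prescription corpora are access-restricted, so the package ships a
generator whose defaults emulate the statistical shape of an ambulatory
prescription corpus: per-label tag rates follow a frequency profile
expressed as expected counts per 1397 documents (FREQ and TIMING near one
per sig; the catch-all INSTRUCTION about three; REFILL, STRENGTH and
DISPENSE rare), abbreviations (TID, b.i.d., p.o., prn) appear at rate 0.3,
number words at 0.3, and single-character misspellings of choice-surface
words — never of numbers — at 0.02, chosen to exercise the Levenshtein
fallback exactly where it is motivated. Unit labels are realized in the
same phrase as their paired quantity label, so coupled pairs share the
pair-mean rate; `expected_tag_counts()` exposes the implied expectations
and the suite checks empirical counts against them (chi-square overall,
±20% bands on well-populated labels). Every template keeps gold attributes
recorded *before* surface rendering, so *three* carries gold value 3
regardless of how it is spelled.

Paired structured records are derived from the same gold attributes
(frequency as codes like TID/Q6H, route as codes like PO). With
`discrepancy_rate > 0`, a sampled fraction of records gets exactly one
comparable field contradicted — always a value change on a field present
on both sides, so each perturbation is detectable as a `mismatch` — and
the perturbation log is returned as ground truth.

**What passing on this benchmark shows** is that the pipeline is wired
correctly end to end: the features can represent the cues, training
converges, normalization inverts the generator's rendering, and
discrepancy detection is exact when the comparison semantics match. **What
it does not show** is performance on real sigs: generated language is
templated, lexically narrow, grammatical, and single-regimen per string,
so span F near 1.0 here says nothing about the mid-0.7s one should expect
on heterogeneous clinical text, and MEDICATION in particular benefits from
the generator's tiny name list in a way no real corpus would permit.

## Discrepancy detection

`compare_record()` compares field by field in normalized space: numbers
exactly after decimal canonicalization (prescriptions are discrete; a
tolerance would mask real errors), unit and form strings after alias
folding (tab/tabs/tablet(s) → tablet), routes after code folding
(PO → oral), and structured frequency codes are decoded into the FREQ
attribute space (TID ⇔ `times_per = 3, unit = day`; Q4-6H ⇔
`every = 4, to_every = 6, unit = hour`) before comparison, because a code
and an attribute map cannot be compared as strings. Values present on one
side only yield `missing_in_structured` / `missing_in_text` findings;
contradictions yield `mismatch`, with the contributing spans cited.
Findings are advisory — the package never auto-corrects either side.

## Problem sizes and runtime choices

The bundled benchmark configuration is 1000 generated documents at seed
17 with an 80/20 split; the tagger trains in seconds at that size and the
attribute bundle in a few seconds more, which keeps the full test suite
comfortable on a single CPU. Classifier fitting caps `multinom` at 300
iterations; the perceptron caps at 10 epochs with early stopping. All of
these are configuration, not constants, and scale linearly for larger
corpora.

## Known limitations

* The number grammar covers sig language (≤ hundreds, halves/quarters,
  mixed fractions); it is not a general English number parser, and does
  not handle fraction glyphs or dates.
* The tagger has no vocabulary features; production use on real text
  should add a medication-name lexicon as an additional feature source.
* FHIR export is Dosage-*shaped* JSON, not a validated FHIR resource;
  strength/dispense/refill information rides in an `extensions` block
  because Dosage has no native home for it. Multiple same-category tags
  in one document are reported as conflicts for the caller to resolve
  (the CLI records them per document rather than failing a whole corpus).
* Attribute models are independent per attribute; no joint inference
  across tags.
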