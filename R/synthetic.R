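# Seeded synthetic sig generator. Emits short prescription-direction
# strings with gold annotations and paired structured records, emulating
# the statistical shape of an ambulatory prescription corpus: per-label
# tag rates follow a configurable frequency profile, number expressions
# appear as digits or words, clinical abbreviations (TID, p.o., prn) and
# single-edit misspellings of choice-surface words occur at configurable
# rates, and a configurable fraction of records carries one deliberately
# contradicted structured field (logged as ground truth).

# Default per-label frequency profile: tag counts observed over a
# reference corpus of 1397 annotated prescriptions.
DEFAULT_TAG_PROFILE <- c(
  DISPENSE = 46, DISPENSE_UNIT = 73, DOSEAMOUNT = 221, DOSEAMOUNT_UNIT = 202,
  DOSEFORM = 533, DURATION = 205, DURATION_UNIT = 193, FREQ = 1329,
  INDICATION = 319, INSTRUCTION = 4075, MEDICATION = 145, PRN = 232,
  REFILL = 70, ROUTE = 591, STRENGTH = 33, STRENGTH_UNIT = 34,
  SUB_STATUS = 112, TAKE = 774, TIMING = 1359)

PROFILE_DOCS <- 1397

#' Configuration for the synthetic sig generator
#'
#' @param n_documents Number of documents to generate.
#' @param seed RNG seed; generation is fully deterministic given the seed.
#' @param tag_frequency_targets Named vector of per-label relative weights,
#'   interpreted as expected tag counts per `profile_docs` documents.
#' @param profile_docs Document count over which the targets are counted.
#' @param noise List with `misspell_prob` (single-character edit applied to
#'   choice-surface words, never numbers), `abbrev_prob` (clinical
#'   abbreviation realization: TID, p.o., ...), `number_word_prob`
#'   (numbers realized as English words).
#' @param discrepancy_rate Fraction of records whose structured fields get
#'   one contradicted value (logged).
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(n_documents = 1000L, seed = 17L,
                             tag_frequency_targets = DEFAULT_TAG_PROFILE,
                             profile_docs = PROFILE_DOCS,
                             noise = list(misspell_prob = 0.02,
                                          abbrev_prob = 0.3,
                                          number_word_prob = 0.3),
                             discrepancy_rate = 0) {
  stopifnot(n_documents >= 1, all(tag_frequency_targets >= 0),
            discrepancy_rate >= 0, discrepancy_rate <= 1)
  noise <- utils::modifyList(list(misspell_prob = 0.02, abbrev_prob = 0.3,
                                  number_word_prob = 0.3), noise)
  stopifnot(all(unlist(noise) >= 0), all(unlist(noise) <= 1))
  structure(list(n_documents = as.integer(n_documents),
                 seed = as.integer(seed),
                 tag_frequency_targets = tag_frequency_targets,
                 profile_docs = profile_docs,
                 noise = noise, discrepancy_rate = discrepancy_rate),
            class = "generator_config")
}

# Per-document inclusion model derived from the profile. Unit labels are
# realized in the same phrase as their paired quantity label, so coupled
# pairs use the pair-mean rate.
inclusion_rates <- function(config) {
  w <- config$tag_frequency_targets
  d <- config$profile_docs
  pair <- function(a, b) mean(c(w[[a]], w[[b]])) / d
  list(
    take = w[["TAKE"]] / d,
    doseform_given_take = min(1, w[["DOSEFORM"]] / max(w[["TAKE"]], 1e-9)),
    doseamount = pair("DOSEAMOUNT", "DOSEAMOUNT_UNIT"),
    strength = pair("STRENGTH", "STRENGTH_UNIT"),
    route = w[["ROUTE"]] / d,
    freq = min(1, w[["FREQ"]] / d),
    timing = min(1, w[["TIMING"]] / d),
    duration = pair("DURATION", "DURATION_UNIT"),
    indication = w[["INDICATION"]] / d,
    prn_given_indication = min(1, w[["PRN"]] / max(w[["INDICATION"]], 1e-9)),
    dispense = pair("DISPENSE", "DISPENSE_UNIT"),
    refill = w[["REFILL"]] / d,
    sub_status = w[["SUB_STATUS"]] / d,
    medication = w[["MEDICATION"]] / d,
    instruction = w[["INSTRUCTION"]] / d)
}

#' Expected per-label tag counts for a generator run
#'
#' The expectation implied by the configuration and the generator's
#' document model; empirical counts concentrate around these values.
#'
#' @param config A [generator_config()].
#' @param n Number of documents (defaults to `config$n_documents`).
#' @return Named numeric vector of expected counts per label.
#' @export
expected_tag_counts <- function(config, n = config$n_documents) {
  r <- inclusion_rates(config)
  n * c(
    DISPENSE = r$dispense, DISPENSE_UNIT = r$dispense,
    DOSEAMOUNT = r$doseamount, DOSEAMOUNT_UNIT = r$doseamount,
    DOSEFORM = r$take * r$doseform_given_take,
    DURATION = r$duration, DURATION_UNIT = r$duration,
    FREQ = r$freq, INDICATION = r$indication,
    INSTRUCTION = r$instruction,
    MEDICATION = r$medication,
    PRN = r$indication * r$prn_given_indication,
    REFILL = r$refill, ROUTE = r$route,
    STRENGTH = r$strength, STRENGTH_UNIT = r$strength,
    SUB_STATUS = r$sub_status, TAKE = r$take, TIMING = r$timing)
}

# ---- surface inventories ---------------------------------------------------

FREQ_VARIANTS <- list(
  list(code = "QD", map = list(times_per = 1, every = 1, unit = "day"),
       phrases = c("once daily", "once a day"), abbrevs = c("q.d.", "QD")),
  list(code = "BID", map = list(times_per = 2, every = 1, unit = "day"),
       phrases = c("2 times a day"),
       words = c("twice a day", "twice daily", "two times a day"),
       abbrevs = c("b.i.d.", "BID")),
  list(code = "TID", map = list(times_per = 3, every = 1, unit = "day"),
       phrases = c("3 times a day", "3 times daily"),
       words = c("three times a day"), abbrevs = c("t.i.d.", "TID")),
  list(code = "QID", map = list(times_per = 4, every = 1, unit = "day"),
       phrases = c("4 times a day"), words = c("four times a day"),
       abbrevs = c("q.i.d.", "QID")),
  list(code = "BID-TID",
       map = list(times_per = 2, to_times_per = 3, every = 1, unit = "day"),
       phrases = c("2-3 times per day", "2-3 times a day"),
       words = c("two to three times a day")),
  list(code = "Q6H", map = list(times_per = 1, every = 6, unit = "hour"),
       phrases = c("every 6 hours"), words = c("every six hours"),
       abbrevs = c("q6h")),
  list(code = "Q8H", map = list(times_per = 1, every = 8, unit = "hour"),
       phrases = c("every 8 hours"), words = c("every eight hours")),
  list(code = "Q12H", map = list(times_per = 1, every = 12, unit = "hour"),
       phrases = c("every 12 hours")),
  list(code = "Q4-6H",
       map = list(times_per = 1, every = 4, to_every = 6, unit = "hour"),
       phrases = c("every 4-6 hours"), words = c("every four to six hours")),
  list(code = "QOD", map = list(times_per = 1, every = 2, unit = "day"),
       phrases = c("every other day")),
  list(code = "Q3D", map = list(times_per = 1, every = 3, unit = "day"),
       phrases = c("every 3 days"), words = c("every three days")),
  list(code = "QWK", map = list(times_per = 1, every = 1, unit = "week"),
       phrases = c("once a week", "weekly")))

TIMING_VARIANTS <- list(
  list(map = list(offset = 1, offset_unit = "hour", direction = "after",
                  event = "meals"),
       phrases = c("1 hour after meals"), words = c("one hour after meals")),
  list(map = list(offset = 30, offset_unit = "minute", direction = "before",
                  event = "breakfast"),
       phrases = c("30 minutes before breakfast")),
  list(map = list(offset = 2, offset_unit = "hour", direction = "before",
                  event = "procedure"),
       phrases = c("2 hours before procedure"),
       words = c("two hours before procedure")),
  list(map = list(direction = "before", event = "meals"),
       phrases = c("before meals")),
  list(map = list(direction = "other", event = "meals"),
       phrases = c("with meals", "with food")),
  list(map = list(direction = "after", event = "dinner"),
       phrases = c("after dinner")),
  list(map = list(event = "bedtime"), phrases = c("at bedtime")),
  list(map = list(event = "morning"), phrases = c("in the morning")),
  list(map = list(event = "evening"), phrases = c("in the evening")))

ROUTE_VARIANTS <- list(
  list(value = "oral", code = "PO", phrases = c("by mouth", "orally"),
       abbrevs = c("p.o.", "PO")),
  list(value = "topical", code = "TOP",
       phrases = c("topically", "on the skin")),
  list(value = "sublingual", code = "SL", phrases = c("under the tongue")),
  list(value = "ophthalmic", code = "OPH", side = "left",
       phrases = c("in left eye")),
  list(value = "ophthalmic", code = "OPH", side = "right",
       phrases = c("in right eye")),
  list(value = "ophthalmic", code = "OPH", side = "both",
       phrases = c("in both eyes")),
  list(value = "otic", code = "OT", side = "both",
       phrases = c("in both ears")),
  list(value = "nasal", code = "NAS", phrases = c("in each nostril")),
  list(value = "inhaled", code = "INH", phrases = c("by inhalation")),
  list(value = "rectal", code = "PR", phrases = c("per rectum")),
  list(value = "subcutaneous", code = "SC", phrases = c("subcutaneously")))

ROUTE_CODES <- c(PO = "oral", TOP = "topical", SL = "sublingual",
                 OPH = "ophthalmic", OT = "otic", NAS = "nasal",
                 INH = "inhaled", PR = "rectal", SC = "subcutaneous")

DOSEFORM_VARIANTS <- list(
  list(value = "tablet", surfaces = c("tablet", "tablets", "tabs")),
  list(value = "capsule", surfaces = c("capsule", "capsules", "caps")),
  list(value = "puff", surfaces = c("puff", "puffs")),
  list(value = "drop", surfaces = c("drop", "drops")),
  list(value = "patch", surfaces = c("patch", "patches")),
  list(value = "spray", surfaces = c("spray", "sprays")),
  list(value = "suppository", surfaces = c("suppository")),
  list(value = "application", surfaces = c("application", "applications")))

DOSE_UNITS <- c("mg", "mcg", "g", "ml", "unit")

MEDICATION_NAMES <- c("ibuprofen", "amoxicillin", "lisinopril", "metformin",
                      "omeprazole", "cetirizine", "zynophex", "cortavil",
                      "relafexin", "dolmiprin")

INDICATIONS <- c("pain", "anxiety", "nausea", "fever", "cough", "insomnia",
                 "inflammation", "allergies")

INSTRUCTION_PHRASES <- c(
  "with a full glass of water", "shake well before use", "do not crush",
  "avoid alcohol", "take with food", "if pain persists call your physician",
  "store at room temperature", "swallow whole", "do not drive after use",
  "finish all medication", "keep out of reach of children",
  "use only as directed")

DURATION_UNIT_SURFACES <- list(day = c("days", "day"), week = c("weeks", "week"),
                               month = c("months", "month"))

# ---- realization helpers ---------------------------------------------------

pick1 <- function(x, prob = NULL) {
  if (length(x) == 1L) return(x[[1]])
  x[[sample.int(length(x), 1L, prob = prob)]]
}

coin <- function(p) stats::runif(1) < p

LETTERS_LC <- letters

misspell_word <- function(word) {
  n <- nchar(word)
  if (n < 3L) return(word)
  op <- pick1(c("sub", "ins", "del"))
  i <- sample.int(n, 1L)
  ch <- pick1(LETTERS_LC)
  switch(op,
    sub = paste0(substr(word, 1, i - 1), ch, substr(word, i + 1, n)),
    ins = paste0(substr(word, 1, i), ch, substr(word, i + 1, n)),
    del = if (n > 3L) paste0(substr(word, 1, i - 1), substr(word, i + 1, n))
          else word)
}

maybe_misspell <- function(word, noise) {
  if (coin(noise$misspell_prob)) misspell_word(word) else word
}

render_value <- function(v, noise) {
  if (coin(noise$number_word_prob) && v == floor(v) && v >= 0 && v <= 99)
    number_to_words(v)
  else if (coin(noise$number_word_prob) && isTRUE(all.equal(v %% 1, 0.5)) &&
           v <= 99)
    number_to_words(v)
  else format_decimal(v)
}

# A document under construction: text pieces plus tags with running offsets.
new_builder <- function() {
  env <- new.env(parent = emptyenv())
  env$pieces <- character(); env$len <- 0; env$tags <- list()
  env
}

b_emit <- function(b, text) {
  if (b$len > 0) { b$pieces <- c(b$pieces, " "); b$len <- b$len + 1 }
  b$pieces <- c(b$pieces, text)
  b$len <- b$len + nchar(text)
  invisible(b)
}

b_emit_tag <- function(b, text, label, attrs = list()) {
  sep <- if (b$len > 0) 1L else 0L
  start <- b$len + sep
  b_emit(b, text)
  b$tags[[length(b$tags) + 1L]] <-
    tag_instance(label, start, start + nchar(text), attrs)
  invisible(b)
}

pick_surface <- function(variant, noise) {
  if (!is.null(variant$abbrevs) && coin(noise$abbrev_prob))
    return(pick1(variant$abbrevs))
  if (!is.null(variant$words) && coin(noise$number_word_prob))
    return(pick1(variant$words))
  pick1(variant$phrases)
}

#' Generate a synthetic corpus with paired structured records
#'
#' Deterministic given `config$seed`. Every emitted document's gold tags
#' validate against the default schema; every record's structured fields
#' agree with the sig's gold attributes except in a `discrepancy_rate`
#' fraction, where exactly one comparable field is contradicted and the
#' perturbation is logged.
#'
#' @param config A [generator_config()].
#' @return List with `documents` (list of [sig_document()]), `records`
#'   (data frame in [read_records()] layout) and `perturbations` (data
#'   frame: `id`, `field`, `original`, `perturbed`).
#' @export
generate_corpus <- function(config = generator_config()) {
  with_seed(config$seed, generate_corpus_impl(config))
}

generate_corpus_impl <- function(config) {
  r <- inclusion_rates(config)
  noise <- config$noise
  docs <- vector("list", config$n_documents)
  recs <- vector("list", config$n_documents)
  perturbations <- data.frame(id = character(), field = character(),
                              original = character(), perturbed = character(),
                              stringsAsFactors = FALSE)
  for (d in seq_len(config$n_documents)) {
    out <- realize_document(sprintf("syn-%05d", d), r, noise)
    doc <- out$doc
    rec <- out$record
    if (coin(config$discrepancy_rate)) {
      pert <- perturb_record(rec)
      if (!is.null(pert)) {
        rec <- pert$record
        perturbations <- rbind(perturbations, data.frame(
          id = rec$id, field = pert$field, original = pert$original,
          perturbed = pert$perturbed, stringsAsFactors = FALSE))
      }
    }
    docs[[d]] <- doc
    recs[[d]] <- rec
  }
  records <- do.call(rbind, lapply(recs, as.data.frame,
                                   stringsAsFactors = FALSE))
  list(documents = docs, records = records, perturbations = perturbations)
}

realize_document <- function(doc_id, r, noise) {
  b <- new_builder()
  rec <- list(id = doc_id, medication = "", route = "", dose = NA_real_,
              dose_units = "", strength = "", take = NA_real_, form = "",
              frequency = "", prn = "0", prn_reason = "",
              duration = NA_real_, duration_units = "",
              dispense_quantity = NA_real_, dispense_quantity_units = "",
              directions = "")

  if (coin(r$medication)) {
    name <- pick1(MEDICATION_NAMES)
    b_emit_tag(b, name, "MEDICATION", list(name = name))
    b_emit(b, ":")
    rec$medication <- toupper(name)
  }
  b_emit(b, pick1(c("take", "take", "use")))

  has_take <- coin(r$take)
  if (has_take) {
    tv <- pick1(list(c(1, NA), c(1, NA), c(2, NA), c(2, NA), c(3, NA),
                     c(4, NA), c(1.5, NA), c(0.5, NA), c(1, 2), c(2, 3)))
    amount <- tv[1]; to_amount <- if (is.na(tv[2])) NULL else tv[2]
    surf <- if (!is.null(to_amount)) {
      if (coin(noise$number_word_prob))
        paste(number_to_words(amount), "to", number_to_words(to_amount))
      else paste0(format_decimal(amount), "-", format_decimal(to_amount))
    } else render_value(amount, noise)
    b_emit_tag(b, surf, "TAKE",
               list(amount = amount, to_amount = to_amount))
    rec$take <- amount
    if (coin(r$doseform_given_take)) {
      fv <- pick1(DOSEFORM_VARIANTS)
      surf <- maybe_misspell(pick1(fv$surfaces), noise)
      b_emit_tag(b, surf, "DOSEFORM", list(form = fv$value))
      rec$form <- fv$value
    }
  }

  if (coin(r$doseamount)) {
    amt <- pick1(c(100, 200, 250, 400, 500, 600, 800, 1000))
    unit <- pick1(DOSE_UNITS)
    b_emit(b, "(")
    b_emit_tag(b, format_decimal(amt), "DOSEAMOUNT", list(amount = amt))
    b_emit_tag(b, maybe_misspell(unit, noise), "DOSEAMOUNT_UNIT",
               list(unit = unit))
    b_emit(b, ")")
    rec$dose <- amt
    rec$dose_units <- toupper(unit)
  }

  if (coin(r$strength)) {
    amt <- pick1(c(5, 10, 20, 25, 50, 100, 400, 500))
    unit <- pick1(c("mg", "mcg"))
    b_emit(b, "strength")
    b_emit_tag(b, format_decimal(amt), "STRENGTH", list(amount = amt))
    b_emit_tag(b, maybe_misspell(unit, noise), "STRENGTH_UNIT",
               list(unit = unit))
    rec$strength <- paste0(format_decimal(amt), toupper(unit))
  }

  if (coin(r$route)) {
    rv <- pick1(ROUTE_VARIANTS)
    surf <- pick_surface(rv, noise)
    if (!grepl("\\.", surf))
      surf <- paste(vapply(strsplit(surf, " ")[[1]], function(w)
        if (w %in% c("left", "right", "both")) w
        else maybe_misspell(w, noise), character(1)), collapse = " ")
    attrs <- list(route = rv$value)
    if (!is.null(rv$side)) attrs$side <- rv$side
    b_emit_tag(b, surf, "ROUTE", attrs)
    rec$route <- rv$code
  }

  if (coin(r$freq)) {
    fv <- pick1(FREQ_VARIANTS)
    b_emit_tag(b, pick_surface(fv, noise), "FREQ", fv$map)
    rec$frequency <- fv$code
  }

  if (coin(r$timing)) {
    tv <- pick1(TIMING_VARIANTS)
    b_emit_tag(b, pick_surface(tv, noise), "TIMING", tv$map)
  }

  if (coin(r$duration)) {
    num <- pick1(c(5, 7, 10, 14, 30, 2, 3, 1))
    to_num <- if (coin(0.15)) num + pick1(c(2, 3)) else NULL
    unit <- pick1(names(DURATION_UNIT_SURFACES))
    b_emit(b, "for")
    nsurf <- if (!is.null(to_num))
      paste0(format_decimal(num), "-", format_decimal(to_num))
    else render_value(num, noise)
    b_emit_tag(b, nsurf, "DURATION", list(num = num, to_num = to_num))
    usurf <- pick1(DURATION_UNIT_SURFACES[[unit]])
    b_emit_tag(b, maybe_misspell(usurf, noise), "DURATION_UNIT",
               list(unit = unit))
    rec$duration <- num
    rec$duration_units <- unit
  }

  if (coin(r$indication)) {
    ind <- pick1(INDICATIONS)
    if (coin(r$prn_given_indication)) {
      prn_surf <- if (coin(noise$abbrev_prob)) pick1(c("prn", "p.r.n."))
                  else "as needed"
      b_emit_tag(b, prn_surf, "PRN")
      rec$prn <- "1"
    }
    b_emit(b, "for")
    b_emit_tag(b, ind, "INDICATION")
    rec$prn_reason <- ind
  }

  if (coin(r$dispense)) {
    qty <- pick1(c(30, 60, 90, 100, 120))
    fv <- pick1(DOSEFORM_VARIANTS[1:4])
    b_emit(b, "dispense")
    b_emit_tag(b, format_decimal(qty), "DISPENSE", list(quantity = qty))
    b_emit_tag(b, maybe_misspell(pick1(fv$surfaces), noise), "DISPENSE_UNIT",
               list(unit = fv$value))
    rec$dispense_quantity <- qty
    rec$dispense_quantity_units <- fv$value
  }

  if (coin(r$refill)) {
    rv <- pick1(list(list(s = "no refills", v = FALSE),
                     list(s = "refills permitted", v = TRUE),
                     list(s = "may refill", v = TRUE)))
    b_emit_tag(b, rv$s, "REFILL", list(refill = rv$v))
  }

  if (coin(r$sub_status)) {
    sv <- pick1(list(list(s = "no substitutions", v = FALSE),
                     list(s = "dispense as written", v = FALSE),
                     list(s = "substitution permitted", v = TRUE)))
    b_emit_tag(b, sv$s, "SUB_STATUS", list(subst = sv$v))
  }

  n_instr <- floor(r$instruction) + coin(r$instruction - floor(r$instruction))
  if (n_instr > 0) for (phrase in sample(INSTRUCTION_PHRASES,
                                         min(n_instr,
                                             length(INSTRUCTION_PHRASES)))) {
    b_emit(b, "-")
    b_emit_tag(b, phrase, "INSTRUCTION", list(note = phrase))
  }

  text <- paste(b$pieces, collapse = "")
  rec$directions <- text
  list(doc = sig_document(doc_id, text, b$tags, source = "synthetic",
                          annotator_id = "generator"),
       record = rec)
}

# One contradicted structured field; returns NULL when the record has no
# comparable populated field. Perturbations always change the normalized
# comparison value, so each logged record yields a mismatch finding.
perturb_record <- function(rec) {
  eligible <- c(
    if (!is.na(rec$take)) "take",
    if (nzchar(rec$frequency)) "frequency",
    if (nzchar(rec$route)) "route",
    if (!is.na(rec$duration)) "duration",
    if (!is.na(rec$dispense_quantity)) "dispense_quantity",
    if (nzchar(rec$form)) "form")
  if (length(eligible) == 0L) return(NULL)
  field <- pick1(eligible)
  original <- as.character(rec[[field]])
  if (field %in% c("take", "duration", "dispense_quantity")) {
    rec[[field]] <- rec[[field]] + 1
  } else if (field == "frequency") {
    codes <- setdiff(vapply(FREQ_VARIANTS, `[[`, character(1), "code"),
                     rec$frequency)
    rec$frequency <- pick1(codes)
  } else if (field == "route") {
    rec$route <- pick1(setdiff(names(ROUTE_CODES), rec$route))
  } else if (field == "form") {
    forms <- setdiff(vapply(DOSEFORM_VARIANTS, `[[`, character(1), "value"),
                     rec$form)
    rec$form <- pick1(forms)
  }
  list(record = rec, field = field, original = original,
       perturbed = as.character(rec[[field]]))
}
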