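# Discrepancy detection: compare the normalized annotations of a sig
# against the pharmacist-entered structured fields of the same
# prescription record and report contradictions.

# Structured Frequency codes map to the same attribute space the FREQ
# normalizer emits; comparison happens in that space.
FREQ_CODE_TABLE <- list(
  QD = list(times_per = 1, every = 1, unit = "day"),
  QHS = list(times_per = 1, every = 1, unit = "day"),
  BID = list(times_per = 2, every = 1, unit = "day"),
  TID = list(times_per = 3, every = 1, unit = "day"),
  QID = list(times_per = 4, every = 1, unit = "day"),
  QOD = list(times_per = 1, every = 2, unit = "day"),
  QWK = list(times_per = 1, every = 1, unit = "week"),
  `BID-TID` = list(times_per = 2, to_times_per = 3, every = 1, unit = "day"))

freq_code_to_map <- function(code) {
  code <- toupper(gsub("[. ]", "", code))
  hit <- FREQ_CODE_TABLE[[code]]
  if (!is.null(hit)) return(hit)
  m <- regmatches(code, regexec("^Q([0-9]+)(?:-([0-9]+))?([HDW])$", code))[[1]]
  if (length(m)) {
    unit <- c(H = "hour", D = "day", W = "week")[[m[4]]]
    out <- list(times_per = 1, every = as.numeric(m[2]), unit = unit)
    if (nzchar(m[3])) out$to_every <- as.numeric(m[3])
    return(out)
  }
  NULL
}

# Unit/form surface aliases folded before comparison.
UNIT_ALIASES <- c("tab" = "tablet", "tabs" = "tablet", "tablets" = "tablet",
                  "cap" = "capsule", "caps" = "capsule",
                  "capsules" = "capsule", "puffs" = "puff",
                  "drops" = "drop", "patches" = "patch", "sprays" = "spray",
                  "applications" = "application")

fold_unit <- function(x) {
  k <- fold_key(x)
  k <- sub("\\(s\\)$", "", k)
  if (k %in% names(UNIT_ALIASES)) unname(UNIT_ALIASES[k]) else k
}

fold_route <- function(x) {
  k <- toupper(gsub("[. ]", "", x))
  if (k %in% names(ROUTE_CODES)) return(unname(ROUTE_CODES[k]))
  fold_key(x)
}

empty_findings <- function() {
  data.frame(field = character(), structured = character(),
             text_value = character(), severity = character(),
             spans = character(), stringsAsFactors = FALSE)
}

#' Compare a prescription record against its annotated sig
#'
#' Field-by-field comparison of the structured data against the
#' text-derived normalized attributes: Take vs TAKE.amount, Frequency
#' (decoded from codes like TID, Q6H through the idiom lexicon) vs the
#' FREQ attribute map, Route (code-folded) vs ROUTE.route, Duration and
#' its units vs DURATION/DURATION_UNIT, Dispense Quantity and units vs
#' DISPENSE/DISPENSE_UNIT, the PRN flag vs PRN tag presence, PRN Reason vs
#' the INDICATION span text, and Form vs DOSEFORM.form. Numeric values
#' compare exactly after decimal canonicalization; unit strings compare
#' after alias folding. A value present on one side only yields a
#' `missing_in_structured` / `missing_in_text` finding; unequal values
#' yield a `mismatch`.
#'
#' @param record One record: a single-row data frame or named list in
#'   [read_records()] layout.
#' @param doc The [sig_document()] for the record's directions, with
#'   normalized attributes.
#' @return An object of class `discrepancy_report`: list with `record_id`
#'   and a `findings` data frame (`field`, `structured`, `text_value`,
#'   `severity`, `spans`).
#' @export
compare_record <- function(record, doc) {
  record <- as.list(record)
  if (!identical(record$directions, doc$text))
    stop("record ", record$id,
         ": directions differ from document text", call. = FALSE)
  findings <- empty_findings()
  by_label <- split(doc$tags, vapply(doc$tags, `[[`, character(1), "label"))
  first_tag <- function(label) {
    ts <- by_label[[label]]
    if (is.null(ts)) NULL else ts[[1]]
  }
  tag_span_str <- function(t) {
    if (is.null(t)) "" else sprintf("%s[%s,%s)", t$label, format(t$start),
                                    format(t$end))
  }
  add <- function(field, structured, text_value, severity, spans = "") {
    findings <<- rbind(findings, data.frame(
      field = field, structured = structured %||% "",
      text_value = text_value %||% "", severity = severity, spans = spans,
      stringsAsFactors = FALSE))
  }
  s_num <- function(x) {
    if (is.null(x) || length(x) == 0L) return(NA_real_)
    suppressWarnings(as.numeric(x))
  }
  cmp_numeric <- function(field, structured, tag, attr) {
    s <- s_num(structured)
    t <- if (is.null(tag)) NULL else tag$attributes[[attr]]
    if (is.na(s) && is.null(t)) return()
    if (is.na(s)) add(field, "", format_decimal(t), "missing_in_structured",
                      tag_span_str(tag))
    else if (is.null(t)) add(field, format_decimal(s), "", "missing_in_text",
                             tag_span_str(tag))
    else if (format_decimal(s) != format_decimal(t))
      add(field, format_decimal(s), format_decimal(t), "mismatch",
          tag_span_str(tag))
  }
  cmp_string <- function(field, structured, tag, attr, fold = fold_unit) {
    s <- as.character(structured %||% "")
    t <- if (is.null(tag)) NULL else tag$attributes[[attr]]
    s_empty <- is.na(s) || !nzchar(s)
    if (s_empty && is.null(t)) return()
    if (s_empty) add(field, "", t, "missing_in_structured", tag_span_str(tag))
    else if (is.null(t)) add(field, s, "", "missing_in_text")
    else if (fold(s) != fold(t)) add(field, s, t, "mismatch",
                                     tag_span_str(tag))
  }

  cmp_numeric("take", record$take, first_tag("TAKE"), "amount")

  # Frequency: decode the structured code into the FREQ attribute space.
  freq_tag <- first_tag("FREQ")
  s_freq <- as.character(record$frequency %||% "")
  if (!is.na(s_freq) && nzchar(s_freq) || !is.null(freq_tag)) {
    if (is.na(s_freq) || !nzchar(s_freq)) {
      add("frequency", "", "FREQ tag", "missing_in_structured",
          tag_span_str(freq_tag))
    } else if (is.null(freq_tag)) {
      add("frequency", s_freq, "", "missing_in_text")
    } else {
      smap <- freq_code_to_map(s_freq)
      tmap <- freq_tag$attributes
      if (is.null(smap)) {
        add("frequency", s_freq, "", "mismatch", tag_span_str(freq_tag))
      } else {
        same <- TRUE
        for (a in c("times_per", "to_times_per", "every", "to_every")) {
          sv <- smap[[a]]; tv <- tmap[[a]]
          sv <- if (is.null(sv) && a %in% c("times_per", "every")) 1 else sv
          tv <- if (is.null(tv) && a %in% c("times_per", "every")) 1 else tv
          if (is.null(sv) != is.null(tv)) { same <- FALSE; break }
          if (!is.null(sv) && format_decimal(sv) != format_decimal(tv)) {
            same <- FALSE; break
          }
        }
        if (same && !identical(smap$unit, tmap$unit)) same <- FALSE
        if (!same)
          add("frequency", s_freq,
              paste0("times_per=", format_decimal(tmap$times_per %||% 1),
                     " every=", format_decimal(tmap$every %||% 1),
                     " unit=", tmap$unit %||% "?"),
              "mismatch", tag_span_str(freq_tag))
      }
    }
  }

  cmp_string("route", record$route, first_tag("ROUTE"), "route",
             fold = fold_route)
  cmp_numeric("duration", record$duration, first_tag("DURATION"), "num")
  cmp_string("duration_units", record$duration_units,
             first_tag("DURATION_UNIT"), "unit",
             fold = function(x) {
               k <- fold_unit(x)
               hit <- TIME_UNIT_LEXICON[k]
               if (!is.na(hit)) unname(hit) else k
             })
  cmp_numeric("dispense_quantity", record$dispense_quantity,
              first_tag("DISPENSE"), "quantity")
  cmp_string("dispense_quantity_units", record$dispense_quantity_units,
             first_tag("DISPENSE_UNIT"), "unit")
  cmp_string("form", record$form, first_tag("DOSEFORM"), "form")

  # PRN: presence comparison.
  prn_tag <- first_tag("PRN")
  s_prn <- fold_key(as.character(record$prn %||% ""))
  prn_structured <- s_prn %in% c("1", "true", "yes", "y", "prn")
  if (prn_structured && is.null(prn_tag))
    add("prn", record$prn, "", "missing_in_text")
  else if (!prn_structured && !is.null(prn_tag))
    add("prn", record$prn %||% "", "PRN tag", "missing_in_structured",
        tag_span_str(prn_tag))

  ind_tag <- first_tag("INDICATION")
  ind_text <- if (is.null(ind_tag)) NULL else
    span_text(doc$text, ind_tag$start, ind_tag$end)
  # INDICATION carries no attribute; compare the span text itself.
  s_reason <- as.character(record$prn_reason %||% "")
  reason_empty <- is.na(s_reason) || !nzchar(s_reason)
  if (!reason_empty || !is.null(ind_text)) {
    if (reason_empty)
      add("prn_reason", "", ind_text, "missing_in_structured",
          tag_span_str(ind_tag))
    else if (is.null(ind_text))
      add("prn_reason", s_reason, "", "missing_in_text")
    else if (fold_key(s_reason) != fold_key(ind_text))
      add("prn_reason", s_reason, ind_text, "mismatch",
          tag_span_str(ind_tag))
  }

  structure(list(record_id = as.character(record$id), findings = findings),
            class = "discrepancy_report")
}

#' Compare many records against their annotated sigs
#'
#' @param records Data frame in [read_records()] layout.
#' @param docs List of [sig_document()] whose `doc_id`s match `records$id`.
#' @return List with `findings` (combined data frame with an `id` column)
#'   and `flagged` (ids of records with at least one `mismatch` finding).
#' @export
compare_records <- function(records, docs) {
  doc_ids <- vapply(docs, `[[`, character(1), "doc_id")
  all_findings <- list()
  for (i in seq_len(nrow(records))) {
    rec <- records[i, , drop = FALSE]
    j <- match(as.character(rec$id), doc_ids)
    if (is.na(j)) stop("no document for record ", rec$id, call. = FALSE)
    rep <- compare_record(rec, docs[[j]])
    if (nrow(rep$findings)) {
      rep$findings$id <- rep$record_id
      all_findings[[length(all_findings) + 1L]] <- rep$findings
    }
  }
  findings <- if (length(all_findings)) do.call(rbind, all_findings)
              else cbind(empty_findings(),
                         data.frame(id = character(),
                                    stringsAsFactors = FALSE))
  list(findings = findings,
       flagged = sort(unique(findings$id[findings$severity == "mismatch"])))
}
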