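# Reading and writing: standoff JSON documents, JSONL corpora, delimited
# prescription record tables, inline XML export, and FHIR-Dosage-shaped
# JSON.

tag_to_list <- function(t) {
  attrs <- t$attributes[!vapply(t$attributes, is.null, logical(1))]
  list(label = t$label, start = t$start, end = t$end,
       attributes = if (length(attrs)) attrs else stats::setNames(list(),
                                                                  character()))
}

doc_to_list <- function(doc) {
  list(doc_id = doc$doc_id, text = doc$text, source = doc$source,
       annotator_id = doc$annotator_id,
       tags = lapply(doc$tags, tag_to_list))
}

list_to_doc <- function(x, schema = NULL) {
  tags <- lapply(x$tags, function(tl) {
    attrs <- tl$attributes %||% list()
    if (length(attrs)) {
      names(attrs) <- canonical_attribute_name(names(attrs))
      attrs <- lapply(attrs, function(v) {
        if (is.logical(v)) v
        else if (is.numeric(v)) as.numeric(v)
        else as.character(v)
      })
    }
    tag_instance(tl$label, tl$start, tl$end, attrs)
  })
  doc <- sig_document(x$doc_id, x$text, tags, source = x$source %||% "human",
                      annotator_id = x$annotator_id)
  if (!is.null(schema)) {
    rep <- validate_document(doc, schema)
    if (nrow(rep$violations))
      stop("invalid standoff document '", doc$doc_id, "': tag ",
           rep$violations$tag[1], " ", rep$violations$rule[1], " (",
           rep$violations$message[1], ")", call. = FALSE)
  }
  doc
}

#' Write and read standoff annotation files
#'
#' The standoff dialect is a JSON object
#' `{"doc_id", "text", "source", "annotator_id", "tags": [{"label",
#' "start", "end", "attributes": {...}}]}` with 0-based half-open character
#' spans; null attributes are omitted. `read_standoff` validates against
#' the registry and names the offending tag on failure; reading back a
#' written document reproduces it exactly.
#'
#' @param doc A [sig_document()].
#' @param path File path.
#' @param schema A [sig_schema()]; pass `NULL` to skip validation.
#' @return `read_standoff` returns a [sig_document()].
#' @export
write_standoff <- function(doc, path) {
  jsonlite::write_json(doc_to_list(doc), path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_standoff
#' @export
read_standoff <- function(path, schema = sig_schema()) {
  x <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  list_to_doc(x, schema)
}

#' Write and read JSONL corpora
#'
#' One standoff document per line, suitable for streaming large synthetic
#' runs.
#'
#' @param corpus List of [sig_document()].
#' @param path File path.
#' @param schema Registry used to validate on read (`NULL` skips).
#' @return `read_sig_corpus` returns a list of [sig_document()].
#' @export
write_sig_corpus <- function(corpus, path) {
  lines <- vapply(corpus, function(d)
    as.character(jsonlite::toJSON(doc_to_list(d), auto_unbox = TRUE,
                                  digits = NA, null = "null")),
    character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_sig_corpus
#' @export
read_sig_corpus <- function(path, schema = sig_schema()) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  lapply(lines, function(l)
    list_to_doc(jsonlite::fromJSON(l, simplifyVector = FALSE), schema))
}

RECORD_FIELDS <- c(
  id = "id", medication = "medication", route = "route", dose = "dose",
  doseunits = "dose_units", strength = "strength", take = "take",
  form = "form", frequency = "frequency", prn = "prn",
  prnreason = "prn_reason", duration = "duration",
  durationunits = "duration_units", dispensequantity = "dispense_quantity",
  dispensequantityunits = "dispense_quantity_units",
  directions = "directions")

RECORD_NUMERIC <- c("dose", "take", "duration", "dispense_quantity")

#' Read a prescription record table
#'
#' Reads a comma- or tab-delimited table (auto-detected from the header
#' line) whose header carries the standard prescription-record field names
#' — ID, Medication, Route, Dose, Dose Units, Strength, Take, Form,
#' Frequency, PRN, PRN Reason, Duration, Duration Units, Dispense
#' Quantity, Dispense Quantity Units, Directions — matched
#' case-insensitively and ignoring spaces/underscores. Missing columns
#' yield empty fields; a missing Directions column is an error since there
#' is then nothing to annotate.
#'
#' @param path File path.
#' @return Data frame with canonical column names, one row per record;
#'   numeric fields (`dose`, `take`, `duration`, `dispense_quantity`) are
#'   numeric, everything else character.
#' @export
read_records <- function(path) {
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = "character", quote = "\"",
                          comment.char = "")
  norm <- gsub("[^a-z]", "", tolower(names(df)))
  out <- data.frame(matrix("", nrow(df), length(RECORD_FIELDS)),
                    stringsAsFactors = FALSE)
  names(out) <- unname(RECORD_FIELDS)
  for (i in seq_along(norm)) {
    canon <- RECORD_FIELDS[norm[i]]
    if (!is.na(canon)) out[[canon]] <- df[[i]]
  }
  if (!"directions" %in% norm)
    stop("record table lacks a Directions column", call. = FALSE)
  for (col in RECORD_NUMERIC)
    out[[col]] <- suppressWarnings(as.numeric(out[[col]]))
  out
}

#' Write a prescription record table
#'
#' @param records Data frame as returned by [read_records()].
#' @param path File path; `.tsv` writes tab-separated, otherwise CSV.
#' @export
write_records <- function(records, path) {
  pretty <- c("ID", "Medication", "Route", "Dose", "Dose Units", "Strength",
              "Take", "Form", "Frequency", "PRN", "PRN Reason", "Duration",
              "Duration Units", "Dispense Quantity",
              "Dispense Quantity Units", "Directions")
  df <- records[, unname(RECORD_FIELDS), drop = FALSE]
  names(df) <- pretty
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  utils::write.table(df, path, sep = sep, row.names = FALSE, na = "",
                     qmethod = "double")
  invisible(path)
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  gsub("\"", "&quot;", x, fixed = TRUE)
}

xml_unescape <- function(x) {
  x <- gsub("&quot;", "\"", x, fixed = TRUE)
  x <- gsub("&gt;", ">", x, fixed = TRUE)
  x <- gsub("&lt;", "<", x, fixed = TRUE)
  gsub("&amp;", "&", x, fixed = TRUE)
}

render_attr_value <- function(v) {
  if (is.logical(v)) tolower(as.character(v))
  else if (is.numeric(v)) format_decimal(v)
  else as.character(v)
}

#' Export a document as inline XML
#'
#' Renders the sig text with each tag as an inline element carrying its
#' attributes — a human-inspectable view of the annotation. Tags must be
#' non-overlapping or properly nested; crossing spans are rejected with an
#' error listing the pair. Stripping the elements (see
#' [strip_inline_xml()]) recovers the original text exactly.
#'
#' @param doc A [sig_document()].
#' @return A single XML string.
#' @examples
#' d <- sig_document("d1", "take 2 tablets",
#'                   list(tag_instance("TAKE", 5, 6, list(amount = 2))))
#' export_inline_xml(d)
#' @export
export_inline_xml <- function(doc) {
  tags <- doc$tags
  if (length(tags) == 0L) return(xml_escape(doc$text))
  if (length(tags) > 1L) {
    for (i in seq_len(length(tags) - 1L)) for (j in seq(i + 1L, length(tags))) {
      a <- tags[[i]]; b <- tags[[j]]
      overlap <- a$start < b$end && b$start < a$end
      nested <- (a$start <= b$start && b$end <= a$end) ||
                (b$start <= a$start && a$end <= b$end)
      if (overlap && !nested)
        stop(sprintf(
          "crossing spans cannot be rendered inline: %s [%s,%s) x %s [%s,%s)",
          a$label, format(a$start), format(a$end),
          b$label, format(b$start), format(b$end)), call. = FALSE)
    }
  }
  # Sort by start asc, end desc so that enclosing tags open first.
  ord <- order(vapply(tags, `[[`, numeric(1), "start"),
               -vapply(tags, `[[`, numeric(1), "end"))
  tags <- tags[ord]
  opens <- vapply(tags, function(t) {
    attrs <- t$attributes[!vapply(t$attributes, is.null, logical(1))]
    a <- if (length(attrs))
      paste0(" ", paste0(names(attrs), "=\"",
                         xml_escape(vapply(attrs, render_attr_value,
                                           character(1))), "\"",
                         collapse = " "))
    else ""
    paste0("<", t$label, a, ">")
  }, character(1))
  events <- rbind(
    data.frame(pos = vapply(tags, `[[`, numeric(1), "start"),
               order_key = seq_along(tags), text = opens,
               close = FALSE, stringsAsFactors = FALSE),
    data.frame(pos = vapply(tags, `[[`, numeric(1), "end"),
               order_key = -seq_along(tags),
               text = vapply(tags, function(t) paste0("</", t$label, ">"),
                             character(1)),
               close = TRUE, stringsAsFactors = FALSE))
  # At equal positions: closes before opens; closes in reverse open order.
  events <- events[order(events$pos, !events$close,
                         ifelse(events$close, events$order_key,
                                events$order_key)), , drop = FALSE]
  out <- character(); cur <- 0
  for (k in seq_len(nrow(events))) {
    if (events$pos[k] > cur)
      out <- c(out, xml_escape(span_text(doc$text, cur, events$pos[k])))
    out <- c(out, events$text[k])
    cur <- events$pos[k]
  }
  if (cur < nchar(doc$text))
    out <- c(out, xml_escape(span_text(doc$text, cur, nchar(doc$text))))
  paste(out, collapse = "")
}

#' Strip inline XML back to plain text
#'
#' @param x Inline XML string from [export_inline_xml()].
#' @return The original sig text.
#' @export
strip_inline_xml <- function(x) {
  xml_unescape(gsub("</?[A-Za-z_][^>]*>", "", x))
}

#' Map a normalized document to a FHIR-Dosage-shaped structure
#'
#' Follows the standard correspondence: TAKE (or, failing that,
#' DOSEAMOUNT) supplies the dose quantity or range; DURATION its duration;
#' FREQ maps to `frequency`/`frequencyMax` (counts) and
#' `period`/`periodMax`/`periodUnit` (intervals); PRN to `asNeeded`;
#' INDICATION to `asNeededReason`; MEDICATION to `medicationText`; ROUTE
#' to `route`; TIMING to `timingWhen` and `timingOffset`; INSTRUCTION
#' notes are joined into `additionalInstructions`. Strength, dispense,
#' refill and substitution information — which has no Dosage home — is
#' emitted under `extensions`. Absent tags yield absent fields; two tags
#' of the same label are a conflict error (the caller resolves).
#'
#' @param doc A [sig_document()] with normalized attributes.
#' @return A list of class `fhir_dosage`, ready for
#'   `jsonlite::toJSON(auto_unbox = TRUE)`.
#' @export
to_fhir_dosage <- function(doc) {
  by_label <- split(doc$tags, vapply(doc$tags, `[[`, character(1), "label"))
  single <- function(label) {
    ts <- by_label[[label]]
    if (is.null(ts)) return(NULL)
    if (length(ts) > 1L)
      stop("conflicting ", label, " tags at spans ",
           paste(vapply(ts, function(t)
             sprintf("[%s,%s)", format(t$start), format(t$end)),
             character(1)), collapse = ", "), call. = FALSE)
    ts[[1]]
  }
  out <- list()
  take <- single("TAKE")
  dosea <- single("DOSEAMOUNT")
  doseform <- single("DOSEFORM")
  dose_src <- take %||% dosea
  if (!is.null(dose_src)) {
    unit <- if (!is.null(take)) {
      if (!is.null(doseform)) doseform$attributes$form else NULL
    } else {
      u <- single("DOSEAMOUNT_UNIT")
      if (!is.null(u)) u$attributes$unit else NULL
    }
    lo <- dose_src$attributes$amount
    hi <- dose_src$attributes$to_amount
    if (is.null(hi)) {
      out$doseQuantity <- list(value = lo)
      if (!is.null(unit)) out$doseQuantity$unit <- unit
    } else {
      out$doseRange <- list(low = lo, high = hi)
      if (!is.null(unit)) out$doseRange$unit <- unit
    }
  }
  dur <- single("DURATION")
  if (!is.null(dur)) {
    out$duration <- dur$attributes$num
    du <- single("DURATION_UNIT")
    if (!is.null(du)) out$durationUnit <- du$attributes$unit
    if (!is.null(dur$attributes$to_num))
      out$durationMax <- dur$attributes$to_num
  }
  freq <- single("FREQ")
  if (!is.null(freq)) {
    at <- freq$attributes
    out$frequency <- at$times_per
    if (!is.null(at$to_times_per)) out$frequencyMax <- at$to_times_per
    out$period <- at$every
    if (!is.null(at$to_every)) out$periodMax <- at$to_every
    out$periodUnit <- at$unit
  }
  if (!is.null(single("PRN"))) out$asNeeded <- TRUE
  ind <- single("INDICATION")
  if (!is.null(ind))
    out$asNeededReason <- span_text(doc$text, ind$start, ind$end)
  med <- single("MEDICATION")
  if (!is.null(med))
    out$medicationText <- med$attributes$name %||%
      span_text(doc$text, med$start, med$end)
  route <- single("ROUTE")
  if (!is.null(route)) out$route <- route$attributes$route
  timing <- single("TIMING")
  if (!is.null(timing)) {
    at <- timing$attributes
    when <- paste(c(at$direction, at$event), collapse = " ")
    if (nzchar(when)) out$timingWhen <- when
    if (!is.null(at$offset)) {
      out$timingOffset <- at$offset
      if (!is.null(at$offset_unit)) out$timingOffsetUnit <- at$offset_unit
    }
  }
  instr <- by_label[["INSTRUCTION"]]
  if (!is.null(instr)) {
    notes <- vapply(instr, function(t)
      t$attributes$note %||% span_text(doc$text, t$start, t$end),
      character(1))
    out$additionalInstructions <- paste(notes, collapse = "; ")
  }
  ext <- list()
  strength <- single("STRENGTH")
  if (!is.null(strength)) {
    ext$strength <- list(value = strength$attributes$amount)
    su <- single("STRENGTH_UNIT")
    if (!is.null(su)) ext$strength$unit <- su$attributes$unit
  }
  disp <- single("DISPENSE")
  if (!is.null(disp)) {
    ext$dispense <- list(quantity = disp$attributes$quantity)
    if (!is.null(disp$attributes$to_quantity))
      ext$dispense$toQuantity <- disp$attributes$to_quantity
    duu <- single("DISPENSE_UNIT")
    if (!is.null(duu)) ext$dispense$unit <- duu$attributes$unit
  }
  refill <- single("REFILL")
  if (!is.null(refill)) ext$refill <- refill$attributes$refill
  subst <- single("SUB_STATUS")
  if (!is.null(subst)) ext$substitutionAllowed <- subst$attributes$subst
  if (length(ext)) out$extensions <- ext
  structure(out, class = "fhir_dosage")
}
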