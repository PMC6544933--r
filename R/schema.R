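#' The medication-regimen annotation schema
#'
#' A sig (free-text prescription direction) is annotated with typed tags
#' drawn from a fixed inventory of 19 concept labels: quantities
#' (DISPENSE, TAKE, STRENGTH, DOSEAMOUNT, DURATION), their unit labels,
#' the drug name (MEDICATION), dose form (DOSEFORM), frequency and timing
#' of administration (FREQ, TIMING), as-needed status and its reason
#' (PRN, INDICATION), route of administration (ROUTE), refill and
#' substitution permissions (REFILL, SUB_STATUS), and a catch-all
#' INSTRUCTION label. Each label carries a set of typed attributes
#' (numeric, choice, boolean or free text) that hold the normalized
#' meaning of the tagged span; an unstated attribute is `NULL`.
#'
#' The value lists for DOSEFORM.form, ROUTE.route and the three dispensing
#' unit labels are deployment-specific; they ship with curated defaults and
#' can be replaced via `config` (only attributes marked configurable may be
#' configured). Choice lists printed in the schema itself (time units,
#' laterality, timing direction/event) are fixed.
#'
#' @param config Optional named list (or path to a YAML/JSON file) of the
#'   form `list(LABEL = list(attribute = c("value", ...)))` overriding the
#'   allowed-value list of configurable choice attributes.
#' @return An object of class `sig_schema`: a registry mapping each of the
#'   19 labels to its attribute specification.
#' @examples
#' sc <- sig_schema()
#' names(sc$labels)
#' sc$labels$FREQ$attributes$unit$allowed_values
#' @export
sig_schema <- function(config = NULL) {
  time_units <- c("minute", "hour", "day", "week", "month", "other")
  forms <- c("tablet", "capsule", "puff", "drop", "patch", "spray",
             "suppository", "ml", "application", "other")
  routes <- c("oral", "topical", "subcutaneous", "intramuscular",
              "intravenous", "inhaled", "rectal", "vaginal", "ophthalmic",
              "otic", "nasal", "transdermal", "sublingual", "other")
  units <- c("tablet", "capsule", "mg", "mcg", "g", "ml", "unit", "puff",
             "drop", "other")

  num <- function(name) list(name = name, kind = "numeric",
                             allowed_values = NULL, configurable = FALSE)
  choice <- function(name, values, configurable = FALSE)
    list(name = name, kind = "choice", allowed_values = values,
         configurable = configurable)
  freetext <- function(name) list(name = name, kind = "free_text",
                                  allowed_values = NULL, configurable = FALSE)
  boolean <- function(name) list(name = name, kind = "boolean",
                                 allowed_values = NULL, configurable = FALSE)
  spec <- function(label, description, ...) {
    attrs <- list(...)
    names(attrs) <- vapply(attrs, `[[`, character(1), "name")
    list(label = label, description = description, attributes = attrs)
  }

  labels <- list(
    spec("DISPENSE", "Quantity of medication to be issued by the pharmacist.",
         num("quantity"), num("to_quantity")),
    spec("DISPENSE_UNIT", "Unit of the dispensed quantity.",
         choice("unit", units, configurable = TRUE)),
    spec("MEDICATION", "Text specifying a specific pharmaceutical product.",
         freetext("name")),
    spec("TAKE", "Quantity of medication per application, from the patient's perspective.",
         num("amount"), num("to_amount")),
    spec("STRENGTH", "Amount of active ingredient per physical quantity of medication.",
         num("amount"), num("to_amount")),
    spec("STRENGTH_UNIT", "Unit of the strength amount.",
         choice("unit", units, configurable = TRUE)),
    spec("DOSEAMOUNT", "Amount of active ingredient per application of medication.",
         num("amount"), num("to_amount")),
    spec("DOSEAMOUNT_UNIT", "Unit of the dose amount.",
         choice("unit", units, configurable = TRUE)),
    spec("DOSEFORM", "The form of medication taken.",
         choice("form", forms, configurable = TRUE)),
    spec("DURATION", "Period of time a patient should continue using a medication.",
         num("num"), num("to_num")),
    spec("DURATION_UNIT", "Unit of the duration.",
         choice("unit", time_units)),
    spec("FREQ", "Frequency of use of a medication.",
         num("times_per"), num("to_times_per"), num("every"), num("to_every"),
         choice("unit", time_units)),
    spec("TIMING", "Temporal alignment of doses relative to life events.",
         num("offset"), num("to_offset"),
         choice("offset_unit", time_units),
         choice("direction", c("before", "after", "other")),
         choice("event", c("breakfast", "lunch", "dinner", "meals", "morning",
                           "noon", "afternoon", "evening", "bedtime",
                           "procedure", "treatment", "other"))),
    spec("PRN", "Medication to be taken only as needed."),
    spec("INDICATION", "Condition for which medication is taken."),
    spec("ROUTE", "A medication's manner or point of application to the body.",
         choice("route", routes, configurable = TRUE),
         choice("side", c("left", "right", "both"))),
    spec("REFILL", "Whether refills are allowed or not.",
         boolean("refill")),
    spec("SUB_STATUS", "Whether substitutions are allowed or not.",
         boolean("subst")),
    spec("INSTRUCTION", "Patient actions not captured by another tag.",
         freetext("note"))
  )
  names(labels) <- vapply(labels, `[[`, character(1), "label")

  registry <- structure(list(labels = labels, version = "1.0"),
                        class = "sig_schema")
  if (!is.null(config)) registry <- apply_schema_config(registry, config)
  registry
}

apply_schema_config <- function(registry, config) {
  if (is.character(config) && length(config) == 1L) {
    config <- if (grepl("\\.ya?ml$", config)) yaml::read_yaml(config)
              else jsonlite::fromJSON(config, simplifyVector = TRUE)
  }
  for (label in names(config)) {
    if (!label %in% names(registry$labels))
      stop("schema config names unknown label: ", label, call. = FALSE)
    for (attr in names(config[[label]])) {
      sp <- registry$labels[[label]]$attributes[[attr]]
      if (is.null(sp))
        stop("schema config names unknown attribute: ", label, ".", attr,
             call. = FALSE)
      if (!isTRUE(sp$configurable))
        stop("attribute ", label, ".", attr, " is not configurable",
             call. = FALSE)
      values <- as.character(unlist(config[[label]][[attr]]))
      if (length(values) == 0L)
        stop("empty value list for ", label, ".", attr, call. = FALSE)
      registry$labels[[label]]$attributes[[attr]]$allowed_values <- values
    }
  }
  registry
}

#' @export
print.sig_schema <- function(x, ...) {
  cat("<sig_schema> version", x$version, "with", length(x$labels),
      "labels\n")
  for (sp in x$labels) {
    at <- if (length(sp$attributes) == 0L) "(no attributes)" else
      paste(names(sp$attributes), collapse = ", ")
    cat(sprintf("  %-15s %s\n", sp$label, at))
  }
  invisible(x)
}

# Attribute names read from serialized annotations may use shortened
# aliases; fold them to canonical names.
ATTRIBUTE_ALIASES <- c(amt = "amount", to_amt = "to_amount")

canonical_attribute_name <- function(name) {
  ifelse(name %in% names(ATTRIBUTE_ALIASES),
         unname(ATTRIBUTE_ALIASES[name]), name)
}

#' Write or read a schema registry
#'
#' The on-disk form is a YAML/JSON document listing each label with its
#' attribute kinds and allowed values; reloading reproduces the registry
#' exactly.
#'
#' @param schema A `sig_schema` object.
#' @param path File path; `.yaml`/`.yml` writes YAML, otherwise JSON.
#' @return `read_schema` returns a `sig_schema`.
#' @export
write_schema <- function(schema, path) {
  body <- list(version = schema$version, labels = schema$labels)
  if (grepl("\\.ya?ml$", path)) yaml::write_yaml(body, path)
  else jsonlite::write_json(body, path, auto_unbox = TRUE, null = "null",
                            digits = NA)
  invisible(path)
}

#' @rdname write_schema
#' @export
read_schema <- function(path) {
  body <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
          else jsonlite::fromJSON(path, simplifyVector = FALSE)
  labels <- lapply(body$labels, function(sp) {
    attrs <- lapply(sp$attributes, function(a)
      list(name = a$name, kind = a$kind,
           allowed_values = if (is.null(a$allowed_values)) NULL
                            else as.character(unlist(a$allowed_values)),
           configurable = isTRUE(a$configurable)))
    list(label = sp$label, description = sp$description, attributes = attrs)
  })
  structure(list(labels = labels, version = body$version),
            class = "sig_schema")
}

#' Construct one annotation tag
#'
#' @param label One of the 19 schema labels.
#' @param start,end 0-based half-open character span over the document text.
#' @param attributes Named list of attribute values; unstated attributes are
#'   omitted (equivalently `NULL`).
#' @return A list of class `tag_instance`.
#' @export
tag_instance <- function(label, start, end, attributes = list()) {
  structure(list(label = label, start = as.numeric(start),
                 end = as.numeric(end),
                 attributes = attributes[!vapply(attributes, is.null,
                                                 logical(1))]),
            class = "tag_instance")
}

#' Construct a sig document
#'
#' @param doc_id Document identifier.
#' @param text The sig string.
#' @param tags List of [tag_instance()] annotations.
#' @param source Provenance: `"human"`, `"model"` or `"synthetic"`.
#' @param annotator_id Optional annotator or model identifier.
#' @return A list of class `sig_document`.
#' @export
sig_document <- function(doc_id, text, tags = list(), source = "human",
                         annotator_id = NULL) {
  structure(list(doc_id = doc_id, text = text, tags = tags, source = source,
                 annotator_id = annotator_id),
            class = "sig_document")
}

empty_violations <- function() {
  data.frame(field = character(), rule = character(), message = character(),
             stringsAsFactors = FALSE)
}

violation <- function(field, rule, message) {
  data.frame(field = field, rule = rule, message = message,
             stringsAsFactors = FALSE)
}

#' Validate one tag against the schema
#'
#' Checks the span bounds and every attribute against the label's
#' specification. Violations are returned, never raised.
#'
#' @param tag A [tag_instance()].
#' @param text_length Length of the document text in characters.
#' @param schema A [sig_schema()] registry.
#' @return A data frame of violations (`field`, `rule`, `message`); empty
#'   when the tag is valid.
#' @export
validate_tag <- function(tag, text_length, schema) {
  out <- empty_violations()
  sp <- schema$labels[[tag$label]]
  if (is.null(sp))
    return(violation("label", "known_label",
                     paste0("unknown label '", tag$label, "'")))
  if (!is_scalar_number(tag$start) || !is_scalar_number(tag$end) ||
      tag$start < 0 || tag$start >= tag$end || tag$end > text_length) {
    out <- rbind(out, violation(
      "span", "span_bounds",
      sprintf("span [%s,%s) invalid for text of length %d",
              format(tag$start), format(tag$end), text_length)))
  }
  for (name in names(tag$attributes)) {
    cname <- canonical_attribute_name(name)
    aspec <- sp$attributes[[cname]]
    value <- tag$attributes[[name]]
    if (is.null(aspec)) {
      out <- rbind(out, violation(
        name, "known_attribute",
        paste0(tag$label, " has no attribute '", name, "'")))
      next
    }
    if (is.null(value)) next
    bad <- switch(aspec$kind,
      numeric = if (!is_scalar_number(value) || value < 0)
        "numeric attribute must be a non-negative number",
      choice = if (!is.character(value) || length(value) != 1L ||
                   !value %in% aspec$allowed_values)
        paste0("value '", paste(value, collapse = ","),
               "' not in {", paste(aspec$allowed_values, collapse = ", "), "}"),
      boolean = if (!is.logical(value) || length(value) != 1L || is.na(value))
        "boolean attribute must be TRUE or FALSE",
      free_text = if (!is.character(value) || length(value) != 1L)
        "free-text attribute must be a single string")
    if (!is.null(bad))
      out <- rbind(out, violation(name, paste0(aspec$kind, "_value"), bad))
  }
  out
}

#' Validate a whole document
#'
#' Aggregates [validate_tag()] over all tags and additionally reports
#' overlapping same-label spans as warnings (the schema permits a span to
#' carry two different labels; same-label overlap is usually an annotation
#' slip but not an error).
#'
#' @param doc A [sig_document()].
#' @param schema A [sig_schema()] registry.
#' @return A list with `violations` (data frame with a `tag` index column)
#'   and `warnings` (character vector).
#' @export
validate_document <- function(doc, schema) {
  n <- nchar(doc$text)
  violations <- empty_violations()
  violations$tag <- integer()
  for (i in seq_along(doc$tags)) {
    v <- validate_tag(doc$tags[[i]], n, schema)
    if (nrow(v)) {
      v$tag <- i
      violations <- rbind(violations, v)
    }
  }
  warnings <- character()
  if (length(doc$tags) > 1L) {
    for (i in seq_len(length(doc$tags) - 1L)) {
      for (j in seq(i + 1L, length(doc$tags))) {
        a <- doc$tags[[i]]; b <- doc$tags[[j]]
        if (a$label == b$label && a$start < b$end && b$start < a$end)
          warnings <- c(warnings, sprintf(
            "overlapping %s spans: [%s,%s) and [%s,%s)", a$label,
            format(a$start), format(a$end), format(b$start), format(b$end)))
      }
    }
  }
  list(violations = violations, warnings = warnings)
}

# All (label, attribute) pairs in a registry, as a data frame.
schema_attribute_index <- function(schema) {
  rows <- lapply(schema$labels, function(sp) {
    if (length(sp$attributes) == 0L) return(NULL)
    data.frame(label = sp$label, attribute = names(sp$attributes),
               kind = vapply(sp$attributes, `[[`, character(1), "kind"),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

# Numeric attribute names (value, to_value) for the pure-numeric labels.
numeric_attribute_names <- function(label) {
  switch(label,
         DISPENSE = c("quantity", "to_quantity"),
         TAKE = , STRENGTH = , DOSEAMOUNT = c("amount", "to_amount"),
         DURATION = c("num", "to_num"),
         stop("label ", label, " has no pure numeric attribute pair"))
}
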