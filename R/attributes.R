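# Attribute normalization: per-attribute predictors (baseline, literal
# match, Levenshtein fallback, maximum-entropy classifier) plus the hybrid
# normalizers for the complex FREQ and TIMING tags and direct numeric
# mapping for the quantity tags.

#' Levenshtein edit distance
#'
#' Unit-cost insert/delete/substitute distance between two strings,
#' used by the Levenshtein-fallback attribute method.
#'
#' @param a,b Character vectors (recycled).
#' @return Integer vector of distances.
#' @examples
#' edit_distance("kitten", "sitting")
#' @export
edit_distance <- function(a, b) {
  as.integer(diag(utils::adist(a, b, costs = 1)))
}

# The closed set of numeric attribute values the classifier method is
# allowed to emit: counts 1-12 plus the clock-friendly 15, 30, 45, 60.
VALID_NUMERIC_SET <- c(1:12, 15, 30, 45, 60)

#' Snap a number to the valid numeric attribute set
#'
#' Returns the member of \{1..12, 15, 30, 45, 60\} nearest to `v`; ties go
#' to the smaller member.
#'
#' @param v Numeric vector.
#' @return Numeric vector of snapped values.
#' @export
snap_valid_numeric <- function(v) {
  vapply(v, function(x) {
    d <- abs(VALID_NUMERIC_SET - x)
    VALID_NUMERIC_SET[which.min(d)]   # set is ascending, so ties -> smaller
  }, numeric(1))
}

#' Build the feature context for a tagged span
#'
#' The context carries the retokenized span text, its lowercased tokens,
#' up to three flanking tokens on each side (taken from the surrounding
#' document when a full document and span are supplied), and the count of
#' number expressions inside the span.
#'
#' @param text Either the span text itself, or the full document text when
#'   `start`/`end` are given.
#' @param start,end Optional 0-based half-open span into `text`.
#' @param flank Number of flanking tokens kept on each side.
#' @return An object of class `span_context`.
#' @export
span_context <- function(text, start = NULL, end = NULL, flank = 3L) {
  if (is.null(start)) {
    surface <- text
    left <- character(); right <- character()
  } else {
    surface <- span_text(text, start, end)
    toks <- sig_tokenize(text)
    lt <- toks$surface[toks$end <= start]
    rt <- toks$surface[toks$start >= end]
    left <- tolower(utils::tail(lt, flank))
    right <- tolower(utils::head(rt, flank))
  }
  nt <- canonicalize_numbers(surface)
  structure(list(
    surface = surface,
    text = nt$text,
    tokens = tolower(sig_tokenize(nt$text)$surface),
    left = left, right = right,
    num_count = nrow(nt$numbers),
    numbers = nt$numbers),
    class = "span_context")
}

as_span_context <- function(x) {
  if (inherits(x, "span_context")) x else span_context(x)
}

# ---- generic attribute predictors -----------------------------------------

context_feature_strings <- function(ctx, use_numcount = FALSE) {
  toks <- ctx$tokens
  feats <- character()
  if (length(toks)) feats <- paste0("u_", toks)
  if (length(toks) > 1L)
    feats <- c(feats, paste0("b_", toks[-length(toks)], "_", toks[-1]))
  if (length(ctx$left)) feats <- c(feats, paste0("l_", ctx$left))
  if (length(ctx$right)) feats <- c(feats, paste0("r_", ctx$right))
  if (use_numcount) feats <- c(feats, paste0("nc_", ctx$num_count))
  unique(feats)
}

NULL_CLASS <- "<null>"

encode_class_values <- function(values) {
  vapply(values, function(v) {
    if (is.null(v) || (length(v) == 1L && is.na(v))) NULL_CLASS
    else if (is.logical(v)) as.character(v)
    else if (is.numeric(v)) format_decimal(v)
    else as.character(v)
  }, character(1))
}

fit_maxent <- function(contexts, classes, use_numcount = FALSE, seed = 1L) {
  classes <- as.character(classes)
  feat_sets <- lapply(contexts, context_feature_strings,
                      use_numcount = use_numcount)
  vocab <- sort(unique(unlist(feat_sets)))
  if (length(unique(classes)) < 2L || length(vocab) == 0L) {
    return(list(kind = "constant", value = majority_value(classes)))
  }
  X <- matrix(0, length(contexts), length(vocab),
              dimnames = list(NULL, vocab))
  for (i in seq_along(feat_sets)) X[i, feat_sets[[i]]] <- 1
  df <- as.data.frame(X)
  names(df) <- paste0("f", seq_along(vocab))
  df$.cls <- factor(classes)
  fit <- with_seed(seed, nnet::multinom(
    .cls ~ ., data = df, trace = FALSE, maxit = 300,
    MaxNWts = (length(vocab) + 2L) * nlevels(df$.cls) + 10L,
    decay = 1e-4))
  list(kind = "multinom", fit = fit, vocab = vocab,
       use_numcount = use_numcount, levels = levels(df$.cls))
}

predict_maxent <- function(model, ctx) {
  if (model$kind == "constant") return(model$value)
  feats <- context_feature_strings(ctx, use_numcount = model$use_numcount)
  x <- matrix(0, 1, length(model$vocab),
              dimnames = list(NULL, model$vocab))
  x[1, intersect(feats, model$vocab)] <- 1
  df <- as.data.frame(x)
  names(df) <- paste0("f", seq_along(model$vocab))
  as.character(stats::predict(model$fit, newdata = df))
}

#' Fit a single-attribute predictor
#'
#' Four methods are available. `baseline` always predicts the most common
#' training value. `literal` memorizes the mapping from (case-folded,
#' whitespace-collapsed) span text to its most common training value and,
#' for unseen spans, falls back to an exact match against the allowed
#' values, then to the training majority. `levenshtein` behaves like
#' `literal` on training-seen spans but resolves unseen spans to the
#' allowed value at minimal edit distance (ties to the more frequent
#' training value, then lexicographic). `classifier` fits a multinomial
#' maximum-entropy model over span bag-of-words and bigram features (plus
#' flanking tokens and, optionally, the number-expression count).
#'
#' @param spans Character vector of span texts (or list of
#'   [span_context()]s for the classifier method).
#' @param values Training values, parallel to `spans`; `NA`/`NULL` entries
#'   are dropped.
#' @param method One of `"baseline"`, `"literal"`, `"levenshtein"`,
#'   `"classifier"`.
#' @param allowed_values Choice list used by the fallback rules.
#' @param use_numcount Add the number-expression count feature
#'   (classifier method).
#' @param seed RNG seed for classifier fitting.
#' @param target Optional `list(label =, attribute =)` bookkeeping.
#' @return An object of class `attribute_predictor`.
#' @export
fit_attribute_predictor <- function(spans, values,
                                    method = c("levenshtein", "literal",
                                               "baseline", "classifier"),
                                    allowed_values = NULL,
                                    use_numcount = FALSE, seed = 1L,
                                    target = NULL) {
  method <- match.arg(method)
  if (is.list(values)) values <- encode_class_values(values)
  values <- as.character(values)
  value_type <- if (all(values %in% c("TRUE", "FALSE", NA))) "logical"
                else "character"
  keep <- !is.na(values) & values != NULL_CLASS
  if (!any(keep)) stop("no non-null training values", call. = FALSE)
  contexts <- NULL
  if (is.list(spans) && length(spans) && inherits(spans[[1]], "span_context")) {
    contexts <- spans[keep]
    spans <- vapply(contexts, `[[`, character(1), "surface")
  } else {
    spans <- as.character(spans)[keep]
  }
  values <- values[keep]

  obj <- list(method = method, target = target, value_type = value_type,
              allowed_values = allowed_values,
              majority = majority_value(values),
              value_freq = table(values))
  if (method %in% c("literal", "levenshtein")) {
    keys <- fold_key(spans)
    tab <- tapply(values, keys, majority_value)
    obj$table <- stats::setNames(as.character(tab), names(tab))
  } else if (method == "classifier") {
    if (is.null(contexts)) contexts <- lapply(spans, span_context)
    obj$model <- fit_maxent(contexts, values, use_numcount = use_numcount,
                            seed = seed)
  }
  structure(obj, class = "attribute_predictor")
}

#' Predict attribute values for new spans
#'
#' @param object An `attribute_predictor`.
#' @param newdata Character vector of span texts or list of
#'   [span_context()]s.
#' @param ... Unused.
#' @return Vector of predicted values (logical for boolean attributes).
#' @export
predict.attribute_predictor <- function(object, newdata, ...) {
  if (inherits(newdata, "span_context")) newdata <- list(newdata)
  if (!is.list(newdata)) newdata <- as.list(as.character(newdata))
  out <- vapply(newdata, function(x) predict_one_attribute(object, x),
                character(1))
  if (object$value_type == "logical") as.logical(out) else out
}

predict_one_attribute <- function(object, x) {
  ctx <- if (inherits(x, "span_context")) x else NULL
  span <- if (is.null(ctx)) x else ctx$surface
  key <- fold_key(span)
  switch(object$method,
    baseline = object$majority,
    literal = {
      hit <- object$table[key]
      if (!is.na(hit)) return(unname(hit))
      if (!is.null(object$allowed_values) && key %in% object$allowed_values)
        return(key)
      object$majority
    },
    levenshtein = {
      hit <- object$table[key]
      if (!is.na(hit)) return(unname(hit))
      cand <- object$allowed_values %||% names(object$value_freq)
      d <- edit_distance(rep(key, length(cand)), cand)
      best <- cand[d == min(d)]
      if (length(best) > 1L) {
        fr <- as.numeric(object$value_freq[best])
        fr[is.na(fr)] <- 0
        best <- best[fr == max(fr)]
      }
      sort(best)[1]
    },
    classifier = {
      if (is.null(ctx)) ctx <- span_context(span)
      predict_maxent(object$model, ctx)
    })
}

# ---- FREQ / TIMING lexicons ------------------------------------------------

TIME_UNIT_LEXICON <- c(
  minute = "minute", minutes = "minute", min = "minute", mins = "minute",
  hour = "hour", hours = "hour", hr = "hour", hrs = "hour", h = "hour",
  day = "day", days = "day", daily = "day", nightly = "day",
  week = "week", weeks = "week", weekly = "week", wk = "week",
  month = "month", months = "month", monthly = "month", mo = "month")

# Frequency idioms: spans that carry counts or intervals without digits.
# Dotted clinical abbreviations are folded to their letters before lookup.
FREQ_IDIOMS <- list(
  once   = list(count = 1),
  twice  = list(count = 2),
  thrice = list(count = 3),
  qd     = list(count = 1, unit = "day"),
  qhs    = list(count = 1, unit = "day"),
  qam    = list(count = 1, unit = "day"),
  qpm    = list(count = 1, unit = "day"),
  bid    = list(count = 2, unit = "day"),
  tid    = list(count = 3, unit = "day"),
  qid    = list(count = 4, unit = "day"),
  qod    = list(every = 2, unit = "day"),
  qwk    = list(count = 1, unit = "week"),
  daily  = list(unit = "day"),
  nightly = list(unit = "day"),
  weekly = list(unit = "week"),
  monthly = list(unit = "month"),
  hourly = list(unit = "hour"))

# Collapse dotted abbreviations: tokens of "b.i.d." -> "bid".
collapse_dotted <- function(tokens) {
  out <- character(); buf <- character()
  for (t in tokens) {
    if (t == ".") next
    if (nchar(t) == 1L && grepl("^[a-z]$", t)) { buf <- c(buf, t); next }
    if (length(buf)) { out <- c(out, paste(buf, collapse = "")); buf <- character() }
    out <- c(out, t)
  }
  if (length(buf)) out <- c(out, paste(buf, collapse = ""))
  out
}

freq_idiom_hits <- function(tokens) {
  toks <- collapse_dotted(tokens)
  hits <- FREQ_IDIOMS[intersect(toks, names(FREQ_IDIOMS))]
  res <- list(count = NULL, every = NULL, unit = NULL)
  for (h in hits) for (k in names(h)) if (is.null(res[[k]])) res[[k]] <- h[[k]]
  if (any(toks == "every") && any(toks == "other") && is.null(res$every))
    res$every <- 2
  res
}

span_unit <- function(tokens) {
  toks <- collapse_dotted(tokens)
  hit <- TIME_UNIT_LEXICON[intersect(toks, names(TIME_UNIT_LEXICON))]
  if (length(hit)) unname(hit[1]) else NULL
}

span_numbers <- function(ctx) {
  ctx$numbers$value
}

# Rule used when no trained classifier is supplied, and as the source of
# the interval-vs-count training labels: an explicit "every"/"q<N>h" marks
# an interval phrase, anything else is a count phrase.
freq_phrase_type_rule <- function(tokens) {
  toks <- collapse_dotted(tokens)
  if (any(toks == "every") || any(grepl("^q[0-9]*h$", toks)) ||
      any(toks == "qod")) "interval" else "count"
}

#' Fit the FREQ attribute normalizer
#'
#' `baseline` memorizes the most common unit and always emits the default
#' numeric values `times_per = 1`, `every = 1` (ranges null). `hybrid`
#' fits maximum-entropy classifiers — over bag-of-words, bigrams and the
#' number-expression count — for the unit and for whether the phrase is an
#' interval ("every N units") or a count ("N times per unit"), then maps
#' the numbers left-to-right from the retokenized span. `classifier` adds
#' one classifier per numeric attribute whose output is snapped to the
#' valid numeric set \{1..12, 15, 30, 45, 60\}.
#'
#' @param contexts List of [span_context()] for gold FREQ spans.
#' @param maps List of gold attribute maps (`times_per`, `to_times_per`,
#'   `every`, `to_every`, `unit`).
#' @param method `"hybrid"`, `"classifier"` or `"baseline"`.
#' @param seed RNG seed for classifier fitting.
#' @return An object of class `freq_normalizer`.
#' @export
fit_freq_normalizer <- function(contexts, maps,
                                method = c("hybrid", "classifier", "baseline"),
                                seed = 1L) {
  method <- match.arg(method)
  contexts <- lapply(contexts, as_span_context)
  units <- vapply(maps, function(m) m$unit %||% NULL_CLASS, character(1))
  obj <- list(method = method, baseline_unit = majority_value(
    units[units != NULL_CLASS]))
  if (method %in% c("hybrid", "classifier")) {
    types <- vapply(maps, function(m) {
      if ((m$every %||% 1) > 1 || !is.null(m$to_every)) "interval" else "count"
    }, character(1))
    obj$unit_clf <- fit_maxent(contexts, units, use_numcount = TRUE,
                               seed = seed)
    obj$type_clf <- fit_maxent(contexts, types, use_numcount = TRUE,
                               seed = seed + 1L)
  }
  if (method == "classifier") {
    obj$num_clfs <- lapply(stats::setNames(nm = c("times_per", "to_times_per",
                                                  "every", "to_every")),
      function(a) {
        vals <- encode_class_values(lapply(maps, `[[`, a))
        fit_maxent(contexts, vals, use_numcount = TRUE, seed = seed + 2L)
      })
  }
  structure(obj, class = "freq_normalizer")
}

#' Normalize a FREQ span to its attribute map
#'
#' With a fitted model, categorical decisions (unit; interval vs count)
#' come from its classifiers; without one, deterministic lexicon rules are
#' used (an explicit "every" marks an interval phrase; the unit comes from
#' a time-word lexicon). Numbers are read left-to-right from the
#' retokenized span: a count phrase fills `times_per` (and `to_times_per`
#' for a range) with `every = 1`; an interval phrase fills `every` (and
#' `to_every`) with `times_per = 1`. Digit-free idioms (once, twice, TID,
#' b.i.d., "every other day") are resolved by a configurable lexicon.
#'
#' @param context A [span_context()] or span string for a FREQ region.
#' @param model Optional [fit_freq_normalizer()] result.
#' @return Named list: `times_per`, `to_times_per`, `every`, `to_every`,
#'   `unit` (unstated entries `NULL`).
#' @examples
#' normalize_freq("2-3 times per day")
#' normalize_freq("every 4-6 hours")
#' @export
normalize_freq <- function(context, model = NULL) {
  ctx <- as_span_context(context)
  if (!is.null(model) && model$method == "baseline") {
    return(list(times_per = 1, to_times_per = NULL, every = 1,
                to_every = NULL, unit = model$baseline_unit))
  }
  idiom <- freq_idiom_hits(ctx$tokens)
  nums <- span_numbers(ctx)
  unit <- NULL; type <- NULL
  if (!is.null(model)) {
    u <- predict_maxent(model$unit_clf, ctx)
    if (u != NULL_CLASS) unit <- u
    type <- predict_maxent(model$type_clf, ctx)
  }
  if (is.null(unit)) unit <- span_unit(ctx$tokens) %||% idiom$unit
  if (is.null(type))
    type <- if (!is.null(idiom$every)) "interval"
            else freq_phrase_type_rule(ctx$tokens)
  out <- list(times_per = 1, to_times_per = NULL, every = 1,
              to_every = NULL, unit = unit)
  if (!is.null(model) && model$method == "classifier" &&
      !is.null(model$num_clfs)) {
    for (a in names(model$num_clfs)) {
      v <- predict_maxent(model$num_clfs[[a]], ctx)
      out[[a]] <- if (v == NULL_CLASS) {
        if (a %in% c("times_per", "every")) 1 else NULL
      } else snap_valid_numeric(as.numeric(v))
    }
    return(out)
  }
  if (type == "interval") {
    out$every <- if (length(nums) >= 1) nums[1] else idiom$every %||% 1
    if (length(nums) >= 2) out$to_every <- nums[2]
  } else {
    out$times_per <- if (length(nums) >= 1) nums[1] else idiom$count %||% 1
    if (length(nums) >= 2) out$to_times_per <- nums[2]
    if (!is.null(idiom$every)) out$every <- idiom$every
  }
  out
}

TIMING_DIRECTION_LEXICON <- c(before = "before", prior = "before",
                              after = "after", following = "after",
                              post = "after", with = "other",
                              during = "other")

TIMING_EVENT_LEXICON <- c(
  breakfast = "breakfast", lunch = "lunch", dinner = "dinner",
  supper = "dinner", meal = "meals", meals = "meals", food = "meals",
  morning = "morning", noon = "noon", afternoon = "afternoon",
  evening = "evening", night = "evening", bedtime = "bedtime",
  bed = "bedtime", hs = "bedtime", procedure = "procedure",
  surgery = "procedure", treatment = "treatment")

#' Fit the TIMING attribute normalizer
#'
#' Same architecture as [fit_freq_normalizer()]: `hybrid` fits classifiers
#' for `direction`, `event` and `offset_unit` and maps the numeric
#' attributes directly from the retokenized span; `classifier` adds
#' numeric-attribute classifiers snapped to the valid numeric set;
#' `baseline` memorizes the most common value of every attribute.
#'
#' @inheritParams fit_freq_normalizer
#' @param maps Gold TIMING attribute maps (`offset`, `to_offset`,
#'   `offset_unit`, `direction`, `event`).
#' @return An object of class `timing_normalizer`.
#' @export
fit_timing_normalizer <- function(contexts, maps,
                                  method = c("hybrid", "classifier",
                                             "baseline"),
                                  seed = 1L) {
  method <- match.arg(method)
  contexts <- lapply(contexts, as_span_context)
  col <- function(a) vapply(maps, function(m) {
    v <- m[[a]]
    if (is.null(v)) NULL_CLASS else as.character(v)
  }, character(1))
  obj <- list(method = method,
              baseline = lapply(stats::setNames(nm = c("direction", "event",
                                                       "offset_unit")),
                                function(a) {
                                  v <- col(a)
                                  v <- v[v != NULL_CLASS]
                                  if (length(v)) majority_value(v) else NULL
                                }),
              baseline_offset = {
                v <- vapply(maps, function(m) m$offset %||% NA_real_,
                            numeric(1))
                if (all(is.na(v))) NULL else
                  as.numeric(majority_value(format_decimal(v[!is.na(v)])))
              })
  if (method %in% c("hybrid", "classifier")) {
    obj$clfs <- lapply(stats::setNames(nm = c("direction", "event",
                                              "offset_unit")),
      function(a) fit_maxent(contexts, col(a), use_numcount = TRUE,
                             seed = seed))
  }
  if (method == "classifier") {
    obj$num_clfs <- lapply(stats::setNames(nm = c("offset", "to_offset")),
      function(a) {
        vals <- encode_class_values(lapply(maps, `[[`, a))
        fit_maxent(contexts, vals, use_numcount = TRUE, seed = seed + 1L)
      })
  }
  structure(obj, class = "timing_normalizer")
}

#' Normalize a TIMING span to its attribute map
#'
#' `offset`/`to_offset` are the first and second number expressions in the
#' retokenized span (null when absent). `direction`, `event` and
#' `offset_unit` come from the fitted classifiers when a model is given,
#' otherwise from lexicons; a bare event phrase ("at bedtime") gets a null
#' direction, since the schema treats unstated attributes as null.
#'
#' @param context A [span_context()] or span string for a TIMING region.
#' @param model Optional [fit_timing_normalizer()] result.
#' @return Named list: `offset`, `to_offset`, `offset_unit`, `direction`,
#'   `event`.
#' @examples
#' normalize_timing("1 hour after meals")
#' @export
normalize_timing <- function(context, model = NULL) {
  ctx <- as_span_context(context)
  nums <- span_numbers(ctx)
  if (!is.null(model) && model$method == "baseline") {
    return(list(offset = model$baseline_offset, to_offset = NULL,
                offset_unit = model$baseline$offset_unit,
                direction = model$baseline$direction,
                event = model$baseline$event))
  }
  out <- list(offset = if (length(nums) >= 1) nums[1] else NULL,
              to_offset = if (length(nums) >= 2) nums[2] else NULL,
              offset_unit = NULL, direction = NULL, event = NULL)
  if (!is.null(model) && !is.null(model$clfs)) {
    for (a in names(model$clfs)) {
      v <- predict_maxent(model$clfs[[a]], ctx)
      if (v != NULL_CLASS) out[[a]] <- v
    }
  } else {
    toks <- collapse_dotted(ctx$tokens)
    d <- TIMING_DIRECTION_LEXICON[intersect(toks,
                                            names(TIMING_DIRECTION_LEXICON))]
    if (length(d)) out$direction <- unname(d[1])
    e <- TIMING_EVENT_LEXICON[intersect(toks, names(TIMING_EVENT_LEXICON))]
    if (length(e)) out$event <- unname(e[1])
    out$offset_unit <- span_unit(ctx$tokens)
  }
  if (!is.null(model) && model$method == "classifier" &&
      !is.null(model$num_clfs)) {
    for (a in names(model$num_clfs)) {
      v <- predict_maxent(model$num_clfs[[a]], ctx)
      out[[a]] <- if (v == NULL_CLASS) NULL else
        snap_valid_numeric(as.numeric(v))
    }
  }
  out
}

#' Map a numeric-attribute span to its value(s)
#'
#' In `normalized` mode the span is passed through the numeric retokenizer
#' and the first (and, for ranges, second) number expression fills the
#' value pair; in `unnormalized` mode the verbatim surface string is the
#' value.
#'
#' @param span Span text of a DISPENSE/TAKE/STRENGTH/DOSEAMOUNT/DURATION
#'   region.
#' @param mode `"normalized"` or `"unnormalized"`.
#' @return `list(value =, to_value =)`; in unnormalized mode `value` is the
#'   surface string. A normalized span with no number expression yields a
#'   null value with a warning.
#' @examples
#' map_numeric("three")                 # value 3
#' map_numeric("2-3")                   # value 2, to_value 3
#' @export
map_numeric <- function(span, mode = c("normalized", "unnormalized")) {
  mode <- match.arg(mode)
  if (mode == "unnormalized") return(list(value = span, to_value = NULL))
  nums <- find_number_expressions(span)
  if (nrow(nums) == 0L) {
    warning("no number expression in numeric span '", span, "'",
            call. = FALSE)
    return(list(value = NULL, to_value = NULL))
  }
  list(value = nums$value[1],
       to_value = if (nrow(nums) >= 2) nums$value[2] else NULL)
}

# ---- whole-document normalization -----------------------------------------

CHOICE_TARGETS <- list(
  DISPENSE_UNIT = "unit", DOSEAMOUNT_UNIT = "unit", STRENGTH_UNIT = "unit",
  DURATION_UNIT = "unit", DOSEFORM = "form", ROUTE = "route")

BOOLEAN_TARGETS <- list(REFILL = "refill", SUB_STATUS = "subst")

NUMERIC_LABELS <- c("DISPENSE", "TAKE", "STRENGTH", "DOSEAMOUNT", "DURATION")

# Route surfaces that defeat edit distance; consulted by the model-free
# rule path only.
ROUTE_SURFACE_ALIASES <- c(
  "po" = "oral", "by mouth" = "oral", "orally" = "oral", "mouth" = "oral",
  "topically" = "topical", "on the skin" = "topical",
  "under the tongue" = "sublingual", "sl" = "sublingual",
  "in each nostril" = "nasal", "per rectum" = "rectal",
  "in the eye" = "ophthalmic", "in the ear" = "otic")

#' Train the full attribute-model bundle on an annotated corpus
#'
#' Fits one predictor per choice and boolean attribute plus the FREQ and
#' TIMING normalizers, using each tag's gold attributes as training values
#' and the tag span (with flanking document context) as input.
#'
#' @param corpus List of [sig_document()] with gold, attribute-bearing tags.
#' @param schema A [sig_schema()] registry.
#' @param choice_method,boolean_method Method for choice/boolean
#'   attributes (see [fit_attribute_predictor()]).
#' @param freq_method,timing_method Method for the complex tags (see
#'   [fit_freq_normalizer()]).
#' @param seed RNG seed for classifier fitting.
#' @return An object of class `attribute_models`.
#' @export
fit_attribute_models <- function(corpus, schema,
                                 choice_method = "levenshtein",
                                 boolean_method = "classifier",
                                 freq_method = "hybrid",
                                 timing_method = "hybrid", seed = 1L) {
  harvest <- function(label) {
    ctxs <- list(); attrs <- list()
    for (doc in corpus) for (t in doc$tags) if (t$label == label) {
      ctxs[[length(ctxs) + 1L]] <- span_context(doc$text, t$start, t$end)
      attrs[[length(attrs) + 1L]] <- t$attributes
    }
    list(contexts = ctxs, attrs = attrs)
  }
  models <- list(schema = schema, choice = list(), boolean = list())
  for (label in names(CHOICE_TARGETS)) {
    attr <- CHOICE_TARGETS[[label]]
    h <- harvest(label)
    vals <- lapply(h$attrs, `[[`, attr)
    keep <- !vapply(vals, is.null, logical(1))
    if (!any(keep)) next
    allowed <- schema$labels[[label]]$attributes[[attr]]$allowed_values
    models$choice[[label]] <- fit_attribute_predictor(
      h$contexts[keep], vals[keep], method = choice_method,
      allowed_values = allowed, seed = seed,
      target = list(label = label, attribute = attr))
    if (label == "ROUTE") {
      sides <- lapply(h$attrs, `[[`, "side")
      skeep <- !vapply(sides, is.null, logical(1))
      if (any(skeep))
        models$route_side <- fit_attribute_predictor(
          h$contexts[skeep], sides[skeep], method = choice_method,
          allowed_values = c("left", "right", "both"), seed = seed,
          target = list(label = "ROUTE", attribute = "side"))
    }
  }
  for (label in names(BOOLEAN_TARGETS)) {
    attr <- BOOLEAN_TARGETS[[label]]
    h <- harvest(label)
    vals <- lapply(h$attrs, `[[`, attr)
    keep <- !vapply(vals, is.null, logical(1))
    if (!any(keep)) next
    models$boolean[[label]] <- fit_attribute_predictor(
      h$contexts[keep], vals[keep], method = boolean_method, seed = seed,
      target = list(label = label, attribute = attr))
  }
  hf <- harvest("FREQ")
  if (length(hf$contexts))
    models$freq <- fit_freq_normalizer(hf$contexts, hf$attrs,
                                       method = freq_method, seed = seed)
  ht <- harvest("TIMING")
  if (length(ht$contexts))
    models$timing <- fit_timing_normalizer(ht$contexts, ht$attrs,
                                           method = timing_method,
                                           seed = seed)
  structure(models, class = "attribute_models")
}

# Rule-only choice normalization used when no trained bundle is supplied.
rule_choice_value <- function(label, attr, span, schema) {
  allowed <- schema$labels[[label]]$attributes[[attr]]$allowed_values
  key <- fold_key(span)
  if (label == "ROUTE" && key %in% names(ROUTE_SURFACE_ALIASES))
    return(unname(ROUTE_SURFACE_ALIASES[key]))
  if (attr %in% c("unit", "form")) key <- sub("\\(s\\)$", "", sub("s$", "", key))
  if (key %in% allowed) return(key)
  d <- edit_distance(rep(key, length(allowed)), allowed)
  allowed[which.min(d)]
}

#' Fill normalized attributes on a document's tags
#'
#' Applies the attribute models (or, when `models` is `NULL`, the
#' deterministic lexicon/edit-distance rules) to every tag: numeric labels
#' through [map_numeric()], FREQ and TIMING through their normalizers,
#' choice and boolean attributes through their predictors, and the
#' free-text attributes default to the span text.
#'
#' @param doc A [sig_document()] (tags may have empty attribute maps, e.g.
#'   straight from [tag_sig()]).
#' @param schema A [sig_schema()] registry.
#' @param models Optional [fit_attribute_models()] bundle.
#' @param numeric_mode Passed to [map_numeric()].
#' @return The document with attribute maps populated.
#' @export
normalize_document <- function(doc, schema, models = NULL,
                               numeric_mode = "normalized") {
  doc$tags <- lapply(doc$tags, function(t) {
    ctx <- span_context(doc$text, t$start, t$end)
    span <- ctx$surface
    if (t$label %in% NUMERIC_LABELS) {
      v <- suppressWarnings(map_numeric(span, numeric_mode))
      nm <- numeric_attribute_names(t$label)
      t$attributes <- stats::setNames(list(v$value, v$to_value), nm)
    } else if (t$label == "FREQ") {
      t$attributes <- normalize_freq(ctx, models$freq)
    } else if (t$label == "TIMING") {
      t$attributes <- normalize_timing(ctx, models$timing)
    } else if (t$label %in% names(CHOICE_TARGETS)) {
      attr <- CHOICE_TARGETS[[t$label]]
      val <- if (!is.null(models$choice[[t$label]]))
        predict(models$choice[[t$label]], list(ctx))
      else rule_choice_value(t$label, attr, span, schema)
      t$attributes[[attr]] <- val
      if (t$label == "ROUTE") {
        toks <- ctx$tokens
        side <- if (any(toks == "both")) "both"
                else if (any(toks == "left")) "left"
                else if (any(toks == "right")) "right" else NULL
        if (!is.null(models$route_side) &&
            any(toks %in% c("left", "right", "both")))
          side <- predict(models$route_side, list(ctx))
        if (!is.null(side)) t$attributes$side <- side
      }
    } else if (t$label %in% names(BOOLEAN_TARGETS)) {
      attr <- BOOLEAN_TARGETS[[t$label]]
      val <- if (!is.null(models$boolean[[t$label]]))
        predict(models$boolean[[t$label]], list(ctx))
      else !any(ctx$tokens %in% c("no", "not", "none", "without", "written"))
      t$attributes[[attr]] <- val
    } else if (t$label == "MEDICATION") {
      t$attributes$name <- span
    } else if (t$label == "INSTRUCTION") {
      t$attributes$note <- span
    }
    t$attributes <- t$attributes[!vapply(t$attributes, is.null, logical(1))]
    t
  })
  doc
}
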