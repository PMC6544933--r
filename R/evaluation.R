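# Scoring: exact span+label precision/recall/F, pairwise inter-annotator
# agreement, attribute accuracy on gold spans, and deterministic corpus
# splitting.

prf_row <- function(tp, fp, fn) {
  # Convention: precision is 1 when nothing spurious was hypothesized
  # (FP = 0) and recall is 1 when nothing was missed (FN = 0); F is 0 when
  # P + R = 0. This reproduces the familiar P = 1.000 / R = 0.000 shape for
  # labels a model never predicts.
  tp <- unname(tp); fp <- unname(fp); fn <- unname(fn)
  p <- if (tp + fp == 0) 1 else tp / (tp + fp)
  r <- if (tp + fn == 0) 1 else tp / (tp + fn)
  f <- if (p + r == 0) 0 else 2 * p * r / (p + r)
  c(precision = p, recall = r, f = f)
}

tag_keys <- function(doc) {
  if (length(doc$tags) == 0L) return(character())
  vapply(doc$tags, function(t)
    paste(t$label, format(t$start), format(t$end), sep = "|"), character(1))
}

#' Score predicted spans against a reference
#'
#' Matching is exact on (start, end, label), one-to-one with multiplicity,
#' per document. Reports per-label and micro-averaged overall precision,
#' recall and F-measure.
#'
#' @param reference,hypothesis Lists of [sig_document()] covering the same
#'   `doc_id`s.
#' @return An object of class `prf_report`: list with `per_label` (data
#'   frame of counts and scores) and `overall`.
#' @export
score_spans <- function(reference, hypothesis) {
  ref_ids <- vapply(reference, `[[`, character(1), "doc_id")
  hyp_ids <- vapply(hypothesis, `[[`, character(1), "doc_id")
  if (!setequal(ref_ids, hyp_ids) || anyDuplicated(ref_ids) ||
      anyDuplicated(hyp_ids))
    stop("reference and hypothesis must cover the same doc_ids; offending: ",
         paste(utils::head(c(setdiff(ref_ids, hyp_ids),
                             setdiff(hyp_ids, ref_ids)), 5), collapse = ", "),
         call. = FALSE)
  hyp_by_id <- stats::setNames(hypothesis, hyp_ids)

  counts <- new.env(parent = emptyenv())
  bump <- function(label, what) {
    cur <- counts[[label]] %||% c(tp = 0, fp = 0, fn = 0)
    cur[what] <- cur[what] + 1
    counts[[label]] <- cur
  }
  for (rd in reference) {
    hd <- hyp_by_id[[rd$doc_id]]
    rk <- tag_keys(rd); hk <- tag_keys(hd)
    rl <- vapply(rd$tags, `[[`, character(1), "label")
    hl <- vapply(hd$tags, `[[`, character(1), "label")
    used <- logical(length(hk))
    for (i in seq_along(rk)) {
      j <- which(!used & hk == rk[i])
      if (length(j)) { used[j[1]] <- TRUE; bump(rl[i], "tp") }
      else bump(rl[i], "fn")
    }
    for (j in which(!used)) bump(hl[j], "fp")
  }
  labels <- sort(ls(counts))
  per_label <- do.call(rbind, lapply(labels, function(l) {
    cc <- counts[[l]]
    data.frame(label = l, tp = cc["tp"], fp = cc["fp"], fn = cc["fn"],
               t(prf_row(cc["tp"], cc["fp"], cc["fn"])),
               row.names = NULL, stringsAsFactors = FALSE)
  }))
  if (is.null(per_label))
    per_label <- data.frame(label = character(), tp = numeric(),
                            fp = numeric(), fn = numeric(),
                            precision = numeric(), recall = numeric(),
                            f = numeric(), stringsAsFactors = FALSE)
  tot <- colSums(per_label[c("tp", "fp", "fn")])
  overall <- as.list(c(tot, prf_row(tot["tp"], tot["fp"], tot["fn"])))
  structure(list(per_label = per_label, overall = overall),
            class = "prf_report")
}

#' @export
print.prf_report <- function(x, ...) {
  cat("<prf_report>\n")
  df <- x$per_label
  df[c("precision", "recall", "f")] <-
    lapply(df[c("precision", "recall", "f")], round, 3)
  print(df, row.names = FALSE)
  cat(sprintf("Overall  P=%.3f R=%.3f F=%.3f (tp=%d fp=%d fn=%d)\n",
              x$overall$precision, x$overall$recall, x$overall$f,
              as.integer(x$overall$tp), as.integer(x$overall$fp),
              as.integer(x$overall$fn)))
  invisible(x)
}

#' Pairwise inter-annotator agreement
#'
#' Agreement between two annotators over the same documents, measured as
#' the span/label F-measure with annotator A as reference and B as
#' hypothesis. F is symmetric under argument swap (precision and recall
#' exchange roles).
#'
#' @param annotations_a,annotations_b Lists of [sig_document()].
#' @return A `prf_report`.
#' @export
pairwise_agreement <- function(annotations_a, annotations_b) {
  score_spans(annotations_a, annotations_b)
}

#' Attribute accuracy on gold spans
#'
#' Compares predicted attribute maps to gold on the gold spans themselves
#' (so span errors never compound with attribute errors). Gold-null
#' attribute values are excluded from the denominator. Numeric values
#' compare after decimal canonicalization; strings compare case-folded.
#'
#' @param gold List of [sig_document()] with gold attributes.
#' @param predicted List of [sig_document()] with the same doc_ids and the
#'   same tag spans, carrying predicted attributes.
#' @return An object of class `accuracy_report`: data frame with `label`,
#'   `attribute`, `correct`, `total`, `accuracy`.
#' @export
attribute_accuracy <- function(gold, predicted) {
  pred_by_id <- stats::setNames(predicted,
                                vapply(predicted, `[[`, character(1),
                                       "doc_id"))
  acc <- new.env(parent = emptyenv())
  bump <- function(label, attr, ok) {
    key <- paste(label, attr, sep = "|")
    cur <- acc[[key]] %||% c(correct = 0, total = 0)
    acc[[key]] <- cur + c(as.numeric(ok), 1)
  }
  same_value <- function(a, b) {
    if (is.null(b)) return(FALSE)
    if (is.numeric(a)) return(is.numeric(b) &&
                                format_decimal(a) == format_decimal(b))
    if (is.logical(a)) return(is.logical(b) && identical(a, b))
    identical(fold_key(as.character(a)), fold_key(as.character(b)))
  }
  for (gd in gold) {
    pd <- pred_by_id[[gd$doc_id]]
    if (is.null(pd)) stop("predicted collection lacks doc ", gd$doc_id,
                          call. = FALSE)
    gk <- tag_keys(gd); pk <- tag_keys(pd)
    extra <- setdiff(pk, gk)
    if (length(extra))
      stop("prediction on span absent from gold in doc ", gd$doc_id, ": ",
           extra[1], call. = FALSE)
    for (i in seq_along(gk)) {
      j <- match(gk[i], pk)
      if (is.na(j)) next
      gt <- gd$tags[[i]]; pt <- pd$tags[[j]]
      for (a in names(gt$attributes)) {
        gv <- gt$attributes[[a]]
        if (is.null(gv)) next
        bump(gt$label, a, same_value(gv, pt$attributes[[a]]))
      }
    }
  }
  keys <- sort(ls(acc))
  out <- do.call(rbind, lapply(keys, function(k) {
    parts <- strsplit(k, "|", fixed = TRUE)[[1]]
    cc <- acc[[k]]
    data.frame(label = parts[1], attribute = parts[2],
               correct = cc["correct"], total = cc["total"],
               accuracy = cc["correct"] / cc["total"],
               row.names = NULL, stringsAsFactors = FALSE)
  }))
  if (is.null(out))
    out <- data.frame(label = character(), attribute = character(),
                      correct = numeric(), total = numeric(),
                      accuracy = numeric(), stringsAsFactors = FALSE)
  structure(out, class = c("accuracy_report", "data.frame"))
}

#' Deterministic train/test split
#'
#' Shuffles the corpus with the given seed and takes the first
#' `round(ratio * N)` documents as the training set.
#'
#' @param corpus List of documents.
#' @param ratio Training fraction in (0, 1).
#' @param seed Shuffle seed.
#' @return `list(train =, test =)`, disjoint and exhaustive.
#' @export
split_corpus <- function(corpus, ratio = 0.8, seed = 1L) {
  if (length(corpus) == 0L) stop("corpus is empty", call. = FALSE)
  stopifnot(ratio > 0, ratio < 1)
  n <- length(corpus)
  perm <- with_seed(seed, sample.int(n))
  k <- round(ratio * n)
  list(train = corpus[perm[seq_len(k)]],
       test = corpus[perm[setdiff(seq_len(n), seq_len(k))]])
}
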