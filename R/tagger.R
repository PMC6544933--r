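# Span tagger: tokenization, feature extraction, BIO encoding, and a
# linear-chain sequence model (averaged structured perceptron trained with
# Viterbi decoding). Decoding exposes a signed bias that trades precision
# against recall by shifting every non-O emission score.

#' Tokenize a sig
#'
#' Splits on whitespace and further splits every punctuation character
#' (including hyphen, slash and period) into its own token, so that range
#' endpoints (`"2-3"`) and dotted abbreviations (`"p.o."`) become separate
#' tokens; abbreviation identity is recovered by the feature set, not the
#' tokenizer. Tokens tile the non-whitespace text exactly.
#'
#' @param text A sig string.
#' @return Data frame with `surface`, `start`, `end` (0-based half-open).
#' @examples
#' sig_tokenize("take 2-3 times")$surface
#' @export
sig_tokenize <- function(text) {
  if (is.na(text) || nchar(text) == 0L)
    return(data.frame(surface = character(), start = numeric(),
                      end = numeric(), stringsAsFactors = FALSE))
  m <- gregexpr("[A-Za-z]+|[0-9]+|[^A-Za-z0-9[:space:]]", text,
                perl = TRUE)[[1]]
  if (m[1] == -1L)
    return(data.frame(surface = character(), start = numeric(),
                      end = numeric(), stringsAsFactors = FALSE))
  start <- as.numeric(m) - 1
  len <- attr(m, "match.length")
  data.frame(surface = substring(text, m, m + len - 1L),
             start = start, end = start + len, stringsAsFactors = FALSE)
}

#' Extract the feature vector for one token position
#'
#' Emits exactly these feature families: prefix and suffix n-grams of the
#' current surface up to length 3; whether the current or previous token
#' starts with a capital letter; whether the current token contains a
#' digit; the surface form of the current token; and the surface forms of
#' the tokens 1, 2 and 3 positions away on either side, with `<S>`/`<E>`
#' boundary placeholders.
#'
#' @param tokens Token table from [sig_tokenize()].
#' @param i Token position (1-based).
#' @return Character vector of feature strings.
#' @export
token_features <- function(tokens, i) {
  surf <- tokens$surface[i]
  n <- nchar(surf)
  feats <- character()
  for (k in 1:3) {
    if (n >= k) {
      feats <- c(feats,
                 paste0("pre", k, "=", substr(surf, 1, k)),
                 paste0("suf", k, "=", substr(surf, n - k + 1, n)))
    }
  }
  if (grepl("^[A-Z]", surf)) feats <- c(feats, "cap")
  if (i > 1L && grepl("^[A-Z]", tokens$surface[i - 1L]))
    feats <- c(feats, "pcap")
  if (grepl("[0-9]", surf)) feats <- c(feats, "dig")
  feats <- c(feats, paste0("w=", surf))
  m <- nrow(tokens)
  for (d in c(-3L, -2L, -1L, 1L, 2L, 3L)) {
    j <- i + d
    w <- if (j < 1L) "<S>" else if (j > m) "<E>" else tokens$surface[j]
    feats <- c(feats, paste0("w", d, "=", w))
  }
  feats
}

#' Encode gold spans as token-level BIO labels
#'
#' A gold span not aligned to token boundaries is snapped outward to whole
#' tokens (with a warning). Every token intersecting a tag span receives
#' `B-LABEL` (first token) or `I-LABEL`; all others are `O`. When spans
#' overlap, the earlier-starting tag wins the contested tokens.
#'
#' @param tokens Token table from [sig_tokenize()].
#' @param tags List of [tag_instance()].
#' @return Character vector of BIO labels, one per token.
#' @export
encode_bio <- function(tokens, tags) {
  labels <- rep("O", nrow(tokens))
  if (length(tags) == 0L) return(labels)
  ord <- order(vapply(tags, `[[`, numeric(1), "start"),
               vapply(tags, `[[`, numeric(1), "end"))
  for (t in tags[ord]) {
    hit <- which(tokens$start < t$end & tokens$end > t$start)
    hit <- hit[labels[hit] == "O"]
    if (length(hit) == 0L) next
    if (tokens$start[hit[1]] < t$start || tokens$end[hit[length(hit)]] > t$end)
      warning("gold span [", t$start, ",", t$end,
              ") snapped outward to token boundaries", call. = FALSE)
    labels[hit[1]] <- paste0("B-", t$label)
    if (length(hit) > 1L)
      labels[hit[-1]] <- paste0("I-", t$label)
  }
  labels
}

#' Convert token-level BIO labels back to tags
#'
#' Maximal B/I runs of one label become a single tag whose span covers the
#' run's tokens; a stray `I-X` without a preceding `B-X` opens a new run
#' (the standard repair).
#'
#' @param tokens Token table.
#' @param labels BIO label vector, one per token.
#' @return List of [tag_instance()] with empty attribute maps.
#' @export
decode_bio <- function(tokens, labels) {
  tags <- list()
  cur <- NULL
  flush <- function() {
    if (!is.null(cur))
      tags[[length(tags) + 1L]] <<- tag_instance(cur$label, cur$start, cur$end)
    cur <<- NULL
  }
  for (i in seq_along(labels)) {
    lab <- labels[i]
    if (lab == "O") { flush(); next }
    kind <- substr(lab, 1, 1)
    name <- substr(lab, 3, nchar(lab))
    if (kind == "B" || is.null(cur) || cur$label != name) {
      flush()
      cur <- list(label = name, start = tokens$start[i], end = tokens$end[i])
    } else {
      cur$end <- tokens$end[i]
    }
  }
  flush()
  tags
}

# ---- model internals -------------------------------------------------------

prepare_training <- function(corpus) {
  feat_env <- new.env(hash = TRUE, parent = emptyenv())
  nfeat <- 0L
  label_set <- "O"
  docs <- vector("list", length(corpus))
  for (d in seq_along(corpus)) {
    doc <- corpus[[d]]
    tokens <- sig_tokenize(doc$text)
    labels <- encode_bio(tokens, doc$tags)
    label_set <- union(label_set, labels)
    fids <- vector("list", nrow(tokens))
    for (i in seq_len(nrow(tokens))) {
      fs <- token_features(tokens, i)
      ids <- integer(length(fs))
      for (k in seq_along(fs)) {
        id <- feat_env[[fs[k]]]
        if (is.null(id)) {
          nfeat <- nfeat + 1L
          id <- nfeat
          feat_env[[fs[k]]] <- id
        }
        ids[k] <- id
      }
      fids[[i]] <- ids
    }
    docs[[d]] <- list(fids = fids, labels = labels)
  }
  label_set <- c("O", sort(setdiff(label_set, "O")))
  list(docs = docs, feat_env = feat_env, nfeat = nfeat, labels = label_set)
}

# Hard BIO validity: I-X may only follow B-X or I-X, and never opens a
# sequence. Encoded as additive masks for Viterbi.
bio_masks <- function(labels) {
  L <- length(labels)
  trans_mask <- matrix(0, L, L)
  start_mask <- numeric(L)
  for (j in seq_len(L)) {
    if (!startsWith(labels[j], "I-")) next
    name <- substring(labels[j], 3)
    ok <- labels %in% paste0(c("B-", "I-"), name)
    trans_mask[!ok, j] <- -1e9
    start_mask[j] <- -1e9
  }
  list(trans = trans_mask, start = start_mask)
}

viterbi_decode <- function(E, trans, start) {
  m <- nrow(E); L <- ncol(E)
  if (m == 0L) return(integer())
  bp <- matrix(0L, m, L)
  delta <- start + E[1, ]
  if (m > 1L) {
    for (i in 2:m) {
      M <- trans + delta          # element (p, c) = delta[p] + trans[p, c]
      bp[i, ] <- max.col(t(M), ties.method = "first")
      delta <- M[cbind(bp[i, ], seq_len(L))] + E[i, ]
    }
  }
  path <- integer(m)
  path[m] <- which.max(delta)
  if (m > 1L) for (i in m:2) path[i - 1L] <- bp[i, path[i]]
  path
}

emission_scores <- function(W, fids, L) {
  m <- length(fids)
  E <- matrix(0, m, L)
  for (i in seq_len(m)) {
    ids <- fids[[i]]
    ids <- ids[ids > 0L & ids <= nrow(W)]
    if (length(ids) == 1L) E[i, ] <- W[ids, ]
    else if (length(ids) > 1L) E[i, ] <- colSums(W[ids, , drop = FALSE])
  }
  E
}

#' Train the span/label sequence tagger
#'
#' Fits a linear-chain sequence model (averaged structured perceptron,
#' decoded with Viterbi) over BIO-encoded labels using the feature set of
#' [token_features()]. Training is deterministic given the corpus order and
#' configuration; documents are visited in corpus order each epoch and
#' weights are averaged over all updates, which is what makes the score of
#' any probe sentence reproducible run to run.
#'
#' @param corpus List of [sig_document()] with gold tags.
#' @param epochs Maximum training epochs (training stops early once an
#'   epoch makes no mistakes).
#' @param seed Stored in the model for provenance; the trainer itself is
#'   deterministic.
#' @param bias_scale Scale constant applied to the decode-time bias.
#' @return An object of class `sig_tagger`.
#' @export
train_tagger <- function(corpus, epochs = 10L, seed = 1L, bias_scale = 1.0) {
  if (length(corpus) == 0L) stop("training corpus is empty", call. = FALSE)
  prep <- prepare_training(corpus)
  L <- length(prep$labels)
  lab_index <- stats::setNames(seq_len(L), prep$labels)
  masks <- bio_masks(prep$labels)
  W <- matrix(0, prep$nfeat, L)
  Tr <- matrix(0, L, L)
  St <- numeric(L)
  Wa <- W; Ta <- Tr; Sa <- St
  updates <- 0L
  for (ep in seq_len(epochs)) {
    mistakes <- 0L
    for (doc in prep$docs) {
      m <- length(doc$fids)
      if (m == 0L) next
      gold <- unname(lab_index[doc$labels])
      E <- emission_scores(W, doc$fids, L)
      pred <- viterbi_decode(E, Tr + masks$trans, St + masks$start)
      if (!identical(pred, gold)) {
        mistakes <- mistakes + 1L
        for (i in seq_len(m)) {
          if (pred[i] != gold[i]) {
            ids <- doc$fids[[i]]
            W[ids, gold[i]] <- W[ids, gold[i]] + 1
            W[ids, pred[i]] <- W[ids, pred[i]] - 1
          }
          if (i == 1L) {
            if (pred[1] != gold[1]) {
              St[gold[1]] <- St[gold[1]] + 1
              St[pred[1]] <- St[pred[1]] - 1
            }
          } else if (pred[i] != gold[i] || pred[i - 1L] != gold[i - 1L]) {
            Tr[gold[i - 1L], gold[i]] <- Tr[gold[i - 1L], gold[i]] + 1
            Tr[pred[i - 1L], pred[i]] <- Tr[pred[i - 1L], pred[i]] - 1
          }
        }
      }
      Wa <- Wa + W; Ta <- Ta + Tr; Sa <- Sa + St
      updates <- updates + 1L
    }
    if (mistakes == 0L) break
  }
  feat_names <- ls(prep$feat_env)
  feat_index <- stats::setNames(
    vapply(feat_names, function(f) prep$feat_env[[f]], integer(1)),
    feat_names)
  structure(list(
    weights = Wa / max(updates, 1L),
    trans = Ta / max(updates, 1L),
    start = Sa / max(updates, 1L),
    feat_index = feat_index,
    labels = prep$labels,
    config = list(epochs = epochs, seed = seed, bias_scale = bias_scale)),
    class = "sig_tagger")
}

#' @export
print.sig_tagger <- function(x, ...) {
  cat("<sig_tagger>", length(x$feat_index), "features,",
      length(x$labels), "BIO labels\n")
  invisible(x)
}

#' Tag a sig with a trained model
#'
#' Decodes BIO labels with Viterbi (under hard BIO validity: `I-X` only
#' continues `B-X`/`I-X`) and converts maximal B/I runs to tags whose
#' spans snap to token boundaries. The signed `bias` sets a decode-time
#' prior cost `bias_scale * bias` on asserting a span. A positive bias
#' suppresses every decoded span whose margin — the drop in Viterbi path
#' score when the span's tokens are forced to O — does not exceed that
#' cost, so predictions shrink monotonically, whole spans at a time,
#' toward the empty set (maximal precision under the empty-hypothesis
#' convention). A negative bias subsidizes every non-O emission score by
#' the same amount, pulling ever more tokens into tags until everything is
#' tagged (maximal recall). Zero decodes unbiased. Features unseen in
#' training are ignored.
#'
#' @param model A `sig_tagger` from [train_tagger()].
#' @param text A sig string.
#' @param bias Signed precision/recall bias; 0 decodes unbiased.
#' @return List of [tag_instance()] with empty attribute maps.
#' @export
tag_sig <- function(model, text, bias = 0) {
  tokens <- sig_tokenize(text)
  if (nrow(tokens) == 0L) return(list())
  L <- length(model$labels)
  fids <- lapply(seq_len(nrow(tokens)), function(i) {
    ids <- model$feat_index[token_features(tokens, i)]
    ids <- ids[!is.na(ids)]
    as.integer(ids)
  })
  E <- emission_scores(model$weights, fids, L)
  masks <- bio_masks(model$labels)
  trans <- model$trans + masks$trans
  start <- model$start + masks$start
  non_o <- model$labels != "O"
  cost <- model$config$bias_scale * bias
  if (bias < 0) E[, non_o] <- E[, non_o] - cost
  path <- viterbi_decode(E, trans, start)
  tags <- decode_bio(tokens, model$labels[path])
  if (bias <= 0 || length(tags) == 0L) return(tags)

  # positive bias: keep a span only if forcing its tokens to O costs the
  # decoder more than the span prior
  base_score <- bio_path_score(E, trans, start, path)
  keep <- vapply(tags, function(t) {
    pos <- which(tokens$start >= t$start & tokens$end <= t$end)
    E2 <- E
    E2[pos, non_o] <- -1e9
    alt <- viterbi_decode(E2, trans, start)
    margin <- base_score - bio_path_score(E2, trans, start, alt)
    margin > cost
  }, logical(1))
  tags[keep]
}

bio_path_score <- function(E, trans, start, path) {
  m <- length(path)
  s <- start[path[1]] + E[1, path[1]]
  if (m > 1L) for (i in 2:m)
    s <- s + trans[path[i - 1L], path[i]] + E[i, path[i]]
  s
}

#' Tag every document in a corpus
#'
#' @param model A `sig_tagger`.
#' @param corpus List of [sig_document()]; gold tags are ignored.
#' @param bias Decode-time precision/recall bias.
#' @param annotator_id Identifier recorded on the output documents.
#' @return List of [sig_document()] with predicted tags, `source = "model"`.
#' @export
tag_corpus <- function(model, corpus, bias = 0, annotator_id = "tagger") {
  lapply(corpus, function(doc) {
    sig_document(doc$doc_id, doc$text, tag_sig(model, doc$text, bias),
                 source = "model", annotator_id = annotator_id)
  })
}
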