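# Numeric retokenizer: find English number expressions in sig text and
# rewrite them to canonical decimal form while keeping a character offset
# map between the original and normalized strings.

NUMBER_UNITS <- c(zero = 0, one = 1, two = 2, three = 3, four = 4, five = 5,
                  six = 6, seven = 7, eight = 8, nine = 9)
NUMBER_TEENS <- c(ten = 10, eleven = 11, twelve = 12, thirteen = 13,
                  fourteen = 14, fifteen = 15, sixteen = 16, seventeen = 17,
                  eighteen = 18, nineteen = 19)
NUMBER_TENS <- c(twenty = 20, thirty = 30, forty = 40, fifty = 50,
                 sixty = 60, seventy = 70, eighty = 80, ninety = 90)
NUMBER_FRACTIONS <- c(half = 0.5, quarter = 0.25)
NUMBER_ORDINALS <- c(first = 1, second = 2, third = 3, fourth = 4,
                     fifth = 5, sixth = 6, seventh = 7, eighth = 8,
                     ninth = 9, tenth = 10, eleventh = 11, twelfth = 12)

# Lexical scan: maximal letter runs, decimal/integer literals, and single
# punctuation characters, with 0-based half-open offsets.
scan_lexemes <- function(text) {
  if (nchar(text) == 0L)
    return(data.frame(surface = character(), start = numeric(),
                      end = numeric(), stringsAsFactors = FALSE))
  m <- gregexpr("[0-9]+\\.[0-9]+|[0-9]+|[A-Za-z]+|[^A-Za-z0-9[:space:]]",
                text, perl = TRUE)[[1]]
  if (m[1] == -1L)
    return(data.frame(surface = character(), start = numeric(),
                      end = numeric(), stringsAsFactors = FALSE))
  start <- as.numeric(m) - 1
  len <- attr(m, "match.length")
  data.frame(surface = substring(text, m, m + len - 1L),
             start = start, end = start + len, stringsAsFactors = FALSE)
}

# TRUE when only whitespace separates lexeme i and lexeme j in the text.
lex_adjacent <- function(lex, i, j) {
  j == i + 1L
}

empty_number_spans <- function() {
  data.frame(start = numeric(), end = numeric(), value = numeric(),
             surface = character(), ordinal = logical(),
             stringsAsFactors = FALSE)
}

#' Find English number expressions in a sig
#'
#' Detects digit literals, decimals, fractions (`1/2`, `2 1/2`), number
#' words up to the hundreds (`three`, `twenty one`, `one hundred`), the
#' `"X and a half/quarter"` idiom, and ordinals (`third`). Matching is
#' left-to-right and longest-match; spans never overlap. A digit range like
#' `"2-3"` yields two spans (one per endpoint), which is what the
#' range-valued attributes downstream require. Ordinal expressions are
#' reported with `ordinal = TRUE` and are not rewritten by
#' [canonicalize_numbers()] (the numeral value is still needed by interval
#' frequency semantics, but rewriting `"every third day"` to `"every 3
#' day"` would corrupt the phrase).
#'
#' @param text A sig string.
#' @return Data frame with columns `start`, `end` (0-based half-open),
#'   `value`, `surface`, `ordinal`.
#' @examples
#' find_number_expressions("take one and a half tablets")
#' find_number_expressions("2-3 times per day")
#' @export
find_number_expressions <- function(text) {
  lex <- scan_lexemes(text)
  n <- nrow(lex)
  out <- empty_number_spans()
  i <- 1L
  while (i <= n) {
    m <- match_number_at(lex, i, text)
    if (is.null(m)) {
      i <- i + 1L
    } else {
      out <- rbind(out, data.frame(
        start = lex$start[i], end = lex$end[m$last],
        value = m$value,
        surface = span_text(text, lex$start[i], lex$end[m$last]),
        ordinal = m$ordinal, stringsAsFactors = FALSE))
      i <- m$last + 1L
    }
  }
  out
}

# Attempt to parse a number expression starting at lexeme i; returns
# list(value, last, ordinal) for the longest match, or NULL.
match_number_at <- function(lex, i, text) {
  s <- tolower(lex$surface[i])
  n <- nrow(lex)
  at <- function(k) if (k <= n) tolower(lex$surface[k]) else ""
  is_digit <- grepl("^[0-9]", s)

  base <- NULL
  if (is_digit) {
    base <- list(value = as.numeric(s), last = i)
    # mixed fraction "2 1/2" or plain fraction "1/2"
    if (at(i + 1) == "/" && grepl("^[0-9]+$", at(i + 2)) &&
        as.numeric(at(i + 2)) > 0 && !grepl("\\.", s)) {
      base <- list(value = as.numeric(s) / as.numeric(at(i + 2)), last = i + 2L)
    } else if (grepl("^[0-9]+$", at(i + 1)) && at(i + 2) == "/" &&
               grepl("^[0-9]+$", at(i + 3)) && as.numeric(at(i + 3)) > 0 &&
               !grepl("\\.", s)) {
      base <- list(value = as.numeric(s) +
                     as.numeric(at(i + 1)) / as.numeric(at(i + 3)),
                   last = i + 3L)
    }
  } else if (s %in% names(NUMBER_ORDINALS)) {
    return(list(value = unname(NUMBER_ORDINALS[s]), last = i, ordinal = TRUE))
  } else if (s %in% names(NUMBER_FRACTIONS)) {
    base <- list(value = unname(NUMBER_FRACTIONS[s]), last = i)
  } else if (s == "a" && at(i + 1) %in% names(NUMBER_FRACTIONS)) {
    # "a half", "a quarter"
    base <- list(value = unname(NUMBER_FRACTIONS[at(i + 1)]), last = i + 1L)
  } else if (s == "a" && at(i + 1) == "hundred") {
    base <- list(value = 100, last = i + 1L)
  } else {
    base <- match_word_number(lex, i)
  }
  if (is.null(base)) return(NULL)

  # "... and a half" / "... and one quarter"
  j <- base$last
  if (at(j + 1) == "and" && at(j + 2) %in% c("a", "one") &&
      at(j + 3) %in% names(NUMBER_FRACTIONS)) {
    base <- list(value = base$value + unname(NUMBER_FRACTIONS[at(j + 3)]),
                 last = j + 3L)
  }
  base$ordinal <- FALSE
  base
}

# Additive/multiplicative word numbers: units, teens, tens (optionally
# hyphenated with a unit), and "<unit|a> hundred [and] <rest>".
match_word_number <- function(lex, i) {
  n <- nrow(lex)
  at <- function(k) if (k <= n) tolower(lex$surface[k]) else ""
  s <- at(i)

  small <- NULL
  if (s %in% names(NUMBER_TENS)) {
    small <- list(value = unname(NUMBER_TENS[s]), last = i)
    j <- i + 1L
    if (at(j) == "-" && at(j + 1) %in% names(NUMBER_UNITS) &&
        at(j + 1) != "zero") {
      small <- list(value = small$value + unname(NUMBER_UNITS[at(j + 1)]),
                    last = j + 1L)
    } else if (at(j) %in% names(NUMBER_UNITS) && at(j) != "zero") {
      small <- list(value = small$value + unname(NUMBER_UNITS[at(j)]),
                    last = j)
    }
  } else if (s %in% names(NUMBER_TEENS)) {
    small <- list(value = unname(NUMBER_TEENS[s]), last = i)
  } else if (s %in% names(NUMBER_UNITS)) {
    small <- list(value = unname(NUMBER_UNITS[s]), last = i)
  }
  if (is.null(small)) return(NULL)

  # "<unit> hundred" with optional "[and] <tens/teens/unit>"
  if (small$value >= 1 && small$value <= 9 && at(small$last + 1) == "hundred") {
    res <- list(value = small$value * 100, last = small$last + 1L)
    k <- res$last + 1L
    if (at(k) == "and") k <- k + 1L
    tail <- if (k <= n && (at(k) %in% c(names(NUMBER_TENS),
                                        names(NUMBER_TEENS),
                                        names(NUMBER_UNITS))) &&
                at(k) != "zero") match_word_number(lex, k) else NULL
    if (!is.null(tail) && tail$value < 100) {
      res <- list(value = res$value + tail$value, last = tail$last)
    }
    return(res)
  }
  small
}

#' Canonicalize number expressions in a sig
#'
#' Rewrites every detected number expression (except ordinals) to its
#' canonical decimal rendering — integers without a decimal point,
#' non-integers with minimal decimal digits — leaving all other characters
#' untouched, and records a monotone offset map between original and
#' normalized positions. The operation is idempotent.
#'
#' @param text A sig string.
#' @return An object of class `normalized_text` with fields `text` (the
#'   rewritten string), `original`, `numbers` (the [find_number_expressions()]
#'   table in original coordinates), and `segments` (the offset map).
#' @examples
#' canonicalize_numbers("take three tablets")$text
#' canonicalize_numbers("one and a half")$numbers$value
#' @export
canonicalize_numbers <- function(text) {
  numbers <- find_number_expressions(text)
  repl <- numbers[!numbers$ordinal, , drop = FALSE]
  segments <- data.frame(os = numeric(), oe = numeric(), ns = numeric(),
                         ne = numeric(), replaced = logical())
  out <- character()
  opos <- 0; npos <- 0
  add_seg <- function(os, oe, ns, ne, replaced) {
    segments[nrow(segments) + 1L, ] <<- list(os, oe, ns, ne, replaced)
  }
  for (k in seq_len(nrow(repl))) {
    s <- repl$start[k]; e <- repl$end[k]
    if (s > opos) {
      gap <- span_text(text, opos, s)
      out <- c(out, gap)
      add_seg(opos, s, npos, npos + nchar(gap), FALSE)
      npos <- npos + nchar(gap)
    }
    canon <- format_decimal(repl$value[k])
    out <- c(out, canon)
    add_seg(s, e, npos, npos + nchar(canon), TRUE)
    npos <- npos + nchar(canon)
    opos <- e
  }
  if (opos < nchar(text) || nrow(segments) == 0L) {
    gap <- span_text(text, opos, nchar(text))
    out <- c(out, gap)
    add_seg(opos, nchar(text), npos, npos + nchar(gap), FALSE)
  }
  structure(list(text = paste(out, collapse = ""), original = text,
                 numbers = numbers, segments = segments),
            class = "normalized_text")
}

map_position <- function(segments, pos, from = c("original", "normalized"),
                         side = c("start", "end")) {
  from <- match.arg(from); side <- match.arg(side)
  if (from == "original") { a <- "os"; b <- "oe"; x <- "ns"; y <- "ne" }
  else { a <- "ns"; b <- "ne"; x <- "os"; y <- "oe" }
  if (nrow(segments) == 0L) return(pos)
  hit <- which(segments[[a]] <= pos & pos <= segments[[b]])
  if (length(hit) == 0L) {
    # beyond either end: clamp
    return(if (pos < segments[[a]][1]) segments[[x]][1]
           else segments[[y]][nrow(segments)])
  }
  # prefer the segment where pos is interior; at shared boundaries any
  # choice gives the same mapped offset for unchanged segments
  i <- if (side == "start") hit[length(hit)] else hit[1]
  seg <- segments[i, ]
  if (!seg$replaced) return(seg[[x]] + (pos - seg[[a]]))
  if (pos <= seg[[a]]) seg[[x]]
  else if (pos >= seg[[b]]) seg[[y]]
  else if (side == "start") seg[[x]] else seg[[y]]
}

#' Map a character span through the normalization offset map
#'
#' Positions outside replaced regions map exactly; a position interior to a
#' replaced number expression is widened to the enclosing replacement, so a
#' round trip always returns a span containing the original.
#'
#' @param nt A `normalized_text` from [canonicalize_numbers()].
#' @param start,end 0-based half-open span.
#' @return Numeric `c(start, end)` in the other coordinate system.
#' @export
span_to_normalized <- function(nt, start, end) {
  c(map_position(nt$segments, start, "original", "start"),
    map_position(nt$segments, end, "original", "end"))
}

#' @rdname span_to_normalized
#' @export
span_to_original <- function(nt, start, end) {
  c(map_position(nt$segments, start, "normalized", "start"),
    map_position(nt$segments, end, "normalized", "end"))
}

# Render a value as an English number phrase (used by the synthetic
# generator when it emits word-form numbers). Supports 0-99 plus the
# "and a half" idiom.
number_to_words <- function(v) {
  stopifnot(is_scalar_number(v), v >= 0)
  frac <- v - floor(v)
  whole <- floor(v)
  words_whole <- function(w) {
    if (w < 10) names(NUMBER_UNITS)[match(w, NUMBER_UNITS)]
    else if (w < 20) names(NUMBER_TEENS)[match(w, NUMBER_TEENS)]
    else if (w < 100) {
      tens <- (w %/% 10) * 10
      rest <- w %% 10
      t <- names(NUMBER_TENS)[match(tens, NUMBER_TENS)]
      if (rest == 0) t else paste(t, names(NUMBER_UNITS)[match(rest, NUMBER_UNITS)])
    } else stop("number_to_words supports 0-99 only")
  }
  if (frac == 0) return(words_whole(whole))
  if (isTRUE(all.equal(frac, 0.5))) {
    if (whole == 0) return("a half")
    return(paste(words_whole(whole), "and a half"))
  }
  stop("unsupported fractional part: ", v)
}
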