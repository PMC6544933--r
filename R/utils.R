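#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

# Run code with a private RNG state so library calls never disturb the
# caller's random stream.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Canonical base-10 rendering of a non-negative decimal: integers without a
# decimal point, otherwise at most 3 decimal digits with trailing zeros
# trimmed. Never scientific notation.
format_decimal <- function(v) {
  stopifnot(is.numeric(v))
  vapply(v, function(x) {
    if (is.na(x)) return(NA_character_)
    r <- round(x, 3)
    if (r == floor(r)) {
      sprintf("%d", as.integer(r))
    } else {
      s <- sprintf("%.3f", r)
      sub("0+$", "", s)
    }
  }, character(1))
}

# Extract the substring covered by a 0-based half-open character span.
span_text <- function(text, start, end) {
  substr(text, start + 1L, end)
}

# Case-fold and collapse internal whitespace; the key normalization used by
# the literal-match attribute method.
fold_key <- function(x) {
  x <- tolower(trimws(x))
  gsub("[[:space:]]+", " ", x)
}

# Most common element; ties broken by lexicographic order for determinism.
majority_value <- function(values) {
  tab <- sort(table(values), decreasing = TRUE)
  best <- names(tab)[tab == tab[1]]
  sort(best)[1]
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x)
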