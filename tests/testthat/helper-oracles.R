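# Independent oracles used to cross-check package primitives. Both are
# deliberately naive: correctness over speed, and no shared code with the
# implementations they check.

# Memoised recursive Levenshtein distance.
oracle_lev <- function(a, b) {
  memo <- new.env(parent = emptyenv())
  rec <- function(a, b) {
    key <- paste(a, b, sep = "\r")
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    res <- if (nchar(a) == 0) nchar(b)
    else if (nchar(b) == 0) nchar(a)
    else {
      ta <- substr(a, 2, nchar(a)); tb <- substr(b, 2, nchar(b))
      cost <- as.integer(substr(a, 1, 1) != substr(b, 1, 1))
      min(rec(ta, b) + 1L, rec(a, tb) + 1L, rec(ta, tb) + cost)
    }
    memo[[key]] <- res
    res
  }
  as.integer(rec(a, b))
}

# All strings over `alphabet` of length 0..n.
strings_up_to <- function(alphabet, n) {
  out <- ""
  cur <- ""
  for (k in seq_len(n)) {
    cur <- as.vector(outer(cur, alphabet, paste0))
    out <- c(out, cur)
  }
  out
}

# English number phrases for 0..100, built by word summation from lookup
# tables local to this oracle.
oracle_number_words <- function() {
  units <- c("zero", "one", "two", "three", "four", "five", "six", "seven",
             "eight", "nine")
  teens <- c("ten", "eleven", "twelve", "thirteen", "fourteen", "fifteen",
             "sixteen", "seventeen", "eighteen", "nineteen")
  tens <- c("twenty", "thirty", "forty", "fifty", "sixty", "seventy",
            "eighty", "ninety")
  phrases <- character(101)
  for (v in 0:100) {
    phrases[v + 1] <- if (v < 10) units[v + 1]
    else if (v < 20) teens[v - 9]
    else if (v == 100) "one hundred"
    else {
      t <- tens[v %/% 10 - 1]
      if (v %% 10 == 0) t else paste(t, units[v %% 10 + 1])
    }
  }
  phrases
}
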