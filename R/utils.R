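# Internal helpers shared across modules.

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Shortest-round-trip style decimal rendering of a weight, capped at `digits`
# significant digits.  Must stay parseable by the expression dialect
# (plain digits, ".", "e" exponent; no spaces).
fmt_num <- function(x, digits = 9L) {
  s <- formatC(x, digits = digits, format = "g", width = 1)
  gsub(" ", "", s, fixed = TRUE)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) {
  length(x) == 1L && is.numeric(x) && is.finite(x) && x == as.integer(x)
}
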