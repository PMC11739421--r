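# Internal helpers: seeded RNG streams and small utilities.

#' @keywords internal
#' @noRd
AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Counter-based sub-seed derivation so that every stochastic step of a
# campaign draws from its own reproducible stream. Keeps results order-stable
# when steps are added or reordered. Always < 2^31.
derive_seed <- function(seed, ...) {
  idx <- c(...)
  s <- as.double(seed) %% 2147483629
  for (i in idx) {
    s <- (s * 69069 + as.double(i) * 2654435761 + 1013904223) %% 2147483629
  }
  as.integer(s)
}

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
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
  expr
}

# Deterministic C-locale ordering: descending score, ties lexicographic.
order_by_score <- function(score, combo) {
  order(-score, combo, method = "radix")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_alde <- function(fmt, ..., class) {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "alde_error")))
}
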