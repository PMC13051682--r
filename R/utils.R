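#' @keywords internal
"_PACKAGE"

# Run code with a temporary RNG state seeded from `seed`, restoring the
# caller's state afterwards. All exported generators take an explicit seed so
# results are reproducible without clobbering the session RNG.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# Shuffle a multiset so that no element repeats twice in a row.
# Backtracking-free greedy with bounded restarts; errors if infeasible.
shuffle_no_repeat <- function(pool, max_tries = 200L) {
  for (try in seq_len(max_tries)) {
    remaining <- pool
    out <- character(0)
    ok <- TRUE
    prev <- NA_character_
    for (i in seq_along(pool)) {
      cand <- unique(remaining)
      cand <- cand[is.na(prev) | cand != prev]
      if (length(cand) == 0L) { ok <- FALSE; break }
      # prefer the most abundant candidates to avoid dead-ends
      counts <- vapply(cand, function(x) sum(remaining == x), integer(1))
      pick <- if (length(cand) == 1L) cand else
        sample(cand, 1L, prob = counts / sum(counts))
      out <- c(out, pick)
      remaining <- remaining[-match(pick, remaining)]
      prev <- pick
    }
    if (ok) return(out)
  }
  stopf("could not order elements without immediate repeats after %d tries",
        max_tries)
}
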