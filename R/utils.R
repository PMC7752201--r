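# Structured condition helpers: every user-facing failure carries a subclass
# so the CLI (and tests) can distinguish validation problems from usage errors.
pte_stop <- function(subclass, ...) {
  msg <- paste0(...)
  stop(errorCondition(msg, class = c(paste0("pte_", subclass, "_error"),
                                     "pte_error")))
}

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# random stream.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}

# Derive a reproducible sub-seed (< 2^31) from a base seed and stream indices.
derive_seed <- function(seed, ...) {
  idx <- c(...)
  s <- as.double(seed) %% 2147483647
  for (i in idx) s <- (s * 69069 + as.double(i) * 101 + 1) %% 2147483647
  as.integer(s)
}
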