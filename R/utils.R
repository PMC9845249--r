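# Run code under a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Stable per-purpose sub-seed derived from a master seed, kept within the
# 32-bit integer range R requires.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 1009 + offset) %% .Machine$integer.max)
}

# TCR identity key for a record table: both chains when present.
tcr_key <- function(records) {
  a <- if ("cdr3a" %in% names(records)) records$cdr3a else NA_character_
  a <- ifelse(is.na(a) | a == "", "-", a)
  paste(a, records$cdr3b, sep = "|")
}
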