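# Internal helpers shared across modules.

# Run code with a private RNG stream, restoring the caller's .Random.seed.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Split a sequence string into a character vector of residues.
seq_chars <- function(seq) strsplit(seq, "", fixed = TRUE)[[1]]

# Deterministic pseudo-random protein string with natural-ish composition.
random_protein <- function(n, seed) {
  with_seed(seed, paste(
    sample(names(AA_BACKGROUND), n, replace = TRUE, prob = AA_BACKGROUND),
    collapse = ""))
}

# Overwrite `motif` into `chars` (character vector) starting at 1-based pos.
splice_motif <- function(chars, pos, motif) {
  m <- seq_chars(motif)
  stopifnot(pos >= 1, pos + length(m) - 1 <= length(chars))
  chars[pos:(pos + length(m) - 1)] <- m
  chars
}

assert_protein_alphabet <- function(seq, id = "<sequence>",
                                    allow_x = TRUE) {
  chars <- seq_chars(seq)
  ok <- if (allow_x) AA_ALPHABET else AA_STANDARD
  bad <- setdiff(unique(chars), ok)
  if (length(bad) > 0)
    stop(sprintf("sequence '%s' contains invalid residue(s): %s",
                 id, paste(bad, collapse = ", ")), call. = FALSE)
  invisible(TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
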