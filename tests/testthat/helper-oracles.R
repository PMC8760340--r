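# Independent oracles used by the tests. These deliberately avoid the code
# paths they check.

# Exhaustive-enumeration optimum for global alignment with affine gaps:
# walks every monotone alignment path, charging open + extend for the first
# residue of each gap run and extend for the rest (end gaps included).
nw_enumeration_oracle <- function(a, b, mat, open = 11, ext = 1) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  na <- length(A); nb <- length(B)
  best <- -Inf
  rec <- function(i, j, prev, sc) {
    if (i > na && j > nb) {
      if (sc > best) best <<- sc
      return(invisible())
    }
    if (i <= na && j <= nb) rec(i + 1, j + 1, "M", sc + mat[A[i], B[j]])
    if (i <= na) rec(i + 1, j, "X",
                     sc - (if (prev == "X") ext else open + ext))
    if (j <= nb) rec(i, j + 1, "Y",
                     sc - (if (prev == "Y") ext else open + ext))
    invisible()
  }
  rec(1L, 1L, "S", 0)
  best
}

blosum62_matrix <- function() {
  env <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = env)
  env$BLOSUM62
}

# Independent Henderson-Hasselbalch net charge (grid evaluation), written
# separately from the package's bisection path.
oracle_net_charge <- function(seq, ph) {
  chars <- strsplit(seq, "")[[1]]
  cnt <- function(a) sum(chars == a)
  pos <- 1 / (1 + 10^(ph - 8.6)) +
    cnt("K") / (1 + 10^(ph - 10.8)) +
    cnt("R") / (1 + 10^(ph - 12.5)) +
    cnt("H") / (1 + 10^(ph - 6.5))
  neg <- 1 / (1 + 10^(3.6 - ph)) +
    cnt("D") / (1 + 10^(3.9 - ph)) +
    cnt("E") / (1 + 10^(4.1 - ph)) +
    cnt("C") / (1 + 10^(8.5 - ph)) +
    cnt("Y") / (1 + 10^(10.1 - ph))
  pos - neg
}

# Column-wise identity recount for substitution-only pairs.
column_identity <- function(a, b) {
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  100 * mean(ca == cb)
}

random_aa_string <- function(n, seed, alphabet = c("A", "C", "D", "E")) {
  set.seed(seed)
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# One shared default synthetic fixture per test run (built lazily).
shared_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- build_synthetic_genome(sim_config(seed = 1))
    cache
  }
})
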