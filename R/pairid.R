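#' Global pairwise alignment with affine gaps
#'
#' Needleman--Wunsch global alignment (BLOSUM62, gap open 11, gap extend 1;
#' a gap run of length L costs open + L * extend), computed with
#' [Biostrings::pairwiseAlignment()]. Percent identity is counted over
#' aligned columns (dual-gap columns cannot occur in a pairwise alignment);
#' coverage is the percentage of query (`a`) residues placed in the
#' alignment, which for a global alignment is 100 by construction.
#'
#' @param a,b Sequence strings or [protein_record()]s (`a` is the query).
#' @param gap_open,gap_extend Affine gap parameters.
#' @return List of class `pairwise_alignment`: `aligned_a`, `aligned_b`
#'   (equal-length gapped strings), `score`, `identity_pct`, `coverage_pct`.
#' @examples
#' global_align("ACDE", "ACDF")$identity_pct  # 75
#' @export
global_align <- function(a, b, gap_open = 11, gap_extend = 1) {
  a <- if (inherits(a, "protein_record")) a$seq else toupper(a)
  b <- if (inherits(b, "protein_record")) b$seq else toupper(b)
  if (!nzchar(a) || !nzchar(b)) stop("empty sequence", call. = FALSE)
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    substitutionMatrix = blosum62(), gapOpening = gap_open,
    gapExtension = gap_extend, type = "global")
  al_a <- as.character(Biostrings::alignedPattern(pa))
  al_b <- as.character(Biostrings::alignedSubject(pa))
  ca <- seq_chars(al_a); cb <- seq_chars(al_b)
  cols <- !(ca == "-" & cb == "-")
  ident <- 100 * sum(ca == cb & ca != "-") / sum(cols)
  cov <- 100 * sum(ca != "-") / nchar(a)
  structure(list(aligned_a = al_a, aligned_b = al_b,
                 score = Biostrings::score(pa),
                 identity_pct = ident, coverage_pct = cov),
            class = "pairwise_alignment")
}

# Self-alignment score without running the aligner: the optimum of a
# sequence against itself is the gapless diagonal.
self_align_score <- function(seq) {
  m <- blosum62()
  chars <- seq_chars(toupper(seq))
  sum(m[cbind(chars, chars)])
}

# BLOSUM62 fetched once from Biostrings' data store.
blosum62 <- local({
  mat <- NULL
  function() {
    if (is.null(mat)) {
      env <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = env)
      mat <<- env$BLOSUM62
    }
    mat
  }
})

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat(sprintf("<pairwise_alignment> score %.0f, identity %.1f%%, coverage %.1f%%\n",
              x$score, x$identity_pct, x$coverage_pct))
  invisible(x)
}

#' Percent identity and coverage of a sequence pair
#'
#' Thin reporting wrapper over [global_align()]; values rounded to 0.1%.
#'
#' @inheritParams global_align
#' @return Named numeric vector `c(identity_pct, coverage_pct)`.
#' @export
percent_identity <- function(a, b) {
  al <- global_align(a, b)
  c(identity_pct = round(al$identity_pct, 1),
    coverage_pct = round(al$coverage_pct, 1))
}

#' Novelty filter by maximum identity to known references
#'
#' A query is discarded when its best global-alignment identity against the
#' reference set strictly exceeds `threshold_pct` (default 45): candidates
#' sharing more than 45% identity with characterized enzymes are excluded to
#' enrich for novelty. Equality at the threshold keeps the query.
#'
#' @param query Sequence string or [protein_record()].
#' @param references List of sequences/records.
#' @param threshold_pct Exclusion threshold, strict inequality.
#' @return List with `keep` (logical), `best_ref` (index into `references`),
#'   `best_id` (its id when available), `identity_pct`.
#' @export
novelty_filter <- function(query, references, threshold_pct = 45) {
  if (length(references) == 0) stop("empty reference set", call. = FALSE)
  ids <- vapply(seq_along(references), function(i) {
    r <- references[[i]]
    if (inherits(r, "protein_record")) r$id else paste0("ref", i)
  }, "")
  idents <- vapply(references, function(r)
    global_align(query, r)$identity_pct, 0)
  best <- which.max(idents)
  list(keep = !(idents[best] > threshold_pct),
       best_ref = best, best_id = ids[best],
       identity_pct = round(idents[best], 1))
}
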