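#' Anchor a query protein to the reference seed set
#'
#' Globally aligns the query against every packaged seed and returns the
#' best-scoring seed when its normalized score clears `anchor_threshold`.
#' The normalized score is the raw alignment score divided by the smaller of
#' the two self-alignment scores, so a perfect match scores 1 and unrelated
#' sequences score near or below 0; the default threshold sits above the
#' maximum normalized score observed for composition-preserving shuffles of
#' the seeds themselves, and well below the score of genuine homologs down
#' to the ~20% identity twilight zone.
#'
#' @param query Sequence string or [protein_record()].
#' @param refset Seed list, defaults to [cgt_reference_seeds()].
#' @param anchor_threshold Minimum normalized score to accept an anchor.
#' @return `NULL`, or a list of class `csr_anchor` with `ref` (the seed),
#'   `alignment` (a `pairwise_alignment`), `nscore`.
#' @export
anchor_to_reference <- function(query, refset = cgt_reference_seeds(),
                                anchor_threshold = 0.15) {
  if (length(refset) == 0) stop("empty reference set", call. = FALSE)
  qseq <- if (inherits(query, "protein_record")) query$seq else toupper(query)
  self_q <- self_align_score(qseq)
  best <- NULL; best_ns <- -Inf
  for (s in refset) {
    al <- global_align(qseq, s$seq)
    self_r <- self_align_score(s$seq)
    ns <- al$score / min(self_q, self_r)
    if (ns > best_ns) {
      best_ns <- ns
      best <- list(ref = s, alignment = al, nscore = ns)
    }
  }
  if (best_ns < anchor_threshold) return(NULL)
  structure(best, class = "csr_anchor")
}

# Map reference positions to query positions through an alignment of
# (query, reference); returns an integer vector indexed by reference
# position, NA where the reference residue is opposite a gap.
ref_to_query_map <- function(alignment) {
  ca <- seq_chars(alignment$aligned_a)  # query
  cb <- seq_chars(alignment$aligned_b)  # reference
  qpos <- 0L; rpos <- 0L
  map <- integer(sum(cb != "-"))
  for (i in seq_along(ca)) {
    if (ca[i] != "-") qpos <- qpos + 1L
    if (cb[i] != "-") {
      rpos <- rpos + 1L
      map[rpos] <- if (ca[i] != "-") qpos else NA_integer_
    }
  }
  map
}

#' Transfer CSR coordinates and diagnostic residues to a query
#'
#' Maps every reference CSR span and diagnostic slot through the anchored
#' alignment into query coordinates, reads the query residues at the mapped
#' positions, and re-scores each CSR window against the packaged per-column
#' log-odds profile within a +/-5-residue slack window (the mapped position
#' is kept unless a strictly better-scoring start exists nearby). Slots or
#' spans that land on alignment gaps are reported absent.
#'
#' @param query Sequence string or [protein_record()].
#' @param anchor A `csr_anchor` from [anchor_to_reference()].
#' @param slack Re-scoring slack window in residues.
#' @return A list of class `csr_report`: `hits` (data frame: csr, start,
#'   end, residues, score), slot positions (`nucleophile_pos`, `glu_pos`,
#'   `asp2_pos`, `h1_pos`, `h2_pos`, `csrV_center_pos`), slot residues,
#'   and `arg_minus2_ok`.
#' @export
map_csr <- function(query, anchor, slack = 5L) {
  if (is.null(anchor)) stop("anchor absent", call. = FALSE)
  qseq <- if (inherits(query, "protein_record")) query$seq else toupper(query)
  qchars <- seq_chars(qseq)
  map <- ref_to_query_map(anchor$alignment)
  profs <- csr_profiles()
  ref <- anchor$ref

  hits <- data.frame(csr = character(), start = integer(), end = integer(),
                     residues = character(), score = numeric())
  for (nm in names(ref$csr_spans)) {
    sp <- ref$csr_spans[[nm]]
    ms <- map[sp[1]]; me <- map[sp[2]]
    if (is.na(ms) || is.na(me)) next
    L <- ncol(profs[[nm]])
    # slack re-scoring: keep the mapped start unless a nearby start scores
    # strictly higher (candidates ordered by |shift|)
    shifts <- (-slack:slack)[order(abs(-slack:slack))]
    best_start <- NA_integer_; best_score <- -Inf
    for (sh in shifts) {
      st <- ms + sh
      if (st < 1 || st + L - 1 > length(qchars)) next
      sc <- profile_score(profs[[nm]], qchars[st:(st + L - 1)])
      if (is.na(sc)) next
      if (sc > best_score + 1e-9) { best_score <- sc; best_start <- st }
    }
    if (is.na(best_start)) next
    hits <- rbind(hits, data.frame(
      csr = nm, start = best_start, end = best_start + L - 1L,
      residues = paste(qchars[best_start:(best_start + L - 1L)],
                       collapse = ""),
      score = best_score))
  }

  slot_pos <- lapply(ref$slots, function(p) {
    q <- map[p]
    if (is.na(q)) NULL else q
  })
  res_at <- function(p) if (is.null(p)) NA_character_ else qchars[p]
  nuc <- slot_pos$nucleophile
  arg_ok <- FALSE
  if (!is.null(nuc) && nuc > 2) arg_ok <- qchars[nuc - 2] == "R"

  structure(list(
    hits = hits,
    nucleophile_pos = slot_pos$nucleophile %||% NA_integer_,
    glu_pos = slot_pos$glu %||% NA_integer_,
    asp2_pos = slot_pos$asp2 %||% NA_integer_,
    h1_pos = slot_pos$h1 %||% NA_integer_,
    h2_pos = slot_pos$h2 %||% NA_integer_,
    csrV_center_pos = slot_pos$csrV_center %||% NA_integer_,
    nucleophile_res = res_at(slot_pos$nucleophile),
    glu_res = res_at(slot_pos$glu),
    asp2_res = res_at(slot_pos$asp2),
    h1_res = res_at(slot_pos$h1),
    h2_res = res_at(slot_pos$h2),
    csrV_center_res = res_at(slot_pos$csrV_center),
    arg_minus2_ok = arg_ok,
    ref_id = ref$id), class = "csr_report")
}

#' @export
print.csr_report <- function(x, ...) {
  cat(sprintf("<csr_report> anchored to %s; %d CSR hit(s)\n", x$ref_id,
              nrow(x$hits)))
  cat(sprintf("  triad: %s%s / %s%s / %s%s; CSR V center %s%s; H1 %s%s H2 %s%s; Arg-2 %s\n",
              x$nucleophile_res, x$nucleophile_pos, x$glu_res, x$glu_pos,
              x$asp2_res, x$asp2_pos, x$csrV_center_res, x$csrV_center_pos,
              x$h1_res, x$h1_pos, x$h2_res, x$h2_pos, x$arg_minus2_ok))
  invisible(x)
}

#' Classify an enzyme from its CSR report
#'
#' Decision table over the diagnostic residues: a complete Asp/Glu/Asp
#' catalytic triad with an aromatic CSR V center (Tyr/Phe) and the
#' hydrophobic pair (H1 in F/W/Y, H2 in F/Y/M) is CGTase-like; a complete
#' triad with a non-aromatic CSR V center is alpha-amylase-like (the usual
#' replacement in amylases); an incomplete triad with at least four CSR
#' hits is another GH13 member; anything else is not recognizably GH13.
#'
#' @param report A `csr_report` from [map_csr()].
#' @return List of class `enzyme_class`: `label` (one of `CGTASE_LIKE`,
#'   `ALPHA_AMYLASE_LIKE`, `GH13_OTHER`, `NOT_GH13`) and `rationale`.
#' @export
classify_enzyme <- function(report) {
  triad <- !is.na(report$nucleophile_pos) && !is.na(report$glu_pos) &&
    !is.na(report$asp2_pos) &&
    identical(report$nucleophile_res, "D") &&
    identical(report$glu_res, "E") && identical(report$asp2_res, "D")
  center_arom <- report$csrV_center_res %in% c("Y", "F")
  h1_ok <- report$h1_res %in% c("F", "W", "Y")
  h2_ok <- report$h2_res %in% c("F", "Y", "M")
  n_hits <- nrow(report$hits)
  rationale <- c(
    sprintf("triad %s", if (triad) "complete" else "incomplete"),
    sprintf("CSR V center %s (%saromatic)", report$csrV_center_res,
            if (isTRUE(center_arom)) "" else "non-"),
    sprintf("H1 %s %s, H2 %s %s", report$h1_res,
            if (isTRUE(h1_ok)) "ok" else "fail",
            report$h2_res, if (isTRUE(h2_ok)) "ok" else "fail"),
    sprintf("%d CSR hits", n_hits))
  label <-
    if (triad && isTRUE(center_arom) && isTRUE(h1_ok) && isTRUE(h2_ok))
      "CGTASE_LIKE"
    else if (triad && !isTRUE(center_arom)) "ALPHA_AMYLASE_LIKE"
    else if (n_hits >= 4) "GH13_OTHER"
    else "NOT_GH13"
  structure(list(label = label, rationale = rationale),
            class = "enzyme_class")
}

#' @export
print.enzyme_class <- function(x, ...) {
  cat(sprintf("<enzyme_class> %s (%s)\n", x$label,
              paste(x$rationale, collapse = "; ")))
  invisible(x)
}
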