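#' Default parameters for the SPII signal-peptide detector
#'
#' The detector is a transparent rule model of bacterial lipoprotein
#' (signal peptidase II) signal peptides: a short positively charged
#' n-region, a hydrophobic h-region, and a lipobox whose last residue is the
#' invariant cysteine that becomes lipid-anchored after cleavage.
#'
#' Defaults: candidate Cys positions 15--35; n-region = residues 2--6 with
#' net charge (K/R = +1, D/E = -1) at least `n_charge_min`; h-region =
#' residues 7 up to three residues before the Cys, mean Kyte--Doolittle
#' hydropathy at least `h_score_min`; lipobox classes (positions -3..-1
#' before the Cys) are deliberately permissive relative to the canonical
#' \[LVI\]\[ASTVIG\]\[GAS\]C box so that naturally occurring boxes with an
#' aromatic -3 residue (e.g. ...F-S-G-C) are accepted.
#'
#' @param min_pos,max_pos Window of admissible lipobox Cys positions.
#' @param n_charge_min Minimum n-region net charge.
#' @param h_score_min Minimum mean hydropathy of the h-region.
#' @param lipobox_m3,lipobox_m2,lipobox_m1 Allowed residue classes at the
#'   three positions before the Cys.
#' @return A parameter list for [detect_spII()].
#' @export
sigpep_params <- function(min_pos = 15L, max_pos = 35L,
                          n_charge_min = 1, h_score_min = 1.0,
                          lipobox_m3 = c("L", "V", "I", "F", "A"),
                          lipobox_m2 = c("A", "S", "T", "V", "I", "G", "F"),
                          lipobox_m1 = c("G", "A", "S")) {
  list(min_pos = min_pos, max_pos = max_pos, n_charge_min = n_charge_min,
       h_score_min = h_score_min, lipobox_m3 = lipobox_m3,
       lipobox_m2 = lipobox_m2, lipobox_m1 = lipobox_m1)
}

#' Detect a lipoprotein (SPII) signal peptide
#'
#' Scans candidate lipobox cysteines from the N terminus and returns the
#' first (lowest-position) Cys whose n-region charge, h-region hydropathy
#' and lipobox residues all satisfy the rules; `NULL` when no window
#' qualifies (absence is a valid result). Cleavage is immediately before the
#' Cys, so `signal_len = cys_pos - 1`.
#'
#' @param record A [protein_record()] or sequence string.
#' @param params See [sigpep_params()].
#' @return `NULL`, or a list of class `spII_call` with `signal_len`,
#'   `cys_pos`, `lipobox` (4 residues ending in C), `n_charge`, `h_score`.
#' @examples
#' detect_spII(paste0("MRKNFKAFVALFAAILLFFSGC", strrep("AGS", 10)))
#' @export
detect_spII <- function(record, params = sigpep_params()) {
  seq <- if (inherits(record, "protein_record")) record$seq else toupper(record)
  if (!nzchar(seq)) stop("empty sequence", call. = FALSE)
  chars <- seq_chars(seq)
  n <- length(chars)
  if (n < params$max_pos) {
    if (n < params$min_pos) return(NULL)
  }
  hi <- min(params$max_pos, n)
  for (p in params$min_pos:hi) {
    if (chars[p] != "C") next
    # n-region: residues 2..6
    nreg <- chars[2:min(6, p - 1)]
    n_charge <- sum(nreg %in% c("K", "R")) - sum(nreg %in% c("D", "E"))
    if (n_charge < params$n_charge_min) next
    # h-region: residues 7 .. p-4 (up to the lipobox)
    if (p - 4 < 7) next
    hreg <- chars[7:(p - 4)]
    h_score <- mean(KYTE_DOOLITTLE[hreg])
    if (is.na(h_score) || h_score < params$h_score_min) next
    # lipobox -3..-1 classes
    if (!(chars[p - 3] %in% params$lipobox_m3)) next
    if (!(chars[p - 2] %in% params$lipobox_m2)) next
    if (!(chars[p - 1] %in% params$lipobox_m1)) next
    return(structure(list(
      signal_len = p - 1L, cys_pos = as.integer(p),
      lipobox = paste(chars[(p - 3):p], collapse = ""),
      n_charge = n_charge, h_score = h_score), class = "spII_call"))
  }
  NULL
}

#' @export
print.spII_call <- function(x, ...) {
  cat(sprintf(
    "<spII_call> signal 1..%d, lipobox %s (Cys%d), n-charge %+d, h %.2f\n",
    x$signal_len, x$lipobox, x$cys_pos, x$n_charge, x$h_score))
  invisible(x)
}
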