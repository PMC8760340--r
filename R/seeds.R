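# Packaged reference seeds.
#
# The seeds are synthetic consensus proteins built in code: a shared
# catalytic-core motif layout (CSR I-VII, the GSISNWN-like H1 motif, the
# catalytic triad with its Arg at -2, the aromatic CSR V center and the
# H1/H2 hydrophobic pair) embedded in seed-specific pseudo-random
# background, one seed per domain architecture. The three-domain seed
# reproduces the canonical precursor coordinates of the CldA-type enzymes
# (lipoprotein signal 1-21 with Cys22, H1 Trp204 in a 199-GSISNWN motif,
# triad Asp250/Glu279/Asp351, CSR V Phe216, H2 Met281, C domain 434-524,
# 524 residues in total), so coordinate arithmetic can be checked exactly
# without vendoring real accessions.

# Shared catalytic-core motif layout (1-based start, motif string).
CORE_MOTIFS <- list(
  VI  = list(start = 90L,  motif = "GVNAIWI"),
  I   = list(start = 140L, motif = "DVVANHA"),
  H1  = list(start = 199L, motif = "GSISNWN"),
  V   = list(start = 213L, motif = "DGAFVLN"),
  II  = list(start = 244L, motif = "GFQVRADKI"),
  III = list(start = 277L, motif = "AAEVMLD"),
  IV  = list(start = 348L, motif = "FIDDHDN"),
  VII = list(start = 374L, motif = "GQPVIAV"))

# Diagnostic-slot positions implied by the layout above.
CORE_SLOTS <- c(h1 = 204L, csrV_center = 216L, arg_minus2 = 248L,
                nucleophile = 250L, glu = 279L, asp2 = 351L, h2 = 281L)

CLD_SIGNAL <- "MRKNFKAFVALFAAILLFFSG"  # residues 1-21; Cys22 follows

# Fixed C-terminal extension sequences shared by the seeds that carry them.
cbm20_segment <- function() random_protein(90L, seed = 9101L)
earch_segment <- function() random_protein(90L, seed = 9102L)

make_seed <- function(id, length, bg_seed, motif_shift, signal = NULL,
                      tail = list(), domain_spans, architecture) {
  chars <- seq_chars(random_protein(length, seed = bg_seed))
  csr_spans <- list()
  for (nm in names(CORE_MOTIFS)) {
    m <- CORE_MOTIFS[[nm]]
    chars <- splice_motif(chars, m$start, m$motif)
    csr_spans[[nm]] <- c(m$start, m$start + nchar(m$motif) - 1L)
  }
  slots <- CORE_SLOTS
  if (!is.null(signal)) chars <- splice_motif(chars, 1L, paste0(signal, "C"))
  for (t in tail) chars <- splice_motif(chars, t$start, t$seq)
  structure(list(id = id, seq = paste(chars, collapse = ""),
                 csr_spans = csr_spans, slots = slots,
                 domain_spans = domain_spans, architecture = architecture),
            class = "reference_seed")
}

#' Packaged reference seeds for anchoring and coordinate transfer
#'
#' Four synthetic clan GH-H seeds, one per CGTase domain architecture:
#' a three-domain ABC seed (`CLD3`, 524 residues, lipoprotein signal
#' peptide, C domain 434-524), a conventional five-domain seed with a
#' CBM20 starch-binding E domain (`FIVE`), a four-domain seed whose CBM20
#' follows the C domain without a D-domain spacer (`FOUR`), and an
#' archaeal-type seed with a C-terminal E-arch domain (`ARCH`). All share
#' one catalytic-core motif layout (CSR I-VII, H1 motif, catalytic triad),
#' so CSR coordinates transfer consistently across architectures.
#'
#' @return Named list of `reference_seed` objects, each with fields `id`,
#'   `seq`, `csr_spans`, `slots` (diagnostic residue positions),
#'   `domain_spans`, `architecture`.
#' @export
cgt_reference_seeds <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    cbm <- cbm20_segment(); ear <- earch_segment()
    seeds <- list(
      CLD3 = make_seed(
        "CLD3", 524L, bg_seed = 9001L, signal = CLD_SIGNAL,
        domain_spans = list(A = c(22L, 433L), B = c(155L, 195L),
                            C = c(434L, 524L)),
        architecture = "ABC"),
      FIVE = make_seed(
        "FIVE", 700L, bg_seed = 9002L,
        tail = list(list(start = 611L, seq = cbm)),
        domain_spans = list(A = c(10L, 433L), B = c(155L, 195L),
                            C = c(434L, 520L), D = c(521L, 610L),
                            E_CBM20 = c(611L, 700L)),
        architecture = "ABCDE_CBM20"),
      FOUR = make_seed(
        "FOUR", 630L, bg_seed = 9003L,
        tail = list(list(start = 531L, seq = cbm)),
        domain_spans = list(A = c(10L, 433L), B = c(155L, 195L),
                            C = c(434L, 520L), E_CBM20 = c(531L, 620L)),
        architecture = "ABCE_CBM20"),
      ARCH = make_seed(
        "ARCH", 700L, bg_seed = 9004L,
        tail = list(list(start = 601L, seq = ear)),
        domain_spans = list(A = c(10L, 433L), B = c(155L, 195L),
                            C = c(434L, 520L), E_arch = c(601L, 690L)),
        architecture = "ABCDE_ARCH"))
    cache <<- seeds
    seeds
  }
})

#' @export
print.reference_seed <- function(x, ...) {
  cat(sprintf("<reference_seed> %s (%d aa, %s)\n", x$id, nchar(x$seq),
              x$architecture))
  invisible(x)
}

# Per-CSR log-odds profiles: add-one smoothed residue counts over the seed
# motif annotations, scored against a uniform 1/20 background.
csr_profiles <- function(refset = cgt_reference_seeds()) {
  profs <- list()
  for (nm in names(CORE_MOTIFS)) {
    mats <- lapply(refset, function(s) {
      sp <- s$csr_spans[[nm]]
      seq_chars(substr(s$seq, sp[1], sp[2]))
    })
    L <- length(mats[[1]])
    prof <- matrix(0, nrow = 20, ncol = L, dimnames = list(AA_STANDARD, NULL))
    for (j in seq_len(L)) {
      cnt <- table(factor(vapply(mats, `[`, "", j), levels = AA_STANDARD))
      prof[, j] <- log((as.numeric(cnt) + 1) / (length(mats) + 20) / (1 / 20))
    }
    profs[[nm]] <- prof
  }
  profs
}

# Score a residue window against a profile; X scores 0, gaps not allowed.
profile_score <- function(prof, window_chars) {
  if (length(window_chars) != ncol(prof)) return(NA_real_)
  sum(vapply(seq_along(window_chars), function(j) {
    r <- window_chars[j]
    if (r %in% rownames(prof)) prof[r, j] else 0
  }, 0))
}
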