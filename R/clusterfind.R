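# CM-CD gene-cluster detection: role assignment by best exemplar identity,
# sliding-window co-occurrence of the synthesis -> transport -> degradation
# chain, cassette-adjacency flags, and sigma-promoter box scanning.

# The minimal role chain required for a cluster call, and the EMP/extended
# roles that upgrade a call: all three published clusters carry the CORE
# chain, while e.g. the Thermoanaerobacterium-type cluster lacks Pgi, which
# is why the EMP genes are EXTENDED-tier evidence rather than CORE.
CMCD_CORE_ROLES <- c("CGTASE", "MDXE", "MDXF", "MDXG", "CDASE", "GP")
CMCD_EXTENDED_ROLES <- c("GA", "PGI", "PFKA", "PYKF")

CMCD_ACCESSORY_FAMILIES <- c(
  "hpr", "murB", "php", "rapZ", "rodZ", "whiA", "fae", "plt",
  "hgd_e1", "hgd_e2", "hbct", "cbs", "polIIIa", "pii", "pepT", "fnr",
  "mthfr", "metH", "trmA", "mate")

MDXE_SIGNAL <- "MKKYSKILALLTAMVFVLSIALTG"  # residues 1-24; Cys25 follows

#' Packaged role exemplars for CM-CD cluster annotation
#'
#' One synthetic exemplar protein per functional role of the CM-CD
#' pathway: the CGTase (the packaged three-domain seed), the MdxEFG sugar
#' ABC-importer components (MdxE carries a lipoprotein signal peptide with
#' the anchoring Cys), the cytoplasmic degradation enzymes (CDase,
#' glucoamylase GA, glucan phosphorylase GP), the EMP glycolysis steps
#' (Pgi, PfkA, PykF), the promiscuous MsmX ATPase, and twenty accessory
#' families co-encoded in the clusters (annotated `ACCESSORY`; they never
#' gate a cluster call).
#'
#' @return Named list: each element has `id`, `role`, `seq`.
#' @export
cmcd_role_exemplars <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    ex <- list()
    add <- function(id, role, seq) ex[[id]] <<- list(id = id, role = role,
                                                     seq = seq)
    add("cgtase_ex", "CGTASE", cgt_reference_seeds()$CLD3$seq)
    add("mdxE_ex", "MDXE",
        paste0(MDXE_SIGNAL, "C", random_protein(400L, seed = 9201L)))
    add("mdxF_ex", "MDXF", paste0("M", random_protein(289L, seed = 9202L)))
    add("mdxG_ex", "MDXG", paste0("M", random_protein(279L, seed = 9203L)))
    add("cdase_ex", "CDASE", paste0("M", random_protein(579L, seed = 9204L)))
    add("ga_ex", "GA", paste0("M", random_protein(649L, seed = 9205L)))
    add("gp_ex", "GP", paste0("M", random_protein(699L, seed = 9206L)))
    add("pgi_ex", "PGI", paste0("M", random_protein(449L, seed = 9207L)))
    add("pfkA_ex", "PFKA", paste0("M", random_protein(319L, seed = 9208L)))
    add("pykF_ex", "PYKF", paste0("M", random_protein(469L, seed = 9209L)))
    add("msmX_ex", "MSMX", paste0("M", random_protein(364L, seed = 9210L)))
    for (i in seq_along(CMCD_ACCESSORY_FAMILIES))
      add(paste0(CMCD_ACCESSORY_FAMILIES[i], "_ex"), "ACCESSORY",
          paste0("M", random_protein(150L + 13L * i, seed = 9300L + i)))
    cache <<- ex
    ex
  }
})

#' Assign CM-CD functional roles to proteins
#'
#' Each protein is globally aligned against every exemplar; the
#' best-scoring exemplar's role is accepted when identity and coverage
#' clear the thresholds (defaults 30% / 70%), otherwise the role is
#' `NONE`. MdxE candidates are additionally checked for a lipobox Cys with
#' [detect_spII()] (reported as `lipobox_ok`; the anchoring cysteine is
#' what tethers MdxE to the outer face of the membrane).
#'
#' @param proteins List of [protein_record()]s.
#' @param exemplars Exemplar list, defaults to [cmcd_role_exemplars()].
#' @param identity_min,coverage_min Acceptance thresholds (percent).
#' @return Data frame: `gene_id`, `role`, `identity_pct`, `coverage_pct`,
#'   `best_exemplar`, `lipobox_ok`.
#' @export
assign_roles <- function(proteins, exemplars = cmcd_role_exemplars(),
                         identity_min = 30, coverage_min = 70) {
  if (length(exemplars) == 0) stop("empty exemplar set", call. = FALSE)
  if (length(proteins) == 0)
    return(data.frame(gene_id = character(), role = character(),
                      identity_pct = numeric(), coverage_pct = numeric(),
                      best_exemplar = character(), lipobox_ok = logical()))
  pset <- Biostrings::AAStringSet(vapply(proteins, `[[`, "", "seq"))
  # one vectorized aligner call per exemplar, all proteins at once
  scores <- vapply(exemplars, function(e)
    Biostrings::score(Biostrings::pairwiseAlignment(
      pset, Biostrings::AAString(e$seq),
      substitutionMatrix = blosum62(), gapOpening = 11, gapExtension = 1,
      type = "global")), numeric(length(proteins)))
  scores <- matrix(scores, nrow = length(proteins))
  rows <- lapply(seq_along(proteins), function(i) {
    best <- which.max(scores[i, ])
    al <- global_align(proteins[[i]], exemplars[[best]]$seq)
    ok <- al$identity_pct >= identity_min && al$coverage_pct >= coverage_min
    role <- if (ok) exemplars[[best]]$role else "NONE"
    lip <- NA
    if (role == "MDXE") lip <- !is.null(detect_spII(proteins[[i]]))
    data.frame(gene_id = proteins[[i]]$id, role = role,
               identity_pct = round(al$identity_pct, 1),
               coverage_pct = round(al$coverage_pct, 1),
               best_exemplar = exemplars[[best]]$id, lipobox_ok = lip)
  })
  do.call(rbind, rows)
}

#' Detect CM-CD gene clusters
#'
#' Slides a window of at most `window_genes` consecutive genes along each
#' contig; windows containing the complete CORE role chain (CGTase,
#' MdxE/F/G, CDase, GP) are emitted, overlapping windows merged, and each
#' merged call trimmed to its first/last role-bearing gene. Each call
#' carries `cassette_adjacent` (MdxE/F/G consecutive on one strand with at
#' most one intervening gene between successive members), `cgt_upstream`
#' (the cassette starts within one gene downstream of a CGTase gene), and
#' a completeness tier: `CORE`, or `EXTENDED` when at least two of the
#' GA/Pgi/PfkA/PykF roles are also present. MsmX assignments are reported
#' genome-wide and flagged distal when they fall outside every call, since
#' the MsmX ATPase gene sits away from the clusters it energizes.
#'
#' @param genes List of [gene_model()]s sorted by contig then start.
#' @param roles Data frame from [assign_roles()].
#' @param window_genes Sliding-window size in genes.
#' @return List of class `cmcd_scan`: `calls` (list of cluster calls) and
#'   `msmx` (data frame of MsmX genes with a `distal` flag).
#' @export
find_cmcd_clusters <- function(genes, roles, window_genes = 40L) {
  gene_ids <- vapply(genes, `[[`, "", "gene_id")
  contigs <- vapply(genes, `[[`, "", "contig")
  role_of <- setNames(roles$role, roles$gene_id)[gene_ids]
  role_of[is.na(role_of)] <- "NONE"
  calls <- list()
  for (ctg in unique(contigs)) {
    idx <- which(contigs == ctg)
    n <- length(idx)
    marked <- logical(n)
    for (i in seq_len(n)) {
      j <- min(i + window_genes - 1L, n)
      win_roles <- role_of[idx[i:j]]
      if (all(CMCD_CORE_ROLES %in% win_roles)) marked[i:j] <- TRUE
    }
    if (!any(marked)) next
    r <- rle(marked)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    for (k in which(r$values)) {
      lo <- starts[k]; hi <- ends[k]
      span_roles <- role_of[idx[lo:hi]]
      with_role <- which(span_roles != "NONE")
      lo2 <- lo + with_role[1] - 1L
      hi2 <- lo + with_role[length(with_role)] - 1L
      span_idx <- idx[lo2:hi2]
      if (!all(CMCD_CORE_ROLES %in% role_of[span_idx])) next
      calls[[length(calls) + 1]] <-
        cluster_call(genes[span_idx], role_of[span_idx], ctg,
                     first = lo2, last = hi2)
    }
  }
  msmx_idx <- which(role_of == "MSMX")
  in_call <- rep(FALSE, length(msmx_idx))
  for (cc in calls)
    in_call <- in_call | gene_ids[msmx_idx] %in% cc$gene_ids
  msmx <- data.frame(gene_id = gene_ids[msmx_idx],
                     contig = contigs[msmx_idx],
                     distal = !in_call)
  structure(list(calls = calls, msmx = msmx), class = "cmcd_scan")
}

cluster_call <- function(span_genes, span_roles, contig, first, last) {
  ids <- vapply(span_genes, `[[`, "", "gene_id")
  strands <- vapply(span_genes, `[[`, "", "strand")
  cassette <- match(c("MDXE", "MDXF", "MDXG"), span_roles)
  cassette_adjacent <- !anyNA(cassette) &&
    all(diff(cassette) >= 1) && all(diff(cassette) <= 2) &&
    length(unique(strands[cassette])) == 1
  cgt_idx <- which(span_roles == "CGTASE")
  cgt_upstream <- cassette_adjacent && length(cgt_idx) > 0 &&
    any(cassette[1] - cgt_idx >= 1 & cassette[1] - cgt_idx <= 2)
  present <- unique(span_roles[span_roles != "NONE"])
  tier <- if (sum(CMCD_EXTENDED_ROLES %in% present) >= 2) "EXTENDED"
          else "CORE"
  structure(list(contig = contig, gene_span = unname(c(first, last)),
                 n_genes = length(span_genes), gene_ids = ids,
                 roles = span_roles, roles_present = present,
                 cassette_adjacent = cassette_adjacent,
                 cgt_upstream = cgt_upstream, tier = tier),
            class = "cluster_call")
}

#' @export
print.cluster_call <- function(x, ...) {
  cat(sprintf(
    "<cluster_call> %s genes %d-%d (%d genes, %s tier)%s%s\n",
    x$contig, x$gene_span[1], x$gene_span[2], x$n_genes, x$tier,
    if (x$cassette_adjacent) ", mdxEFG cassette" else "",
    if (x$cgt_upstream) " downstream of CGTase" else ""))
  invisible(x)
}

#' @export
print.cmcd_scan <- function(x, ...) {
  cat(sprintf("<cmcd_scan> %d cluster call(s), %d MsmX gene(s)\n",
              length(x$calls), nrow(x$msmx)))
  for (cc in x$calls) print(cc)
  invisible(x)
}

# Position weight matrices for the sigma-promoter boxes, trained on the two
# deduced promoter box pairs plus the sigma-A consensus, add-one smoothed
# against a uniform nucleotide background.
promoter_pwms <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    build <- function(seqs) {
      mats <- lapply(seqs, seq_chars)
      prof <- matrix(0, 4, 6, dimnames = list(c("A", "C", "G", "T"), NULL))
      for (j in 1:6) {
        cnt <- table(factor(vapply(mats, `[`, "", j),
                            levels = c("A", "C", "G", "T")))
        prof[, j] <- log((as.numeric(cnt) + 1) / (length(mats) + 4) / 0.25)
      }
      prof
    }
    cache <<- list(box35 = build(c("TGCACT", "TTTCGA", "TTGACA")),
                   box10 = build(c("TAATAT", "CATATT", "TATAAT")))
    cache
  }
})

#' Scan an upstream window for sigma-promoter box pairs
#'
#' Scores every hexamer of the window against -35 and -10 position weight
#' matrices and reports all (box35, box10) pairs where both boxes clear
#' `box_min` and the spacer (nucleotides between the boxes) lies in
#' `spacer_range`. Hits are sorted best-first by total score.
#'
#' @param dna_window Strand-oriented upstream DNA string (typically the
#'   200 nt upstream of a CGTase gene); windows shorter than 30 nt return
#'   no hits.
#' @param spacer_range Allowed spacer lengths, inclusive.
#' @param box_min Per-box log-odds acceptance threshold; the default of
#'   2.3 admits every box the PWMs were trained on while keeping random
#'   200-nt windows nearly always empty.
#' @return Data frame: `pos_35`, `pos_10` (1-based starts in the window),
#'   `spacer`, `score`.
#' @export
scan_promoter <- function(dna_window, spacer_range = c(15L, 19L),
                          box_min = 2.3) {
  dna <- toupper(dna_window)
  out <- data.frame(pos_35 = integer(), pos_10 = integer(),
                    spacer = integer(), score = numeric())
  if (nchar(dna) < 30) return(out)
  chars <- seq_chars(dna)
  pwms <- promoter_pwms()
  hex_score <- function(pwm, st) {
    w <- chars[st:(st + 5L)]
    if (!all(w %in% rownames(pwm))) return(-Inf)
    sum(vapply(1:6, function(j) pwm[w[j], j], 0))
  }
  n <- length(chars)
  s35 <- vapply(seq_len(n - 5L), function(st) hex_score(pwms$box35, st), 0)
  s10 <- vapply(seq_len(n - 5L), function(st) hex_score(pwms$box10, st), 0)
  for (p35 in which(s35 >= box_min)) {
    for (sp in spacer_range[1]:spacer_range[2]) {
      p10 <- p35 + 6L + sp
      if (p10 > n - 5L) next
      if (s10[p10] >= box_min)
        out <- rbind(out, data.frame(pos_35 = p35, pos_10 = p10,
                                     spacer = sp,
                                     score = s35[p35] + s10[p10]))
    }
  }
  out[order(-out$score), , drop = FALSE]
}
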