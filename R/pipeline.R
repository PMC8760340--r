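#' Scan one protein through the classification stages
#'
#' Anchors the query to the packaged seeds, transfers CSR coordinates,
#' classifies the enzyme and its domain architecture, and runs the SPII
#' signal-peptide detector. A query that does not anchor is `NOT_GH13`
#' with architecture `OTHER`.
#'
#' @param record A [protein_record()] or sequence string.
#' @param refset Seed list, defaults to [cgt_reference_seeds()].
#' @return List of class `protein_scan`: `anchor`, `report` (`csr_report`
#'   or `NULL`), `class` label, `arch` (`architecture_call`), `sigpep`.
#' @export
scan_protein <- function(record, refset = cgt_reference_seeds()) {
  anchor <- anchor_to_reference(record, refset)
  report <- NULL
  cls <- "NOT_GH13"
  if (!is.null(anchor)) {
    report <- map_csr(record, anchor)
    cls <- classify_enzyme(report)$label
  }
  arch <- classify_architecture(record, anchor)
  sp <- detect_spII(record)
  structure(list(anchor = anchor, report = report, class = cls,
                 arch = arch, sigpep = sp), class = "protein_scan")
}

#' @export
print.protein_scan <- function(x, ...) {
  cat(sprintf("<protein_scan> %s, architecture %s, signal %s\n", x$class,
              x$arch$label,
              if (is.null(x$sigpep)) "none"
              else sprintf("1..%d", x$sigpep$signal_len)))
  invisible(x)
}

#' Run the mining pipeline
#'
#' Orchestrates the full screen over a proteome and (optionally) an
#' annotated genome: per protein, seed anchoring, enzyme class, domain
#' architecture, SPII signal peptide and the novelty filter against the
#' packaged seeds; per genome, CM-CD role assignment, cluster detection
#' and sigma-promoter scanning upstream of CGTase-like genes. All
#' thresholds used are echoed in the returned config.
#'
#' @param proteins List of [protein_record()]s, or a FASTA path.
#' @param genes Optional list of [gene_model()]s (e.g. from
#'   [read_gff3()] or [synthetic_gene_models()]).
#' @param contigs Optional named character vector of contig DNA (needed
#'   for promoter scanning).
#' @param novelty_threshold Novelty-filter identity threshold (percent).
#' @param novelty_refs References for the novelty filter; defaults to the
#'   packaged seed sequences.
#' @param run_phylo_stage Unused toggle kept for stage isolation: the
#'   classification output never depends on the phylogenetic stage.
#' @param upstream_nt Length of the promoter scan window.
#' @return List of class `mining_report`: `proteins` (one row per query),
#'   `clusters` (a `cmcd_scan` or `NULL`), `promoters`, `config`.
#' @export
run_mine <- function(proteins, genes = NULL, contigs = NULL,
                     novelty_threshold = 45, novelty_refs = NULL,
                     run_phylo_stage = FALSE, upstream_nt = 200L) {
  if (is.character(proteins) && length(proteins) == 1)
    proteins <- read_fasta(proteins)
  refset <- cgt_reference_seeds()
  if (is.null(novelty_refs))
    novelty_refs <- lapply(refset, function(s) protein_record(s$id, s$seq))
  rows <- lapply(proteins, function(p) {
    sc <- scan_protein(p, refset)
    nov <- novelty_filter(p, novelty_refs, novelty_threshold)
    data.frame(
      id = p$id,
      anchored = !is.null(sc$anchor),
      anchor_ref = if (is.null(sc$anchor)) NA_character_ else
        sc$anchor$ref$id,
      class = sc$class,
      arch = sc$arch$label,
      signal_len = if (is.null(sc$sigpep)) NA_integer_ else
        sc$sigpep$signal_len,
      cys_pos = if (is.null(sc$sigpep)) NA_integer_ else sc$sigpep$cys_pos,
      novelty_keep = nov$keep,
      novelty_best = nov$best_id,
      novelty_identity = nov$identity_pct)
  })
  prot_df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(id = character(), anchored = logical(),
               anchor_ref = character(), class = character(),
               arch = character(), signal_len = integer(),
               cys_pos = integer(), novelty_keep = logical(),
               novelty_best = character(), novelty_identity = numeric())

  clusters <- NULL; promoters <- NULL
  if (!is.null(genes)) {
    gene_prots <- lapply(genes, `[[`, "protein")
    roles <- assign_roles(gene_prots)
    clusters <- find_cmcd_clusters(genes, roles)
    if (!is.null(contigs)) {
      cand <- prot_df$id[prot_df$class == "CGTASE_LIKE"]
      phits <- list()
      for (g in genes) {
        if (!g$gene_id %in% cand) next
        win <- upstream_window(contigs, g, upstream_nt)
        if (is.null(win)) next
        hits <- scan_promoter(win)
        if (nrow(hits) > 0) {
          best <- hits[1, ]
          phits[[length(phits) + 1]] <- cbind(
            data.frame(gene_id = g$gene_id, contig = g$contig), best)
        }
      }
      promoters <- if (length(phits)) do.call(rbind, phits) else
        data.frame(gene_id = character(), contig = character(),
                   pos_35 = integer(), pos_10 = integer(),
                   spacer = integer(), score = numeric())
    }
  }
  structure(list(proteins = prot_df, clusters = clusters,
                 promoters = promoters,
                 config = list(novelty_threshold = novelty_threshold,
                               upstream_nt = upstream_nt,
                               version = as.character(
                                 utils::packageVersion("cdmine")))),
            class = "mining_report")
}

# Strand-oriented upstream window of a gene; NULL when off-contig.
upstream_window <- function(contigs, gene, upstream_nt) {
  dna <- contigs[[gene$contig]]
  if (is.null(dna)) return(NULL)
  if (gene$strand == "+") {
    en <- gene$start - 1L
    st <- max(1L, en - upstream_nt + 1L)
    if (en < 1L) return(NULL)
    substr(dna, st, en)
  } else {
    st <- gene$end + 1L
    en <- min(nchar(dna), st + upstream_nt - 1L)
    if (st > nchar(dna)) return(NULL)
    as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(substr(dna, st, en))))
  }
}

#' @export
print.mining_report <- function(x, ...) {
  cat(sprintf("<mining_report> %d protein(s)\n", nrow(x$proteins)))
  if (nrow(x$proteins) > 0)
    print(table(x$proteins$class))
  if (!is.null(x$clusters)) print(x$clusters)
  invisible(x)
}

#' Write a mining report to TSV and JSON
#'
#' @param report A `mining_report` from [run_mine()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_mine_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(report$proteins, file.path(dir, "proteins.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(report$promoters))
    utils::write.table(report$promoters, file.path(dir, "promoters.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(report$clusters)) {
    calls <- lapply(report$clusters$calls, unclass)
    jsonlite::write_json(
      list(calls = calls, msmx = report$clusters$msmx,
           config = report$config),
      file.path(dir, "clusters.json"), auto_unbox = TRUE, digits = NA)
  }
  jsonlite::write_json(report$config, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
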