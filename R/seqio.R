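#' Protein record
#'
#' Lightweight container for a protein sequence. Residue coordinates used
#' throughout the package are 1-based on the sequence exactly as provided
#' (precursor numbering: position 1 is the initiator Met when present).
#'
#' @param id Record identifier (first whitespace-delimited header token).
#' @param seq Amino-acid string over the 20 standard letters plus `X`.
#' @param description Remainder of the FASTA header, possibly empty.
#' @return An object of class `protein_record` with fields `id`,
#'   `description` and `seq`.
#' @examples
#' protein_record("p1", "MKKLLVAC")
#' @export
protein_record <- function(id, seq, description = "") {
  stopifnot(is.character(id), length(id) == 1, nzchar(id),
            is.character(seq), length(seq) == 1)
  if (!nzchar(seq)) stop("empty sequence for record '", id, "'", call. = FALSE)
  seq <- toupper(seq)
  assert_protein_alphabet(seq, id)
  structure(list(id = id, description = description, seq = seq),
            class = "protein_record")
}

#' @export
print.protein_record <- function(x, ...) {
  cat(sprintf("<protein_record> %s (%d aa)%s\n", x$id, nchar(x$seq),
              if (nzchar(x$description)) paste0(" ", x$description) else ""))
  invisible(x)
}

#' Read a protein FASTA file
#'
#' Wrapper over [Biostrings::readAAStringSet()] that enforces the package
#' conventions: unique record identifiers (no silent overwrite), a non-empty
#' sequence per record, and the 20-standard-letters-plus-X alphabet.
#'
#' @param path Path to a FASTA file.
#' @return A list of [protein_record()] objects in file order; an empty list
#'   for an empty file.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (file.size(path) == 0) return(list())
  set <- tryCatch(
    Biostrings::readAAStringSet(path),
    error = function(e) stop("FASTA parse error in '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  if (anyDuplicated(ids))
    stop("duplicate FASTA id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  recs <- vector("list", length(set))
  for (i in seq_along(set))
    recs[[i]] <- protein_record(ids[i], as.character(set[[i]]), desc[i])
  recs
}

#' Write protein records to FASTA
#'
#' @param records List of [protein_record()] objects.
#' @param path Output path. Sequences are wrapped at 60 columns.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  set <- Biostrings::AAStringSet(vapply(records, `[[`, "", "seq"))
  names(set) <- vapply(records, function(r)
    if (nzchar(r$description)) paste(r$id, r$description) else r$id, "")
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}

#' Gene model
#'
#' One protein-coding gene: 1-based inclusive nucleotide coordinates on its
#' contig (GFF3 dialect) plus the translated product.
#'
#' @param gene_id Gene identifier.
#' @param contig Contig name.
#' @param start,end 1-based inclusive coordinates, `start <= end`.
#' @param strand `"+"` or `"-"`.
#' @param protein The translated product as a [protein_record()].
#' @return An object of class `gene_model`.
#' @export
gene_model <- function(gene_id, contig, start, end, strand, protein) {
  stopifnot(start >= 1, start <= end, strand %in% c("+", "-"))
  structure(list(gene_id = gene_id, contig = contig,
                 start = as.integer(start), end = as.integer(end),
                 strand = strand, protein = protein),
            class = "gene_model")
}

#' Read CDS features from GFF3 with their genome
#'
#' Parses a GFF3 annotation (via [rtracklayer::readGFF()]), extracts CDS
#' features, translates each from the genome FASTA (reverse-complementing
#' minus-strand features), and returns gene models sorted by contig then
#' start coordinate.
#'
#' @param path GFF3 file (must carry the `##gff-version 3` pragma).
#' @param fasta_path Genome FASTA with the contigs named in the GFF3.
#' @return List of [gene_model()] objects.
#' @export
read_gff3 <- function(path, fasta_path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  first <- readLines(path, n = 1)
  if (!grepl("^##gff-version\\s+3", first))
    stop("missing '##gff-version 3' pragma in ", path, call. = FALSE)
  gff <- as.data.frame(rtracklayer::readGFF(path))
  gff <- gff[gff$type == "CDS", , drop = FALSE]
  genome <- Biostrings::readDNAStringSet(fasta_path)
  names(genome) <- sub("\\s.*$", "", names(genome))
  if (nrow(gff) == 0) return(list())
  if (!"ID" %in% names(gff) || anyNA(gff$ID) || any(!nzchar(gff$ID)))
    stop("CDS feature without an ID attribute", call. = FALSE)
  gff <- gff[order(as.character(gff$seqid), gff$start), , drop = FALSE]
  models <- vector("list", nrow(gff))
  for (i in seq_len(nrow(gff))) {
    contig <- as.character(gff$seqid[i])
    if (!contig %in% names(genome))
      stop("contig '", contig, "' not in genome FASTA", call. = FALSE)
    st <- gff$start[i]; en <- gff$end[i]
    if (st < 1 || en > length(genome[[contig]]))
      stop("CDS '", gff$ID[i], "' outside contig bounds", call. = FALSE)
    if ((en - st + 1) %% 3 != 0)
      stop("CDS '", gff$ID[i], "' length not divisible by 3", call. = FALSE)
    dna <- Biostrings::subseq(genome[[contig]], st, en)
    if (as.character(gff$strand[i]) == "-")
      dna <- Biostrings::reverseComplement(dna)
    aa <- as.character(Biostrings::translate(dna))
    aa <- sub("\\*$", "", aa)  # strip the stop
    models[[i]] <- gene_model(as.character(gff$ID[i]), contig, st, en,
                              as.character(gff$strand[i]),
                              protein_record(as.character(gff$ID[i]), aa))
  }
  models
}

#' Molecular mass and isoelectric point
#'
#' Average molecular mass is the sum of average residue masses plus one
#' water. The theoretical isoelectric point is found by bisection on the
#' Henderson--Hasselbalch net charge using the pinned EMBOSS-style pKa set
#' (see `?"cdmine-constants"`). `X` residues are rejected: an ambiguity code
#' has no mass.
#'
#' @param record A [protein_record()] (or a plain sequence string).
#' @return List with `mw_da` (Daltons) and `pi`.
#' @examples
#' compute_physchem(protein_record("g", "G"))$mw_da  # 75.07
#' @export
compute_physchem <- function(record) {
  seq <- if (inherits(record, "protein_record")) record$seq else toupper(record)
  chars <- seq_chars(seq)
  if ("X" %in% chars)
    stop("sequence contains X; mass/pI undefined", call. = FALSE)
  assert_protein_alphabet(seq, allow_x = FALSE)
  mw <- sum(AA_MONO_AVG_MASS[chars]) + WATER_MASS
  counts <- table(factor(chars, levels = AA_STANDARD))
  charge_at <- function(ph) {
    pos <- 1 / (1 + 10^(ph - PKA_TERMINI[["nterm"]])) +
      sum(vapply(c("K", "R", "H"), function(a)
        counts[[a]] / (1 + 10^(ph - PKA_SIDECHAIN[[a]])), 0))
    neg <- 1 / (1 + 10^(PKA_TERMINI[["cterm"]] - ph)) +
      sum(vapply(c("D", "E", "C", "Y"), function(a)
        counts[[a]] / (1 + 10^(PKA_SIDECHAIN[[a]] - ph)), 0))
    pos - neg
  }
  lo <- 0; hi <- 14
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    if (charge_at(mid) > 0) lo <- mid else hi <- mid
  }
  list(mw_da = mw, pi = (lo + hi) / 2)
}
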