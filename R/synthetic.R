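# Synthetic proteomes and annotated genomes with known truth. The
# generator's defaults emulate the statistical structure of the mined
# families and clusters: an identity ladder echoing the reported 98/80/45/38
# percent levels among three-domain CGTases, CGTases of every architecture,
# alpha-amylase-like and knockout decoys, and one genome carrying a
# 30-gene cld-style CM-CD cluster (synthesis, mdxEFG cassette, degradation,
# EMP genes, twenty accessory families) plus a decoy cluster missing a core
# role and a distally placed msmX gene.

#' Substitution-only mutation to a target percent identity
#'
#' Applies exactly `round((1 - target/100) * n)` residue substitutions at
#' distinct unprotected positions (no indels), so the realized column-wise
#' identity equals the target up to rounding. Deterministic per seed.
#'
#' @param seq Sequence string or [protein_record()].
#' @param target_pct Target identity in \[20, 100\].
#' @param seed Integer seed.
#' @param protect_positions Integer positions that must not be mutated.
#' @return The mutated sequence string.
#' @export
mutate_to_identity <- function(seq, target_pct, seed,
                               protect_positions = integer()) {
  s <- if (inherits(seq, "protein_record")) seq$seq else toupper(seq)
  stopifnot(target_pct >= 20, target_pct <= 100)
  chars <- seq_chars(s)
  n <- length(chars)
  k <- round((1 - target_pct / 100) * n)
  if (k == 0) return(s)
  free <- setdiff(seq_len(n), protect_positions)
  if (length(free) < k)
    stop("identity target unreachable with the protected positions",
         call. = FALSE)
  with_seed(seed, {
    pos <- sample(free, k)
    for (p in pos)
      chars[p] <- sample(setdiff(AA_STANDARD, chars[p]), 1)
  })
  paste(chars, collapse = "")
}

#' Evolve a family along a tree by substitution
#'
#' Starting from the root sequence, draws `Poisson(branch_length * rate *
#' length)` substitutions on every branch (substitution-only, so the
#' resulting leaves are an alignment with no indels). Deterministic per
#' seed.
#'
#' @param root_seq Root sequence string.
#' @param tree A `phylo` tree with branch lengths.
#' @param rate Expected substitutions per site per unit branch length.
#' @param seed Integer seed.
#' @return Named character vector of leaf sequences (tip labels as names).
#' @export
evolve_family <- function(root_seq, tree, rate, seed) {
  stopifnot(rate >= 0, !is.null(tree$edge.length))
  n <- nchar(root_seq)
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  seqs <- vector("list", ntip + tree$Nnode)
  seqs[[root]] <- seq_chars(toupper(root_seq))
  tree <- ape::reorder.phylo(tree, "cladewise")  # edges in preorder
  with_seed(seed, {
    for (k in seq_len(nrow(tree$edge))) {
      par <- tree$edge[k, 1]; ch <- tree$edge[k, 2]
      chars <- seqs[[par]]
      nsub <- stats::rpois(1, tree$edge.length[k] * rate * n)
      if (nsub > 0) {
        pos <- sample.int(n, min(nsub, n))
        for (p in pos) chars[p] <- sample(setdiff(AA_STANDARD, chars[p]), 1)
      }
      seqs[[ch]] <- chars
    }
  })
  out <- vapply(seq_len(ntip), function(i) paste(seqs[[i]], collapse = ""),
                "")
  names(out) <- tree$tip.label
  out
}

#' Construct a classification decoy from an annotated seed
#'
#' `AMYLASE_FLIP` replaces the CSR V aromatic center with Leu (the
#' CGTase-to-amylase conversion edit); `TRIAD_KO` replaces the catalytic
#' nucleophile Asp with Ala; `TRUNCATE` cuts the sequence inside domain B;
#' `SHUFFLE` permutes all residues (destroying any anchorable homology).
#'
#' @param seed_obj A `reference_seed` (slot annotations are required for
#'   the targeted edits).
#' @param kind One of `AMYLASE_FLIP`, `TRIAD_KO`, `TRUNCATE`, `SHUFFLE`.
#' @param seed Integer seed (used by `SHUFFLE`).
#' @return List with `seq` and `truth` (the expected downstream label).
#' @export
make_decoy <- function(seed_obj, kind, seed = 1) {
  stopifnot(inherits(seed_obj, "reference_seed"))
  kind <- match.arg(kind, c("AMYLASE_FLIP", "TRIAD_KO", "TRUNCATE",
                            "SHUFFLE"))
  chars <- seq_chars(seed_obj$seq)
  if (kind == "AMYLASE_FLIP") {
    p <- seed_obj$slots[["csrV_center"]]
    if (is.na(p)) stop("CSR V center slot absent", call. = FALSE)
    chars[p] <- "L"
    return(list(seq = paste(chars, collapse = ""),
                truth = "ALPHA_AMYLASE_LIKE"))
  }
  if (kind == "TRIAD_KO") {
    p <- seed_obj$slots[["nucleophile"]]
    if (is.na(p)) stop("nucleophile slot absent", call. = FALSE)
    chars[p] <- "A"
    return(list(seq = paste(chars, collapse = ""), truth = "GH13_OTHER"))
  }
  if (kind == "TRUNCATE") {
    b <- seed_obj$domain_spans$B
    if (is.null(b)) stop("domain B span absent", call. = FALSE)
    cut <- floor(mean(b))
    return(list(seq = paste(chars[1:cut], collapse = ""),
                truth = "NOT_GH13"))
  }
  shuffled <- with_seed(seed, paste(sample(chars), collapse = ""))
  list(seq = shuffled, truth = "NOT_GH13")
}

#' Simulation configuration
#'
#' Defaults define the study conditions the generator emulates: a
#' three-domain family at the reported identity ladder (98, 80, 45, 38
#' percent to the packaged three-domain seed), tail-bearing architectures
#' at 98/80/60 percent, one full cld-style 30-gene cluster with the mdxEFG
#' cassette immediately downstream of the CGTase gene and a
#' TGCACT-17bp-TAATAT promoter upstream of it, a decoy cluster missing the
#' MdxF core role, and a distal msmX gene.
#'
#' @param seed Master integer seed; fixes all randomness.
#' @param abc_identity_ladder Identities for the planted three-domain
#'   variants.
#' @param arch_identities Identities for the planted five/four-domain and
#'   archaeal-type variants.
#' @param role_identities Named identities used for cluster gene proteins.
#' @param intergenic_len Intergenic gap length (nt).
#' @param n_flank Random flank genes on each side of the planted cluster.
#' @param promoter_spacer Spacer planted between the promoter boxes.
#' @param n_clusters Number of planted full clusters (0 or 1).
#' @return A config list for [build_synthetic_genome()].
#' @export
sim_config <- function(seed = 1L,
                       abc_identity_ladder = c(98, 80, 45, 38),
                       arch_identities = c(98, 80, 60),
                       role_identities = c(
                         CGTASE = 98, MDXE = 40, MDXF = 40, MDXG = 40,
                         CDASE = 88, GA = 60, GP = 60, PGI = 60,
                         PFKA = 60, PYKF = 60, MSMX = 64, ACCESSORY = 60),
                       intergenic_len = 150L, n_flank = 8L,
                       promoter_spacer = 17L, n_clusters = 1L) {
  stopifnot(all(abc_identity_ladder >= 20 & abc_identity_ladder <= 100),
            n_clusters %in% c(0L, 1L))
  list(seed = as.integer(seed),
       abc_identity_ladder = abc_identity_ladder,
       arch_identities = arch_identities,
       role_identities = role_identities,
       intergenic_len = as.integer(intergenic_len),
       n_flank = as.integer(n_flank),
       promoter_spacer = as.integer(promoter_spacer),
       n_clusters = as.integer(n_clusters))
}

# Fixed reverse-translation codon table (one codon per residue).
CODON_OF <- c(
  A = "GCT", R = "CGT", N = "AAT", D = "GAT", C = "TGT", Q = "CAA",
  E = "GAA", G = "GGT", H = "CAT", I = "ATT", L = "CTT", K = "AAA",
  M = "ATG", F = "TTT", P = "CCT", S = "TCT", T = "ACT", W = "TGG",
  Y = "TAT", V = "GTT")

reverse_translate <- function(protein_seq) {
  paste0(paste(CODON_OF[seq_chars(protein_seq)], collapse = ""), "TAA")
}

random_dna <- function(n, seed) {
  with_seed(seed, paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                        collapse = ""))
}

# Positions that must survive mutation for a planted CGTase to keep its
# truth labels: signal + lipobox Cys, every CSR span, diagnostic slots.
cgtase_protected_positions <- function(seed_obj, with_signal = TRUE) {
  pos <- unlist(lapply(seed_obj$csr_spans, function(sp) sp[1]:sp[2]))
  pos <- c(pos, unname(seed_obj$slots),
           unname(seed_obj$slots[c("nucleophile")]) - 2L)
  if (with_signal) pos <- c(pos, 1:22)
  sort(unique(pos))
}

# Remove chance lipobox signals from a protein meant to carry none: any Cys
# in the candidate window that yields a call is substituted by Ser.
strip_chance_signal <- function(seq) {
  repeat {
    call <- detect_spII(seq)
    if (is.null(call)) return(seq)
    chars <- seq_chars(seq)
    chars[call$cys_pos] <- "S"
    seq <- paste(chars, collapse = "")
  }
}

#' Build a synthetic annotated genome with ground truth
#'
#' Produces two contigs. Contig `ctgA` carries random flank genes, then the
#' planted 30-gene cld-style cluster in the canonical role order (CGTase;
#' mdxEFG cassette immediately downstream on one strand; CDase, GA, GP;
#' Pgi, PfkA, PykF; twenty accessory genes), with sigma-promoter boxes
#' planted upstream of the CGTase gene, then flank genes. Contig `ctgB`
#' carries a decoy cluster missing the MdxF core role, a distal msmX gene,
#' the three-domain identity ladder, tail-bearing architecture variants,
#' and the four classification decoys, separated by random genes. Cluster
#' gene proteins are exemplar mutants at the configured role identities;
#' planted CGTases keep their signal peptide and diagnostic slots through
#' mutation, and proteins meant to carry no signal peptide are guaranteed
#' clean by construction.
#'
#' @param config A [sim_config()].
#' @return List of class `synthetic_genome`: `contigs` (named DNA
#'   strings), `genes` (data frame: gene_id, contig, start, end, strand),
#'   `proteins` (named list of [protein_record()]), `truth` (list with
#'   `proteins` data frame, `clusters`, `promoters`), and `config`.
#' @export
build_synthetic_genome <- function(config = sim_config()) {
  seeds <- cgt_reference_seeds()
  exemplars <- cmcd_role_exemplars()
  base <- config$seed
  sub_seed <- function(k) (base * 1009L + k) %% 2147483563L

  truth_rows <- list()
  proteins <- list()
  note_protein <- function(id, seq, role, class, arch, signal_len, group) {
    proteins[[id]] <<- protein_record(id, seq)
    truth_rows[[length(truth_rows) + 1]] <<- data.frame(
      gene_id = id, role = role, class = class, arch = arch,
      signal_len = signal_len, group = group)
  }

  rand_gene <- function(id, k, len = NULL) {
    len <- len %||% (180L + (k * 37L) %% 240L)
    seq <- strip_chance_signal(
      paste0("M", random_protein(len, seed = sub_seed(500L + k))))
    note_protein(id, seq, "NONE", "NOT_GH13", "OTHER", NA, "flank")
  }

  cluster_roles <- c("CGTASE", "MDXE", "MDXF", "MDXG", "CDASE", "GA",
                     "GP", "PGI", "PFKA", "PYKF",
                     rep("ACCESSORY", length(CMCD_ACCESSORY_FAMILIES)))
  accessory_ids <- paste0(CMCD_ACCESSORY_FAMILIES, "_ex")
  exemplar_of_role <- function(role, j)
    if (role == "ACCESSORY") exemplars[[accessory_ids[j]]]
    else exemplars[[which(vapply(exemplars, `[[`, "", "role") == role)[1]]]

  planted_cluster_gene <- function(id, role, j, k) {
    ex <- exemplar_of_role(role, j)
    ident <- config$role_identities[[role]]
    if (role == "CGTASE") {
      seq <- mutate_to_identity(
        seeds$CLD3$seq, ident, seed = sub_seed(100L + k),
        protect_positions = cgtase_protected_positions(seeds$CLD3))
      note_protein(id, seq, "CGTASE", "CGTASE_LIKE", "ABC", 21L, "cluster")
    } else if (role == "MDXE") {
      seq <- mutate_to_identity(ex$seq, ident, seed = sub_seed(100L + k),
                                protect_positions = 1:25)
      note_protein(id, seq, role, "NOT_GH13", "OTHER", 24L, "cluster")
    } else {
      seq <- strip_chance_signal(
        mutate_to_identity(ex$seq, ident, seed = sub_seed(100L + k),
                           protect_positions = 1L))
      note_protein(id, seq, role, "NOT_GH13", "OTHER", NA, "cluster")
    }
  }

  # --- contig A: flanks + planted cluster + flanks -------------------------
  ctgA_ids <- character()
  for (k in seq_len(config$n_flank)) {
    id <- sprintf("A_flank%02d", k); rand_gene(id, k); ctgA_ids <- c(ctgA_ids, id)
  }
  cluster_ids <- character()
  if (config$n_clusters > 0) {
    acc_j <- 0L
    for (k in seq_along(cluster_roles)) {
      role <- cluster_roles[k]
      if (role == "ACCESSORY") acc_j <- acc_j + 1L
      id <- sprintf("cld_%02d_%s", k,
                    if (role == "ACCESSORY") CMCD_ACCESSORY_FAMILIES[acc_j]
                    else tolower(role))
      planted_cluster_gene(id, role, acc_j, k)
      ctgA_ids <- c(ctgA_ids, id)
    }
    cluster_ids <- ctgA_ids[(config$n_flank + 1):(config$n_flank +
                                                    length(cluster_roles))]
  }
  for (k in seq_len(config$n_flank)) {
    id <- sprintf("A_flank%02d", config$n_flank + k)
    rand_gene(id, 50L + k); ctgA_ids <- c(ctgA_ids, id)
  }

  # --- contig B: decoy cluster, msmX, variants, decoys ---------------------
  ctgB_ids <- character()
  decoy_roles <- c("CGTASE", "MDXE", "MDXG", "CDASE", "GA", "GP", "PGI")
  for (k in seq_along(decoy_roles)) {
    id <- sprintf("dec_%02d_%s", k, tolower(decoy_roles[k]))
    planted_cluster_gene(id, decoy_roles[k], 1L, 60L + k)
    ctgB_ids <- c(ctgB_ids, id)
  }
  for (k in 1:6) {  # spacer genes between decoy cluster and the rest
    id <- sprintf("B_flank%02d", k); rand_gene(id, 100L + k)
    ctgB_ids <- c(ctgB_ids, id)
  }
  msmx_seq <- strip_chance_signal(mutate_to_identity(
    exemplars$msmX_ex$seq, config$role_identities[["MSMX"]],
    seed = sub_seed(300L), protect_positions = 1L))
  note_protein("msmX_distal", msmx_seq, "MSMX", "NOT_GH13", "OTHER", NA,
               "msmx")
  ctgB_ids <- c(ctgB_ids, "msmX_distal")

  for (i in seq_along(config$abc_identity_ladder)) {
    ident <- config$abc_identity_ladder[i]
    id <- sprintf("abc_id%02.0f", ident)
    seq <- mutate_to_identity(
      seeds$CLD3$seq, ident, seed = sub_seed(310L + i),
      protect_positions = cgtase_protected_positions(seeds$CLD3))
    note_protein(id, seq, "CGTASE", "CGTASE_LIKE", "ABC", 21L, "ladder")
    ctgB_ids <- c(ctgB_ids, id)
    idr <- sprintf("B_rand%02d", i); rand_gene(idr, 150L + i)
    ctgB_ids <- c(ctgB_ids, idr)
  }
  arch_seeds <- c("FIVE", "FOUR", "ARCH")
  for (a in seq_along(arch_seeds)) for (i in seq_along(config$arch_identities)) {
    sd <- seeds[[arch_seeds[a]]]
    ident <- config$arch_identities[i]
    id <- sprintf("%s_id%02.0f", tolower(arch_seeds[a]), ident)
    seq <- strip_chance_signal(mutate_to_identity(
      sd$seq, ident, seed = sub_seed(330L + 10L * a + i),
      protect_positions = cgtase_protected_positions(sd, with_signal = FALSE)))
    note_protein(id, seq, "CGTASE", "CGTASE_LIKE", sd$architecture, NA,
                 "arch")
    ctgB_ids <- c(ctgB_ids, id)
  }
  decoys <- c("AMYLASE_FLIP", "TRIAD_KO", "TRUNCATE", "SHUFFLE")
  for (i in seq_along(decoys)) {
    d <- make_decoy(seeds$CLD3, decoys[i], seed = sub_seed(360L + i))
    id <- paste0("decoy_", tolower(decoys[i]))
    seq <- if (decoys[i] %in% c("TRUNCATE", "SHUFFLE"))
      strip_chance_signal(d$seq) else d$seq
    arch_truth <- if (decoys[i] %in% c("AMYLASE_FLIP", "TRIAD_KO")) "ABC"
                  else "OTHER"
    sig_truth <- if (decoys[i] %in% c("AMYLASE_FLIP", "TRIAD_KO")) 21L
                 else NA_integer_
    note_protein(id, seq, NA, d$truth, arch_truth, sig_truth, "decoy")
    ctgB_ids <- c(ctgB_ids, id)
  }

  # --- lay out contigs -----------------------------------------------------
  gap <- config$intergenic_len
  promoter_target <- if (length(cluster_ids)) cluster_ids[1] else ""
  promoters <- NULL
  lay_out <- function(contig, ids, seed_off) {
    dna <- character(); pos <- 0L
    rows <- list()
    for (i in seq_along(ids)) {
      id <- ids[i]
      inter <- random_dna(gap, seed = sub_seed(seed_off + i))
      if (id == promoter_target) {
        sp <- config$promoter_spacer
        lead <- gap - (6L + sp + 6L + 41L)
        inter <- paste0(substr(inter, 1, lead), "TGCACT",
                        random_dna(sp, seed = sub_seed(990L)),
                        "TAATAT", substr(inter, 1, 41L))
        promoters <<- data.frame(
          gene_id = id, contig = contig,
          pos_35 = pos + lead + 1L,
          pos_10 = pos + lead + 6L + sp + 1L, spacer = sp)
      }
      dna <- c(dna, inter); pos <- pos + nchar(inter)
      cds <- reverse_translate(proteins[[id]]$seq)
      strand <- if (grepl("flank", id) && i %% 3 == 0) "-" else "+"
      gene_dna <- if (strand == "-") as.character(
        Biostrings::reverseComplement(Biostrings::DNAString(cds))) else cds
      rows[[length(rows) + 1]] <- data.frame(
        gene_id = id, contig = contig, start = pos + 1L,
        end = pos + nchar(gene_dna), strand = strand)
      dna <- c(dna, gene_dna); pos <- pos + nchar(gene_dna)
    }
    dna <- c(dna, random_dna(gap, seed = sub_seed(seed_off)))
    list(seq = paste(dna, collapse = ""), genes = do.call(rbind, rows))
  }
  A <- lay_out("ctgA", ctgA_ids, 700L)
  B <- lay_out("ctgB", ctgB_ids, 800L)

  truth_proteins <- do.call(rbind, truth_rows)
  truth <- list(
    proteins = truth_proteins,
    clusters = if (length(cluster_ids)) list(list(
      contig = "ctgA", gene_ids = cluster_ids,
      n_genes = length(cluster_ids), tier = "EXTENDED",
      cassette_adjacent = TRUE, cgt_upstream = TRUE)) else list(),
    promoters = promoters)
  structure(list(contigs = c(ctgA = A$seq, ctgB = B$seq),
                 genes = rbind(A$genes, B$genes),
                 proteins = proteins, truth = truth, config = config),
            class = "synthetic_genome")
}

#' @export
print.synthetic_genome <- function(x, ...) {
  cat(sprintf(
    "<synthetic_genome> %d contig(s), %d gene(s), %d planted cluster(s)\n",
    length(x$contigs), nrow(x$genes), length(x$truth$clusters)))
  invisible(x)
}

#' Write a synthetic genome to standard files
#'
#' Emits `genome.fna`, `genes.gff3` (CDS features, `##gff-version 3`
#' pragma), `proteins.faa`, `truth_proteins.tsv` and `truth.json`.
#'
#' @param sim A `synthetic_genome` from [build_synthetic_genome()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_synthetic_genome <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  dna <- Biostrings::DNAStringSet(sim$contigs)
  Biostrings::writeXStringSet(dna, file.path(dir, "genome.fna"), width = 70L)
  g <- sim$genes
  lines <- c("##gff-version 3",
             sprintf("%s\tcdmine_sim\tCDS\t%d\t%d\t.\t%s\t0\tID=%s",
                     g$contig, g$start, g$end, g$strand, g$gene_id))
  writeLines(lines, file.path(dir, "genes.gff3"))
  write_fasta(unname(sim$proteins), file.path(dir, "proteins.faa"))
  utils::write.table(sim$truth$proteins,
                     file.path(dir, "truth_proteins.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(sim$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Gene models of a synthetic genome
#'
#' Converts the generator's gene table into [gene_model()] objects (with
#' the planted proteins attached), sorted by contig then start.
#'
#' @param sim A `synthetic_genome`.
#' @return List of [gene_model()]s.
#' @export
synthetic_gene_models <- function(sim) {
  g <- sim$genes[order(sim$genes$contig, sim$genes$start), ]
  lapply(seq_len(nrow(g)), function(i)
    gene_model(g$gene_id[i], g$contig[i], g$start[i], g$end[i],
               g$strand[i], sim$proteins[[g$gene_id[i]]]))
}
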