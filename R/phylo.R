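# Distance phylogenetics for protein families: Poisson-corrected distances,
# neighbor-joining trees (via ape), column-bootstrap support, and monophyly
# tests on unrooted bipartitions.

#' Poisson-corrected protein distance matrix
#'
#' For each pair, p is the proportion of mismatching residues over columns
#' where both sequences have a residue (gap-free in both); the distance is
#' the Poisson correction `-ln(1 - p)`. Saturated pairs (`p >= 0.95`) are
#' clamped at 0.95 with a warning; a pair sharing no columns is an error.
#'
#' @param alignment Named character vector (or list) of equal-length
#'   aligned sequences, gaps as `-`.
#' @return A symmetric matrix with zero diagonal, taxa as dimnames.
#' @export
protein_distance <- function(alignment) {
  seqs <- vapply(alignment, identity, "")
  if (length(seqs) < 2) stop("need at least 2 taxa", call. = FALSE)
  if (length(unique(nchar(seqs))) != 1)
    stop("aligned sequences must have equal length", call. = FALSE)
  if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
    stop("alignment must be named", call. = FALSE)
  chars <- lapply(seqs, seq_chars)
  n <- length(seqs)
  d <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    shared <- chars[[i]] != "-" & chars[[j]] != "-"
    if (!any(shared))
      stop(sprintf("taxa '%s' and '%s' share no aligned columns",
                   names(seqs)[i], names(seqs)[j]), call. = FALSE)
    p <- mean(chars[[i]][shared] != chars[[j]][shared])
    if (p >= 0.95) {
      warning(sprintf("pair %s/%s is saturated (p = %.2f); clamped",
                      names(seqs)[i], names(seqs)[j], p))
      p <- 0.95
    }
    d[i, j] <- d[j, i] <- -log(1 - p)
  }
  d
}

#' Neighbor-joining tree
#'
#' Standard Saitou--Nei agglomeration (via [ape::nj()]) on a symmetric
#' distance matrix; negative branch lengths are clamped to zero.
#'
#' @param d Symmetric distance matrix with taxa dimnames, >= 3 taxa.
#' @return An unrooted `phylo` tree.
#' @export
nj_tree <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) < 3) stop("need at least 3 taxa", call. = FALSE)
  if (!isSymmetric(unname(d), tol = 1e-8))
    stop("distance matrix must be symmetric", call. = FALSE)
  tr <- ape::nj(as.dist(d))
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

# Canonical keys for the non-trivial bipartitions (internal-edge splits) of
# an unrooted tree: each split is represented by the tip-label set on the
# side not containing the lexicographically smallest label.
tree_splits <- function(tree) {
  tips <- tree$tip.label
  ntip <- length(tips)
  anchor <- sort(tips)[1]
  # tip sets below each node, by postorder accumulation
  below <- vector("list", ntip + tree$Nnode)
  for (i in seq_len(ntip)) below[[i]] <- tips[i]
  edge <- ape::reorder.phylo(tree, "postorder")$edge
  for (k in seq_len(nrow(edge))) {
    par <- edge[k, 1]; ch <- edge[k, 2]
    below[[par]] <- c(below[[par]], below[[ch]])
  }
  out <- list()
  for (k in seq_len(nrow(tree$edge))) {
    ch <- tree$edge[k, 2]
    if (ch <= ntip) next          # trivial split
    side <- below[[ch]]
    if (anchor %in% side) side <- setdiff(tips, side)
    if (length(side) == 0 || length(side) == ntip) next
    out[[length(out) + 1]] <- list(edge = k, node = ch,
                                   key = paste(sort(side), collapse = "\r"))
  }
  out
}

#' Bootstrap support by column resampling
#'
#' Resamples alignment columns with replacement, rebuilds a
#' Poisson-distance NJ tree per replicate, and reports for each internal
#' edge of the original tree the percentage of replicates whose tree
#' contains the same bipartition. Reproducible for a fixed seed.
#'
#' @param alignment Named aligned sequences (see [protein_distance()]).
#' @param n_reps Number of replicates (>= 1).
#' @param seed Integer seed.
#' @return The NJ tree of the full alignment with internal-node labels set
#'   to the support values (root node unlabelled).
#' @export
bootstrap_support <- function(alignment, n_reps = 100, seed = 1) {
  stopifnot(n_reps >= 1)
  seqs <- vapply(alignment, identity, "")
  tree <- nj_tree(protein_distance(seqs))
  splits <- tree_splits(tree)
  counts <- setNames(numeric(length(splits)),
                     vapply(splits, `[[`, "", "key"))
  L <- nchar(seqs[1])
  mats <- do.call(rbind, lapply(seqs, seq_chars))
  with_seed(seed, {
    for (r in seq_len(n_reps)) {
      cols <- sample.int(L, L, replace = TRUE)
      rs <- apply(mats[, cols, drop = FALSE], 1, paste, collapse = "")
      names(rs) <- names(seqs)
      rd <- suppressWarnings(protein_distance(rs))
      rt <- nj_tree(rd)
      rkeys <- vapply(tree_splits(rt), `[[`, "", "key")
      hit <- names(counts) %in% rkeys
      counts[hit] <- counts[hit] + 1
    }
  })
  support <- 100 * counts / n_reps
  ntip <- length(tree$tip.label)
  labels <- rep("", tree$Nnode)
  for (i in seq_along(splits))
    labels[splits[[i]]$node - ntip] <- format(support[i])
  tree$node.label <- labels
  tree
}

#' Test monophyly of a label set
#'
#' True iff some bipartition of the (unrooted) tree separates exactly the
#' label set from its complement. Trivial splits (a single taxon, or all
#' taxa) are monophyletic by definition with support 100. For internal
#' splits, the support is the matching edge's node label when the tree
#' carries bootstrap labels, otherwise `NA`.
#'
#' @param tree A `phylo` tree.
#' @param labels Character vector of tip labels.
#' @return List with `monophyletic` (logical) and `support`.
#' @export
is_monophyletic <- function(tree, labels) {
  tips <- tree$tip.label
  unknown <- setdiff(labels, tips)
  if (length(unknown))
    stop("unknown label(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  labels <- unique(labels)
  if (length(labels) %in% c(1L, length(tips)))
    return(list(monophyletic = TRUE, support = 100))
  anchor <- sort(tips)[1]
  side <- if (anchor %in% labels) setdiff(tips, labels) else labels
  key <- paste(sort(side), collapse = "\r")
  splits <- tree_splits(tree)
  for (s in splits) {
    if (s$key == key) {
      sup <- NA_real_
      if (!is.null(tree$node.label)) {
        lab <- tree$node.label[s$node - length(tips)]
        if (nzchar(lab)) sup <- as.numeric(lab)
      }
      return(list(monophyletic = TRUE, support = sup))
    }
  }
  list(monophyletic = FALSE, support = NA_real_)
}

#' Read / write Newick trees
#'
#' Thin wrappers over [ape::read.tree()] and [ape::write.tree()]; bootstrap
#' supports travel as internal-node labels.
#'
#' @param tree A `phylo` object.
#' @param path File path.
#' @return `read_newick` returns a `phylo`; `write_newick` returns `path`.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' @rdname write_newick
#' @export
read_newick <- function(path) ape::read.tree(path)
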