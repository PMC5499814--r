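# Species-tree inference from concatenated complete assignments:
# equal-length chunks, per-chunk unrooted parsimony (exhaustive for small
# taxon sets, NNI hill-climbing from a neighbor-joining start otherwise),
# then majority-rule consensus with branch lengths averaged over the
# chunk trees carrying the corresponding split.

#' Concatenate complete assignments into a chunked superalignment
#'
#' Only assignments that still contain all requested species after
#' divergence filtering are used.  Their codon alignments are
#' concatenated, cut into \code{n_chunks} pieces of equal length (the last
#' may be shorter) and each chunk is column-filtered.
#'
#' @param assignments List of (filtered) isoform assignments.
#' @param species Species that must all be present.
#' @param n_chunks Number of chunks.
#' @param mask_params Column-filter parameters for the chunks.
#' @return List of filtered chunk alignments (codon-state matrices).
#' @export
build_superalignment <- function(assignments, species, n_chunks = 20,
                                 mask_params = list(cons_frac = NULL,
                                                    min_block = 5,
                                                    allow_gaps = FALSE)) {
  complete <- Filter(function(a)
    setequal(a$transcripts$species, species), assignments)
  if (!length(complete))
    stop("no complete assignment covers all species; provide a tree")
  alns <- lapply(complete, codon_align)
  alns <- Filter(length, alns)
  states <- do.call(cbind, lapply(alns, function(a)
    a$states[species, , drop = FALSE]))
  aa <- do.call(cbind, lapply(alns, function(a) a$aa[species, , drop = FALSE]))
  ncols <- ncol(states)
  size <- ceiling(ncols / n_chunks)
  chunks <- split(seq_len(ncols), (seq_len(ncols) - 1) %/% size)
  out <- lapply(chunks, function(idx) {
    ch <- list(states = states[, idx, drop = FALSE],
               aa = aa[, idx, drop = FALSE])
    mask <- filter_columns(ch, cons_frac = mask_params$cons_frac,
                           min_block = mask_params$min_block,
                           allow_gaps = isTRUE(mask_params$allow_gaps))
    ch$states <- ch$states[, mask$keep, drop = FALSE]
    ch$aa <- ch$aa[, mask$keep, drop = FALSE]
    ch
  })
  Filter(function(ch) ncol(ch$states) > 0, out)
}

# codon-state chunk -> nucleotide phyDat
.chunk_phydat <- function(states) {
  tab <- codon_tables()
  nt <- matrix("-", nrow(states), 3 * ncol(states),
               dimnames = list(rownames(states), NULL))
  for (i in seq_len(nrow(states))) {
    cod <- states[i, ]
    chars <- rep("---", length(cod))
    chars[!is.na(cod)] <- tab$codons[cod[!is.na(cod)]]
    nt[i, ] <- unlist(strsplit(chars, ""))
  }
  phangorn::phyDat(nt, type = "DNA")
}

#' Parsimony tree for one alignment chunk
#'
#' Finds the unrooted topology minimizing the Fitch parsimony score --
#' exhaustively for up to 6 taxa, otherwise by NNI hill-climbing from a
#' neighbor-joining start tree.  Branch lengths are reconstructed changes
#' per nucleotide site (ACCTRAN), divided by the chunk's site count.
#'
#' @param chunk Chunk alignment (list with a \code{states} matrix).
#' @param chunk_index Bookkeeping index.
#' @return \code{phylo} with attribute \code{parsimony_score}.
#' @export
parsimony_tree <- function(chunk, chunk_index = 1L) {
  states <- chunk$states
  stopifnot(nrow(states) >= 3, ncol(states) >= 1)
  pd <- .chunk_phydat(states)
  nsites <- 3 * ncol(states)
  if (nrow(states) <= 6) {
    cand <- phangorn::allTrees(nrow(states), tip.label = rownames(states))
    sc <- vapply(cand, function(tr) phangorn::fitch(tr, pd), numeric(1))
    best <- cand[[which.min(sc)]] # ties: first in enumeration order
  } else {
    dm <- phangorn::dist.hamming(pd)
    nj <- ape::nj(dm)
    best <- phangorn::optim.parsimony(nj, pd, method = "fitch",
                                      rearrangements = "NNI", trace = 0)
  }
  score <- phangorn::fitch(best, pd)
  wt <- phangorn::acctran(best, pd)
  wt$edge.length <- wt$edge.length / nsites
  if (ape::is.rooted(wt)) wt <- ape::unroot(wt)
  structure(wt, parsimony_score = score, chunk_index = chunk_index)
}

# canonical key of the split below an edge: sorted tip labels of the side
# not containing the alphabetically first label
.edge_splits <- function(tree) {
  labs <- sort(tree$tip.label)
  ntip <- length(tree$tip.label)
  desc <- phangorn::Descendants(tree, tree$edge[, 2], "tips")
  vapply(desc, function(d) {
    side <- sort(tree$tip.label[d])
    if (labs[1] %in% side) side <- setdiff(labs, side)
    paste(side, collapse = "|")
  }, character(1))
}

#' Majority-rule consensus with averaged branch lengths
#'
#' Splits present in strictly more than half the chunk trees are retained.
#' Each internal consensus branch receives the arithmetic mean of the
#' lengths of the equivalent branch over the chunk trees containing that
#' split; terminal branches are averaged over all chunk trees.  Split
#' support fractions are stored in \code{node.label}.
#'
#' @param chunk_trees List of \code{phylo} over identical leaf sets.
#' @return Unrooted consensus \code{phylo} with attribute
#'   \code{support} (named split -> fraction).
#' @export
consensus_with_lengths <- function(chunk_trees) {
  stopifnot(length(chunk_trees) >= 2)
  ntrees <- length(chunk_trees)
  cons <- ape::consensus(chunk_trees, p = 0.5 + 1e-9, check.labels = TRUE)
  if (ape::is.rooted(cons)) cons <- ape::unroot(cons)
  cons_splits <- .edge_splits(cons)
  ntip <- length(cons$tip.label)
  acc <- stats::setNames(vector("list", length(cons_splits)), NULL)
  sup <- numeric(length(cons_splits))
  lens <- vector("list", length(cons_splits))
  for (k in seq_along(lens)) lens[[k]] <- numeric(0)
  for (tr in chunk_trees) {
    sp <- .edge_splits(tr)
    m <- match(cons_splits, sp)
    hit <- !is.na(m)
    sup[hit] <- sup[hit] + 1
    for (k in which(hit))
      lens[[k]] <- c(lens[[k]], tr$edge.length[m[k]])
  }
  cons$edge.length <- vapply(lens, function(x)
    if (length(x)) mean(x) else 0, numeric(1))
  support <- sup / ntrees
  names(support) <- cons_splits
  structure(cons, support = support)
}

#' Infer the species tree from filtered assignments
#'
#' @inheritParams build_superalignment
#' @return Consensus species tree (\code{phylo}).
#' @export
infer_species_tree <- function(assignments, species, n_chunks = 20,
                               mask_params = list(cons_frac = NULL,
                                                  min_block = 5,
                                                  allow_gaps = FALSE)) {
  chunks <- build_superalignment(assignments, species, n_chunks, mask_params)
  trees <- lapply(seq_along(chunks), function(i)
    parsimony_tree(chunks[[i]], i))
  if (length(trees) == 1) return(trees[[1]])
  consensus_with_lengths(trees)
}
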