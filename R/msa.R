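# Progressive protein multiple alignment and MSA-based similarities.
#
# The aligner is a classical progressive scheme: a UPGMA guide tree on
# k-mer distances determines the merge order (more similar sequences are
# aligned first, which lowers the chance of aligning non-homologous
# regions such as alternative exons); groups are merged by affine-gap
# profile-profile alignment under BLOSUM62.

.aa_alphabet <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L",
                  "K", "M", "F", "P", "S", "T", "W", "Y", "V", "X")

.blosum_sub <- function() {
  data("BLOSUM62", package = "Biostrings", envir = environment())
  B <- get("BLOSUM62", envir = environment())
  B[.aa_alphabet, .aa_alphabet]
}

# fraction of shared k-mers, as a distance
.kmer_dist <- function(seqs, k = 3) {
  km <- lapply(seqs, function(s) {
    n <- nchar(s)
    if (n < k) return(s)
    unique(substring(s, 1:(n - k + 1), k:n))
  })
  n <- length(seqs)
  d <- matrix(0, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    shared <- length(intersect(km[[i]], km[[j]]))
    denom <- min(length(km[[i]]), length(km[[j]]))
    d[i, j] <- d[j, i] <- 1 - shared / max(denom, 1)
  }
  d
}

.profile_of <- function(rows) {
  # residue frequency columns, gap mass excluded (columns divided by the
  # number of sequences so gappy columns weigh less)
  mat <- do.call(rbind, strsplit(rows, ""))
  ncolu <- ncol(mat)
  prof <- matrix(0, length(.aa_alphabet), ncolu,
                 dimnames = list(.aa_alphabet, NULL))
  for (a in .aa_alphabet) prof[a, ] <- colSums(mat == a)
  sweep(prof, 2, nrow(mat), "/")
}

.merge_by_path <- function(rowsA, rowsB, path) {
  splA <- strsplit(rowsA, ""); splB <- strsplit(rowsB, "")
  takeA <- path %in% c(0L, 1L); takeB <- path %in% c(0L, 2L)
  n <- length(path)
  resA <- matrix("-", length(rowsA), n)
  resB <- matrix("-", length(rowsB), n)
  for (s in seq_along(splA)) resA[s, takeA] <- splA[[s]]
  for (s in seq_along(splB)) resB[s, takeB] <- splB[[s]]
  c(apply(resA, 1, paste, collapse = ""),
    apply(resB, 1, paste, collapse = ""))
}

#' Progressive protein multiple sequence alignment
#'
#' @param sequences Named character vector of protein sequences (>= 2).
#' @param gap_open,gap_ext Affine gap penalties for the profile alignment.
#' @return Named character vector of aligned rows (equal lengths, gaps as
#'   \code{"-"}), in the input order.
#' @export
progressive_protein_msa <- function(sequences, gap_open = 10, gap_ext = 0.5) {
  stopifnot(length(sequences) >= 2, all(nchar(sequences) > 0))
  nm <- names(sequences)
  if (is.null(nm)) nm <- paste0("seq", seq_along(sequences))
  sub <- .blosum_sub()
  n <- length(sequences)
  if (n == 2) {
    groups <- list(sequences[1], sequences[2])
    merge_order <- matrix(c(-1L, -2L), 1)
  } else {
    d <- .kmer_dist(sequences)
    hc <- stats::hclust(stats::as.dist(d), method = "average")
    merge_order <- hc$merge
    groups <- as.list(sequences)
  }
  merged <- vector("list", nrow(merge_order))
  members <- vector("list", nrow(merge_order))
  get_group <- function(id) {
    if (id < 0) list(rows = unname(sequences[-id]), idx = -id)
    else list(rows = merged[[id]], idx = members[[id]])
  }
  for (m in seq_len(nrow(merge_order))) {
    A <- get_group(merge_order[m, 1]); B <- get_group(merge_order[m, 2])
    path <- cpp_profile_align(.profile_of(A$rows), .profile_of(B$rows),
                              sub, gap_open, gap_ext)
    rows <- .merge_by_path(A$rows, B$rows, path)
    merged[[m]] <- rows
    members[[m]] <- c(A$idx, B$idx)
  }
  out <- merged[[nrow(merge_order)]]
  ord <- order(members[[nrow(merge_order)]])
  stats::setNames(out[ord], nm)
}

#' Pairwise identities over an MSA
#'
#' Identity between two aligned rows is the fraction of identical residues
#' over columns where both rows are non-gap; 0 if no such column exists.
#'
#' @param msa Named character vector of aligned rows.
#' @return Symmetric matrix of identities in \[0, 1\].
#' @export
msa_identity <- function(msa) {
  mat <- do.call(rbind, strsplit(msa, ""))
  n <- nrow(mat)
  out <- matrix(1, n, n, dimnames = list(names(msa), names(msa)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    both <- mat[i, ] != "-" & mat[j, ] != "-"
    out[i, j] <- out[j, i] <-
      if (!any(both)) 0 else mean(mat[i, both] == mat[j, both])
  }
  out
}
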