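# Stringent removal of gapped and unreliable codon columns prior to tree
# building and selection testing.  Columns are removed on codon level but
# conservation is judged on the amino-acid translation; retained columns
# must form blocks of a minimum length so isolated conserved islands
# between gaps are discarded.

#' Filter codon alignment columns
#'
#' A codon column is candidate-kept iff (a) it contains no gap and no
#' N-containing codon (unless \code{allow_gaps}), and (b) at least
#' \code{cons_frac} of the sequences share the majority amino acid.
#' Maximal runs of candidate-kept columns shorter than \code{min_block}
#' are dropped.
#'
#' @param aln A codon alignment from [codon_align()] (or any list with a
#'   \code{states} matrix and an \code{aa} character matrix).
#' @param cons_frac Minimum fraction sharing the majority amino acid;
#'   default \code{0.5 + 1/n_seq}.
#' @param min_block Minimum retained block length in codon columns.
#' @param allow_gaps Keep columns with gaps/N codons if they pass (b).
#' @return A column mask: list with logical \code{keep}, the parameters
#'   and summary \code{counts}.
#' @export
filter_columns <- function(aln, cons_frac = NULL, min_block = 5,
                           allow_gaps = FALSE) {
  states <- aln$states
  aa <- aln$aa
  n <- nrow(states)
  stopifnot(n >= 2)
  if (is.null(cons_frac)) cons_frac <- 0.5 + 1 / n
  no_gap <- colSums(is.na(states)) == 0
  conserved <- vapply(seq_len(ncol(aa)), function(j) {
    col <- aa[, j]
    col <- col[col != "-" & col != "X"]
    if (!length(col)) return(FALSE)
    max(table(col)) / n >= cons_frac
  }, logical(1))
  cand <- conserved & (no_gap | allow_gaps)
  keep <- cand
  r <- rle(cand)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  for (k in seq_along(r$values))
    if (r$values[k] && r$lengths[k] < min_block)
      keep[starts[k]:ends[k]] <- FALSE
  list(keep = keep,
       params = list(cons_frac = cons_frac, min_block = min_block,
                     allow_gaps = allow_gaps),
       counts = c(columns = length(keep), candidate = sum(cand),
                  kept = sum(keep)))
}

#' Serialize a column mask as kept-interval TSV
#'
#' Intervals are 1-based inclusive codon columns of the alignment; if the
#' alignment carries anchor-codon coordinates, intervals on the ungapped
#' anchor sequence are written too.
#'
#' @param mask From [filter_columns()].
#' @param aln The codon alignment the mask belongs to.
#' @param path Output TSV.
#' @export
write_mask <- function(mask, aln, path) {
  iv <- function(idx) {
    if (!length(idx)) return(data.frame(start = integer(), end = integer()))
    br <- c(0, which(diff(idx) > 1), length(idx))
    data.frame(start = idx[br[-length(br)] + 1], end = idx[br[-1]])
  }
  kept <- which(mask$keep)
  d <- iv(kept)
  d$frame <- "alignment"
  if (!is.null(aln$anchor_codon)) {
    ac <- aln$anchor_codon[kept]
    ac <- ac[!is.na(ac)]
    if (length(ac)) {
      d2 <- iv(sort(ac))
      d2$frame <- "anchor"
      d <- rbind(d, d2)
    }
  }
  .write_tsv(d[c("frame", "start", "end")], path,
             params = sprintf("cons_frac=%.4f min_block=%d allow_gaps=%s",
                              mask$params$cons_frac, mask$params$min_block,
                              mask$params$allow_gaps))
}
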