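#' @useDynLib posiselect, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Internal codon bookkeeping for the universal genetic code.
#
# Codons are indexed 1..61 over the sense codons (stops TAA, TAG, TGA
# excluded), in lexicographic order over the bases A, C, G, T.  The
# substitution-type matrix classifies every ordered codon pair as
# unreachable (multi-nucleotide change), synonymous/nonsynonymous and
# transition/transversion, which is all the GY94-type rate construction
# needs.

.codon_env <- new.env(parent = emptyenv())

.build_codon_tables <- function() {
  bases <- c("A", "C", "G", "T")
  # lexicographic order over positions 1,2,3
  all64 <- sort(apply(expand.grid(bases, bases, bases,
                                  stringsAsFactors = FALSE)[, 3:1], 1, paste0,
                      collapse = ""))
  gc <- Biostrings::GENETIC_CODE
  aa <- unname(gc[all64])
  sense <- all64[aa != "*"]
  sense_aa <- aa[aa != "*"]
  n <- length(sense)
  stopifnot(n == 61L)

  is_transition <- function(x, y) {
    (x == "A" & y == "G") | (x == "G" & y == "A") |
      (x == "C" & y == "T") | (x == "T" & y == "C")
  }
  cmat <- do.call(rbind, strsplit(sense, ""))
  type <- matrix(0L, n, n)
  for (i in seq_len(n)) {
    diffs <- cmat != matrix(cmat[i, ], n, 3, byrow = TRUE)
    nd <- rowSums(diffs)
    one <- which(nd == 1L)
    for (j in one) {
      pos <- which(diffs[j, ])
      ts <- is_transition(cmat[i, pos], cmat[j, pos])
      syn <- sense_aa[i] == sense_aa[j]
      type[i, j] <- if (syn) (if (ts) 2L else 1L) else (if (ts) 4L else 3L)
    }
  }
  list(codons = sense, aa = sense_aa, type = type,
       index = stats::setNames(seq_len(n), sense))
}

codon_tables <- function() {
  if (is.null(.codon_env$tab)) .codon_env$tab <- .build_codon_tables()
  .codon_env$tab
}

#' Sense codons of the universal genetic code
#'
#' @return Character vector of the 61 sense codons, in the fixed internal
#'   order used for all codon-state vectors and rate matrices.
#' @export
sense_codons <- function() codon_tables()$codons

# map a vector of codon strings to state indices; NA for gaps ("---"),
# codons containing N/gap characters, or stop codons
codon_states <- function(codons) {
  tab <- codon_tables()
  idx <- tab$index[codons]
  unname(idx)
}
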