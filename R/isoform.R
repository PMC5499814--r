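# Isoform selection and divergence filtering.
#
# For every isoform of the user-chosen anchor species, the most similar
# isoform of each other species is picked from a group-wide protein MSA
# over *all* isoforms of all member species, so there are as many isoform
# assignments per ortholog group as the anchor species has isoforms.
# Divergent sequences are then removed by a two-threshold rule: anchor
# similarity below theta_anchor, and an iterative pairwise rule among the
# non-anchor sequences.

#' Select one isoform per species against each anchor isoform
#'
#' @param group Transcript data.frame of one ortholog group (possibly
#'   several isoforms per species).
#' @param anchor_species Anchor species name; groups lacking it are skipped
#'   (return value \code{NULL}).
#' @return List of isoform assignments, one per anchor isoform. Each is a
#'   list with the anchor transcript id, the chosen transcripts
#'   (data.frame, anchor first), \code{similarity_to_anchor} and the
#'   \code{pairwise} identity matrix among chosen non-anchor sequences.
#' @export
select_isoforms <- function(group, anchor_species) {
  if (!anchor_species %in% group$species) return(NULL)
  ids <- paste(group$species, group$transcript_id, sep = "|")
  if (nrow(group) == 1) {
    a <- group[1, , drop = FALSE]
    return(list(list(anchor_transcript = a$transcript_id,
                     transcripts = a,
                     similarity_to_anchor = numeric(0),
                     pairwise = matrix(numeric(0), 0, 0))))
  }
  msa <- progressive_protein_msa(stats::setNames(group$protein, ids))
  idm <- msa_identity(msa)
  anchors <- which(group$species == anchor_species)
  other_species <- setdiff(unique(group$species), anchor_species)
  lapply(anchors, function(ai) {
    chosen <- integer(0)
    for (sp in sort(other_species)) {
      cand <- which(group$species == sp)
      sim <- idm[ai, cand]
      # deterministic tie-break: highest identity, then smallest id
      best <- cand[order(-sim, group$transcript_id[cand])][1]
      chosen <- c(chosen, best)
    }
    rows <- group[c(ai, chosen), , drop = FALSE]
    sim_anchor <- stats::setNames(idm[ai, chosen], group$species[chosen])
    pw <- idm[chosen, chosen, drop = FALSE]
    dimnames(pw) <- list(group$species[chosen], group$species[chosen])
    list(anchor_transcript = group$transcript_id[ai], transcripts = rows,
         similarity_to_anchor = sim_anchor, pairwise = pw)
  })
}

#' Default similarity thresholds for divergence filtering
#' @param theta_anchor Minimum identity of a non-anchor sequence to the
#'   anchor sequence.
#' @param theta_pair Minimum identity required between non-anchor pairs.
#' @export
filter_thresholds <- function(theta_anchor = 0.5, theta_pair = 0.5) {
  stopifnot(theta_anchor >= 0, theta_anchor <= 1,
            theta_pair >= 0, theta_pair <= 1)
  list(theta_anchor = theta_anchor, theta_pair = theta_pair)
}

#' Remove divergent sequences from an isoform assignment
#'
#' First every non-anchor sequence whose anchor similarity is below
#' \code{theta_anchor} is removed.  Then, while any remaining non-anchor
#' pair falls below \code{theta_pair}, the sequence violating the pairwise
#' rule most often is removed; ties are broken by the lowest similarity to
#' the anchor sequence, then by species name.  Violations are recounted
#' after each removal.  The anchor is never removed.
#'
#' @param assignment An isoform assignment from [select_isoforms()].
#' @param thresholds From [filter_thresholds()].
#' @return The reduced assignment plus a \code{removed} data.frame
#'   (species, transcript_id, reason, violations).
#' @export
filter_divergent <- function(assignment, thresholds = filter_thresholds()) {
  sim <- assignment$similarity_to_anchor
  pw <- assignment$pairwise
  removed <- data.frame(species = character(), transcript_id = character(),
                        reason = character(), violations = integer(),
                        stringsAsFactors = FALSE)
  tx <- assignment$transcripts
  anchor_sp <- tx$species[1]
  drop_sp <- names(sim)[sim < thresholds$theta_anchor]
  for (sp in drop_sp)
    removed <- rbind(removed, data.frame(
      species = sp, transcript_id = tx$transcript_id[tx$species == sp][1],
      reason = "below_anchor_threshold", violations = NA_integer_))
  keep <- setdiff(names(sim), drop_sp)
  repeat {
    if (length(keep) < 2) break
    sub <- pw[keep, keep, drop = FALSE]
    viol <- rowSums(sub < thresholds$theta_pair) -
      as.integer(diag(sub) < thresholds$theta_pair)
    if (all(viol == 0)) break
    worst <- max(viol)
    cand <- names(viol)[viol == worst]
    cand <- cand[order(sim[cand], cand)][1]
    removed <- rbind(removed, data.frame(
      species = cand,
      transcript_id = tx$transcript_id[tx$species == cand][1],
      reason = "pairwise_violations", violations = as.integer(worst)))
    keep <- setdiff(keep, cand)
  }
  out <- assignment
  out$similarity_to_anchor <- sim[keep]
  out$pairwise <- pw[keep, keep, drop = FALSE]
  out$transcripts <- tx[tx$species %in% c(anchor_sp, keep), , drop = FALSE]
  out$removed <- removed
  out
}
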