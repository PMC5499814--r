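# Ortholog catalog construction: protein similarity search (exact
# Smith-Waterman under BLOSUM62 with a k-mer prescreen standing in for
# BLAST) and isoform-aware group-to-group best-bidirectional-hit
# assignment of new species into an existing catalog.

#' Local protein similarity
#'
#' Smith-Waterman local alignment under BLOSUM62 with affine gaps
#' (open 11, extend 1).  Identity is identical positions over aligned
#' positions (alignment length including gaps).
#'
#' @param a,b Non-empty protein sequences.
#' @return List with \code{score}, \code{identity} and
#'   \code{aligned_length}.
#' @export
protein_similarity <- function(a, b) {
  stopifnot(nchar(a) > 0, nchar(b) > 0)
  al <- Biostrings::pairwiseAlignment(Biostrings::AAString(a),
                                      Biostrings::AAString(b),
                                      type = "local",
                                      substitutionMatrix = "BLOSUM62",
                                      gapOpening = 11, gapExtension = 1)
  alen <- nchar(as.character(Biostrings::alignedPattern(al)))
  list(score = Biostrings::score(al),
       identity = Biostrings::nmatch(al) / alen,
       aligned_length = alen)
}

# shared 5-mer prescreen: cheap filter before exact alignment
.shares_kmer <- function(a, b, k = 5) {
  if (nchar(a) < k || nchar(b) < k) return(TRUE)
  ka <- unique(substring(a, 1:(nchar(a) - k + 1), k:nchar(a)))
  kb <- unique(substring(b, 1:(nchar(b) - k + 1), k:nchar(b)))
  length(intersect(ka, kb)) > 0
}

#' Similarity search parameters
#' @param min_identity Reporting floor on identity.
#' @param min_aligned Reporting floor on aligned length (residues).
#' @param kmer_prescreen Require a shared 5-mer before aligning.
#' @export
similarity_params <- function(min_identity = 0.25, min_aligned = 30,
                              kmer_prescreen = TRUE) {
  list(min_identity = min_identity, min_aligned = min_aligned,
       kmer_prescreen = kmer_prescreen)
}

# best hit of a query protein set against a subject transcript table;
# returns NULL if nothing clears the floor
.best_hit <- function(queries, subjects, params) {
  best <- NULL
  for (qi in seq_along(queries)) {
    q <- queries[qi]
    for (si in seq_len(nrow(subjects))) {
      s <- subjects$protein[si]
      if (params$kmer_prescreen && !.shares_kmer(q, s)) next
      hit <- protein_similarity(q, s)
      if (hit$identity < params$min_identity ||
          hit$aligned_length < params$min_aligned) next
      cand <- list(query = names(queries)[qi],
                   subject = subjects$transcript_id[si],
                   subject_species = subjects$species[si],
                   score = hit$score, identity = hit$identity)
      if (is.null(best) || cand$score > best$score ||
          (cand$score == best$score && cand$subject < best$subject))
        best <- cand
    }
  }
  best
}

#' Best-hit group of a gene
#'
#' Finds the catalog group containing the subject transcript with the
#' maximum Smith-Waterman score over all isoform x catalog-member pairs.
#' Ties are broken by the lexicographically smallest
#' (group_id, subject transcript_id).
#'
#' @param gene Transcript data.frame of one gene (its isoforms).
#' @param catalog Catalog data.frame.
#' @param transcripts Transcript table covering the catalog members.
#' @param params From [similarity_params()].
#' @return List (\code{group_id}, \code{hit}) or \code{NULL} when no hit
#'   clears the reporting floor.
#' @export
best_hit_group <- function(gene, catalog, transcripts,
                           params = similarity_params()) {
  stopifnot(nrow(catalog) > 0)
  queries <- stats::setNames(gene$protein, gene$transcript_id)
  best <- NULL
  for (gid in sort(unique(catalog$group_id))) {
    mem <- catalog[catalog$group_id == gid, ]
    subj <- merge(mem[c("species", "transcript_id")], transcripts,
                  by = c("species", "transcript_id"), sort = TRUE)
    if (!nrow(subj)) next
    hit <- .best_hit(queries, subj, params)
    if (is.null(hit)) next
    if (is.null(best) || hit$score > best$hit$score ||
        (hit$score == best$hit$score &&
         (gid < best$group_id ||
          (gid == best$group_id && hit$subject < best$hit$subject))))
      best <- list(group_id = gid, hit = hit)
  }
  best
}

#' Assign a new species to a catalog by bidirectional best hits
#'
#' A gene X of the new species joins group Y iff the best hit over all
#' isoforms of X lies in Y *and* the best hit from Y's members against the
#' whole new-species transcript set lands on an isoform of X
#' (group-to-group best-bidirectional-hit criterion).  Each gene joins at
#' most one group.
#'
#' @param catalog Existing catalog data.frame.
#' @param transcripts Transcript table covering catalog members.
#' @param new_transcripts Transcripts of the new species (absent from the
#'   catalog).
#' @param params From [similarity_params()].
#' @return List with the extended \code{catalog} and a \code{report}
#'   data.frame (gene, assigned group or NA, reason).
#' @export
assign_species <- function(catalog, transcripts, new_transcripts,
                           params = similarity_params()) {
  new_sp <- unique(new_transcripts$species)
  stopifnot(length(new_sp) == 1)
  if (new_sp %in% catalog$species)
    stop("species already present in catalog: ", new_sp)
  genes <- split(new_transcripts, new_transcripts$gene_id)
  report <- list(); added <- list()
  for (gname in sort(names(genes))) {
    gene <- genes[[gname]]
    fwd <- best_hit_group(gene, catalog, transcripts, params)
    if (is.null(fwd)) {
      report[[gname]] <- data.frame(gene_id = gname, group_id = NA,
                                    reason = "no_forward_hit")
      next
    }
    mem <- catalog[catalog$group_id == fwd$group_id, ]
    subj <- merge(mem[c("species", "transcript_id")], transcripts,
                  by = c("species", "transcript_id"), sort = TRUE)
    back <- .best_hit(stats::setNames(subj$protein, subj$transcript_id),
                      new_transcripts, params)
    if (is.null(back) ||
        !back$subject %in% gene$transcript_id) {
      report[[gname]] <- data.frame(gene_id = gname, group_id = NA,
                                    reason = "not_bidirectional")
      next
    }
    added[[gname]] <- data.frame(group_id = fwd$group_id, species = new_sp,
                                 gene_id = gname,
                                 transcript_id = gene$transcript_id,
                                 stringsAsFactors = FALSE)
    report[[gname]] <- data.frame(gene_id = gname, group_id = fwd$group_id,
                                  reason = "assigned")
  }
  list(catalog = rbind(catalog, do.call(rbind, unname(added))),
       report = do.call(rbind, c(unname(report),
                                 list(data.frame(gene_id = character(),
                                                 group_id = character(),
                                                 reason = character())))))
}

#' Seed a catalog de novo by single-linkage of bidirectional best hits
#'
#' For every ordered species pair among the core species, gene-level best
#' hits are computed (max over isoform pairs); bidirectional best-hit gene
#' pairs are linked and connected components become seed groups.
#'
#' @param transcripts Transcript table of the core species.
#' @param core_species Species to seed from (default: all).
#' @param params From [similarity_params()].
#' @return Catalog data.frame with groups \code{OG000001}, ...
#' @export
seed_catalog_bbh <- function(transcripts, core_species = NULL,
                             params = similarity_params()) {
  if (is.null(core_species)) core_species <- sort(unique(transcripts$species))
  tx <- transcripts[transcripts$species %in% core_species, ]
  gene_key <- paste(tx$species, tx$gene_id, sep = "|")
  genes <- split(tx, gene_key)
  gnames <- sort(names(genes))
  best_of <- function(gq, sp_subj) {
    subj <- tx[tx$species == sp_subj, ]
    hit <- .best_hit(stats::setNames(gq$protein, gq$transcript_id), subj,
                     params)
    if (is.null(hit)) return(NA_character_)
    paste(sp_subj, subj$gene_id[subj$transcript_id == hit$subject][1],
          sep = "|")
  }
  bb <- list()
  for (g in gnames) {
    sp <- genes[[g]]$species[1]
    for (sp2 in setdiff(core_species, sp))
      bb[[paste(g, sp2)]] <- best_of(genes[[g]], sp2)
  }
  parent <- stats::setNames(gnames, gnames)
  find <- function(x) { while (parent[[x]] != x) x <- parent[[x]]; x }
  union_ <- function(a, b) { parent[[find(a)]] <<- find(b) }
  for (g in gnames) {
    sp <- genes[[g]]$species[1]
    for (sp2 in setdiff(core_species, sp)) {
      h <- bb[[paste(g, sp2)]]
      if (is.na(h)) next
      back <- bb[[paste(h, sp)]]
      if (!is.null(back) && !is.na(back) && back == g) union_(g, h)
    }
  }
  comp <- vapply(gnames, find, character(1))
  gid_of <- stats::setNames(sprintf("OG%06d", match(comp, sort(unique(comp)))),
                            gnames)
  out <- tx
  out$group_id <- gid_of[paste(out$species, out$gene_id, sep = "|")]
  out <- out[order(out$group_id, out$species, out$transcript_id),
             c("group_id", "species", "gene_id", "transcript_id")]
  rownames(out) <- NULL
  out
}
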