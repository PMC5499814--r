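# The branch-site scan: per-assignment codon alignment, column masking,
# sister-taxon gating, likelihood-ratio testing, plausibility filtering,
# multiple-testing correction and ranked reporting.

#' Codon-level alignment of an isoform assignment
#'
#' Aligns the chosen protein sequences with the internal progressive
#' aligner (an external aligner can be plugged in through \code{aligner})
#' and back-threads the protein alignment to codons: every aligned residue
#' maps to its source codon, gaps become missing codons.
#'
#' @param assignment Isoform assignment (or any transcript data.frame in
#'   \code{assignment$transcripts}) with >= 3 sequences.
#' @param aligner Function \code{(named protein vector) -> named aligned
#'   vector}; defaults to [progressive_protein_msa()].
#' @return Codon alignment: list with \code{states} (codon-state matrix,
#'   NA for gap or N codon), \code{aa} (aligned residue matrix),
#'   \code{species}, \code{anchor} and \code{anchor_codon} (per column the
#'   1-based codon of the anchor's ungapped CDS, NA at anchor gaps), or an
#'   empty list with attribute \code{"skip_reason"} for < 3 sequences.
#' @export
codon_align <- function(assignment, aligner = progressive_protein_msa) {
  tx <- assignment$transcripts
  if (nrow(tx) < 3)
    return(structure(list(), skip_reason = "fewer_than_3_sequences"))
  prots <- stats::setNames(tx$protein, tx$species)
  msa <- aligner(prots)
  aa <- do.call(rbind, strsplit(msa, ""))
  rownames(aa) <- tx$species
  ncols <- ncol(aa)
  states <- matrix(NA_integer_, nrow(tx), ncols,
                   dimnames = list(tx$species, NULL))
  for (i in seq_len(nrow(tx))) {
    resi <- which(aa[i, ] != "-")
    if (3 * length(resi) != nchar(tx$cds[i]))
      stop("translation/alignment length mismatch for ", tx$species[i])
    cods <- substring(tx$cds[i], 3 * seq_along(resi) - 2, 3 * seq_along(resi))
    states[i, resi] <- unname(codon_tables()$index[cods])
  }
  anchor <- tx$species[1]
  anchor_codon <- rep(NA_integer_, ncols)
  resi <- which(aa[anchor, ] != "-")
  anchor_codon[resi] <- seq_along(resi)
  list(states = states, aa = aa, species = tx$species, anchor = anchor,
       anchor_codon = anchor_codon)
}

#' Sister-taxon requirement for branch localization
#'
#' A gene alignment is only testable if at least one species of the sister
#' clade of the foreground branch is present; otherwise selection cannot
#' be localized to the tested branch rather than earlier lineages.  The
#' sister clade is taken as the smallest subtree adjacent to the outer
#' endpoint of the foreground edge.
#'
#' @param tree Unrooted species tree (\code{phylo}).
#' @param foreground Foreground leaf species (branch specification).
#' @param species_in_msa Species present in the alignment.
#' @return \code{TRUE}/\code{FALSE}; attribute \code{"sister"} carries the
#'   sister species set.
#' @export
sister_taxon_check <- function(tree, foreground, species_in_msa) {
  if (!any(foreground %in% species_in_msa))
    return(structure(FALSE, sister = character(0)))
  fe <- foreground_edge(tree, foreground)
  ntip <- length(tree$tip.label)
  fg_idx <- sort(match(foreground, tree$tip.label))
  desc <- sort(phangorn::Descendants(tree, tree$edge[fe, 2], "tips")[[1]])
  outer_node <- if (identical(desc, fg_idx)) tree$edge[fe, 1]
                else tree$edge[fe, 2]
  # neighbor subtrees at the outer endpoint, excluding the foreground side
  nb <- rbind(tree$edge, tree$edge[, 2:1])
  adj <- nb[nb[, 1] == outer_node, 2]
  subtrees <- lapply(adj, function(v) {
    reach <- .reachable_tips(tree, v, outer_node)
    sort(reach)
  })
  subtrees <- Filter(function(s) !identical(s, fg_idx), subtrees)
  if (!length(subtrees)) return(structure(FALSE, sister = character(0)))
  sizes <- lengths(subtrees)
  sister <- tree$tip.label[subtrees[[which.min(sizes)]]]
  structure(any(species_in_msa %in% sister), sister = sister)
}

.reachable_tips <- function(tree, from, avoid) {
  ntip <- length(tree$tip.label)
  nb <- rbind(tree$edge, tree$edge[, 2:1])
  seen <- c(avoid)
  stack <- from
  tips <- integer(0)
  while (length(stack)) {
    v <- stack[1]; stack <- stack[-1]
    if (v %in% seen) next
    seen <- c(seen, v)
    if (v <= ntip) tips <- c(tips, v)
    else stack <- c(stack, nb[nb[, 1] == v, 2])
  }
  tips
}

#' Default plausibility-filter thresholds
#'
#' @param min_cols Minimum retained codon columns.
#' @param min_frac Minimum retained fraction of anchor codons.
#' @param omega_cap Foreground omega at or above which the fit is
#'   considered implausible.
#' @param max_psel_weight Maximum estimated mass of the positively
#'   selected classes (p2a + p2b).
#' @param max_site_fraction Maximum fraction of sites with posterior > 0.5.
#' @export
plausibility_thresholds <- function(min_cols = 50, min_frac = 0.2,
                                    omega_cap = 100, max_psel_weight = 0.8,
                                    max_site_fraction = 0.6) {
  list(min_cols = min_cols, min_frac = min_frac, omega_cap = omega_cap,
       max_psel_weight = max_psel_weight,
       max_site_fraction = max_site_fraction)
}

#' Plausibility filtering of a fitted gene result
#'
#' Flags results that are statistically significant but implausible:
#' too little retained alignment, too few sequences, disproportionate
#' foreground dN/dS, or an implausibly high fraction of positively
#' selected sites.  A result with any flag is never counted as a PSG.
#'
#' @param result A single gene-result list (as assembled by [run_scan()]).
#' @param thresholds From [plausibility_thresholds()].
#' @return The result with its \code{flags} character vector extended.
#' @export
plausibility_filter <- function(result, thresholds = plausibility_thresholds()) {
  fl <- result$flags
  if (!is.null(result$codons_retained) &&
      (result$codons_retained < thresholds$min_cols ||
       result$frac_anchor_retained < thresholds$min_frac))
    fl <- c(fl, "too_few_columns")
  if (!is.null(result$n_species) && result$n_species < 3)
    fl <- c(fl, "too_few_sequences")
  if (!is.null(result$fg_omega) && is.finite(result$fg_omega) &&
      result$fg_omega >= thresholds$omega_cap)
    fl <- c(fl, "omega_extreme")
  psel <- result$p2a_p2b
  if (!is.null(psel) && is.finite(psel)) {
    frac_sites <- if (is.null(result$posteriors) || !length(result$posteriors))
      0 else mean(result$posteriors > 0.5)
    if (psel > thresholds$max_psel_weight ||
        frac_sites > thresholds$max_site_fraction)
      fl <- c(fl, "too_many_selected_sites")
  }
  result$flags <- unique(fl)
  result
}

#' Multiple-testing correction
#'
#' @param p Vector of nominal p-values in \[0, 1\].
#' @param method \code{"bonferroni"} or \code{"bh"}
#'   (Benjamini-Hochberg step-up).
#' @return Adjusted p-values (same order as input).
#' @export
adjust_pvalues <- function(p, method = c("bonferroni", "bh")) {
  method <- match.arg(method)
  stopifnot(all(is.na(p) | (p >= 0 & p <= 1)))
  stats::p.adjust(p, method = if (method == "bh") "BH" else "bonferroni")
}

#' Scan configuration
#'
#' @param transcripts Validated transcript data.frame.
#' @param catalog Ortholog catalog data.frame.
#' @param anchor Anchor species.
#' @param foreground Tested branch: a species name or character vector of
#'   the leaf species below an internal branch.
#' @param tree Species tree (\code{phylo}) or \code{NULL} to infer one
#'   from the complete assignments.
#' @param alpha Nominal significance level defining PSG candidates.
#' @param thresholds Similarity thresholds ([filter_thresholds()]).
#' @param filter Plausibility thresholds ([plausibility_thresholds()]).
#' @param mask_params Column-filter parameters (list with
#'   \code{cons_frac}, \code{min_block}, \code{allow_gaps}).
#' @param kappa Fixed transition/transversion ratio, or NULL to estimate
#'   per gene.
#' @param n_chunks Chunk count for tree inference when \code{tree} is NULL.
#' @export
scan_config <- function(transcripts, catalog, anchor, foreground,
                        tree = NULL, alpha = 0.05,
                        thresholds = filter_thresholds(),
                        filter = plausibility_thresholds(),
                        mask_params = list(cons_frac = NULL, min_block = 5,
                                           allow_gaps = FALSE),
                        kappa = NULL, n_chunks = 20) {
  list(transcripts = transcripts, catalog = catalog, anchor = anchor,
       foreground = foreground, tree = tree, alpha = alpha,
       thresholds = thresholds, filter = filter, mask_params = mask_params,
       kappa = kappa, n_chunks = n_chunks)
}

#' Genome-wide branch-site scan
#'
#' Runs the whole per-gene pipeline over every ortholog group: isoform
#' selection against the anchor species, divergence filtering, codon
#' alignment, column masking, sister-taxon gating, the branch-site LRT,
#' plausibility filtering and multiple-testing correction.  Per-gene
#' failures are isolated and reported, never abort the scan.
#'
#' @param config From [scan_config()].
#' @return List with \code{table} (ranked results, one row per isoform
#'   assignment, sorted by nominal p), \code{details} (per-assignment
#'   result objects) and \code{tree} (the species tree used).
#' @export
run_scan <- function(config) {
  tx <- config$transcripts
  groups <- catalog_groups(config$catalog)
  rows <- list(); details <- list()
  assignments <- list()
  for (gid in names(groups)) {
    g <- merge(groups[[gid]], tx, by = c("species", "transcript_id"),
               sort = FALSE, suffixes = c(".cat", ""))
    if (!nrow(g)) next
    g <- g[order(g$species, g$transcript_id), ]
    asg <- select_isoforms(g, config$anchor)
    if (is.null(asg)) {
      rows[[length(rows) + 1]] <- .scan_row(gid, NA, 0, flags = "no_anchor")
      next
    }
    for (a in asg) {
      a <- filter_divergent(a, config$thresholds)
      a$group_id <- gid
      assignments[[length(assignments) + 1]] <- a
    }
  }
  tree <- config$tree
  if (is.null(tree)) {
    species_all <- sort(unique(tx$species))
    tree <- infer_species_tree(assignments, species_all,
                               n_chunks = config$n_chunks)
  }
  for (a in assignments) {
    res <- tryCatch(
      .test_assignment(a, tree, config),
      error = function(e) .scan_row(a$group_id, a$anchor_transcript,
                                    nrow(a$transcripts),
                                    flags = paste0("error:",
                                                   conditionMessage(e))))
    if (!is.null(attr(res, "detail")))
      details[[paste(a$group_id, a$anchor_transcript, sep = "/")]] <-
        attr(res, "detail")
    attr(res, "detail") <- NULL
    rows[[length(rows) + 1]] <- res
  }
  tab <- do.call(rbind, rows)
  if (is.null(tab)) {
    warning("empty catalog: no assignments to test")
    tab <- .scan_row("x", NA, 0)[0, ]
  }
  tab$p_bonf <- adjust_pvalues(tab$p, "bonferroni")
  tab$p_bh <- adjust_pvalues(tab$p, "bh")
  tab$psg <- !is.na(tab$p) & tab$p <= config$alpha & tab$flags == ""
  ord <- order(tab$p, tab$gene, method = "radix", na.last = TRUE)
  tab <- tab[ord, ]
  rownames(tab) <- NULL
  list(table = tab, details = details, tree = tree)
}

.scan_row <- function(gene, transcript, n_species, codons_retained = NA,
                      frac_anchor_retained = NA, lnL0 = NA, lnL1 = NA,
                      lrt_stat = NA, p = NA, fg_omega = NA,
                      n_sites_p95 = NA, sites = "", flags = character(0)) {
  data.frame(gene = gene, transcript = transcript, n_species = n_species,
             codons_retained = codons_retained,
             frac_anchor_retained = frac_anchor_retained, lnL0 = lnL0,
             lnL1 = lnL1, lrt_stat = lrt_stat, p = p, fg_omega = fg_omega,
             n_sites_p95 = n_sites_p95, sites = sites,
             flags = paste(sort(unique(flags)), collapse = ","),
             stringsAsFactors = FALSE)
}

.test_assignment <- function(a, tree, config) {
  gid <- a$group_id
  aln <- codon_align(a)
  if (!length(aln))
    return(.scan_row(gid, a$anchor_transcript, nrow(a$transcripts),
                     flags = attr(aln, "skip_reason")))
  flags <- character(0)
  sis <- sister_taxon_check(tree, config$foreground, aln$species)
  if (!sis) flags <- c(flags, "no_sister_taxon")
  mask <- filter_columns(aln, cons_frac = config$mask_params$cons_frac,
                         min_block = config$mask_params$min_block,
                         allow_gaps = isTRUE(config$mask_params$allow_gaps))
  n_anchor <- sum(!is.na(aln$anchor_codon))
  kept <- sum(mask$keep)
  frac <- if (n_anchor) sum(mask$keep & !is.na(aln$anchor_codon)) / n_anchor
          else 0
  if (kept < 1 || "no_sister_taxon" %in% flags) {
    r <- .scan_row(gid, a$anchor_transcript, nrow(a$transcripts), kept,
                   frac, flags = c(flags, if (kept < 1) "too_few_columns"))
    return(r)
  }
  states <- aln$states[, mask$keep, drop = FALSE]
  fit1 <- fit_branch_site(states, tree, config$foreground, "alternative",
                          kappa = config$kappa)
  fit0 <- fit1$null
  if (!isTRUE(fit1$converged) || !isTRUE(fit0$converged))
    flags <- c(flags, "nonconvergent")
  lr <- lrt(fit0$lnL, fit1$lnL)
  post <- site_posteriors(fit1)
  kept_cols <- which(mask$keep)
  sel <- which(post > 0.95)
  anchor_pos <- aln$anchor_codon[kept_cols[sel]]
  anchor_row <- aln$aa[aln$anchor, kept_cols[sel]]
  sites <- if (length(sel))
    paste(sprintf("%d:%s:%.3f", anchor_pos, anchor_row, post[sel]),
          collapse = "|") else ""
  res <- list(codons_retained = kept, frac_anchor_retained = frac,
              n_species = nrow(a$transcripts), fg_omega = fit1$omega2,
              p2a_p2b = 1 - fit1$p0 - fit1$p1, posteriors = post,
              flags = flags)
  res <- plausibility_filter(res, config$filter)
  row <- .scan_row(gid, a$anchor_transcript, nrow(a$transcripts), kept, frac,
                   fit0$lnL, fit1$lnL, lr$statistic, lr$p_value, fit1$omega2,
                   sum(post > 0.95), sites, res$flags)
  attr(row, "detail") <- list(alignment = aln, mask = mask, fit = fit1,
                              posteriors = post, assignment = a)
  row
}

#' Write a ranked scan table as TSV
#' @param scan Result of [run_scan()].
#' @param path Output file.
#' @param params Character vector recorded in the commented header.
#' @export
write_scan_table <- function(scan, path, params = character(0)) {
  .write_tsv(scan$table, path, params = params)
}

#' Per-residue annotation of a tested alignment
#'
#' Joins, for every residue of the anchor sequence, its alignment column,
#' whether the column was tested (column mask), the posterior probability
#' of positive selection and overlapping protein domains.  Optionally
#' renders a simple HTML view with tested blocks and high-posterior sites
#' marked.
#'
#' @param detail A per-gene detail object from [run_scan()]
#'   (\code{scan$details[[i]]}).
#' @param domains Optional data.frame (start_codon, end_codon, label) for
#'   the anchor transcript.
#' @param html_path Optional path for an HTML rendering.
#' @return Annotation data.frame (one row per anchor residue).
#' @export
render_annotation <- function(detail, domains = NULL, html_path = NULL) {
  aln <- detail$alignment
  mask <- detail$mask
  post <- detail$posteriors
  kept_cols <- which(mask$keep)
  col_of_anchor <- which(!is.na(aln$anchor_codon))
  anchor_pos <- aln$anchor_codon[col_of_anchor]
  tested <- col_of_anchor %in% kept_cols
  pst <- rep(NA_real_, length(col_of_anchor))
  m <- match(col_of_anchor, kept_cols)
  pst[!is.na(m)] <- post[m[!is.na(m)]]
  dom <- rep("", length(anchor_pos))
  if (!is.null(domains) && nrow(domains))
    for (k in seq_len(nrow(domains))) {
      hit <- anchor_pos >= domains$start_codon[k] &
        anchor_pos <= domains$end_codon[k]
      dom[hit] <- ifelse(dom[hit] == "", domains$label[k],
                         paste(dom[hit], domains$label[k], sep = ";"))
    }
  ann <- data.frame(anchor_codon = anchor_pos,
                    anchor_aa = aln$aa[aln$anchor, col_of_anchor],
                    alignment_column = col_of_anchor, tested = tested,
                    posterior = pst, selected = !is.na(pst) & pst > 0.95,
                    domains = dom, stringsAsFactors = FALSE)
  if (!is.null(html_path)) .render_html(aln, mask, ann, html_path)
  ann
}

.render_html <- function(aln, mask, ann, path) {
  rows <- apply(aln$aa, 1, paste, collapse = "")
  marks <- ifelse(mask$keep, "=", ".")
  sel_cols <- ann$alignment_column[ann$selected]
  marks[sel_cols] <- "*"
  html <- c("<html><body><pre>",
            paste0(format(names(rows), width = 12), " ", rows),
            paste0(format("tested", width = 12), " ",
                   paste(marks, collapse = "")),
            "</pre>",
            "<p>= tested column, . masked, * posterior &gt; 0.95</p>",
            "</body></html>")
  writeLines(html, path)
  invisible(path)
}
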