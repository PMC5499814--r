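# Readers/writers and the core sequence data model.
#
# A set of transcripts is kept as a plain data.frame with one row per
# transcript and columns species, gene_id, transcript_id, cds, protein,
# plus a list column `domains` (each element NULL or a data.frame with
# columns start_codon, end_codon, label, 1-based inclusive codon
# coordinates).  Invalid records are never silently dropped: parsers
# return them in a separate `rejected` data.frame with a reason.

#' Translate a coding sequence
#'
#' Translates a nucleotide CDS under the universal genetic code. Codons
#' containing \code{N} translate to \code{X}; stop codons to \code{*}.
#'
#' @param cds Character vector of nucleotide sequences (lengths divisible
#'   by 3).
#' @return Character vector of amino-acid sequences.
#' @export
translate_cds <- function(cds) {
  gc <- Biostrings::GENETIC_CODE
  vapply(cds, function(s) {
    n <- nchar(s)
    if (n == 0L) return("")
    cods <- substring(s, seq(1L, n, 3L), pmin(seq(3L, n + 2L, 3L), n))
    aa <- gc[cods]
    aa[is.na(aa)] <- "X"
    paste0(aa, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# Validate one CDS string.  Trailing partial codons are trimmed, trailing
# stop codons stripped; internal stops or characters outside A,C,G,T,N
# invalidate the record (unrecognized pseudogenes and annotation errors
# are a major source of spurious selection signals).
validate_cds <- function(cds) {
  cds <- toupper(cds)
  if (grepl("[^ACGTN]", cds))
    return(list(cds = cds, protein = NA_character_, valid = FALSE,
                reason = "non_ACGTN_character"))
  extra <- nchar(cds) %% 3L
  if (extra > 0L) cds <- substr(cds, 1L, nchar(cds) - extra)
  if (nchar(cds) == 0L)
    return(list(cds = cds, protein = NA_character_, valid = FALSE,
                reason = "empty_after_trimming"))
  prot <- translate_cds(cds)
  if (substr(prot, nchar(prot), nchar(prot)) == "*") {
    cds <- substr(cds, 1L, nchar(cds) - 3L)
    prot <- substr(prot, 1L, nchar(prot) - 1L)
  }
  if (nchar(prot) == 0L)
    return(list(cds = cds, protein = NA_character_, valid = FALSE,
                reason = "empty_after_trimming"))
  if (grepl("*", prot, fixed = TRUE))
    return(list(cds = cds, protein = prot, valid = FALSE,
                reason = "internal_stop_codon"))
  list(cds = cds, protein = prot, valid = TRUE, reason = NA_character_)
}

.empty_transcripts <- function() {
  data.frame(species = character(), gene_id = character(),
             transcript_id = character(), cds = character(),
             protein = character(), stringsAsFactors = FALSE)
}

.finish_transcripts <- function(species, gene_id, transcript_id, cds,
                                domains = NULL) {
  n <- length(cds)
  val <- lapply(cds, validate_cds)
  df <- data.frame(species = species, gene_id = gene_id,
                   transcript_id = transcript_id,
                   cds = vapply(val, `[[`, "", "cds"),
                   protein = vapply(val, `[[`, "", "protein"),
                   stringsAsFactors = FALSE)
  df$domains <- if (is.null(domains)) vector("list", n) else domains
  ok <- vapply(val, `[[`, TRUE, "valid")
  reason <- vapply(val, `[[`, "", "reason")
  dup <- duplicated(df[c("species", "transcript_id")])
  if (any(dup & ok)) {
    reason[dup & ok] <- "duplicate_species_transcript_id"
    ok <- ok & !dup
  }
  rejected <- df[!ok, c("species", "gene_id", "transcript_id")]
  rejected$reason <- reason[!ok]
  rownames(rejected) <- NULL
  accepted <- df[ok, ]
  rownames(accepted) <- NULL
  list(transcripts = accepted, rejected = rejected)
}

#' Parse coding sequences from FASTA or GenBank
#'
#' FASTA headers must encode identity as \code{species|gene_id|transcript_id}
#' (configurable through \code{header_regex}, a PCRE pattern with named
#' captures \code{species}, \code{gene_id} and \code{transcript_id}).
#' GenBank flat files must carry a CDS feature per record; \code{Region}
#' features inside the CDS are recorded as protein domains in codon
#' coordinates.
#'
#' @param path Input file.
#' @param format \code{"fasta"} or \code{"genbank"}.
#' @param header_regex PCRE with named captures applied to FASTA headers.
#' @return List with elements \code{transcripts} (validated records) and
#'   \code{rejected} (excluded records with a \code{reason} column).
#'   Accepted plus rejected rows account for every input record.
#' @export
parse_transcripts <- function(path, format = c("fasta", "genbank"),
                              header_regex = .default_header_regex) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("cannot read sequence file: ", path)
  if (format == "fasta") .parse_fasta(path, header_regex)
  else .parse_genbank(path)
}

.default_header_regex <-
  "^(?<species>[^|]+)\\|(?<gene_id>[^|]+)\\|(?<transcript_id>\\S+)"

.named_captures <- function(x, pattern) {
  m <- regexpr(pattern, x, perl = TRUE)
  if (m == -1L) return(NULL)
  st <- attr(m, "capture.start")[1, ]
  len <- attr(m, "capture.length")[1, ]
  out <- substring(x, st, st + len - 1L)
  names(out) <- colnames(attr(m, "capture.start"))
  out
}

.parse_fasta <- function(path, header_regex) {
  seqs <- Biostrings::readBStringSet(path)
  lines <- readLines(path, warn = FALSE)
  header_lines <- which(startsWith(lines, ">"))
  heads <- names(seqs)
  sp <- gid <- tid <- character(length(seqs))
  bad <- logical(length(seqs))
  for (i in seq_along(heads)) {
    cap <- .named_captures(heads[i], header_regex)
    if (is.null(cap) ||
        !all(c("species", "gene_id", "transcript_id") %in% names(cap))) {
      bad[i] <- TRUE
      warning(sprintf("FASTA header at line %d does not match convention: %s",
                      header_lines[i], heads[i]), call. = FALSE)
      sp[i] <- gid[i] <- tid[i] <- NA_character_
    } else {
      sp[i] <- cap[["species"]]; gid[i] <- cap[["gene_id"]]
      tid[i] <- cap[["transcript_id"]]
    }
  }
  res <- .finish_transcripts(sp[!bad], gid[!bad], tid[!bad],
                             as.character(seqs)[!bad])
  if (any(bad)) {
    rej <- data.frame(species = NA_character_, gene_id = NA_character_,
                      transcript_id = heads[bad],
                      reason = "header_not_matching_convention",
                      stringsAsFactors = FALSE)
    res$rejected <- rbind(res$rejected, rej)
  }
  res
}

# Minimal GenBank flat-file parser: LOCUS name or ACCESSION as transcript
# id, ORGANISM as species, /gene qualifier of the CDS as gene id. Region
# features overlapping the CDS become domain annotations (codon units
# relative to the CDS).  Only plain and join() locations are supported.
.parse_genbank <- function(path) {
  lines <- readLines(path, warn = FALSE)
  recs <- split(lines, cumsum(c(TRUE, head(lines, -1) == "//")))
  sp <- gid <- tid <- cds <- character(0)
  doms <- list()
  for (rec in recs) {
    if (!any(startsWith(rec, "LOCUS"))) next
    locus <- strsplit(trimws(sub("^LOCUS", "", rec[startsWith(rec, "LOCUS")][1])),
                      "\\s+")[[1]][1]
    org <- rec[grepl("^\\s+ORGANISM", rec)]
    species <- if (length(org)) trimws(sub("^\\s+ORGANISM\\s+", "", org[1]))
               else NA_character_
    ftab <- .gb_features(rec)
    cds_feat <- Filter(function(f) f$key == "CDS", ftab)
    if (!length(cds_feat)) next
    f <- cds_feat[[1]]
    seq <- .gb_origin(rec)
    segs <- f$segments
    cds_seq <- paste0(substring(seq, segs[, 1], segs[, 2]), collapse = "")
    gene <- if (!is.null(f$qualifiers[["gene"]])) f$qualifiers[["gene"]]
            else locus
    cds_start <- segs[1, 1]
    dom <- NULL
    for (rf in Filter(function(x) x$key == "Region", ftab)) {
      s <- rf$segments
      start_codon <- (s[1, 1] - cds_start) %/% 3L + 1L
      end_codon <- (s[1, 2] - cds_start) %/% 3L + 1L
      lab <- rf$qualifiers[["region_name"]]
      if (is.null(lab)) lab <- rf$qualifiers[["note"]]
      if (is.null(lab)) lab <- "region"
      dom <- rbind(dom, data.frame(start_codon = start_codon,
                                   end_codon = end_codon, label = lab,
                                   stringsAsFactors = FALSE))
    }
    sp <- c(sp, species); gid <- c(gid, gene); tid <- c(tid, locus)
    cds <- c(cds, cds_seq); doms <- c(doms, list(dom))
  }
  if (!length(tid)) stop("no GenBank records with CDS features in ", path)
  .finish_transcripts(sp, gid, tid, cds, doms)
}

.gb_features <- function(rec) {
  i0 <- which(startsWith(rec, "FEATURES"))
  iend <- which(startsWith(rec, "ORIGIN"))
  if (!length(i0)) return(list())
  if (!length(iend)) iend <- length(rec) + 1L
  block <- rec[(i0[1] + 1L):(iend[1] - 1L)]
  starts <- which(grepl("^\\s{1,10}\\S", block) & !grepl("^\\s{10,}", block))
  feats <- list()
  for (k in seq_along(starts)) {
    from <- starts[k]
    to <- if (k < length(starts)) starts[k + 1L] - 1L else length(block)
    chunk <- block[from:to]
    hdr <- strsplit(trimws(chunk[1]), "\\s+")[[1]]
    key <- hdr[1]
    loc <- paste0(hdr[-1], collapse = "")
    body <- trimws(chunk[-1])
    qual_lines <- body[startsWith(body, "/")]
    loc <- paste0(loc, paste0(body[!startsWith(body, "/")], collapse = ""))
    loc <- gsub("join\\(|complement\\(|\\)|<|>", "", loc)
    parts <- strsplit(loc, ",")[[1]]
    segs <- do.call(rbind, lapply(strsplit(parts, "\\.\\."), function(p)
      as.integer(c(p[1], p[length(p)]))))
    quals <- list()
    for (q in qual_lines) {
      kv <- sub("^/", "", q)
      if (grepl("=", kv)) {
        key2 <- sub("=.*", "", kv)
        val <- gsub('^"|"$', "", sub("^[^=]*=", "", kv))
        quals[[key2]] <- val
      } else quals[[kv]] <- TRUE
    }
    feats[[length(feats) + 1L]] <- list(key = key, segments = segs,
                                        qualifiers = quals)
  }
  feats
}

.gb_origin <- function(rec) {
  i0 <- which(startsWith(rec, "ORIGIN"))
  if (!length(i0)) stop("GenBank record without ORIGIN block")
  iend <- which(rec == "//")
  iend <- iend[iend > i0[1]]
  iend <- if (length(iend)) iend[1] else length(rec) + 1L
  body <- rec[(i0[1] + 1L):(iend - 1L)]
  toupper(gsub("[^A-Za-z]", "", paste0(body, collapse = "")))
}

#' Read a species tree in Newick format
#'
#' The tree is unrooted internally (a rooted binary input has its root edge
#' merged into a basal multifurcation); branch lengths are preserved.
#'
#' @param path Newick file.
#' @param species Optional character vector of expected species; a leaf
#'   label outside this set is a fatal error.
#' @return An unrooted \code{ape} \code{phylo} object.
#' @export
read_species_tree <- function(path, species = NULL) {
  tr <- ape::read.tree(path)
  if (is.null(tr)) stop("cannot parse Newick tree in ", path)
  if (!is.null(species)) {
    unknown <- setdiff(tr$tip.label, species)
    if (length(unknown))
      stop("tree leaf not in the species set: ", paste(unknown, collapse = ", "))
  }
  if (ape::is.rooted(tr)) tr <- ape::unroot(tr)
  tr
}

#' Write a species tree in Newick format
#' @param tree \code{phylo} object.
#' @param path Output file.
#' @export
write_species_tree <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

# commented header naming tool version and parameters, then TSV body
.write_tsv <- function(df, path, params = character(0)) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  ver <- as.character(utils::packageVersion("posiselect"))
  writeLines(paste0("# posiselect ", ver,
                    if (length(params)) paste0(" | ", paste(params, collapse = " "))
                    else ""), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                    stringsAsFactors = FALSE, quote = "")
}

#' Read an ortholog catalog
#'
#' A catalog is a TSV with columns \code{group_id}, \code{species},
#' \code{gene_id}, \code{transcript_id}; one row per transcript membership.
#' Duplicate (species, transcript) rows within a group are dropped with a
#' warning.  If \code{transcripts} is supplied, rows referencing unknown
#' transcripts are omitted with a warning and counted in the
#' \code{"report"} attribute.
#'
#' @param path Catalog TSV.
#' @param transcripts Optional transcript data.frame to validate against.
#' @return Catalog data.frame; attribute \code{"report"} holds counts of
#'   read/kept/dropped rows.
#' @export
read_catalog <- function(path, transcripts = NULL) {
  df <- .read_tsv(path)
  need <- c("group_id", "species", "gene_id", "transcript_id")
  if (!all(need %in% names(df)))
    stop("catalog must have columns ", paste(need, collapse = ", "))
  df <- df[need]
  df[] <- lapply(df, as.character)
  n_in <- nrow(df)
  dup <- duplicated(df[c("group_id", "species", "transcript_id")])
  if (any(dup)) {
    warning(sum(dup), " duplicate catalog row(s) removed")
    df <- df[!dup, ]
  }
  n_missing <- 0L
  if (!is.null(transcripts)) {
    key <- paste(df$species, df$transcript_id)
    known <- paste(transcripts$species, transcripts$transcript_id)
    miss <- !(key %in% known)
    n_missing <- sum(miss)
    if (n_missing) {
      warning(n_missing, " catalog row(s) reference unknown transcripts; omitted")
      df <- df[!miss, ]
    }
  }
  rownames(df) <- NULL
  attr(df, "report") <- c(rows_read = n_in, rows_kept = nrow(df),
                          rows_duplicate = sum(dup), rows_missing = n_missing)
  df
}

#' Write an ortholog catalog
#' @param catalog Catalog data.frame.
#' @param path Output TSV.
#' @export
write_catalog <- function(catalog, path) {
  .write_tsv(catalog[c("group_id", "species", "gene_id", "transcript_id")],
             path, params = "catalog")
}

# split a catalog into a list of per-group member data.frames
catalog_groups <- function(catalog) {
  split(catalog, catalog$group_id)
}
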