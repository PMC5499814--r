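# Shared fixtures, generated in code.

# deterministic random CDS without internal stops
random_cds <- function(n_codons, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(sense_codons(), n_codons, replace = TRUE), collapse = "")
}

fixture_fasta <- function(records, path = tempfile(fileext = ".fa")) {
  writeLines(unlist(lapply(names(records), function(h)
    c(paste0(">", h), records[[h]]))), path)
  path
}

# a small transcript table across three species, one gene, two isoforms in
# one species (the second isoform lacks an internal exon)
fixture_transcripts <- function() {
  base <- random_cds(60, seed = 42)
  exon <- random_cds(10, seed = 43)
  with_exon <- paste0(substr(base, 1, 90), exon, substr(base, 91, 180))
  mut <- function(s, k, seed) {
    set.seed(seed)
    pos <- sample(nchar(s) %/% 3, k)
    cods <- sample(sense_codons(), k, replace = TRUE)
    for (i in seq_len(k))
      substr(s, 3 * pos[i] - 2, 3 * pos[i]) <- cods[i]
    s
  }
  df <- data.frame(
    species = c("hs", "hs", "pt", "mm"),
    gene_id = "G1",
    transcript_id = c("T1", "T2", "T3", "T4"),
    cds = c(with_exon, base, mut(with_exon, 4, 1), mut(base, 12, 2)),
    stringsAsFactors = FALSE)
  df$protein <- translate_cds(df$cds)
  df$domains <- vector("list", nrow(df))
  df
}

fixture_genbank <- function(path = tempfile(fileext = ".gb")) {
  cds <- "ATGAAACCCGGGTTTACATGGCATAAGCTGATCGTAGCTGCTGGATCAGCTCAGATTTGA"
  seqlines <- paste0("        1 ", tolower(cds))
  writeLines(c(
    "LOCUS       TX01                 60 bp    DNA     linear   PRI",
    "DEFINITION  synthetic test record.",
    "ACCESSION   TX01",
    "  ORGANISM  hs",
    "FEATURES             Location/Qualifiers",
    "     CDS             1..60",
    "                     /gene=\"G9\"",
    "     Region          13..60",
    "                     /region_name=\"DemoDomain\"",
    "ORIGIN",
    seqlines,
    "//"), path)
  path
}

# quick simulated gene family (reduced tree for cheap tests)
fixture_family <- function(seed = 1, root_length = 120, scheme = NULL,
                           tested = NULL) {
  set.seed(seed)
  cfg <- simulation_config(root_length = root_length,
                           tested_branch = tested, tested_scheme = scheme)
  evolve(cfg, "g1")
}
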