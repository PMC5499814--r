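test_that("FASTA parsing, translation and CDS validation follow the rules", {
  fa <- fixture_fasta(list(
    "hs|G1|T1" = "ATGAAATAG",        # trailing stop stripped
    "hs|G1|T2" = "ATGTAAAAA",        # internal stop -> invalid
    "pt|G1|T3" = "ATGAAAC",          # trailing partial codon trimmed
    "mm|G1|T4" = "ATGRRR"            # ambiguity code -> rejected
  ))
  res <- parse_transcripts(fa, "fasta")
  expect_equal(nrow(res$transcripts) + nrow(res$rejected), 4L)
  t1 <- res$transcripts[res$transcripts$transcript_id == "T1", ]
  expect_equal(t1$protein, "MK")
  expect_equal(t1$cds, "ATGAAA")
  expect_true("T2" %in% res$rejected$transcript_id)
  expect_equal(res$rejected$reason[res$rejected$transcript_id == "T2"],
               "internal_stop_codon")
  t3 <- res$transcripts[res$transcripts$transcript_id == "T3", ]
  expect_equal(t3$cds, "ATGAAA")
  expect_equal(res$rejected$reason[res$rejected$transcript_id == "T4"],
               "non_ACGTN_character")
})

test_that("headers violating the convention are reported, not coerced", {
  fa <- fixture_fasta(list("hs|G1|T1" = "ATGAAA", "badheader" = "ATGCCC"))
  expect_warning(res <- parse_transcripts(fa, "fasta"), "line 3")
  expect_equal(nrow(res$transcripts), 1L)
  expect_equal(res$rejected$reason, "header_not_matching_convention")
})

test_that("translation agrees with Biostrings for all 61 sense codons", {
  cods <- sense_codons()
  mine <- translate_cds(cods)
  ref <- vapply(cods, function(cd)
    as.character(Biostrings::translate(Biostrings::DNAString(cd),
                                       no.init.codon = TRUE)),
    character(1), USE.NAMES = FALSE)
  expect_equal(mine, ref)
})

test_that("GenBank records yield CDS and domain features in codon units", {
  gb <- fixture_genbank()
  res <- parse_transcripts(gb, "genbank")
  expect_equal(nrow(res$transcripts), 1L)
  tx <- res$transcripts
  expect_equal(tx$species, "hs")
  expect_equal(tx$gene_id, "G9")
  expect_equal(tx$transcript_id, "TX01")
  expect_equal(nchar(tx$cds), 57)  # trailing TGA stripped
  dom <- tx$domains[[1]]
  expect_equal(dom$start_codon, 5L)
  expect_equal(dom$end_codon, 20L)
  expect_equal(dom$label, "DemoDomain")
})

test_that("Newick trees are unrooted with lengths preserved", {
  p <- tempfile(fileext = ".nwk")
  writeLines("((A:0.1,B:0.2):0.05,C:0.3,D:0.4);", p)
  tr <- read_species_tree(p)
  expect_false(ape::is.rooted(tr))
  expect_equal(length(tr$tip.label), 4L)
  expect_equal(nrow(tr$edge), 5L)

  writeLines("((A:0.1,B:0.2):0.05,(C:0.3,D:0.4):0.02);", p)
  tr2 <- read_species_tree(p)
  expect_false(ape::is.rooted(tr2))
  # root edge merged: the AB|CD split carries length 0.05 + 0.02
  sp <- posiselect:::.edge_splits(tr2)
  internal <- which(sp == "C|D")
  expect_equal(tr2$edge.length[internal], 0.07)

  expect_error(read_species_tree(p, species = c("A", "B", "C")), "D")

  # round trip
  p2 <- tempfile(fileext = ".nwk")
  write_species_tree(tr2, p2)
  tr3 <- read_species_tree(p2)
  expect_equal(ape::dist.topo(tr2, tr3), structure(0, class = NULL),
               ignore_attr = TRUE)
  expect_equal(sort(tr3$edge.length), sort(tr2$edge.length))
})

test_that("catalog read/write round-trips and deduplicates", {
  cat0 <- data.frame(
    group_id = c("OG1", "OG1", "OG2", "OG2", "OG2"),
    species = c("hs", "pt", "hs", "pt", "pt"),
    gene_id = c("G1", "G1", "G2", "G2", "G2"),
    transcript_id = c("T1", "T3", "T5", "T6", "T6"),
    stringsAsFactors = FALSE)
  p <- tempfile(fileext = ".tsv")
  write_catalog(cat0, p)
  expect_warning(cat1 <- read_catalog(p), "duplicate")
  expect_equal(nrow(cat1), 4L)
  expect_equal(length(catalog_groups(cat1)), 2L)

  # round-trip identity on a larger random catalog
  set.seed(9)
  big <- data.frame(
    group_id = sprintf("OG%03d", rep(1:50, each = 3)),
    species = rep(c("hs", "pt", "mm"), 50),
    gene_id = sprintf("G%03d", rep(1:50, each = 3)),
    transcript_id = sprintf("T%04d", 1:150),
    stringsAsFactors = FALSE)
  p2 <- tempfile(fileext = ".tsv")
  write_catalog(big, p2)
  back <- read_catalog(p2)
  attr(back, "report") <- NULL
  expect_equal(back, big, ignore_attr = TRUE)

  # unknown transcript reference -> warning + omission, counted
  tx <- data.frame(species = "hs", transcript_id = "T1",
                   stringsAsFactors = FALSE)
  write_catalog(cat0[1:2, ], p)
  expect_warning(cat2 <- read_catalog(p, transcripts = tx), "unknown")
  expect_equal(nrow(cat2), 1L)
  expect_equal(unname(attr(cat2, "report")["rows_missing"]), 1L)
})
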