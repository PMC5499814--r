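test_that("protein similarity is Smith-Waterman under BLOSUM62", {
  # hand sum of BLOSUM62 diagonal entries: M5 + K5 + V4 = 14
  h <- protein_similarity("MKV", "MKV")
  expect_equal(h$score, 14)
  expect_equal(h$identity, 1)

  set.seed(1)
  s <- paste(sample(posiselect:::.aa_alphabet[1:20], 100, TRUE), collapse = "")
  self <- protein_similarity(s, s)
  expect_equal(self$identity, 1)
  expect_gt(self$score, 0)
  # symmetry
  s2 <- paste(sample(posiselect:::.aa_alphabet[1:20], 80, TRUE), collapse = "")
  expect_equal(protein_similarity(s, s2)$score,
               protein_similarity(s2, s)$score)
  expect_error(protein_similarity("", "MK"))
})

test_that("unrelated random sequences rarely clear the reporting floor", {
  # random pairs either align only short local segments or align longer
  # stretches at low identity, so the floor (identity >= 0.25 AND aligned
  # length >= 30) rejects them with high probability
  set.seed(7)
  aas <- posiselect:::.aa_alphabet[1:20]
  pass <- replicate(60, {
    a <- paste(sample(aas, 100, TRUE), collapse = "")
    b <- paste(sample(aas, 100, TRUE), collapse = "")
    h <- protein_similarity(a, b)
    h$aligned_length >= 30 && h$identity >= 0.4
  })
  expect_lt(mean(pass), 0.1)
})

# a constructed score world: proteins built from distinct motifs so that
# best hits are unambiguous and enumerable
.make_world <- function() {
  set.seed(5)
  aas <- posiselect:::.aa_alphabet[1:20]
  motif <- function() paste(sample(aas, 60, TRUE), collapse = "")
  fams <- replicate(3, motif())
  mut <- function(s, k) {
    pos <- sample(nchar(s), k)
    for (p in pos) substr(s, p, p) <- sample(aas, 1)
    s
  }
  tx <- function(sp, g, t, seqs) data.frame(
    species = sp, gene_id = g, transcript_id = t, cds = NA, protein = seqs,
    stringsAsFactors = FALSE)
  catalog_tx <- rbind(
    tx("hs", "HG1", "HT1", fams[1]), tx("hs", "HG1", "HT1b", mut(fams[1], 2)),
    tx("hs", "HG2", "HT2", fams[2]),
    tx("hs", "HG3", "HT3", fams[3]))
  catalog <- data.frame(group_id = c("Y1", "Y1", "Y2", "Y3"),
                        species = "hs", gene_id = catalog_tx$gene_id,
                        transcript_id = catalog_tx$transcript_id,
                        stringsAsFactors = FALSE)
  new_tx <- rbind(
    tx("mm", "MG1", "MT1", mut(fams[1], 4)),
    tx("mm", "MG1", "MT1b", mut(fams[1], 8)),
    tx("mm", "MG2", "MT2", mut(fams[2], 5)),
    tx("mm", "MG3", "MT3", mut(fams[3], 6)))
  list(catalog = catalog, catalog_tx = catalog_tx, new_tx = new_tx)
}

test_that("best_hit_group matches a brute-force scan of the score table", {
  w <- .make_world()
  gene <- w$new_tx[w$new_tx$gene_id == "MG1", ]
  got <- best_hit_group(gene, w$catalog, w$catalog_tx)
  # oracle: exhaustive score table over all isoform x member pairs
  best <- NULL
  for (qi in seq_len(nrow(gene))) for (si in seq_len(nrow(w$catalog_tx))) {
    sc <- protein_similarity(gene$protein[qi], w$catalog_tx$protein[si])$score
    if (is.null(best) || sc > best$sc)
      best <- list(sc = sc,
                   gid = w$catalog$group_id[
                     w$catalog$transcript_id == w$catalog_tx$transcript_id[si]])
  }
  expect_equal(got$group_id, best$gid)
  expect_equal(got$hit$score, best$sc)
})

test_that("assignment is bidirectional, partial and order-invariant", {
  w <- .make_world()
  res <- assign_species(w$catalog, w$catalog_tx, w$new_tx)
  asg <- res$report[res$report$reason == "assigned", ]
  expect_equal(sort(asg$gene_id), c("MG1", "MG2", "MG3"))
  expect_equal(asg$group_id[asg$gene_id == "MG1"], "Y1")
  # each gene joins at most one group
  expect_false(any(duplicated(
    unique(res$catalog[res$catalog$species == "mm",
                       c("gene_id", "group_id")])$gene_id)))
  # order invariance
  res2 <- assign_species(w$catalog[4:1, ], w$catalog_tx[4:1, ],
                         w$new_tx[4:1, ])
  expect_equal(res2$report[order(res2$report$gene_id), "group_id"],
               res$report[order(res$report$gene_id), "group_id"])
})

test_that("asymmetric best hits leave a gene unassigned", {
  w <- .make_world()
  # make the back-hit land on a different new gene: add a new-species gene
  # that is an exact copy of the catalog sequence of Y2
  clone <- data.frame(species = "mm", gene_id = "MGX", transcript_id = "MTX",
                      cds = NA,
                      protein = w$catalog_tx$protein[
                        w$catalog_tx$transcript_id == "HT2"],
                      stringsAsFactors = FALSE)
  new_tx <- rbind(w$new_tx, clone)
  res <- assign_species(w$catalog, w$catalog_tx, new_tx)
  rep_mg2 <- res$report[res$report$gene_id == "MG2", ]
  expect_equal(rep_mg2$reason, "not_bidirectional")
  expect_equal(res$report$group_id[res$report$gene_id == "MGX"], "Y2")
})

test_that("de novo BBH seeding groups homologous genes", {
  w <- .make_world()
  tx <- rbind(w$catalog_tx, w$new_tx)
  seeded <- seed_catalog_bbh(tx)
  grp_of <- function(g) unique(seeded$group_id[seeded$gene_id == g])
  expect_equal(grp_of("HG1"), grp_of("MG1"))
  expect_equal(grp_of("HG2"), grp_of("MG2"))
  expect_false(grp_of("HG1") == grp_of("HG2"))
})
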