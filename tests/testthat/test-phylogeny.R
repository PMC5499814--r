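# small codon alignment chunks built directly as state matrices
.chunk_from_codons <- function(codons) {
  states <- apply(codons, c(1, 2), function(x)
    if (x == "---") NA_integer_ else unname(posiselect:::codon_states(x)))
  list(states = states)
}

test_that("4-taxon parsimony finds the topology supported by the sites", {
  # sites supporting only the AB|CD split: A,B share one codon, C,D another
  ab <- "ATG"; cd <- "CCC"
  cods <- matrix(rep(c(ab, ab, cd, cd), 10), nrow = 4,
                 dimnames = list(c("A", "B", "C", "D"), NULL))
  ch <- .chunk_from_codons(cods)
  tr <- parsimony_tree(ch)
  # oracle: exhaustive scan over the 3 unrooted 4-taxon topologies
  pd <- posiselect:::.chunk_phydat(ch$states)
  all3 <- phangorn::allTrees(4, tip.label = rownames(cods))
  scores <- vapply(all3, function(t) phangorn::fitch(t, pd), numeric(1))
  expect_equal(attr(tr, "parsimony_score"), min(scores))
  split <- posiselect:::.edge_splits(tr)
  expect_true("C|D" %in% split)
  # Fitch score equals number of variable nucleotide positions here
  # (each variable position needs exactly one change on AB|CD)
  nvar <- sum(apply(do.call(rbind, strsplit(c(ab, ab, cd, cd), "")), 2,
                    function(x) length(unique(x)) > 1))
  expect_equal(attr(tr, "parsimony_score"), 10 * nvar)
})

test_that("constant alignments give score zero", {
  cods <- matrix(rep("ATG", 4 * 8), nrow = 4,
                 dimnames = list(c("A", "B", "C", "D"), NULL))
  tr <- parsimony_tree(.chunk_from_codons(cods))
  expect_equal(attr(tr, "parsimony_score"), 0)
  expect_true(all(tr$edge.length == 0))
})

test_that("NNI hill-climbing never scores worse than the NJ start", {
  set.seed(8)
  cods <- matrix(sample(sense_codons(), 7 * 30, TRUE), nrow = 7,
                 dimnames = list(paste0("s", 1:7), NULL))
  ch <- .chunk_from_codons(cods)
  pd <- posiselect:::.chunk_phydat(ch$states)
  nj <- ape::nj(phangorn::dist.hamming(pd))
  tr <- parsimony_tree(ch)
  expect_lte(attr(tr, "parsimony_score"), phangorn::fitch(nj, pd))
})

test_that("consensus keeps strict-majority splits with averaged lengths", {
  t1 <- ape::read.tree(text = "((A:1,B:1):0.1,(C:1,D:1):0.1,E:1);")
  t2 <- ape::read.tree(text = "((A:1,B:1):0.3,(C:1,D:1):0.5,E:1);")
  t3 <- ape::read.tree(text = "((A:1,C:1):0.2,(B:1,D:1):0.2,E:1);")
  cons <- consensus_with_lengths(list(t1, t2, t3))
  sp <- posiselect:::.edge_splits(cons)
  sup <- attr(cons, "support")
  # AB|CDE in 2/3 trees -> kept with mean length (0.1+0.3)/2
  ab <- which(sp == "C|D|E")
  expect_length(ab, 1L)
  expect_equal(cons$edge.length[ab], 0.2)
  expect_equal(unname(sup[ab]), 2 / 3)
  # AC|BDE in 1/3 -> absent
  expect_false("B|D|E" %in% sp[sup > 0.5])
  # identical trees reproduce themselves exactly
  cons2 <- consensus_with_lengths(list(t1, t1, t1))
  expect_equal(sort(posiselect:::.edge_splits(cons2)),
               sort(posiselect:::.edge_splits(t1)))
  m <- match(posiselect:::.edge_splits(t1), posiselect:::.edge_splits(cons2))
  expect_equal(cons2$edge.length[m], t1$edge.length)
  # permutation invariance of the averaging
  cons3 <- consensus_with_lengths(list(t3, t2, t1))
  m2 <- match(posiselect:::.edge_splits(cons), posiselect:::.edge_splits(cons3))
  expect_equal(cons3$edge.length[m2], cons$edge.length)
})

test_that("a split at exactly 50% is excluded (strict majority)", {
  t1 <- ape::read.tree(text = "((A:1,B:1):0.1,(C:1,D:1):0.1,E:1);")
  t3 <- ape::read.tree(text = "((A:1,C:1):0.2,(B:1,D:1):0.2,E:1);")
  cons <- consensus_with_lengths(list(t1, t3))
  sup <- attr(cons, "support")
  internal <- sup[!grepl("^[A-E]$", names(sup))]
  expect_false(any(internal[internal <= 0.5] > 0))  # none retained at 0.5
  # the consensus backbone has no internal split from either tree
  expect_equal(cons$Nnode, 1L)
})

test_that("superalignment concatenates, chunks and filters", {
  fams <- lapply(1:2, function(i) fixture_family(seed = i, root_length = 60))
  assignments <- lapply(fams, function(f) {
    tx <- f$transcripts
    tx <- tx[order(match(tx$species, c("human", setdiff(tx$species, "human")))), ]
    list(transcripts = tx)
  })
  sp <- sort(assignments[[1]]$transcripts$species)
  chunks <- build_superalignment(assignments, sp, n_chunks = 4)
  expect_gt(length(chunks), 0)
  tot <- sum(vapply(chunks, function(c) ncol(c$states), numeric(1)))
  alns <- lapply(assignments, codon_align)
  raw <- sum(vapply(alns, function(a) ncol(a$states), numeric(1)))
  expect_lte(tot, raw)  # filtering never adds columns
  # all species present in every chunk
  for (ch in chunks) expect_setequal(rownames(ch$states), sp)
  expect_error(build_superalignment(assignments, c(sp, "yeti"), 4),
               "complete")
})

test_that("the inferred species tree recovers the generating topology", {
  # parameter recovery: simulate a long gene family along the known tree,
  # then rebuild the tree from chunked parsimony + consensus
  fam <- fixture_family(seed = 99, root_length = 1200)
  tx <- fam$transcripts
  tx <- tx[order(match(tx$species, c("human", setdiff(tx$species, "human")))), ]
  tr <- infer_species_tree(list(list(transcripts = tx)),
                           sort(tx$species), n_chunks = 6)
  expect_equal(ape::dist.topo(ape::unroot(tr), default_mammal_tree()), 0,
               ignore_attr = TRUE)
})
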