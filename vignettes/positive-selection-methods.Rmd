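---
title: "Methods: genome-wide branch-site scans for positive selection"
author: "posiselect"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: genome-wide branch-site scans for positive selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`posiselect` scans protein-coding gene families for positive selection on
one chosen branch of a species tree.  The signal is the ratio
$\omega = d_N/d_S$ of non-synonymous to synonymous substitution rates;
$\omega > 1$ at some sites on the tested ("foreground") branch is the
hallmark of episodic positive selection.  The package covers the whole
path from raw coding sequences to a ranked candidate table: ortholog
cataloguing, isoform selection, codon alignment, alignment filtering,
species-tree inference, the branch-site likelihood-ratio test, and
plausibility filtering with multiple-testing correction.  A codon
evolution simulator with indels generates fully annotated gene families
for validation of every stage.

# The codon substitution model

The substitution process is a GY94-type Markov process on the 61 sense
codons.  For codons $i \ne j$ differing at exactly one nucleotide,

$$ q_{ij} = \pi_j \cdot \kappa^{[\text{transition}]} \cdot
            \omega^{[\text{non-synonymous}]}, $$

zero for multi-nucleotide changes, with $\pi$ the stationary codon
frequencies (estimated F3x4 from the masked alignment by default),
$\kappa$ the transition/transversion rate ratio and $\omega$ the
selection parameter.  The process is reversible; transition probabilities
are computed by symmetric eigendecomposition.

The branch-site mixture ("model A") has four site classes:

| class | background $\omega$ | foreground $\omega$ | weight |
|-------|--------------------|--------------------|--------|
| 0     | $\omega_0 \le 1$   | $\omega_0$         | $p_0$  |
| 1     | 1                  | 1                  | $p_1$  |
| 2a    | $\omega_0$         | $\omega_2 \ge 1$   | $(1-p_0-p_1)\,p_0/(p_0{+}p_1)$ |
| 2b    | 1                  | $\omega_2$         | $(1-p_0-p_1)\,p_1/(p_0{+}p_1)$ |

The null model fixes $\omega_2 = 1$; the alternative frees it.  Twice the
log-likelihood difference is referred to $\chi^2_1$.  This is the plain
$\chi^2_1$ reference explicitly, not the 50:50 boundary mixture sometimes
recommended; the plain reference is conservative, which suits a
genome-wide scan oriented toward precision.  Per-site posterior
probabilities of the positively selected classes (2a $\cup$ 2b) are naive
empirical Bayes at the ML estimates; a full Bayes-empirical-Bayes
integration over parameter uncertainty is a noted extension, not
implemented.

## Likelihood evaluation and optimization

Site patterns are collapsed before pruning.  The tree is rooted *on the
foreground edge*: conditional likelihood vectors for the two flanking
subtrees are computed once per background $\omega$ (classes 0/2a share
the $\omega_0$ conditionals, classes 1/2b the neutral ones), and the four
class likelihoods differ only in the transition matrix applied across the
foreground edge.  This roughly halves the cost of a likelihood
evaluation; the implementation is in C++ (RcppArmadillo).

Free parameters are handled in three tiers, a deliberate deviation from
re-estimating everything in every model:

* **Branch lengths** are taken from the species tree up to a single
  free scale factor, fitted in every model.  Estimating all branch
  lengths per gene is available (`fit_branch_site(..., variant = "m0",
  estimate_branch_lengths = TRUE)`, coordinate-wise Brent descent) and is
  used by the branch-length-recovery validation, but is too slow for a
  genome-wide default and adds variance on short alignments.
* **$\kappa$** is estimated per gene under a single-ratio (M0) pre-fit
  and held fixed in the null/alternative fits; $\kappa$ is nearly
  orthogonal to the selection parameters, and freeing it roughly doubles
  optimization cost for no measurable change in the LRT.
* **$(\omega_0, \text{scale}[, \omega_2])$** are optimized by bounded
  quasi-Newton (L-BFGS-B on log scale, $\omega_0 \in [10^{-4},1]$,
  $\omega_2 \in [1,999]$) with three deterministic starts; the first
  alternative start sits at the null solution so the alternative can
  never fall below the null.  The class proportions are profiled out by
  an inner Nelder-Mead simplex in $(\text{logit}\,s, \text{logit}\,r)$
  with $s = p_0+p_1$, $r = p_0/(p_0+p_1)$ — in this parameterization the
  four class weights are an outer product, and the constraint surface is
  a box.  The inner warm start is pulled off the $s = 1$ boundary, where
  the likelihood is flat in $\omega_2$; without this the alternative fit
  can silently return the null.

Two safeguards make the LRT an honest contrast in $\omega_2$ alone:
the alternative is seeded at the fitted null, and the null is re-polished
from the alternative's $(\omega_0, \text{scale})$ basin after the
alternative fit.  Without the second guard a single replicate in
validation produced a spurious LRT statistic of 207 purely from the null
optimizer landing in a worse basin.

# Alignment and filtering

Protein MSAs are progressive: a UPGMA guide tree on 3-mer distances,
profile-profile merges under BLOSUM62 with affine gaps (open 10, extend
0.5).  Codon alignments are back-threaded from the protein MSA, so every
aligned residue maps to its source codon.  An adapter seam
(`codon_align(aligner = ...)`) accepts any function from named protein
sequences to a named aligned set, for users who prefer an external,
phylogeny-aware aligner on real data.

Isoform handling follows the anchor-species design: for each anchor
isoform, the most similar isoform (MSA identity over shared non-gap
columns) of every other species is chosen, giving as many assignments per
ortholog group as the anchor has isoforms.  Divergent sequences are then
removed: first everything below `theta_anchor` identity to the anchor,
then iteratively the sequence with most pairwise violations of
`theta_pair` (ties: lowest anchor similarity).  Both thresholds default
to 0.5 — the published design names the thresholds but not their values,
and 0.5 identity is where protein alignments of true orthologs rarely
fall while non-homologous picks commonly do.

Column filtering is stringent, in the tradition of block-filtering
before selection tests: a codon column is kept iff it has no gap and no
N-containing codon, and at least `cons_frac` of the sequences share the
majority amino acid (`0.5 + 1/n` by default, i.e. an absolute majority
plus one); kept runs shorter than `min_block = 5` codons are dropped.
Conservation is judged on the translation but removal acts on codons.
**A known, intended consequence**: columns carrying substitutions on deep
internal branches fail the majority rule (a primate-stem change leaves a
5/9 majority in the nine-species set) and are removed, so branch lengths
re-estimated from the *masked* alignment are biased short on deep
branches — by up to 70% in our measurements.  This is why the
branch-length-recovery validation disables the conservation component
(`cons_frac = 0`, a supported configuration) and checks the estimator on
gap-free columns, where it recovers all branches within 10% (plus
per-branch Poisson counting noise) at 10,000 codons.

# Species-tree inference

Assignments that retain all requested species are codon-aligned,
concatenated, cut into `n_chunks = 20` equal chunks, and column-filtered.
Each chunk yields one unrooted parsimony tree — exhaustive search up to
six taxa, otherwise NNI hill-climbing from a neighbor-joining start
(phangorn).  Branch lengths are ACCTRAN-reconstructed changes per
nucleotide site; the classical implementation delegates this to a
parsimony program whose internal method is not restated anywhere, so
ACCTRAN is this package's documented choice.  The consensus keeps splits
in strictly more than half the chunk trees; each consensus branch gets
the arithmetic mean of the matching branch over the chunk trees that
contain its split (terminal branches over all trees).

# The scan and its filters

A gene family is tested only if at least one species from the sister
clade of the foreground branch is present — otherwise selection cannot be
localized to the tested branch rather than an earlier lineage.  On an
unrooted tree "the sister" is rooting-dependent; the package uses the
smallest subtree adjacent to the outer endpoint of the foreground edge,
which gives chimp for the human branch and macaque for the
human/chimp/gorilla ancestor on the default mammalian topology, matching
the rooted intuition whenever the implied root lies in the larger
remainder.

Candidates must survive four plausibility filters (all thresholds
configurable): (i) at least 50 retained codon columns **and** 20% of the
anchor codons, (ii) at least 3 sequences, (iii) foreground
$\hat\omega_2 < 100$ (disproportionate ratios indicate alignment
artifacts, not biology), (iv) no implausibly broad selection signal
(estimated $p_{2a}+p_{2b} \le 0.8$ and at most 60% of sites with
posterior $> 0.5$).  Only the $\ge 100$ cap is a published number; the
others are this package's defaults.  A PSG candidate is a gene with
nominal $p \le \alpha$ ($0.05$) and **no** flags; Bonferroni and
Benjamini-Hochberg adjusted p-values are always reported alongside.

# The simulator

Gene families evolve along the species tree by exact Gillespie
simulation.  Site-wise selection follows a discrete baseline
distribution: 20 equiprobable atoms, log-spaced across $(0.001, 1]$ and
power-rescaled so the mean is 0.21222 with no atom above 1 (a power
transform keeps the support inside $(0,1]$, which a multiplicative
rescale would not).  Scheme N is this baseline everywhere.  Schemes A-E
flag 1/3/5/7/9% of sites as selected; on the tested branch those sites
evolve at $\omega_+$ solving
$(1-f)\,\bar\omega_{\text{base}} + f\,\omega_+ = 0.9$
(for scheme A, $\omega_+ = 68.99$).  Selected flags are drawn at site
creation; they matter only on the tested branch.

Indels are frame-preserving, geometric in codon units with $q = 0.35$
(mean 1.54, SD 0.91 codons), occur at 1/43 of the substitution event
rate (an event-rate reading of the published substitution:indel ratio),
split 1:1 insertion:deletion, insert content from $\pi$ at uniform
positions, and never delete the whole sequence.  Site homology across
the tree is tracked by fractional position keys, so the true alignment
and per-site true annotations are available to validation code without
a separate homology reconstruction.

Each branch's generator is normalized so one time unit is one expected
substitution per codon *under that branch's scheme*; configured tree
lengths are expected substitutions per codon and are multiplied by
`branch_scale = 3` inside the simulator, mirroring the branch-length
convention conversion the original validation describes for its
sequence simulator.

## The default world, and what a green test establishes

Defaults are fixed once: $\kappa = 2$; root length 400 codons; uniform
codon frequencies (the original validation used the codon frequencies of
a single globin gene, which are not printed anywhere; any 61-vector can
be supplied via `pi`); and a nine-taxon mammalian topology
(((((human,chimp),gorilla),macaque), (mouse,rat), ((dog,cat),cattle))
with literature-plausible per-codon branch lengths (human terminal 0.020
substitutions/codon).  The published figure shows its tree to scale but
the lengths are not machine-readable, so these values are this package's
choice — the single largest uncertainty when comparing simulated
sensitivity numbers against the published table, since branch-site power
is steep in foreground branch length.

The simulator emulates: site-wise rate variation with episodic positive
selection, indel length and rate statistics of mammalian coding regions,
and stationary base composition.  It does **not** emulate paralogy,
annotation errors, sequencing errors, alignment uncertainty of real
genomes, GC-biased gene conversion, or CpG hypermutability.  A green
validation therefore establishes that the pipeline controls false
positives and detects concentrated selection *under the model's own
assumptions* — it does not certify performance on real genomes, where
alignment quality dominates.

At desk scale (200 no-selection families, 200-codon roots) the scan's
false-positive fraction at nominal $p \le 0.05$ is ~0-1%, consistent
with the published sub-1% rate; sensitivity is highest for the most
concentrated scheme and decreases as the same total selection pressure
is spread over more sites.  Strict monotonicity across all five schemes
at 100 replicates each is fragile even in the ideal case: adjacent
published rates differ by less than one sampling standard deviation, so
a single adjacent inversion in a fixed-seed run is expected binomial
noise.

# Numerical choices and degenerate inputs

* Transition matrices are clamped at 0 elementwise after
  eigendecomposition (rounding can produce $-10^{-18}$).
* Codons containing N, and gap codons, are missing data: partial
  likelihood 1 over all 61 states.  Other ambiguity codes reject the
  record; internal stops invalidate a transcript (unrecognized
  pseudogenes are a classic false-positive source); trailing stops and
  partial codons are trimmed.
* A zero-total-length tree with non-identical sequences has likelihood
  zero; the log-likelihood is reported as `-Inf` and the gene is flagged
  rather than aborting the scan.
* Ties are broken deterministically everywhere (lexicographic ids for
  best hits and isoform choice; lowest anchor similarity, then species
  name, in divergence filtering; first-enumerated topology in exhaustive
  parsimony), so a fixed seed reproduces results byte-for-byte.
* F3x4 frequencies carry a 0.5 pseudocount per nucleotide per position
  to avoid zero stationary probabilities on short alignments.

# Known limitations

* The internal progressive aligner is quadratic in sequence length and
  not phylogeny-aware; for real data, plugging a dedicated aligner into
  the `codon_align` adapter is recommended.  Misalignment is the main
  false-positive channel the filters exist to suppress.
* NEB (not BEB) site identification: posteriors ignore parameter
  uncertainty and are anticonservative on short alignments; the
  candidate-level test does not share this issue.
* The $\chi^2_1$ reference is conservative near the $\omega_2 = 1$
  boundary.
* Parsimony branch lengths undercount multiple hits on long branches;
  the consensus tree is meant for topology and rough scale, while
  model-based lengths come from the M0 machinery.
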