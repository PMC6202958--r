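---
title: "Quantifying phototrophy marker genes: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying phototrophy marker genes: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(photomarker)
```

## The scientific problem

Marine picoplankton harvest light through two very different machineries:
chlorophyll-based photosystems (oxygenic photosynthesis, marked by *psaA*;
aerobic anoxygenic photosynthesis, marked by *pufM*) and the single-protein
retinal pump proteorhodopsin (PR). Comparing how *common* each mechanism is
(metagenome) with how *expressed* it is (metatranscriptome) requires four
estimators that this package implements end to end:

1. **recA-normalized gene abundance.** Reads recruited to a marker gene,
   divided by the profile length, relative to the same quantity for the
   near-universal single-copy gene *recA*:
   `(funcAbun / funcLen) / (RecAAbun / RecALen)`. The result reads as "the
   fraction of genomes carrying the marker" and may legitimately exceed 1
   (multi-copy genes, co-occurring variants), so it is never clipped.
2. **RNA:DNA expression ratio.** A marker's relative abundance in the RNA
   library over its relative abundance in the DNA library — a
   depth-independent proxy for expression per gene copy.
3. **Cluster composition and evenness.** PR reads are assigned to
   reference-tree leaves, aggregated to clusters (SAR11,
   Gammaproteobacteria, other Alphaproteobacteria, environmental clades,
   viral, archaeal, other), and summarized by Pielou evenness
   `J = H / ln S` (natural log, as in vegan).
4. **Spectral tuning.** The residue at PR's frequency-tuning site (FTS)
   classifies each read as blue-absorbing (glutamine), green-absorbing
   (leucine or methionine) or other; other residues are rare and excluded
   from the blue fraction. Below a chlorophyll-*a* threshold of
   0.25 µg L⁻¹ the blue fraction tracks `ln(Chl-a)` linearly, and
   `fit_tuning_trend()` fits exactly that stratified model.

## Recruitment model

Short reads are translated in six frames under the standard genetic code,
split at stop codons (codons containing `N` translate to `X`), and
fragments of at least 15 residues proceed. The homology search is a
two-stage design mirroring the classic translated-search-then-profile
protocol:

* **Candidate screen.** A fragment survives for a marker iff it shares at
  least one exact amino-acid 4-mer with any reference peptide. The screen
  exists to bound runtime, not to decide membership.
* **Profile alignment.** Each surviving fragment is aligned locally to a
  position-specific scoring profile built from the marker's curated
  reference alignment. Match columns are alignment columns with gap
  fraction below 0.5; scores are per-column log-odds in bits,
  `log2(((count + pc * bg_r) / (n + pc)) / bg_r)` with a Laplace-style
  pseudocount (`pc = 1` by default). Gaps are affine — a gap of length *g*
  costs `4 + (g - 1) * 1` bits — and alignments may not start or end in a
  gap. `X` residues score 0 bits anywhere. The implementation is an Rcpp
  dynamic program; the test suite checks it cell-for-cell against an
  exhaustive enumeration of all local alignments on small instances.

A full profile HMM would add insert/delete state transitions estimated
from the alignment; the log-odds matrix with affine gaps keeps every
number in the model auditable and lets the brute-force oracle verify the
optimization exactly, which we valued more than Plan7 fidelity.

### Score cutoffs

Tool-specific e-values do not transfer between implementations, so the
recruitment threshold is calibrated empirically: `calibrate_cutoff()`
scores random peptides drawn from the profile's background distribution
and takes the empirical `1 - target_fpr` quantile, floored at 10 bits.
Two choices matter:

* **Background.** For profiles that screen six-frame translations of
  partially non-coding DNA, the correct null composition is not uniform:
  translating uniform random nucleotides yields residues in proportion to
  their synonymous-codon multiplicities (leucine at 6/61, methionine at
  1/61, ...). `aa_background("codon")` provides this distribution and the
  pipeline builds its profiles against it; with a uniform background the
  decoys are systematically easier than real translated background and
  the realized false-positive rate exceeds its target several-fold (we
  measured roughly 8x on simulated libraries).
* **Multiplicity.** A read offers up to six frames times four markers of
  recruitment chances. `calibrate_cutoffs()` therefore interprets
  `target_fpr` per *read* and calibrates each profile at the
  Bonferroni-corrected per-comparison rate, using decoys of the full
  translated read length (the hardest case). On 50,000-read pure
  background libraries this realizes about 4 x 10⁻⁴ recruited fraction at
  a 10⁻³ target — conservative, as intended for abundance work where
  false positives inflate rare markers.

Each read is assigned to at most one marker: the best-scoring
(marker, frame) pair, ties broken by marker order PR < psaA < pufM < recA
and then lower frame, counted only if it reaches the winning marker's
cutoff.

## Leaf placement

Maximum-likelihood placement tools report positions on internal edges as
well as leaves; the analyses here only ever use leaf-level assignments.
`assign_leaves()` therefore implements the equivalent decision directly:
identity to every leaf over the profile match columns inside the read's
aligned span (gap against residue counts as a mismatch; double gaps are
skipped), requiring at least 20 compared columns and an identity margin of
at least 0.01 over the runner-up. Anything more ambiguous is UNPLACED —
the analogue of discarding internal-node placements. On error-free
simulated reads this rule recovers the true leaf whenever the margin is
positive.

## The synthetic community generator

Real libraries from the study region are deep-sequenced and not
redistributable at package scale, so every estimator is validated against
a generator with known truth. A `community_spec` fixes, per taxon:
relative genome abundance, marker gene complement, gene lengths,
expression multipliers (RNA copies per gene copy, recA = 1), a PR cluster
label, and a tuning-site residue. `generate_reference_set()` mutates one
random ancestor protein per marker at a configurable divergence
(default 0.1), forces the FTS residue, back-translates with uniform
synonymous codons, and builds the PR tree by single-linkage on protein
identity.

Reads are sampled as a multinomial: background (random uniform
nucleotides) with probability `background_fraction`, otherwise source
gene (taxon, marker) with probability proportional to
`abundance x length` (DNA) or `abundance x length x multiplier` (RNA) —
the sampling law of uniform shotgun coverage over equal-size genomes.
This joint weighting (rather than "pick a taxon, then one of its genes")
is what makes the recA-normalized estimator and the RNA:DNA ratios
consistent with `truth_summary()`'s closed-form expectations regardless
of how unevenly gene complements are distributed across taxa. Substitution
errors are independent per base; strands are random; with a fixed seed
every file is bit-identical.

Defaults represent the study conditions the estimators face: 150 bp
single-end reads (only forward reads are placed; merging is out of
scope), 0.5% substitution error, 80% non-marker background so that
specificity is genuinely exercised, divergence 0.1 between reference
variants. `example_community()` encodes the survey-scale scenario — PR in
90% of genomes, psaA 20%, pufM 10%, expression multipliers averaging
26.2 / 11 / 0.013 relative to recA, SAR11 at 52% of PR transcripts, and a
63.3% blue tuning-site fraction — used by the acceptance script and the
recovery tests.

What the generator deliberately does not emulate: real phylogenetic
structure (mutations are i.i.d. across sites, so placement is easier than
on natural trees with rate variation), indels (reference alignments are
gapless, so the gap machinery is exercised only by alignment noise),
paired-end reads, quality scores, chimeras and contamination. Passing
recovery tests therefore demonstrates correctness of the estimators under
the stated sampling model, not robustness to every artifact of real
libraries.

## Statistical layer

Evenness comparisons between gene abundance and expression within samples
use the one-sided paired *t*-test and the one-sided paired Wilcoxon
signed-rank test (exact null for up to 25 untied differences, normal
approximation with continuity correction beyond; zero differences are
dropped by convention). Environmental correlations use Spearman's rank
correlation with Benjamini–Hochberg q-values computed over whatever pair
family the user declares — the package does not guess which variable
family belongs in one correction. The tuning trend is ordinary least
squares of the blue fraction on `ln(Chl-a)` restricted to samples below
`tau = 0.25` µg L⁻¹; samples at or above the threshold form an unmodeled
stratum summarized by their mean blue fraction. The model is fitted on
the fraction scale; percentages are presentation only.

## Numerical and interface choices

* Residues are ordered `ACDEFGHIKLMNPQRSTVWY` everywhere; profiles store
  an `L_func x 20` matrix of doubles in bits.
* Reference rows shorter than 200 ungapped residues are dropped on load,
  mirroring ORF curation; the threshold is a parameter because test
  fixtures are legitimately tiny.
* The tuning-site coordinate is supplied as an anchor (sequence id plus
  ungapped position) because numbering conventions differ between PR
  references; the simulator places it at residue 105 of a 250-residue PR
  by default, the canonical tuning-site numbering.
* Ties in recruitment and placement are broken deterministically; every
  stochastic step takes an explicit seed and derived child seeds stay
  within 32-bit integer range, so reruns are bit-identical.
* Degenerate inputs are flagged, not thrown: zero recA counts give `NA`
  abundance, a missing DNA library flags the ratio undefined, evenness is
  undefined for a single occupied cluster, constant differences flag the
  paired tests degenerate.

## Problem sizes used in validation

The recovery tests run the generator at 50,000 reads per library for
abundance and expression (10 and 20 seeds respectively), 12,000-read
libraries for tuning (20 seeds, 1,000 tuning-site reads each), 16,000
reads for placement (5,000+ placed), and 2,500-read libraries for the
end-to-end determinism check; the alignment oracle grid covers several
hundred exhaustive instances up to 8 columns x 12 residues. These sizes
hold the binomial standard errors of every recovered quantity a factor of
two or more inside the stated tolerance bands.

## Known limitations

* The RNA:DNA ratio of a transcript rarer than the false-recruitment
  floor (here pufM, expected well below one read per library at the
  study's expression levels) is reported honestly but is dominated by
  that floor; interpret ratios only for markers with tens of recruited
  reads or more.
* The profile model has no position-specific gap penalties and no
  insert-state emissions; highly gappy reference alignments will recruit
  less sensitively than a full profile HMM.
* Placement identity is computed on match columns only; reads dominated
  by insertions relative to the reference carry little placement signal
  and end UNPLACED.
* The trend model assumes the declared threshold; it does not estimate a
  change point.
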