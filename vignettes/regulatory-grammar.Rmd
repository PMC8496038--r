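---
title: "Occupancy calculus and sequence models of regulatory-element grammar"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Occupancy calculus and sequence models of regulatory-element grammar}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(regspec)
```

## The question

Mammalian genomes carry on the order of a million candidate regulatory
elements, of which roughly 1–2% (100,000–200,000 sites) are active in any
one cell type. Two extreme mechanisms could explain how transcription
factors (TFs) recognize these elements:

* **billboard**: only the *collection* of TF binding sites (TFBSs) in a
  window matters, not their relative geometry;
* **SAOC** (spacing-and-orientation constraint, the "enhanceosome" picture):
  TFs bind as rigid multimeric assemblies whose composite site has fixed
  internal spacing and orientation.

`regspec` implements a desk-scale test bench for asking whether either
regime is compatible with five global properties of regulatory sequence —
length, uniqueness, frequency, evolutionary turnover, and master-regulator
dominance — using closed-form occupancy combinatorics, multimeric-motif
construction, an exact PWM scanner, a hit-count logistic-regression
classifier, and neutral-mutation turnover simulations, all driven by a
seeded synthetic-data generator with known ground truth.

## The occupancy calculus

For `n` TFs (human scale: 1600), a pairwise cooperativity rate `c` (0.03,
the observed fraction of TF pairs with preferred spacing/orientation in
CAP-SELEX style data), and a genome of `G` bp:

* possible k-TF composite motifs: `n` for k = 1, else `n^k / 2` (ordered
  sequences collapsed for reverse-complement symmetry);
* the fraction whose k−1 junctions all cooperate: `c^(k-1)`;
* expected hits of one motif in the genome: `G * 4^-L_eff(k)`, where the
  effective length `L_eff = IC/2` converts information content into
  base-pair equivalents (defaults 6, 8, 12.25, 16.25, 21, 25.5 bp for
  arities 1–6);
* expected total hits: the product of the three quantities above.

```{r}
table2()
```

Two printed reference cells are known rounding anomalies of the source
(3-TF possible combinations and 6-TF total hits), and the 5-TF expected
motif count rounds to 4.2e9 where 4.3e9 was printed; the acceptance tests
compare at 2.5% relative tolerance accordingly.

Uniqueness of regulatory sequence under strict SAOC requires the motif
repertoire to exceed the 1–3 million distinct regulatory sites per genome;
with defaults that happens at arity 4:

```{r}
uniqueness_arity(occupancy_params(), n_regulatory = 3e6)
```

## The Poisson specificity framework

Treating each active TF as hitting a 200-bp window independently with
probability 1/20, the number of TFBSs in a window is Poisson with
`lambda = n_active / 20`. A regulatory element needs enough co-occurring
sites that the genome-wide positive rate stays within the observed ~0.5–3%:

```{r}
sapply(c(10, 50, 100), min_sites_for_specificity)
```

A deliberate numerical choice: the per-TF window hit probability defaults to
the rounded constant 1/20 *exactly*, not the derivation `200/4096 = 0.0488`
(exposed as `site_hit_probability()`). The two differ enough to shift the
100-TF answer from 11 to 10 sites; the framework's published numbers use
1/20. Master-regulator variants multiply the tail by the Poisson PMF of
exactly one master hit (`mr_adjusted_probability()`), and
`mr_constrained_combinations()` counts composite motifs containing at least
one of `m` designated masters as `(n^k - (n-m)^k)/2`.

The feasibility scan asks how many expressed TFs make the expected
genome-wide 4-TF multimer hit count land in the 30,000–200,000 band of
active sites per cell type:

```{r}
tf_count_for_target_sites(4, step = 100)
```

We use the 30,000–200,000 band (the figure-caption band) rather than the
100,000–200,000 quoted in running text, because only the former reproduces
the published ~300-TF answer under the reconstructed combinatorics.

## Multimeric motif construction

3-TF motifs are built from two dimers sharing a member (A-B plus C-B); the
shared member must be palindromic in both, because chaining requires
reverse-complementing one dimer so the non-shared members extend on
opposite sides. The two matrices are superimposed on the shared site and
averaged per base, per position over the overlap; non-overlapping columns
pass through. Extension to arities 4–6 repeats the step against a terminal
member.

One design departure worth knowing about: we do *not* choose the merge
orientation by a blind full-matrix best-scoring alignment. For dimers with
uniform gap columns, the spurious full-length overlap (gap-on-gap plus
shared-on-shared) can tie or beat the correct shared-site overlap, and the
original procedure resolved orientation manually. We instead use the dimer
annotations' half-spans to place the shared member's halves on each other
(fine offset still chosen by `align_pfms`, the ungapped column-Pearson
alignment with exhaustive offset search), and orient the incoming dimer so
its new member extends outward. Uniform (zero-variance) column pairs score
1 against each other and 0 against informative columns.

## The exact scanner

`threshold_from_pvalue()` discretizes log-odds scores to an integer grid
(default 1000 bins per bit, applied per cell) and convolves the per-column
score distributions under the i.i.d. background — the resulting threshold
is the *exact* quantile of the discretized word-score distribution, and
scanning compares the same integer scores, so the DP and the scanner agree
by construction (verified against brute-force 4^L enumeration in the test
suite). Scanning is a naive full column-sum at every position on both
strands; no lookahead or filtration heuristics. Ambiguous bases score
effectively minus infinity. A plus and a minus hit at the same interval of
a palindromic motif are both counted.

## Classifier pipeline

Hit counts (p = 1e-4 thresholds) per motif are z-scored and fed to a
logistic regression. The sklearn-default L2 model maps to
`glmnet(alpha = 0, lambda = 1/(n*C))` with C = 1; recursive feature
elimination drops the lowest-|weight| 10% per round to an exact feature
count; lasso and elastic-net selection use the published strengths
(C = 0.00125 and C = 0.0007 with l1_ratio 0.5). Evaluation holds out whole
chromosomes (16 train / 7 test) so sequence-composition leakage across
splits is structurally impossible. `calibrate_threshold()` converts window
score tracks into a decision threshold achieving a ~1% genome positive
rate, mirroring how published intrinsic thresholds were tightened before
turnover simulations.

## Turnover simulations

`mutate_sequence()` substitutes each base independently at the neutral rate
(6% human/macaque, 49% human/mouse), drawing replacements uniformly from
the three alternatives. `classifier_dropout()` re-scores mutated elements
against the calibrated threshold. `multimer_turnover()` scans a streamed
random corpus (default 100 Mb — the desk-scale stand-in for a 32-Gb
genome-sized sequence source) for multimer hits at p cutoffs 1e-11, 1e-10,
1e-9, then mutates each hit locus plus a one-motif-length flank and
rescans that window at the same threshold. Mutating only the hit locus is
equivalent to mutating the whole corpus for retention purposes and keeps
the computation tractable; a mutated window is scored as retained if any
position in it still meets the threshold, on either strand. Strata with no
pre-mutation hits are reported as NA rather than zero. Very stringent
cutoffs can be genuinely unattainable for motifs with many uninformative
(gap) columns — the best word's tail probability is then larger than the
cutoff — and such strata are naturally empty.

## The synthetic world and what a green test establishes

`make_monomer_catalog()` draws near-consensus PFMs whose dominant-base
probability is solved from the IC target (12 bits, the catalog-scale
median), with per-column jitter and unevenly split minor probabilities so
word-score distributions are dense. The default monomer length is 8 bp: a
6-bp motif cannot attain a p = 1e-4 threshold at all (its single best word
has probability 4^-6 ≈ 2.4e-4), while the IC target keeps the *effective*
length at 6 bp as in the occupancy table. `make_dimer_catalog()` joins
floor(0.03 × n_pairs) random pairs with 0–4 bp gaps and random half
orientations; a configurable fraction of participating TFs is palindromized
(mirror-image halves), and palindromy flags are *measured* from the
matrices, so accidental palindromes count. The turnover acceptance run
raises the palindrome fraction to 0.5 and uses 80 TFs so that legal 4-6-TF
chains exist in a catalog ~6x smaller than the experimental dimer set; this
choice affects only how many multimers are available to scan, not the
retention statistics being tested.

Positives implant either sampled monomer sites at random non-overlapping
positions/strands (billboard) or one sampled multimer instance (saoc);
negatives are GC-matched i.i.d. background. What the generator does *not*
emulate: repeat elements and repeat-fraction matching (real null-set
construction matches them), dinucleotide composition, peak-shape signal,
and low-affinity/cooperative binding energetics. A green end-to-end test
therefore establishes that the pipeline recovers planted structure at
realistic sizes and noise — not that it would achieve any particular AUROC
on real open-chromatin data.

## Reproducibility and limits

Every stochastic step takes an explicit seed (`withr::with_seed`), and
identical inputs give byte-identical reports. Known limitations: ungapped
PFM alignment only; a single best spacing per dimer pair (experimental
data show multiple spacings are common); no transition/transversion or CpG
effects in the mutation model; and the 100 Mb corpus leaves the two most
stringent scan cutoffs with few or no hits, exactly as expected from their
per-position probabilities.
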