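---
title: "Comparative codon-preference analysis: models and methods"
author: "codonpref"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative codon-preference analysis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(codonpref)
```

## The scientific question

Organisms living under extreme temperature, pH, salinity or pressure bias
their synonymous codon choice relative to mesophilic relatives: thermophiles
and barophiles over-use AGG (arginine, whose surface salt bridges stabilise
proteins), psychrophiles and mesophiles over-use CAA (glutamine, a
thermolabile residue), halophiles over-use GAC (aspartate, driving acidic
surface charge). `codonpref` quantifies such preferences from paired
homologous coding sequences (CDS): each extremophilic CDS is matched with a
non-extremophilic homolog, and per-codon usage is compared across the N
pairs of a comparing dataset (conventionally labelled T-M, P-M, T-P, A-B,
H-Nh, B-Nb for the six extremophile classes against their counterparts).

## Feature representation

Every CDS is cleaned (uppercased, RNA U→T, frame-0 triplets, trailing
partial codon dropped, ambiguous codons excluded by default or rejected in
strict mode) and reduced to a 64-dimensional percentage vector over the
canonical alphabetical codon ordering (AAA … TTT). Stop codons are counted
as ordinary features and included in the percentage denominator: stop-codon
usage differs between classes in published comparisons, and excluding stops
would silently rescale all other percentages. A paired dataset is then two
N × 64 matrices whose i-th rows describe the two members of pair i.

## Significance filtering

Each codon is screened with the two-sample Kolmogorov–Smirnov test on its N
extremophile percentages versus the N counterpart percentages; codons with
p < 0.05 (no multiple-testing correction, to match the screening character
of the procedure; a Benjamini–Hochberg option exists but is off by default)
form the significant set used by every downstream stage.

Two numerical choices matter here.

* **Exact rather than asymptotic p-values.** Codon percentages are counts
  on a lattice of 1/(gene length), so the samples are heavily tied. The
  asymptotic two-sample KS p-value is severely conservative under these
  ties — at N = 100 pairs of 300-codon genes its measured type-I rate is
  below 0.01 at a nominal 0.05, which would cripple the filter's power.
  The package therefore defaults to the exact method (permutation-exact in
  the presence of ties) whenever the product of the two sample sizes is at
  most 40 000 (up to 200 vs 200), falling back to the asymptotic
  approximation beyond that.
* **Unpaired testing of paired data.** The KS test compares two samples
  without using the pairing. Because the two members of a homologous pair
  share an amino-acid composition, the two samples are positively
  correlated and the unpaired test is conservative; single-codon families
  (ATG, TGG) are byte-identical across classes and can never be flagged.
  In null simulations the realised per-codon false-positive rate is about
  0.017 at α = 0.05 rather than 0.05. This conservatism is a property of
  the design, not a defect; users should read the filter as a screening
  step whose effective level is below its nominal one.

Degenerate codons (identical values in both samples, e.g. a codon absent
everywhere) receive D = 0, p = 1 rather than an error.

## Relative abundance

For each significant codon the class means over the N pairs,
$\bar\alpha_e$ and $\bar\alpha_{ne}$, are plain arithmetic means of the
per-CDS percentages. Their difference $\alpha_j$ is normalised by the
maximum **absolute** difference over the significant set:

$$\beta_{rel} = \frac{\bar\alpha_e - \bar\alpha_{ne}}{\max_j |\alpha_j|}$$

so that $\beta_{rel} \in [-1, 1]$ and its sign always tracks the direction
of preference. The literal signed maximum (normalising by
$\max_j \alpha_j$) is available via `alpha_max = "signed"`; it leaves
$\beta_{rel}$ unbounded below whenever differences of both signs occur,
which is why it is not the default. Codons with $\beta_{rel} > 0$ strictly
are the *positive contributors* — the extremophile-preferred codons used by
the composition and harmony stages.

## The 1–9 preference scale

Each significant codon's *ratio weight* is
$\xi_i = \bar\alpha_e / \bar\alpha_{ne}$, min–max scaled onto the 1–9
interval:

$$W_i = \frac{\xi_i - \min_j \xi_j}{\max_j \xi_j - \min_j \xi_j} \times 8 + 1$$

Integer ranks are `W` rounded half-up, so the most preferred codon is
always rank 9 and the least rank 1. Edge cases are handled explicitly: a
zero counterpart mean gets a pseudocount of half the smallest non-zero
class mean in the table (flagged in the output); if every ratio weight is
equal, all codons get mid-scale rank 5 with a warning; exact ties at the
scale extremes are broken lexicographically on the codon string so
`extreme_codons()` is deterministic.

```{r rank-demo}
rank_codons(c(CAA = 0.5, ACC = 1.0, AGG = 1.5))
```

## Composition and harmony

A codon is *AT-rich* when at least two of its three bases are A or T, and
*GC-rich* otherwise; its *ending* label is decided solely by the wobble
(third) base. The two label families each split the 64 codons 32/32.
`composition_summary()` reports the label percentages over a preferred
set; `harmony_table()` crosses the preferred sets of up to six extremophile
classes into a 64-row membership matrix with per-codon shared counts and
the set of codons preferred by no class. Harmony membership is defined by
abundance positivity alone (ranking is not additionally required); that
choice is an interpretation of a procedure whose exact derivation is
underdetermined, and is recorded here.

## Machine-learning stages

The feature table pools both classes (2N rows) over the significant-codon
percentages.

**Attribute weighting.** Seven algorithms weight each codon's
discriminative value: chi-squared statistic (on 5 equal-frequency bins —
the discretisation any binned criterion uses here), information gain, gain
ratio, Gini-impurity reduction, absolute Pearson correlation, symmetric
uncertainty, and Relief (one nearest hit and miss per instance,
range-normalised features, negative relevances clipped to zero so constant
or worse-than-chance features score 0). Each algorithm's weights are
min–max normalised across codons to [0, 1] — normalisation is
per-algorithm, so "weight ≥ 0.5" counts in `support_counts()` compare like
with like. Plug-in weighters are accepted as plain functions.

**Classification.** `train_eval()` makes a stratified 70/30 train/test
split (the fraction is configurable; the seed is explicit and propagated to
every stochastic fit) and reports held-out accuracy for k-NN (default
k = 10), naive Bayes, logistic regression, a single decision tree, random
forest, and optional SVM and feed-forward network backends. Trees accept
four split criteria: information gain and Gini (native `rpart`), plus gain
ratio and accuracy implemented as user-written `rpart` split functions.
The random forest splits on Gini regardless of the requested criterion (a
warning says so).

**Rule extraction.** Every root-to-leaf path of the fitted tree becomes an
ordered rule of threshold conditions, rendered as e.g.

```
If % GAC (>8.861] → Halophile
If % GAC (≤8.861] and % AGG (>1.441] → Non-halophile
```

Thresholds are printed with three decimals; the half-open semantics are
strict `>` versus `≤`. A single-leaf tree yields an empty rule list with a
warning.

## The synthetic generator

Real curated extremophile/counterpart collections are not redistributable,
so validation uses a generator that emulates their operative property:
*homologous* pairs are two CDS encoding the identical amino-acid sequence
with class-specific synonymous-codon choice. Amino acids are drawn i.i.d.
from a profile (default uniform over the 20), each position's codon is
sampled independently from the class's within-family probability vector
(default uniform within each family), and one stop codon is appended by
default. Known biases are injected by moving `delta` of within-family mass
onto a target codon, renormalising its siblings proportionally; moves that
leave the probability simplex raise an error rather than clipping. The
generator exposes the closed-form expected percentage of every codon
(family probability × amino-acid frequency × sense-codon fraction), which
the tests use as ground truth.

The defaults encode the study conditions used throughout the test suite:
100–200 pairs of 300-codon genes and within-family shifts of
`delta = 0.3` (e.g. AGG enriched and CAA depleted in a thermophile-like
class); these sizes match the published comparisons (40–116 pairs) while
keeping the full suite within a few minutes on one CPU.

What the generator deliberately does **not** model: amino-acid divergence
between pair members (real homologs differ), positional autocorrelation and
dinucleotide effects, genome-wide GC gradients, and gene-length variation.
Passing recovery tests therefore show that the pipeline detects known
within-family usage shifts in idealised homologous pairs — not that it is
robust to alignment error, compositional confounding or phylogenetic
non-independence in real data.

Two structural consequences of the identical-protein design are worth
knowing. First, the two class samples share amino-acid counts, which makes
the unpaired KS filter conservative (measured ≈ 0.017 per-codon false-positive
rate at nominal 0.05). Second, in a two-codon family a "single" codon bias
necessarily shifts the sibling codon by the same amount in the opposite
direction, so sibling features are equally informative — recovery tests for
a uniquely most-shifted codon use a six-codon family (Arg/AGG) for that
reason. Threshold-location checks are also granular: with 300-codon genes,
percentages live on a 1/301 lattice, so a fitted tree threshold can only
fall on half-integer-count midpoints ~0.33 % apart.

## Reproducibility

Every stochastic stage takes an explicit seed; `run_all()` propagates one
global seed, and the same configuration, inputs and seed reproduce every
artifact byte-for-byte. Stage outputs are plain TSV/JSON carrying codon
names, so any downstream stage can be re-run from the files alone.

## Known limitations

* The significance filter's effective level is below nominal on paired
  data (see above); a paired test variant is intentionally out of scope.
* Ratio weights are undefined for codons absent from the counterpart
  class; the pseudocount fallback is ad hoc and flagged in the output.
* The attribute-weighting normalisation is per-algorithm min–max, so
  weights are comparable within an algorithm but only ordinal across
  algorithms.
* Rule thresholds inherit the percentage lattice of the gene length and
  should be read with that granularity in mind.
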