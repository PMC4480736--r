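---
title: "Methods: naive-Bayes PPI prediction and apoptotic hub discovery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: naive-Bayes PPI prediction and apoptotic hub discovery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(apoppi)
```

## The model

`apoppi` treats protein–protein interaction prediction as binary
classification of unordered protein pairs. Four evidence channels feed the
classifier:

* **Co-expression** — the Pearson correlation of the two genes' expression
  profiles, pooled over all samples of both conditions. The estimator is
  the standard product-moment form,
  $\rho = \sum_i (x_i-\bar x)(y_i-\bar y) / ((n-1)\, s_x s_y)$ with sample
  standard deviations, i.e. `stats::cor()`.
* **Domain–domain interaction (DDI)** — the maximum curated confidence
  grade over all cross-products of the two proteins' domain sets.
* **Interologs** — the number of distinct model organisms in which an
  ortholog pair of the two proteins interacts.
* **Smallest shared biological process (SSBP)** — over all process terms
  annotating both proteins, the assigned-protein count of the smallest;
  small, specific shared processes are stronger evidence than large,
  general ones.

Each channel is discretized into bins, and per-bin likelihood ratios
$LR(E_i) = P(\text{bin} \mid \text{interacting}) /
P(\text{bin} \mid \text{non-interacting})$ are estimated from the gold
standards. Under the naive-Bayes assumption that channels are conditionally
independent given interaction status, the composite likelihood ratio is the
product of the per-channel ratios, and posterior odds are prior odds times
that product. The prior odds are a constant across pairs, so ranking and
thresholding happen on the composite LR; `prior_odds` (default 1) is
carried separately and never folded into the reported LRs.

**Gold standards.** The positive set is the canonical, deduplicated union
of curated interaction tables; symmetric duplicates collapse and self-pairs
are dropped. The negative set is every pair of a plasma-membrane-only
protein with a nucleus-only protein, minus pairs already curated positive.
Proteins annotated to both compartments are excluded from both sides: the
negative set's rationale (the two partners cannot be co-localized) does not
hold for dual-localized proteins. Other localizations contribute to
neither side — a deliberately conservative choice.

**Missing versus informative absence.** The scorers distinguish an
*unmeasurable* channel (a protein without domain annotation, without any
ortholog, without process annotation, or a zero-variance expression
profile) from an *informative absence* (domains present but no curated
domain pair; orthologs present but no model-organism interaction; both
proteins annotated but no shared term). Informative absences get their own
bins — DDI level 0, interolog support 0, the "no shared term" SSBP bin —
and thus their own (typically < 1) likelihood ratios, because the absence
of curated support is itself evidence. Missing channels contribute a
factor of 1 and are excluded from that channel's gold-standard
denominators.

## Binning and estimation choices

No bin counts or edges are prescribed by the underlying procedure ("each
dataset could be divided into several bins due to their intrinsic
characters"), so the schemes are chosen per channel and kept configurable:

* co-expression: 10 equal-width bins over $[-1, 1]$;
* DDI: one bin per confidence grade plus the level-0 bin;
* interolog: one bin per support count $0..n_\text{species}$;
* SSBP: log2-spaced size bins ($[2]$, $[3,4]$, $[5,8]$, ...) plus the
  "none" bin.

Schemes are built once from the full candidate universe and re-applied to
the gold subsets, so every bin a scored pair can fall into exists in the
likelihood table (bins with zero gold counts get pseudocount-only
estimates). Estimation uses a Laplace-style pseudocount of 0.5 per bin:
$P(\text{bin}\mid\text{pos}) = (n_\text{bin} + c)/(N + Bc)$ with $B$ the
bin count. The pseudocount keeps every LR finite and positive when a bin
has zero counts in one class, which otherwise produces infinite or zero
products; 0.5 (Jeffreys-style) perturbs well-populated bins negligibly.

The scored universe is every pair of the protein roster with at least one
non-missing channel; since co-expression is computable for every profiled
gene pair, this is in practice the full quadratic universe — feasible at
the package's desk scale (hundreds to a few thousand proteins).

**Network assembly.** The predicted set at a cutoff uses a closed threshold
(`lr_combined >= cutoff`): the cutoff is an indicator of bearing the
functional relation, so ties are included. The final network is the union
of the prediction set and the full positive set, with provenance
(`predicted` / `gold_positive` / `both`) marking each edge. The historical
operating point LR = 117 is the default cutoff, but since no selection
procedure for it is documented, the package treats it as configurable and
provides two diagnostics instead of guessing: the TP/FP-ratio-versus-cutoff
curve and F1-maximizing selection on a validation split
(`lr_cutoff = "auto"`).

**Evaluation.** ROC curves sweep every distinct score; AUC is trapezoidal,
which equals the tie-corrected Mann–Whitney probability that a random
positive outscores a random negative (an identity the test suite asserts to
1e-9). A fraction (default 30%) of each gold-standard set is held out from
likelihood estimation for evaluation and cutoff selection; the holdout
evaluator refuses test sets overlapping the training pairs. Labeled pairs
without a score are treated as score 0 — real classifier abstentions that
would otherwise silently inflate specificity — and their count is reported.

## Hub criteria

Hubs are proteins passing all four enabled criteria: degree ≥ 300; links to
known apoptotic proteins ≥ 300 for classical hubs (proteins inside the
apoptotic annotation set) or ≥ 200 for novel hubs (outside it); membership
in the network's dense area; and divergent expression by SAM. Two design
points were genuinely open:

* **"Dense area"** is operationalized as the k-core index — the largest
  $k$ such that the protein survives iterative deletion of nodes with
  degree < $k$. It is the standard deterministic dense-subgraph index with
  a single integer parameter; in auto mode the threshold is the 75th
  percentile of the network's core indices.
* **SAM** is implemented in its canonical two-class unpaired form:
  $d = (\bar x_2 - \bar x_1)/(s + s_0)$ with pooled standard error $s$ and
  exchangeability constant $s_0$ = median of all $s$; significance compares
  observed order statistics with their expectation over seeded label
  permutations, the delta threshold is the smallest meeting the requested
  estimated FDR (median permutation exceedances, scaled by the standard
  $\pi_0$ estimate, over observed calls), and both cutoffs and the design
  are configurable. Whether the original analysis used a paired or
  multiclass design is unstated; two-class unpaired is the default
  assumption.

The 300/300/200 thresholds refer to a 13,128-protein interactome; on
smaller networks they would be unsatisfiable (a 300-degree hub cannot exist
in a 300-node graph), so by default they are scaled by
$|V|/13128$ and rounded up, with the original values echoed in the report.
Criteria combine conjunctively — the stated purpose of using four standards
is to decrease false positives, implying intersection — and any criterion
can be disabled, which is recorded and can only grow the hub set
(anti-monotonicity is part of the test suite).

**Prioritization.** The core subnetwork is the induced subgraph on all
called hubs. Novel hubs are ranked by links to other hubs (ties broken
lexicographically and flagged). Dual-target candidates are all pairs among
the top-K ranked novel hubs (default 5), scored by exact set arithmetic on
their hub interactors with the two targets excluded from each other's sets
("links to *other* hub proteins"). Note the published overlap percentages
for the flagship kinase pair are not reproducible from the printed counts
by plain set arithmetic (67 common of 87 and 76 interactors gives
67/96 = 69.8% of the union, not 72.04%); the package therefore reports the
exact fractions and makes no attempt to match those percentages.

## What the synthetic world emulates

The generator provides a ground-truth interactome with known effect sizes
so every downstream stage is testable without downloads:

* **Topology** — preferential attachment (`attachment_edges_per_node = 3`)
  gives the heavy-tailed degree distribution the hub criteria presuppose.
  Planted hubs (3 classical inside the apoptotic set, 2 novel outside it)
  receive 80 extra edges each, 80% targeted into the apoptotic set, plus a
  clique among themselves — emulating classical apoptotic hubs and novel
  kinases with unexpectedly high apoptotic connectivity.
* **Apoptotic annotation** — 60 of 500 proteins (~12%, the prevalence of
  apoptosis annotation in a 13k proteome), exposed to the pipeline as an
  ordinary biological-process term, exactly as an analysis driven by GO
  annotation would consume it. The ground-truth sidecar (true edges,
  planted hubs, DE genes) is written for tests only and never read by the
  pipeline.
* **Co-expression** — each true edge carries a latent factor mixed into
  both endpoints' otherwise independent Gaussian profiles with weight
  `coexpr_effect` (default 0.8), normalized by the square root of the
  degree so profiles keep unit variance. Expected correlation for an edge
  is therefore $w^2/\sqrt{d_i d_j}$ — deliberately diluted for hubs, which
  is both realistic and a reason co-expression is the weakest channel.
* **DDI / interologs** — pair-level emission: a true edge gets a
  compatible domain pair with probability 0.7 (confidence skewed high)
  versus 0.02 for non-edges (skewed low); per species, a mappable true
  edge gets an interacting ortholog pair with probability 0.5 versus 0.01,
  with 80% ortholog coverage over six model organisms. Domains are private
  to each protein so these probabilities act exactly as specified, without
  cross-contamination through shared domains.
* **SSBP** — 60 background terms of 5–40 proteins create chance term
  sharing; in addition each true edge is, with probability 0.6,
  co-annotated to its own two-protein process term, emulating small,
  specific shared processes.
* **Expression contrast** — 10% of genes (always including the planted
  hubs) are shifted by 2 SD in condition 2, with 10 samples per condition;
  this drives the SAM criterion.

Two conditions with a Gaussian design are a stand-in for the original
stress-treatment arrays, not a claim about them. The generator does not
emulate real database schemas, GO's term hierarchy (terms are flat labels;
no true-path propagation), shared domains across proteins, or correlated
evidence channels — each channel draws from its own stream derived from
the master seed, so changing one effect size leaves the other channels'
draws unchanged. Consequently, passing tests demonstrate correctness and
calibration of the machinery under a favorable independence structure;
they do not certify performance on real data, where evidence channels are
correlated and coverage is biased.

A side effect worth knowing: because differential expression shifts
condition-2 means and correlation is computed over pooled samples, DE
genes are mutually correlated regardless of interaction — a realistic
stress-response artifact that slightly blunts the co-expression channel.

## Numerical and degenerate-input conventions

* Pair canonicalization is plain lexicographic ordering of identifier
  strings; self-pairs are rejected (or dropped and counted when cleaning
  curated tables).
* Zero-variance expression profiles yield `NA` correlation (missing), not
  an error.
* TP/FP ratio: `Inf` when there are true positives and no false positives,
  `NaN` when a cutoff calls nothing.
* SAM requires ≥ 2 samples per condition and warns below 25 permutations;
  with no delta meeting the target FDR it calls nothing.
* All TSV artifacts use a `#`-prefixed header, empty fields for missing
  values, and shortest round-trip decimal formatting, so emit-then-parse
  is lossless and identical seeds give byte-identical files.
* The master seed fans out into fixed per-stage streams (world generation,
  holdout split, SAM permutations), all below $2^{31}$.

## Problem sizes

The validation study runs at 500 proteins (~124,750 candidate pairs,
~1,900 true edges, ~1,600 GSP / ~17,000 GSN pairs) across five seeds;
calibration studies (chance-level and perfectly separating evidence) at
300 proteins; oracle-equivalence checks at 10–14 proteins against
brute-force reimplementations over 100 seeded fixtures. Null calibration
of the classifier is measured on pairs outside the gold standards, so the
likelihood tables are evaluated on pairs they were not fitted to;
including the training pairs inflates the null AUC by roughly 0.03 of
training optimism.

## Known limitations

* The naive independence assumption is taken as given (that is the model);
  no dependence-aware integration is attempted.
* GSN membership is localization-based and contains a small fraction of
  true interactions mislabeled negative (membrane–nucleus edges absent
  from the positive set); with pair-level evidence this attenuates but
  does not bias rankings noticeably at the simulated scale.
* Identifier harmonization across naming systems is out of scope; inputs
  are assumed pre-harmonized.
* The auto-scaled hub thresholds are permissive on very small networks
  (tens of nodes), where a chance high-degree node can pass all criteria;
  the intended operating scale is hundreds of nodes and up.
* No cross-validation beyond the single configurable holdout split, and no
  alternative centrality measures for the dense-area criterion.
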