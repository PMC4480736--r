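# apoppi

Naive-Bayes integration of heterogeneous functional-genomics evidence for
predicting protein–protein interaction (PPI) networks, with downstream
identification of apoptotic hub proteins and prioritization of dual kinase
targets.

## The problem

Individual sources of evidence for whether two proteins interact — gene
co-expression, curated domain–domain interactions (DDI), interactions of
orthologous pairs in model organisms (interologs), and co-annotation to
specific biological processes — are each noisy and incomplete. `apoppi`
combines them the way systems-biology discovery pipelines do: each evidence
type is discretized into bins, and per-bin likelihood ratios are estimated
from a Gold Standard Positive set (GSP, curated interactions unioned over
several source databases) and a Gold Standard Negative set (GSN, all pairs
of a plasma-membrane protein with a nuclear protein, a compartment
combination that cannot physically interact).

For a pair with evidence values E1, .., En, Bayes' theorem gives

    O_posterior = O_prior * LR(E1, .., En),
    LR(E1, .., En) = P(E1, .., En | positive) / P(E1, .., En | negative)

and under the naive (conditional-independence) assumption the composite
likelihood ratio factors as

    LR(E1, .., En) = prod_i LR(Ei),    LR(Ei) = P(bin_i | pos) / P(bin_i | neg).

Because the prior odds are a constant, pairs are ranked and thresholded on
the composite LR itself (the classical operating point for the apoptotic
network is LR >= 117; the package also offers validation-based cutoff
selection and TP/FP-ratio diagnostics). The classifier is evaluated by ROC
curves (sensitivity = TP/positives, specificity = 1 − FP/negatives) on a
held-out split of the gold standards.

On the assembled network (prediction set ∪ positive set), apoptotic hub
proteins are called by four golden standards: degree ≥ 300, links to known
apoptotic proteins ≥ 300 (classical hubs, themselves apoptosis-annotated)
or ≥ 200 (novel hubs, not annotated), membership in the dense area of the
network (k-core index), and divergent expression by SAM (significance
analysis of microarrays, a moderated difference statistic with
permutation-estimated FDR). The count thresholds refer to a 13,128-protein
interactome and are auto-scaled to smaller networks. Finally, novel hubs
are ranked by their links to other hub proteins, and pairs among the
top-ranked are scored by exact set arithmetic on their shared hub
interactors — the dual-target analysis that singles out kinase pairs
co-regulating a large fraction of the apoptotic hub network.

Everything is exercisable without any external download: a synthetic-data
generator (`simulate_world()`) emits a complete input bundle — curated
interaction sources, localization/process annotation, a two-condition
expression matrix, ortholog tables, per-species model-organism interaction
lists, domain assignments and a DDI table — from a scale-free ground-truth
interactome with planted classical and novel hubs and known effect sizes.

## Worked example

```r
library(apoppi)

cfg <- run_config(simulation = sim_config(), lr_cutoff = "auto", seed = 1)
run <- run_pipeline(cfg, quiet = TRUE)
print(run)
#> Pipeline run (seed 1): 2018 network edges over 500 proteins;
#> validation AUC 0.995; 3 classical / 2 novel hubs

print(run$objects$network)
#> Protein interaction network: 2018 edges over 500 proteins (LR cutoff 14.8942)
#>   provenance        n
#> 1 both           1456
#> 2 gold_positive   118
#> 3 predicted       444

glance(run$objects$hub_report)
#>   n_proteins n_classical n_novel degree_threshold links_threshold_classical
#> 1        500           3       2               12                        12

run$objects$candidates
#>   target_a target_b   n_a   n_b n_common n_union frac_common_of_union
#> 1 P0168    P0447        3     3        3       3                    1
```

Reading the output: on the default 500-protein synthetic study the
classifier reaches validation AUC 0.995; the assembled network combines
1,574 gold-positive pairs with 444 newly predicted ones at the
F1-maximizing cutoff (LR ≈ 14.9 on this run). The three planted classical
and two planted novel hubs are exactly the hubs called (thresholds scaled
from 300/300/200 to 12/12/8 at this network size), and the top dual-target
candidate pair is the planted novel-kinase pair, which shares its entire
hub neighborhood (3 of 3 common interactors).

The likelihood tables themselves are informative: e.g. interolog support in
two or more model organisms multiplies a pair's odds by two to three orders
of magnitude, while support in none divides them by ~10 — the classic
pattern that makes the naive-Bayes product discriminative.

Per-result plotting: `autoplot()` on the ROC (`run$objects$evaluation$roc`),
the likelihood table and the SAM fit; `tidy()`/`glance()` give broom-style
tables for all of them.

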