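---
title: "Mapping convergent losses of mitochondrial complex I"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping convergent losses of mitochondrial complex I}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ciloss)
```

## The problem

NADH:ubiquinone oxidoreductase (complex I, CI) is the largest and most
conserved complex of oxidative phosphorylation, yet it has been lost
repeatedly and independently in eukaryotes — most often in fungi, where
several yeast lineages dispensed with it while keeping the rest of the
respiratory chain. Because the seven mitochondrially encoded subunits
(ND1–ND6 and ND4L, the KEGG orthologue clusters K03878–K03884) are always
co-lost with the nuclear ones, their absence from a mitochondrial genome is
a reliable proxy for loss of the whole complex.

`ciloss` implements the comparative-genomics machinery needed to study such
convergent losses end to end: calling CI status per genome and species,
enumerating independent loss events on a species tree, and asking which
gene-family, selection, localization and pathway changes recur across
independent losses. Every stage can be exercised on synthetic data with
planted truth, so the behaviour of each statistic is testable without any
database access.

## Calling CI status

A subunit is *present* in a genome when it is annotated, or when a
homology-based gene prediction covers at least 50% of its coding region
(inclusive boundary). Genomes with fewer than 3 annotated CDS are treated
as incomplete assemblies and discarded, and at most 50 genomes per species
are retained (seeded uniform subsample) so heavily resequenced species do
not dominate. A genome is CI-absent when it misses at least 5 of the 7
subunits — a one-sided rule justified by the strongly bimodal distribution
of subunit counts across real mitochondrial genomes; genomes missing 3–4
subunits are rare, kept as CI-present, and flagged with a warning.

Aggregation to species level is deliberately conservative: a species is
`absent` only when **all** retained genomes miss ≥ 5 subunits, `present`
only when all miss ≤ 2, and `conflicting` otherwise. Disagreements between
assemblies of one species are, on real data, resolved by manual curation;
the machine-checkable analogue here is to flag and exclude them from
downstream monophyly analyses, together with species lacking mitochondrial
genomes (`no_data`).

```{r screen}
sim <- simulate_ci_dataset(sim_config(seed = 1))
status <- call_ci_status(filter_genomes(sim$genomes),
                         all_species = sim$states$species_id)
table(status$status)
```

## Independent losses on the species tree

An *independent loss* is a maximal clade whose known-status tips are all
CI-absent while the parent clade contains a CI-present tip; under
irreversible loss (no regain) each such clade corresponds to exactly one
present→absent transition, and the event count equals the Camin–Sokal
parsimony count — a property the test suite verifies exhaustively against a
brute-force oracle on 6-tip trees. Polytomies are scored as given.

Events are classified by taxonomy: a loss spanning two or more genera is
`ancient`; a loss confined to one genus that still contains a CI-present
species elsewhere is `recent`. When a single-genus loss has no CI-present
congener the rule is silent, and rather than guessing we label the event
`recent_unconfirmed`.

```{r losses}
ev <- classify_recency(find_independent_losses(sim$tree, sim$states),
                       sim$states)
ev[, c("event_id", "n_tips", "n_genera", "recency")]
```

## Copy-number association (clade-median KS)

For each gene family, orthologue counts are summarized as one median per
maximal CI-uniform clade, and the CI-absent medians are compared with the
CI-present medians by a two-sided two-sample Kolmogorov–Smirnov test
(significance at p < 0.05). Running the test on clade medians — one value
per node rather than one per species — keeps deep, species-rich clades from
swamping the comparison, at the price of small sample sizes; the exact KS
distribution is therefore used whenever the product of the two node counts
is at most 10,000 (R's `ks.test` computes exact two-sample p-values in the
presence of ties). Whether one should pool raw per-species counts instead
is a genuinely open design point; the pooled variant is available via
`method = "pooled"`.

Because the node medians are small discrete samples, the exact KS test is
conservative: on null families its realized false-positive rate sits below
the nominal 5% (about 2–4% under the default configuration), which the
acceptance checks treat as an upper bound rather than a target to hit.

## Positive-selection overlap

Genes are called positively selected per species by Benjamini–Hochberg FDR
(< 0.05) over branch-site likelihood-ratio-test p-values; the statistic of
interest is the number of families with a PS gene in *every* focal species.
Its null distribution is obtained by reassigning, per species
independently, the same number of PS calls to genes uniformly without
replacement (10,000 draws by default) and recomputing the overlap. The
p-value uses the add-one estimator `(k + 1)/(n + 1)`, which never reports
exactly zero — the standard permutation-test convention. The suite verifies
the permutation estimate against exhaustive enumeration of all per-species
call combinations on small instances.

Whether a family tested through several genes should count once or once per
gene in the null is not fixed by the design; the default permutes at the
gene level (a family is PS if any member gene is), and `unit = "family"`
switches to one call per family.

## Mitochondrial retargeting

Localization predictors output a probability vector over nine compartments
plus a membrane score. Retargeting of a CI-absent gene is scored as the
difference between its mitochondrial probability and that of its sister
CI-present orthologues; the call threshold is a strict `delta > 0.2`, the
value that maximizes sensitivity at high precision in benchmarks of
labelled paralogue pairs (`benchmark_thresholds()` reproduces that
selection rule, maximizing sensitivity subject to a precision floor,
default 0.7). "Greater than any of the sisters" admits two readings; the
conservative one — the target must exceed **all** sisters, i.e. the delta
is taken against the sister maximum — is the default, with
`quantifier = "any"` (delta against the minimum) available. Profiles are
validated to sum to 1 within 0.01 (files are often rounded) and
renormalized with a warning otherwise; argmax ties break towards the fixed
compartment order, mitochondrion first, for determinism. A family's main
localizations are the compartments that are the argmax for at least 50% of
its proteins (inclusive, so a 50/50 split yields two).

## Pathway convergence scoring

Gene-level events (duplication D, positive selection PS, retargeting MR,
loss L) are rolled up to KEGG enzymes and pathways under six positive
parameters: gene scores (`p4` for PS/MR/D, `p5` for loss only, `-p6`
otherwise, each multiplied by 10 or 1 for high/low-identity KEGG mappings),
enzyme co-occurrence bonuses (`p1` when exactly two focal species carry an
innovation event at the enzyme, `p2` when all three do), an enzyme
uniqueness bonus (`p3`, when the enzyme's presence is strictly coupled to
CI loss relative to the sister species), and a `-p6` penalty per enzyme
unmapped in a species. Loss scores below innovation scores encode the
assumption that losing one gene copy reflects diminished activity rather
than innovation.

No principled choice of the six weights exists, so pathways are scored
under a full grid: each parameter takes the lower bound, midpoint and upper
bound of its interval (`p5 ∈ [0.5, 5]`, `p4, p6 ∈ [p5+1, 10]`,
`p3 ∈ [p4+5, 50]`, `p1 ∈ [p3+10, 100]`, `p2 ∈ [p1+20, 200]`, dependent
bounds evaluated at the parent's chosen value), giving 3^6 = 729
combinations. Interval endpoints are treated as inclusive — with open
intervals the printed bounds would be unreachable and the grid
underdetermined. Raw scores are z-scored across pathways per (species,
parameter set), averaged over the grid and then across species, and
pathways are ranked by the mean final score; the z-normalization is exact
to 1e-9 and checked as an invariant. Zero-variance slices (degenerate
inputs where all pathways tie) get z = 0 with a warning instead of
crashing. The raw score is linear in the six parameters, which the
implementation exploits: one feature vector per pathway/species, then a
single matrix product against the grid.

```{r pathways}
ps <- score_pathways(sim$pathway_map, sim$pathway_events,
                     sim$focal_species)
head(ps$table[, c("pathway_id", "mean_final", "rank")], 5)
sim$truth$altered_pathway_ids
```

## Convergent GO enrichment

Per-species enrichment is a one-sided hypergeometric over-representation
test with BH-FDR across terms, with annotations propagated through the
is_a/part_of ancestor closure (`term_ancestors()`; the closure is computed
from a term→parent table, and propagation can be switched off). A term is
convergently associated with CI loss at level `X` when its raw p-value is
below 0.05 in every focal species, and at level `XX` when the FDR-adjusted
p-value is too. Using raw p-values within species avoids false negatives in
small categories (e.g. intersections such as duplication ∧ PS); demanding
the signal in *all* independent losses is itself a biological correction
for the false positives this admits. The background set is taken to be each
species' full annotated gene universe unless the caller narrows it.

## The synthetic generator

`simulate_ci_dataset()` emits every input of the pipeline with known
planted truth, from a single seed (each stage derives its own stream
through fixed stage-name offsets, so datasets are reproducible and stages
independent). Default study conditions, chosen once as a desk-scale
emulation of a realistic screen:

* 40 species, 6 planted independent losses (half spanning several genera,
  half within one genus with a CI-present congener), 3 genomes per
  species. Forty tips with six losses gives 6 CI-absent and typically
  12–18 CI-present maximal clades — enough node medians for the exact KS
  test to resolve a clear shift.
* Orthologue counts are Poisson with mean 2, truncated at zero by nature
  of the distribution; the 6 planted associated families have mean 2 + 4
  in CI-absent clades. A +4 copy shift is the scale of the family
  expansions (alternative dehydrogenases, glutathione transferases) that
  motivate the analysis. Poisson is the simplest overdispersion-free model
  matching count semantics — a stand-in, not an inference about real data.
* 8 families planted as PS in all 3 focal species (LRT p-values in
  [1e-8, 1e-4] against a uniform background, so BH keeps them).
* Localization vectors are Dirichlet draws over the nine compartments with
  a dominant cytoplasm component (softmax-like predictor output); the 10
  planted retargeted pairs exceed their sister maximum by exactly the
  configured delta (0.6), background pairs stay within ±0.1.
* 20 pathways of 5 enzymes; the 3 planted ones receive convergent
  PS/MR/D events in all focal species at ~85% of their enzymes; enzymes
  are unmapped in a species with probability 0.1, producing the −p6
  penalties.
* Noise: 1% per-subunit evidence corruption and 5% incomplete genomes by
  default; the planted-truth acceptance checks run the noiseless setting
  (both rates 0), where species calls must equal the truth exactly.

What the generator does *not* emulate: phylogenetic autocorrelation of
counts along the tree (counts are i.i.d. given the clade), annotation-name
ambiguity (the distilled evidence table carries a pre-resolved annotated
flag; on real data this step is manual curation), gene-tree discordance,
overdispersed copy numbers, and correlated localization errors. Passing the
planted-truth suite therefore demonstrates correctness of the inference
machinery under its stated assumptions, not robustness to every real-data
pathology.

## Numerical and design choices

* Tips with unknown/conflicting/no-data status are excluded from monophyly
  evaluation rather than breaking clades, mirroring the exclusion of
  species without mitochondrial genomes from loss mapping.
* Losses are treated as irreversible for event counting.
* The sister-similarity filter compares per event type (D with D, L with
  L, …); "similar evolution" has no sharper operational definition, and
  the per-type rule is the narrowest reading that is still mechanical.
* Medians of even-sized sets are the mean of the two central values
  throughout (node medians, ancestral copy numbers).
* All seeds are 32-bit safe; per-stage seeds are derived as
  `(seed * 7919 + hash(stage)) mod (2^31 - 59)`.
* Test and acceptance problem sizes (40 species, 60 families, 20 pathways,
  20 replicate seeds, 10,000 permutation draws) are the package's chosen
  desk-scale study conditions; they complete in seconds while leaving the
  statistics enough resolution to be meaningful.

## Limitations

The package consumes upstream outputs (branch-site p-values, localization
probability vectors, KEGG mappings, gene trees) and does not re-implement
the tools that produce them. Species-level aggregation and the
recent/ancient classification depend on taxonomy labels being meaningful.
The pathway score is a ranking device, not a calibrated statistic: its
z-scores order pathways within a dataset but carry no significance level.
And with only a handful of independent losses in any real dataset, all
cross-species convergence statistics rest on few effective replicates —
the permutation test quantifies chance overlap, not causality.
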