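---
title: "Reporter pathway analysis: model, background correction, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reporter pathway analysis: model, background correction, and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reporterpa)
```

## The problem

A perturbation — a gene deletion, an environmental shift, a disease state —
rarely announces itself through a handful of strongly differentially
expressed genes. More often it produces small, coordinated shifts across the
enzymes of a few metabolic routes. Reporter analysis exploits the topology
of a genome-scale metabolic network to pool that weak evidence: instead of
thresholding genes first and asking which pathways are enriched afterwards,
it maps *every* gene's differential-expression statistic onto the network
and aggregates over neighborhoods, so genes that are individually
unremarkable can still surface as a significant group.

`reporterpa` scores pathways in two ways:

* **Reaction-centric** (`reporter_pathways_rpar()`): a pathway is evidenced
  only by the genes of its own member reactions. This is the classical
  formulation.
* **Metabolite-centric** (`reporter_pathways_rpam()`): a pathway is
  evidenced through its metabolites, and a metabolite's score draws on
  *every* reaction that consumes or produces it — including reactions
  catalogued under other pathways. Inter-pathway ("cross-link") reactions
  and branch-point metabolites therefore contribute, which is exactly the
  cross-talk the reaction-centric view discards.

## The model

Per gene, a two-sample t-test (pooled variance by default; Welch optional)
yields a p-value $p_i$, converted to a Z-score by the inverse normal CDF,
$Z_i = \Phi^{-1}(1 - p_i)$. When a reaction is controlled by several genes,
the gene with the minimum p-value represents it (ties break
lexicographically, so runs are deterministic).

A metabolite with $k$ distinct neighbor genes (the selected genes of its
adjacent measured reactions; a gene selected by two adjacent reactions
counts once) receives the Stouffer aggregate

$$Z^m_{\mathrm{raw}} = \frac{1}{\sqrt{k}} \sum_{i=1}^{k} Z_i ,$$

which is standardized against the empirical mean $\mu_k$ and standard
deviation $\sigma_k$ of the same aggregate over many random size-$k$ gene
sets:

$$Z^m = \frac{Z^m_{\mathrm{raw}} - \mu_k}{\sigma_k}.$$

Pathways are then scored the same way one level up. The metabolite-centric
pathway statistic aggregates the corrected scores of the pathway's $n$
scorable metabolites; the reaction-centric statistic aggregates the
selected-gene Z-scores of the pathway's $p$ measured member reactions (one
term per reaction, even when one gene serves several). Both pathway
aggregates are background-corrected and converted to one-sided p-values,
$P = 1 - \Phi(Z)$: the statistic deliberately looks for coordinated change
in the "significant" direction of the Z-scale, and up/down attribution is
delegated to the directional analysis below. Benjamini–Hochberg q-values
are reported across each table.

Note the branch-point property that follows from scoring through
metabolites: a gene whose reactions touch $m$ distinct metabolites of one
pathway contributes $m$ terms to that pathway's evidence. This implicit
up-weighting of hub neighborhoods is intended — branch points are where
metabolic regulation concentrates — but it is a modeling commitment, not a
neutrality.

## Background correction: which null, exactly?

The correction in the equation above needs a definition of "random set",
and the choice matters more at the pathway level than at the metabolite
level.

At the **metabolite level** the pool is the measured genes attached to the
network, and random size-$k$ subsets are exchangeable with a null
metabolite's neighborhood, so the corrected scores are standard normal
under a global null. (By default the pool consists of the distinct selected
genes of measured reactions — the quantities the score is built from; a
full measured-gene pool can be supplied via `gene_pool`.)

At the **pathway level** a naive analogue — random size-$n$ sets of
corrected metabolite scores — is *not* exchangeable with a real pathway:
adjacent metabolites of a pathway share neighbor genes, so a pathway's
metabolite scores are positively correlated while a random set's are not.
Standardizing against independent sets leaves the corrected pathway score
over-dispersed (on chain-like pathways its null standard deviation
approaches $\sqrt{2}$), which inflates the false-positive rate several-fold
at $\alpha = 0.01$.

`reporterpa`'s default (`universe = "gene"`) therefore uses a
structure-preserving permutation null: for each pathway, random distinct
genes from the measured pool are substituted into the pathway's own
metabolite-neighborhood incidence structure (same metabolite count, same
per-metabolite $k$, same gene sharing between metabolites), and the full
metabolite-correction + pathway-aggregation is re-applied. Under a global
null the observed pathway and its permuted versions are exchangeable by
construction, so the corrected pathway Z is calibrated; the validation
suite checks this empirically (see below). The independent-set universe is
retained as `universe = "metabolite"` because it is the simpler
formulation and the natural one for a brute-force cross-check; its
anti-conservatism on connected pathways is the reason it is not the
default. The reaction-centric statistic needs no such device: its terms are
distinct reactions, which are exchangeable with random reaction sets under
the null.

Two further conventions: the metabolite score entering the pathway
aggregate is the *corrected* one (`metabolite_value = "raw"` switches to
raw aggregates), and backgrounds are sampled from *measured* items only —
unmeasured genes carry no Z-score and cannot appear in an observed
neighborhood either.

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `min_reactions` | 3 | pathways with fewer member reactions are not reported; tiny pathways make fragile aggregates |
| `n_samples` | 10000 | Monte Carlo sets per size $k$; the relative error of $\sigma_k$ is $\approx 1/\sqrt{2\,n_{\mathrm{samples}}}$ |
| `seed` | — | every random draw in a run derives from it; identical manifests give byte-identical reports |
| `alpha` | 0.01 | significance cutoff on the uncorrected p-value; 0.005 is a useful stricter choice for the metabolite-centric table, which reports more pathways by design |
| p-value clamp | $[10^{-15}, 1-10^{-15}]$ | keeps $\Phi^{-1}$ finite |
| `var_equal` | TRUE | pooled-variance t-test, the common default for the generic two-sample test; Welch available |

Degenerate inputs are surfaced, not papered over: a constant background
pool ($\sigma_k = 0$) is an error; constant genes get $p = 1-\varepsilon$
with a warning and sign 0; pathways with no scored metabolite (or no
measured reaction) are dropped with a warning naming them; metabolites with
no measured neighbor are omitted with a message.

## Directional (up/down) analysis

`reporter_pathways_directional()` restricts the gene table to one sign of
change (sign of mean(condition) − mean(reference)), converts the two-sided
p-values to one-tailed ones ($p/2$, exact for the symmetric t statistic),
and re-runs the mapping, metabolite scoring and metabolite-centric pathway
scoring on the restricted set. Each metabolite's $k$ shrinks to its
matching-sign neighbors, and the background pool shrinks with it, so the
correction stays self-consistent. Because the restriction discards
connectivity (a pathway whose genes all move the other way simply vanishes
from the table), directional results are flagged and meant to be read next
to the undirected run, never instead of it.

## The synthetic harness

Real network exports and transcriptome datasets change under the analyst's
feet; the package therefore validates against synthetic data with known
truth (`generate_network()`, `plant_perturbation()`,
`generate_expression()`, `evaluate_recovery()`).

What the generator emulates: a multi-pathway network (default 20 pathways
of 6 reactions, each a metabolite chain; a hub topology exercises
branch-point weighting); inter-pathway reactions (by default 20% of
reactions also touch a uniformly chosen foreign pathway's metabolite —
the cross-talk conduit of the metabolite-centric statistic); one gene per
reaction by default, so the minimum-p mapping is the identity and the gene
pool is unbiased under the null (a `shared_genes` mode exercises the
min-p and distinct-gene rules); and an additive mean shift of chosen size
on the perturbed pathway's neighborhood genes over i.i.d. Gaussian noise
(default 5 samples per group, unit noise) — the model under which the
t-test is exact.

What it does not emulate: correlated noise between genes, heavy-tailed or
count-distributed expression, unbalanced designs, isozyme-rich
gene–reaction maps, stoichiometry, or the size heterogeneity of curated
pathway databases. Passing the validation suite therefore demonstrates
correctness and calibration of the *statistics under their own
assumptions*, not robustness to everything real data does.

## What the validation suite computes

The test suite and `scripts/acceptance.R` recompute, from scratch:

* **Equivalence with a brute-force evaluator** — on 25 random networks of
  at most 50 reactions, metabolite and pathway tables match an
  independently coded plain-loop evaluation of the scoring equations to
  within $10^{-9}$, given shared background models (Monte Carlo samples of
  300 per size on these small pools).
* **Null calibration** — 50 null-expression replicates on the default
  20-pathway network (backgrounds of 1000 samples per size): the fraction
  of pathway p-values below 0.01 stays within 3 Monte Carlo standard
  errors of 0.01 for both statistics, and the pooled corrected Z-scores
  pass a Kolmogorov–Smirnov test against N(0,1).
* **Planted-pathway recovery** — a 3-sigma shift on one pathway's
  neighborhood, 5 samples per group: the perturbed pathway ranks first
  under the metabolite-centric statistic in at least 90% of 50 replicates.
* **Cross-link discordance** — the operational form of the method's
  central claim: planting the shift *only* on foreign reactions touching a
  victim pathway's metabolites lowers the victim's metabolite-centric
  p-value (paired sign test over 50 replicates) while leaving its
  reaction-centric p-value distribution unchanged (KS test). The victim is
  the first pathway with at least two cross-linking reactions: the planted
  set must be non-trivial, but a large one would leak into every pathway's
  correction through the shared background pool, since the pool is
  estimated from the perturbed data itself.
* **Directional consistency** — an upregulated perturbation is significant
  in the up-analysis and not in the down-analysis in at least 90% of 50
  replicates.
* **Determinism and round-trips** — identical run settings give
  byte-identical report files, and `parse_network()` after
  `write_network()` is the identity.

The replicate counts and Monte Carlo sizes above are the package's
simulation-study choices; the in-analysis default for backgrounds remains
`n_samples = 10000`.

## Worked example

```{r example, eval = FALSE}
sim <- rpa_simulate("sim", seed = 42, effect_size = 3)
res <- rpa_run(network_file = sim$paths$network, output_dir = "out",
               expression_file = sim$paths$expression,
               groups_file = sim$paths$groups, seed = 42)
head(res$report)
evaluate_recovery(res$rpam, sim$truth, network = res$network)
compare_reports(res$rpam, res$rpar)
```

## Known limitations

* The background pool is estimated from the analyzed data, so a
  perturbation touching a large share of the network deflates every
  corrected score slightly; this is inherent to data-derived backgrounds.
* The metabolite-centric statistic reports more pathways by construction;
  when specificity matters, use the stricter 0.005 cutoff and read the
  discordance flags of `compare_reports()`.
* Compartment-qualified metabolite names are kept verbatim; the same
  chemical in two compartments is two nodes. Currency metabolites are not
  excluded by default (cofactor neighborhoods can be genuine signal), but
  `parse_network(exclude_metabolites = ...)` accepts a list.
* One-sided p-values mean coordinated *downregulation* appears as a
  corrected score in the lower tail, not as a small p-value; use the
  directional analysis to attribute direction.
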