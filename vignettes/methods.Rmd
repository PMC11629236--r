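---
title: "Imputing reactomes and gap-filling metabolic models: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Imputing reactomes and gap-filling metabolic models: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Genome-scale metabolic models (GSMMs) reconstructed from incomplete
genomes — above all metagenome-assembled genomes — miss reactions, and a
model with gaps in its central pathways cannot carry flux through its
biomass reaction, so it cannot be simulated at all. Gap-filling adds
reactions from a biochemistry database until biomass flux becomes
possible, but the set of reactions that restores growth is far from
unique, and an unweighted gap-filler picks an arbitrary minimal set that
need not resemble the organism's actual metabolism.

panfill couples two ideas. First, reaction presence and absence across
the bacterial domain is highly structured: a reaction's overall
frequency, and its co-occurrence with other reactions (pathways travel
as blocks), carry real information about whether an unobserved reaction
belongs in a particular genome. A neural network trained on corrupted
reaction sets learns exactly this structure. Second, a linear-programming
gap-filler can be *guided*: each candidate reaction gets a cost, and the
optimiser prefers cheap reactions, so turning imputation scores into
costs steers gap-filling toward biologically plausible completions.

# The imputer

## Data representation

The coordinate system is the **pan-reactome**: the ordered union of all
gene-associated reactions observed across a genome collection. Each
genome is a binary vector over it, and the collection is a binary
incidence matrix (`build_incidence_matrix()`, `generate_incidence()`).
Only gene-associated reactions enter this matrix: injecting database
reactions without genetic evidence would teach the network the biases of
automated reconstruction pipelines rather than biology.

Genome selection and splitting follow sequencing quality: within each
species (and, for the test split, each genus) the genome maximising
`completeness - 5 * contamination` wins, ties broken by coarse
consistency and then lexicographically by genome id so that selection is
fully deterministic (`select_best_genomes()`, `split_train_test()`).
The best genome per genus goes to the test set; everything else trains.
Splitting by genus rather than at random keeps the test set
taxonomically diverse and prevents a species-rich genus from appearing
on both sides.

## Corruption

Training pairs are made by deleting reactions from intact genomes
(`corrupt()`). Two schemes are supported (`deletion_scheme()`):

* **uniform** — exactly `round(0.3 * n_present)` present reactions are
  removed, drawn uniformly. We delete an exact count rather than
  tossing a coin per reaction: it matches the "delete 30%" protocol
  exactly and makes every test deterministic given a seed.
* **rare_biased** — each present reaction is deleted independently with
  a logistic probability of its frequency,
  `D(frac) = 1 - 1/(1 + exp(-10 (frac - 0.5)))`, so rare reactions are
  deleted almost surely and core reactions almost never. This emulates
  the biases of real metagenome assembly and annotation, where
  accessory genes go missing first. The same logistic is sometimes
  written with the opposite sign in the exponent, which *increases*
  deletion with frequency; that orientation contradicts the stated
  intent of biasing deletion toward rare reactions, so the decreasing
  form is the default and the increasing one is available behind
  `as_printed = TRUE`. The biased scheme does not target a particular
  total deletion fraction; an optional `rescale` flag normalises the
  expected deletion to `target_fraction`, off by default.

Per-sample seeds are derived by hashing `(base_seed, genome_id,
replicate)` into 31 bits, so any single sample can be regenerated
without replaying the stream.

## Network and loss

The imputer (`build_network()`, `train_imputer()`) is a fully connected
feed-forward network mapping the pan-reactome onto itself: input width =
output width = pan-reactome size, three hidden layers of 256 rectified
units, dropout 0.1 after each hidden layer, sigmoid outputs. The
defaults — 256 nodes, 3 layers, dropout 0.1, batch 50, 10 epochs, Adam
with learning rate 0.005, beta1 0.9, beta2 0.999, epsilon 1e-8, and
per-step learning-rate decay 0.01 — are adopted as tuned constants.
Where the architecture leaves details open we took the standard choices
for dense binary imputers: rectifier hidden activations, He
initialisation, sigmoid output (binary cross-entropy needs outputs in
(0,1)), and "decay" interpreted as the optimiser's per-step
learning-rate decay `lr / (1 + decay * step)`.

The loss (`masked_loss()`) is a masked, class-weighted binary
cross-entropy. For output `O`, truth `T` and input `I`:

$$\mathrm{mCE} = (1 - I) \circ \left[ -(1 - b_0)\, T \circ \log O \;-\;
  b_0\, (1 - T) \circ \log (1 - O) \right]$$

averaged over positions. Two features matter:

* the **mask** `(1 - I)` zeroes every position the network was given as
  input, so it is rewarded only for *completing* the reaction set, never
  for echoing its input;
* the **class weight** `b0 = 0.3` down-weights the absent class: a
  typical genome carries far fewer reactions than the pan-reactome has
  columns, and without the weight the network would buy accuracy by
  predicting absence everywhere.

Outputs are clipped to `[1e-7, 1 - 1e-7]` before the logarithms; the
gradient uses the standard stable product form, so no NaN can arise from
saturated sigmoids. The loss is averaged (not summed) over positions and
batch so that `b0` keeps the same meaning whatever the pan-reactome
size. Training is plain mini-batch Adam written in R matrix code; at the
problem sizes this package targets (a few hundred to a few thousand
columns) one training run takes seconds to minutes on one CPU.

# The gap-filler

## Costs

`make_costs()` implements four weighting schemes plus one variant, all
defined on a prepared candidate database:

| scheme | cost of reaction $r$ | evidence used |
|--------|-------------------|----------------|
| W1 | 50 | none |
| W2 | 1 if $r$ in the training pan-reactome, else 50 | membership |
| W3 | $1 - \mathrm{frac}_r$, else 50 outside the pan-reactome | frequency |
| W4 | $1 - p_{NN}(r)$, else 50 unscored | imputer score |
| W4neg | $1 - 2\,p_{NN}(r)$ | imputer score, negative for $p_{NN} > 0.5$ |

The negative variant actively pulls confidently predicted reactions into
the solution instead of merely tolerating them. No closed form for it is
established elsewhere; the affine map sending $p = 0 \mapsto +1$ and
$p = 1 \mapsto -1$ is this package's choice. Negative costs can make an
LP unbounded, so every candidate's flux is capped (`candidate_ub`,
default 1000).

## Preparation and the search

`prepare_database()` removes biomass-class reactions (artificial
constructs, never legitimate candidates) and splits each reversible
reaction into `_f`/`_b` irreversible halves with negated stoichiometry,
so all candidate fluxes are non-negative and "reaction used" is simply
`flux > tolerance`.

`halfinterval_gapfill()` merges the model with the candidate database
and solves

$$\max\; \alpha f_b - \sum_{r \in M} c_r f_r$$

subject to steady-state mass balance and bounds, where model reactions
are cost-free (annotation evidence is free, and annotation reactions are
never removed — gap-filling is strictly additive). The scalar
$\alpha$ trades biomass against cost; a half-interval (bisection) search
finds the smallest $\alpha$ whose optimum reaches $f_b \ge \epsilon$.
At that point the LP funnels biomass through the cheapest available
route and the candidates carrying flux above `flux_tol` are the
gap-fill set. Numerical choices, each configurable:

* `epsilon = 1e-6` (model flux units): "greater than zero" needs a
  strict LP threshold;
* `flux_tol = 1e-9`: separates numerically zero fluxes from used
  reactions;
* `alpha_tol = 0.05` relative bisection width, giving
  $O(\log 1/\mathrm{tol})$ LP solves per gap-fill (typically 8–12);
* tie-breaking: equal-cost alternatives are genuine alternative optima;
  passing a `seed` permutes candidate order so ties break randomly
  rather than by database order (without a seed the result is
  deterministic in database order).

Because each LP is solved by a simplex method, the solution is always a
vertex of the flux polytope: flux never splits across equal-cost
parallel routes, so the added set stays parsimonious. The LP backend is
a dense two-phase primal simplex with Bland's-rule fallback, written for
this package (no LP solver package is assumed); it is cross-checked
against `boot::simplex` in the test suite. Infeasible gap-fills (no
candidate superset can reach biomass) raise an error listing which
biomass precursors cannot be produced.

# Evaluation conventions

* Prediction confusion counts (`confusion_from_predictions()`) use
  masked positions only, mirroring the loss, with a default
  binarisation threshold of 0.5 (no canonical value exists; it is a
  flag).
* Gap-fill recovery (`confusion_from_gapfill()`): deleted-and-re-added
  = TP, deleted-not-re-added = FN, added-never-present = FP; TNs are
  counted against the prepared candidate database as the universe.
* `metrics()` returns precision, recall, F1, specificity and balanced
  accuracy `(specificity + recall)/2`, with zero-denominator cases
  defined as 0.
* `frequency_binned_metrics()` pools confusion counts within occurrence
  bins (sum counts, then divide) rather than averaging per-reaction
  ratios, so empty-denominator reactions do not distort bins.
* `nearest_neighbor_distance()` is the minimum Jaccard distance from a
  query reaction set to any training genome — a cheap, alignment-free
  stand-in for phylogenetic distance.
* `essential_reactions()` is a single-deletion screen at the same
  growth threshold as the gap-filler, and `carbon_profile()` swaps one
  carbon source at a time into a base medium, calling growth at the
  same threshold; models that grow on the empty medium are flagged
  invalid and should be excluded from profile comparisons.

# The synthetic world

Real pan-reactome corpora cannot ship with a package, so the benchmark
world is generated (`synthetic_world_config()`, `generate_incidence()`,
`world_biochemistry()`). It emulates the three features that make
imputation learnable, and nothing else:

* a **core** present in every genome (frequency exactly 1) — the
  backbone of central metabolism;
* **modules** of 8 reactions gained and lost as blocks, each with a
  home clade: within the home clade a genome carries the module with a
  per-module gain probability spread evenly over 0.35–0.95, outside it
  with probability 0.02. The gradient matters: real pathway
  frequencies span a continuum, and without one, frequency-based costs
  (W3) and frequency-binned evaluation would be degenerate;
* **accessory** reactions carried independently with probabilities
  0.02–0.12, plus 1% flip noise on all non-core entries.

The default world is 400 reactions (100 core + 30×8 module + 60
accessory) across 6 clades × 40 genomes, each clade split into 10
genera so the genus-level train/test split yields 180 training and 60
test genomes. These sizes train the imputer in seconds and keep the
full acceptance analysis in minutes on one CPU.

The stoichiometric layer gives every reaction a mass-balanced role: the
core is a linear chain from an exchanged nutrient to the terminal
biomass precursor; the two modules of a pair are *twin pathways* with
identical stoichiometry (shared substrate, intermediates and product),
so flux analysis alone cannot tell which twin a genome actually
carries — only frequency or learned co-occurrence can; accessory
reactions duplicate core steps like isozymes; and the candidate
database adds non-pan decoys (twins and two-step shortcuts) that an
unweighted gap-filler cannot distinguish from genuine reactions. Each
genome's biomass reaction consumes the terminal core precursor plus the
product of every module pair the genome carries, so deleting a module
step genuinely breaks growth and must be repaired.

What the world does **not** model: real biochemistry (compartments,
cofactors, energy metabolism), contamination (falsely added reactions),
horizontal transfer beyond the uniform leak, or any correlation between
genome quality metadata and reaction content. Passing benchmarks on
this world therefore demonstrates that the machinery works and that the
relative ordering of weighting schemes behaves as designed — not that a
particular F1 will be attained on real genomes.

# Benchmark protocol and problem sizes

The acceptance analysis (`scripts/acceptance.R`, mirrored by the
acceptance test suite) uses the default world and the standard
protocol: 30% uniform deletion, 30 corruption replicates per training
genome, 10 per test genome. Frequency-binned recall uses bins of 10
genomes on the 60-genome test split — the classic 50-genome binning
scaled to a small test set; narrower bins hold too few reactions for
stable pooled recall. The gap-fill scheme comparison corrupts 12 of the
60 test genomes in triplicate and gap-fills each under every scheme
(180 gap-fills), comparing paired per-model F1 with a one-sided
Wilcoxon signed-rank test. The distance analysis retrains the imputer
with one full clade excluded and relates each held-out genome's F1 to
its nearest-neighbour Jaccard distance into the reduced training set.
The soundness suite solves 100 random toy instances with at most 8
candidates each and compares against exhaustive enumeration
(`bruteforce_gapfill()`).

# Known limitations

* The half-interval LP search is a relaxation: it is not guaranteed to
  find the exact minimum-cost reaction set (solutions are non-unique
  anyway); the brute-force comparison bounds the gap at 5% on small
  instances, but no such bound is proven in general.
* The imputer sees only presence/absence — no fluxes, pathway
  annotations, network topology or phylogeny.
* Determinism of training holds for a fixed BLAS; exotic threaded BLAS
  libraries may reorder floating-point reductions.
* The SBML reader covers Level 3 core plus fbc flux bounds as commonly
  emitted by COBRA tools; it is not a general SBML implementation.
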