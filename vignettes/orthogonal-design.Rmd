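---
title: "Designing orthogonal protein-protein interactions with a generative Potts model"
author: "orthopotts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing orthogonal protein-protein interactions with a generative Potts model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orthopotts)
```

## The problem

Two interacting proteins A and B (the motivating system is a bacterial
two-component pair: a sensor histidine kinase and its response regulator)
are to be re-engineered into a mutant pair (A\*, B\*) that still binds
itself (the *cognate* interaction) but no longer binds the native partners
(no A\*-B or A-B\* *cross-talk*). Such a pair is called *orthogonal*; a pair
that retains cross-talk is *promiscuous*. The package mimics natural gene
duplication and divergence: it learns the mutational preferences of the
family from a paired multiple sequence alignment (MSA) of interacting
homologs, then samples and scores candidate mutants from that learned model.

## The model

Sequences are rows of a paired MSA: A columns first, B columns after the
boundary `n_a`, each position taking one of `q = 21` states (20 amino acids
and a gap). The package fits the pairwise maximum-entropy (Potts) model

$$P(s) = \frac{1}{Z}\exp(-E(s)), \qquad
E(s) = -\sum_i h_i(s_i) - \sum_{i<j} J_{ij}(s_i, s_j),$$

so that **lower statistical energy means higher model probability**. Two
sign/counting conventions are fixed once and used everywhere:

* *Sign*: `E` is defined with the explicit minus signs above, so favourable
  sequences score negative. (The equivalent convention that writes the
  exponent with positive sums and calls that quantity `-E` appears in parts
  of the literature; the package state is unambiguous: `energy()` returns
  the quantity whose Boltzmann weight is `exp(-E/T)`.)
* *Pair counting*: each unordered site pair contributes once (`i < j`).
  Writing the double sum over ordered pairs only rescales `J` by 2; the
  single-counting convention avoids that ambiguity in sums, gradients and
  the L2 penalty alike.

Because the alignment is a concatenation, `E` splits exactly into
`E_intra(A) + E_intra(B) + E_inter(A, B)`, where `E_inter` collects the
couplings that cross the boundary. `E_inter` is the interaction score: for a
mutant pair, the five wild-type-normalized scores

`dE_intra(A*)`, `dE_intra(B*)`, `dE_inter(A*,B*)`, `dE_inter(A*,B)`,
`dE_inter(A,B*)`

(each `dE = E(mutant term) - E(wild-type term)`; the last two evaluated on
the chimera of one mutant protein with its native partner) summarize
fold/function cost, cognate binding and cross-talk. `delta_scores()`
computes all five; they vanish identically for the wild type.

### Gauge

The Potts parametrization is redundant. After training, models are shifted
to the zero-sum gauge (`sum_a h_i(a) = 0`, `sum_{ab} J_{ij}(a,b) = 0`) by
the standard shift: each coupling block loses its per-state row and column
means (plus the grand mean), which are absorbed into the fields, and fields
are centered. Only the constraints are canonical; this particular shift is
chosen because it is the field-standard one. The transform changes every
energy by one common constant, so all energy *differences* — everything the
method reports — are invariant (verified by full enumeration in the tests).

## Training

Parameters are fitted by Boltzmann machine learning: plain gradient descent
on the L2-regularized negative log-likelihood, with the model-expectation
term of the gradient estimated each step by Metropolis sampling of the
current model at `T = 1` (all recorded configurations from all chains
pooled). The loss is defined *per sequence* (mean NLL over the alignment
plus `lambda * (||h||^2 + sum_{i<j} ||J_ij||^2)`), so the gradient for each
parameter is exactly `(sample moment - data moment) + 2*lambda*theta`.
Using the mean rather than the sum over the `B` alignment rows only rescales
`lambda` and `eta` jointly; it keeps both independent of alignment size.

Key settings (all exposed in `train_potts()`):

* `eta = 0.01` — reference step size; desk-scale toys tolerate `0.05`.
* `n_steps = 2000`, `n_chains = 128`, `n_sweeps = 1e5`, `record_every = 100`
  — the reference schedule for a real family-sized alignment. All tests and
  the acceptance script use reduced schedules (hundreds of steps, tens of
  chains, hundreds of sweeps) on toy systems of 6-8 sites and 3-4 states,
  where they demonstrably recover the generating model's one- and two-site
  marginals to ~0.01.
* `lambda_reg = 0.01` default — the regularization weight is a modelling
  choice (common practice for Boltzmann-machine DCA); every quantitative
  check in this package states its `lambda` explicitly.
* Termination is by fixed step count, with no early stopping; chains restart
  each step from alignment rows (`init = "msa"`), with uniform-random and
  persistent-chain modes available.
* No pseudocount by default; L2 regularization handles unobserved state
  combinations. A small uniform admixture (`pseudocount`) is available for
  deliberately degenerate toy alignments.

Sequence weighting beyond the 90% identity filter is not applied by default
(uniform weights), but `site_marginals()` accepts explicit weights since
reweighting is standard DCA practice.

## Sampling

A single Metropolis kernel serves training and generation. One sweep is `L`
single-site proposals: a uniform random site, a uniform random one of the
`q - 1` other states, accepted with probability `min(1, exp(-dE/T))`. The
virtual temperature `T` rescales the whole energy; `T > 1` broadens the
sampled repertoire at the cost of higher energies, `T < 1` concentrates near
the native optimum. Per-chain random streams derive from one master seed via
a splitmix64 mixer feeding xoshiro256++ generators, so every run is exactly
reproducible across machines and independent of R's global RNG state.
Recording starts after the first `record_every` sweeps with no additional
burn-in, mirroring the reference protocol; stationarity at this spacing is
verified against exact enumeration (total variation < 0.02 with 1e6 pooled
samples at `T` in {0.5, 1, 2}).

### Constrained generation

`direct_sample()` explores the space of mutant pairs with *exactly* `k_a`
substitutions in A and `k_b` in B (reference values 6 and 5), at virtual
temperature `T` (reference 2). The constraint is maintained by a reversible
move mixture on a uniformly chosen protein:

* *resample* — redraw the residue at a currently mutated position among the
  other legal mutant states (symmetric proposal);
* *swap* — revert one mutated position to wild type and mutate a
  currently-wild-type position to a legal mutant state. The acceptance
  carries the Hastings factor `m_new / m_old` (the counts of legal mutant
  states at the gaining and losing positions), which makes the kernel exact
  even when positions differ in their number of legal states (e.g. when the
  wild type carries a gap).

Gap-state mutations are excluded by default — a designed protein should not
acquire alignment gaps — and can be enabled by flag. Mutations can be
restricted to an arbitrary position subset per protein. The five delta
scores are tracked incrementally during sampling and attached to every
recorded mutant, so generation and scoring cannot drift apart.

`conditional_sample()` adds a cross-talk-aware term: its stationary
distribution is proportional to

$$\exp\!\Big({-\tfrac{E_{intra}(A^*) + E_{intra}(B^*) + E_{inter}(A^*,B^*)}{T}}
      + \tfrac{E_{inter}(A^*,B) + E_{inter}(A,B^*)}{T_2}\Big),$$

rewarding mutants whose chimeras with the native partners score poorly
(i.e. candidates with low cross-talk potential). A consequence worth
stating plainly: the reward coefficient is `1/T_2`, so the mean cross-talk
score of the repertoire is highest at small `T_2` and decays monotonically
toward the direct-sampling mean as `T_2` grows (at `T_2 -> Inf` the law
reduces exactly to direct sampling — verified by enumeration). On systems
with strongly asymmetric coupling structure the two cross-talk components
can respond very differently to `T_2`, since the tilt acts on their sum; on
generic toy systems both components decrease with `T_2`.

## Selection

Orthogonal candidates are selected in the plane of the two cross-talk
scores (`dE_inter(A*,B)`, `dE_inter(A,B*)`): high values in both
coordinates mean insulation from both native partners.
`select_orthogonal()` scans the 45-degree line through the cloud mean for
the threshold pair `(E1, E2)` at which the retained fraction (points
strictly above both thresholds) first reaches the target `F` (reference
`F = 0.15`). Quadrant membership is induced by the thresholds themselves —
the scan line passes through the mean, not through zero. Tie-break:
candidates exactly on a threshold are excluded (strict inequality), making
selection deterministic; `F = 0` selects nothing and `F = 1` everything
(thresholds at `-Inf`).

## Classification protocol

For labeled (orthogonal/promiscuous) mutant pairs, the five delta scores
form the feature vector, and an L2-regularized logistic regression with
regularization constant `C = 1` (intercept unpenalized; implemented as
ridge-penalized logistic regression with penalty `1/(n*C)`, the exact
objective-level equivalence) is evaluated over 100 random 31/10
train/test splits. Mean accuracy, mean AUC (positive class: promiscuous),
the row-normalized confusion matrix and per-feature coefficient means/SDs
are reported. Features are not standardized by default (a flag exists;
standardization changes coefficients but little else at these scales).

One protocol subtlety is handled deliberately. When the pool barely exceeds
`train + test` (e.g. 41 samples for 31/10), the test set is nearly the
complement of the training set, so train and test class compositions are
anti-correlated and the *true* null mean accuracy of the protocol lies
visibly below 0.5 (simulation: ~0.47 for a 41-sample balanced pool, with a
majority-rule limit of ~0.39). Null-calibration checks in this package
therefore use a larger balanced pool (200 samples) and a fresh label
permutation per split, for which the usual binomial band around 0.5 is the
statistically correct reference; the 41-sample configuration is exercised
by the planted-signal fixtures instead.

## Repertoire characterization

* Amino acid usage and substitution enrichment: frequencies among the
  *introduced* residues of the selected repertoire divided by the same
  frequencies in the pre-selection background (ratios of 1 mean no
  selection effect; ratios are flagged undefined when both frequencies are
  zero and infinite when only the background is zero). Counting over
  introduced mutations (not whole sequences) matches the substitution
  framing of the enrichment analyses.
* Positional enrichment: mutation events inside vs outside a position set
  (e.g. structural interface columns), against uniform position
  availability, assessed by a two-tailed Fisher exact test.
* Interface calling: residues with any cross-protein heavy-atom pair
  strictly closer than 6 Å.
* Sequence-space embedding: one-hot encoding over all 21 states of the full
  concatenated sequence, mean-centered (no scaling), PCA by `prcomp`;
  optional seeded k-means. The number of clusters is an input — the package
  reports a within-cluster inertia sweep (`kmeans_inertia_sweep()`) rather
  than fixing a value, since any specific count is a judgment call about a
  particular system.
* Diversity: the full distribution of intragroup pairwise Hamming
  distances.

## The synthetic fixtures

All quantitative guarantees are established on synthetic systems with known
ground truth: `make_toy_model()` draws fields and couplings from zero-mean
normals at stated scales (cross-boundary couplings separately scalable),
`enumerate_distribution()` computes the exact Boltzmann law for spaces up
to 1e7 sequences, `sample_synthetic_msa()` draws exact i.i.d. rows, and
`make_labeled_mutant_set()` plants an orthogonal/promiscuous structure by
rejection on the model's own cross-talk score `dE_inter(A,B*)` (default
16 + 25 labels, matching the shape of the experimental reference set).

What the fixtures emulate: the statistical structure the method relies on —
site-wise preferences, pairwise (including cross-boundary) couplings, and
score-consistent labels. What they do not emulate: phylogenetic relatedness
and sampling bias of real alignments (the fixtures are i.i.d., which is
also why the 90% identity filter — designed for redundant real data — is
not applied to them), alignment errors, gap patterns, and any biophysical
notion of binding beyond the model's own energies. Passing tests therefore
demonstrate that the machinery is correct and self-consistent, not that the
model is biologically adequate for a given family — that depends on the
real alignment's depth and divergence.

Desk-scale problem sizes used throughout tests and the acceptance script:
6-8 sites, 3-4 states, alignments of 2,000-5,000 rows, repertoires of
1e4-1e6 samples. These enumerable sizes make every check an exact-oracle
comparison and keep the full suite in the minutes range.

## Numerical choices

* Decomposition identity `e_total = e_intra_a + e_intra_b + e_inter` holds
  exactly (same summation path), and is asserted, not just documented.
* Incremental energy bookkeeping in the samplers is O(L) per proposal; its
  consistency with full recomputation is tested to 1e-9.
* The identity filter is greedy first-come in input order (deterministic);
  identity counts all columns, gap-gap matches included.
* `.` and lowercase characters in FASTA input normalize to gap/uppercase.
* Degenerate inputs fail loudly: ragged alignments name the offending
  record, unknown characters report record and position, empty MSAs and
  single-class label sets are errors, corrupt model files are rejected
  without returning a partial model.

## Limitations

* Dense coupling storage is `(Lq)^2` doubles — about 140 MB for a
  180-position concatenated alignment at `q = 21`. Adequate for the
  intended single-family scale; not for proteome-wide scans.
* Boltzmann-machine training at the reference schedule is compute-heavy by
  design; the package does not implement pseudo-likelihood or mean-field
  shortcuts (out of scope), so family-scale training is an hours-to-days
  job on one core.
* The conditional sampler's `T_2` tilt acts on the *sum* of the two
  cross-talk scores; systems that need the two chimeras penalized very
  differently would need an obvious two-temperature extension that is not
  provided.
* Scores are statistical energies of an evolutionary model, not physical
  binding free energies; decomposition into intra/inter terms approximates
  the underlying energetics.
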