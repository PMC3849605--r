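---
title: "Context-based mean-force potentials for disulfide bond prediction"
author: "CysBond maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Context-based mean-force potentials for disulfide bond prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(CysBond)
```

# The model

Disulfide bonds are covalent links between the sulfur atoms of two
cysteine residues. CysBond predicts them from sequence alone in two
stages: a per-cysteine *bonding state* classifier, then a *connectivity*
stage that scores candidate pairs among the predicted-bonded cysteines
and resolves them into a pattern in which each cysteine participates in
at most one bond (a matching).

The central modelling idea is that the local sequence neighbourhood of a
cysteine carries most of the signal about its oxidation state: cysteines
occur in short functional motifs, and residues up to three positions away
correlate strongly with bonding. These correlations are captured as
knowledge-based *mean-force potentials*.

## Context statistics

For a statistics window of `K` residues centred on a cysteine (default
`K = 7`, i.e. offsets −3 … +3), first-order statistics record the
profile-weighted probability of seeing residue type `R` at offset `k`
next to a bonded (or free) cysteine. Each cysteine contributes with
weight `PSSM(C at i)` — the profile frequency of cysteine at its own
position — and each neighbour with its profile row, so a diverged
alignment contributes fractional counts rather than hard letters.
Second-order statistics record the co-occurrence of two neighbours at
offsets `k1 < k2` (the `choose(K-1, 2) = 15` offset pairs for `K = 7`),
weighted by the triple product of profile frequencies. The window size 7
default reflects the `i ± 3` motif range (Cys-X-X-Cys and relatives);
larger windows add mostly long-range terms that accumulate sampling
noise faster than signal.

Cysteine *pairs* are treated analogously. The 2(K−1) neighbour slots of a
pair are indexed by (member, offset), where member 1 is the N-terminal
cysteine of the pair; second-order statistics range over all unordered
slot-pairs, deduplicated under the symmetry that exchanges the two
members (36 orbits for `K = 7`). The connected class accumulates over
annotated bonds, the unconnected class over all other same-chain
cysteine pairs with sequence separation ≥ 2 (disulfides link nonadjacent
cysteines); the reference state is the class sum, i.e. all sampled
pairs. Offsets truncated by the chain termini contribute to neither
numerator nor denominator of their position.

`ContextStatistics` objects store *raw* numerators and denominators.
That keeps two useful identities exact: with a single populated class
the observed and reference tables coincide, and the class-prior mixture
of the observed tables reconstructs the reference exactly (for
full-coverage windows). Pseudocount smoothing is deferred to the point
where logarithms are taken.

## Potentials

`buildPotentials()` converts smoothed probabilities into pseudo-energies
via the inverse-Boltzmann relation,

\[ U_1(R, k \mid c) \;=\; -RT\,\ln\frac{P_{\mathrm{obs}}(c \mid R(k))}{P_{\mathrm{ref}}(R(k))}, \]

and for two positions the symmetric second-order correction

\[ U_2 \;=\; -RT\,\ln\frac{P^{(2)}_{\mathrm{obs}}\;P^{(1)}_{\mathrm{ref}}(k_1)\,P^{(1)}_{\mathrm{ref}}(k_2)}
{P^{(2)}_{\mathrm{ref}}\;P^{(1)}_{\mathrm{obs}}(k_1)\,P^{(1)}_{\mathrm{obs}}(k_2)}, \]

which is exactly zero when the two neighbour positions are independent,
so `U_2` isolates the genuine two-neighbour effect rather than double
counting the marginals. `RT` defaults to 1: the absolute energy scale is
absorbed by the downstream network weights, and no claim is made about
kcal/mol.

Smoothing follows the pseudocount rule
`(w + λ·comp) / (W + λ)` with `λ = 1` unit of profile mass, where `comp`
is the corpus amino-acid composition (outer product of compositions at
second order, with one uniform pseudo-position so no residue has
composition exactly zero). This guarantees strictly positive
probabilities and finite potentials even for sparse corpora.

## Scores and encodings

A cysteine's context score for a class is the *profile expectation* of
the summed first- and second-order potentials over its window; pair
scores run over the pair's slots and slot-pair orbits. Expectation
(rather than scoring the argmax residue) mirrors the profile-weighted
statistics on the training side; this was a genuinely open choice and is
flagged here.

The bonding-state network input is a 15-residue window, 21 values per
position (20 profile frequencies plus a terminal-overlap indicator that
is 1 outside the chain), plus the two standardised context scores:
`15·21 + 2 = 317` values. The connectivity input concatenates both
windows, a 2×2 one-hot encoding of the thresholded state predictions,
and the two pair scores: `2·15·21 + 6 = 636` values. The six extra
connectivity inputs are decomposed this way by analogy with the state
encoder's two-score convention. Context scores are z-standardised with
training-set constants stored on the model (raw energies have arbitrary
scale) and clipped at ±6 standard deviations so rare extreme energies
cannot saturate the hidden layer.

## Networks and training

Both stages use a single-hidden-layer feed-forward network with logistic
hidden and output units (100 hidden nodes for states, 150 for
connectivity), trained by backpropagation on cross-entropy with
mini-batch gradient descent plus momentum and optional L2 decay. Hidden
and output activations and the stopping rule are design choices
(logistic + validation early stopping); training is deterministic given
the seed, and the analytic gradients are verified against central finite
differences in the test suite.

Two calibration choices differ between the stages, deliberately. The
state network is trained *unweighted*: its 0.5 decision threshold then
corresponds to the corpus prior (~21% bonded), which is what the fixed
threshold semantics require — inverse-frequency weighting would shift
the posterior to the balanced prior and systematically over-call
"bonded" (observed: specificity dropping from ~0.93 to ~0.49 on the
synthetic corpus). The connectivity network *is* class-weighted: its
output feeds the matcher as an edge weight, where balanced calibration
is preferable.

### Jackknife feature generation

At training time, each chain's context scores are computed from
potential tables built on the *other* chain groups (10 groups by
default). Without this, the desk-scale second-order tables — a few
profile-mass units per cell — partially memorise the very chains they
were accumulated from, the encoded score distribution at training time
diverges from the one seen at prediction time, and the connectivity
network collapses. Corpora the size of non-redundant PDB chain sets
(tens of thousands of cysteines) make this self-contribution mild, but
at a few thousand cysteines the jackknife is essential. Prediction-time
scoring always uses the full statistics.

## Connectivity resolution

Candidate pairs are all nonadjacent (separation ≥ 2) pairs of
predicted-bonded cysteines. Their predicted probabilities become edge
weights of a maximum-weight matching, computed exactly by bitmask
dynamic programming up to 22 candidate cysteines (a greedy pairing takes
over beyond that, which in practice never triggers for globular
proteins). Ties break deterministically toward the lexicographically
smallest pair. This formalises the narrative conflict-resolution rule of
two-stage predictors: an edge with the single highest probability is
rejected when the complement it forces is poorly supported.

Matched edges are kept regardless of their probability
(`minBondProb = 0`). Whether matched low-probability edges should be
filtered was an open question; the package resolves it by the
architecture's division of labour — stage 1 decides *which* cysteines
bond, stage 2 only *pairs* them — and by measurement: filtering at 0.5
routinely deletes the forced single pair of two-cysteine chains and cut
planted-bond recovery from ~0.82 to ~0.21 on synthetic corpora. The
cutoff remains exposed for users who want conservative patterns.

# Coordinates and formats

All residue positions are 1-based, in internals, file formats and
reports alike — natural for R and identical to the user-facing
convention. FASTA provides sequences; PSI-BLAST ASCII PSSMs provide
profiles, read from the *percentage* columns (the frequency
interpretation; log-odds columns are ignored), with all-zero rows
replaced by the query residue's one-hot distribution. Disulfide
annotations use a minimal tab-separated dialect
(`chain TAB pos1 TAB chain TAB pos2`), one bond per line, the form a
few lines of shell produce from DSSP SS-bridge or PDB SSBOND records;
inter-chain pairs mark their cysteines as excluded rather than bonded.
Cysteines with undetermined structure are likewise an input flag
(`excludedCys`), since no sequence-level rule can identify them.
Residues outside the 20-letter alphabet become `X`, contribute no
statistics, and carry a uniform profile row if none is provided.

# The synthetic generator

`generateCorpus()` emulates the statistical shape of a filtered,
non-redundant chain corpus: chains of 60–200 residues, cysteine density
0.035 (about 4.5 cysteines per chain, matching the ~4.9 of real filtered
chain sets), a target bonded fraction of 0.2127 (the corpus-level figure
for non-redundant PDB chain sets), profiles as Dirichlet perturbations
of the one-hot truth (concentration 50 — mild divergence, standing in
for real alignment depth we cannot reproduce), bonding labels from a
logistic model with planted (residue, offset) odds multipliers, and
connectivity as a weighted random matching with per-slot multipliers.
The intercept is calibrated iteratively against the *post-pairing*
realized bonded fraction, because the odd-cysteine relabel rule (a
drawn-bonded cysteine that finds no partner becomes free) would
otherwise bias the realized fraction far below target.

Two structural properties of this design matter for interpreting test
results:

* **Parity noise.** Whether a drawn-bonded cysteine stays bonded depends
  on the parity and pairability of the *other* draws in its chain —
  information no local-window classifier can see. At the default
  density (~1.4 bonded draws per chain) roughly a third of drawn-bonded
  cysteines are relabelled, which caps the achievable residue-level
  accuracy regardless of signal strength. The strong-signal preset uses
  density 0.04 as a compromise.
* **Draw entropy.** The planted matching is a weighted *draw*, not an
  argmax. For chains with ≥ 4 bonded cysteines, even the true planted
  weights identify the drawn pattern only ~83% of the time under the
  preset's ladders, so perfect pair prediction could not reach 100%
  recovery there. Moreover, the pairwise-probability architecture
  estimates a pooled marginal, which attenuates the within-chain ranking
  relative to the conditional (per-chain choice) model that the draw
  follows; a conditional-logit second stage would recover more, but is
  outside this architecture.

Consequently, passing end-to-end tests demonstrate that the pipeline
learns planted neighbourhood signal and resolves consistent patterns —
they do not calibrate expected accuracy on real proteins, where the
"labels" are crystallographic and the neighbourhood statistics are both
richer and subtler. Conversely, the end-to-end bond-recovery figure on
the synthetic corpus (typically 0.83–0.95 depending on the seed's share
of multi-bond chains) sits close to the generator's own draw-entropy
ceiling, not the pipeline's.

The familiar relation Qp ≤ Qc (protein-level vs residue-level accuracy)
holds whenever all chains carry equally many cysteines, and in every
evaluation this package performs; it is not a theorem for unequal
cysteine counts (two fully correct one-cysteine chains plus one fully
wrong four-cysteine chain give Qc = 1/3 < Qp = 2/3), which is why the
property tests assert it only where it is one.

# Numerical choices and degenerate inputs

* Probabilities are estimated with `λ = 1` pseudocount mass toward the
  corpus composition; logs are therefore always finite.
* A zero-weight network outputs exactly 0.5; probabilities are clamped
  away from {0, 1} only inside the cross-entropy, never in reports.
* State probabilities exactly at the threshold count as bonded (≥).
* Chains with no cysteines yield an empty state prediction and an empty
  pattern, not an error; corpora with no usable cysteines or no bonded
  pairs raise explicit empty-statistics errors.
* Metric denominators of zero yield `NA` markers, and cross-validation
  excludes such folds from the affected metric's unweighted mean with a
  warning.
* The Matthews correlation denominator is computed in double precision
  (integer counts overflow 32-bit arithmetic at corpus scale).
* K-fold splits sort chains by id before the seeded shuffle, so fold
  membership is independent of input order.

# Problem sizes

The shipped tests and the acceptance script run entirely on synthetic
data at sizes chosen to exercise every code path while completing on a
single CPU in minutes: toy corpora of ≤ 5 chains for brute-force oracle
comparisons, 500-chain corpora across 20 seeds for planted-signal
recovery, and 2000-chain corpora (1600/200/200 train/validation/test)
for the end-to-end two-stage runs.

# Known limitations

* Second-order tables at desk scale are noise-dominated per cell; the
  jackknife removes the memorisation artefact but cannot add sample
  mass. On real PDB-scale corpora the same code yields usable
  second-order signal.
* The connectivity stage scores pairs independently; chains whose
  pairing is determined by global competition (the draw-entropy point
  above) are fundamentally hard for it.
* The greedy fallback beyond 22 candidate cysteines is a heuristic;
  exact matching for such chains would need a blossom implementation.
* No attempt is made to model temperature, redox environment, or
  inter-chain disulfides (inter-chain bonded cysteines are excluded from
  statistics, following the corpus convention).
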