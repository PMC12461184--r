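---
title: "Predicting reaction barrier heights with a condensed-graph D-MPNN"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting reaction barrier heights with a condensed-graph D-MPNN}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

The barrier height (activation energy) of an elementary reaction — the energy
difference between the reactant and the transition state, in kcal/mol — is
the quantity that controls reaction rates, and computing it ab initio
requires locating a transition state, which is far more expensive than a
ground-state calculation. `cgrnn` implements a machine-learning surrogate: a
directed message-passing neural network (D-MPNN) over the condensed graph of
reaction (CGR), optionally augmented with auxiliary quantum-chemical
descriptors and with 3D positional descriptors computed from reactant,
transition-state (TS) and product conformers. The interesting scientific
question the package makes testable is *how much of the barrier is only
visible in 3D*: a 2D reaction graph cannot see the TS geometry, and the
package's synthetic benchmark quantifies exactly what is gained when TS
coordinates are supplied.

## The model

**CGR.** A reaction is given as balanced, atom-mapped, explicit-hydrogen
reaction SMILES. Both sides are parsed into attributed graphs and
superimposed: atoms are matched by atom-map index, the edge set is the union
of the reactant and product bond sets, and every atom/bond feature vector is
the concatenation of a reactant-side half and a product-side half. A bond
present on one side only has an all-zero half on the other side — the empty
bond-order one-hot block is an unambiguous absence code, so no extra
presence bit is added. Bond formation, cleavage and order change are thereby
explicit in the graph.

Per-side atom features: element one-hot (default H, C, N, O, S, F, Cl, Br,
I; out-of-list elements raise an error rather than bucketing silently),
degree (0–4 + overflow), formal charge (−2…+2 + overflow), hybridization
(S/SP/SP2/SP3/SP3D/SP3D2/other), hydrogen count (0–4 + overflow), an
aromaticity flag, and atomic mass divided by 100. Per-side bond features:
order one-hot (single/double/triple/aromatic), conjugation, in-ring flag and
smallest-ring size (one-hot 3–8, larger rings set only the flag). These are
the conventional chemprop-style encodings; which properties enter is
standard, while the exact one-hot layout is a design choice of this
package.

**D-MPNN.** For every undirected CGR edge \{v, w\} the model keeps two
directed states. With $e_{vw} = \mathrm{cat}(x_v, \text{bond}_{vw})$:

$$h^0_{vw} = W_i\, e_{vw} + b_i \qquad\text{(linear, no activation)}$$
$$h^{t+1}_{vw} = \tau\Big(h^0_{vw} + W_h \sum_{k \in N(v)\setminus\{w\}} h^t_{kv} + b_h\Big)$$
$$h_v = \tau\big(W_0\, \mathrm{cat}(x_v, \textstyle\sum_{k\in N(v)} h^T_{kv}) + b_0\big)
\qquad h_m = \mathrm{pool}(\{h_v\})$$

with $\tau = \mathrm{ReLU}$ throughout, mean pooling by default (sum
configurable) and a feed-forward head mapping $h_m$ to the scalar barrier.
The update above is the standard directed-MPNN recursion: messages flow along
directed edges and the update for $v\to w$ excludes the reverse edge's
contribution, which prevents immediate echo. Depth $T = 0$ is legal and
returns the initialized states.

Because no deep-learning framework is available in this R stack — and
because the network *is* the method — the forward pass, the analytic
backward pass and the AdamW optimizer are implemented directly in base R
matrix code. Graphs in a batch are collated into one disjoint-union graph so
each training step is a handful of dense matrix products plus `rowsum()`
scatter-adds. A deliberately naive per-edge-loop evaluator
(`dmpnn_forward_reference`) re-derives neighbor sets by scanning the edge
list and serves as an independent oracle; the test suite requires agreement
with the fast path to 1e-6 on random graphs, and the analytic gradients are
checked against central finite differences for every parameter tensor and
every embedding route.

## Extra features

Auxiliary descriptors attach to the CGR at three levels, always
reactant-half then product-half:

* **atom level** — appended to `atom_features`, with the appended column
  range tracked so the embedding routes can treat the block separately;
* **bond level** — appended to the per-edge features (plain concatenation);
* **molecule level** — stored on the graph and concatenated to $h_m$ after
  pooling, just before the FFN.

The quantum-chemical descriptor schema mirrors the published 37-descriptor
set (13 atom-level, 4 bond-level, 20 molecular-level; NPA charges, Parr
functions, NMR shieldings, valence occupancies; bond order/length, bonding
electrons, natural ionicity; energy gaps, ionization potential, electron
affinity, dipole/quadrupole moments). Entries whose published names are not
in the available text carry stable placeholder names (`mlqm_atom_07`, ...)
so column identities survive. Computing the values is delegated to table
input — the pretrained descriptor-prediction networks are out of scope — and
columns can be z-scored with training-set statistics
(`scale_extra_features`), which is advisable because raw QM descriptor
magnitudes span orders of magnitude.

Per-atom extras enter the network through one of the routes:
`route2_plain` (direct concatenation), `route1_linear_relu` (linear + ReLU
embedding), or `route1_linear_relu_attention`, which adds one residual
single-head scaled-dot-product self-attention pass over the atoms of each
molecule. Published descriptions of such attention layers leave the architecture
open; a minimal residual single-head layer is the design choice here. Each route can be placed `before_mpnn` (the embedded extras
join $x_v$ and propagate through message passing) or `after_mpnn`
(concatenated to $h_v$ just before pooling). With no extras configured the
placement flag is provably irrelevant, which the tests assert.

## 3D positional descriptors

Two analytic per-atom environment descriptors are implemented:

* **AEV** — modified Behler–Parrinello symmetry functions as used by the
  ANI potentials: per-species radial Gaussians on a shift grid under a
  smooth cosine cutoff, and per-species-pair angular terms
  $2^{1-\zeta}(1+\cos(\theta-\theta_s))^{\zeta}
  e^{-\eta_a(\bar r - R_s)^2} f_c f_c$, with the angle computed from a
  0.95-scaled cosine as in the ANI implementations (this keeps `acos` away
  from its singular endpoints, so collinear triples — ubiquitous in
  transition-state geometries — stay numerically stable under rigid
  motions). Defaults: radial cutoff 5.2 Å with
  16 shifts ($\eta = 16$), angular cutoff 3.5 Å with 8 angle × 4 distance
  shifts ($\zeta = 32$, $\eta_a = 8$) — the reference implementations'
  grids. The descriptor families fix the functional form, not the
  hyperparameters, so these defaults are configurable choices.
* **SOAP** — a smooth-overlap power spectrum in the point-density limit:
  each neighbor contributes a Gaussian radial-basis evaluation times real
  spherical harmonics (degree ≤ `l_max`, default 4; `n_max` = 6 radial
  functions to 5.0 Å), and the reported features are the per-species-pair
  power spectra $p_{nn'l} = \sum_m c_{nlm} c_{n'lm}$, which are exactly
  rotation- and translation-invariant. Associated Legendre polynomials come
  from `pracma`.

Both are invariant to rigid motions to better than 1e-8 and exactly local:
atoms beyond the cutoff contribute nothing. Learned descriptors
(MACE/Equiformer hidden states) enter only through a provider interface — a
function or table keyed like a conformer — since re-running foundation
models is out of scope. Conformers are read from standard XYZ files whose
comment line carries `id=... role=<r|ts|p> maps=...`; rows are realigned
from file order to CGR atom order via the map metadata, and role blocks are
always concatenated in the fixed order r, ts, p regardless of request order
so column semantics stay stable. A missing conformer is a hard error; an
explicit `impute_missing` flag substitutes a zero block for ablation
studies. For multi-fragment sides one combined coordinate block per role is
used, so inter-fragment terms within the cutoff are included.

## Data splitting

* `random_split` — seeded shuffle, validation/test sizes are floors of their
  fractions, remainder to train (100 ids at 0.90/0.05/0.05 give 90/5/5).
* `core_split` — reactions are clustered by a canonical reaction-core key:
  the bonds formed, broken or order-changed plus their endpoint atoms
  (environment radius 0, the strictest reading of a "common core"),
  serialized from Weisfeiler–Lehman-refined labels so the key is stable
  under relabeling. Whole clusters are routed greedily: a cluster goes to
  validation or test only while it fits that partition's remaining deficit,
  otherwise to train — so a dominant cluster lands in train and realized
  fractions (recorded in the provenance) may deviate from the targets. WL
  refinement can in principle merge non-isomorphic cores; on tiny cores this
  is practically irrelevant and any collision only merges clusters, which is
  conservative (never leaks).
* `barrier_split` — sort by barrier (ties broken by id), lowest extreme to
  validation and highest to test by default; which extreme goes where is
  pure convention, so it is configurable and recorded in the split
  provenance.

All splitters return disjoint, covering, seed-deterministic partitions and
serialize to JSON.

## Training protocol

AdamW ($\beta_1 = 0.9$, $\beta_2 = 0.999$, $\epsilon = 10^{-8}$), batch
size 50, cosine-annealed learning rate with a 10-step linear warmup.
Warmup "steps" could be read as optimizer steps or epochs; here the
scheduler ticks once per epoch, which keeps the warmup a fixed fraction of
desk-scale runs. The loss is mean squared error on z-scored targets
(standardized with training-partition statistics; predictions are un-scaled
back to kcal/mol for reporting); MSE is the natural partner of RMSE-oriented
evaluation. Decoupled weight decay defaults to 0 and gradient
clipping is off by default; both are configurable. Model selection keeps the
checkpoint with the lowest validation MAE. With a fixed seed, runs are
bit-reproducible: initialization, batch shuffling and dropout all draw from
one seeded stream.

Permutation feature importance permutes one extra-feature column at a time
across the evaluation set (5 seeded repeats by default; reactant-side and
product-side tables are shuffled with independent draws) and reports the
mean change in MAE against the unpermuted baseline. A column the model
provably ignores (zero downstream weights) gives a delta of exactly 0;
negative deltas are legal and mark features that hurt the model.
`select_feature_subset` narrows a dataset to named columns for
top-k retraining, and `config_grid_search` is a plain declarative grid hook
(no Bayesian optimization).

## The synthetic benchmark

`generate_fixtures` emulates the statistical shape of reaction datasets
without any download: templated hydrogen-transfer reactions
R1–H + R2 → R1 + R2–H over a C/N/O alphabet (plain and methyl-substituted
centers), balanced, atom-mapped, explicit-H, with crude tetrahedral r/TS/p
geometries. Barriers follow

$$\Delta E^\ddagger = \beta_0 + \beta_\mathrm{brk}[X] + \beta_\mathrm{frm}[Y]
 + \gamma\, d_\mathrm{TS} + \varepsilon,$$

where $d_\mathrm{TS}$, the forming-bond H⋯Y distance in the TS, is uniform
on 1.0–2.2 Å and independent of everything the 2D graph can see, and
$\varepsilon \sim N(0, \sigma^2)$. Defaults: $\beta_0 = 8$,
$\beta_\mathrm{brk} = (10, 7, 4)$ and $\beta_\mathrm{frm} = (-6, -3, 0)$
kcal/mol for C/N/O, $\gamma = 6$ kcal/mol/Å and $\sigma = 0.5$ kcal/mol, so
the geometry term's standard deviation is ≈ 2 kcal/mol — large enough that
the with/without-coordinates gap is detectable at n = 2000 in minutes on one
CPU. Because $d_\mathrm{TS}$ is independent of the graph, the best possible
coordinate-blind predictor has residual
$\gamma(d - \bar d) + \varepsilon$, whose expected absolute value
`geometry_mae_floor()` computes by numerical integration (≈ 1.83 kcal/mol at
the defaults); supplying TS positions through AEV features is the only way
below that floor. Geometry signal deliberately enters *only* through the TS,
mirroring the empirical finding that TS positions are the informative role.
Conformer file order is shuffled per record so alignment code is always
exercised, each conformer gets a random rigid motion, and every record
retains its generative components so `barrier_oracle` can round-trip the
formula exactly.

What the fixtures do *not* emulate: chemically realistic TS geometries or
energetics, conformer ensembles, heavy-atom rearrangements, charged or
radical-specific electronics beyond formal charge, and the long-tailed
barrier distributions of real datasets. A model passing the fixture suite is
therefore validated as *machinery* — featurization, propagation, training,
splitting, importance — not as a chemistry-accurate predictor; accuracy
claims require the real benchmark sets.

## Numerical choices and degenerate inputs

* Weight init: uniform fan-in $U(\pm 1/\sqrt{d_\mathrm{in}})$, seeded; bias
  terms in every linear map (including the message-passing update).
* Edge initialization is linear without activation; all other layers ReLU.
* An identity reaction (no changed bonds) is a degenerate core and a hard
  error in `reaction_core_key`.
* Isolated atoms are legal: their incoming-message sum is the zero vector.
* Smallest-ring detection caps at 12; ring-size one-hots cover 3–8, larger
  rings set only the in-ring flag.
* Hybridization is assigned by a deterministic valence heuristic (triple or
  cumulated double → SP, any double/aromatic → SP2, hypervalent degree →
  SP3D/SP3D2, else SP3; hydrogens S): the restricted parser does not run a
  full perception algorithm, and the heuristic is documented rather than
  hidden.
* Ties in the barrier split break by id; batch shuffling and all other
  randomness derive from the run seed.

## Problem sizes used in the checks

The packaged checks run at desk scale, chosen so the whole suite finishes in
minutes on one CPU: oracle agreement on 50 random ≤ 6-atom graphs;
invariance under 20 rigid motions per conformer; parameter recovery and the
coordinate-gap experiment on n = 2000 fixtures with h = 64, T = 3, 30
epochs, batch 50; importance on n = 400 with h = 32, T = 2, 15 epochs. The
`scripts/acceptance.R` entry point recomputes all of these from scratch and
writes them as JSON.

## Known limitations

* The restricted SMILES parser covers the mapped, balanced, explicit-H
  grammar the pipeline requires (brackets, branches, ring closures, dots,
  aromatic subset) — it is not a general SMILES implementation, performs no
  aromaticity perception beyond lowercase notation, and ignores
  stereochemistry by design.
* SOAP is implemented in the point-density (delta-smearing) limit; absolute
  values differ from Gaussian-smeared implementations, while the symmetry
  and locality properties are identical.
* Training is single-CPU dense linear algebra: ideal for thousands of small
  reactions, not for production-scale datasets.
* The ml-QM descriptor *values* must be supplied as tables; only the schema
  and the attachment machinery are implemented here.
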