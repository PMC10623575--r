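---
title: "Function-based ligand screening with LRIPs: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Function-based ligand screening with LRIPs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lripscreen)
```

# The problem and the model

Binding affinity alone does not tell you whether a GPCR ligand is an
agonist or an antagonist: both can bind tightly, in the same pocket.  The
premise of this package is that *function follows the interaction
pattern*: agonists of a receptor engage a characteristic set of residues
of the active-state structure, antagonists a different set of the
inactive-state structure.  That pattern is captured by the
**ligand-residue interaction profile (LRIP)** — the vector of
ensemble-averaged interaction energies between the ligand and each
receptor residue.

## Per-residue energy decomposition

Given a snapshot of a receptor-ligand complex, the interaction energy
attributed to receptor residue $r$ is

$$E(r) \;=\; \underbrace{\sum_{i \in \mathrm{lig}}\sum_{j \in r}
\frac{k\,q_i q_j}{\epsilon_{in} r_{ij}}}_{\text{Coulomb}}
\;+\; \underbrace{\sum_{i \in \mathrm{lig}}\sum_{j \in r}
\epsilon_{ij}\!\left[\Big(\tfrac{R_{min,ij}}{r_{ij}}\Big)^{12}
- 2\Big(\tfrac{R_{min,ij}}{r_{ij}}\Big)^{6}\right]}_{\text{Lennard-Jones}}
\;+\; \Delta G_{GB}(r),$$

with $k = 332.0636$ kcal·Å/(mol·e²),
$R_{min,ij} = R_{min,i}/2 + R_{min,j}/2$ and
$\epsilon_{ij} = \sqrt{\epsilon_i\epsilon_j}$.  The polar solvation
cross-term uses the Still pairwise generalized-Born form

$$\Delta G_{GB} = -\frac{k}{2}\Big(\frac{1}{\epsilon_{in}} -
\frac{1}{\epsilon_{out}}\Big)\sum_{i,j}
\frac{q_i q_j}{f_{GB}(r_{ij}, R_i, R_j)},\qquad
f_{GB} = \sqrt{r_{ij}^2 + R_i R_j e^{-r_{ij}^2/4R_iR_j}},$$

where the effective radii $R_i$ come from Hawkins-Cramer-Truhlar (HCT)
pairwise descreening: the inverse effective radius is the inverse
intrinsic radius minus the analytic integral of the Coulomb-field
approximation over each neighbour's screened sphere
($s_j = S_j\,\rho_j$).  Effective radii are computed on the *complex*
snapshot, so a residue's GB cross-term feels the ligand-induced
desolvation of its environment.  The full unordered-pair GB term of each
(ligand atom, residue atom) pair is assigned to that residue; self terms
and all receptor-receptor / ligand-internal terms are excluded.  This
makes the decomposition exactly additive: summing $E(r)$ over residues
reproduces the total intermolecular Coulomb + LJ + GB-cross energy of the
snapshot (a tested invariant, tolerance $10^{-6}$ kcal/mol).

Averaging $E(r)$ with uniform weights over the snapshot ensemble gives
the LRIP.  Snapshots are "evenly collected": a stride $s$ over $n$ frames
keeps exactly $\lceil n/s\rceil$ frames in order.

## Signatures and similarity

A residue is a **key residue** of a profile when its energy is stronger
than $-0.1$ kcal/mol, read as $E(r) \le -0.1$ (favourable-interaction
convention; the boundary is included — the sources never exhibit a
boundary case, so we declare inclusion once and test it).  The
**signature** of a (receptor, state) pair is the per-residue mean of the
reference ligands' LRIPs over the combined key-residue set.  Design
choices here, each taken once and tested:

* **Union vs intersection** of key residues: union by default (keeps
  every hotspot any reference sees), intersection by flag.
* **Missing residues fill with 0 kcal/mol**, not removal: vectors stay
  aligned across compounds and a compound lacking a signature hotspot is
  penalized rather than silently excused.
* The "small deviations" selection of signature residues is unquantified
  in the source protocol; it is exposed as an optional `sd_cap` (drop
  residues whose cross-reference sd exceeds the cap) with default *no
  cap*.
* **Sample sd** (n−1 denominator) across references; a single reference
  gets sd 0.

Similarity of a query LRIP $q$ to a signature $m$ over the signature's
$p \ge 3$ residues:

$$R = \mathrm{cor}(q, m),\quad
\mathrm{ASE} = \overline{q - m},\quad
\mathrm{AUE} = \overline{|q - m|},\quad
\mathrm{RMSE} = \sqrt{\overline{(q-m)^2}}.$$

Pearson correlation, not Spearman: the decision threshold is quoted as
$R > 0.84$, equivalently $R^2 > 0.7$, which presumes a linear
correlation.  "ASE" is implemented as the *signed* mean error — the only
reading that complements AUE and RMSE.  RMSE ≥ AUE ≥ |ASE| holds for
every input (Jensen / triangle inequalities; property-tested).  If
either vector has zero variance, $R$ is undefined; the record is flagged
and fails the correlation gate downstream rather than erroring.

## Binding energy and the decision flow

The end-point binding energy uses the single-trajectory protocol: each
component is $E(\mathrm{complex}) - E(\mathrm{receptor}) -
E(\mathrm{ligand})$ on *identical* coordinates, so internal bonded terms
cancel identically and never need to be computed:

$$\Delta E = \Delta E_{ele} + \Delta E_{vdw} + \Delta G^{sol}_{p}
+ \Delta G^{sol}_{np}, \qquad \Delta G = \Delta E - T\Delta S.$$

$\Delta G^{sol}_{np} = \gamma\,\mathrm{SASA} + \beta$ per system
(Shrake-Rupley areas on a deterministic golden-spiral lattice);
$T\Delta S$ is a pluggable weighted-SASA (WSAS) linear model
$S = \sum_a w(\mathrm{type}_a)\,\mathrm{SASA}_a + c$.  The cited WSAS
parameterization is not reproduced in the sources, so the default weight
set is zero — $T\Delta S = 0$ and $\Delta G$ reduces to $\Delta E$ —
with the estimator fully configurable.  Default strides mirror the
published protocol: energy components on every retained snapshot, the
entropy estimate on an evenly spaced 1-in-25 subsample (5000 → 200).

The classifier applies four gates in screening order — docking pass, MD
stability, $R > 0.84$, $\Delta E < -10$ kcal/mol — all strict
("larger than", "better than").  Docking and MD stability enter as
precomputed booleans because docking and simulation are out of scope and
the "decent docking score" criterion has no stated cutoff.  The source
protocol is ambiguous about whether the $-10$ kcal/mol gate consumes
$\Delta E$ (MM-GBSA) or $\Delta G$ (with entropy); both are reported, and
the gate defaults to $\Delta E$, which is what the decision-flow chart
names.  Non-agonists are subclassified as antagonist candidates when an
inactive-state correlation is supplied and exceeds the threshold — an
extension; the original protocol lumps antagonists and undetermined
compounds together.

Published percentages are reproduced with nearest-integer rounding
(29/42 → 69%, 16/26 → 62%).  The sources also print "70%" for the same
29/42 ratio in summary passages; this package reports one rounding (69)
and notes the discrepancy here rather than switching per context.

# Numerical choices

| Parameter | Default | Unit | Why |
|---|---|---|---|
| `eps_in` | 1.0 | — | standard MM interior dielectric |
| `eps_out` | 78.5 | — | water at 298 K |
| `coulomb_k` | 332.0636 | kcal·Å/(mol·e²) | AMBER-compatible constant |
| `sasa_gamma` | 0.0072 | kcal/(mol·Å²) | common GBSA surface tension |
| `sasa_beta` | 0.0 | kcal/mol | no offset |
| `probe_radius` | 1.4 | Å | water probe |
| `sasa_points` | 960 | — | ≤1% sphere-area error, deterministic |
| key-residue threshold | −0.1 | kcal/mol | stated protocol value |
| `r_threshold` | 0.84 | — | stated protocol value ($R^2 > 0.7$) |
| `de_threshold` | −10 | kcal/mol | stated protocol value |

None of the dielectric/surface constants are stated by the source
protocol (which used AMBER defaults upstream); they are declared here,
not inferred, and all are configurable.  The Poisson-Boltzmann polar
term of the published MM-PBSA totals is approximated by GB throughout:
the decision rule consumes energies at kcal/mol granularity, the LRIP
itself is GBSA-based in the source protocol, and no PB solver is in
scope.  Degenerate inputs are hard errors (overlapping atoms, missing
parameter rows, inconsistent snapshot atom ordering, empty ligand,
nonpositive effective radii) — this is a screening tool, silently
"fixing" a broken ensemble would corrupt downstream calls.  SASA is
exactly deterministic for a fixed lattice size; no randomness enters any
energy path.

# What the synthetic generator emulates — and what it does not

`make_toy_complex()` builds a ring of receptor residues (8 × 3 atoms by
default) around a compact 6-atom ligand, with partial charges uniform in
[−0.5, 0.5] e shifted so each segment's net charge is an exact integer,
LJ/GB parameters inside physical ranges, and snapshots formed by seeded
Gaussian jitter (sd 0.15 Å by default — the scale of heavy-atom thermal
fluctuation about a bound pose).  It emulates: multi-snapshot averaging,
per-residue locality of interactions, and realistic parameter magnitudes.
It does **not** emulate: real protein geometry, correlated collective
motions, conformational transitions, charged-residue salt bridges, or
binding-competent poses — the toy ligand binds weakly (positive ΔE), so a
green decomposition test establishes *energetic bookkeeping correctness*,
never predictive accuracy on real receptors.  Likewise
`simulate_profiles()` draws profiles whose *sample* correlation with a
signature equals the target ρ exactly before residue-wise Gaussian noise
is added (an exact Gram-Schmidt construction; stricter than a
population-level target and still converging to ρ as noise → 0).  The
Gaussian noise model is declared scaffolding for metric property tests,
not a claim about MM-GBSA error structure.

The packaged 42-compound evaluation fixture is *count-faithful, not
value-faithful*: only a few compound identities (6, 8, 38, 39, 40) are
recoverable from the published text, so the remaining rows carry
synthetic ids flagged `provenance = synthetic`, including one synthetic
antagonist row required to meet the printed "3 correct antagonists"
count.  Regenerating the published per-compound LRIPs or the R values of
the supplementary tables would require the original ~115 ns
membrane-embedded GPCR trajectories and is out of scope by design; those
values are covered as fixtures and I/O examples only.

# Known limitations

* GB replaces PB for the polar term everywhere; absolute ΔE values will
  differ from PB-based totals by a method-dependent offset.
* No distance cutoffs and exact O(N²) sums: correct and
  oracle-comparable at toy scale, not tuned for 10⁵-atom systems.
* The HCT radii use no intrinsic-radius offset; AMBER's 0.09 Å offset
  convention can be emulated by adjusting the input `gb_radius` column.
* Ballesteros-Weinstein labels are user-supplied opaque strings; the
  package never computes them.
* Ensembles must be pre-stripped to the complex (no solvent/lipid
  handling, no periodic imaging).
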