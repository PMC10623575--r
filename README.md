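# lripscreen

Function-based virtual screening for GPCR ligands: does a candidate
compound *activate* a receptor (agonist) or merely occupy it?  Structure-based
docking scores binding strength but is largely blind to function.
`lripscreen` implements a screening protocol that decides function from the
*pattern* of per-residue interaction energies — the ligand–residue
interaction profile (LRIP) — rather than from the total affinity alone.  It
was designed around cannabinoid receptor (CB1/CB2) agonist discovery, where
CB2-selective agonists are therapeutically attractive and CNS side effects
from CB1 activation must be avoided, but nothing in the code is specific to
cannabinoid receptors.

## The method

For a receptor–ligand complex sampled by MD (here: any multi-model PDB
ensemble), the intermolecular energy is decomposed per receptor residue *r*
in the MM-GBSA fashion:

    E(r) = E_ele(r) + E_vdw(r) + ΔG_GB(r)        [kcal/mol]

with Coulomb and Lennard-Jones 12-6 terms summed over ligand×residue atom
pairs and the polar solvation cross-term from the Hawkins–Cramer–Truhlar
(HCT) pairwise-descreening generalized Born model with the Still
interpolation formula.  Snapshot averages of E(r) form the LRIP.  *Key
residues* are those with LRIP ≤ −0.1 kcal/mol; averaging the key-residue
energies of reference agonists (active state) or antagonists (inactive
state) yields a *signature profile*.  A query compound is compared to the
signature with four metrics — Pearson R (and R²), RMSE, AUE, ASE — and the
decision flow calls it an **agonist** iff it passes, in order:

1. docking gate (precomputed boolean),
2. MD-stability gate (precomputed boolean),
3. R > 0.84 against the active-state agonist signature (strict),
4. binding energy ΔE < −10 kcal/mol (strict),

where ΔE is the single-trajectory MM-GBSA total
ΔE = ΔE_ele + ΔE_vdw + ΔG_p + ΔG_np, optionally extended to
ΔG = ΔE − TΔS with a weighted-SASA (WSAS) entropy estimator.  Everything
else is a non-agonist (antagonist candidate when the inactive-state
correlation exceeds the threshold, otherwise undetermined).

## Worked example

A seeded toy complex (8 ring residues around a 6-atom ligand, thermal
jitter 0.15 Å) exercises the whole pipeline:

```r
library(lripscreen)

ens  <- make_toy_complex(n_snapshots = 20, seed = 1)
rows <- decompose_ligand_residue(ens)
prof <- build_profile(rows, compound_id = "toy1", receptor_state = "CB2_active")
prof
#> LRIP for toy1 ( CB2_active ), 8 residues, mean over 20 snapshot(s)
#>      R1      R2      R3      R4      R5      R6      R7      R8
#>  0.1704 -0.2628 -0.3642  0.4583 -0.1900 -0.3982 -0.3426  0.2905

sig <- build_signature(simulate_profiles(
  build_signature(list(prof)), rho = 0.95, noise_sd = 0.05,
  n_compounds = 3, seed = 7))
similarity(prof, sig)
#> Similarity over 5 residues: R = 0.9169  R2 = 0.8407  RMSE = 0.0320  AUE = 0.0255  ASE = -0.0085

rep <- binding_energy(ens, stride_de = 1, stride_tds = 5)
rep$de_total
#> [1] 0.2014

classify(compound_evidence("toy1", TRUE, TRUE,
                           r_active = 0.9169, de = 0.2014))
#> toy1 -> NON_AGONIST (UNDETERMINED)
#>   gates: docking:pass  md_stability:pass  r_active:pass  binding_energy:fail
```

The LRIP shows five residues interacting at ≤ −0.1 kcal/mol (the key
residues entering the signature); the profile correlates with its
signature at R = 0.92 (passing the 0.84 gate) but the toy complex binds
far too weakly (ΔE = +0.2 kcal/mol, nowhere near −10), so the decision
flow correctly refuses to call it an agonist.

Evaluating the packaged 42-compound prediction/assay fixture reproduces
the published summary:

```r
ev <- paper_fixture("evaluation_42")
evaluate(ev[c("compound_id", "predicted")], ev[c("compound_id", "truth")])
#> Evaluation over 42 compounds
#>   predicted agonists:      26 (of which 16 confirmed agonists; success 62%)
#>   predicted non-agonists:  16 (3 confirmed antagonists, 10 confirmed inactive)
#>   overall accuracy:        69%
```

## Command line

The same workflow is scriptable via `exec/lrip`
(`Rscript exec/lrip <command>` from a checkout, or the installed
`exec/lrip` after installation):

```sh
lrip simulate-complex --seed 1 --n-snapshots 20 --out toy/
lrip decompose toy/complex.pdb toy/params.tsv toy/labels.tsv --out rows.tsv
lrip profile rows.tsv --id toy1 --state CB2_active --out toy1.profile.tsv
lrip signature ref1.tsv ref2.tsv --rule union --out cb2_active.sig.tsv
lrip compare toy1.profile.tsv cb2_active.sig.tsv
lrip classify evidence.tsv --out calls.tsv
lrip evaluate calls.tsv outcomes.tsv
```

## Scope

The package starts from *pre-computed* conformational ensembles: docking,
MD simulation, topology building, RESP charges, and Poisson–Boltzmann
solvation are out of scope (the polar term is always generalized Born).
The published per-compound LRIP tables cannot be regenerated without the
original ~100 ns membrane-GPCR trajectories; they ship as plain-text
fixtures instead (`paper_fixture()`).  See `vignettes/lrip-methods.Rmd`
for the model details, parameter defaults, and limitations.
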