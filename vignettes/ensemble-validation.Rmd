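---
title: "Validating NMR ensembles: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating NMR ensembles: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nmrvalid)
```

This vignette explains what `nmrvalid` computes, the assumptions and
conventions behind each step, why the defaults are what they are, and
what the synthetic test fixtures do and do not demonstrate about real
deposited data.

## The validation problem

An NMR structure determination produces an *ensemble* of conformers,
all consistent with the experimental restraints. Validation therefore
has two distinguishable questions: **precision** (how similar are the
conformers to each other?) and **accuracy against data** (how well does
each conformer satisfy the distance restraints, dihedral restraints,
residual dipolar couplings and chemical shifts?). `nmrvalid` answers
both per residue and aggregates the evidence into a red/orange/green
verdict.

Atoms are addressed throughout by the triple (chain, author residue
number, atom name), written `"A/5/HB2"`. Insertion codes are rejected,
which keeps these keys totally ordered; entries using insertion codes
must be renumbered upstream. Alternate locations other than blank/`A`
are dropped (NMR entries rarely carry altlocs), and hydrogens are kept
because NOE and RDC data live on them.

## Ensemble precision

### Dihedral order parameter

For residue-level precision we use a circular order parameter over the
backbone dihedrals $\gamma_{ij}$ (angle type $i$ of $M$, conformer $j$
of $N$):

$$ s_i = \left(\tfrac1N\sum_j \cos\gamma_{ij}\right)^2 +
         \left(\tfrac1N\sum_j \sin\gamma_{ij}\right)^2, \qquad
   S^2 = \tfrac1M\sum_i s_i . $$

$s_i$ is the squared length of the mean resultant vector of circular
statistics: 1 when the angle is identical in all conformers, tending to
0 for angles spread uniformly. **Design choice:** each angle type gets
its own $s_i$ and $S^2$ is their arithmetic mean, rather than pooling
all angles into a single resultant. Pooling would conflate *between
angle-type* differences (φ and ψ legitimately differ by ~100° in a
helix) with *between conformer* scatter, which is the quantity of
interest; the per-angle form is also the one consistent with indexing
the angle types separately from the conformers. Angles undefined in any
conformer (termini, missing atoms) drop that angle type from $M$; a
residue with no complete angle type gets a null $S^2$. A single-model
ensemble returns 1 with a warning, since no dispersion is observable.

Dihedrals are computed from the standard four-atom torsions (φ, ψ for
proteins; α–ζ for nucleotides) via `atan2`, degrees in (−180, 180];
near-collinear geometry (cross-product norm < 1e−9) makes the angle
undefined with a warning rather than returning numerical noise.

### Superposition, clustering and the representative model

Pairwise model RMSDs use Kabsch superposition on backbone heavy atoms
(N, CA, C, O for proteins; P, O5′, C5′, C4′, C3′, O3′ for nucleic
acids). The SVD-based solution corrects reflections through the sign of
$\det(VU^\top)$, so the rotation is always proper; rank-deficient
(collinear) point sets are an error. Models are clustered by
average-linkage agglomeration on that matrix, cut at 2.0 Å — a
deliberately simple, reproducible procedure (cutoff configurable via
`nmr_config(cluster_cutoff_A=)`); 2.0 Å separates genuinely distinct
backbone conformations while tolerating ordinary ensemble scatter. Each
cluster's representative is its *medoid* (minimum summed RMSD to the
other members) and the ensemble representative is the medoid of the
largest cluster, ties broken toward the lower model id. The
representative — not model 1 — is the reference conformer for secondary
structure, solvent accessibility and the RDC unit-convention probe,
since deposition order carries no meaning. If all pairwise RMSDs fall
below the cutoff the ensemble is trivially one cluster (this also
avoids cutting a degenerate zero-height dendrogram).

## Restraint validation

Distance restraints may be ambiguous: several candidate atom pairs per
restraint, combined as $d_\mathrm{eff} = (\sum_p d_p^{-6})^{-1/6}$, the
r⁻⁶ sum-average appropriate for NOE intensities. $d_\mathrm{eff}$ is
always ≤ the shortest member distance and can only decrease as members
are added — both properties are tested. Bounds are closed:
$d_\mathrm{eff}$ exactly at a bound is satisfied. Violation magnitude
is the distance past the nearer bound, evaluated per model and
aggregated (count, max, mean over violating models).

Sequence-range classes follow the standard convention — intra-residue,
short (1–2 apart), medium (3–4), long-range (≥5). For ambiguous
restraints the class uses the **maximum** separation over member pairs,
and inter-chain pairs are long-range: a restraint is as informative as
its longest-reaching interpretation, which is the conservative choice
for "how much does this restraint position remote parts of the chain".
Long-range counts credit **both** endpoint residues once per restraint
(not once per member pair); per-residue graphs made from these counts
are therefore symmetric in the two partners.

Dihedral restraints are arcs traversed counter-clockwise from lower to
upper; `lower > upper` legally encodes wrapping through ±180°. A
violated angle's magnitude is the shortest angular distance (≤180°) to
the nearer arc endpoint. Models where the angle is undefined are
skipped and counted separately rather than treated as satisfied or
violated.

## RDC alignment-tensor fits

Each coupling contributes a linear equation
$D = \mathbf{a}\cdot\mathbf{s}$ with design row
$\mathbf{a} = (x^2{-}z^2,\; y^2{-}z^2,\; 2xy,\; 2xz,\; 2yz)$ from the
unit internuclear vector and unknowns
$\mathbf{s} = (S_{xx}, S_{yy}, S_{xy}, S_{xz}, S_{yz})$,
$S_{zz} = -S_{xx}-S_{yy}$ enforcing tracelessness. The system is solved
by SVD pseudo-inverse; at least 5 couplings are required, and a design
condition number above 1e6 (e.g. all bond vectors parallel) flags the
fit as degenerate rather than failing. One tensor is fitted per model
per alignment medium; vectors come straight from each model's
coordinates with no librational correction.

Mixed-type couplings are first normalised to the N–HN scale with
$(\gamma_N\gamma_H/r_{NH}^3)/(\gamma_A\gamma_B/r_{AB}^3)$; the shipped
bond table uses $r_{NH}=1.02$ Å, $r_{CH}=1.09$ Å, $r_{NC'}=1.329$ Å and
signed gyromagnetic ratios (¹⁵N negative), all conventions rather than
results, and editable via `nmr_config(bond_table=)`. When a medium
contains ≥2 types, both the "raw" and "already prescaled" hypotheses
are fitted and the lower Cornilescu Q decides; with a single type the
two differ only by an overall factor, so "raw" is returned by
convention and both Q values are recorded in the report.

Conventions: eigenvalues ordered $|\lambda_1|\le|\lambda_2|\le
|\lambda_3|$, $D_a = \lambda_3/2$,
$R = 2(\lambda_1-\lambda_2)/(3\lambda_3) \in [0, 2/3]$ — the standard
alignment-tensor convention. $Q = \mathrm{rms(obs-calc)}/
\mathrm{rms(obs)}$ (the original form); the variant normalised by
$\sqrt{2D_a^2(4+3R^2)/5}$ is available via
`nmr_config(rdc_q_norm = "da")`. Pearson R is null when the observed
values have zero variance; Q is null when all observed values are zero.
Principal axes are sign-normalised (largest component positive), so
eigenvector sign flips cannot leak into report diffs. Both per-model
tensors and ensemble statistics of calculated couplings (mean, sd,
min, max per constraint) are emitted, since either view can be the one
a reader needs.

## Chemical-shift validation

A two-step procedure. **Step 1, re-referencing:** for each nucleus
class (¹H, ¹⁵N, ¹³C_aliphatic, ¹³C_aromatic, ¹³C′), the offset is the
median of (observed − reference mean) over all shifts of that class
with a matching reference entry, requiring at least 10 matched atoms
(below that the offset is 0 with a warning — a handful of atoms cannot
support a systematic correction). The median, rather than a fit against
a hand-curated correctly-referenced corpus, is a deliberate
replacement: it is robust to the very outliers step 2 is meant to find,
and it makes the reference table the only external input. **Step 2,
Z-scores:** $z = (\delta_\mathrm{obs} - \mathrm{offset} - \mu)/\sigma$
against the environment-matched reference entry, used only when that
entry aggregates ≥ 10 observations; $|z| > 3$ (strictly) flags an
outlier. The display color ramps from green (|z| ≤ 2) through yellow
(3.5) to red (≥ 5), linear in |z| per channel.

The *environment* conditioning the lookup is deliberately coarse:
secondary structure H/E/C from the representative model's φ/ψ (helix
window φ∈(−100,−30), ψ∈(−80,−5); strand window φ∈(−180,−45),
ψ∈(90,180]∪(−180,−150); otherwise coil, termini coil), and a two-bin
relative solvent accessibility — heavy-atom Shrake–Rupley ASA (probe
1.4 Å, 256 deterministic golden-spiral points per atom) divided by the
residue's Gly-X-Gly maximum, buried below 0.20. Finer binning would
demand far larger reference tables than users typically have; both the
bin edges and the minimum counts are config-exposed.

Aromatic ring currents are **not** modelled. Instead residues with any
atom within 5 Å of another residue's ring centroid (PHE/TYR/TRP six-
and HIS five-membered rings) are marked `near_aromatic`, so that
outliers there can be discounted by the reader.

## ROG scoring

A residue is **red** when any distance restraint touching it is
violated by > 0.5 Å in ≥ 50% of models, any dihedral restraint by
> 20°, or any shift has |Z| > 5; **orange** for the same with 0.3 Å /
10° or 3 < |Z| ≤ 5; **green** otherwise. The ≥ 50%-of-models rule
makes the score an ensemble property: a restraint flickering in one
conformer of twenty should not condemn a residue. The thresholds are
original defaults, live in the config, and are embedded verbatim in
every report, so a score can always be traced to its rule. Every fired
trigger is listed in the residue's rationale, and scoring is monotone:
worsening any single piece of evidence never moves a residue toward
green (property-tested).

## Report format

Reports are strict JSON (no NaN; null for undefined), UTF-8, fixed key
order, full numeric precision — two runs on the same inputs are
byte-identical, which makes reports diffable artifacts. The shipped
schema (`report_schema_path()`) documents the structure;
`check_report_schema()` enforces the load-bearing parts (required keys,
enums, S² range). Per-model violation detail is off by default
(`per_model = TRUE` to include) to bound file size.

## The synthetic fixtures: what they show and what they don't

The generator builds poly-alanine chains from ideal internal
coordinates (φ = −57°, ψ = −47°, standard bond lengths/angles, NeRF
chain extension), jitters each model with isotropic Gaussian noise, and
can plant: a two-conformation split (hinge rotation of the C-terminal
half in half the models), restraint violations of stated size (bounds
tightened past the reference-model truth), an alignment tensor of
stated $D_a$ and $R$ (couplings computed exactly from the design
matrix, optional noise, raw or prescaled), per-class referencing
offsets and +k·σ shift outliers. All randomness flows from one seed,
recorded in file headers; identical spec + seed gives byte-identical
files.

Fixture conditions used by the tests and the acceptance script (sizes
chosen as the smallest that exercise every code path with comfortable
statistical margins): 20 residues, 10 models; jitter 0.05 Å for
precision/shift fixtures and 0.02 Å for the violation and RDC fixtures,
so that planted 1.0 Å / 20° violations dominate the jitter and nothing
else crosses its ±0.5 Å / ±20° bounds; the clustered preset uses a 60°
hinge, far beyond the 2.0 Å cutoff; RDC recovery uses 30 couplings,
noise studies 200 replicates at σ = 1 Hz; shift false-positive rates
pool 10 seeds (~1100 nominal atoms). One caveat worth knowing: planted
violation magnitudes are defined relative to the reference model, so
the measured maximum over models is the planted size plus model
jitter — for dihedrals that jitter is a few degrees at σ = 0.02 Å.

What passing these tests demonstrates: the estimators recover known
ground truth exactly in the noiseless limit, degrade unbiasedly under
noise, and the bookkeeping (classification, counting, aggregation,
serialisation) is internally consistent. What they do **not**
demonstrate: behaviour on real data with heterogeneous chemistry
(side-chain NOEs, prolines and glycines with their own shift
statistics, genuine coil regions), mis-assigned restraints, incomplete
atom nomenclature, or reference tables of realistic granularity. The
fixtures are poly-alanine helices; the secondary-structure classifier
and accessibility binning see essentially two of their classes there.

## Known limitations

* NMR-STAR/NEF restraint formats are not parsed; the TSV dialects are
  the input contract. No CIF writing, no insertion codes, no
  multi-entity assemblies beyond simple chains.
* Nucleic-acid support covers backbone torsions and clustering
  selections; the fixture generator and shift validation are
  protein-only.
* No restraint-energy or information-content analysis, no core-domain
  detection, no shift prediction — the shift check is reference-table
  statistics, not a physics model.
* The clustering stand-in is intentionally simple (average linkage +
  fixed cut); it resolves clearly separated conformations, not subtle
  sub-states.
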