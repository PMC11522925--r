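---
title: "Methods: contact, entry, free-energy and kinetics analysis for PET hydrolases"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: contact, entry, free-energy and kinetics analysis for PET hydrolases}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(petentry)
```

`petentry` quantifies the two physical prerequisites of enzymatic PET
degradation — adsorption of the hydrolase onto the polymer and entry of a
chain segment into the binding cleft — from molecular-simulation
trajectories, and links them to interfacial Michaelis–Menten kinetics.
This vignette explains the models behind each stage, the tunable
parameters and the reasoning behind their defaults, what the synthetic
data generator does and does not emulate, and the numerical choices made
where the design was genuinely open.

## Data model and units

A `molecular_system` couples an atom table (charges in e, Lennard-Jones
σ in Å and ε in kcal/mol) with the annotations the analyses need: the
catalytic serine's γ-oxygen, the two oxyanion-hole amide hydrogens, the
ordered polymer repeat units, and the ester-bond triplets (carbonyl C,
carbonyl O, ester O). Residue numbering is taken verbatim from the PDB
residue field; nothing is renumbered. Coordinates are Ångström
throughout; interaction energies are kcal/mol; free energies are reported
in kJ/mol (conversion 4.184, applied only when a free-energy surface is
built), matching the units each kind of quantity is conventionally
reported in. Trajectories carry optional per-frame orthorhombic boxes
(minimum-image convention when present, free space otherwise), replica
indices and non-negative frame weights; every statistic in the package is
weight-aware, and unit weights recover the plain unweighted result.

Because PET parameterizations differ in atom naming, ester triplets are
identified through a configurable atom-name template per polymer residue
(or supplied explicitly), and the nonbonded parameter table is an
external TSV keyed by residue and atom name — the package deliberately
does not hard-code any charge set.

## Contacts and persistence

A residue contacts the polymer in a frame when the minimum
heavy-atom–heavy-atom distance is ≤ 3 Å (`contact_cutoff`). The boundary
is inclusive at both this and the 12 Å proximal radius, and "heavy atom"
means element ≠ H — the field's convention for contact maps. Persistent
contacts are those held for at least 75 % (`persistence_fraction`) of the
weighted simulation time, computed per trajectory by default (pooling
across simulations is available by concatenating trajectories, since the
criterion is a weighted fraction either way).

A contact in a frame is *proximal* when the polymer atoms in contact with
that residue come within 12 Å (`proximal_radius`) of the serine γ-oxygen
in the same frame, *distal* otherwise. Per-residue aggregation uses a 90 %
majority: residues whose contact frames are ≥ 90 % proximal (distal) get
that label, anything in between is labelled `both`. The majority threshold
is a tunable default — region maps of this kind are usually drawn
visually, and 90 % keeps the `both` class for genuinely mixed sites
without letting single frames flip a label.

The production path uses a cell list (cell edge = cutoff) for free-space
frames and a dense vectorized minimum-image computation for periodic
frames; both are held equal to a brute-force all-pairs oracle in the test
suite, which is the correctness guarantee.

## Interaction energies

Interaction energies are plain truncated Coulomb plus Lennard-Jones 12-6
with Lorentz–Berthelot combination, dielectric 1, a 12 Å pair cutoff and
no switching function or long-range correction:

E = Σ_{i∈A, j∈B, r ≤ r_c} [ k qᵢqⱼ/r + 4εᵢⱼ((σᵢⱼ/r)¹² − (σᵢⱼ/r)⁶) ],
k = 332.0636 kcal·Å·mol⁻¹·e⁻².

Absolute values of such energies are engine- and scheme-dependent; the
package uses them only for orderings, onsets and differences (per-class
profiles, binding onset below −10 kcal/mol, site-wise parent-vs-variant
shifts, unit–unit polymer energies), which are robust to the truncation
scheme. The class profile groups residues as apolar
{A,V,L,I,M,G,P,C}, polar {S,T,N,Q}, charged {D,E,K,R,H} and aromatic
{F,Y,W}, and scales each class sum by the number of contacting residues
of that class so that classes with many members do not dominate by count.
Histidine sits in the charged class by default (it is the catalytic base
here); the map is an argument, so moving it to aromatic is a one-line
override. Per-class standard errors can be taken per simulation or per
frame; both variances are accessible because the per-residue,
per-frame series are returned intact.

## Productive poses, faces and entry phases

The entry reaction coordinate is the SER–C distance: serine γ-oxygen to
the carbonyl carbon of the nearest ester, re-evaluated every frame. A
pose is *productive* when SER–C **and** both oxyanion distances (the same
ester's carbonyl oxygen to each of the two amide hydrogens) are ≤ 4 Å
(`productive_cutoff`); the conjunction is deliberate — a single oxyanion
contact does not stabilize the tetrahedral intermediate.

The si/re face of the serine approach is the sign of the projection of
(Oγ − C) onto the ester-plane normal, taken as the cross product of
(carbonyl O − C) and (ester O − C) in that order. Projections within
±0.1 Å of the plane are `undefined`. Full CIP prochirality perception is
out of scope; instead the sign-to-label convention is anchored to a
shipped reference geometry (`inst/extdata/si_reference.pdb`, documented
as si-face), which makes the convention testable: rigid motions leave
labels unchanged and mirror reflections flip them, both asserted in the
suite.

Entry events are maximal runs in which SER–C passes from above 6 Å
(`outer_boundary`, the outside phase) to below 4 Å (the inside phase);
the entry phase is the frames strictly between the last frame above 6 Å
and the first below 4 Å. One frame below the inner boundary closes an
event — no hysteresis by default, because debouncing conventions vary; a
width-5 running-median filter is available by flag for noisy coordinates.
An event is productive if any inside-phase frame is productive, and its
face label is taken at the first productive frame.

## Free-energy surfaces

`fes2d()` bins weighted samples on a 50 × 50 grid (default) spanning the
sampled range expanded by 5 % — the resolution of published surfaces of
this kind is rarely stated, and 50 bins resolves the well/barrier
structure at the sample sizes used here. ΔG = −k_B T ln(P/P_max) with
k_B = 0.0083145 kJ/(mol·K) and T = 303 K by default, so the global
minimum is 0 and every sampled bin is non-negative. Unsampled bins are
masked, never padded with pseudo-counts, and are impassable in
path-finding. Replica ensembles are pooled with per-replica weights
supplied as data (`pool_replicas()`); the package does not guess a
weighting scheme for replica ladders because none is canonical — uniform
weighting is the default and anything else must be given explicitly.

Feature extraction finds local minima (bins below all sampled
8-neighbours; on a perfectly flat plateau the lowest-linear-index bin is
reported with depth 0), splits them at the 4 Å boundary into productive
and non-productive, and computes the barrier between the deepest minima
of the two kinds as the bottleneck value of the minimax path over sampled
bins (exact Dijkstra-type dynamic programming, 8-connected).

`compare_fes()` classifies a variant against its parent with labels
*stabilized-productive*, *reduced-nonproductive* and *smoother-path*.
Each label compares its own feature — productive-minimum depth,
nonproductive-minimum depth, barrier height — directly between the two
min-referenced surfaces, with a 1 k_BT threshold (≈ 2.52 kJ/mol at
303 K): published comparisons of such surfaces are visual, and thermal
energy is the minimal defensible quantization. Comparing each feature
directly (rather than, say, productive depth *relative to* the
nonproductive well) keeps the three labels independent: raising the
nonproductive well alone yields exactly `reduced-nonproductive`, not a
spurious stabilization label as a relative measure would.

## Entry-pathway PCA

For every entry event, the feature vector per frame is the distance from
the tracked ester carbon to each enzyme Cα within 10 Å (`pca_radius`)
during the entry and inside phases; the feature residue set is the union
over all events. Frames where a selected residue drifts out of range get
its distance capped at 2 × radius: PCA needs complete rows, and the cap
bounds the leverage of out-of-range frames while recording (in the
returned object) that capping occurred. The PCA itself is an
eigendecomposition of the weighted covariance of column-centered
features, with a deterministic sign convention (largest-magnitude loading
entry positive). Pathway assignment clusters *event-level* mean
projections in the (PC1, PC2) plane with seeded k-means (50 restarts),
because a pathway is a property of a whole entry trajectory, not of
single frames; clusters are renumbered by increasing mean PC1.
Per-residue contributions to a component are absolute loadings, with
|loading| > 1/√d (the uniform-loading baseline over d features) as the
default significance threshold — any published count of "significant"
positions depends on an unstated criterion, so the threshold is exposed
as a parameter rather than fixed.

## Michaelis–Menten kinetics

Two designs are supported: conventional (substrate load in g/L varied at
fixed enzyme concentration) and inverse (enzyme concentration in µM
varied at fixed insoluble substrate load — the natural design when
accessible attack sites, not bulk substrate, saturate). Both are fit by
Levenberg–Marquardt nonlinear least squares of v = V_max x/(K_m + x)
with start values V_max = max rate and K_m interpolated at half-maximal
rate; standard errors come from the linearized covariance at the optimum.

The secondary parameters convert the conventional K_m (g/L) to a molar
attack-site concentration with a user-supplied conversion factor — this
factor depends on substrate crystallinity and particle geometry and is
therefore required input, never defaulted. k_cat is either supplied
directly or derived from the inverse-mode saturation plateau normalized
by the molar substrate-load context; the result records which route was
used, since the derivation chain behind published k_cat values is not
always stated. The molar efficiency is the exact ratio
η = k_cat / ᵐᵒˡᵃʳK_m, and report tables round half-even to 3 decimals.

## The synthetic generator: what it emulates, and what it does not

The generator stands in for microsecond-scale (replica-exchange)
simulation data that cannot be shipped. It emulates the *statistical
structure* the analyses consume:

- a pseudo-enzyme as a Cα bead shell (radius 12 Å) with a catalytic site
  at one pole (γ-oxygen bead plus two flanking amide-hydrogen beads) and
  a PET-like bead chain with one ester triplet per unit junction;
- entry trajectories whose tracked ester carbon follows one of three
  guide corridors (120° apart around the catalytic pole) from 9.5 Å down
  to a productive pose at 2.8 Å, with Gaussian positional noise
  (default 0.3 Å) on every polymer atom. The approach direction retains a
  small corridor-specific tilt in the bound state so a route leaves a
  recoverable signature, and three planted "loop" beads sit beside the
  corridors as the known route-discriminating residues. Ground-truth
  phase boundaries are the 6/4 Å crossings of the *noiseless* guide
  curve — the generator uses positional noise rather than Langevin
  dynamics precisely so that this truth stays analytic. The ramp steps
  ≈ 0.45 Å per frame, so 0.3 Å noise misplaces a detected boundary by
  more than 2 frames only with probability ≈ Φ(−3);
- contact fixtures that place polymer atoms 2.5 Å from planted residues
  in a seeded fraction of frames (default 0.8) and far away otherwise,
  so persistence filtering has an exact expected answer;
- Metropolis samples from analytic 2D potentials (harmonic; double well
  with minima at 3 and 7 Å and a 6 kJ/mol barrier) to validate the
  Boltzmann inversion quantitatively;
- Michaelis–Menten rate data with x log-spaced over K_m/10…10 K_m and
  Gaussian noise proportional to V_max, truncated at zero.

What it does **not** emulate: real adsorption physics, amorphous-polymer
bulk structure, force-field energetics (toy parameters are plausible but
arbitrary), solvent, kinetic barriers along the entry route, or the
relative populations of si vs re approaches. Consequently, passing tests
demonstrate that the *analysis machinery* is correct and well-calibrated
on data of the right shape — not that any particular enzyme shows a
particular contact map or pathway count. Published trajectory-derived
counts (tens of productive entries per enzyme, tens of significant PCA
positions) require the original simulations and are deliberately not
reproduction targets.

## Numerical choices and degenerate inputs

- Distance boundaries are inclusive (≤) everywhere, matching the
  criteria's "≤" phrasing; applied uniformly so monotonicity properties
  hold exactly.
- Zero interatomic distance inside the cutoff is an error (clashing
  coordinates), not an infinity.
- A collinear ester triplet degenerates the plane; the face is
  `undefined` with a warning.
- Flat free-energy plateaus tie-break to the lowest linear bin index;
  disconnected well pairs report an infinite barrier.
- k-means uses 50 restarts under a fixed seed; with fewer events than
  clusters the assignment errors out rather than degenerating.
- The Metropolis sampler reports acceptance and a crude autocorrelation
  ESS; zero acceptance over a run is an error pointing at the step size.

## Problem sizes

The shipped validation uses 30-residue/5-unit toy systems, 60-frame entry
trajectories (100 for detection statistics, 30 for pathway recovery),
10⁵ retained Metropolis samples (thinning 10) for the surface-recovery
check, and 200 replicates for kinetic-recovery statistics; the full suite
plus the acceptance script completes in well under a minute on one core.
These sizes were chosen so each statistical check has comfortable margin
(e.g. ≥ 100 effective samples per compared FES bin) while staying
desk-scale.

## Interface note

The stages are exposed as plain R functions plus the `run_all()`
orchestrator; this is a library meant to be driven from R scripts, so no
shell command-line wrapper is shipped.

## Known limitations

- The energy model is not an engine reproduction: no PME, no switching,
  no dispersion correction. Only relative statements should be drawn
  from it (which is how it is used).
- The si/re convention is anchored, not derived from CIP rules; exotic
  ester substitution patterns outside the anchored geometry class are
  not validated.
- `pool_replicas()` applies whatever replica weights it is given; it
  performs no MBAR/WHAM-style reweighting.
- Per-event k-means assumes roughly convex route clusters in the PC
  plane; strongly curved or overlapping routes would need density-based
  clustering.
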