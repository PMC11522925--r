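# petentry

Trajectory-analysis and kinetics toolkit for studying how PET-degrading
enzymes (polyester hydrolases such as leaf-branch compost cutinase and
related cutinase-family enzymes) bind and thread a poly(ethylene
terephthalate) chain into their catalytic cleft.

Enzymatic PET degradation starts with two physical steps that precede any
chemistry: adsorption of the enzyme onto the polymer surface, and entry of a
chain segment into the binding cleft until an ester bond sits in a
hydrolysis-competent pose at the Ser–His–Asp triad. `petentry` implements
the standard analyses used to quantify both steps from molecular-simulation
output, plus the interfacial kinetics used to connect them to experiment:

- **Contacts** — per-frame residue–polymer contact maps (heavy-atom minimum
  distance ≤ 3 Å), persistence filtering (contacts held ≥ 75 % of the
  simulation time), and classification of binding sites as *proximal* or
  *distal* depending on whether the contacting polymer comes within 12 Å of
  the catalytic serine's γ-oxygen.
- **Energetics** — pairwise nonbonded interaction energies
  E = Σᵢⱼ [k qᵢqⱼ/rᵢⱼ + 4εᵢⱼ((σᵢⱼ/rᵢⱼ)¹² − (σᵢⱼ/rᵢⱼ)⁶)] (truncated Coulomb
  plus Lennard-Jones 12-6, Lorentz–Berthelot combination, minimum image),
  aggregated per residue, per physicochemical class (apolar / polar /
  charged / aromatic, scaled by the number of contacting residues of each
  class), between non-adjacent polymer repeat units, and compared per
  mutation site between parent and variant.
- **Entry** — the SER–C reaction coordinate (serine Oγ to the carbonyl
  carbon of the nearest polymer ester), productive-pose detection (SER–C
  and both oxyanion-hole amide-hydrogen distances ≤ 4 Å), si/re
  prochiral-face labels of the serine approach, and segmentation of
  trajectories into outside (> 6 Å), entry, and inside (< 4 Å) phases.
- **FES** — weighted 2D free-energy surfaces ΔG = −k_B T ln(P/P_max) from
  replica-pooled ensembles, with minima/barrier extraction and a
  parent-vs-variant classifier (stabilized-productive,
  reduced-nonproductive, smoother-path; 1 k_BT threshold).
- **Pathways** — PCA of ester-carbon-to-Cα distance features over entry
  events, per-residue component contributions, and k-means assignment of
  events to entry routes in the (PC1, PC2) plane.
- **Kinetics** — conventional (vary substrate load S₀ at fixed enzyme E₀)
  and inverse (vary E₀ at fixed S₀) Michaelis–Menten fits
  v = V_max·x/(K_m + x), and the molar secondary parameters k_cat,
  ᵐᵒˡᵃʳK_m and ᵐᵒˡᵃʳη = k_cat/ᵐᵒˡᵃʳK_m for insoluble substrates.

Because simulation trajectories of this size are rarely redistributable,
the package ships a first-class synthetic-fixture generator
(`make_toy_system()`, `simulate_entry()`, `make_contact_trajectory()`,
`sample_boltzmann2d()`, `make_kinetic_data()`) whose outputs carry known
ground truth — planted persistent contacts, planted entry-phase boundaries
and corridors, analytic generating potentials, true kinetic parameters —
so every stage is validated end to end.

## Worked example

```r
library(petentry)

sys  <- make_toy_system(seed = 42)         # annotated toy enzyme + PET 5-mer
traj <- simulate_entry(sys, corridor = 2, seed = 42, noise = 0.3)

es     <- entry_series(traj, sys)          # SER-C + oxyanion distances per frame
events <- segment_entries(es)
events[[1]]
#> <entry_event> outside 1-19, entry 20-25, inside 26-60; productive (re-face)

fit <- fit_mm(make_kinetic_data(km = 0.3, vmax = 1.0, n = 8,
                                noise = 0.05, seed = 42))
fit
#> <mm_fit> conventional Michaelis-Menten
#>   K_m   = 0.282 +/- 0.0379
#>   V_max = 1.02 +/- 0.0409

secondary_params(k_cat = 0.047, molar_km = 0.357)
#> <secondary_params> k_cat = 0.047 1/min/uM (supplied), molar K_m = 0.357 uM,
#>   molar eta = 0.132 1/min/uM^2
```

The entry event reports the frame ranges of the three phases delimited by
the 6 Å / 4 Å boundaries and whether a hydrolysis-competent pose was
reached inside. The Michaelis–Menten fit recovers the generating
parameters (K_m = 0.3, V_max = 1.0) within the noise, and the secondary
parameters combine a turnover number with a molar Michaelis constant into
the molar catalytic efficiency (here 0.132 µM⁻¹ min⁻¹ µM⁻¹).

The whole pipeline runs from one configuration:

```r
run_all(list(seed = 42))
#> <run_report> seed 42
#>   contacts   ok
#>   ...
#>   persistent contacts: 3
#>   entries: 6 events, 6 productive ( 5 si / 0 re )
#>   pathway sizes: 1:2 2:2 3:2
```

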