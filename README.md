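# mdpolar

Polar-contact classification, water-bridge lifetimes and bitopic linker
design from molecular-dynamics trajectories.

## What this is for

Bitopic ligands for class A GPCRs — one pharmacophore in the orthosteric
pocket, a charged "warhead" reaching into the allosteric sodium pocket
around the conserved aspartate at Ballesteros–Weinstein position 2.50 —
live or die by how that warhead engages the pocket: directly, through a
bridging water, or not at all, and for how long. `mdpolar` provides the
desk-scale analysis layer for that question:

* **Per-frame contact detection** — hydrogen bonds (heavy-atom distance
  ≤ 3.5 Å, D–H···A ≥ 120° when hydrogens exist), salt bridges (charged N
  to carboxylate O ≤ 4.0 Å), single-water bridges (one water
  hydrogen-bonded to ligand and pocket residue in the same frame), and
  hydrophobic contacts (minimal C–C ≤ 4.5 Å). All cutoffs inclusive,
  configurable, and echoed into every output.
* **Three-way classification** of each frame's engagement of a focal
  residue: `DIRECT_INTERACTION` (direct H-bond/salt bridge, with or
  without supplementary water bridges), `WATER_MEDIATED_ONLY` (a water
  bridge to any pocket residue, no direct contact), `NO_POLAR_CONTACT`.
* **Lifetimes** — intermittent indicator autocorrelation
  `C(t) = <h(s)h(s+t)>/<h(s)^2>`, correlation time τ by plateau-corrected
  integral or exponential fit, censoring when C never decays, replica-level
  mean ± SEM, and bridging-water identity-exchange statistics.
* **Static geometry** — Ballesteros–Weinstein residue resolution, Kabsch
  superposition and RMSD, Cα/sidechain displacement metrics, and the
  anchor-to-pocket design distance with explicit atom specs.
* **Linker proposal** — candidate aliphatic chain lengths for a measured
  target reach, `reach(n) = anchor_offset + n × per_methylene`.
* **Synthetic ground truth** — a generator whose bound/unbound dynamics
  follow a two-state Markov process with known occupancy
  `k_on/(k_on+k_off)` and relaxation time `1/(k_on+k_off)`, so every
  stage is testable without any external data.

Structure/trajectory parsing (PDB, mmCIF, DCD) is delegated to `bio3d`;
the analysis layer is this package. See the methods vignette
(`vignettes/mdpolar-methods.Rmd`) for the model, estimators, and design
choices.

## Worked example

Generate four synthetic replicas (200 ns each at 0.1 ns/frame) with
symmetric rates `k_on = k_off = 0.1/ns` — truth: 50% direct occupancy,
5 ns relaxation time, bridging water in half of the unbound frames,
identity swap probability 0.5 — then analyse them exactly as one would a
real trajectory set:

```r
library(mdpolar)

g <- generate_contact_trajectory(out_dir = tempfile("demo"), n_replicas = 4,
                                 n_frames = 2000, k_on = 0.1, k_off = 0.1,
                                 seed = 7)
model <- load_structure(g$paths$topology,
                        ligand_roles = synthetic_ligand_roles())
lig <- select_atoms(model$topology, resno = 900)
analyses <- lapply(seq_along(g$paths$trajectories), function(r) {
  frames <- read_frames(g$paths$trajectories[r], model$topology, dt_ns = 0.1)
  analyze_contacts(frames, model$topology, lig, focal_resno = 95,
                   pocket_resnos = c(95, 155), replica_id = r)
})

category_fractions(analyses)
#> pooled: 48.7% direct, 25.8% water-mediated-only, 25.5% none (n=4 replicas)

taus <- sapply(analyses, function(an) {
  s <- indicator_series(an, "direct")
  correlation_time(autocorrelation(s), "integral")$tau_ns
})
aggregate_replicas(taus)
#> mean 4.49 +/- 0.796 (SEM, n=4)

water_exchange(analyses[[1]]$bridges)$switch_fraction
#> [1] 0.473
```

The recovered fractions sit at the configured 50/25/25 mixture within
sampling error, the correlation time recovers the 5 ns ground truth
within its replica SEM, and the bridging-water switch fraction matches
the configured 0.5 — while the water-mediated indicator itself is
identity-agnostic, so the exchange does not interrupt the interaction.

For design work, a measured anchor-to-pocket distance maps to candidate
linker lengths:

```r
propose_linker_lengths(11.2)
#> linker proposal for target 11.20 A (offset 4.30 + n x 1.25 A, tol 0.70 A)
#>  n_carbons modeled_reach_A slack_A within_tolerance
#>          6           11.80    0.60             TRUE
#>          5           10.55   -0.65             TRUE
#>          7           13.05    1.85            FALSE
#>          4            9.30   -1.90            FALSE
```

An 11.2 Å reach — the distance from the naltrindole basic amine to the
sodium-pocket aspartate carboxylate in the inactive-state δ-opioid
receptor — selects the 5- and 6-carbon linkers.

A thin command-line wrapper over the same functions ships at
`inst/cli/mdpolar.R` (subcommands `simulate`, `contacts`, `lifetimes`,
`geometry`, `design`, `report`); a full `report` run writes TSV tables
plus a JSON manifest carrying the config, cutoffs and seed, and is
byte-for-byte reproducible for a given config and seed.

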