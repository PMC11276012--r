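---
title: "Polar-contact classification, water-bridge lifetimes and linker design: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Polar-contact classification, water-bridge lifetimes and linker design: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mdpolar)
```

## Scope and model

`mdpolar` analyses how a ligand engages a focal receptor residue across a
molecular-dynamics trajectory, with the class A GPCR sodium pocket as the
motivating use case: a bitopic ligand's charged warhead reaching toward the
conserved aspartate at Ballesteros–Weinstein position 2.50 can touch it
directly, through a single bridging water, or not at all. Each frame of
each replica is assigned exactly one of three categories:

* **DIRECT_INTERACTION** — at least one hydrogen bond or salt bridge links
  ligand and focal residue. Water bridges may coexist; they do not change
  the call.
* **WATER_MEDIATED_ONLY** — no direct contact, but at least one water is
  simultaneously hydrogen-bonded to a ligand atom and to an atom of any
  residue in the configured pocket set.
* **NO_POLAR_CONTACT** — neither of the above.

The categories are exhaustive and mutually exclusive by construction, so
their counts always sum to the number of analysed frames.

## Geometric criteria

The defaults live in `inst/extdata/default_config.yaml`, are echoed into
every output's metadata sidecar, and are deliberately conventional for MD
contact analysis; they are package choices, and any published analysis
using different cutoffs can be matched by editing the config:

| criterion | default | notes |
|---|---|---|
| hydrogen bond | donor–acceptor ≤ 3.5 Å | heavy atoms; inclusive |
| H-bond angle | D–H···A ≥ 120° | only when the donor has hydrogens |
| salt bridge | charged N to carboxylate O ≤ 4.0 Å | inclusive |
| hydrophobic | minimal C–C ≤ 4.5 Å | per residue |

Every boundary comparison is inclusive (`<=`), so a pair exactly at a
cutoff is deterministically counted. Crystal structures lack hydrogens;
all criteria therefore have a heavy-atom-only fallback, and the angle test
activates only when hydrogens are present within 1.25 Å of the donor.
Distances use the minimum-image convention whenever a frame carries a
periodic box (general triclinic handled through the fractional-coordinate
wrap); static models are measured without imaging. Donor/acceptor/charge
roles for the standard amino acids and water come from built-in lookup
tables; roles for any other residue must be declared in the configuration
and are never inferred, because novel ligands appear in no dictionary.

Water bridges are order-1 only: exactly one bridging water, both
hydrogen-bond legs satisfied in the same frame. Chains of two or more
waters are out of scope. The water-mediated indicator is
identity-agnostic — bulk exchange of the bridging water molecule does not
interrupt the interaction — and the identity record is kept separately so
exchange can be quantified (`water_exchange()` counts successive
bridge-carrying frames whose bridging-water sets are disjoint).

## Lifetimes

For an interaction indicator `h(t)` (1 when present), the package uses the
intermittent, history-independent autocorrelation

\[ C(t) = \frac{\langle h(s)\,h(s+t)\rangle_s}{\langle h(s)^2\rangle_s}, \]

which allows an interaction to break and reform inside the lag window.
The continuous (first-passage) definition was considered and rejected as
the default: persistence times a substantial fraction of the trajectory
length are incompatible with strict continuous-bond survival, while the
intermittent definition with plateau correction reproduces them
naturally. For a binary indicator, `C(0) = 1` and `C(t) → p` (the mean
occupancy) at long lags.

Two correlation-time estimators are exposed, and every reported value
carries its `tau_method`:

* **integral** — `τ = ∫ (C(t) − C∞)/(1 − C∞) dt`, trapezoidal. The
  integral is truncated at the first lag where `C` crosses the plateau:
  beyond that point the integrand is mean-zero sampling noise whose
  accumulated area would otherwise dominate the estimate (on synthetic
  series it inflated single-replica estimates severalfold).
* **exponential_fit** — least-squares fit of
  `C(t) = C∞ + (1 − C∞) exp(−t/τ)` (Levenberg–Marquardt).

For indicator-derived curves the plateau `C∞` is taken as the mean
occupancy, its exact long-lag limit; this is markedly more stable than a
tail-window mean on any single replica, whose long-lag `C` wanders with
few effective samples. Curves supplied without an occupancy fall back to
the tail-window mean (window: last 10% of lags). When `C` never decays
below `1 − 0.02` the estimate is censored: `τ` is reported as the maximum
usable lag and flagged as a lower bound. The lag grid equals the frame
spacing and the maximum lag is half the series duration.

Replicas are the unit of error: a statistic is computed per replica and
reported as mean ± SEM over replicas (`aggregate_replicas()`), matching
the standard multi-replica MD design (8 replicas by default). Whether a
published "±" is SEM, SD, or a fit error is often unstated; this package
always reports SEM over replicas and says so. Block averaging within one
replica is deliberately not offered.

## Category statistics and comparisons

`category_fractions()` reports both per-replica fractions and a
frame-count-weighted pooled triple, because published percentages rarely
state which aggregation they use; both are labelled in the output.
`distance_summary()` takes, per frame, the closest qualifying pair
distance (a guanidinium can bridge both carboxylate oxygens at once; the
contact distance is the near one), averages per replica, then across
replicas. Between-ligand comparisons use Welch's unequal-variance t-test
on per-replica summaries, two-sided, with no multiple-testing correction
by default (a Holm option is in the config); the degenerate
zero-variance case is handled explicitly since `t.test()` refuses
constant data.

## Static-structure geometry and linker design

Ballesteros–Weinstein codes resolve through a user-supplied two-column
map (`read_bw_map()`); the package performs no automatic numbering from
sequence. Superposition is the closed-form Kabsch solution (SVD with a
determinant correction, proper rotation guaranteed), cross-checked in the
test suite against an independent reference implementation. Displacement
metrics (`calpha`, `sidechain_centroid`, `sidechain_max`) require the two
models to be in a common frame; when measuring the movement of a mobile
element such as TM6, the superposition selection should exclude that
element, else the moving part biases the reference frame — the helper
workflow in the tests superposes on the undisplaced residues.

The linker-design calculation is pure reach arithmetic:
`reach(n) = anchor_offset + n × per_methylene`, with candidates returned
for every chain length whose reach is within a tolerance of the measured
anchor-to-pocket distance and the nearest out-of-tolerance lengths
flagged. The shipped calibration (1.25 Å per methylene — the projected
per-CH2 advance of an extended all-anti chain — 4.3 Å anchor offset
covering the terminal warhead group plus the polar-contact gap, 0.7 Å
tolerance) was fixed once against the known outcome that an 11.2 Å
anchor-to-aspartate distance selects 5- and 6-carbon linkers, and lives
in the config, not in code. No conformational modelling of the linker is
attempted.

The atom choices behind any published distance are rarely stated;
`measure_design_distance()` therefore returns the atom specifications
alongside the number, and the basic-amine-to-carboxylate convention used
here is group-minimum over the carboxylate oxygens.

## Synthetic ground truth

Because production MD trajectories are cluster-scale and rarely
deposited, every analysis stage is validated against a generator whose
truth is known exactly (`generate_contact_trajectory()`). The scene is a
minimal rigid fragment — a focal aspartate, a pocket serine, an inert
scaffold, a three-atom ligand with one charged warhead nitrogen, and a
set of single-atom waters. Per frame, a two-state Markov chain with
user-set on/off rates (sampled through the exact finite-time transition
probabilities) decides bound/unbound; bound frames place the warhead at
salt-bridge range (2.9 Å), unbound frames beyond every cutoff (5.8 Å)
with a bridging water inserted midway with configured probability; the
bridging water's identity switches between frames with a configured swap
probability. Coordinate jitter (σ = 0.02 Å) keeps frames from being
literal copies while staying an order of magnitude below every cutoff
margin. Replica r is seeded `base_seed + r`, so outputs are bit-identical
given a seed and replicas are independent.

The generator emulates the statistical structure of the analysis —
occupancy, relaxation time, category mixture, water exchange — not the
physics: there are no forces, no realistic water geometry beyond
satisfying the hydrogen-bond criteria, and no conformational coupling.
Passing tests therefore demonstrate that the detectors, classifier and
estimators are correct and well-calibrated on data whose truth is known;
they do not validate force fields, sampling adequacy, or criterion
choices on real trajectories.

Default generator settings mirror the reference study design where one
exists (8 replicas; 0.1 ns frame spacing; symmetric rates 0.1/ns giving a
5 ns relaxation for estimator checks) and otherwise use one-time choices
documented here: swap probability 0.5 (bulk exchange is fast on the frame
timescale), bridge probability 0.5 in unbound frames, 6 waters.

## Problem sizes and numerical choices

The test and acceptance runs use desk-scale sizes chosen as the smallest
that leave the statistical contracts comfortably testable: estimator
checks use 8 replicas × 5000 frames of pure indicator series (500 ns at
0.1 ns/frame, i.e. 100× the 5 ns relaxation time), while full geometric
runs use 8 replicas × 400 frames. τ recovery is asserted within 20% at
those sizes; category mixtures within the binomial-scale sampling error
implied by the realized autocorrelation; detector correctness is exact
(oracle equivalence against brute force on 1000 random frames).

Other numerical conventions: alternate locations resolve to the highest
occupancy conformer, ties broken alphabetically; trajectory striding
keeps every k-th frame starting at the first; DCD output is
single-precision (0.001 Å round-trip accuracy asserted for text PDB,
~1e-6 Å relative for DCD floats); degenerate inputs (collinear
superposition selections, empty selections, all-zero indicators,
fewer than two replicas for a comparison) raise errors rather than
returning silent defaults.

## Known limitations

* XTC trajectories are not read (no reader in the R dependency stack);
  DCD and multi-model PDB are supported, with nm→Å conversion therefore
  never needed at the boundary.
* Water bridges are single-water only; π–π geometry is not detected (an
  aromatic stacking partner appears only through the hydrophobic C–C
  profile).
* The three-way classification is as good as the configured focal/pocket
  sets and cutoffs; the package surfaces these in every output rather
  than asserting them as ground truth.
* Correlation times approaching the trajectory length are reported with
  the censoring flag, but no extrapolation beyond the observed lags is
  attempted.
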