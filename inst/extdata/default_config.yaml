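# mdpolar default run configuration.
# Every geometric criterion and calibration lives here, not in code, and is
# echoed into every output's metadata sidecar. All cutoff comparisons are
# inclusive (<=).

criteria:
  hbond_dist_A: 3.5        # heavy-atom donor-acceptor distance
  hbond_angle_deg: 120     # D-H...A angle, applied only when hydrogens exist
  saltbridge_dist_A: 4.0   # charged N to carboxylate O
  hydrophobic_dist_A: 4.5  # minimal C-C distance

classification:
  focal_bw: "2.50"         # focal residue for the 3-way classification
  pocket_bw: ["2.50", "3.35", "3.39", "7.45", "7.46"]  # water-bridge scan set

lifetimes:
  tau_method: integral     # integral | exponential_fit
  plateau_tol: 0.02        # censoring threshold on C(t) decay
  tail_frac: 0.10          # tail window for the plateau estimate
  max_lag_frac: 0.5        # max lag as a fraction of series duration

linker:
  # reach(n) = anchor_offset_A + n * per_methylene_A; candidates within
  # tolerance_A of the target distance. per_methylene: extended all-anti
  # chain projection per CH2; anchor_offset: terminal warhead reach plus
  # polar-contact gap. Calibrated once against the known C5/C6 outcome for
  # an 11.2 A anchor-to-pocket distance.
  per_methylene_A: 1.25
  anchor_offset_A: 4.3
  tolerance_A: 0.7

trajectory:
  stride: 1
  dt_ns: 0.1               # frame spacing of stored frames
  wrapped: true            # whether waters are assumed wrapped into the box

generator:
  k_on: 0.1                # per-ns on rate of the two-state contact process
  k_off: 0.1               # per-ns off rate
  water_swap_prob: 0.5     # per-bridged-frame bridging-water identity swap
  p_bridge_unbound: 0.5    # P(bridging water | unbound frame)
  p_bridge_bound: 0.3      # P(supplementary bridge | bound frame)
  n_replicas: 8
  n_frames: 1000
  dt_ns: 0.1
  n_waters: 6
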