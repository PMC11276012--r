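# Synthetic trajectory and structure generation with known ground truth.
# The scene is deliberately minimal (tens of atoms): contact analysis needs
# geometry that satisfies or violates the criteria, not physics.

#' Simulate a two-state Markov interaction indicator
#'
#' Continuous-time two-state process (rates per ns) sampled on a uniform
#' frame grid via the exact finite-time transition probabilities. The
#' stationary occupancy is `k_on / (k_on + k_off)` and the relaxation time
#' `1 / (k_on + k_off)`; the indicator autocorrelation decays as
#' `C(t) = occ + (1 - occ) exp(-(k_on + k_off) t)`.
#'
#' @param n_frames number of frames.
#' @param k_on,k_off switching rates, per ns (non-negative, sum > 0; a
#'   zero rate freezes the corresponding transition, e.g. `k_off = 0`
#'   keeps a bound start bound forever).
#' @param dt_ns frame spacing, ns.
#' @param start optional initial state (0/1); default drawn from the
#'   stationary distribution.
#' @return integer 0/1 vector of length `n_frames`. Uses the current RNG
#'   state; seed externally for reproducibility.
#' @export
simulate_two_state <- function(n_frames, k_on, k_off, dt_ns, start = NULL) {
  if (k_on < 0 || k_off < 0 || k_on + k_off <= 0)
    stop("rates must be non-negative with a positive sum")
  r <- k_on + k_off
  occ <- k_on / r
  decay <- exp(-r * dt_ns)
  p01 <- occ * (1 - decay)        # off -> on over one frame interval
  p10 <- (1 - occ) * (1 - decay)  # on -> off
  h <- integer(n_frames)
  h[1] <- if (is.null(start)) stats::rbinom(1, 1, occ) else as.integer(start)
  u <- stats::runif(n_frames - 1)
  for (i in seq_len(n_frames - 1)) {
    h[i + 1] <- if (h[i] == 1L) {
      if (u[i] < p10) 0L else 1L
    } else {
      if (u[i] < p01) 1L else 0L
    }
  }
  h
}

# Fixed scene geometry (Angstrom). The focal aspartate's carboxylate sits
# at the origin; the ligand warhead nitrogen approaches along +x.
.SCENE <- list(
  bound_NG        = c(2.9, 0, 0),    # salt-bridge range of OD1
  unbound_NG      = c(5.8, 0, 0),    # beyond all polar cutoffs
  bridge_water    = c(2.9, 0, 0),    # midpoint when NG is unbound
  bound_bridge_water = c(2.9, 0, 2.8),  # bridges bound NG and the serine OG
  ser_OG          = c(2.9, 0, 5.6),
  focal_resno     = 95L,
  pocket_resnos   = c(95L, 155L),
  ligand_resno    = 900L,
  water_resno0    = 500L
)

#' Ligand polar-role declaration for the synthetic warhead
#'
#' The synthetic ligand (residue `LIG`) carries a single guanidine-like
#' nitrogen `NG` acting as cation and donor; roles are declared, never
#' inferred, mirroring how novel ligands must be configured.
#' @return named list suitable for `ligand_roles` arguments.
#' @export
synthetic_ligand_roles <- function() {
  list(LIG = list(donor = "NG", cation = "NG"))
}

# atom table + base coordinates of the synthetic scene
.scene_atoms <- function(n_waters) {
  stopifnot(n_waters >= 2)
  rows <- list(
    # focal aspartate (mimics the sodium-pocket D 2.50)
    list("CA",  "C", 95L, "ASP", "R", c(-2.8, 1.1, 1.2)),
    list("CB",  "C", 95L, "ASP", "R", c(-2.1, 1.1, 0.0)),
    list("CG",  "C", 95L, "ASP", "R", c(-0.7, 1.1, 0.0)),
    list("OD1", "O", 95L, "ASP", "R", c(0.0, 0.0, 0.0)),
    list("OD2", "O", 95L, "ASP", "R", c(0.0, 2.2, 0.0)),
    # pocket serine (mimics 3.39): water-bridge acceptor above the ligand
    list("CA", "C", 155L, "SER", "R", c(4.5, 0.0, 6.5)),
    list("CB", "C", 155L, "SER", "R", c(3.6, 0.0, 6.0)),
    list("OG", "O", 155L, "SER", "R", .SCENE$ser_OG),
    # inert scaffold (keeps the fragment non-degenerate and far away)
    list("CA", "C", 10L, "GLY", "R", c(-12, -8, 4)),
    list("CA", "C", 11L, "GLY", "R", c(-14, -4, -6)),
    list("CA", "C", 12L, "GLY", "R", c(-10, 6, -8)),
    list("CA", "C", 13L, "GLY", "R", c(-15, 2, 8)),
    # ligand: two aliphatic carbons and the warhead nitrogen
    list("C1", "C", 900L, "LIG", "L", c(7.2, 0.5, 0.0)),
    list("C2", "C", 900L, "LIG", "L", c(8.6, 0.5, 0.0)),
    list("NG", "N", 900L, "LIG", "L", .SCENE$unbound_NG)
  )
  # bulk waters on a ring well outside every cutoff
  for (i in seq_len(n_waters)) {
    ang <- 2 * pi * (i - 1) / n_waters
    rows[[length(rows) + 1]] <- list(
      "O", "O", .SCENE$water_resno0 + i - 1L, "HOH", "W",
      c(18 * cos(ang), 18 * sin(ang), 10))
  }
  data.frame(
    atom_id = seq_along(rows),
    name = vapply(rows, `[[`, character(1), 1),
    element = vapply(rows, `[[`, character(1), 2),
    resno = vapply(rows, `[[`, integer(1), 3),
    resname = vapply(rows, `[[`, character(1), 4),
    chain = vapply(rows, `[[`, character(1), 5),
    x = t(vapply(rows, `[[`, numeric(3), 6)),
    stringsAsFactors = FALSE
  )
}

#' Generate synthetic contact trajectories with known ground truth
#'
#' Per frame, a two-state Markov chain (rates `k_on`, `k_off`) decides
#' whether the ligand warhead is bound: bound frames place it in
#' salt-bridge range of the focal aspartate (direct interaction); unbound
#' frames place it beyond all cutoffs but, with probability
#' `p_bridge_unbound`, insert a bridging water satisfying both
#' hydrogen-bond legs (water-mediated-only frames). Bound frames gain a
#' supplementary bridge to the pocket serine with probability
#' `p_bridge_bound` (which never changes their category). The bridging
#' water's identity switches with probability `water_swap_prob` per
#' bridged frame. Gaussian jitter (sd `jitter_A`) is added everywhere but
#' is far too small to cross any cutoff.
#'
#' Replica r uses RNG seed `seed + r`, so replicas are independent and the
#' whole output is bit-identical for a given seed.
#'
#' @param out_dir directory for output files (created if needed); `NULL`
#'   keeps everything in memory.
#' @param k_on,k_off Markov switching rates, per ns.
#' @param water_swap_prob per-bridged-frame identity swap probability.
#' @param p_bridge_unbound,p_bridge_bound bridge insertion probabilities.
#' @param n_replicas,n_frames,dt_ns trajectory dimensions.
#' @param n_waters number of water molecules in the scene (>= 2).
#' @param jitter_A coordinate jitter standard deviation.
#' @param seed base RNG seed.
#' @param format trajectory file format, `"dcd"` or `"pdb"` (multi-model).
#' @return list of class `"synthetic_trajectory"`: `topology`,
#'   `frames` (list per replica of lists of `"md_frame"`), `truth`
#'   (parameters plus implied `occupancy`, `relax_time_ns`, and realized
#'   per-replica occupancies/swap fractions/category fractions), `layout`
#'   (focal/pocket/ligand residue numbers, ligand roles), and file `paths`
#'   when `out_dir` is given.
#' @export
generate_contact_trajectory <- function(out_dir = NULL,
                                        k_on = 0.1, k_off = 0.1,
                                        water_swap_prob = 0.5,
                                        p_bridge_unbound = 0.5,
                                        p_bridge_bound = 0.3,
                                        n_replicas = 8L, n_frames = 1000L,
                                        dt_ns = 0.1, n_waters = 6L,
                                        jitter_A = 0.02, seed = 1L,
                                        format = c("dcd", "pdb")) {
  format <- match.arg(format)
  if (k_on < 0 || k_off < 0 || k_on + k_off <= 0)
    stop("rates must be non-negative with a positive sum")
  if (jitter_A > 0.1)
    stop("config error: jitter_A large enough to cross contact cutoffs")
  atoms <- .scene_atoms(n_waters)
  base <- as.matrix(atoms[, c("x.1", "x.2", "x.3")])
  colnames(base) <- NULL
  topology <- build_topology(atoms[, c("atom_id", "name", "element",
                                       "resno", "resname", "chain")],
                             ligand_roles = synthetic_ligand_roles())
  ng_row <- which(atoms$name == "NG")
  lig_rows <- which(atoms$resname == "LIG")
  water_rows <- which(atoms$resname == "HOH")

  replicas <- vector("list", n_replicas)
  realized <- list()
  for (r in seq_len(n_replicas)) {
    set.seed(seed + r)
    state <- simulate_two_state(n_frames, k_on, k_off, dt_ns)
    # pre-drawn random streams: the bound/bridge pattern is then invariant
    # to the swap-probability setting (only water identities change)
    u_bridge <- stats::runif(n_frames)
    u_swap <- stats::runif(n_frames)
    k_swap <- 1L + as.integer(floor(stats::runif(n_frames) *
                                      max(1L, n_waters - 1L)))
    jitter <- array(stats::rnorm(n_frames * nrow(base) * 3, 0, jitter_A),
                    dim = c(nrow(base), 3, n_frames))
    frames <- vector("list", n_frames)
    cur_w <- 1L       # index into water_rows of the current bridging water
    n_bridged <- 0L; n_sw <- 0L; n_wmo <- 0L; n_sup <- 0L
    waters_seen <- integer(0)
    for (f in seq_len(n_frames)) {
      x <- base
      bound <- state[f] == 1L
      x[ng_row, ] <- if (bound) .SCENE$bound_NG else .SCENE$unbound_NG
      # keep the aliphatic tail attached to the warhead
      x[lig_rows[1], ] <- x[ng_row, ] + c(1.4, 0.5, 0)
      x[lig_rows[2], ] <- x[ng_row, ] + c(2.8, 0.5, 0)
      bridge <- u_bridge[f] < (if (bound) p_bridge_bound else p_bridge_unbound)
      if (bridge) {
        if (n_bridged > 0L && n_waters > 1 &&
            u_swap[f] < water_swap_prob) {
          # uniform over the other waters
          cur_w <- ((cur_w - 1L + k_swap[f]) %% n_waters) + 1L
          n_sw <- n_sw + 1L
        }
        wpos <- if (bound) .SCENE$bound_bridge_water else .SCENE$bridge_water
        x[water_rows[cur_w], ] <- wpos
        n_bridged <- n_bridged + 1L
        waters_seen <- union(waters_seen, cur_w)
        if (bound) n_sup <- n_sup + 1L else n_wmo <- n_wmo + 1L
      }
      x <- x + jitter[, , f]
      frames[[f]] <- make_frame(x, index = f - 1L, time_ns = (f - 1) * dt_ns)
    }
    replicas[[r]] <- frames
    realized[[r]] <- data.frame(
      replica_id = r,
      occupancy = mean(state),
      f_water_only = n_wmo / n_frames,
      n_bridge_frames = n_bridged,
      n_switches = n_sw,
      distinct_waters = length(waters_seen),
      swap_fraction = if (n_bridged >= 2) n_sw / (n_bridged - 1) else NA_real_)
  }
  realized <- do.call(rbind, realized)

  truth <- list(
    k_on = k_on, k_off = k_off,
    occupancy = k_on / (k_on + k_off),
    relax_time_ns = 1 / (k_on + k_off),
    water_swap_prob = water_swap_prob,
    p_bridge_unbound = p_bridge_unbound,
    p_bridge_bound = p_bridge_bound,
    seed = seed, n_replicas = n_replicas, n_frames = n_frames,
    dt_ns = dt_ns, n_waters = n_waters, jitter_A = jitter_A,
    realized = realized)
  layout <- list(focal_resno = .SCENE$focal_resno,
                 pocket_resnos = .SCENE$pocket_resnos,
                 ligand_resno = .SCENE$ligand_resno,
                 ligand_roles = synthetic_ligand_roles())
  paths <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    top_path <- file.path(out_dir, "topology.pdb")
    write_structure_pdb(topology, replicas[[1]][[1]]$coords, top_path)
    traj_paths <- character(n_replicas)
    for (r in seq_len(n_replicas)) {
      coords <- lapply(replicas[[r]], `[[`, "coords")
      if (format == "dcd") {
        traj_paths[r] <- file.path(out_dir, sprintf("replica_%02d.dcd", r))
        write_dcd(coords, traj_paths[r])
      } else {
        traj_paths[r] <- file.path(out_dir, sprintf("replica_%02d.pdb", r))
        write_structure_pdb(topology, coords, traj_paths[r])
      }
    }
    truth_path <- file.path(out_dir, "truth.json")
    jsonlite::write_json(truth, truth_path, auto_unbox = TRUE, digits = NA,
                         dataframe = "columns")
    paths <- list(topology = top_path, trajectories = traj_paths,
                  truth = truth_path)
  }
  structure(list(topology = topology, frames = replicas, truth = truth,
                 layout = layout, paths = paths),
            class = "synthetic_trajectory")
}

# helix-like non-degenerate scaffold of ALA residues (N, CA, CB, C, O each)
.scaffold_atoms <- function(n_residues = 10L) {
  rows <- list()
  for (i in seq_len(n_residues)) {
    ang <- i * 100 * pi / 180
    ca <- c(2.3 * cos(ang), 2.3 * sin(ang), 1.5 * i)
    offs <- list(N = c(-1.2, 0.4, -0.5), CA = c(0, 0, 0),
                 CB = c(0.6, 1.2, 0.6), C = c(1.3, -0.4, 0.4),
                 O = c(1.6, -1.0, 1.3))
    for (nm in names(offs)) {
      rows[[length(rows) + 1]] <- list(
        nm, substr(nm, 1, 1), i, "ALA", "A", ca + offs[[nm]])
    }
  }
  data.frame(
    atom_id = seq_along(rows),
    name = vapply(rows, `[[`, character(1), 1),
    element = vapply(rows, `[[`, character(1), 2),
    resno = vapply(rows, `[[`, integer(1), 3),
    resname = vapply(rows, `[[`, character(1), 4),
    chain = vapply(rows, `[[`, character(1), 5),
    x = t(vapply(rows, `[[`, numeric(3), 6)),
    stringsAsFactors = FALSE
  )
}

#' Random proper rotation + translation
#'
#' @param max_shift_A translation component range.
#' @return list with `rotation` (3x3, det +1) and `translation`. Uses the
#'   current RNG state.
#' @export
random_rigid_transform <- function(max_shift_A = 10) {
  qr_ <- qr(matrix(stats::rnorm(9), 3, 3))
  R <- qr.Q(qr_)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  list(rotation = R,
       translation = stats::runif(3, -max_shift_A, max_shift_A))
}

#' Generate a pair of static structures with known displacements
#'
#' Model B is model A under a rigid transform plus stated per-residue
#' displacement vectors (applied to all atoms of the residue, after the
#' transform), so superposition on the undisplaced residues must recover
#' each displaced residue's shift exactly.
#'
#' @param displacements named list: residue number -> length-3 displacement
#'   vector (Angstrom). May be empty.
#' @param transform a list with `rotation`/`translation`
#'   ([random_rigid_transform()]), or `NULL` for identity.
#' @param n_residues scaffold size (>= 3).
#' @param out_dir optional directory; writes `model_a.pdb`, `model_b.pdb`,
#'   `truth.json`.
#' @return list of class `"synthetic_pair"`: `model_a`, `model_b`
#'   (structure models), `truth` (displacement magnitudes, rmsd over all
#'   Calpha implied by the displacements, the transform), `paths`.
#' @export
generate_static_pair <- function(displacements = list(), transform = NULL,
                                 n_residues = 10L, out_dir = NULL) {
  if (n_residues < 3) stop("scaffold needs at least 3 residues")
  atoms <- .scaffold_atoms(n_residues)
  base <- as.matrix(atoms[, c("x.1", "x.2", "x.3")])
  colnames(base) <- NULL
  topo <- build_topology(atoms[, c("atom_id", "name", "element", "resno",
                                   "resname", "chain")])
  xb <- base
  if (!is.null(transform))
    xb <- sweep(xb %*% t(transform$rotation), 2, transform$translation, "+")
  mags <- numeric(n_residues)
  for (rs in names(displacements)) {
    v <- displacements[[rs]]
    sel <- atoms$resno == as.integer(rs)
    if (!any(sel)) stop("displacement names unknown residue ", rs)
    xb[sel, ] <- sweep(xb[sel, , drop = FALSE], 2, v, "+")
    mags[as.integer(rs)] <- sqrt(sum(v^2))
  }
  model_a <- structure(list(topology = topo,
                            frame = make_frame(base)),
                       class = "structure_model")
  model_b <- structure(list(topology = topo,
                            frame = make_frame(xb)),
                       class = "structure_model")
  truth <- list(displacement_A = mags,
                rmsd_calpha_A = sqrt(mean(mags^2)),
                has_transform = !is.null(transform))
  paths <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    pa <- file.path(out_dir, "model_a.pdb")
    pb <- file.path(out_dir, "model_b.pdb")
    write_structure_pdb(topo, base, pa)
    write_structure_pdb(topo, xb, pb)
    pt <- file.path(out_dir, "truth.json")
    jsonlite::write_json(truth, pt, auto_unbox = TRUE, digits = NA)
    paths <- list(model_a = pa, model_b = pb, truth = pt)
  }
  structure(list(model_a = model_a, model_b = model_b, truth = truth,
                 paths = paths), class = "synthetic_pair")
}
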