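# Per-frame geometric contact detection: hydrogen bonds, salt bridges,
# single-water bridges, hydrophobic contacts, and the three-way polar
# contact classification of ligand engagement with a focal residue.

#' Default geometric contact criteria
#'
#' All comparisons against cutoffs are inclusive (<=), so boundary cases are
#' deterministic. The hydrogen-bond angle criterion applies only when
#' hydrogen atoms are present (crystal structures typically lack them); the
#' heavy-atom distance criterion is always applied.
#'
#' @param hbond_dist_A heavy-atom donor-acceptor distance cutoff, Angstrom.
#' @param hbond_angle_deg minimum D-H...A angle, degrees, applied when the
#'   donor has attached hydrogens.
#' @param saltbridge_dist_A cation-nitrogen to anion-oxygen cutoff, Angstrom.
#' @param hydrophobic_dist_A carbon-carbon cutoff, Angstrom.
#' @return named list of class `"contact_criteria"`.
#' @export
contact_criteria <- function(hbond_dist_A = 3.5, hbond_angle_deg = 120,
                             saltbridge_dist_A = 4.0,
                             hydrophobic_dist_A = 4.5) {
  stopifnot(hbond_dist_A > 0, saltbridge_dist_A > 0, hydrophobic_dist_A > 0,
            hbond_angle_deg >= 0, hbond_angle_deg <= 180)
  structure(list(hbond_dist_A = hbond_dist_A,
                 hbond_angle_deg = hbond_angle_deg,
                 saltbridge_dist_A = saltbridge_dist_A,
                 hydrophobic_dist_A = hydrophobic_dist_A),
            class = "contact_criteria")
}

# displacement vectors under the minimum-image convention (general
# triclinic box; reduces to the familiar wrap for orthorhombic boxes)
.min_image <- function(d, box) {
  if (is.null(box)) return(d)
  frac <- d %*% solve(box)
  (frac - round(frac)) %*% box
}

# all-pairs distance matrix between two coordinate blocks
.pair_dists <- function(xa, xb, box = NULL) {
  na <- nrow(xa); nb <- nrow(xb)
  d <- matrix(0, na, nb)
  for (i in seq_len(na)) {
    disp <- sweep(xb, 2, xa[i, ])
    disp <- .min_image(disp, box)
    d[i, ] <- sqrt(rowSums(disp * disp))
  }
  d
}

#' Minimum distance between two atom selections
#'
#' Minimum over all atom pairs of the Euclidean distance, using the
#' minimum-image convention when the frame carries a periodic box.
#'
#' @param frame an `"md_frame"`.
#' @param topology the matching `"topology"`.
#' @param sel_a,sel_b integer atom-id vectors (non-empty).
#' @return single numeric distance in Angstrom.
#' @export
min_distance <- function(frame, topology, sel_a, sel_b) {
  .check_frame(frame, topology)
  if (length(sel_a) == 0 || length(sel_b) == 0)
    stop("empty selection in min_distance")
  ia <- .atom_rows(topology, sel_a)
  ib <- .atom_rows(topology, sel_b)
  d <- .pair_dists(frame$coords[ia, , drop = FALSE],
                   frame$coords[ib, , drop = FALSE], frame$box)
  # identical atoms give distance 0 trivially; ignore self-pairs
  if (length(intersect(sel_a, sel_b)) > 0) {
    self <- outer(sel_a, sel_b, "==")
    d[self] <- Inf
  }
  min(d)
}

# hydrogens covalently attached to a donor heavy atom: same residue,
# element H, within 1.25 A
.attached_hydrogens <- function(topology, coords, donor_row, box) {
  a <- topology$atoms
  cand <- which(a$is_hydrogen &
                a$resno == a$resno[donor_row] &
                a$chain == a$chain[donor_row])
  if (length(cand) == 0) return(integer(0))
  disp <- sweep(coords[cand, , drop = FALSE], 2, coords[donor_row, ])
  disp <- .min_image(disp, box)
  cand[sqrt(rowSums(disp * disp)) <= 1.25]
}

.angle_deg <- function(v1, v2) {
  cosang <- sum(v1 * v2) / (sqrt(sum(v1^2)) * sqrt(sum(v2^2)))
  acos(pmin(1, pmax(-1, cosang))) * 180 / pi
}

.empty_hbonds <- function() {
  data.frame(donor_atom = integer(0), hydrogen_atom = integer(0),
             acceptor_atom = integer(0), distance_A = numeric(0),
             angle_deg = numeric(0))
}

#' Detect hydrogen bonds between two atom groups
#'
#' A bond is recorded for every donor heavy atom in one group and acceptor
#' in the other with heavy-atom distance at most the cutoff (inclusive).
#' When the donor has attached hydrogens, the best D-H...A angle must also
#' reach the angle cutoff; donors with no hydrogens (e.g. crystal
#' structures) fall back to the distance-only criterion. Pairs within the
#' same residue are never reported. The result is symmetric in group order.
#'
#' @param frame,topology frame and matching topology.
#' @param group_a,group_b atom-id selections (non-empty).
#' @param criteria a [contact_criteria()] list.
#' @return data.frame with columns `donor_atom`, `hydrogen_atom` (NA when
#'   hydrogens absent), `acceptor_atom`, `distance_A`, `angle_deg` (NA when
#'   no hydrogen).
#' @export
detect_hbonds <- function(frame, topology, group_a, group_b,
                          criteria = contact_criteria()) {
  .check_frame(frame, topology)
  if (length(group_a) == 0 || length(group_b) == 0)
    stop("empty selection in detect_hbonds")
  a <- topology$atoms
  coords <- frame$coords
  out <- list()
  directions <- list(c(1, 2), c(2, 1))
  groups <- list(group_a, group_b)
  for (dir in directions) {
    gd <- groups[[dir[1]]]; ga <- groups[[dir[2]]]
    rd <- .atom_rows(topology, gd)
    ra <- .atom_rows(topology, ga)
    rd <- rd[a$donor[rd] & !a$is_hydrogen[rd]]
    ra <- ra[a$acceptor[ra] & !a$is_hydrogen[ra]]
    if (length(rd) == 0 || length(ra) == 0) next
    dm <- .pair_dists(coords[rd, , drop = FALSE],
                      coords[ra, , drop = FALSE], frame$box)
    hits <- which(dm <= criteria$hbond_dist_A, arr.ind = TRUE)
    for (k in seq_len(nrow(hits))) {
      i <- rd[hits[k, 1]]; j <- ra[hits[k, 2]]
      if (i == j) next
      if (a$resno[i] == a$resno[j] && a$chain[i] == a$chain[j]) next
      hyd <- .attached_hydrogens(topology, coords, i, frame$box)
      best_h <- NA_integer_; best_ang <- NA_real_
      if (length(hyd) > 0) {
        angs <- vapply(hyd, function(h) {
          dh <- .min_image(matrix(coords[h, ] - coords[i, ], 1), frame$box)
          ha <- .min_image(matrix(coords[j, ] - coords[h, ], 1), frame$box)
          .angle_deg(-dh[1, ], ha[1, ])  # angle at H between H->D and H->A
        }, numeric(1))
        best <- which.max(angs)
        if (angs[best] < criteria$hbond_angle_deg) next
        best_h <- a$atom_id[hyd[best]]; best_ang <- angs[best]
      }
      out[[length(out) + 1]] <- data.frame(
        donor_atom = a$atom_id[i], hydrogen_atom = best_h,
        acceptor_atom = a$atom_id[j],
        distance_A = dm[hits[k, 1], hits[k, 2]], angle_deg = best_ang)
    }
  }
  if (length(out) == 0) return(.empty_hbonds())
  res <- do.call(rbind, out)
  res <- res[!duplicated(res[, c("donor_atom", "acceptor_atom")]), ,
             drop = FALSE]
  res[order(res$donor_atom, res$acceptor_atom), , drop = FALSE]
}

#' Detect salt bridges between two atom groups
#'
#' Every cation heavy atom in one group within the cutoff (inclusive) of an
#' anion heavy atom in the other group is reported, in both group orders.
#'
#' @inheritParams detect_hbonds
#' @return data.frame with columns `cation_atom`, `anion_atom`,
#'   `distance_A`.
#' @export
detect_salt_bridges <- function(frame, topology, group_a, group_b,
                                criteria = contact_criteria()) {
  .check_frame(frame, topology)
  if (length(group_a) == 0 || length(group_b) == 0)
    stop("empty selection in detect_salt_bridges")
  a <- topology$atoms
  out <- list()
  for (dir in list(list(group_a, group_b), list(group_b, group_a))) {
    rc <- .atom_rows(topology, dir[[1]])
    rn <- .atom_rows(topology, dir[[2]])
    rc <- rc[a$cation[rc] & !a$is_hydrogen[rc]]
    rn <- rn[a$anion[rn] & !a$is_hydrogen[rn]]
    if (length(rc) == 0 || length(rn) == 0) next
    dm <- .pair_dists(frame$coords[rc, , drop = FALSE],
                      frame$coords[rn, , drop = FALSE], frame$box)
    hits <- which(dm <= criteria$saltbridge_dist_A, arr.ind = TRUE)
    for (k in seq_len(nrow(hits))) {
      out[[length(out) + 1]] <- data.frame(
        cation_atom = a$atom_id[rc[hits[k, 1]]],
        anion_atom = a$atom_id[rn[hits[k, 2]]],
        distance_A = dm[hits[k, 1], hits[k, 2]])
    }
  }
  if (length(out) == 0)
    return(data.frame(cation_atom = integer(0), anion_atom = integer(0),
                      distance_A = numeric(0)))
  res <- do.call(rbind, out)
  res <- res[!duplicated(res[, c("cation_atom", "anion_atom")]), ,
             drop = FALSE]
  res[order(res$cation_atom, res$anion_atom), , drop = FALSE]
}

#' Detect single-water bridges between ligand and target atoms
#'
#' A bridge is recorded for every water whose oxygen simultaneously
#' hydrogen-bonds (per [detect_hbonds()]) to at least one ligand atom and
#' at least one target atom in the same frame; one row per
#' (ligand atom, water, target atom) triple. Only order-1 bridges (exactly
#' one bridging water) are considered.
#'
#' @inheritParams detect_hbonds
#' @param ligand_atoms,target_atoms atom-id selections.
#' @return data.frame with columns `ligand_atom`, `water_resno`,
#'   `target_atom`, `dist_ligand_A`, `dist_target_A`.
#' @export
detect_water_bridges <- function(frame, topology, ligand_atoms, target_atoms,
                                 criteria = contact_criteria()) {
  .check_frame(frame, topology)
  a <- topology$atoms
  waters <- select_atoms(topology, role = "water", element = "O")
  empty <- data.frame(ligand_atom = integer(0), water_resno = integer(0),
                      target_atom = integer(0), dist_ligand_A = numeric(0),
                      dist_target_A = numeric(0))
  if (length(waters) == 0) {
    warning("no waters in topology; no bridges detectable")
    return(empty)
  }
  leg1 <- detect_hbonds(frame, topology, ligand_atoms, waters, criteria)
  if (nrow(leg1) == 0) return(empty)
  leg2 <- detect_hbonds(frame, topology, waters, target_atoms, criteria)
  if (nrow(leg2) == 0) return(empty)

  water_of <- function(atom_ids) a$resno[.atom_rows(topology, atom_ids)]
  is_water_atom <- function(atom_ids) a$is_water[.atom_rows(topology, atom_ids)]

  # orient each leg as (partner, water)
  l1_water <- ifelse(is_water_atom(leg1$donor_atom), leg1$donor_atom,
                     leg1$acceptor_atom)
  l1_lig <- ifelse(is_water_atom(leg1$donor_atom), leg1$acceptor_atom,
                   leg1$donor_atom)
  l2_water <- ifelse(is_water_atom(leg2$donor_atom), leg2$donor_atom,
                     leg2$acceptor_atom)
  l2_tgt <- ifelse(is_water_atom(leg2$donor_atom), leg2$acceptor_atom,
                   leg2$donor_atom)
  keep1 <- is_water_atom(l1_water) & !is_water_atom(l1_lig) &
    l1_lig %in% ligand_atoms
  keep2 <- is_water_atom(l2_water) & !is_water_atom(l2_tgt) &
    l2_tgt %in% target_atoms

  out <- list()
  w1 <- water_of(l1_water)
  w2 <- water_of(l2_water)
  for (i in which(keep1)) {
    js <- which(keep2 & w2 == w1[i])
    for (j in js) {
      out[[length(out) + 1]] <- data.frame(
        ligand_atom = l1_lig[i], water_resno = w1[i],
        target_atom = l2_tgt[j],
        dist_ligand_A = leg1$distance_A[i],
        dist_target_A = leg2$distance_A[j])
    }
  }
  if (length(out) == 0) return(empty)
  res <- do.call(rbind, out)
  res <- res[!duplicated(res[, c("ligand_atom", "water_resno",
                                 "target_atom")]), , drop = FALSE]
  res[order(res$ligand_atom, res$water_resno, res$target_atom), ,
      drop = FALSE]
}

#' Contact category levels
#' @export
CONTACT_CATEGORIES <- c("NO_POLAR_CONTACT", "WATER_MEDIATED_ONLY",
                        "DIRECT_INTERACTION")

#' Classify one frame's polar engagement of the focal residue
#'
#' The three categories are exhaustive and mutually exclusive:
#' `DIRECT_INTERACTION` when any direct hydrogen bond or salt bridge links
#' ligand and focal residue (whether or not water bridges also exist);
#' otherwise `WATER_MEDIATED_ONLY` when any single-water bridge links the
#' ligand to any pocket residue; otherwise `NO_POLAR_CONTACT`.
#'
#' @param direct_hbonds,direct_saltbridges contact tables restricted to the
#'   focal residue (as returned by the detectors).
#' @param bridges water-bridge table to the pocket residue set.
#' @return one of [CONTACT_CATEGORIES], as character.
#' @export
classify_frame <- function(direct_hbonds, direct_saltbridges, bridges) {
  n_direct <- NROW(direct_hbonds) + NROW(direct_saltbridges)
  if (n_direct > 0) return("DIRECT_INTERACTION")
  if (NROW(bridges) > 0) return("WATER_MEDIATED_ONLY")
  "NO_POLAR_CONTACT"
}

#' Detect hydrophobic contacts between a ligand and a residue set
#'
#' One record per residue whose minimal carbon-carbon distance to the
#' ligand selection is at most the cutoff (inclusive).
#'
#' @inheritParams detect_hbonds
#' @param ligand_atoms atom-id selection for the ligand.
#' @param residue_set integer vector of residue numbers to profile.
#' @return data.frame with columns `resno`, `min_distance_A`.
#' @export
detect_hydrophobic_contacts <- function(frame, topology, ligand_atoms,
                                        residue_set,
                                        criteria = contact_criteria()) {
  .check_frame(frame, topology)
  if (length(residue_set) == 0)
    return(data.frame(resno = integer(0), min_distance_A = numeric(0)))
  lig_c <- intersect(ligand_atoms, select_atoms(topology, role = "hydrophobic"))
  out <- list()
  for (rs in residue_set) {
    res_c <- select_atoms(topology, resno = rs, role = "hydrophobic")
    res_c <- setdiff(res_c, ligand_atoms)
    if (length(lig_c) == 0 || length(res_c) == 0) next
    d <- min_distance(frame, topology, lig_c, res_c)
    if (d <= criteria$hydrophobic_dist_A)
      out[[length(out) + 1]] <- data.frame(resno = rs, min_distance_A = d)
  }
  if (length(out) == 0)
    return(data.frame(resno = integer(0), min_distance_A = numeric(0)))
  do.call(rbind, out)
}

#' Per-frame contact analysis of a trajectory
#'
#' Runs the full per-frame detection for one replica: direct hydrogen
#' bonds and salt bridges between the ligand and the focal residue,
#' single-water bridges between the ligand and the pocket residue set, the
#' three-way classification, and (optionally) hydrophobic contact
#' profiling.
#'
#' @param frames list of `"md_frame"` objects (one replica, time order).
#' @param topology matching `"topology"`.
#' @param ligand_atoms atom ids of the ligand.
#' @param focal_resno residue number of the focal residue (the classified
#'   partner, e.g. the sodium-pocket aspartate).
#' @param pocket_resnos residue numbers of the pocket set scanned for water
#'   bridges (should include `focal_resno`).
#' @param criteria a [contact_criteria()] list.
#' @param hydrophobic_resnos optional residue numbers for hydrophobic
#'   profiling.
#' @param replica_id integer label carried into all outputs.
#' @return list of class `"contact_analysis"` with data.frames:
#'   `categories` (frame, time_ns, category), `direct` (per-frame direct
#'   contacts with distances), `bridges` (per-frame water bridges),
#'   `hydrophobic`, and the `replica_id`.
#' @export
analyze_contacts <- function(frames, topology, ligand_atoms, focal_resno,
                             pocket_resnos = focal_resno,
                             criteria = contact_criteria(),
                             hydrophobic_resnos = NULL,
                             replica_id = 1L) {
  if (length(frames) == 0) stop("empty trajectory: no frames to analyze")
  focal_atoms <- select_atoms(topology, resno = focal_resno)
  if (length(focal_atoms) == 0) stop("focal residue not found: ", focal_resno)
  pocket_atoms <- select_atoms(topology, resno = pocket_resnos)
  cats <- character(length(frames))
  times <- vapply(frames, function(f) f$time_ns, numeric(1))
  idx <- vapply(frames, function(f) f$index, integer(1))
  direct_rows <- list(); bridge_rows <- list(); hydro_rows <- list()
  for (k in seq_along(frames)) {
    fr <- frames[[k]]
    hb <- detect_hbonds(fr, topology, ligand_atoms, focal_atoms, criteria)
    sb <- detect_salt_bridges(fr, topology, ligand_atoms, focal_atoms,
                              criteria)
    br <- suppressWarnings(
      detect_water_bridges(fr, topology, ligand_atoms, pocket_atoms,
                           criteria))
    cats[k] <- classify_frame(hb, sb, br)
    if (nrow(hb) > 0)
      direct_rows[[length(direct_rows) + 1]] <-
        cbind(frame = idx[k], time_ns = times[k], type = "hbond",
              atom_a = hb$donor_atom, atom_b = hb$acceptor_atom,
              distance_A = hb$distance_A)
    if (nrow(sb) > 0)
      direct_rows[[length(direct_rows) + 1]] <-
        cbind(frame = idx[k], time_ns = times[k], type = "salt_bridge",
              atom_a = sb$cation_atom, atom_b = sb$anion_atom,
              distance_A = sb$distance_A)
    if (nrow(br) > 0)
      bridge_rows[[length(bridge_rows) + 1]] <-
        data.frame(frame = idx[k], time_ns = times[k],
                   ligand_atom = br$ligand_atom,
                   water_resno = br$water_resno,
                   target_atom = br$target_atom)
    if (!is.null(hydrophobic_resnos)) {
      hc <- detect_hydrophobic_contacts(fr, topology, ligand_atoms,
                                        hydrophobic_resnos, criteria)
      if (nrow(hc) > 0)
        hydro_rows[[length(hydro_rows) + 1]] <-
          data.frame(frame = idx[k], time_ns = times[k], resno = hc$resno,
                     min_distance_A = hc$min_distance_A)
    }
  }
  bind <- function(rows, proto) {
    if (length(rows) == 0) return(proto)
    df <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
    for (col in setdiff(names(df), "type")) df[[col]] <- as.numeric(df[[col]])
    df
  }
  structure(list(
    replica_id = as.integer(replica_id),
    criteria = criteria,
    categories = data.frame(frame = idx, time_ns = times, category = cats,
                            stringsAsFactors = FALSE),
    direct = bind(direct_rows,
                  data.frame(frame = numeric(0), time_ns = numeric(0),
                             type = character(0), atom_a = numeric(0),
                             atom_b = numeric(0), distance_A = numeric(0))),
    bridges = if (length(bridge_rows) == 0)
      data.frame(frame = numeric(0), time_ns = numeric(0),
                 ligand_atom = numeric(0), water_resno = numeric(0),
                 target_atom = numeric(0))
      else do.call(rbind, bridge_rows),
    hydrophobic = if (length(hydro_rows) == 0)
      data.frame(frame = numeric(0), time_ns = numeric(0),
                 resno = numeric(0), min_distance_A = numeric(0))
      else do.call(rbind, hydro_rows)
  ), class = "contact_analysis")
}
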