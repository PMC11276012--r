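# Geometric contact detection and the three-way polar classification.

# tiny scene builder: explicit atoms with coordinates and declared roles
scene <- function(rows, ligand_roles = NULL) {
  atoms <- data.frame(
    atom_id = seq_along(rows),
    name = vapply(rows, `[[`, character(1), 1),
    element = vapply(rows, `[[`, character(1), 2),
    resno = vapply(rows, function(r) as.integer(r[[3]]), integer(1)),
    resname = vapply(rows, `[[`, character(1), 4),
    chain = "A", stringsAsFactors = FALSE)
  topo <- build_topology(atoms, ligand_roles = ligand_roles)
  coords <- t(vapply(rows, `[[`, numeric(3), 5))
  list(topology = topo, frame = make_frame(coords))
}

lig_roles <- list(LIG = list(donor = "NG", cation = "NG", acceptor = "OL"))

test_that("hydrogen bonds obey distance and angle criteria", {
  # donor O with H pointing at acceptor O 2.8 A away: one bond
  s <- scene(list(
    list("OG", "O", 1, "SER", c(0, 0, 0)),
    list("HG", "H", 1, "SER", c(1, 0, 0)),
    list("O",  "O", 2, "GLY", c(2.8, 0, 0))))  # backbone O: acceptor only
  hb <- detect_hbonds(s$frame, s$topology, 1:2, 3)
  expect_equal(nrow(hb), 1)
  expect_equal(hb$distance_A, 2.8, tolerance = 1e-9)
  expect_equal(hb$angle_deg, 180, tolerance = 1e-6)

  # 10 A apart: nothing
  s2 <- scene(list(
    list("OG", "O", 1, "SER", c(0, 0, 0)),
    list("O",  "O", 2, "GLY", c(10, 0, 0))))
  expect_equal(nrow(detect_hbonds(s2$frame, s2$topology, 1, 2)), 0)

  # 3.4 A but D-H...A angle 100 deg < 120: rejected
  h_pos <- c(cos(80 * pi / 180), sin(80 * pi / 180), 0)
  s3 <- scene(list(
    list("OG", "O", 1, "SER", h_pos * 0),
    list("HG", "H", 1, "SER", h_pos),
    list("O",  "O", 2, "GLY", c(3.4, 0, 0))))
  ang <- {
    v1 <- c(0, 0, 0) - h_pos; v2 <- c(3.4, 0, 0) - h_pos
    acos(sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))) * 180 / pi
  }
  expect_lt(ang, 120)
  expect_equal(nrow(detect_hbonds(s3$frame, s3$topology, 1:2, 3)), 0)

  # symmetric in group order
  hb_rev <- detect_hbonds(s$frame, s$topology, 3, 1:2)
  expect_equal(hb_rev$donor_atom, hb$donor_atom)
  expect_equal(hb_rev$acceptor_atom, hb$acceptor_atom)

  expect_error(detect_hbonds(s$frame, s$topology, integer(0), 3),
               "empty selection")
})

test_that("salt bridges use the inclusive cutoff on charged heavy atoms", {
  mk <- function(d) scene(list(
    list("NG",  "N", 900, "LIG", c(0, 0, 0)),
    list("OD1", "O", 95, "ASP", c(d, 0, 0))), ligand_roles = lig_roles)
  s <- mk(3.0)
  sb <- detect_salt_bridges(s$frame, s$topology, 1, 2)
  expect_equal(nrow(sb), 1)
  expect_equal(sb$distance_A, 3.0, tolerance = 1e-9)
  expect_equal(nrow(detect_salt_bridges(mk(8)$frame, mk(8)$topology, 1, 2)), 0)
  # exactly at the 4.0 A default cutoff: included
  s4 <- mk(4.0)
  expect_equal(nrow(detect_salt_bridges(s4$frame, s4$topology, 1, 2)), 1)
})

test_that("water bridges require both legs in the same frame", {
  s <- scene(list(
    list("NG",  "N", 900, "LIG", c(0, 0, 0)),
    list("O",   "O", 500, "HOH", c(2.9, 0, 0)),
    list("OD1", "O", 95, "ASP", c(5.7, 0, 0))), ligand_roles = lig_roles)
  br <- detect_water_bridges(s$frame, s$topology, 1, 3)
  expect_equal(nrow(br), 1)
  expect_equal(br$water_resno, 500)
  expect_equal(br$ligand_atom, 1)
  expect_equal(br$target_atom, 3)

  # water H-bonded to the ligand only: no bridge
  s1 <- scene(list(
    list("NG",  "N", 900, "LIG", c(0, 0, 0)),
    list("O",   "O", 500, "HOH", c(2.9, 0, 0)),
    list("OD1", "O", 95, "ASP", c(12, 0, 0))), ligand_roles = lig_roles)
  expect_equal(nrow(detect_water_bridges(s1$frame, s1$topology, 1, 3)), 0)

  # no waters at all: empty with a warning, not an error
  s2 <- scene(list(
    list("NG",  "N", 900, "LIG", c(0, 0, 0)),
    list("OD1", "O", 95, "ASP", c(5.7, 0, 0))), ligand_roles = lig_roles)
  expect_warning(br2 <- detect_water_bridges(s2$frame, s2$topology, 1, 2),
                 "no waters")
  expect_equal(nrow(br2), 0)
})

test_that("frame classification is exhaustive and follows the hierarchy", {
  hb1 <- data.frame(donor_atom = 1, hydrogen_atom = NA, acceptor_atom = 2,
                    distance_A = 2.9, angle_deg = NA)
  sb1 <- data.frame(cation_atom = 1, anion_atom = 2, distance_A = 2.9)
  br1 <- data.frame(ligand_atom = 1, water_resno = 500, target_atom = 3)
  none <- data.frame()
  # direct contact wins even when supplemented by water bridges
  expect_equal(classify_frame(none, sb1, br1), "DIRECT_INTERACTION")
  expect_equal(classify_frame(hb1, none, none), "DIRECT_INTERACTION")
  # bridge to any pocket residue without direct contact
  expect_equal(classify_frame(none, none, br1), "WATER_MEDIATED_ONLY")
  expect_equal(classify_frame(none, none, none), "NO_POLAR_CONTACT")
})

test_that("hydrophobic contacts use minimal C-C distance, inclusive", {
  mk <- function(d) scene(list(
    list("C1",  "C", 900, "LIG", c(0, 0, 0)),
    list("CD1", "C", 132, "MET", c(d, 0, 0)),
    list("CA",  "C", 132, "MET", c(d + 1.5, 0, 0))))
  s <- mk(4.0)
  hc <- detect_hydrophobic_contacts(s$frame, s$topology, 1, 132)
  expect_equal(nrow(hc), 1)
  expect_equal(hc$min_distance_A, 4.0, tolerance = 1e-9)
  expect_equal(nrow(detect_hydrophobic_contacts(mk(10)$frame,
                                                mk(10)$topology, 1, 132)), 0)
  s45 <- mk(4.5)
  expect_equal(nrow(detect_hydrophobic_contacts(s45$frame, s45$topology,
                                                1, 132)), 1)
  expect_equal(nrow(detect_hydrophobic_contacts(s$frame, s$topology, 1,
                                                integer(0))), 0)
})

test_that("min_distance handles plain and minimum-image geometry", {
  s <- scene(list(
    list("C1", "C", 1, "LIG", c(0, 0, 0)),
    list("C2", "C", 2, "LIG", c(3, 4, 0))))
  expect_equal(min_distance(s$frame, s$topology, 1, 2), 5.0)
  # 9 A apart in a 10 A box: 1 A under minimum image
  f_box <- make_frame(rbind(c(0, 0, 0), c(9, 0, 0)), box = diag(c(10, 10, 10)))
  expect_equal(min_distance(f_box, s$topology, 1, 2), 1.0, tolerance = 1e-9)
  expect_equal(oracle_dist(c(0, 0, 0), c(9, 0, 0), diag(c(10, 10, 10))), 1.0)
  expect_error(min_distance(s$frame, s$topology, integer(0), 2),
               "empty selection")
  # identical selections: min over distinct pairs
  expect_equal(min_distance(s$frame, s$topology, 1:2, 1:2), 5.0)
})

test_that("all detectors match the brute-force oracle on random frames", {
  # bulk of the random-frame budget lives in the acceptance suite; this is
  # the fast per-module version with a different seed
  set.seed(42)
  crit <- contact_criteria()
  for (rep in 1:120) {
    sc <- random_frame_scene(with_box = rep %% 3 == 0)
    hb <- detect_hbonds(sc$frame, sc$topology, sc$group_a, sc$group_b, crit)
    ohb <- oracle_hbonds(sc$frame, sc$topology, sc$group_a, sc$group_b, crit)
    expect_equal(cbind(hb$donor_atom, hb$acceptor_atom),
                 matrix(as.integer(ohb), ncol = 2), ignore_attr = TRUE)
    sb <- detect_salt_bridges(sc$frame, sc$topology, sc$group_a, sc$group_b,
                              crit)
    osb <- oracle_salt_bridges(sc$frame, sc$topology, sc$group_a,
                               sc$group_b, crit)
    expect_equal(cbind(sb$cation_atom, sb$anion_atom),
                 matrix(as.integer(osb), ncol = 2), ignore_attr = TRUE)
    expect_equal(min_distance(sc$frame, sc$topology, sc$group_a, sc$group_b),
                 oracle_min_distance(sc$frame, sc$topology, sc$group_a,
                                     sc$group_b), tolerance = 1e-9)
    br <- suppressWarnings(
      detect_water_bridges(sc$frame, sc$topology, sc$group_a, sc$group_b,
                           crit))
    obr <- oracle_water_bridges(sc$frame, sc$topology, sc$group_a,
                                sc$group_b, crit)
    expect_equal(cbind(br$ligand_atom, br$water_resno, br$target_atom),
                 matrix(as.integer(obr), ncol = 3), ignore_attr = TRUE)
  }
})

test_that("loosening a cutoff never decreases the number of contacts", {
  set.seed(7)
  for (rep in 1:25) {
    sc <- random_frame_scene()
    tight <- contact_criteria(hbond_dist_A = 3.0, saltbridge_dist_A = 3.5)
    loose <- contact_criteria(hbond_dist_A = 4.0, saltbridge_dist_A = 4.5)
    expect_lte(
      nrow(detect_hbonds(sc$frame, sc$topology, sc$group_a, sc$group_b, tight)),
      nrow(detect_hbonds(sc$frame, sc$topology, sc$group_a, sc$group_b, loose)))
    expect_lte(
      nrow(detect_salt_bridges(sc$frame, sc$topology, sc$group_a,
                               sc$group_b, tight)),
      nrow(detect_salt_bridges(sc$frame, sc$topology, sc$group_a,
                               sc$group_b, loose)))
  }
})

test_that("category counts sum to frame count; DIRECT frames ignore waters", {
  g <- generate_contact_trajectory(n_replicas = 2, n_frames = 60, seed = 21)
  topo <- g$topology
  lig <- select_atoms(topo, resno = g$layout$ligand_resno)
  for (r in 1:2) {
    an <- analyze_contacts(g$frames[[r]], topo, lig,
                           focal_resno = g$layout$focal_resno,
                           pocket_resnos = g$layout$pocket_resnos,
                           replica_id = r)
    expect_equal(nrow(an$categories), 60)
    expect_equal(sum(table(factor(an$categories$category,
                                  levels = CONTACT_CATEGORIES))), 60)
  }
  # removing all waters never changes a DIRECT frame's category
  an <- analyze_contacts(g$frames[[1]], topo, lig,
                         focal_resno = g$layout$focal_resno,
                         pocket_resnos = g$layout$pocket_resnos)
  keep <- !topo$atoms$is_water
  atoms_dry <- topo$atoms[keep, c("atom_id", "name", "element", "resno",
                                  "resname", "chain")]
  atoms_dry$atom_id <- seq_len(nrow(atoms_dry))
  topo_dry <- build_topology(atoms_dry,
                             ligand_roles = synthetic_ligand_roles())
  frames_dry <- lapply(g$frames[[1]], function(f)
    make_frame(f$coords[keep, ], index = f$index, time_ns = f$time_ns))
  lig_dry <- select_atoms(topo_dry, resno = g$layout$ligand_resno)
  an_dry <- suppressWarnings(
    analyze_contacts(frames_dry, topo_dry, lig_dry,
                     focal_resno = g$layout$focal_resno,
                     pocket_resnos = g$layout$pocket_resnos))
  was_direct <- an$categories$category == "DIRECT_INTERACTION"
  expect_identical(an_dry$categories$category[was_direct],
                   an$categories$category[was_direct])
})
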