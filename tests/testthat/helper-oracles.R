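# Independent reference implementations used as oracles. Deliberately
# naive: explicit loops, no shared code with the package internals.

# minimum-image distance by explicit search over the 27 neighbour images
oracle_dist <- function(p, q, box = NULL) {
  if (is.null(box)) return(sqrt(sum((p - q)^2)))
  best <- Inf
  for (i in -1:1) for (j in -1:1) for (k in -1:1) {
    shift <- i * box[1, ] + j * box[2, ] + k * box[3, ]
    d <- sqrt(sum((p - (q + shift))^2))
    if (d < best) best <- d
  }
  best
}

oracle_min_distance <- function(frame, topology, sel_a, sel_b) {
  a <- topology$atoms
  best <- Inf
  for (i in sel_a) for (j in sel_b) {
    if (i == j) next
    d <- oracle_dist(frame$coords[match(i, a$atom_id), ],
                     frame$coords[match(j, a$atom_id), ], frame$box)
    if (d < best) best <- d
  }
  best
}

# all donor->acceptor pairs across two groups meeting the distance (and,
# when the donor has hydrogens, angle) criteria; same-residue pairs skipped
oracle_hbonds <- function(frame, topology, ga, gb, criteria) {
  a <- topology$atoms
  x <- frame$coords
  res <- list()
  for (pair in list(c("a", "b"), c("b", "a"))) {
    gd <- if (pair[1] == "a") ga else gb
    gacc <- if (pair[2] == "a") ga else gb
    for (i in gd) for (j in gacc) {
      ri <- match(i, a$atom_id); rj <- match(j, a$atom_id)
      if (!a$donor[ri] || a$is_hydrogen[ri]) next
      if (!a$acceptor[rj] || a$is_hydrogen[rj]) next
      if (i == j) next
      if (a$resno[ri] == a$resno[rj] && a$chain[ri] == a$chain[rj]) next
      d <- oracle_dist(x[ri, ], x[rj, ], frame$box)
      if (d > criteria$hbond_dist_A) next
      hyds <- which(a$is_hydrogen & a$resno == a$resno[ri] &
                    a$chain == a$chain[ri])
      if (length(hyds) > 0)
        hyds <- hyds[vapply(hyds, function(h)
          oracle_dist(x[h, ], x[ri, ], frame$box) <= 1.25, logical(1))]
      if (length(hyds) > 0) {
        angs <- sapply(hyds, function(h) {
          v1 <- x[ri, ] - x[h, ]; v2 <- x[rj, ] - x[h, ]
          cosv <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
          acos(max(-1, min(1, cosv))) * 180 / pi
        })
        if (max(angs) < criteria$hbond_angle_deg) next
      }
      res[[length(res) + 1]] <- c(donor = i, acceptor = j)
    }
  }
  if (length(res) == 0) return(matrix(numeric(0), ncol = 2))
  m <- unique(do.call(rbind, res))
  m[order(m[, 1], m[, 2]), , drop = FALSE]
}

oracle_salt_bridges <- function(frame, topology, ga, gb, criteria) {
  a <- topology$atoms
  x <- frame$coords
  res <- list()
  for (pair in 1:2) {
    gc_ <- if (pair == 1) ga else gb
    gn <- if (pair == 1) gb else ga
    for (i in gc_) for (j in gn) {
      ri <- match(i, a$atom_id); rj <- match(j, a$atom_id)
      if (!a$cation[ri] || a$is_hydrogen[ri]) next
      if (!a$anion[rj] || a$is_hydrogen[rj]) next
      if (oracle_dist(x[ri, ], x[rj, ], frame$box) <= criteria$saltbridge_dist_A)
        res[[length(res) + 1]] <- c(cation = i, anion = j)
    }
  }
  if (length(res) == 0) return(matrix(numeric(0), ncol = 2))
  m <- unique(do.call(rbind, res))
  m[order(m[, 1], m[, 2]), , drop = FALSE]
}

oracle_water_bridges <- function(frame, topology, lig, tgt, criteria) {
  a <- topology$atoms
  waters <- a$atom_id[a$is_water & a$element == "O"]
  res <- list()
  for (w in waters) {
    hb1 <- oracle_hbonds(frame, topology, lig, w, criteria)
    hb2 <- oracle_hbonds(frame, topology, w, tgt, criteria)
    if (nrow(hb1) == 0 || nrow(hb2) == 0) next
    lig_part <- unique(as.vector(hb1))
    lig_part <- lig_part[lig_part %in% lig]
    tgt_part <- unique(as.vector(hb2))
    tgt_part <- tgt_part[tgt_part %in% tgt]
    wres <- a$resno[match(w, a$atom_id)]
    for (l in lig_part) for (t in tgt_part)
      res[[length(res) + 1]] <- c(l, wres, t)
  }
  if (length(res) == 0) return(matrix(numeric(0), ncol = 3))
  m <- unique(do.call(rbind, res))
  m[order(m[, 1], m[, 2], m[, 3]), , drop = FALSE]
}

# analytic two-state indicator autocorrelation (intermittent definition)
oracle_two_state_C <- function(t, k_on, k_off) {
  occ <- k_on / (k_on + k_off)
  occ + (1 - occ) * exp(-(k_on + k_off) * t)
}

# closed-form Welch statistic and two-sided p
oracle_welch <- function(a, b) {
  va <- var(a) / length(a); vb <- var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  list(statistic = t, p = 2 * pt(-abs(t), df))
}

# random small scene with explicit role flags, for oracle-equivalence runs
random_frame_scene <- function(n_atoms = NULL, with_box = FALSE) {
  if (is.null(n_atoms)) n_atoms <- sample(10:50, 1)
  n_waters <- sample(0:4, 1)
  n_prot <- n_atoms - n_waters
  atoms <- data.frame(
    atom_id = seq_len(n_atoms),
    name = paste0("X", seq_len(n_atoms)),
    element = sample(c("C", "N", "O"), n_atoms, replace = TRUE),
    resno = seq_len(n_atoms),   # one atom per residue: all pairs eligible
    resname = c(rep("UNK", n_prot), rep("HOH", n_waters)),
    chain = "A", stringsAsFactors = FALSE)
  if (n_waters > 0) {
    wi <- (n_prot + 1):n_atoms
    atoms$element[wi] <- "O"
    atoms$name[wi] <- "O"
  }
  topo <- build_topology(atoms)
  # random role flags on non-water atoms (overrides the name lookup so the
  # role pattern is arbitrary; both detector and oracle read these flags)
  nw <- !topo$atoms$is_water
  topo$atoms$donor[nw] <- runif(sum(nw)) < 0.4
  topo$atoms$acceptor[nw] <- runif(sum(nw)) < 0.4
  topo$atoms$cation[nw] <- runif(sum(nw)) < 0.25
  topo$atoms$anion[nw] <- runif(sum(nw)) < 0.25
  box <- if (with_box) diag(runif(3, 8, 15)) else NULL
  frame <- make_frame(matrix(runif(n_atoms * 3, 0, 10), n_atoms, 3),
                      box = box)
  half <- floor(n_prot / 2)
  list(topology = topo, frame = frame,
       group_a = atoms$atom_id[seq_len(half)],
       group_b = atoms$atom_id[(half + 1):n_prot])
}
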