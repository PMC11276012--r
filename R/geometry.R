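# Static-structure geometry: Ballesteros-Weinstein residue resolution,
# distances, Kabsch superposition, and displacement metrics.

#' Read a Ballesteros-Weinstein numbering map
#'
#' Two-column whitespace-separated text table: BW code (`helix.position`,
#' e.g. `2.50`) and residue as `chain:resseq` or `chain:resseq:resname`.
#' Lines starting with `#` are ignored.
#'
#' @param path path to the map file.
#' @return named list of class `"bw_map"`; each entry holds `chain`,
#'   `resno`, and optional `resname`.
#' @export
read_bw_map <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  entries <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "[[:space:]]+")[[1]]
    if (length(parts) != 2) stop("malformed BW map line: ", ln)
    code <- parts[1]
    if (!is.null(entries[[code]])) stop("duplicate BW code: ", code)
    bits <- strsplit(parts[2], ":")[[1]]
    if (length(bits) < 2) stop("malformed residue spec in BW map: ", parts[2])
    entries[[code]] <- list(chain = bits[1], resno = as.integer(bits[2]),
                            resname = if (length(bits) >= 3) bits[3] else NA)
  }
  structure(entries, class = "bw_map")
}

#' Build a BW map in code
#'
#' @param codes character vector of BW codes.
#' @param chains,resnos,resnames parallel vectors.
#' @return a `"bw_map"`.
#' @export
bw_map <- function(codes, chains, resnos, resnames = NA) {
  if (anyDuplicated(codes)) stop("BW codes must be unique")
  resnames <- rep_len(resnames, length(codes))
  chains <- rep_len(chains, length(codes))
  entries <- Map(function(ch, rn, nm) list(chain = ch, resno = rn,
                                           resname = nm),
                 chains, resnos, resnames)
  names(entries) <- codes
  structure(entries, class = "bw_map")
}

#' Resolve a BW code to a residue
#'
#' @param map a `"bw_map"`.
#' @param code BW code such as `"2.50"`.
#' @param model optional `"structure_model"` used to verify that the
#'   residue exists and that its name matches the map (mismatch warns).
#' @return list with `chain`, `resno`, `resname`.
#' @export
bw_resolve <- function(map, code, model = NULL) {
  hit <- map[[code]]
  if (is.null(hit)) stop("unknown BW code: ", code)
  if (!is.null(model)) {
    a <- model$topology$atoms
    sel <- a$resno == hit$resno & a$chain == hit$chain
    if (!any(sel)) stop("BW code ", code, " resolves to ", hit$chain, ":",
                        hit$resno, " which is absent from the structure")
    name_in_struct <- unique(a$resname[sel])[1]
    if (!is.na(hit$resname) && name_in_struct != hit$resname)
      warning("BW code ", code, ": map says ", hit$resname,
              " but structure has ", name_in_struct)
    hit$resname <- name_in_struct
  }
  hit
}

# parse "chain:resseq:atomname" / "chain:resseq" atom specs
.resolve_spec <- function(model, spec) {
  if (is.numeric(spec)) return(as.integer(spec))
  bits <- strsplit(spec, ":")[[1]]
  ids <- select_atoms(model$topology,
                      chain = bits[1], resno = as.integer(bits[2]),
                      name = if (length(bits) >= 3) bits[3] else NULL)
  if (length(ids) == 0) stop("atom spec matches no atoms: ", spec)
  ids
}

#' Distance between two atom specifications in a static model
#'
#' Plain Euclidean distance (no periodic imaging for crystal models). In
#' `atom_atom` mode both specs must resolve to exactly one atom; in
#' `group_min` mode the minimum over all pairs is returned, which is the
#' natural measurement between chemical groups (e.g. a basic amine
#' nitrogen and the nearer of a carboxylate's two oxygens).
#'
#' @param model a `"structure_model"`.
#' @param spec_a,spec_b atom specs (`"chain:resseq:atomname"`,
#'   `"chain:resseq"`, or integer atom ids).
#' @param mode `"atom_atom"` or `"group_min"`.
#' @return distance in Angstrom.
#' @export
atom_distance <- function(model, spec_a, spec_b,
                          mode = c("group_min", "atom_atom")) {
  mode <- match.arg(mode)
  ia <- .resolve_spec(model, spec_a)
  ib <- .resolve_spec(model, spec_b)
  if (mode == "atom_atom" && (length(ia) != 1 || length(ib) != 1))
    stop("atom_atom mode requires specs resolving to single atoms")
  ra <- .atom_rows(model$topology, ia)
  rb <- .atom_rows(model$topology, ib)
  d <- .pair_dists(model$frame$coords[ra, , drop = FALSE],
                   model$frame$coords[rb, , drop = FALSE], box = NULL)
  min(d)
}

# Kabsch: optimal proper rotation/translation minimizing RMSD of paired
# coordinate sets (rows)
.kabsch <- function(mobile, reference) {
  cm <- colMeans(mobile); cr <- colMeans(reference)
  P <- sweep(mobile, 2, cm)
  Q <- sweep(reference, 2, cr)
  H <- t(P) %*% Q
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  list(rotation = R, translation = as.vector(cr - R %*% cm))
}

#' Least-squares rigid superposition (Kabsch)
#'
#' Finds the proper rotation and translation minimizing the RMSD of the
#' selected atom pairs, and reports the minimized RMSD.
#'
#' @param mobile,reference `"structure_model"` objects.
#' @param sel_mobile,sel_reference paired atom-id vectors of equal length
#'   (>= 3 non-collinear atoms).
#' @return list of class `"superposition"`: `rotation` (3x3, det +1),
#'   `translation` (length 3, Angstrom), `rmsd_A`, `n_atoms_used`.
#' @export
superpose <- function(mobile, reference, sel_mobile, sel_reference) {
  if (length(sel_mobile) != length(sel_reference))
    stop("paired selections must have equal length")
  if (length(sel_mobile) < 3)
    stop("superposition needs at least 3 paired atoms")
  xm <- mobile$frame$coords[.atom_rows(mobile$topology, sel_mobile), ,
                            drop = FALSE]
  xr <- reference$frame$coords[.atom_rows(reference$topology,
                                          sel_reference), , drop = FALSE]
  # collinearity check: rank of centered reference coordinates
  ctr <- sweep(xr, 2, colMeans(xr))
  if (sum(svd(ctr)$d > 1e-8) < 2)
    stop("degenerate (collinear) selection: superposition undefined")
  k <- .kabsch(xm, xr)
  fitted <- sweep(xm %*% t(k$rotation), 2, k$translation, "+")
  rmsd <- sqrt(mean(rowSums((fitted - xr)^2)))
  structure(list(rotation = k$rotation, translation = k$translation,
                 rmsd_A = rmsd, n_atoms_used = length(sel_mobile)),
            class = "superposition")
}

#' Apply a superposition transform to a model
#'
#' Returns a copy of the model with all coordinates transformed; the model
#' is marked as superposed so displacement metrics can verify their
#' precondition.
#'
#' @param model a `"structure_model"`.
#' @param sup a `"superposition"` from [superpose()].
#' @return transformed `"structure_model"`.
#' @export
apply_superposition <- function(model, sup) {
  x <- model$frame$coords
  model$frame$coords <- sweep(x %*% t(sup$rotation), 2, sup$translation, "+")
  attr(model, "superposed") <- TRUE
  model
}

.BACKBONE_NAMES <- c("N", "CA", "C", "O", "OXT")

#' Per-residue displacement between two (superposed) models
#'
#' Both models must already be in the same frame of reference (superposed
#' on a stated selection); a contract warning is raised otherwise.
#'
#' @param model_a,model_b `"structure_model"` objects.
#' @param chain,resno residue to measure (must exist in both).
#' @param mode `"calpha"` (Calpha displacement), `"sidechain_centroid"`
#'   (displacement of the heavy-sidechain centroid), or `"sidechain_max"`
#'   (maximum per-atom displacement over sidechain atoms shared by name).
#' @return displacement in Angstrom.
#' @export
residue_displacement <- function(model_a, model_b, chain, resno,
                                 mode = c("calpha", "sidechain_centroid",
                                          "sidechain_max")) {
  mode <- match.arg(mode)
  if (is.null(attr(model_a, "superposed")) &&
      is.null(attr(model_b, "superposed")))
    warning("neither model is marked superposed; displacement assumes a ",
            "common reference frame")
  get_res <- function(model) {
    a <- model$topology$atoms
    sel <- a$chain == chain & a$resno == resno & !a$is_hydrogen
    if (!any(sel)) stop("residue ", chain, ":", resno,
                        " missing from a model")
    cbind(a[sel, c("name"), drop = FALSE],
          as.data.frame(model$frame$coords[sel, , drop = FALSE]))
  }
  ra <- get_res(model_a); rb <- get_res(model_b)
  if (mode == "calpha") {
    ca_a <- ra[ra$name == "CA", 2:4]; ca_b <- rb[rb$name == "CA", 2:4]
    if (nrow(ca_a) == 0 || nrow(ca_b) == 0) stop("no CA atom in residue")
    return(sqrt(sum((as.numeric(ca_a[1, ]) - as.numeric(ca_b[1, ]))^2)))
  }
  sa <- ra[!ra$name %in% .BACKBONE_NAMES, , drop = FALSE]
  sb <- rb[!rb$name %in% .BACKBONE_NAMES, , drop = FALSE]
  if (nrow(sa) == 0 || nrow(sb) == 0)
    stop("residue has no sidechain heavy atoms")
  if (mode == "sidechain_centroid") {
    return(sqrt(sum((colMeans(sa[, 2:4]) - colMeans(sb[, 2:4]))^2)))
  }
  shared <- intersect(sa$name, sb$name)
  if (length(shared) == 0) stop("no shared sidechain atoms")
  max(vapply(shared, function(nm) {
    pa <- as.numeric(sa[sa$name == nm, 2:4][1, ])
    pb <- as.numeric(sb[sb$name == nm, 2:4][1, ])
    sqrt(sum((pa - pb)^2))
  }, numeric(1)))
}

#' Anchor-to-pocket design distance
#'
#' Group-minimum distance between a ligand anchor group (e.g. the
#' morphinan basic tertiary amine nitrogen) and a receptor target group
#' (e.g. the sodium-pocket aspartate carboxylate oxygens) in a static
#' structure. This is the measurement that sets the target reach for a
#' bitopic linker.
#'
#' @param model a `"structure_model"`.
#' @param anchor_spec,target_spec atom specs (see [atom_distance()]).
#' @return list with `distance_A`, `anchor_spec`, `target_spec` (the specs
#'   are reported alongside the number, since group choices are part of the
#'   measurement).
#' @export
measure_design_distance <- function(model, anchor_spec, target_spec) {
  d <- atom_distance(model, anchor_spec, target_spec, mode = "group_min")
  list(distance_A = d, anchor_spec = anchor_spec, target_spec = target_spec)
}
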