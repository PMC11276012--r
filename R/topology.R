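#' @keywords internal
"_PACKAGE"

# Water residue names recognised by default. Configurable everywhere a
# topology is built.
DEFAULT_WATER_RESNAMES <- c("HOH", "WAT", "TIP3", "TIP", "SOL", "SPC", "H2O")

# Hydrogen-bond donor heavy atoms of the standard amino acids (sidechains;
# the backbone amide N is a donor for every residue type).
.SIDECHAIN_DONORS <- list(
  SER = "OG", THR = "OG1", TYR = "OH", CYS = "SG",
  ASN = "ND2", GLN = "NE2", HIS = c("ND1", "NE2"),
  TRP = "NE1", LYS = "NZ", ARG = c("NE", "NH1", "NH2")
)

# Acceptor heavy atoms (backbone carbonyl O and terminal OXT accepted for
# every residue type).
.SIDECHAIN_ACCEPTORS <- list(
  SER = "OG", THR = "OG1", TYR = "OH", CYS = "SG",
  ASN = "OD1", GLN = "OE1", HIS = c("ND1", "NE2"),
  ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"), MET = "SD"
)

# Formal-charge carriers at physiological pH.
.SIDECHAIN_CATIONS <- list(LYS = "NZ", ARG = c("NE", "NH1", "NH2", "CZ"))
.SIDECHAIN_ANIONS  <- list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"))

.AMINO3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
             "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
             "TYR", "VAL", "HSD", "HSE", "HSP")

.match_role <- function(resname, name, table) {
  hit <- table[[resname]]
  !is.null(hit) && name %in% hit
}

#' Build a topology from an atom table
#'
#' A topology is the static half of the internal trajectory model: one row
#' per atom with residue membership, element, and polar/hydrophobic role
#' flags. Roles for the twenty standard amino acids and for water are
#' assigned from built-in lookup tables; roles for any other residue
#' (ligands, ions) must be declared explicitly via `ligand_roles` and are
#' never inferred.
#'
#' @param atoms data.frame with columns `atom_id` (integer, unique),
#'   `name` (atom name, e.g. `"OD1"`), `element` (e.g. `"O"`),
#'   `resno` (residue sequence number), `resname`, `chain`.
#' @param water_resnames residue names treated as water.
#' @param ligand_roles optional named list: one entry per residue name, each
#'   a list with any of the character vectors `donor`, `acceptor`, `cation`,
#'   `anion` naming atoms of that residue carrying the role.
#' @return object of class `"topology"`: list with `atoms` (the table plus
#'   logical role columns `is_water`, `is_hydrogen`, `donor`, `acceptor`,
#'   `cation`, `anion`, `hydrophobic`) and `n_atoms`.
#' @export
build_topology <- function(atoms, water_resnames = DEFAULT_WATER_RESNAMES,
                           ligand_roles = NULL) {
  required <- c("atom_id", "name", "element", "resno", "resname", "chain")
  missing <- setdiff(required, names(atoms))
  if (length(missing) > 0)
    stop("atom table missing column(s): ", paste(missing, collapse = ", "))
  if (nrow(atoms) == 0) stop("empty model: topology must contain at least one atom")
  if (anyDuplicated(atoms$atom_id))
    stop("atom_ids must be unique")

  a <- atoms
  a$element <- toupper(a$element)
  a$is_water <- a$resname %in% water_resnames
  a$is_hydrogen <- a$element == "H"

  n <- nrow(a)
  donor <- acceptor <- cation <- anion <- logical(n)

  std <- a$resname %in% .AMINO3
  # backbone roles for standard residues
  donor[std & a$name == "N"] <- TRUE
  acceptor[std & a$name %in% c("O", "OXT")] <- TRUE
  anion[std & a$name == "OXT"] <- TRUE
  for (i in which(std)) {
    rn <- a$resname[i]; nm <- a$name[i]
    if (.match_role(rn, nm, .SIDECHAIN_DONORS))    donor[i] <- TRUE
    if (.match_role(rn, nm, .SIDECHAIN_ACCEPTORS)) acceptor[i] <- TRUE
    if (.match_role(rn, nm, .SIDECHAIN_CATIONS))   cation[i] <- TRUE
    if (.match_role(rn, nm, .SIDECHAIN_ANIONS))    anion[i] <- TRUE
  }

  # water oxygen both donates and accepts
  wox <- a$is_water & a$element == "O"
  donor[wox] <- TRUE
  acceptor[wox] <- TRUE

  # declared ligand roles
  if (!is.null(ligand_roles)) {
    for (rn in names(ligand_roles)) {
      decl <- ligand_roles[[rn]]
      sel <- a$resname == rn
      donor[sel & a$name %in% decl$donor] <- TRUE
      acceptor[sel & a$name %in% decl$acceptor] <- TRUE
      cation[sel & a$name %in% decl$cation] <- TRUE
      anion[sel & a$name %in% decl$anion] <- TRUE
    }
  }

  a$donor <- donor
  a$acceptor <- acceptor
  a$cation <- cation
  a$anion <- anion
  # contact profiling uses minimal carbon-carbon distances, so every carbon
  # is a candidate hydrophobic atom
  a$hydrophobic <- a$element == "C"

  structure(list(atoms = a, n_atoms = n), class = "topology")
}

#' @export
print.topology <- function(x, ...) {
  cat("topology:", x$n_atoms, "atoms,",
      length(unique(paste(x$atoms$chain, x$atoms$resno))), "residues,",
      sum(x$atoms$is_water & x$atoms$element == "O"), "waters\n")
  invisible(x)
}

#' Construct a single coordinate frame
#'
#' @param coords numeric matrix, `n_atoms` x 3, in Angstrom.
#' @param index integer frame index (position in the source trajectory).
#' @param time_ns time of the frame in nanoseconds.
#' @param box optional 3x3 matrix of box vectors (rows), Angstrom. Must be
#'   invertible when given.
#' @return object of class `"md_frame"`.
#' @export
make_frame <- function(coords, index = 0L, time_ns = 0, box = NULL) {
  coords <- as.matrix(coords)
  if (ncol(coords) != 3) stop("coords must have 3 columns")
  if (time_ns < 0) stop("time_ns must be non-negative")
  if (!is.null(box)) {
    box <- as.matrix(box)
    if (!all(dim(box) == c(3, 3))) stop("box must be 3x3")
    if (abs(det(box)) < 1e-9) stop("box matrix is singular")
  }
  structure(list(index = as.integer(index), time_ns = time_ns,
                 coords = coords, box = box), class = "md_frame")
}

.check_frame <- function(frame, topology) {
  if (nrow(frame$coords) != topology$n_atoms)
    stop("topology mismatch: frame has ", nrow(frame$coords),
         " atoms, topology has ", topology$n_atoms)
  invisible(TRUE)
}

#' Select atom ids from a topology
#'
#' All supplied filters are combined with AND; vector-valued filters match
#' any of their values.
#'
#' @param topology a `"topology"`.
#' @param resno,resname,chain,name,element optional filters.
#' @param role optional role filter: one of `"donor"`, `"acceptor"`,
#'   `"cation"`, `"anion"`, `"hydrophobic"`, `"water"`, `"heavy"`.
#' @return integer vector of atom ids (possibly empty).
#' @export
select_atoms <- function(topology, resno = NULL, resname = NULL, chain = NULL,
                         name = NULL, element = NULL, role = NULL) {
  a <- topology$atoms
  keep <- rep(TRUE, nrow(a))
  if (!is.null(resno))   keep <- keep & a$resno %in% resno
  if (!is.null(resname)) keep <- keep & a$resname %in% resname
  if (!is.null(chain))   keep <- keep & a$chain %in% chain
  if (!is.null(name))    keep <- keep & a$name %in% name
  if (!is.null(element)) keep <- keep & a$element %in% toupper(element)
  if (!is.null(role)) {
    keep <- keep & switch(role,
      donor = a$donor, acceptor = a$acceptor, cation = a$cation,
      anion = a$anion, hydrophobic = a$hydrophobic, water = a$is_water,
      heavy = !a$is_hydrogen,
      stop("unknown role: ", role))
  }
  a$atom_id[keep]
}

# rows of the atom table for a set of atom ids, in id order
.atom_rows <- function(topology, atom_ids) {
  idx <- match(atom_ids, topology$atoms$atom_id)
  if (anyNA(idx)) stop("unknown atom id(s): ",
                       paste(atom_ids[is.na(idx)], collapse = ", "))
  idx
}
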