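# Structure and trajectory I/O. Parsing of the standard formats is
# delegated to bio3d; this layer resolves alternate locations, assigns
# polar roles, and converts everything to the internal model (Angstrom, ns).

.element_from_name <- function(name) {
  # PDB convention: strip digits/primes, first remaining letter run; two
  # letter elements only for common hetero cases
  core <- gsub("[0-9']", "", name)
  first <- toupper(substr(core, 1, 1))
  if (first == "") "X" else first
}

# keep the highest-occupancy altloc per (chain, resno, insert, name); ties
# broken alphabetically by altloc code
.resolve_altlocs <- function(atom) {
  alt <- atom$alt
  alt[is.na(alt)] <- ""
  if (all(alt == "")) return(atom)
  occ <- atom$o
  occ[is.na(occ)] <- 1
  key <- paste(atom$chain, atom$resno, atom$insert, atom$elety, sep = "|")
  ord <- order(key, -occ, alt)
  keep_first <- !duplicated(key[ord])
  atom[sort(ord[keep_first]), , drop = FALSE]
}

#' Load a static structure from PDB or mmCIF
#'
#' Coordinates are kept in Angstrom and residue numbering is preserved
#' verbatim from the file. Alternate locations are resolved to the highest
#' occupancy conformer (ties broken alphabetically by altloc code).
#'
#' @param path path to a PDB or mmCIF file.
#' @param format `"pdb"`, `"mmcif"`, or `"auto"` (by extension; `.cif` ->
#'   mmCIF).
#' @param water_resnames,ligand_roles passed to [build_topology()].
#' @return object of class `"structure_model"`: list with `topology` and
#'   `frame` (a single [make_frame()] frame).
#' @export
load_structure <- function(path, format = c("auto", "pdb", "mmcif"),
                           water_resnames = DEFAULT_WATER_RESNAMES,
                           ligand_roles = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("cif", "mmcif")) "mmcif" else "pdb"
  }
  pdb <- tryCatch(
    if (format == "mmcif") bio3d::read.cif(path, verbose = FALSE)
    else bio3d::read.pdb(path, rm.alt = FALSE, verbose = FALSE),
    error = function(e) stop("parse error reading ", path, ": ",
                             conditionMessage(e), call. = FALSE))
  atom <- pdb$atom
  if (is.null(atom) || nrow(atom) == 0)
    stop("empty model: no atoms in ", path)
  atom <- .resolve_altlocs(atom)

  elesy <- atom$elesy
  if (is.null(elesy)) elesy <- rep(NA_character_, nrow(atom))
  blank <- is.na(elesy) | trimws(elesy) == ""
  elesy[blank] <- vapply(atom$elety[blank], .element_from_name, character(1))
  chain <- atom$chain
  chain[is.na(chain)] <- " "

  atoms <- data.frame(
    atom_id = seq_len(nrow(atom)),
    name = atom$elety,
    element = trimws(elesy),
    resno = atom$resno,
    resname = trimws(atom$resid),
    chain = chain,
    stringsAsFactors = FALSE
  )
  topology <- build_topology(atoms, water_resnames = water_resnames,
                             ligand_roles = ligand_roles)
  coords <- cbind(atom$x, atom$y, atom$z)
  structure(list(topology = topology,
                 frame = make_frame(coords, index = 0L, time_ns = 0)),
            class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  cat("structure_model: ")
  print(x$topology)
  invisible(x)
}

#' Read trajectory frames
#'
#' Supported coordinate formats are DCD (CHARMM/NAMD convention, Angstrom)
#' and multi-model PDB. Frames are returned in time order with `index`
#' reflecting the 0-based position in the source file.
#'
#' @param traj_path path to a `.dcd` or multi-model `.pdb` file.
#' @param topology the matching `"topology"`; atom counts must agree.
#' @param stride keep every `stride`-th frame, starting at the first.
#' @param dt_ns time spacing between consecutive stored frames, ns.
#' @param format `"auto"`, `"dcd"` or `"pdb"`.
#' @return list of `"md_frame"` objects, length `ceiling(n_frames/stride)`.
#' @export
read_frames <- function(traj_path, topology, stride = 1L, dt_ns = 0.1,
                        format = c("auto", "dcd", "pdb")) {
  format <- match.arg(format)
  if (!file.exists(traj_path)) stop("file not found: ", traj_path)
  stride <- as.integer(stride)
  if (stride < 1) stop("stride must be a positive integer")
  if (format == "auto") {
    ext <- tolower(tools::file_ext(traj_path))
    format <- switch(ext, dcd = "dcd", pdb = "pdb",
                     stop("unsupported trajectory format: .", ext,
                          " (supported: dcd, pdb)"))
  }
  xyz <- if (format == "dcd") {
    bio3d::read.dcd(traj_path, verbose = FALSE)
  } else {
    bio3d::read.pdb(traj_path, multi = TRUE, verbose = FALSE)$xyz
  }
  xyz <- as.matrix(xyz)
  if (ncol(xyz) != 3L * topology$n_atoms)
    stop("topology mismatch: trajectory has ", ncol(xyz) / 3,
         " atoms per frame, topology has ", topology$n_atoms)
  picks <- seq(1L, nrow(xyz), by = stride)
  lapply(picks, function(i) {
    make_frame(matrix(xyz[i, ], ncol = 3, byrow = TRUE),
               index = i - 1L, time_ns = (i - 1L) * dt_ns)
  })
}

#' Write a structure model (or one frame of a topology) as PDB
#'
#' @param topology a `"topology"`.
#' @param coords one n x 3 matrix or a list of them (multi-model output).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_structure_pdb <- function(topology, coords, path) {
  a <- topology$atoms
  if (!is.list(coords) || is.matrix(coords)) coords <- list(coords)
  xyz <- do.call(rbind, lapply(coords, function(m) as.vector(t(as.matrix(m)))))
  bio3d::write.pdb(file = path, xyz = xyz,
                   type = ifelse(a$resname %in% .AMINO3, "ATOM", "HETATM"),
                   resno = a$resno, resid = a$resname, eleno = a$atom_id,
                   elety = a$name, chain = a$chain,
                   o = rep(1, nrow(a)), b = rep(0, nrow(a)),
                   elesy = a$element)
  invisible(path)
}

#' Write coordinate frames as a CHARMM-convention DCD file
#'
#' Minimal single-precision little-endian DCD writer (no unit cell
#' records). Output is readable by [bio3d::read.dcd()] and by the common
#' MD analysis stacks.
#'
#' @param frames list of n x 3 coordinate matrices (Angstrom), or a list of
#'   `"md_frame"` objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_dcd <- function(frames, path) {
  coords <- lapply(frames, function(f) {
    if (inherits(f, "md_frame")) f$coords else as.matrix(f)
  })
  nf <- length(coords)
  if (nf == 0) stop("no frames to write")
  natom <- nrow(coords[[1]])
  con <- file(path, "wb")
  on.exit(close(con))
  wint <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  # header block: 'CORD' + 20-slot control array (counts, timestep, flags)
  wint(84L)
  writeChar("CORD", con, nchars = 4, eos = NULL)
  wint(c(nf, 1L, 1L, nf, 0L, 0L, 0L, 0L, 0L))
  writeBin(1, con, size = 4, endian = "little")   # nominal timestep slot
  wint(c(0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L, 24L))
  wint(84L)
  title <- sprintf("%-80s", "mdpolar synthetic trajectory")
  wint(84L + 0L)  # 4 + 80*1
  wint(1L)
  writeChar(title, con, nchars = 80, eos = NULL)
  wint(84L)
  wint(4L); wint(natom); wint(4L)
  for (m in coords) {
    if (nrow(m) != natom) stop("inconsistent atom count across frames")
    for (axis in 1:3) {
      wint(4L * natom)
      writeBin(as.numeric(m[, axis]), con, size = 4, endian = "little")
      wint(4L * natom)
    }
  }
  invisible(path)
}

#' Write a data frame as TSV with a JSON metadata sidecar
#'
#' Every analysis table is written together with the parameters that
#' produced it, so no output carries bare numbers.
#'
#' @param df data frame to write.
#' @param path output TSV path; the sidecar goes to `<path>.meta.json`.
#' @param meta named list of run metadata (inputs, cutoffs, seed, ...).
#' @return `path`, invisibly.
#' @export
write_tsv_report <- function(df, path, meta = list()) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  meta$written <- basename(path)
  meta$package_version <- as.character(utils::packageVersion("mdpolar"))
  jsonlite::write_json(meta, paste0(path, ".meta.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
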