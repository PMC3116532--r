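#' @importFrom stats rnorm sd setNames
#' @importFrom utils head tail write.table
NULL

WATER_RESNAMES <- c("HOH", "WAT", "H2O", "DOD", "SOL", "TIP3")

PROTEIN_RESNAMES <- c(
  "ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
  "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL",
  "MSE", "HSD", "HSE", "HSP"
)

NUCLEIC_RESNAMES <- c(
  "A", "C", "G", "U", "I", "DA", "DC", "DG", "DT", "DU",
  "RA", "RC", "RG", "RU", "ADE", "CYT", "GUA", "URA", "THY",
  "1MA", "2MG", "5MC", "5MU", "7MG", "H2U", "M2G", "OMC", "OMG", "PSU", "YG"
)

# Backbone/sugar atom names of a nucleotide; everything else (heavy, non-H)
# counts as a base atom for contact analysis.
SUGAR_PHOSPHATE_ATOMS <- c(
  "P", "OP1", "OP2", "OP3", "O1P", "O2P", "O3P",
  "O5'", "C5'", "C4'", "O4'", "C3'", "O3'", "C2'", "O2'", "C1'",
  "O5*", "C5*", "C4*", "O4*", "C3*", "O3*", "C2*", "O2*", "C1*"
)

#' Construct an atomic structure
#'
#' The central container for an ordered set of atom records. Atom order is
#' stable: selections and round-trips preserve it.
#'
#' @param atoms data.frame with columns `serial`, `name`, `resname`, `chain`,
#'   `resid` (integer residue number), `insert` (insertion code, "" if none),
#'   `element`, `x`, `y`, `z` (Angstrom).
#' @param annotation free-form named list of metadata (source id, state label
#'   such as A/T, A, P, P/E, generator parameters, ...).
#' @return object of class `mdmd_structure`.
#' @export
new_structure <- function(atoms, annotation = list()) {
  required <- c("serial", "name", "resname", "chain", "resid", "insert",
                "element", "x", "y", "z")
  missing_cols <- setdiff(required, names(atoms))
  if (length(missing_cols)) {
    stop("atoms is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z))) {
    stop("atom coordinates must be finite")
  }
  key <- paste(atoms$chain, atoms$resid, atoms$insert, atoms$name)
  if (anyDuplicated(key)) {
    stop("duplicate (chain, resid, name) atom records: ",
         paste(unique(key[duplicated(key)])[1], collapse = " "))
  }
  rownames(atoms) <- NULL
  structure(list(atoms = atoms, annotation = annotation),
            class = "mdmd_structure")
}

#' @export
print.mdmd_structure <- function(x, ...) {
  cat(sprintf("mdmd_structure: %d atoms, %d residues, chains: %s\n",
              nrow(x$atoms),
              length(unique(paste(x$atoms$chain, x$atoms$resid))),
              paste(unique(x$atoms$chain), collapse = ",")))
  invisible(x)
}

#' Number of atoms in a structure
#' @param s an `mdmd_structure`.
#' @return integer atom count.
#' @export
n_atoms <- function(s) nrow(s$atoms)

#' Extract coordinates as an N x 3 matrix
#' @param s an `mdmd_structure`.
#' @return numeric matrix with columns x, y, z (Angstrom).
#' @export
coords <- function(s) {
  as.matrix(s$atoms[, c("x", "y", "z")])
}

#' Replace the coordinates of a structure
#' @param s an `mdmd_structure`.
#' @param xyz N x 3 matrix or length-3N vector (bio3d convention).
#' @return structure with updated coordinates.
#' @export
set_coords <- function(s, xyz) {
  if (is.null(dim(xyz))) xyz <- matrix(xyz, ncol = 3, byrow = TRUE)
  if (nrow(xyz) != n_atoms(s)) {
    stop("coordinate count (", nrow(xyz), ") does not match atom count (",
         n_atoms(s), ")")
  }
  s$atoms$x <- xyz[, 1]
  s$atoms$y <- xyz[, 2]
  s$atoms$z <- xyz[, 3]
  s
}

#' Select a subset of atoms
#'
#' Subsets preserve original atom order. All filters are ANDed; `NULL` means
#' "no constraint".
#'
#' @param s an `mdmd_structure`.
#' @param resid integer vector of residue numbers, or a selection string such
#'   as `"1-7,66-72"` (see [parse_selection()]).
#' @param name atom-name filter (e.g. `"P"`).
#' @param chain chain-id filter.
#' @param base_only if TRUE keep only nucleotide base atoms (heavy atoms that
#'   are not part of the sugar-phosphate backbone).
#' @return an `mdmd_structure` with the selected atoms.
#' @export
select_atoms <- function(s, resid = NULL, name = NULL, chain = NULL,
                         base_only = FALSE) {
  keep <- rep(TRUE, n_atoms(s))
  if (!is.null(resid)) {
    if (is.character(resid)) resid <- parse_selection(resid)
    keep <- keep & s$atoms$resid %in% resid
  }
  if (!is.null(name)) keep <- keep & s$atoms$name %in% name
  if (!is.null(chain)) keep <- keep & s$atoms$chain %in% chain
  if (base_only) {
    keep <- keep & !(s$atoms$name %in% SUGAR_PHOSPHATE_ATOMS) &
      !(s$atoms$element %in% c("H", "D"))
  }
  new_structure(s$atoms[keep, , drop = FALSE], s$annotation)
}

#' Parse a residue-range selection string
#'
#' Compact grammar used throughout the command-line interface and analysis
#' defaults: comma-separated residue numbers or hyphenated ranges, e.g.
#' `"1-7,66-72"`.
#'
#' @param text selection string.
#' @return sorted integer vector of residue numbers.
#' @export
parse_selection <- function(text) {
  if (!is.character(text) || length(text) != 1 || !nzchar(trimws(text))) {
    stop("selection must be a non-empty string like \"1-7,66-72\"")
  }
  parts <- strsplit(trimws(text), ",", fixed = TRUE)[[1]]
  out <- integer(0)
  for (p in parts) {
    p <- trimws(p)
    if (grepl("^-?[0-9]+--?[0-9]+$", p)) {
      bounds <- as.integer(strsplit(sub("^(-?[0-9]+)-", "\\1 ", p), " ")[[1]])
      out <- c(out, seq(bounds[1], bounds[2]))
    } else if (grepl("^-?[0-9]+$", p)) {
      out <- c(out, as.integer(p))
    } else {
      stop("cannot parse selection token: '", p, "'")
    }
  }
  sort(unique(out))
}

guess_element <- function(name) {
  nm <- gsub("[^A-Za-z]", "", name)
  two <- toupper(substr(nm, 1, 2))
  ifelse(two %in% c("CL", "BR", "NA", "MG", "FE", "ZN", "MN", "SE"),
         two, toupper(substr(nm, 1, 1)))
}

#' Read a PDB-format structure
#'
#' Parses ATOM and non-water HETATM records. Alternate locations are resolved
#' to the highest occupancy (ties keep altloc "A" for determinism); insertion
#' codes are preserved.
#'
#' @param source path to a PDB file, or a character string holding PDB text
#'   (recognized by embedded newlines).
#' @param keep_water include water molecules (default FALSE).
#' @param keep_hetatm include non-water HETATM records (default TRUE).
#' @return an `mdmd_structure`.
#' @export
read_pdb <- function(source, keep_water = FALSE, keep_hetatm = TRUE) {
  path <- source
  if (length(source) > 1 || grepl("\n", source)) {
    path <- tempfile(fileext = ".pdb")
    on.exit(unlink(path), add = TRUE)
    writeLines(unlist(strsplit(paste(source, collapse = "\n"), "\n")), path)
  }
  if (!file.exists(path)) stop("PDB file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  rec <- grepl("^(ATOM  |HETATM)", lines)
  if (!any(rec)) stop("no ATOM/HETATM records in ", path)
  # validate coordinate fields up front so errors carry a line number
  for (i in which(rec)) {
    fields <- c(substr(lines[i], 31, 38), substr(lines[i], 39, 46),
                substr(lines[i], 47, 54))
    if (anyNA(suppressWarnings(as.numeric(fields)))) {
      stop("malformed coordinate field at line ", i, ": ", lines[i])
    }
  }
  pdb <- bio3d::read.pdb(path, verbose = FALSE, hex = TRUE, rm.alt = FALSE)
  at <- pdb$atom
  keep <- rep(TRUE, nrow(at))
  is_water <- at$resid %in% WATER_RESNAMES
  if (!keep_water) keep <- keep & !is_water
  if (!keep_hetatm) keep <- keep & (at$type == "ATOM" | is_water & keep_water)
  at <- at[keep, , drop = FALSE]
  if (!nrow(at)) stop("no atoms left after filtering in ", path)

  at$chain[is.na(at$chain)] <- ""
  at$insert[is.na(at$insert)] <- ""
  at$alt[is.na(at$alt)] <- ""
  at$o[is.na(at$o)] <- 1

  # resolve alternate locations: highest occupancy wins, tie -> altloc "A"
  key <- paste(at$chain, at$resno, at$insert, at$elety)
  ord <- order(match(key, unique(key)), -at$o, at$alt)
  at <- at[ord, , drop = FALSE]
  at <- at[!duplicated(paste(at$chain, at$resno, at$insert, at$elety)), ,
           drop = FALSE]
  at <- at[order(match(paste(at$chain, at$resno, at$insert, at$elety),
                       unique(key))), , drop = FALSE]

  elem <- at$elesy
  elem[is.na(elem) | !nzchar(trimws(elem))] <- NA
  elem <- ifelse(is.na(elem), guess_element(at$elety), trimws(elem))

  atoms <- data.frame(
    serial = at$eleno, name = at$elety, resname = at$resid,
    chain = at$chain, resid = at$resno, insert = at$insert,
    element = elem, x = at$x, y = at$y, z = at$z,
    stringsAsFactors = FALSE
  )
  new_structure(atoms, annotation = list(source = as.character(source)[1]))
}

#' Write a structure to a PDB file
#'
#' @param s an `mdmd_structure`.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_pdb <- function(s, file) {
  a <- s$atoms
  bio3d::write.pdb(
    file = file,
    xyz = as.vector(t(coords(s))),
    type = rep("ATOM", nrow(a)),
    resno = a$resid, resid = a$resname, chain = a$chain,
    insert = a$insert, eleno = a$serial, elety = a$name,
    elesy = a$element
  )
  invisible(file)
}

#' Construct a trajectory
#'
#' Ordered coordinate frames congruent with a topology structure. Frames use
#' the bio3d layout: one row per frame, 3N columns (x1, y1, z1, x2, ...).
#'
#' @param topology an `mdmd_structure` giving atom identities.
#' @param xyz numeric matrix (frames x 3N) or a list of N x 3 matrices.
#' @param time optional per-frame time/iteration labels.
#' @return object of class `mdmd_trajectory`.
#' @export
new_trajectory <- function(topology, xyz, time = NULL) {
  if (is.list(xyz) && !is.matrix(xyz)) {
    xyz <- do.call(rbind, lapply(xyz, function(m) as.vector(t(m))))
  }
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  if (ncol(xyz) != 3 * n_atoms(topology)) {
    stop("frame width ", ncol(xyz), " does not match 3 x ", n_atoms(topology),
         " topology atoms")
  }
  if (nrow(xyz) == 0) stop("trajectory must contain at least one frame")
  if (is.null(time)) time <- seq_len(nrow(xyz))
  structure(list(topology = topology, xyz = xyz, time = time),
            class = "mdmd_trajectory")
}

#' @export
print.mdmd_trajectory <- function(x, ...) {
  cat(sprintf("mdmd_trajectory: %d frames x %d atoms\n",
              nrow(x$xyz), n_atoms(x$topology)))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj an `mdmd_trajectory`.
#' @return integer frame count.
#' @export
n_frames <- function(traj) nrow(traj$xyz)

#' Extract one frame of a trajectory as a structure
#' @param traj an `mdmd_trajectory`.
#' @param i frame index.
#' @return an `mdmd_structure`.
#' @export
frame_structure <- function(traj, i) {
  set_coords(traj$topology, traj$xyz[i, ])
}

#' Read a multi-model PDB file as a trajectory
#'
#' The first MODEL supplies the topology; every MODEL must have the same
#' atom count.
#'
#' @param source path to a multi-model PDB file.
#' @return an `mdmd_trajectory` (a single-model file gives one frame).
#' @export
read_trajectory_pdb <- function(source) {
  if (!file.exists(source)) stop("PDB file not found: ", source)
  pdb <- bio3d::read.pdb(source, multi = TRUE, verbose = FALSE, hex = TRUE)
  top <- read_pdb(source)
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  if (ncol(xyz) != 3 * n_atoms(top)) {
    # filtering (e.g. waters) changed the atom count; re-read per model is
    # not supported for filtered trajectories
    stop("trajectory atom count differs from filtered topology; ",
         "remove waters/altlocs from the file first")
  }
  new_trajectory(top, xyz)
}

#' Write a trajectory as a multi-model PDB file
#' @param traj an `mdmd_trajectory`.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_trajectory_pdb <- function(traj, file) {
  con <- file(file, "w")
  on.exit(close(con))
  tmp <- tempfile(fileext = ".pdb")
  on.exit(unlink(tmp), add = TRUE)
  for (i in seq_len(n_frames(traj))) {
    write_pdb(frame_structure(traj, i), tmp)
    body <- readLines(tmp, warn = FALSE)
    body <- body[!grepl("^END", body)]
    writeLines(sprintf("MODEL     %4d", i), con)
    writeLines(body, con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(file)
}
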