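#' Stem definition for interarm geometry
#'
#' Residue windows, in canonical cloverleaf numbering 1-76, defining the two
#' helical arms of the L and the hinge between them. These are
#' configuration, not code: supply your own windows for non-canonical
#' numbering.
#'
#' @param acceptor_stem residues of the acceptor stem (default 1-7 and
#'   66-72).
#' @param anticodon_stem residues of the anticodon stem (default 27-31 and
#'   39-43).
#' @param hinge hinge residues (default 26, 44, 45).
#' @return object of class `stem_definition`.
#' @export
stem_definition <- function(acceptor_stem = c(1:7, 66:72),
                            anticodon_stem = c(27:31, 39:43),
                            hinge = c(26, 44, 45)) {
  if (is.character(acceptor_stem)) acceptor_stem <- parse_selection(acceptor_stem)
  if (is.character(anticodon_stem)) anticodon_stem <- parse_selection(anticodon_stem)
  if (is.character(hinge)) hinge <- parse_selection(hinge)
  if (length(intersect(acceptor_stem, anticodon_stem))) {
    stop("acceptor and anticodon stems must be disjoint")
  }
  structure(list(acceptor_stem = acceptor_stem,
                 anticodon_stem = anticodon_stem, hinge = hinge),
            class = "stem_definition")
}

stem_p_coords <- function(s, residues, what) {
  sel <- select_atoms(s, resid = residues, name = c("P", "CA"))
  if (n_atoms(sel) < 4) {
    stop("stem selection '", what, "' resolves to ", n_atoms(sel),
         " P atoms; need >= 4")
  }
  coords(sel)
}

# Dominant principal axis of a point cloud, oriented away from the hinge
# centroid so the interarm angle is a true bend angle.
oriented_axis <- function(pts, hinge_centroid) {
  centroid <- colMeans(pts)
  ev <- eigen(stats::cov(pts), symmetric = TRUE)
  axis <- ev$vectors[, 1]
  if (sum(axis * (centroid - hinge_centroid)) < 0) axis <- -axis
  axis / sqrt(sum(axis^2))
}

#' Interarm and hinge geometry of a tRNA structure
#'
#' Internal workhorse shared by [interarm_angle()] and [deform_hinge()]:
#' oriented principal axes of the two stems' phosphorus atoms and the hinge
#' centroid.
#' @noRd
interarm_geometry <- function(s, stems = stem_definition()) {
  hinge_sel <- select_atoms(s, resid = stems$hinge, name = c("P", "CA"))
  if (n_atoms(hinge_sel) < 1) {
    stop("hinge selection resolves to 0 P atoms")
  }
  hinge_centroid <- colMeans(coords(hinge_sel))
  acc <- stem_p_coords(s, stems$acceptor_stem, "acceptor_stem")
  anti <- stem_p_coords(s, stems$anticodon_stem, "anticodon_stem")
  list(acceptor_axis = oriented_axis(acc, hinge_centroid),
       anticodon_axis = oriented_axis(anti, hinge_centroid),
       hinge_centroid = hinge_centroid)
}

#' Interarm bend angle of a tRNA structure
#'
#' Angle between the oriented principal axes of the acceptor-stem and
#' anticodon-stem phosphorus point clouds. Each axis points from the stem
#' end nearest the hinge outward, so the result is a true bend angle in
#' [0, 180] degrees, invariant under rigid transforms and atom reordering.
#'
#' @param s an `mdmd_structure`.
#' @param stems a `stem_definition`.
#' @return angle in degrees.
#' @export
interarm_angle <- function(s, stems = stem_definition()) {
  g <- interarm_geometry(s, stems)
  cosang <- sum(g$acceptor_axis * g$anticodon_axis)
  acos(pmin(1, pmax(-1, cosang))) * 180 / pi
}

#' Per-residue fluctuation (RMSF) over a trajectory
#'
#' Frames are first superposed (twice, onto a refined mean) using the
#' alignment selection, then the root-mean-square fluctuation of each
#' residue's P atom (or C-alpha for protein residues) about its mean
#' position is reported. This quantifies the spread a jittergram rendering
#' shows qualitatively.
#'
#' @param traj an `mdmd_trajectory` with >= 2 frames.
#' @param align_resid residues used for the superposition (selection string
#'   or integer vector); default all residues.
#' @param align_name atom names used for the superposition (default P and
#'   CA).
#' @return data.frame with columns `resid` and `rmsf` (Angstrom).
#' @export
per_residue_fluctuation <- function(traj, align_resid = NULL,
                                    align_name = c("P", "CA")) {
  if (n_frames(traj) < 2) stop("RMSF needs at least 2 frames")
  top <- traj$topology
  keep <- rep(TRUE, n_atoms(top))
  if (!is.null(align_resid)) {
    r <- align_resid
    if (is.character(r)) r <- parse_selection(r)
    keep <- keep & top$atoms$resid %in% r
  }
  if (!is.null(align_name)) keep <- keep & top$atoms$name %in% align_name
  sel_idx <- which(keep)
  if (length(sel_idx) < 3) stop("alignment selection resolves to < 3 atoms")
  xi <- bio3d::atom2xyz(sel_idx)
  xyz <- traj$xyz
  ref <- xyz[1, ]
  for (pass in 1:2) {
    xyz <- bio3d::fit.xyz(fixed = ref, mobile = xyz,
                          fixed.inds = xi, mobile.inds = xi)
    if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
    ref <- colMeans(xyz)
  }
  meas_idx <- which(top$atoms$name %in% c("P", "CA"))
  resids <- top$atoms$resid[meas_idx]
  rmsf <- vapply(seq_along(meas_idx), function(k) {
    cols <- bio3d::atom2xyz(meas_idx[k])
    pos <- xyz[, cols, drop = FALSE]
    mu <- colMeans(pos)
    sqrt(mean(rowSums(sweep(pos, 2, mu)^2)))
  }, numeric(1))
  agg <- tapply(rmsf, resids, mean)
  data.frame(resid = as.integer(names(agg)), rmsf = as.numeric(agg),
             row.names = NULL)
}

#' Dock a trajectory into a reference frame
#'
#' Superposes every frame into the coordinate frame of a static reference
#' (e.g. a ribosome model containing a bound-tRNA placement) by
#' least-squares fitting of an anchor selection (default: the anticodon
#' residues 34-36) onto the matching reference atoms.
#'
#' @param traj an `mdmd_trajectory`.
#' @param reference an `mdmd_structure` holding the target placement.
#' @param anchor_resid anchor residues (default 34:36).
#' @param anchor_name optional atom-name filter for the anchor.
#' @return a docked `mdmd_trajectory` (same topology).
#' @export
dock_trajectory <- function(traj, reference, anchor_resid = 34:36,
                            anchor_name = NULL) {
  pr <- pair_atoms(traj$topology, reference, resid = anchor_resid,
                   name = anchor_name)
  ref_xyz <- coords(reference)[pr$reference_idx, , drop = FALSE]
  check_pairing_geometry(ref_xyz)
  fitted <- bio3d::fit.xyz(
    fixed = as.vector(t(coords(reference))),
    mobile = traj$xyz,
    fixed.inds = bio3d::atom2xyz(pr$reference_idx),
    mobile.inds = bio3d::atom2xyz(pr$mobile_idx)
  )
  if (is.null(dim(fitted))) fitted <- matrix(fitted, nrow = 1)
  new_trajectory(traj$topology, fitted, traj$time)
}

residue_kind <- function(resname) {
  ifelse(resname %in% PROTEIN_RESNAMES, "protein",
         ifelse(resname %in% NUCLEIC_RESNAMES, "rna", "other"))
}

#' Contact map between a docked tRNA trajectory and a partner structure
#'
#' A (tRNA residue, partner residue) pair is in contact in a frame when:
#' for a protein partner residue, any of its C-alpha atoms lies within
#' `cutoff` of any base atom of the tRNA residue (mode `"ca-base"`); for an
#' RNA partner residue, any of its base atoms lies within `cutoff` of any
#' base atom of the tRNA residue (mode `"base-base"`). Base atoms are the
#' heavy atoms outside the sugar-phosphate backbone. Occupancy is the
#' fraction of all frames in contact; only pairs observed in at least one
#' frame are reported.
#'
#' @param docked an `mdmd_trajectory` already in the partner coordinate
#'   frame (see [dock_trajectory()]).
#' @param partner an `mdmd_structure` with protein and/or RNA residues.
#' @param cutoff contact distance cutoff, Angstrom (default 4.0).
#' @return object of class `mdmd_contact_map`: list with `entries`
#'   (data.frame: trna_resid, partner_chain, partner_resid, mode, occupancy)
#'   and `cutoff`.
#' @export
contact_map <- function(docked, partner, cutoff = 4.0) {
  top <- docked$topology
  trna_base <- which(!(top$atoms$name %in% SUGAR_PHOSPHATE_ATOMS) &
                       !(top$atoms$element %in% c("H", "D")))
  if (!length(trna_base)) stop("trajectory topology has no base atoms")
  pk <- residue_kind(partner$atoms$resname)
  part_idx <- which(
    (pk == "protein" & partner$atoms$name == "CA") |
      (pk == "rna" & !(partner$atoms$name %in% SUGAR_PHOSPHATE_ATOMS) &
         !(partner$atoms$element %in% c("H", "D"))))
  if (!length(part_idx)) {
    stop("partner has neither C-alpha nor RNA base atoms")
  }
  part_xyz <- coords(partner)[part_idx, , drop = FALSE]
  part_res <- paste(partner$atoms$chain[part_idx],
                    partner$atoms$resid[part_idx], sep = ":")
  part_mode <- ifelse(pk[part_idx] == "protein", "ca-base", "base-base")
  trna_res <- top$atoms$resid[trna_base]

  nfr <- n_frames(docked)
  counts <- new.env(parent = emptyenv())
  for (f in seq_len(nfr)) {
    fx <- matrix(docked$xyz[f, ], ncol = 3, byrow = TRUE)
    tx <- fx[trna_base, , drop = FALSE]
    # pairwise distances tRNA base atoms x partner atoms
    d2 <- outer(rowSums(tx^2), rowSums(part_xyz^2), "+") -
      2 * tcrossprod(tx, part_xyz)
    hit <- which(d2 <= cutoff^2, arr.ind = TRUE)
    if (nrow(hit)) {
      keys <- unique(paste(trna_res[hit[, 1]], part_res[hit[, 2]],
                           part_mode[hit[, 2]], sep = "|"))
      for (k in keys) {
        counts[[k]] <- (if (is.null(counts[[k]])) 0 else counts[[k]]) + 1
      }
    }
  }
  keys <- ls(counts)
  if (!length(keys)) {
    entries <- data.frame(trna_resid = integer(0),
                          partner_chain = character(0),
                          partner_resid = integer(0), mode = character(0),
                          occupancy = numeric(0))
  } else {
    parts <- do.call(rbind, strsplit(keys, "|", fixed = TRUE))
    cr <- do.call(rbind, strsplit(parts[, 2], ":", fixed = TRUE))
    entries <- data.frame(
      trna_resid = as.integer(parts[, 1]),
      partner_chain = cr[, 1],
      partner_resid = as.integer(cr[, 2]),
      mode = parts[, 3],
      occupancy = vapply(keys, function(k) counts[[k]], numeric(1)) / nfr,
      row.names = NULL
    )
    entries <- entries[order(entries$trna_resid, entries$partner_chain,
                             entries$partner_resid), ]
    rownames(entries) <- NULL
  }
  structure(list(entries = entries, cutoff = cutoff),
            class = "mdmd_contact_map")
}

#' @export
print.mdmd_contact_map <- function(x, ...) {
  cat(sprintf("mdmd_contact_map: %d contacts within %.1f A\n",
              nrow(x$entries), x$cutoff))
  if (nrow(x$entries)) print(utils::head(x$entries, 10))
  invisible(x)
}

#' Write a contact map as TSV
#' @param cm an `mdmd_contact_map`.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_contact_map <- function(cm, file) {
  write.table(cm$entries, file, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(file)
}

#' Radius of gyration
#'
#' Mass-unweighted by default (uniform weights) about the centroid; pass
#' per-atom masses for the mass-weighted variant.
#'
#' @param x an `mdmd_structure` or an N x 3 coordinate matrix.
#' @param mass optional per-atom masses.
#' @return Rg in Angstrom.
#' @export
radius_of_gyration <- function(x, mass = NULL) {
  xyz <- if (inherits(x, "mdmd_structure")) coords(x) else as.matrix(x)
  if (nrow(xyz) < 1) stop("need at least one atom")
  w <- if (is.null(mass)) rep(1, nrow(xyz)) else rep_len(mass, nrow(xyz))
  cen <- colSums(xyz * w) / sum(w)
  sqrt(sum(w * rowSums(sweep(xyz, 2, cen)^2)) / sum(w))
}
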