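#' Pair atoms between two structures
#'
#' Pairing is by (chain, resid, insert, atom name); if that yields fewer than
#' three pairs (e.g. chain ids differ between files) the chain id is dropped
#' from the key. Unmatched atoms are dropped with a message reporting the
#' count.
#'
#' @param mobile,reference `mdmd_structure` objects.
#' @param resid,name,chain optional filters applied to both structures before
#'   pairing (see [select_atoms()]); `resid` may be a selection string.
#' @return list with integer index vectors `mobile_idx` and `reference_idx`
#'   into the atom tables of the unfiltered structures.
#' @export
pair_atoms <- function(mobile, reference, resid = NULL, name = NULL,
                       chain = NULL) {
  filt <- function(s) {
    keep <- rep(TRUE, n_atoms(s))
    r <- resid
    if (!is.null(r)) {
      if (is.character(r)) r <- parse_selection(r)
      keep <- keep & s$atoms$resid %in% r
    }
    if (!is.null(name)) keep <- keep & s$atoms$name %in% name
    if (!is.null(chain)) keep <- keep & s$atoms$chain %in% chain
    which(keep)
  }
  mi <- filt(mobile)
  ri <- filt(reference)
  key <- function(s, idx, with_chain) {
    a <- s$atoms[idx, ]
    if (with_chain) paste(a$chain, a$resid, a$insert, a$name)
    else paste(a$resid, a$insert, a$name)
  }
  for (with_chain in c(TRUE, FALSE)) {
    km <- key(mobile, mi, with_chain)
    kr <- key(reference, ri, with_chain)
    common <- intersect(km, kr)
    if (length(common) >= 3 || !with_chain) break
  }
  dropped <- (length(km) - length(common)) + (length(kr) - length(common))
  if (dropped > 0) {
    message("pair_atoms: dropped ", dropped, " unmatched atoms (",
            length(common), " pairs kept)")
  }
  list(mobile_idx = mi[match(common, km)],
       reference_idx = ri[match(common, kr)])
}

check_pairing_geometry <- function(ref_xyz) {
  if (nrow(ref_xyz) < 3) {
    stop("degenerate selection: need at least 3 paired atoms, got ",
         nrow(ref_xyz))
  }
  sv <- svd(scale(ref_xyz, scale = FALSE))$d
  if (sv[2] < 1e-8 * max(sv[1], 1)) {
    stop("degenerate selection: paired atoms are collinear")
  }
}

rmsd_xyz <- function(a, b) {
  sqrt(mean(rowSums((a - b)^2)))
}

#' Rigid-body least-squares superposition
#'
#' Superposes `mobile` onto `reference` by the rotation + translation (no
#' scaling, no reflection; the rotation determinant is forced +1 so chirality
#' is preserved) minimizing the RMSD over the paired selection. The whole
#' mobile structure is transformed; the RMSD is reported over the selection.
#'
#' @param mobile,reference `mdmd_structure` objects.
#' @param resid,name,chain selection filters passed to [pair_atoms()].
#' @return list with elements `structure` (transformed mobile), `rmsd`
#'   (Angstrom, over the paired selection) and `n_paired`.
#' @export
superpose <- function(mobile, reference, resid = NULL, name = NULL,
                      chain = NULL) {
  pr <- pair_atoms(mobile, reference, resid = resid, name = name,
                   chain = chain)
  ref_xyz <- coords(reference)[pr$reference_idx, , drop = FALSE]
  check_pairing_geometry(ref_xyz)
  fitted <- bio3d::fit.xyz(
    fixed = as.vector(t(coords(reference))),
    mobile = as.vector(t(coords(mobile))),
    fixed.inds = bio3d::atom2xyz(pr$reference_idx),
    mobile.inds = bio3d::atom2xyz(pr$mobile_idx)
  )
  moved <- matrix(fitted, ncol = 3, byrow = TRUE)
  list(structure = set_coords(mobile, moved),
       rmsd = rmsd_xyz(moved[pr$mobile_idx, , drop = FALSE], ref_xyz),
       n_paired = length(pr$mobile_idx))
}

#' Pairwise RMSD matrix between two trajectories
#'
#' Entry (i, j) is the RMSD after least-squares superposition of frame i of
#' `traj_a` onto frame j of `traj_b`, computed over the paired selection.
#' Symmetric (within numerical tolerance) when both arguments are the same
#' trajectory.
#'
#' @param traj_a,traj_b `mdmd_trajectory` objects.
#' @param resid,name optional selection filters (see [pair_atoms()]).
#' @return numeric matrix of Angstrom values.
#' @export
rmsd_matrix <- function(traj_a, traj_b = traj_a, resid = NULL, name = NULL) {
  if (n_frames(traj_a) < 1 || n_frames(traj_b) < 1) {
    stop("empty trajectory")
  }
  pr <- pair_atoms(traj_a$topology, traj_b$topology, resid = resid,
                   name = name)
  ai <- bio3d::atom2xyz(pr$mobile_idx)
  bi <- bio3d::atom2xyz(pr$reference_idx)
  out <- matrix(0, n_frames(traj_a), n_frames(traj_b))
  for (j in seq_len(n_frames(traj_b))) {
    fixed <- traj_b$xyz[j, ]
    ref <- matrix(fixed[bi], ncol = 3, byrow = TRUE)
    check_pairing_geometry(ref)
    fitted <- bio3d::fit.xyz(fixed = fixed, mobile = traj_a$xyz,
                             fixed.inds = bi, mobile.inds = ai)
    if (is.null(dim(fitted))) fitted <- matrix(fitted, nrow = 1)
    for (i in seq_len(n_frames(traj_a))) {
      mov <- matrix(fitted[i, ai], ncol = 3, byrow = TRUE)
      out[i, j] <- rmsd_xyz(mov, ref)
    }
  }
  out
}

#' Convergence test on an RMSD value
#'
#' A conformation is called converged when its RMSD to the reference drops
#' below the threshold (default 3 Angstrom).
#'
#' @param rmsd_value RMSD in Angstrom (must be >= 0).
#' @param threshold convergence threshold in Angstrom (default 3.0).
#' @return logical: TRUE iff `rmsd_value < threshold`.
#' @export
check_convergence <- function(rmsd_value, threshold = 3.0) {
  if (any(!is.finite(rmsd_value)) || any(rmsd_value < 0)) {
    stop("rmsd_value must be finite and non-negative")
  }
  rmsd_value < threshold
}
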