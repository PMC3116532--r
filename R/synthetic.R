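#' Rotation matrix about an arbitrary axis
#' @param axis 3-vector (need not be normalized).
#' @param angle_deg rotation angle, degrees (right-hand rule).
#' @return 3 x 3 rotation matrix.
#' @export
rotation_matrix <- function(axis, angle_deg) {
  n <- sqrt(sum(axis^2))
  if (n < 1e-12) stop("degenerate rotation axis")
  u <- axis / n
  th <- angle_deg * pi / 180
  ct <- cos(th); st <- sin(th)
  ux <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0), 3, 3,
               byrow = TRUE)
  diag(3) * ct + st * ux + (1 - ct) * tcrossprod(u)
}

#' Specification for a synthetic pseudo-tRNA
#'
#' Desk-scale stand-in for the L-shaped tRNA tertiary structure: two helical
#' arms (acceptor arm and anticodon arm) of coarse-grained residues meeting
#' at a hinge with a controllable bend angle, numbered with the canonical
#' cloverleaf convention 1-76 so the default [stem_definition()] windows
#' resolve. One "P" pseudo-atom per residue traces the backbone; two base
#' pseudo-atoms ("N1", "C4") per residue give the density and contact code
#' something base-like to work with.
#'
#' @param arm_lengths residues per arm: c(acceptor, anticodon); default
#'   c(33, 43), total 76.
#' @param rise rise per residue along the arm axis, Angstrom (default 2.8,
#'   the A-form helical rise).
#' @param radius helix radius, Angstrom (default 2.5).
#' @param hinge_angle interarm bend angle, degrees, in the open interval
#'   (0, 180); default 90.
#' @param twist rigid twist of the anticodon arm about its own axis,
#'   degrees (default 0; models the kinked pre-accommodation A/T twist).
#' @param seed generator seed (the default geometry is deterministic; the
#'   seed is recorded for provenance and used by downstream noise).
#' @return object of class `pseudo_trna_spec`.
#' @export
pseudo_trna_spec <- function(arm_lengths = c(33, 43), rise = 2.8,
                             radius = 2.5, hinge_angle = 90, twist = 0,
                             seed = 1L) {
  if (sum(arm_lengths) < 8) stop("total residues must be >= 8")
  if (!(hinge_angle > 0 && hinge_angle < 180)) {
    stop("hinge_angle must lie strictly inside (0, 180) degrees")
  }
  if (rise <= 0 || radius < 0) stop("rise must be > 0 and radius >= 0")
  structure(list(arm_lengths = arm_lengths, rise = rise, radius = radius,
                 hinge_angle = hinge_angle, twist = twist,
                 seed = as.integer(seed)),
            class = "pseudo_trna_spec")
}

# Residue layout of the default 76-residue pseudo-tRNA. Each residue gets:
# arm ("acceptor"/"anticodon"), rank (distance from the hinge in rise
# units), lateral ("axis" for on-arm residues, "dloop" for the D-arm bulge),
# and phase_offset (0 or 180 degrees; paired strands sit phase-opposed so
# stem principal axes coincide exactly with the arm axes).
pseudo_trna_layout <- function(n_acc, n_anti) {
  if (n_acc == 33 && n_anti == 43) {
    resid <- 1:76
    arm <- ifelse(resid >= 8 & resid <= 50, "anticodon", "acceptor")
    rank <- numeric(76)
    phase <- numeric(76)
    lateral <- rep("axis", 76)
    # acceptor arm: T-stem/T-loop 51..65 run outward, acceptor stem 66..72
    # continues, CCA tip 73..76; 5' strand 1..7 pairs back onto 66..72
    rank[51:76] <- 1:26
    rank[1:7] <- 23 - (1:7)          # resid 1 pairs with 72, 7 with 66
    phase[1:7] <- 180
    # anticodon arm: linker, D-arm bulge, anticodon stem/loop hairpin
    rank[8:9] <- c(0.7, 0.4)
    rank[10:13] <- 1:4;  lateral[10:13] <- "dloop"
    rank[14:21] <- c(4.5, 5, 5.3, 5.4, 5.3, 5, 4.5, 4.2)
    lateral[14:21] <- "dloop"
    rank[22:25] <- c(3, 2, 1, 0.6);  lateral[22:25] <- "dloop"
    phase[22:25] <- 180
    rank[26] <- 0.2
    rank[27:31] <- 1:5
    rank[32:38] <- c(5.8, 6.4, 6.9, 7.1, 6.9, 6.4, 5.8)
    rank[39:43] <- 5:1;  phase[39:43] <- 180
    rank[44:45] <- c(0.35, 0.2)
    rank[46:50] <- c(0.55, 0.45, 0.4, 0.3, 0.15); phase[46:50] <- 90
    data.frame(resid = resid, arm = arm, rank = rank, lateral = lateral,
               phase = phase, stringsAsFactors = FALSE)
  } else {
    # generic fallback: two plain out-and-back hairpins
    n <- n_acc + n_anti
    resid <- seq_len(n)
    arm <- c(rep("acceptor", n_acc), rep("anticodon", n_anti))
    hairpin <- function(k) {
      t <- seq_len(k) - 1
      list(rank = pmin(t, k - 1 - t) + 1,
           phase = ifelse(t > (k - 1) / 2, 180, 0))
    }
    ha <- hairpin(n_acc); hb <- hairpin(n_anti)
    data.frame(resid = resid, arm = arm,
               rank = c(ha$rank, hb$rank),
               lateral = "axis",
               phase = c(ha$phase, hb$phase), stringsAsFactors = FALSE)
  }
}

#' Generate a synthetic L-shaped pseudo-tRNA
#'
#' Deterministic given the spec. The acceptor arm runs along +z from the
#' hinge (at the origin); the anticodon arm runs along an axis at
#' `hinge_angle` degrees from +z in the xz-plane, so
#' `interarm_angle(make_pseudo_trna(spec))` recovers `spec$hinge_angle`.
#'
#' @param spec a `pseudo_trna_spec`.
#' @return an `mdmd_structure` with generator annotation (true hinge angle,
#'   per-arm residue sets).
#' @export
make_pseudo_trna <- function(spec = pseudo_trna_spec()) {
  lay <- pseudo_trna_layout(spec$arm_lengths[1], spec$arm_lengths[2])
  th <- spec$hinge_angle * pi / 180
  axes <- list(acceptor = c(0, 0, 1),
               anticodon = c(sin(th), 0, cos(th)))
  # per-arm orthonormal frames for the radial offset
  frames <- lapply(axes, function(u) {
    ref <- if (abs(u[2]) < 0.9) c(0, 1, 0) else c(1, 0, 0)
    n1 <- ref - sum(ref * u) * u
    n1 <- n1 / sqrt(sum(n1^2))
    n2 <- c(u[2] * n1[3] - u[3] * n1[2],
            u[3] * n1[1] - u[1] * n1[3],
            u[1] * n1[2] - u[2] * n1[1])
    list(u = u, n1 = n1, n2 = n2)
  })
  resnames <- rep(c("G", "C", "A", "U"), length.out = nrow(lay))
  atoms <- vector("list", nrow(lay))
  for (i in seq_len(nrow(lay))) {
    fr <- frames[[lay$arm[i]]]
    u <- fr$u
    if (lay$lateral[i] == "dloop") {
      # D-arm bulge: sticks out of the L plane from near the hinge
      u <- fr$n2
    }
    phi <- (100 * lay$rank[i] + lay$phase[i]) * pi / 180
    radial <- cos(phi) * fr$n1 + sin(phi) * fr$n2
    if (lay$lateral[i] == "dloop") radial <- cos(phi) * fr$n1 +
        sin(phi) * fr$u
    p <- u * lay$rank[i] * spec$rise + spec$radius * radial
    b1 <- p + radial * 1.6 + fr$u * 0.4
    b2 <- p + radial * 2.9 - fr$u * 0.3
    atoms[[i]] <- data.frame(
      serial = 0L,
      name = c("P", "N1", "C4"),
      resname = resnames[i], chain = "A", resid = lay$resid[i],
      insert = "", element = c("P", "N", "C"),
      x = c(p[1], b1[1], b2[1]),
      y = c(p[2], b1[2], b2[2]),
      z = c(p[3], b1[3], b2[3]),
      stringsAsFactors = FALSE
    )
  }
  atoms <- do.call(rbind, atoms)
  atoms$serial <- seq_len(nrow(atoms))
  s <- new_structure(atoms, annotation = list(
    source = "pseudo-tRNA generator",
    hinge_angle = spec$hinge_angle,
    arm_residues = list(
      acceptor = lay$resid[lay$arm == "acceptor"],
      anticodon = lay$resid[lay$arm == "anticodon"]),
    spec = spec
  ))
  if (abs(spec$twist) > 0) {
    s <- deform_hinge(s, delta_angle = 0, delta_twist = spec$twist)
  }
  s
}

#' Rigidly bend (and twist) a structure about its hinge
#'
#' Rotates the anticodon-arm residues about the hinge axis (the normal of
#' the plane spanned by the two oriented stem axes, through the hinge
#' centroid) by `delta_angle`, then about the (rotated) anticodon-arm axis
#' by `delta_twist`. Positive `delta_angle` opens the interarm angle. The
#' acceptor arm is untouched; atom count is preserved; the operation
#' composes additively in `delta_angle` and is exactly invertible.
#'
#' @param s an `mdmd_structure`.
#' @param delta_angle bend change, degrees.
#' @param delta_twist twist about the anticodon-arm axis, degrees.
#' @param stems a `stem_definition`.
#' @param arm_residues residues that move with the anticodon arm; defaults
#'   to the generator annotation if present, else 8-50.
#' @return the deformed `mdmd_structure`.
#' @export
deform_hinge <- function(s, delta_angle, delta_twist = 0,
                         stems = stem_definition(), arm_residues = NULL) {
  if (is.null(arm_residues)) {
    arm_residues <- s$annotation$arm_residues$anticodon
    if (is.null(arm_residues)) arm_residues <- 8:50
  }
  idx <- which(s$atoms$resid %in% arm_residues)
  if (!length(idx)) stop("anticodon-arm selection resolves to 0 atoms")
  g <- interarm_geometry(s, stems)
  bend_axis <- c(
    g$acceptor_axis[2] * g$anticodon_axis[3] -
      g$acceptor_axis[3] * g$anticodon_axis[2],
    g$acceptor_axis[3] * g$anticodon_axis[1] -
      g$acceptor_axis[1] * g$anticodon_axis[3],
    g$acceptor_axis[1] * g$anticodon_axis[2] -
      g$acceptor_axis[2] * g$anticodon_axis[1]
  )
  if (sqrt(sum(bend_axis^2)) < 1e-9) {
    stop("degenerate hinge axis: arm axes are parallel")
  }
  xyz <- coords(s)
  piv <- g$hinge_centroid
  arm <- sweep(xyz[idx, , drop = FALSE], 2, piv)
  if (abs(delta_angle) > 0) {
    # rotating the anticodon axis about acceptor x anticodon opens the angle
    arm <- arm %*% t(rotation_matrix(bend_axis, delta_angle))
  }
  if (abs(delta_twist) > 0) {
    anti_axis <- as.numeric(
      rotation_matrix(bend_axis, delta_angle) %*% g$anticodon_axis)
    arm <- arm %*% t(rotation_matrix(anti_axis, delta_twist))
  }
  xyz[idx, ] <- sweep(arm, 2, piv, "+")
  set_coords(s, xyz)
}

#' Synthesize a target density map with optional noise
#'
#' Simulated density of the structure on its default grid, plus seeded
#' additive Gaussian voxel noise (standard deviation given as a fraction of
#' the clean map's maximum), clipped at 0 to preserve non-negativity.
#'
#' @param s an `mdmd_structure`.
#' @param resolution nominal resolution, Angstrom.
#' @param noise_sigma noise s.d. as a fraction of the clean maximum
#'   (default 0).
#' @param seed noise seed.
#' @param spacing,pad grid overrides passed to [default_grid()].
#' @return a `density_map`.
#' @export
make_target_map <- function(s, resolution, noise_sigma = 0, seed = 1L,
                            spacing = NULL, pad = NULL) {
  if (resolution <= 0) stop("resolution must be positive")
  if (noise_sigma < 0) stop("noise_sigma must be >= 0")
  kernel <- kernel_params(resolution = resolution)
  grid <- default_grid(s, kernel, spacing = spacing, pad = pad)
  map <- simulate_density(s, grid, kernel)
  if (noise_sigma > 0) {
    v <- map$values
    noise <- with_seed(seed,
                       array(rnorm(length(v), 0, noise_sigma * max(v)),
                             dim = dim(v)))
    map$values <- pmax(v + noise, 0)
  }
  map
}

#' End-to-end parameter-recovery experiment
#'
#' Builds a pseudo-tRNA, bends it by `delta_angle` to create the (possibly
#' noisy) target map, then runs MdMD from the undeformed structure with the
#' hinge Monte-Carlo propagator and measures how well the deformation was
#' recovered.
#'
#' @param spec a `pseudo_trna_spec`.
#' @param delta_angle true bend applied to create the target, degrees.
#' @param resolution target map resolution, Angstrom (default 8).
#' @param noise_sigma map noise level (fraction of max; default 0).
#' @param config an `mdmd_config`; its `seed` drives the whole experiment.
#' @return list with `angle_error` (degrees, |recovered - truth|),
#'   `final_cc`, `initial_cc`, `true_angle`, `recovered_angle`,
#'   `iterations`, `accepted`, `status`, and the full `result`.
#' @export
recovery_experiment <- function(spec = pseudo_trna_spec(), delta_angle = 25,
                                resolution = 8, noise_sigma = 0,
                                config = mdmd_config()) {
  s0 <- make_pseudo_trna(spec)
  truth <- deform_hinge(s0, delta_angle)
  target <- make_target_map(truth, resolution, noise_sigma,
                            seed = config$seed)
  kernel <- kernel_params(resolution = resolution)
  engine <- hinge_mc_engine(s0)
  progress <- cc_progress(target, kernel)
  result <- run_mdmd(s0, progress, engine, config)
  fin <- final_structure(s0, result)
  true_angle <- interarm_angle(truth)
  rec_angle <- interarm_angle(fin)
  list(angle_error = abs(rec_angle - true_angle),
       final_cc = if (length(result$cc_trace)) tail(result$cc_trace, 1)
                  else result$initial_cc,
       initial_cc = result$initial_cc,
       true_angle = true_angle,
       recovered_angle = rec_angle,
       iterations = nrow(result$log),
       accepted = length(result$cc_trace),
       status = result$status,
       result = result)
}
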