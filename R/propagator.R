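# Units: lengths in Angstrom, time in ps, mass in amu, energy in kcal/mol.
KB_AMU <- 0.8314462618      # Boltzmann constant, amu A^2 / (ps^2 K)
KCAL_TO_AMU <- 418.4        # 1 kcal/mol = 418.4 amu A^2 / ps^2

# Run `expr` under a fixed RNG seed without disturbing the caller's stream.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Construct a propagator state
#'
#' The unit advanced by one MD sprint: coordinates, velocities, a seedable
#' RNG state and the simulation clock.
#'
#' @param coordinates N x 3 matrix, Angstrom.
#' @param velocities N x 3 matrix, Angstrom/ps (default zero).
#' @param rng_state integer seed controlling the stochastic part of the next
#'   propagation.
#' @param time simulation time, ps.
#' @return object of class `propagator_state`.
#' @export
propagator_state <- function(coordinates, velocities = NULL, rng_state = 1L,
                             time = 0) {
  coordinates <- as.matrix(coordinates)
  if (ncol(coordinates) != 3) stop("coordinates must be N x 3")
  if (is.null(velocities)) {
    velocities <- matrix(0, nrow(coordinates), 3)
  }
  velocities <- as.matrix(velocities)
  if (!identical(dim(velocities), dim(coordinates))) {
    stop("velocities must be congruent with coordinates")
  }
  structure(list(coordinates = coordinates, velocities = velocities,
                 rng_state = as.integer(rng_state), time = time),
            class = "propagator_state")
}

state_from_structure <- function(s, rng_state = 1L) {
  propagator_state(coords(s), rng_state = rng_state)
}

#' Redraw velocities from the Maxwell-Boltzmann distribution
#'
#' Coordinates are untouched; each velocity component is drawn as
#' N(0, kB T / m). Temperature 0 gives all-zero velocities.
#'
#' @param state a `propagator_state`.
#' @param temperature Kelvin (>= 0).
#' @param seed integer seed; identical seeds give identical velocities.
#' @param mass per-atom mass, amu (scalar or length-N vector).
#' @return a new `propagator_state`.
#' @export
reset_velocities <- function(state, temperature = 300, seed = 1L,
                             mass = 330) {
  if (temperature < 0) stop("temperature must be >= 0")
  n <- nrow(state$coordinates)
  m <- rep_len(mass, n)
  if (temperature == 0) {
    v <- matrix(0, n, 3)
  } else {
    sdv <- sqrt(KB_AMU * temperature / m)
    v <- with_seed(seed, matrix(rnorm(3 * n), n, 3) * sdv)
  }
  state$velocities <- v
  state$rng_state <- as.integer(seed)
  state
}

#' Remove center-of-mass and rigid-rotation motion
#'
#' Sets the net linear momentum and the net angular momentum about the
#' center of mass to zero by subtracting the corresponding velocity fields
#' (the "flying ice-cube" correction). Coordinates are unchanged.
#'
#' @param state a `propagator_state`.
#' @param mass per-atom mass, amu (scalar or vector).
#' @return a new `propagator_state`.
#' @export
remove_com_motion <- function(state, mass = 330) {
  x <- state$coordinates
  v <- state$velocities
  n <- nrow(x)
  if (n < 1) stop("state has no atoms")
  m <- rep_len(mass, n)
  M <- sum(m)
  vcom <- colSums(v * m) / M
  v <- sweep(v, 2, vcom)
  if (n >= 2) {
    com <- colSums(x * m) / M
    r <- sweep(x, 2, com)
    L <- colSums(m * cbind(r[, 2] * v[, 3] - r[, 3] * v[, 2],
                           r[, 3] * v[, 1] - r[, 1] * v[, 3],
                           r[, 1] * v[, 2] - r[, 2] * v[, 1]))
    r2 <- rowSums(r^2)
    I <- diag(sum(m * r2), 3) - crossprod(sqrt(m) * r)
    # I can be singular for collinear systems; solve in the least-norm sense
    omega <- tryCatch(solve(I, L), error = function(e) {
      sv <- svd(I)
      d <- ifelse(sv$d > 1e-10 * max(sv$d), 1 / sv$d, 0)
      sv$v %*% (d * crossprod(sv$u, L))
    })
    v <- v - cbind(omega[2] * r[, 3] - omega[3] * r[, 2],
                   omega[3] * r[, 1] - omega[1] * r[, 3],
                   omega[1] * r[, 2] - omega[2] * r[, 1])
  }
  state$velocities <- v
  state
}

#' Harmonic tether restraint
#'
#' Tethers selected atoms to fixed anchor positions with energy
#' `E = k * |r - anchor|^2` per atom (note: `k d^2`, not `(1/2) k d^2`; the
#' force constant is quoted in kcal/(mol A^2) per atom). Used to mimic
#' codon-anticodon base pairing by restraining the hydrogen-bonding atoms of
#' anticodon nucleotides 34-36.
#'
#' @param atom_idx integer indices of restrained atoms in the topology.
#' @param anchors N x 3 matrix of anchor positions, Angstrom.
#' @param k force constant, kcal/(mol A^2); the study range is 1-10.
#' @return object of class `tether_restraint`.
#' @export
tether_restraint <- function(atom_idx, anchors, k = 5) {
  if (length(atom_idx) == 0) stop("restraint selection resolves to 0 atoms")
  anchors <- as.matrix(anchors)
  if (nrow(anchors) != length(atom_idx) || ncol(anchors) != 3) {
    stop("anchors must be a length(atom_idx) x 3 matrix")
  }
  if (k <= 0) stop("force constant must be positive")
  structure(list(atom_idx = as.integer(atom_idx), anchors = anchors, k = k),
            class = "tether_restraint")
}

#' Tether the anticodon of a tRNA structure at its current position
#'
#' Convenience constructor: restrains the hydrogen-bond-capable base atoms
#' (N and O) of the anticodon nucleotides, anchored at their coordinates in
#' `s`.
#'
#' @param s an `mdmd_structure`.
#' @param residues anticodon residue numbers (default 34:36).
#' @param k force constant, kcal/(mol A^2) per atom, in the 1-10 range.
#' @return a `tether_restraint`.
#' @export
anticodon_tether <- function(s, residues = 34:36, k = 5) {
  sel <- s$atoms$resid %in% residues &
    !(s$atoms$name %in% SUGAR_PHOSPHATE_ATOMS) &
    s$atoms$element %in% c("N", "O")
  idx <- which(sel)
  if (!length(idx)) {
    # coarse-grained models may carry only C/N pseudo-atoms; fall back to
    # all base pseudo-atoms of the anticodon
    idx <- which(s$atoms$resid %in% residues &
                   !(s$atoms$name %in% SUGAR_PHOSPHATE_ATOMS) &
                   !(s$atoms$element %in% c("H", "D")))
  }
  if (!length(idx)) stop("no anticodon atoms found for residues ",
                         paste(residues, collapse = ","))
  tether_restraint(idx, coords(s)[idx, , drop = FALSE], k = k)
}

#' Restraint energy and forces
#'
#' @param state a `propagator_state` (or an N x 3 coordinate matrix).
#' @param restraints list of `tether_restraint` objects (a single restraint
#'   is accepted).
#' @return list with `energy` (kcal/mol) and `forces` (N x 3,
#'   kcal/(mol Angstrom); the negative gradient).
#' @export
apply_restraint_energy <- function(state, restraints) {
  x <- if (inherits(state, "propagator_state")) state$coordinates
       else as.matrix(state)
  if (inherits(restraints, "tether_restraint")) restraints <- list(restraints)
  energy <- 0
  forces <- matrix(0, nrow(x), 3)
  for (r in restraints) {
    if (max(r$atom_idx) > nrow(x)) {
      stop("restrained atom index out of range")
    }
    d <- x[r$atom_idx, , drop = FALSE] - r$anchors
    energy <- energy + r$k * sum(d^2)
    forces[r$atom_idx, ] <- forces[r$atom_idx, ] - 2 * r$k * d
  }
  list(energy = energy, forces = forces)
}

#' Elastic-network-model Langevin engine
#'
#' Coarse-grained stand-in for an all-atom MD engine: every atom pair of the
#' input structure closer than `cutoff` is connected by a harmonic spring
#' with energy `spring_k * (r - r0)^2` (r0 = input distance), and the system
#' is advanced by BAOAB Langevin dynamics at the given temperature and
#' friction. With `friction = 0` the integrator reduces to velocity Verlet
#' (NVE).
#'
#' @param s an `mdmd_structure` defining the network topology and rest
#'   lengths.
#' @param cutoff spring contact radius, Angstrom (default 10).
#' @param spring_k uniform spring constant, kcal/(mol A^2) (default 1).
#' @param mass per-atom mass, amu (default 330, one coarse-grained
#'   nucleotide-scale site).
#' @param temperature thermostat temperature, K (default 300).
#' @param friction Langevin friction, 1/ps (default 1; 0 disables the
#'   thermostat).
#' @param timestep integration timestep, ps (default 0.002 = 2 fs).
#' @param restraints optional list of `tether_restraint` objects.
#' @return engine object of class `c("enm_engine", "mdmd_engine")`.
#' @export
enm_engine <- function(s, cutoff = 10, spring_k = 1, mass = 330,
                       temperature = 300, friction = 1, timestep = 0.002,
                       restraints = list()) {
  xyz <- coords(s)
  n <- nrow(xyz)
  if (n < 2) stop("ENM needs at least 2 atoms")
  dmat <- as.matrix(stats::dist(xyz))
  pairs <- which(upper.tri(dmat) & dmat <= cutoff & dmat > 1e-6,
                 arr.ind = TRUE)
  if (nrow(pairs) == 0) stop("no ENM contacts within cutoff ", cutoff, " A")
  structure(list(
    topology = s,
    i = pairs[, 1], j = pairs[, 2],
    r0 = dmat[pairs],
    spring_k = spring_k, mass = rep_len(mass, n),
    temperature = temperature, friction = friction, timestep = timestep,
    restraints = restraints
  ), class = c("enm_engine", "mdmd_engine"))
}

enm_forces <- function(engine, x) {
  d <- x[engine$i, , drop = FALSE] - x[engine$j, , drop = FALSE]
  r <- sqrt(rowSums(d^2))
  # E = k (r - r0)^2  =>  f_pair = -2 k (r - r0) along the bond
  fmag <- -2 * engine$spring_k * (r - engine$r0) / r
  fij <- d * fmag
  f <- matrix(0, nrow(x), 3)
  contrib <- rowsum(rbind(fij, -fij), group = c(engine$i, engine$j))
  f[as.integer(rownames(contrib)), ] <- contrib
  if (length(engine$restraints)) {
    f <- f + apply_restraint_energy(x, engine$restraints)$forces
  }
  f
}

enm_energy <- function(engine, x, v) {
  d <- x[engine$i, , drop = FALSE] - x[engine$j, , drop = FALSE]
  r <- sqrt(rowSums(d^2))
  pot <- engine$spring_k * sum((r - engine$r0)^2)
  if (length(engine$restraints)) {
    pot <- pot + apply_restraint_energy(x, engine$restraints)$energy
  }
  kin <- 0.5 * sum(engine$mass * rowSums(v^2)) / KCAL_TO_AMU
  list(potential = pot, kinetic = kin, total = pot + kin)
}

#' Advance a propagator state by one MD sprint
#'
#' Deterministic given `state$rng_state`; the input state is not modified.
#'
#' @param engine an engine built by [enm_engine()] or [hinge_mc_engine()].
#' @param state a `propagator_state`.
#' @param duration sprint length, ps (>= 0; 0 returns the state unchanged).
#' @param ... unused.
#' @return the advanced `propagator_state`.
#' @export
propagate <- function(engine, state, duration, ...) {
  UseMethod("propagate")
}

#' @export
propagate.enm_engine <- function(engine, state, duration, ...) {
  if (duration < 0) stop("duration must be >= 0")
  nsteps <- round(duration / engine$timestep)
  if (nsteps == 0) return(state)
  x <- state$coordinates
  v <- state$velocities
  m <- engine$mass
  dt <- engine$timestep
  # forces are in kcal/(mol A); convert to amu A/ps^2 for the integrator
  acc <- function(xx) enm_forces(engine, xx) * KCAL_TO_AMU / m
  gamma <- engine$friction
  use_ou <- gamma > 0 && engine$temperature > 0
  c1 <- exp(-gamma * dt)
  c2 <- sqrt(pmax(0, (1 - c1^2) * KB_AMU * engine$temperature / m))
  with_seed(state$rng_state, {
    a <- acc(x)
    for (step in seq_len(nsteps)) {
      if (any(!is.finite(a))) {
        bad <- which(!is.finite(rowSums(a)))[1]
        stop("integration failure: non-finite force on atom ", bad)
      }
      v <- v + 0.5 * dt * a             # B
      x <- x + 0.5 * dt * v             # A
      if (use_ou) {                     # O
        v <- c1 * v + c2 * matrix(rnorm(3 * nrow(x)), nrow(x), 3)
      } else if (gamma > 0) {
        v <- c1 * v
      }
      x <- x + 0.5 * dt * v             # A
      a <- acc(x)
      v <- v + 0.5 * dt * a             # B
    }
  })
  propagator_state(x, v,
                   rng_state = (state$rng_state * 69069 + 12345) %% 2147483647,
                   time = state$time + nsteps * dt)
}

#' Hinge Monte-Carlo engine
#'
#' Fast synthetic propagator: each sprint proposes one rigid rotation of the
#' anticodon-arm atoms about the current hinge axis (bend) and about the
#' anticodon-arm axis (twist), with Gaussian step sizes that scale with
#' sqrt(duration) so that the adaptive sprint schedule controls the move
#' size. Velocities are ignored.
#'
#' @param s an `mdmd_structure` (used for topology and default arm
#'   annotation).
#' @param stems a `stem_definition` (default canonical tRNA numbering).
#' @param arm_residues residues rotated as the anticodon arm; defaults to the
#'   structure's generator annotation, else residues 8-50.
#' @param bend_step bend step scale, degrees per sqrt(ps).
#' @param twist_step twist step scale, degrees per sqrt(ps).
#' @return engine object of class `c("hinge_mc_engine", "mdmd_engine")`.
#' @export
hinge_mc_engine <- function(s, stems = stem_definition(),
                            arm_residues = NULL, bend_step = 6,
                            twist_step = 6) {
  if (is.null(arm_residues)) {
    arm_residues <- s$annotation$arm_residues$anticodon
    if (is.null(arm_residues)) arm_residues <- 8:50
  }
  idx <- which(s$atoms$resid %in% arm_residues)
  if (!length(idx)) stop("anticodon-arm selection resolves to 0 atoms")
  structure(list(topology = s, stems = stems, arm_idx = idx,
                 arm_residues = arm_residues,
                 bend_step = bend_step, twist_step = twist_step,
                 mass = 330, temperature = 300),
            class = c("hinge_mc_engine", "mdmd_engine"))
}

#' @export
propagate.hinge_mc_engine <- function(engine, state, duration, ...) {
  if (duration < 0) stop("duration must be >= 0")
  if (duration == 0) return(state)
  s <- set_coords(engine$topology, state$coordinates)
  steps <- with_seed(state$rng_state,
                     rnorm(2) * sqrt(duration) *
                       c(engine$bend_step, engine$twist_step))
  s2 <- deform_hinge(s, delta_angle = steps[1], delta_twist = steps[2],
                     stems = engine$stems,
                     arm_residues = engine$arm_residues)
  propagator_state(coords(s2), state$velocities,
                   rng_state = (state$rng_state * 69069 + 12345) %% 2147483647,
                   time = state$time + duration)
}
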