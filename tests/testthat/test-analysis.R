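# Two ideal straight "stems" built along chosen axes, with the canonical
# residue windows of stem_definition().
orthogonal_stem_structure <- function(angle_deg = 90) {
  th <- angle_deg * pi / 180
  u <- c(sin(th), 0, cos(th))            # anticodon axis
  v <- c(0, 0, 1)                        # acceptor axis
  pts <- list()
  add <- function(resid, pos) {
    pts[[length(pts) + 1]] <<- data.frame(resid = resid, x = pos[1],
                                          y = pos[2], z = pos[3])
  }
  for (i in seq_along(c(1:7, 66:72))) {
    add(c(1:7, 66:72)[i], v * (4 + 0.7 * i))
  }
  for (i in seq_along(c(27:31, 39:43))) {
    add(c(27:31, 39:43)[i], u * (4 + 0.7 * i))
  }
  for (r in c(26, 44, 45)) add(r, c(0, 0, 0))
  df <- do.call(rbind, pts)
  toy_structure(as.matrix(df[, c("x", "y", "z")]), resid = df$resid)
}

test_that("interarm angle recovers constructed geometry and is rigid- and
           order-invariant", {
  s <- orthogonal_stem_structure(90)
  expect_equal(interarm_angle(s), 90, tolerance = 1e-6)
  for (ang in c(60, 75, 105, 140)) {
    expect_equal(interarm_angle(orthogonal_stem_structure(ang)), ang,
                 tolerance = 1e-6)
  }
  moved <- apply_rigid(s, random_rotation(3), c(10, -4, 7))
  expect_equal(interarm_angle(moved), interarm_angle(s), tolerance = 1e-8)
  shuffled <- new_structure(s$atoms[sample(n_atoms(s)), ], s$annotation)
  expect_equal(interarm_angle(shuffled), interarm_angle(s),
               tolerance = 1e-10)
})

test_that("interarm angle validates its stem selections", {
  s <- orthogonal_stem_structure()
  few <- select_atoms(s, resid = c(1:3, 27:31, 39:43, 26, 44, 45))
  expect_error(interarm_angle(few), "acceptor_stem")
  expect_error(stem_definition(acceptor_stem = 1:10, anticodon_stem = 8:20),
               "disjoint")
})

test_that("generator hinge angle and measured interarm angle agree within
           2 degrees across 60-120", {
  for (ang in seq(60, 120, by = 10)) {
    s <- make_pseudo_trna(pseudo_trna_spec(hinge_angle = ang))
    expect_lt(abs(interarm_angle(s) - ang), 2)
  }
})

test_that("per-residue fluctuation: zeros, closed form and rigid invariance", {
  set.seed(23)
  base <- toy_structure(matrix(rnorm(18, sd = 6), 6, 3))
  same <- new_trajectory(base, list(coords(base), coords(base),
                                    coords(base)))
  rf <- per_residue_fluctuation(same)
  expect_equal(rf$rmsf, rep(0, 6), tolerance = 1e-8)
  # one atom oscillating +/- d with symmetric sampling -> RMSF = d
  d <- 1.7
  f1 <- coords(base); f1[6, 1] <- f1[6, 1] + d
  f2 <- coords(base); f2[6, 1] <- f2[6, 1] - d
  osc <- new_trajectory(base, list(f1, f2))
  rf <- per_residue_fluctuation(osc, align_resid = 1:5)
  expect_equal(rf$rmsf[rf$resid == 6], d, tolerance = 1e-6)
  expect_equal(rf$rmsf[rf$resid %in% 1:5], rep(0, 5), tolerance = 1e-6)
  # rigid-body-moved copies of one frame: all-zero after alignment
  frames <- lapply(1:4, function(k)
    coords(apply_rigid(base, random_rotation(k), c(k, 2 * k, -k))))
  rigid <- new_trajectory(base, frames)
  rf <- per_residue_fluctuation(rigid)
  expect_equal(max(rf$rmsf), 0, tolerance = 1e-6)
  expect_error(per_residue_fluctuation(new_trajectory(base,
                                                      list(coords(base)))),
               "2 frames")
})

test_that("docking recovers scrambled frames and never worsens the anchor
           fit", {
  s <- make_pseudo_trna()
  frames <- lapply(1:3, function(k) coords(deform_hinge(s, 5 * k)))
  traj <- new_trajectory(s, frames)
  docked_same <- dock_trajectory(traj, s)
  # frame 1 anchors (residues 34-36, acceptor arm fixed? no: arm moves) --
  # docking an already-docked trajectory changes nothing measurable
  redocked <- dock_trajectory(docked_same, s)
  expect_equal(redocked$xyz, docked_same$xyz, tolerance = 1e-6)
  # scramble frames by random rigid motions; docking restores the originals
  scrambled <- new_trajectory(s, lapply(seq_along(frames), function(k) {
    m <- matrix(docked_same$xyz[k, ], ncol = 3, byrow = TRUE)
    m2 <- m %*% t(random_rotation(10 + k))
    sweep(m2, 2, c(5, -3, 2 * k), "+")
  }))
  recovered <- dock_trajectory(scrambled, s)
  expect_equal(recovered$xyz, docked_same$xyz, tolerance = 1e-6)
  # least-squares optimality: anchor RMSD never increases through docking
  anchor_idx <- which(s$atoms$resid %in% 34:36)
  ai <- bio3d::atom2xyz(anchor_idx)
  ref <- matrix(as.vector(t(coords(s)))[ai], ncol = 3, byrow = TRUE)
  for (k in seq_along(frames)) {
    before <- matrix(scrambled$xyz[k, ai], ncol = 3, byrow = TRUE)
    after <- matrix(recovered$xyz[k, ai], ncol = 3, byrow = TRUE)
    expect_lte(sqrt(mean(rowSums((after - ref)^2))),
               sqrt(mean(rowSums((before - ref)^2))) + 1e-9)
  }
})

test_that("contact rule: 3.9 A pair in, 4.1 A pair out, occupancy counts
           all frames", {
  trna <- toy_structure(matrix(c(0, 0, 0), 1, 3), name = "N1",
                        resname = "G", resid = 10)
  partner_near <- toy_structure(matrix(c(3.9, 0, 0), 1, 3), name = "CA",
                                resname = "ALA", chain = "L", resid = 50,
                                element = "C")
  partner_far <- toy_structure(matrix(c(4.1, 0, 0), 1, 3), name = "CA",
                               resname = "ALA", chain = "L", resid = 50,
                               element = "C")
  one <- new_trajectory(trna, list(coords(trna)))
  cm <- contact_map(one, partner_near)
  expect_equal(nrow(cm$entries), 1)
  expect_equal(cm$entries$occupancy, 1)
  expect_equal(cm$entries$mode, "ca-base")
  expect_equal(cm$entries$partner_chain, "L")
  expect_equal(nrow(contact_map(one, partner_far)$entries), 0)
  # two frames, contact in exactly one -> occupancy 0.5
  away <- coords(trna); away[1, 1] <- -10
  two <- new_trajectory(trna, list(coords(trna), away))
  cm <- contact_map(two, partner_near)
  expect_equal(cm$entries$occupancy, 0.5)
})

test_that("base-base contacts use base atoms only and grow with cutoff", {
  trna <- toy_structure(matrix(c(0, 0, 0, 1, 0, 0), 2, 3, byrow = TRUE),
                        name = c("P", "N1"), resname = "G", resid = c(10, 10))
  # RNA partner: backbone P at 2 A (must NOT count), base N1 at 4.5 A
  partner <- toy_structure(matrix(c(2, 0, 0, 4.5, 0, 0), 2, 3,
                                  byrow = TRUE),
                           name = c("P", "N1"), resname = "C", chain = "R",
                           resid = c(7, 7))
  traj <- new_trajectory(trna, list(coords(trna)))
  expect_equal(nrow(contact_map(traj, partner, cutoff = 3)$entries), 0)
  cm <- contact_map(traj, partner, cutoff = 4)   # base N1(1,0,0)->N1(4.5): 3.5
  expect_equal(nrow(cm$entries), 1)
  expect_equal(cm$entries$mode, "base-base")
  # occupancy is monotonically non-decreasing in the cutoff
  occ_at <- function(cut) {
    e <- contact_map(traj, partner, cutoff = cut)$entries
    if (nrow(e)) sum(e$occupancy) else 0
  }
  occs <- vapply(c(2, 3.5, 4, 6), occ_at, numeric(1))
  expect_true(all(diff(occs) >= 0))
  expect_error(contact_map(traj, toy_structure(matrix(0, 1, 3), name = "P",
                                               resname = "XXX")),
               "neither")
})

test_that("radius of gyration matches closed forms and direct summation", {
  expect_equal(radius_of_gyration(matrix(c(1, 2, 3), 1, 3)), 0)
  two <- matrix(c(0, 0, 0, 2, 0, 0), 2, 3, byrow = TRUE)
  expect_equal(radius_of_gyration(two), 1)
  set.seed(31)
  pts <- matrix(rnorm(300, sd = 7), 100, 3)
  direct <- sqrt(mean(rowSums(sweep(pts, 2, colMeans(pts))^2)))
  expect_equal(radius_of_gyration(pts), direct, tolerance = 1e-10)
  # mass weighting shifts the centroid
  expect_false(isTRUE(all.equal(
    radius_of_gyration(pts, mass = seq_len(100)),
    radius_of_gyration(pts))))
})
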