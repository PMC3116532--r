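test_that("read_pdb parses handcrafted records and filters water", {
  txt <- paste(
    pdb_line(1, "P", "G", "A", 1, 1.234, -2.5, 3.75),
    pdb_line(2, "N1", "G", "A", 1, 0.5, 0.25, -1.125),
    pdb_line(3, "P", "C", "A", 2, 4, 5, 6),
    "END", sep = "\n")
  s <- read_pdb(txt)
  expect_equal(n_atoms(s), 3)
  expect_equal(coords(s)[1, ], c(1.234, -2.5, 3.75), ignore_attr = TRUE)
  expect_equal(s$atoms$resid, c(1, 1, 2))

  with_water <- paste(
    pdb_line(1, "P", "G", "A", 1, 0, 0, 0),
    pdb_line(2, "P", "G", "A", 2, 3, 0, 0),
    pdb_line(3, "O", "HOH", "B", 100, 9, 9, 9, record = "HETATM"),
    sep = "\n")
  expect_equal(n_atoms(read_pdb(with_water)), 2)
  expect_equal(n_atoms(read_pdb(with_water, keep_water = TRUE)), 3)
})

test_that("read_pdb resolves altlocs to highest occupancy, ties to A", {
  two_alt <- function(occ_a, occ_b) paste(
    pdb_line(1, "P", "G", "A", 1, 1, 0, 0, altloc = "A", occ = occ_a),
    pdb_line(2, "P", "G", "A", 1, 2, 0, 0, altloc = "B", occ = occ_b),
    sep = "\n")
  s <- read_pdb(two_alt(0.4, 0.6))
  expect_equal(n_atoms(s), 1)
  expect_equal(s$atoms$x, 2)          # B wins on occupancy
  s <- read_pdb(two_alt(0.5, 0.5))
  expect_equal(s$atoms$x, 1)          # tie: altloc A wins
})

test_that("read_pdb errors name the offending line and reject empty input", {
  bad <- paste(
    pdb_line(1, "P", "G", "A", 1, 0, 0, 0),
    sub("   0.000", "  badxyz", pdb_line(2, "P", "G", "A", 2, 0, 1, 2)),
    sep = "\n")
  expect_error(read_pdb(bad), "line 2")
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines("REMARK nothing here", f)
  expect_error(read_pdb(f), "no ATOM")
})

test_that("PDB write/read round-trip preserves coordinates to 3 decimals", {
  set.seed(11)
  s <- toy_structure(matrix(rnorm(30, sd = 20), 10, 3),
                     name = rep(c("P", "N1"), 5), resid = rep(1:5, each = 2))
  f <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(s, f)
  s2 <- read_pdb(f)
  expect_equal(n_atoms(s2), n_atoms(s))
  # first write rounds onto the format's 3-decimal grid ...
  expect_lt(max(abs(coords(s2) - coords(s))), 5.01e-4)
  # ... after which a second round-trip is exact
  write_pdb(s2, f)
  expect_identical(coords(read_pdb(f)), coords(s2))
  expect_equal(s2$atoms$name, s$atoms$name)
  expect_equal(s2$atoms$resid, s$atoms$resid)
})

test_that("selections preserve atom order and structure invariants hold", {
  s <- make_pseudo_trna()
  sel <- select_atoms(s, resid = "27-31,39-43", name = "P")
  expect_equal(n_atoms(sel), 10)
  expect_false(is.unsorted(match(sel$atoms$serial, s$atoms$serial)))
  expect_error(new_structure(rbind(s$atoms, s$atoms[1, ])), "duplicate")
  bad <- s$atoms; bad$x[1] <- NaN
  expect_error(new_structure(bad), "finite")
})

test_that("parse_selection handles ranges, lists and bad tokens", {
  expect_equal(parse_selection("1-3,7"), c(1, 2, 3, 7))
  expect_equal(parse_selection("5"), 5)
  expect_error(parse_selection("1-3,x"), "cannot parse")
  expect_error(parse_selection(""), "non-empty")
})

test_that("superposition is exact for self and rigid copies, and excludes
           reflections", {
  set.seed(3)
  s <- toy_structure(matrix(rnorm(21, sd = 5), 7, 3))
  expect_equal(superpose(s, s)$rmsd, 0, tolerance = 1e-10)
  moved <- apply_rigid(s, random_rotation(4), c(3, -8, 2))
  expect_equal(superpose(moved, s)$rmsd, 0, tolerance = 1e-8)
  # chirality must be preserved: a mirrored copy cannot fit to zero
  xyz <- coords(s); xyz[, 1] <- -xyz[, 1]
  mirrored <- set_coords(s, xyz)
  expect_gt(superpose(mirrored, s)$rmsd, 0.1)
})

test_that("superposition RMSD is rigid-invariant and symmetric", {
  set.seed(8)
  for (k in 1:5) {
    a <- toy_structure(matrix(rnorm(24, sd = 6), 8, 3))
    b <- set_coords(a, coords(a) + matrix(rnorm(24), 8, 3))
    r_ab <- superpose(a, b)$rmsd
    # applying any rigid transform to the mobile first changes nothing
    a2 <- apply_rigid(a, random_rotation(k), c(k, -k, 2 * k))
    expect_equal(superpose(a2, b)$rmsd, r_ab, tolerance = 1e-6)
    expect_equal(superpose(b, a)$rmsd, r_ab, tolerance = 1e-6)
  }
})

test_that("superposition requires 3+ non-collinear pairs", {
  line <- toy_structure(cbind(1:5, 0, 0))
  expect_error(superpose(line, line), "collinear")
  two <- toy_structure(matrix(rnorm(6), 2, 3))
  expect_error(superpose(two, two), "at least 3")
})

test_that("4-point superposition matches a rotation-grid brute force", {
  set.seed(42)
  A <- matrix(rnorm(12, sd = 4), 4, 3)
  B <- A %*% t(random_rotation(9)) +
    matrix(rnorm(12, sd = 0.3), 4, 3)   # rigid motion + noise
  sa <- toy_structure(A)
  sb <- toy_structure(B)
  r_pkg <- superpose(sa, sb)$rmsd
  r_grid <- grid_search_rmsd(A, B)
  expect_lt(abs(r_pkg - r_grid), 1e-3)
  expect_lte(r_pkg, r_grid + 1e-9)  # package result is the true optimum
})

test_that("rmsd_matrix matches pairwise superpose calls and is symmetric", {
  set.seed(21)
  top <- toy_structure(matrix(rnorm(15, sd = 5), 5, 3))
  frames <- lapply(1:3, function(i) coords(top) + matrix(rnorm(15), 5, 3))
  traj <- new_trajectory(top, frames)
  M <- rmsd_matrix(traj, traj)
  expect_equal(diag(M), rep(0, 3), tolerance = 1e-8)
  expect_equal(M, t(M), tolerance = 1e-6)
  for (i in 1:3) for (j in 1:3) {
    direct <- superpose(set_coords(top, frames[[i]]),
                        set_coords(top, frames[[j]]))$rmsd
    expect_equal(M[i, j], direct, tolerance = 1e-8)
  }
  # two single-frame trajectories differing by a rigid motion
  t1 <- new_trajectory(top, list(coords(top)))
  t2 <- new_trajectory(top, list(coords(apply_rigid(top,
                                                    random_rotation(2),
                                                    c(1, 2, 3)))))
  expect_equal(rmsd_matrix(t1, t2)[1, 1], 0, tolerance = 1e-8)
})

test_that("trajectory round-trips through multi-model PDB", {
  set.seed(5)
  top <- toy_structure(round(matrix(rnorm(18, sd = 8), 6, 3), 3))
  traj <- new_trajectory(top, lapply(1:3, function(i)
    coords(top) + i))
  f <- withr::local_tempfile(fileext = ".pdb")
  write_trajectory_pdb(traj, f)
  traj2 <- read_trajectory_pdb(f)
  expect_equal(n_frames(traj2), 3)
  expect_equal(traj2$xyz, traj$xyz, tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("convergence rule is a strict 3-Angstrom threshold", {
  expect_true(check_convergence(2.9))
  expect_false(check_convergence(3.0))
  expect_false(check_convergence(3.1))
  expect_true(check_convergence(0))
  expect_true(check_convergence(3.5, threshold = 4))
  expect_error(check_convergence(-0.1), "non-negative")
})
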