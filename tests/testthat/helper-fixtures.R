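# Fixtures are built in code; nothing is read from disk.

# One fixed-column PDB ATOM/HETATM line.
pdb_line <- function(serial, name, resname, chain, resid, x, y, z,
                     record = "ATOM", altloc = "", occ = 1, element = NULL) {
  if (is.null(element)) element <- substr(gsub("[^A-Za-z]", "", name), 1, 1)
  name_field <- if (nchar(name) < 4) sprintf(" %-3s", name)
                else sprintf("%-4s", name)
  sprintf("%-6s%5d %s%1s%-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial, name_field, altloc, resname, chain, resid,
          x, y, z, occ, 0, toupper(element))
}

# Minimal hand-built structure from a coordinate matrix; one P atom per
# residue unless names/resnames are given.
toy_structure <- function(xyz, name = "P", resname = "G", chain = "A",
                          resid = NULL, element = NULL) {
  xyz <- as.matrix(xyz)
  n <- nrow(xyz)
  if (is.null(resid)) resid <- seq_len(n)
  name <- rep_len(name, n)
  if (is.null(element)) element <- substr(gsub("[^A-Za-z]", "", name), 1, 1)
  new_structure(data.frame(
    serial = seq_len(n), name = name, resname = rep_len(resname, n),
    chain = rep_len(chain, n), resid = resid, insert = rep("", n),
    element = rep_len(element, n),
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], stringsAsFactors = FALSE))
}

random_rotation <- function(seed) {
  set.seed(seed)
  q <- rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

apply_rigid <- function(s, R, t = c(0, 0, 0)) {
  set_coords(s, sweep(coords(s) %*% t(R), 2, t, "+"))
}

euler_rotation <- function(a, b, g) {
  rotation_matrix(c(0, 0, 1), a) %*% rotation_matrix(c(0, 1, 0), b) %*%
    rotation_matrix(c(0, 0, 1), g)
}

# Brute-force rigid superposition: refine an Euler-angle grid; translation
# is optimal (centroid-matching) at every candidate rotation. Independent of
# the package's SVD-based path.
grid_search_rmsd <- function(A, B) {
  Ac <- scale(A, scale = FALSE)
  Bc <- scale(B, scale = FALSE)
  rmsd_at <- function(a, b, g) {
    M <- Ac %*% t(euler_rotation(a, b, g))
    sqrt(mean(rowSums((M - Bc)^2)))
  }
  best <- c(0, 0, 0)
  step <- 30
  vals_at <- function(center, step) {
    grid <- expand.grid(a = center[1] + step * (-6:6),
                        b = center[2] + step * (-6:6),
                        g = center[3] + step * (-6:6))
    r <- mapply(rmsd_at, grid$a, grid$b, grid$g)
    list(best = as.numeric(grid[which.min(r), ]), min = min(r))
  }
  res <- vals_at(best, step)
  for (lev in 1:6) {
    step <- step / 4
    res <- vals_at(res$best, step)
  }
  res$min
}
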