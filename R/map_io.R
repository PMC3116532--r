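#' Write a density map as an MRC/CCP4 (2014) file
#'
#' Mode 2 (32-bit float), column axis = x (fastest), row = y, section = z,
#' origin stored in the MRC2014 ORIGIN words. Written little-endian.
#'
#' @param map a `density_map`.
#' @param dest output path.
#' @return `dest`, invisibly.
#' @export
write_map <- function(map, dest) {
  dims <- dim(map$values)
  sp <- spacing3(map)
  con <- file(dest, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  v <- as.numeric(map$values)
  wi(dims)                       # NX NY NZ (cols, rows, sections)
  wi(2)                          # MODE 2: float32
  wi(c(0, 0, 0))                 # NXSTART..NZSTART
  wi(dims)                       # MX MY MZ
  wf(dims * sp)                  # CELLA
  wf(c(90, 90, 90))              # CELLB
  wi(c(1, 2, 3))                 # MAPC MAPR MAPS
  wf(c(min(v), max(v), mean(v))) # DMIN DMAX DMEAN
  wi(1)                          # ISPG
  wi(0)                          # NSYMBT
  wi(rep(0L, 25))                # EXTRA (words 25-49)
  wf(map$origin)                 # ORIGIN (words 50-52, MRC2014)
  writeBin(charToRaw("MAP "), con)             # word 53
  writeBin(as.raw(c(0x44, 0x41, 0x00, 0x00)), con)  # MACHST little-endian
  wf(stats::sd(v))               # RMS
  wi(0)                          # NLABL
  writeBin(raw(800), con)        # labels
  writeBin(v, con, size = 4, endian = "little")
  invisible(dest)
}

#' Read an MRC/CCP4 (2014) density map
#'
#' Supports mode 2 (float32), mode 1 (int16) and mode 0 (int8). Axis order
#' is normalized to the package's internal convention (x fastest) using the
#' MAPC/MAPR/MAPS header words. The origin is taken from the MRC2014 ORIGIN
#' words when nonzero, otherwise from NXSTART * spacing. Anisotropic voxel
#' spacing is accepted and recorded; negative densities (e.g. from
#' experimental maps) are clipped to 0 with a warning, since every consumer
#' in this package assumes non-negative density.
#'
#' @param source path to the map file.
#' @return a `density_map`.
#' @export
read_map <- function(source) {
  if (!file.exists(source)) stop("map file not found: ", source)
  con <- file(source, "rb")
  on.exit(close(con))
  ri <- function(n) readBin(con, "integer", n = n, size = 4,
                            endian = "little")
  rf <- function(n) readBin(con, "numeric", n = n, size = 4,
                            endian = "little")
  nxyz <- ri(3)
  mode <- ri(1)
  nstart <- ri(3)
  mxyz <- ri(3)
  cella <- rf(3)
  rf(3)                          # CELLB, ignored (orthogonal assumed)
  mapcrs <- ri(3)
  rf(3)                          # DMIN DMAX DMEAN
  ri(2)                          # ISPG NSYMBT
  ri(25)                         # EXTRA
  origin_words <- rf(3)
  readBin(con, "raw", n = 4)     # "MAP "
  readBin(con, "raw", n = 4)     # MACHST
  rf(1)                          # RMS
  ri(1)                          # NLABL
  readBin(con, "raw", n = 800)
  nvox <- prod(nxyz)
  if (mode == 2) {
    v <- rf(nvox)
  } else if (mode == 1) {
    v <- readBin(con, "integer", n = nvox, size = 2, endian = "little")
  } else if (mode == 0) {
    v <- readBin(con, "integer", n = nvox, size = 1, signed = TRUE)
  } else {
    stop("unsupported MRC mode ", mode, " (supported: 0, 1, 2)")
  }
  if (length(v) < nvox) stop("truncated map data in ", source)
  arr <- array(v, dim = nxyz)    # file layout: column fastest

  if (any(sort(mapcrs) != 1:3)) stop("invalid MAPC/MAPR/MAPS: ",
                                     paste(mapcrs, collapse = ","))
  # permute so that dimension d of the result is crystallographic axis d
  perm <- match(1:3, mapcrs)
  arr <- aperm(arr, perm)
  spacing <- (cella / mxyz)[1:3]
  if (max(spacing) - min(spacing) < 1e-6 * max(spacing)) {
    spacing <- spacing[1]
  }
  nstart_xyz <- nstart[perm]
  origin <- if (any(abs(origin_words) > 1e-12)) origin_words
            else nstart_xyz * (if (length(spacing) == 1) rep(spacing, 3)
                               else spacing)
  if (any(arr < 0)) {
    warning("negative density values clipped to 0 on read")
    arr[arr < 0] <- 0
  }
  density_map(arr, origin = origin, spacing = spacing)
}
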