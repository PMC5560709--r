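## Minimal MRC2014 / CCP4 volume I/O. The installed stack has no R reader
## for this format; the header layout is fixed 4-byte words, which readBin
## handles directly. Only mode-2 (float32) data are written; modes 0/1/2
## are read.

#' Density map on a regular voxel grid
#'
#' @param grid 3D numeric array indexed `[i, j, k]` along world x, y, z.
#' @param voxel_size length-3 positive vector, Angstrom per voxel per axis.
#' @param origin world coordinate (Angstrom) of the center of voxel
#'   `[1, 1, 1]` (index origin; indices are 0-based in the world transform
#'   `world(i,j,k) = origin + (i,j,k) * voxel_size` with `i,j,k` counted
#'   from zero).
#' @param resolution_annotation nominal resolution in Angstrom (metadata).
#' @return object of class `density_map`.
#' @export
density_map <- function(grid, voxel_size, origin = c(0, 0, 0),
                        resolution_annotation = NA_real_) {
  if (length(dim(grid)) != 3L) stop("grid must be a 3D array")
  if (any(dim(grid) < 1L)) stop("grid dimensions must be >= 1")
  voxel_size <- rep_len(as.numeric(voxel_size), 3L)
  if (any(!is.finite(voxel_size)) || any(voxel_size <= 0))
    stop("voxel_size must be positive on all axes")
  origin <- rep_len(as.numeric(origin), 3L)
  structure(list(grid = grid, voxel_size = voxel_size, origin = origin,
                 resolution_annotation = resolution_annotation),
            class = "density_map")
}

#' @export
print.density_map <- function(x, ...) {
  cat(sprintf("density_map: %s voxels, voxel size %s A, origin (%s) A\n",
              paste(dim(x$grid), collapse = " x "),
              paste(signif(x$voxel_size, 4), collapse = ", "),
              paste(signif(x$origin, 4), collapse = ", ")))
  invisible(x)
}

#' Voxel indices to world coordinates
#'
#' Affine map `world = origin + ijk0 * voxel_size` where `ijk0` are 0-based
#' voxel indices (possibly fractional).
#' @param map a [density_map()].
#' @param ijk0 M x 3 matrix of 0-based indices.
#' @return M x 3 matrix of world coordinates (Angstrom).
#' @export
voxel_to_world <- function(map, ijk0) {
  ijk0 <- matrix(as.numeric(ijk0), ncol = 3)
  sweep(sweep(ijk0, 2, map$voxel_size, "*"), 2, map$origin, "+")
}

#' World coordinates to (fractional, 0-based) voxel indices
#' @param map a [density_map()].
#' @param xyz M x 3 world coordinates (Angstrom).
#' @return M x 3 matrix of fractional 0-based indices.
#' @export
world_to_voxel <- function(map, xyz) {
  xyz <- matrix(as.numeric(xyz), ncol = 3)
  sweep(sweep(xyz, 2, map$origin, "-"), 2, map$voxel_size, "/")
}

.mrc_header_skeleton <- function() integer(256)

#' Read an MRC/CCP4 density map
#'
#' Parses the 1024-byte header, applies the MAPC/MAPR/MAPS axis
#' permutation so the in-memory grid is always ordered x, y, z, and
#' computes the world origin as `ORIGIN + nstart * voxel_size` (covering
#' both the MRC2014 origin record and CCP4-style start offsets).
#'
#' @param path MRC/CCP4 file.
#' @return a [density_map()].
#' @export
read_density_map <- function(path) {
  if (!file.exists(path)) stop("cannot read map file: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "integer", 1, size = 4, endian = "little")
  seek(con, 0)
  ## detect byte order from a sane NX (maps never have > 2^24 columns)
  endian <- if (magic >= 0 && magic < 2^24) "little" else "big"
  ih <- readBin(con, "integer", 256, size = 4, endian = endian)
  seek(con, 0)
  fh <- readBin(con, "numeric", 256, size = 4, endian = endian)
  nxyz <- ih[1:3]          # columns, rows, sections
  mode <- ih[4]
  nstart <- ih[5:7]
  mxyz <- ih[8:10]
  cella <- fh[11:13]
  mapcrs <- ih[17:19]
  if (any(nxyz < 1) || !mode %in% c(0L, 1L, 2L) ||
      !all(sort(mapcrs) == 1:3))
    stop("malformed MRC header in ", path)
  nsymbt <- ih[24]
  origin_rec <- fh[50:52]
  seek(con, 1024 + nsymbt)
  nvox <- prod(nxyz)
  data <- switch(as.character(mode),
    "0" = as.numeric(readBin(con, "integer", nvox, size = 1, signed = TRUE)),
    "1" = as.numeric(readBin(con, "integer", nvox, size = 2, endian = endian)),
    "2" = readBin(con, "numeric", nvox, size = 4, endian = endian))
  if (length(data) != nvox) stop("truncated MRC data block in ", path)
  arr <- array(data, dim = nxyz)   # fastest axis first = columns
  ## axis c/r/s corresponds to world axis mapcrs[.]; permute to x,y,z
  perm <- order(mapcrs)            # position of x, y, z among c,r,s
  arr <- aperm(arr, perm)
  mxyz_w <- mxyz; cella_w <- cella # cell is already in x,y,z order
  voxel <- ifelse(mxyz_w > 0, cella_w / mxyz_w, 1)
  nstart_w <- nstart[perm]         # start offsets follow the data axes
  origin <- origin_rec + nstart_w * voxel
  density_map(arr, voxel_size = voxel, origin = origin)
}

#' Write a density map in MRC2014 format (mode 2)
#'
#' Support utility for offline round-trip tests and for exporting the
#' synthetic maps produced by [make_synthetic_map()]; axes are written in
#' x, y, z order (MAPC/MAPR/MAPS = 1, 2, 3) with the world origin in the
#' ORIGIN record.
#'
#' @param map a [density_map()].
#' @param path output file.
#' @return invisibly, the path.
#' @export
write_density_map <- function(map, path) {
  stopifnot(inherits(map, "density_map"))
  d <- dim(map$grid)
  ih <- integer(256)
  fh <- numeric(256)
  ih[1:3] <- d
  ih[4] <- 2L
  ih[5:7] <- 0L
  ih[8:10] <- d
  fh[11:13] <- d * map$voxel_size
  fh[14:16] <- 90
  ih[17:19] <- 1:3
  fh[20] <- min(map$grid); fh[21] <- max(map$grid); fh[22] <- mean(map$grid)
  ih[23] <- 1L                     # ISPG = 1 (volume)
  ih[24] <- 0L                     # no symmetry records
  fh[50:52] <- map$origin
  ih[53] <- readBin(charToRaw("MAP "), "integer", size = 4)
  ih[54] <- readBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), "integer", size = 4)
  con <- file(path, "wb")
  on.exit(close(con))
  ## write word-by-word: integer words except the float fields
  float_words <- c(11:16, 20:22, 50:52)
  for (w in 1:256) {
    if (w %in% float_words)
      writeBin(fh[w], con, size = 4, endian = "little")
    else
      writeBin(ih[w], con, size = 4, endian = "little")
  }
  writeBin(as.numeric(map$grid), con, size = 4, endian = "little")
  invisible(path)
}

#' Convert a thresholded density map to a weighted point cloud
#'
#' One point per voxel with density above `threshold`, located at the
#' voxel's world center. Weights are `density - threshold` (so the cloud
#' is insensitive to the map's additive baseline) rescaled to mean 1, so
#' the total weight equals the surviving voxel count.
#'
#' @param map a [density_map()].
#' @param threshold density value; voxels with `density > threshold` are kept.
#' @return a [point_cloud()].
#' @export
map_to_weighted_points <- function(map, threshold) {
  stopifnot(inherits(map, "density_map"))
  keep <- which(map$grid > threshold)
  if (!length(keep)) stop("no voxel above threshold")
  d <- dim(map$grid)
  ijk <- arrayInd(keep, d) - 1L
  pos <- voxel_to_world(map, ijk)
  w <- map$grid[keep] - threshold
  w <- w / mean(w)
  point_cloud(pos, weights = w, source_id = "density_map")
}
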