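# MRC2014 volume input/output. Only the common modes are supported
# (0 = int8, 1 = int16, 2 = float32); maps are written in mode 2.
# Lengths in the header are Angstrom per the format; the package works in
# nm internally, so voxel sizes are converted exactly once at this
# boundary (1 nm = 10 A).

#' Read / write density maps in MRC2014 format
#'
#' `readDensityMap` parses an MRC2014 file into a [DensityMap-class] with
#' its voxel size converted from Angstrom to nm. `writeDensityMap` writes a
#' map as little-endian mode-2 (float32) MRC2014 with recomputed density
#' statistics in the header; `write` then `read` is an identity up to
#' float32 precision.
#'
#' Maps with anisotropic voxels are read with a warning; symmetry
#' operations reject them (resample first).
#'
#' @param path file path.
#' @param map a [DensityMap-class].
#' @return `readDensityMap`: a [DensityMap-class]. `writeDensityMap`: the
#'   path, invisibly.
#' @examples
#' f <- tempfile(fileext = ".mrc")
#' m <- DensityMap(array(rnorm(8^3), c(8, 8, 8)), voxelSize = 0.5)
#' writeDensityMap(m, f)
#' m2 <- readDensityMap(f)
#' max(abs(voxels(m2) - voxels(m)))
#' @export
readDensityMap <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  ints1 <- readBin(con, "integer", n = 10, size = 4, endian = "little")
  nx <- ints1[1]; ny <- ints1[2]; nz <- ints1[3]; mode <- ints1[4]
  mx <- ints1[8]; my <- ints1[9]; mz <- ints1[10]
  cella <- readBin(con, "numeric", n = 3, size = 4, endian = "little")
  readBin(con, "numeric", n = 3, size = 4, endian = "little")   # cellb
  mapcrs <- readBin(con, "integer", n = 3, size = 4, endian = "little")
  readBin(con, "numeric", n = 3, size = 4, endian = "little")   # dmin/max/mean
  readBin(con, "integer", n = 2, size = 4, endian = "little")   # ispg, nsymbt
  readBin(con, "raw", n = 100)                                  # extra
  readBin(con, "numeric", n = 3, size = 4, endian = "little")   # origin
  magic <- rawToChar(readBin(con, "raw", n = 4))
  readBin(con, "raw", n = 4)                                    # machst
  readBin(con, "numeric", n = 1, size = 4, endian = "little")   # rms
  readBin(con, "raw", n = 1024 - 220)                           # nlabl+labels
  if (magic != "MAP ")
    stop("not an MRC2014 file (missing 'MAP ' magic): ", path)
  if (nx < 1 || ny < 1 || nz < 1)
    stop("corrupt MRC header: non-positive dimensions")
  if (!identical(mapcrs, 1:3))
    stop("unsupported MRC axis order (mapc/mapr/maps must be 1,2,3)")
  n <- nx * ny * nz
  vals <- switch(as.character(mode),
    "0" = as.numeric(readBin(con, "integer", n = n, size = 1, signed = TRUE)),
    "1" = as.numeric(readBin(con, "integer", n = n, size = 2,
                             endian = "little")),
    "2" = readBin(con, "numeric", n = n, size = 4, endian = "little"),
    stop("unsupported MRC mode ", mode, " (modes 0, 1, 2 supported)"))
  if (length(vals) != n) stop("truncated MRC data block: ", path)
  vsA <- cella / c(mx, my, mz)
  vs_nm <- vsA / 10
  if (max(vs_nm) - min(vs_nm) > 1e-6 * max(vs_nm))
    warning("anisotropic voxels (", paste(signif(vs_nm, 5), collapse = " x "),
            " nm); symmetry operations will refuse this map")
  DensityMap(array(vals, c(nx, ny, nz)), voxelSize = vs_nm)
}

#' @rdname readDensityMap
#' @export
writeDensityMap <- function(map, path) {
  stopifnot(is(map, "DensityMap"))
  vox <- voxels(map)
  d <- dim(vox)
  vsA <- voxelSize(map) * 10
  con <- file(path, "wb")
  on.exit(close(con))
  wInt <- function(x) writeBin(as.integer(x), con, size = 4,
                               endian = "little")
  wFlt <- function(x) writeBin(as.numeric(x), con, size = 4,
                               endian = "little")
  wInt(c(d, 2L, 0L, 0L, 0L, d))                 # nx..nz, mode, start, mx..mz
  wFlt(d * vsA)                                 # cella (Angstrom)
  wFlt(c(90, 90, 90))                           # cellb
  wInt(1:3)                                     # mapc, mapr, maps
  wFlt(c(min(vox), max(vox), mean(vox)))        # dmin, dmax, dmean
  wInt(c(0L, 0L))                               # ispg, nsymbt
  wInt(0L); wInt(0L)                            # extra words 1-2
  writeBin(charToRaw("MRCO"), con)              # exttyp
  wInt(20140L)                                  # nversion
  writeBin(raw(100 - 16), con)                  # remaining extra
  wFlt(c(0, 0, 0))                              # origin
  writeBin(charToRaw("MAP "), con)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # machst little-endian
  wFlt(stats::sd(as.numeric(vox)) * sqrt((length(vox) - 1) / length(vox)))
  wInt(0L)                                      # nlabl
  writeBin(raw(800), con)                       # labels
  wFlt(as.numeric(vox))
  invisible(path)
}

#' Recompute density statistics stored in an MRC header
#'
#' Returns the min/max/mean/rms a conformant writer stores, computed from
#' the voxel values; used to check header consistency.
#'
#' @param map a [DensityMap-class].
#' @return named numeric vector `dmin`, `dmax`, `dmean`, `rms`.
#' @export
mapStatistics <- function(map) {
  v <- as.numeric(voxels(map))
  c(dmin = min(v), dmax = max(v), dmean = mean(v),
    rms = sqrt(mean((v - mean(v))^2)))
}
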