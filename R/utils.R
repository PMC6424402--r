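# Internal helpers shared across modules.

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG
# state. `seed = NULL` leaves the current stream untouched.
.withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Uniform random points in an axis-aligned ellipse centred at the origin.
.runifEllipse <- function(n, a, b) {
  r <- sqrt(stats::runif(n))
  th <- stats::runif(n, 0, 2 * pi)
  cbind(x_nm = a * r * cos(th), y_nm = b * r * sin(th))
}

.inEllipse <- function(xy, a, b) {
  (xy[, 1] / a)^2 + (xy[, 2] / b)^2 <= 1
}

# Trilinear interpolation of a 3D array at fractional voxel coordinates
# (1-based). Points outside the grid evaluate to `fill`.
.interpTrilinear <- function(vox, x, y, z, fill = 0) {
  d <- dim(vox)
  i0 <- floor(x); j0 <- floor(y); k0 <- floor(z)
  fx <- x - i0; fy <- y - j0; fz <- z - k0
  ok <- i0 >= 1 & i0 + 1 <= d[1] & j0 >= 1 & j0 + 1 <= d[2] &
        k0 >= 1 & k0 + 1 <= d[3]
  out <- rep(fill, length(x))
  if (!any(ok)) return(out)
  i0 <- i0[ok]; j0 <- j0[ok]; k0 <- k0[ok]
  fx <- fx[ok]; fy <- fy[ok]; fz <- fz[ok]
  nx <- d[1]; nxy <- d[1] * d[2]
  base <- i0 + (j0 - 1) * nx + (k0 - 1) * nxy
  v000 <- vox[base];             v100 <- vox[base + 1]
  v010 <- vox[base + nx];        v110 <- vox[base + nx + 1]
  v001 <- vox[base + nxy];       v101 <- vox[base + nxy + 1]
  v011 <- vox[base + nx + nxy];  v111 <- vox[base + nx + nxy + 1]
  out[ok] <-
    (1 - fz) * ((1 - fy) * ((1 - fx) * v000 + fx * v100) +
                fy * ((1 - fx) * v010 + fx * v110)) +
    fz * ((1 - fy) * ((1 - fx) * v001 + fx * v101) +
          fy * ((1 - fx) * v011 + fx * v111))
  out
}

.assertIsotropic <- function(map, what) {
  vs <- voxelSize(map)
  if (max(vs) - min(vs) > 1e-9 * max(vs))
    stop(what, " requires cubic (isotropic) voxels; resample the map first")
  vs[1]
}

# FNV-1a hash of a character scalar, as an 8-digit hex string; used for
# config fingerprints in logs. 32-bit arithmetic done in doubles by
# splitting the multiply so intermediates stay exactly representable.
.fnv1a <- function(txt) {
  bytes <- as.integer(charToRaw(txt))
  h <- 2166136261
  p <- 16777619
  for (b in bytes) {
    h <- .bitXor32(h, b)
    h1 <- h %/% 65536; h0 <- h %% 65536
    h <- ((h1 * p) %% 65536 * 65536 + h0 * p) %% 4294967296
  }
  sprintf("%04x%04x", h %/% 65536, h %% 65536)
}

# XOR for non-negative doubles < 2^32 (bitwXor works on 32-bit signed ints).
.bitXor32 <- function(a, b) {
  hi <- bitwXor(a %/% 65536, b %/% 65536)
  lo <- bitwXor(a %% 65536, b %% 65536)
  hi * 65536 + lo
}
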