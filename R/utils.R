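# Deterministic sub-seed derivation: hash a character key into [1, 2^31-2]
# and mix with the master seed. Linear congruential mixing in double
# precision (all intermediates < 2^53, so exact).
split_seed <- function(seed, ...) {
  key <- paste(c(...), collapse = "/")
  h <- 0
  for (c in utf8ToInt(key)) h <- (h * 31 + c) %% 2147483647
  mix <- (seed %% 2147483647) * 48271 %% 2147483647 * 69621 %% 2147483647
  as.integer((mix + h) %% 2147483646) + 1L
}

# run code under a seed without disturbing the caller's RNG stream
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# trilinear interpolation of a 3D field at fractional voxel indices
# (0-based, voxel-centre convention); queries outside the grid return `fill`
trilinear <- function(field, ix, iy, iz, fill) {
  d <- dim(field)
  x0 <- floor(ix); y0 <- floor(iy); z0 <- floor(iz)
  fx <- ix - x0; fy <- iy - y0; fz <- iz - z0
  inside <- x0 >= 0 & y0 >= 0 & z0 >= 0 &
    x0 <= d[1] - 1 & y0 <= d[2] - 1 & z0 <= d[3] - 1 &
    ix >= 0 & iy >= 0 & iz >= 0 &
    ix <= d[1] - 1 & iy <= d[2] - 1 & iz <= d[3] - 1
  out <- rep(fill, length(ix))
  if (!any(inside)) return(out)
  x0 <- x0[inside]; y0 <- y0[inside]; z0 <- z0[inside]
  fx <- fx[inside]; fy <- fy[inside]; fz <- fz[inside]
  x1 <- pmin(x0 + 1, d[1] - 1)
  y1 <- pmin(y0 + 1, d[2] - 1)
  z1 <- pmin(z0 + 1, d[3] - 1)
  at <- function(i, j, k) field[cbind(i + 1, j + 1, k + 1)]
  v <- at(x0, y0, z0) * (1 - fx) * (1 - fy) * (1 - fz) +
    at(x1, y0, z0) * fx * (1 - fy) * (1 - fz) +
    at(x0, y1, z0) * (1 - fx) * fy * (1 - fz) +
    at(x1, y1, z0) * fx * fy * (1 - fz) +
    at(x0, y0, z1) * (1 - fx) * (1 - fy) * fz +
    at(x1, y0, z1) * fx * (1 - fy) * fz +
    at(x0, y1, z1) * (1 - fx) * fy * fz +
    at(x1, y1, z1) * fx * fy * fz
  out[inside] <- v
  out
}
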