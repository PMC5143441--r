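# Internal numeric helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Run `expr` under a private RNG stream seeded with `seed`, restoring the
# caller's .Random.seed afterwards so generators never perturb user state.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("`seed` must be a single integer", call. = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# FFT sample frequencies (cycles per meter) for n samples at spacing d,
# in the native unshifted FFT ordering.
fft_freq <- function(n, d) {
  i <- 0:(n - 1L)
  ifelse(i < (n + 1L) %/% 2, i, i - n) / (n * d)
}

# Signed lag offsets (in samples) matching fft_freq ordering.
fft_lags <- function(n) {
  i <- 0:(n - 1L)
  ifelse(i < (n + 1L) %/% 2, i, i - n)
}

# Reorder an FFT-ordered matrix so zero frequency/lag sits at the center
# cell (floor(n/2)+1 along each axis).
fft_shift2 <- function(m) {
  nx <- nrow(m); ny <- ncol(m)
  sx <- c(seq((nx %/% 2) + 1L, nx), seq_len(nx %/% 2))
  sy <- c(seq((ny %/% 2) + 1L, ny), seq_len(ny %/% 2))
  m[sx, sy, drop = FALSE]
}

# Periodic 2D Gaussian smoothing via FFT; sigma in pixels (scalar).
# sigma = 0 returns the input unchanged.
gauss_smooth2 <- function(m, sigma) {
  if (sigma <= 0) return(m)
  nx <- nrow(m); ny <- ncol(m)
  fx <- fft_freq(nx, 1); fy <- fft_freq(ny, 1)
  gk <- exp(-2 * pi^2 * sigma^2 * outer(fx^2, fy^2, `+`))
  out <- Re(stats::fft(stats::fft(m) * gk, inverse = TRUE)) / (nx * ny)
  out
}

# Raised-cosine amplitude taper over `w` voxels at each lateral edge of an
# nx-by-ny lattice; emulates radiating boundaries together with padding.
taper_window <- function(nx, ny, w) {
  ramp <- function(n) {
    v <- rep(1, n)
    if (w > 0 && n > 2 * w) {
      t <- 0.5 * (1 - cos(pi * (seq_len(w) - 0.5) / w))
      v[seq_len(w)] <- t
      v[n + 1L - seq_len(w)] <- t
    }
    v
  }
  outer(ramp(nx), ramp(ny))
}

# Replicate-pad a matrix to np x nq, centering the original block at
# offset (i0, j0) (number of leading pad cells).
pad_replicate <- function(m, np, nq, i0, j0) {
  ix <- pmin(pmax(seq_len(np) - i0, 1L), nrow(m))
  iy <- pmin(pmax(seq_len(nq) - j0, 1L), ncol(m))
  m[ix, iy, drop = FALSE]
}

# Zero-pad a complex matrix into an np x nq lattice at offset (i0, j0).
pad_zero <- function(m, np, nq, i0, j0) {
  out <- matrix(0 + 0i, np, nq)
  out[i0 + seq_len(nrow(m)), j0 + seq_len(ncol(m))] <- m
  out
}

# Wrap angles to the principal interval (-pi, pi].
wrap_phase <- function(phi) {
  w <- (phi + pi) %% (2 * pi) - pi
  w[w == -pi] <- pi
  w
}

# Trilinear interpolation of a complex 3D field at a physical point.
# Interpolates real and imaginary parts (the phasor), never the angle,
# so phase wrapping cannot corrupt the result.  `point` must lie inside
# the voxel-center hull of the region covered by `field` (grid `grid`,
# optionally offset by 1-based start indices `start`).
interp_complex3 <- function(field, grid, point, start = c(1L, 1L, 1L)) {
  d <- dim(field)
  # continuous index (1-based) within the field block
  u <- (as.numeric(point) - grid$origin) / grid$spacing + 1 - (start - 1L)
  if (any(u < 1 - 1e-9) || any(u > d + 1e-9))
    stop("target lies outside the stored region", call. = FALSE)
  u <- pmin(pmax(u, 1), d)
  i0 <- pmin(floor(u), d - 1L); i0 <- pmax(i0, 1L)
  fr <- u - i0
  i1 <- pmin(i0 + 1L, d)
  c000 <- field[i0[1], i0[2], i0[3]]; c100 <- field[i1[1], i0[2], i0[3]]
  c010 <- field[i0[1], i1[2], i0[3]]; c110 <- field[i1[1], i1[2], i0[3]]
  c001 <- field[i0[1], i0[2], i1[3]]; c101 <- field[i1[1], i0[2], i1[3]]
  c011 <- field[i0[1], i1[2], i1[3]]; c111 <- field[i1[1], i1[2], i1[3]]
  c00 <- c000 * (1 - fr[1]) + c100 * fr[1]
  c10 <- c010 * (1 - fr[1]) + c110 * fr[1]
  c01 <- c001 * (1 - fr[1]) + c101 * fr[1]
  c11 <- c011 * (1 - fr[1]) + c111 * fr[1]
  c0 <- c00 * (1 - fr[2]) + c10 * fr[2]
  c1 <- c01 * (1 - fr[2]) + c11 * fr[2]
  c0 * (1 - fr[3]) + c1 * fr[3]
}
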