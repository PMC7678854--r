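# Internal numerics shared across modules.

# FFT angular frequencies (rad/um) for an n-point grid of pitch dx,
# in the native unshifted FFT ordering.
fftAngularFreq <- function(n, dx) {
  2 * pi * c(0:(n / 2 - 1), -(n / 2):-1) / (n * dx)
}

# Evaluate an expression with a locally-set RNG seed; the caller's RNG
# state is restored afterwards. seed = NULL evaluates without seeding.
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

# Centered coordinates (um) of an n-sample grid of pitch d. Index
# floor(n/2)+1 sits at 0, matching the FFT origin convention.
centeredCoords <- function(n, d) {
  (seq_len(n) - (floor(n / 2) + 1)) * d
}

# 3D circular convolution via FFT. kernel is zero-embedded at the array
# origin with its centre voxel (floor(dim/2)+1) wrapped to index 1, so a
# centred delta kernel is the identity.
circularConvolve3 <- function(a, kernel) {
  d <- dim(a)
  stopifnot(all(dim(kernel) <= d))
  kpad <- array(0, d)
  kd <- dim(kernel)
  kc <- floor(kd / 2) + 1L
  # indices of the kernel relative to its centre, wrapped into a
  idx <- lapply(1:3, function(i) ((seq_len(kd[i]) - kc[i]) %% d[i]) + 1L)
  kpad[idx[[1]], idx[[2]], idx[[3]]] <- kernel
  re <- Re(fft(fft(a) * fft(kpad), inverse = TRUE)) / prod(d)
  re
}

# Smallest highly-composite (2,3,5-smooth) integer >= n, for fast FFTs.
goodFFTSize <- function(n) {
  vapply(n, function(x) as.integer(stats::nextn(x, c(2, 3, 5))), integer(1))
}

# Linear (zero-padded) convolution of a 3D array with a centred kernel,
# returning an array of dim(a). Padding is rounded up to FFT-friendly
# sizes.
linearConvolve3 <- function(a, kernel) {
  d <- dim(a)
  kd <- dim(kernel)
  half <- floor(kd / 2)
  dp <- goodFFTSize(d + 2L * half)
  ap <- array(0, dp)
  ap[half[1] + seq_len(d[1]), half[2] + seq_len(d[2]),
     half[3] + seq_len(d[3])] <- a
  out <- circularConvolve3(ap, kernel)
  out[half[1] + seq_len(d[1]), half[2] + seq_len(d[2]),
      half[3] + seq_len(d[3])]
}

# Reflectively pad a 3D array by `lo`/`hi` voxels per axis (hi defaults
# to lo). Mirror indices are clamped for pads larger than the array.
reflectPad3 <- function(a, lo, hi = lo) {
  d <- dim(a)
  ix <- lapply(1:3, function(i) {
    n <- d[i]
    pre <- if (lo[i] > 0) pmin(pmax(rev(seq_len(lo[i])), 1L), n)
           else integer()
    post <- if (hi[i] > 0) pmax(pmin(n - seq_len(hi[i]) + 1L, n), 1L)
            else integer()
    c(pre, seq_len(n), post)
  })
  a[ix[[1]], ix[[2]], ix[[3]], drop = FALSE]
}

# Quadratic (three-point) refinement of a discrete peak. Returns the
# sub-sample offset (in samples, in [-0.5, 0.5]) and the refined height.
refinePeak <- function(ym1, y0, yp1) {
  den <- ym1 - 2 * y0 + yp1
  if (!is.finite(den) || den >= 0) return(c(offset = 0, height = y0))
  off <- 0.5 * (ym1 - yp1) / den
  off <- max(-0.5, min(0.5, off))
  h <- y0 - 0.25 * (ym1 - yp1) * off
  c(offset = off, height = h)
}

# Linear interpolation of the crossing position of `level` between
# samples (x1,y1) and (x2,y2).
crossingPosition <- function(x1, y1, x2, y2, level) {
  if (y2 == y1) return((x1 + x2) / 2)
  x1 + (x2 - x1) * (level - y1) / (y2 - y1)
}

stopIfNot3D <- function(stack) {
  if (!is(stack, "ImageStack3D"))
    stop("expected an ImageStack3D", call. = FALSE)
}
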