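# Internal numeric helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stopIfNot <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)

nextPow2 <- function(n) 2L^ceiling(log2(max(2, n)))

# Derive reproducible child seeds (< 2^31) from one master seed.
deriveSeeds <- function(seed, n) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
    globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

# Linear convolution of x with kernel h via FFT, returning the "full"
# convolution of length length(x) + length(h) - 1.
fftConvolve <- function(x, h) {
  n <- length(x) + length(h) - 1L
  N <- nextPow2(n)
  y <- Re(stats::fft(stats::fft(c(x, rep(0, N - length(x)))) *
                     stats::fft(c(h, rep(0, N - length(h)))),
                     inverse = TRUE)) / N
  y[seq_len(n)]
}

# Sliding-window sums of x over windows of length m (valid lags only).
slidingSum <- function(x, m) {
  cs <- cumsum(c(0, x))
  cs[(m + 1):length(cs)] - cs[1:(length(cs) - m)]
}

# Sliding dot products sum_i x[k+i-1] * e[i] for all valid lags k.
slidingDot <- function(x, e) {
  full <- fftConvolve(x, rev(e))
  m <- length(e)
  full[m:(length(x))]
}

# Zero-phase FIR filtering: equivalent to applying the (linear-phase) FIR
# kernel h forward and then backward, i.e. convolving with the
# autocorrelation of h, so the net filter has |H(f)|^2 response and zero
# phase. Implemented in one FFT pass with reflection padding at the ends.
zeroPhaseFir <- function(x, h) {
  n <- length(x)
  L <- length(h)
  stopIfNot(n >= 3L * L,
            "signal shorter than 3x the filter length; cannot filter")
  pad <- min(n - 1L, 3L * L)
  xe <- c(2 * x[1] - rev(x[2:(pad + 1)]), x,
          2 * x[n] - rev(x[(n - pad):(n - 1)]))
  M <- length(xe)
  N <- nextPow2(M + 2L * L)
  H <- stats::fft(c(h, rep(0, N - L)))
  X <- stats::fft(c(xe, rep(0, N - M)))
  y <- Re(stats::fft(X * H * Conj(H), inverse = TRUE)) / N
  # H * Conj(H) is the DFT of the circular autocorrelation of h, whose
  # zero-lag tap sits at index 1: the output is already aligned with xe
  # (negative lags wrap into the zero padding).
  y[(pad + 1):(pad + n)]
}

# Perimeter of a closed polygon given as an n x 2 vertex matrix.
polygonPerimeter <- function(p) {
  q <- rbind(p, p[1, , drop = FALSE])
  sum(sqrt(rowSums(diff(q)^2)))
}

# Signed Euclidean distance from points (px, py) to a closed polygon
# boundary: negative inside, positive outside.
signedDistanceToPolygon <- function(px, py, poly) {
  nv <- nrow(poly)
  ax <- poly[, 1]; ay <- poly[, 2]
  bx <- c(ax[-1], ax[1]); by <- c(ay[-1], ay[1])
  d2 <- rep(Inf, length(px))
  for (i in seq_len(nv)) {
    vx <- bx[i] - ax[i]; vy <- by[i] - ay[i]
    len2 <- vx * vx + vy * vy
    t <- if (len2 == 0) rep(0, length(px)) else
      pmin(1, pmax(0, ((px - ax[i]) * vx + (py - ay[i]) * vy) / len2))
    dx <- px - (ax[i] + t * vx); dy <- py - (ay[i] + t * vy)
    d2 <- pmin(d2, dx * dx + dy * dy)
  }
  inside <- pracma::inpolygon(px, py, ax, ay, boundary = TRUE)
  sqrt(d2) * ifelse(inside, -1, 1)
}

# Regular n-vertex polygon approximating a circle.
circlePolygon <- function(cx, cy, r, n = 96) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  cbind(cx + r * cos(th), cy + r * sin(th))
}
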