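#' Frequency-band specification for sliding-window power
#'
#' The conventional bands and windows: theta 4-12 Hz with 1 s windows and
#' 0.8 s overlap; beta 18-30 Hz with 1 s windows and 0.5 s overlap; gamma
#' (bounds not fixed by convention; 40-100 Hz used here) with 0.15 s
#' windows and 0.1 s overlap.
#'
#' @param name band name.
#' @param fLo,fHi band edges (Hz).
#' @param window,overlap sliding-window length and overlap (s).
#' @return A \code{BandSpec} list.
#' @export
BandSpec <- function(name, fLo, fHi, window, overlap) {
  stopIfNot(fLo > 0 && fHi > fLo, "need 0 < fLo < fHi")
  stopIfNot(overlap >= 0 && overlap < window,
            "need 0 <= overlap < window")
  structure(list(name = name, fLo = fLo, fHi = fHi, window = window,
                 overlap = overlap), class = "BandSpec")
}

#' @rdname BandSpec
#' @export
thetaBand <- function() BandSpec("theta", 4, 12, 1, 0.8)

#' @rdname BandSpec
#' @export
betaBand <- function() BandSpec("beta", 18, 30, 1, 0.5)

#' @rdname BandSpec
#' @export
gammaBand <- function() BandSpec("gamma", 40, 100, 0.15, 0.1)

#' Multitaper parameters
#'
#' @param timeBandwidth time-bandwidth product (TW).
#' @param nTapers number of Slepian tapers (K <= 2 TW - 1).
#' @return A \code{MultitaperParams} list.
#' @export
MultitaperParams <- function(timeBandwidth = 3, nTapers = 5) {
  stopIfNot(nTapers <= 2 * timeBandwidth - 1,
            "nTapers must be <= 2*timeBandwidth - 1")
  structure(list(timeBandwidth = timeBandwidth, nTapers = nTapers),
            class = "MultitaperParams")
}

# DPSS (Slepian) taper cache. Tapers are eigenvectors of the standard
# symmetric tridiagonal matrix (Percival & Walden); columns normalized to
# unit energy, sign fixed so each taper's leading lobe is positive.
.taperCache <- new.env(parent = emptyenv())

#' Discrete prolate spheroidal (Slepian) tapers
#'
#' @param n taper length (samples).
#' @param nw time-bandwidth product.
#' @param k number of tapers (<= 2 nw - 1).
#' @return n x k matrix; columns have unit energy.
#' @export
dpssTapers <- function(n, nw, k) {
  stopIfNot(k <= 2 * nw - 1, "k must be <= 2*nw - 1")
  stopIfNot(n >= 2 * k, "segment too short for the requested tapers")
  key <- paste(n, nw, k, sep = "_")
  hit <- .taperCache[[key]]
  if (!is.null(hit)) return(hit)
  w <- nw / n
  i <- 0:(n - 1)
  A <- matrix(0, n, n)
  diag(A) <- ((n - 1 - 2 * i) / 2)^2 * cos(2 * pi * w)
  off <- (1:(n - 1)) * (n - (1:(n - 1))) / 2
  A[cbind(1:(n - 1), 2:n)] <- off
  A[cbind(2:n, 1:(n - 1))] <- off
  ev <- eigen(A, symmetric = TRUE)
  V <- ev$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    V[, j] <- V[, j] / sqrt(sum(V[, j]^2))
    s <- sum(V[, j])
    if (abs(s) > 1e-10) { if (s < 0) V[, j] <- -V[, j] }
    else if (V[which.max(abs(V[, j]) > 1e-3), j] < 0) V[, j] <- -V[, j]
  }
  .taperCache[[key]] <- V
  V
}

#' Condition a raw LFP: band-limit and downsample to 1 kHz
#'
#' Two zero-phase FIR stages: an anti-alias low-pass at the upper band
#' edge applied at the raw rate before integer decimation to
#' \code{fsOut}, then a high-pass at the lower edge applied at the output
#' rate. Each stage is a windowed-sinc (Blackman) kernel applied
#' forward-backward, so the net response has zero phase.
#'
#' @param raw \linkS4class{LfpRecording} with fs >= 2 kHz and fs an
#'   integer multiple of \code{fsOut}.
#' @param fLo,fHi passband edges (Hz).
#' @param fsOut output rate (Hz).
#' @param hpKernelDur high-pass kernel duration (s); the signal must be
#'   at least 3 kernels long.
#' @return band-limited \linkS4class{LfpRecording} at \code{fsOut}.
#' @export
preprocessLfp <- function(raw, fLo = 0.7, fHi = 400, fsOut = 1000,
                          hpKernelDur = 6) {
  fs <- sampleRate(raw)
  stopIfNot(fs >= 2000, "raw sampling rate must be >= 2 kHz")
  stopIfNot(abs(fs / fsOut - round(fs / fsOut)) < 1e-9,
            "fs must be an integer multiple of fsOut")
  x <- samples(raw)
  dec <- as.integer(round(fs / fsOut))
  # anti-alias low-pass (Blackman windowed sinc), transition ~0.2*fHi
  ntap <- 2L * ceiling(5.5 * fs / (0.25 * fHi) / 2) + 1L
  lp <- signal::fir1(ntap - 1L, fHi / (fs / 2), type = "low",
                     window = signal::blackman(ntap))
  x <- zeroPhaseFir(x, lp)
  x <- x[seq(1, length(x), by = dec)]
  # high-pass at the output rate
  nhp <- 2L * floor(hpKernelDur * fsOut / 2) + 1L
  stopIfNot(length(x) >= 3L * nhp,
            "signal shorter than 3x the high-pass kernel")
  hp <- signal::fir1(nhp - 1L, fLo / (fsOut / 2), type = "high",
                     window = signal::blackman(nhp))
  x <- zeroPhaseFir(x, hp)
  LfpRecording(x, fs = fsOut, t0 = raw@t0,
               meta = c(raw@meta, list(preprocessed = TRUE)))
}

# One-sided multitaper eigenspectrum average for a windowed segment
# matrix (n x nwin). Returns list(freq, psd) with psd n/2+1 x nwin;
# sum(psd) * df equals the tapered-segment variance (Parseval).
mtPsdMatrix <- function(W, fs, mt) {
  n <- nrow(W)
  V <- dpssTapers(n, mt$timeBandwidth, mt$nTapers)
  nf <- floor(n / 2) + 1L
  acc <- matrix(0, nf, ncol(W))
  for (j in seq_len(mt$nTapers)) {
    F <- stats::mvfft(W * V[, j])
    P <- (Mod(F[seq_len(nf), , drop = FALSE])^2) / fs
    if (n %% 2 == 0) P[2:(nf - 1), ] <- 2 * P[2:(nf - 1), ] else
      P[2:nf, ] <- 2 * P[2:nf, ]
    acc <- acc + P
  }
  list(freq = (0:(nf - 1)) * fs / n, psd = acc / mt$nTapers)
}

#' Multitaper power spectral density of one segment
#'
#' Mean over Slepian-taper eigenspectra; one-sided, in uV^2/Hz, so that
#' the PSD integrated over frequency equals the signal variance.
#'
#' @param segment \linkS4class{LfpRecording} (or numeric vector with
#'   \code{fs} supplied).
#' @param mt \code{\link{MultitaperParams}}.
#' @param fs sampling rate, required when \code{segment} is numeric.
#' @return data.frame with \code{freq} (Hz) and \code{psd} (uV^2/Hz).
#' @export
multitaperPsd <- function(segment, mt = MultitaperParams(), fs = NULL) {
  if (is(segment, "LfpRecording")) {
    fs <- sampleRate(segment)
    x <- samples(segment)
  } else x <- as.numeric(segment)
  stopIfNot(!is.null(fs), "fs required for numeric input")
  stopIfNot(length(x) >= 2 * mt$nTapers,
            "segment must be at least 2*nTapers samples")
  r <- mtPsdMatrix(matrix(x, ncol = 1), fs, mt)
  data.frame(freq = r$freq, psd = r$psd[, 1])
}

# Sliding-window band power core: windows of winLen samples every hop
# samples; per-window one-sided multitaper PSD summed over [fLo, fHi]
# (power in uV^2: sum of psd * df). Chunked to bound memory.
slidingBandPower <- function(x, fs, winLen, hop, mt, fLo, fHi,
                             starts = NULL) {
  n <- length(x)
  if (is.null(starts)) starts <- seq(1L, n - winLen + 1L, by = hop)
  df <- fs / winLen
  nf <- floor(winLen / 2) + 1L
  fr <- (0:(nf - 1)) * df
  sel <- fr >= fLo & fr <= fHi
  stopIfNot(any(sel), "band contains no frequency bins")
  out <- numeric(length(starts))
  chunk <- max(1L, floor(2e6 / winLen))
  for (b in seq(1, length(starts), by = chunk)) {
    ii <- b:min(length(starts), b + chunk - 1L)
    idx <- outer(0:(winLen - 1L), starts[ii], `+`)
    W <- matrix(x[idx], nrow = winLen)
    r <- mtPsdMatrix(W, fs, mt)
    out[ii] <- colSums(r$psd[sel, , drop = FALSE]) * df
  }
  list(starts = starts, power = out)
}

#' Sliding-window band power time course
#'
#' Multitaper PSD in sliding windows of \code{band$window} seconds with
#' \code{band$overlap} overlap, summed across the band.
#'
#' @param lfp preprocessed \linkS4class{LfpRecording}.
#' @param band \code{\link{BandSpec}}.
#' @param mt \code{\link{MultitaperParams}}.
#' @param hop optional hop (s) overriding \code{window - overlap} (used
#'   for fine-grained event-triggered power).
#' @return data.frame with \code{t} (window centers, s) and \code{power}
#'   (uV^2).
#' @export
bandPowerTimecourse <- function(lfp, band = betaBand(),
                                mt = MultitaperParams(), hop = NULL) {
  fs <- sampleRate(lfp)
  stopIfNot(band$fHi < fs / 2, "band extends above Nyquist")
  winLen <- round(band$window * fs)
  hopLen <- max(1L, round((hop %||% (band$window - band$overlap)) * fs))
  x <- samples(lfp)
  stopIfNot(length(x) >= winLen, "signal shorter than one window")
  r <- slidingBandPower(x, fs, winLen, hopLen, mt, band$fLo, band$fHi)
  data.frame(t = lfp@t0 + (r$starts - 1 + winLen / 2) / fs,
             power = r$power)
}

#' Morlet wavelet spectrogram
#'
#' Complex Morlet wavelets at \code{nFreq} log-spaced center frequencies
#' spanning \code{fLim}, each \code{nCycles} cycles long (Gaussian
#' envelope SD = nCycles / (2 pi f), truncated at 5 SD).
#'
#' @param lfp \linkS4class{LfpRecording} with fs >= 2 * max frequency.
#' @param fLim frequency span (Hz).
#' @param nFreq number of center frequencies.
#' @param nCycles wavelet length in cycles.
#' @param tDecim integer time-decimation factor for the output.
#' @return list with \code{t}, \code{freq} (length \code{nFreq}) and
#'   \code{power} (nFreq x time matrix, uV^2).
#' @export
morletSpectrogram <- function(lfp, fLim = c(1, 120), nFreq = 40,
                              nCycles = 10, tDecim = 1L) {
  fs <- sampleRate(lfp)
  stopIfNot(fs >= 2 * fLim[2], "sampling rate below 2x the top frequency")
  x <- samples(lfp)
  freqs <- exp(seq(log(fLim[1]), log(fLim[2]), length.out = nFreq))
  # support of the slowest wavelet
  sd0 <- nCycles / (2 * pi * freqs[1])
  stopIfNot(length(x) / fs >= 2 * 5 * sd0,
            "signal shorter than the lowest-frequency wavelet support")
  keep <- seq(1, length(x), by = tDecim)
  P <- matrix(0, nFreq, length(keep))
  for (i in seq_len(nFreq)) {
    sdT <- nCycles / (2 * pi * freqs[i])
    half <- ceiling(5 * sdT * fs)
    tt <- (-half:half) / fs
    wav <- exp(-tt^2 / (2 * sdT^2)) * exp(2i * pi * freqs[i] * tt)
    wav <- wav / sum(abs(wav))
    re <- fftConvolve(x, Re(wav))
    im <- fftConvolve(x, Im(wav))
    mid <- (half + 1):(half + length(x))
    P[i, ] <- (re[mid][keep]^2 + im[mid][keep]^2)
  }
  list(t = lfp@t0 + (keep - 1) / fs, freq = freqs, power = P)
}
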