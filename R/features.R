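# Front-end feature extraction: spike-count smoothing, raw-LFP band
# limiting, and LFP band log-powers. All three paths produce series on a
# common 50-ms time base so they can be modeled interchangeably; feature
# extraction is deterministic.

#' Bin and smooth spike counts
#'
#' Spike counts in nonoverlapping 10-ms bins are smoothed with a Gaussian
#' kernel (sd 50 ms, truncated at 4 sd, weights normalized to sum to one)
#' and downsampled to a 50-ms step by keeping every (out_step/bin)-th
#' sample.
#'
#' @param counts (T_raw x channels) nonnegative spike counts at `bin` ms
#' @param bin raw bin width in ms (default 10)
#' @param sigma Gaussian kernel standard deviation in ms (default 50)
#' @param out_step output step in ms (default 50); must be a multiple of
#'   `bin`
#' @return (T x channels) smoothed, downsampled series
#' @export
bin_and_smooth_spikes <- function(counts, bin = 10, sigma = 50,
                                  out_step = 50) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("spike counts must be nonnegative")
  if (out_step %% bin != 0) stop("bin must divide out_step")
  half <- ceiling(4 * sigma / bin)
  tt <- (-half:half) * bin
  kern <- exp(-tt^2 / (2 * sigma^2))
  kern <- kern / sum(kern)
  sm <- apply(counts, 2, function(v) {
    vp <- c(numeric(half), v, numeric(half))  # zero counts outside recording
    stats::filter(vp, kern, method = "convolution",
                  sides = 2)[(half + 1):(half + length(v))]
  })
  step <- out_step %/% bin
  idx <- seq(step, nrow(counts), by = step)
  out <- sm[idx, , drop = FALSE]
  out
}

#' Band-limited raw LFP feature at 20 Hz
#'
#' High-pass filters the signal above 0.5 Hz (baseline removal), low-pass
#' filters below 10 Hz (antialiasing), both zero-phase (forward-backward
#' Butterworth), then resamples to the 50-ms (20 Hz) behavior time base.
#' The zero-phase filtering is noncausal within this preprocessing stage
#' only.
#'
#' @param lfp (T_raw x channels) signal at sampling rate `fs`
#' @param fs sampling rate in Hz (> 20)
#' @return (T x channels) series at 20 Hz
#' @export
raw_lfp_feature <- function(lfp, fs) {
  if (fs <= 20) stop("sampling rate must exceed the 20 Hz target rate")
  lfp <- as.matrix(lfp)
  hp <- signal::butter(2, 0.5 / (fs / 2), type = "high")
  lp <- signal::butter(4, 10 / (fs / 2), type = "low")
  filt <- apply(lfp, 2, function(v) {
    v <- signal::filtfilt(hp, v)
    signal::filtfilt(lp, v)
  })
  t_raw <- (seq_len(nrow(lfp)) - 1) / fs
  t_out <- seq(0, max(t_raw), by = 1 / 20)
  out <- apply(filt, 2, function(v) stats::approx(t_raw, v, t_out)$y)
  matrix(out, length(t_out), ncol(lfp))
}

#' @keywords internal
lfp_bands <- function() {
  data.frame(
    band = c("delta", "theta", "alpha", "low_beta", "mid_beta",
             "high_beta", "low_gamma", "high_gamma"),
    lo = c(0.1, 4, 8, 12, 24, 34, 65, 130),
    hi = c(4, 8, 12, 24, 34, 55, 95, 170)
  )
}

#' @keywords internal
welch_psd <- function(v, fs, n_sub = 8, overlap = 0.5) {
  # Welch's method: n_sub half-overlapping Hann subwindows, zero-padded
  # FFT for a finer frequency grid
  N <- length(v)
  sub <- floor(N / (1 + (n_sub - 1) * (1 - overlap)))
  step <- floor(sub * (1 - overlap))
  starts <- seq(1, N - sub + 1, by = max(step, 1))
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(sub) / (sub + 1))
  nfft <- max(256, 2^ceiling(log2(sub)))
  acc <- numeric(nfft %/% 2 + 1)
  for (s in starts) {
    seg <- v[s:(s + sub - 1)] * w
    sp <- stats::fft(c(seg, numeric(nfft - sub)))
    pxx <- Mod(sp[1:(nfft %/% 2 + 1)])^2 / (fs * sum(w^2))
    acc <- acc + pxx
  }
  list(freq = (0:(nfft %/% 2)) * fs / nfft, psd = acc / length(starts))
}

#' LFP band log-powers on the 50-ms time base
#'
#' For every output step, a 300-ms window of signal ending at that step
#' (causal alignment) is analyzed with Welch's method (eight
#' half-overlapping subwindows); the log of the mean power within each of
#' the eight standard bands (delta 0.1-4, theta 4-8, alpha 8-12, low beta
#' 12-24, mid beta 24-34, high beta 34-55, low gamma 65-95, high gamma
#' 130-170 Hz) is the feature. Bands containing no spectral bin fall back
#' to the power interpolated at the band center.
#'
#' @param lfp (T_raw x channels) signal at sampling rate `fs`
#' @param fs sampling rate in Hz (>= 340 so the high-gamma band is
#'   resolvable)
#' @param window window length in ms (default 300)
#' @param step output step in ms (default 50)
#' @return (T x 8*channels) matrix; columns ordered channel-major
#'   (channel 1's eight bands, then channel 2's, ...)
#' @export
lfp_band_log_powers <- function(lfp, fs, window = 300, step = 50) {
  if (fs < 2 * 170) stop("sampling rate too low to resolve the high-gamma band")
  lfp <- as.matrix(lfp)
  wlen <- round(window / 1000 * fs)
  slen <- round(step / 1000 * fs)
  if (wlen > nrow(lfp)) stop("analysis window exceeds the data length")
  bands <- lfp_bands()
  ends <- seq(wlen, nrow(lfp), by = slen)
  out <- matrix(NA_real_, length(ends), 8 * ncol(lfp))
  for (ch in seq_len(ncol(lfp))) {
    for (i in seq_along(ends)) {
      seg <- lfp[(ends[i] - wlen + 1):ends[i], ch]
      ps <- welch_psd(seg, fs)
      bp <- vapply(seq_len(nrow(bands)), function(b) {
        inb <- ps$freq >= bands$lo[b] & ps$freq <= bands$hi[b]
        if (any(inb)) mean(ps$psd[inb])
        else stats::approx(ps$freq, ps$psd,
                           (bands$lo[b] + bands$hi[b]) / 2)$y
      }, numeric(1))
      out[i, (ch - 1) * 8 + seq_len(8)] <- log(pmax(bp, 1e-300))
    }
  }
  colnames(out) <- as.vector(outer(bands$band, seq_len(ncol(lfp)),
                                   function(b, c_) paste0("ch", c_, "_", b)))
  out
}
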