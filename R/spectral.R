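#' Welch power spectral density per channel
#'
#' Averaged modified periodogram: the signal is cut into `seg_s`-second
#' segments with 50% overlap, Hann-tapered, and the window-power-corrected
#' periodograms are averaged. The estimate is interpolated onto the
#' requested frequency grid. With the window correction, total power over
#' the full grid matches the time-domain variance (Parseval) for broadband
#' signals.
#'
#' @param rec An [eeg_recording()], or a channels x samples matrix (then
#'   `fs` must be given).
#' @param grid Frequencies (Hz) at which the PSD is returned; default 1-45
#'   Hz on 1-Hz bins, the honest range for a 0.1-45 Hz filtered recording.
#' @param seg_s Segment length in seconds (default 2).
#' @param overlap Fractional overlap between segments (default 0.5).
#' @param fs Sampling rate, only needed when `rec` is a bare matrix.
#' @return Channels x frequencies matrix of PSD values (uV^2/Hz) with the
#'   grid stored in `attr(, "grid")`.
#' @export
power_spectrum <- function(rec, grid = 1:45, seg_s = 2, overlap = 0.5, fs = NULL) {
  if (inherits(rec, "eeg_recording")) {
    x <- rec$data
    fs <- rec$fs
  } else {
    x <- as.matrix(rec)
    if (is.null(fs)) pg_stop("fs is required for matrix input", "pg_spectrum_error")
  }
  if (ncol(x) == 0) pg_stop("empty signal", "pg_spectrum_error")
  if (max(grid) > fs / 2) pg_stop("grid exceeds Nyquist", "pg_spectrum_error")
  nseg <- round(seg_s * fs)
  nseg <- min(nseg, ncol(x))
  step <- max(1L, round(nseg * (1 - overlap)))
  starts <- seq(1L, ncol(x) - nseg + 1L, by = step)
  w <- 0.5 * (1 - cos(2 * pi * seq(0, nseg - 1) / (nseg - 1)))  # Hann
  u <- sum(w^2)                                                 # window power
  n_half <- nseg %/% 2L
  freqs <- (0:n_half) * fs / nseg
  acc <- matrix(0, nrow(x), n_half + 1L)
  for (s in starts) {
    seg <- x[, s:(s + nseg - 1L), drop = FALSE]
    seg <- seg - rowMeans(seg)
    SF <- stats::mvfft(t(seg * rep(w, each = nrow(seg))))
    pgram <- (Mod(SF[1:(n_half + 1L), , drop = FALSE])^2) / (fs * u)
    # one-sided: double everything except DC (and Nyquist for even nseg)
    sc <- rep(2, n_half + 1L)
    sc[1] <- 1
    if (nseg %% 2L == 0L) sc[n_half + 1L] <- 1
    acc <- acc + t(pgram * sc)
  }
  psd <- acc / length(starts)
  out <- t(apply(psd, 1, function(p) {
    stats::approx(freqs, p, xout = grid, rule = 2)$y
  }))
  out[out < 0] <- 0
  rownames(out) <- rownames(x)
  attr(out, "grid") <- grid
  attr(out, "fs") <- fs
  out
}

#' Power-weighted mean frequency
#'
#' `MF = sum(P(f) * f) / sum(P(f))` over the evaluation grid: the centroid
#' of the power spectrum. Invariant to uniform amplitude scaling of the
#' signal.
#'
#' @param p PSD values (vector, or channels x frequencies matrix as from
#'   [power_spectrum()], which is first averaged over channels).
#' @param grid Frequency grid in Hz (defaults to `attr(p, "grid")`).
#' @return Mean frequency in Hz.
#' @export
mean_frequency <- function(p, grid = attr(p, "grid")) {
  force(grid)
  if (is.matrix(p)) p <- colMeans(p)
  if (is.null(grid)) pg_stop("a frequency grid is required", "pg_spectrum_error")
  tot <- sum(p)
  if (!(tot > 0)) pg_stop("zero total power; mean frequency undefined",
                          "pg_spectrum_error")
  sum(p * grid) / tot
}

#' Frontal laterality index
#'
#' `LI = (P_left - P_right) / (P_left + P_right)` where `P_left` is the
#' average power of the left frontal electrodes (Fp1, F3, F7) and
#' `P_right` of the right frontal electrodes (Fp2, F4, F8), integrated
#' over the evaluation grid. LI lies in `[-1, 1]`, is 0 for symmetric
#' frontal power and negates under a left/right swap.
#'
#' @param psd Channels x frequencies matrix from [power_spectrum()], with
#'   electrode rownames.
#' @param left,right Electrode label sets (defaults [frontal_left()] /
#'   [frontal_right()]).
#' @return List with `li`, `p_left`, `p_right`.
#' @export
laterality_index <- function(psd, left = frontal_left(), right = frontal_right()) {
  missing <- setdiff(c(left, right), rownames(psd))
  if (length(missing) > 0) {
    pg_stop(sprintf("missing frontal electrode(s): %s",
                    paste(missing, collapse = ", ")), "pg_spectrum_error")
  }
  p_left <- mean(rowSums(psd[left, , drop = FALSE]))
  p_right <- mean(rowSums(psd[right, , drop = FALSE]))
  denom <- p_left + p_right
  li <- if (denom > 0) (p_left - p_right) / denom else NA_real_
  list(li = li, p_left = p_left, p_right = p_right)
}

#' Spectral summary table for one subject
#'
#' Mean frequency and frontal laterality index, broadband (grid range) and
#' per band, as one tidy row per band.
#'
#' @param rec An [eeg_recording()].
#' @param bands Band table as from [eeg_bands()].
#' @param grid Frequency grid for the underlying PSD.
#' @return data.frame with columns `subject_id`, `band`, `mf_hz`, `li`,
#'   `p_left`, `p_right`.
#' @export
spectral_summary <- function(rec, bands = eeg_bands(), grid = 1:45) {
  psd <- power_spectrum(rec, grid = grid)
  rows <- lapply(c("broadband", bands$name), function(bn) {
    if (bn == "broadband") {
      sub <- psd
      g <- grid
    } else {
      b <- band_spec(bn, bands)
      keep <- grid >= b$f_lo & grid <= b$f_hi
      sub <- psd[, keep, drop = FALSE]
      g <- grid[keep]
    }
    attr(sub, "grid") <- g
    lat <- laterality_index(sub)
    data.frame(subject_id = rec$subject_id, band = bn,
               mf_hz = mean_frequency(sub, g), li = lat$li,
               p_left = lat$p_left, p_right = lat$p_right,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
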