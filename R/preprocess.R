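#' Construct an EEG recording object
#'
#' Container for a multichannel scalp EEG recording: a channels x samples
#' matrix in microvolts, its sampling rate and ordered electrode labels.
#'
#' @param data Numeric matrix, channels x samples (uV).
#' @param fs Sampling rate in Hz.
#' @param labels Character vector of electrode names, one per row of `data`.
#' @param subject_id Opaque subject identifier.
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, fs, labels, subject_id = "") {
  data <- as.matrix(data)
  if (!is.numeric(data) || any(!is.finite(data))) {
    pg_stop("recording data must be a finite numeric matrix", "pg_recording_error")
  }
  if (length(fs) != 1 || !is.finite(fs) || fs <= 0) {
    pg_stop("fs must be a single positive number", "pg_recording_error")
  }
  if (length(labels) != nrow(data)) {
    pg_stop("one label per channel is required", "pg_recording_error")
  }
  if (anyDuplicated(labels)) {
    pg_stop("electrode labels must be unique", "pg_recording_error")
  }
  rownames(data) <- labels
  structure(
    list(data = data, fs = fs, labels = as.character(labels),
         subject_id = as.character(subject_id)),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz (%.1f s)%s\n",
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs,
              if (nzchar(x$subject_id)) paste0(" [", x$subject_id, "]") else ""))
  invisible(x)
}

#' Re-reference a recording to the common average
#'
#' Subtracts the instantaneous mean across all channels from every channel,
#' so that at each sample the montage average is zero. Average referencing
#' removes the contribution of the original reference electrode and any
#' common-mode activity before connectivity estimation.
#'
#' @param rec An [eeg_recording()].
#' @return The re-referenced `eeg_recording`.
#' @export
average_reference <- function(rec) {
  if (nrow(rec$data) < 2) {
    pg_stop("average reference needs at least 2 channels", "pg_reference_error")
  }
  rec$data <- sweep(rec$data, 2, colMeans(rec$data))
  rec
}

#' Design a band-pass FIR filter
#'
#' Windowed-sinc (Hamming) linear-phase band-pass design. The transition
#' width defaults to `max(1, 0.25 * f_lo)` Hz and the number of taps follows
#' the standard Hamming rule `3.3 * fs / transition` (rounded up to an odd
#' count), giving roughly 53 dB stop-band attenuation one transition width
#' beyond the band edges.
#'
#' @param f_lo,f_hi Band edges in Hz.
#' @param fs Sampling rate in Hz.
#' @param transition Transition width in Hz (default `max(1, 0.25 * f_lo)`).
#' @param n_taps Optional explicit (odd) tap count overriding the rule.
#' @return Numeric vector of FIR coefficients (odd length, symmetric).
#' @export
design_bandpass_fir <- function(f_lo, f_hi, fs, transition = NULL, n_taps = NULL) {
  if (!(f_lo > 0 && f_lo < f_hi)) {
    pg_stop("band edges must satisfy 0 < f_lo < f_hi", "pg_filter_error")
  }
  if (f_hi >= fs / 2) {
    pg_stop(sprintf("upper band edge %g Hz is at or above Nyquist (%g Hz)",
                    f_hi, fs / 2), "pg_filter_error")
  }
  if (is.null(transition)) transition <- max(1, 0.25 * f_lo)
  if (is.null(n_taps)) {
    order <- ceiling(3.3 * fs / transition)
    if (order %% 2L == 1L) order <- order + 1L
  } else {
    if (n_taps %% 2L != 1L) pg_stop("n_taps must be odd", "pg_filter_error")
    order <- n_taps - 1L
  }
  signal::fir1(order, c(f_lo, f_hi) / (fs / 2), type = "pass")
}

#' Band-pass filter a recording
#'
#' Applies the windowed-sinc FIR of [design_bandpass_fir()] with zero net
#' phase shift (linear-phase kernel, group delay compensated), so that
#' downstream phase estimates are not biased by filter delay.
#'
#' @inheritParams design_bandpass_fir
#' @param rec An [eeg_recording()].
#' @return The filtered `eeg_recording`.
#' @export
bandpass_fir <- function(rec, f_lo, f_hi, transition = NULL, n_taps = NULL) {
  b <- design_bandpass_fir(f_lo, f_hi, rec$fs, transition, n_taps)
  rec$data <- fir_zerophase_mat(rec$data, b)
  rownames(rec$data) <- rec$labels
  rec
}

#' Band-decompose and epoch a recording
#'
#' Applies the broadband filter (default 0.1-45 Hz), then for each requested
#' band filters the continuous recording and cuts the first `total_s`
#' seconds into non-overlapping epochs. Filtering precedes epoching so that
#' filter transients fall only at the recording boundaries, not inside every
#' epoch.
#'
#' @param rec An [eeg_recording()].
#' @param bands A band table as from [eeg_bands()]; rows named by `name`.
#' @param epoch_length_s Epoch length in seconds (default 10, i.e. 9 epochs
#'   per 90-s recording). Set to `total_s` for a single epoch.
#' @param total_s Total analyzed duration in seconds (default 90).
#' @param broadband Two-element numeric, the broadband pre-filter edges in
#'   Hz, or `NULL` to skip it.
#' @return An `eeg_epochs` object: per-band arrays of dimension
#'   epochs x channels x samples, plus sampling metadata.
#' @export
make_epochs <- function(rec, bands = eeg_bands(), epoch_length_s = 10,
                        total_s = 90, broadband = c(0.1, 45)) {
  n_total <- round(total_s * rec$fs)
  if (ncol(rec$data) < n_total) {
    pg_stop(sprintf("recording is %.1f s but %g s were requested",
                    ncol(rec$data) / rec$fs, total_s), "pg_epoch_error")
  }
  if (epoch_length_s <= 0 || epoch_length_s > total_s) {
    pg_stop("epoch_length_s must be in (0, total_s]", "pg_epoch_error")
  }
  n_epochs <- floor(total_s / epoch_length_s)
  n_per <- round(epoch_length_s * rec$fs)
  if (!is.null(broadband)) {
    rec <- bandpass_fir(rec, broadband[1], broadband[2])
  }
  out <- vector("list", nrow(bands))
  names(out) <- bands$name
  for (k in seq_len(nrow(bands))) {
    filt <- bandpass_fir(rec, bands$f_lo[k], bands$f_hi[k])
    arr <- array(NA_real_, dim = c(n_epochs, nrow(rec$data), n_per))
    for (e in seq_len(n_epochs)) {
      arr[e, , ] <- filt$data[, ((e - 1L) * n_per + 1L):(e * n_per)]
    }
    out[[k]] <- arr
  }
  structure(
    list(data = out, bands = bands, fs = rec$fs, labels = rec$labels,
         epoch_length_s = epoch_length_s, total_s = total_s,
         subject_id = rec$subject_id),
    class = "eeg_epochs"
  )
}

#' @export
print.eeg_epochs <- function(x, ...) {
  d <- dim(x$data[[1]])
  cat(sprintf("<eeg_epochs> %d band(s) x %d epochs x %d channels x %d samples @ %g Hz\n",
              length(x$data), d[1], d[2], d[3], x$fs))
  invisible(x)
}

#' Zero selected components of an external unmixing
#'
#' Hook for manually curated artifact removal: given an unmixing matrix (for
#' example from an ICA performed elsewhere), reconstructs the recording with
#' the listed components zeroed. The package does not fit ICA itself;
#' component selection is a human-in-the-loop step.
#'
#' @param rec An [eeg_recording()].
#' @param unmixing Components x channels matrix `U` such that sources
#'   `S = U %*% data`.
#' @param drop Integer indices of components to zero.
#' @return The cleaned `eeg_recording`.
#' @export
remove_components <- function(rec, unmixing, drop) {
  U <- as.matrix(unmixing)
  if (ncol(U) != nrow(rec$data)) {
    pg_stop("unmixing must have one column per channel", "pg_ica_error")
  }
  S <- U %*% rec$data
  S[drop, ] <- 0
  rec$data <- solve(U) %*% S
  rownames(rec$data) <- rec$labels
  rec
}
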