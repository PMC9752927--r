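#' Instantaneous phase of band-limited signals
#'
#' Computes the analytic signal of each channel by the frequency-domain
#' (Hilbert) method and returns its phase angle. The first and last
#' `trim_s` seconds are discarded to remove analytic-transform edge
#' effects before any phase statistic is formed.
#'
#' @param x Channels x samples numeric matrix, already band-pass filtered.
#' @param fs Sampling rate in Hz.
#' @param trim_s Seconds trimmed from each end (default 0.5).
#' @return Channels x samples matrix of phases in `(-pi, pi]`.
#' @export
instantaneous_phase <- function(x, fs, trim_s = 0.5) {
  x <- as.matrix(x)
  rng <- apply(x, 1, function(r) max(r) - min(r))
  if (any(rng == 0)) {
    ch <- rownames(x)[which(rng == 0)[1]] %||% as.character(which(rng == 0)[1])
    pg_stop(sprintf("channel '%s' is constant; phase is undefined", ch),
            "pg_phase_error")
  }
  ph <- Arg(analytic_signal_mat(x))
  n_trim <- round(trim_s * fs)
  n <- ncol(ph)
  if (2 * n_trim >= n) {
    pg_stop("trim_s leaves no samples", "pg_phase_error")
  }
  keep <- (n_trim + 1L):(n - n_trim)
  ph <- ph[, keep, drop = FALSE]
  rownames(ph) <- rownames(x)
  ph
}

#' Phase lag index matrix of one epoch
#'
#' For every channel pair computes `PLI = |< sign(delta_phi) >|`: the
#' absolute time average of the sign of the wrapped instantaneous phase
#' difference. PLI is 0 for a symmetric phase-difference distribution
#' (including exactly zero lag, since `sign(0) = 0`) and 1 for a fixed
#' nonzero lag; it is insensitive to zero-lag (volume-conducted) coupling
#' by construction.
#'
#' @param phases Channels x samples matrix of phases (radians), as from
#'   [instantaneous_phase()].
#' @param labels Optional electrode labels (defaults to rownames).
#' @param band Optional band name carried in the result.
#' @return A `pli_matrix` object: symmetric `pli` matrix in `[0, 1]` with
#'   zero diagonal, plus `labels`, `band`, `n_epochs`.
#' @export
pli_matrix <- function(phases, labels = rownames(phases), band = NA_character_) {
  phases <- as.matrix(phases)
  n_ch <- nrow(phases)
  if (n_ch < 2) pg_stop("PLI needs at least 2 channels", "pg_pli_error")
  if (ncol(phases) < 100) {
    pg_stop("PLI needs at least 100 phase samples", "pg_pli_error")
  }
  if (is.null(labels)) labels <- paste0("ch", seq_len(n_ch))
  P <- matrix(0, n_ch, n_ch, dimnames = list(labels, labels))
  n_s <- ncol(phases)
  for (i in seq_len(n_ch - 1L)) {
    pi_row <- phases[i, ]
    for (j in (i + 1L):n_ch) {
      # raw difference lies in (-2*pi, 2*pi); the wrapped sign is positive
      # on (0, pi] and (-2*pi, -pi], negative elsewhere, zero only at 0.
      d <- pi_row - phases[j, ]
      n_pos <- sum((d > 0 & d <= pi) | d <= -pi)
      n_neg <- sum((d < 0 & d > -pi) | d > pi)
      v <- abs(n_pos - n_neg) / n_s
      P[i, j] <- v
      P[j, i] <- v
    }
  }
  structure(list(pli = P, labels = labels, band = band, n_epochs = 1L),
            class = "pli_matrix")
}

#' Average connectivity matrices over epochs
#'
#' Element-wise arithmetic mean of per-epoch PLI matrices; the number of
#' epochs averaged is recorded. Averaging preserves symmetry and the
#' `[0, 1]` range.
#'
#' @param cms List of `pli_matrix` objects with matching labels and band.
#' @return A single epoch-averaged `pli_matrix`.
#' @export
average_epochs <- function(cms) {
  if (length(cms) == 0) pg_stop("no matrices to average", "pg_pli_error")
  ref <- cms[[1]]
  for (cm in cms[-1]) {
    if (!identical(cm$labels, ref$labels) || !identical(cm$band, ref$band)) {
      pg_stop("labels/band mismatch across epochs", "pg_pli_error")
    }
  }
  P <- Reduce(`+`, lapply(cms, `[[`, "pli")) / length(cms)
  structure(list(pli = P, labels = ref$labels, band = ref$band,
                 n_epochs = sum(vapply(cms, `[[`, integer(1), "n_epochs"))),
            class = "pli_matrix")
}

#' Epoch-averaged PLI connectivity per band
#'
#' Runs phase extraction and PLI estimation on every epoch of every band of
#' an [make_epochs()] result and averages the per-epoch matrices.
#'
#' @param epochs An `eeg_epochs` object.
#' @param trim_s Seconds trimmed from each epoch end before the sign mean.
#' @return Named list of epoch-averaged `pli_matrix` objects, one per band.
#' @export
pli_connectivity <- function(epochs, trim_s = 0.5) {
  out <- vector("list", length(epochs$data))
  names(out) <- names(epochs$data)
  for (bn in names(epochs$data)) {
    arr <- epochs$data[[bn]]
    cms <- lapply(seq_len(dim(arr)[1]), function(e) {
      x <- arr[e, , ]
      rownames(x) <- epochs$labels
      pli_matrix(instantaneous_phase(x, epochs$fs, trim_s),
                 labels = epochs$labels, band = bn)
    })
    out[[bn]] <- average_epochs(cms)
  }
  out
}

#' @export
print.pli_matrix <- function(x, ...) {
  cat(sprintf("<pli_matrix> %d nodes, band %s, %d epoch(s), mean PLI %.3f\n",
              length(x$labels), x$band, x$n_epochs,
              mean(x$pli[upper.tri(x$pli)])))
  invisible(x)
}

#' Connectivity matrix as a long edge table
#'
#' @param cm A `pli_matrix`.
#' @return data.frame with columns `band`, `node_i`, `node_j`, `pli`.
#' @export
pli_edges <- function(cm) {
  idx <- which(upper.tri(cm$pli), arr.ind = TRUE)
  data.frame(
    band = cm$band,
    node_i = cm$labels[idx[, 1]],
    node_j = cm$labels[idx[, 2]],
    pli = cm$pli[idx],
    stringsAsFactors = FALSE
  )
}
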