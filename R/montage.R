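#' The 25-channel IFCN scalp montage
#'
#' Electrode labels of the IFCN 25-channel system: the conventional 10-20
#' array extended with the inferior temporal chain (F9/F10, T9/T10, P9/P10),
#' which raises the diagnostic yield for temporal-lobe pathology to that of
#' high-density recordings.
#'
#' @return Character vector of 25 electrode labels.
#' @export
ifcn_montage <- function() {
  c("Fp1", "Fp2", "F9", "F10", "T9", "T10", "P9", "P10",
    "F7", "F8", "T7", "T8", "P7", "P8",
    "F3", "F4", "C3", "C4", "P3", "P4",
    "O1", "O2", "Fz", "Cz", "Pz")
}

#' The 16-electrode frontotemporal node set
#'
#' Frontal and temporal electrodes (both hemispheres, including the inferior
#' chain) used to build the frontotemporal subnetwork in which theta-band
#' coupling changes concentrate in temporal lobe epilepsy.
#'
#' @return Character vector of 16 electrode labels.
#' @export
frontotemporal_set <- function() {
  c("Fp1", "Fp2", "F3", "F4", "F9", "F10", "T9", "T10",
    "P9", "P10", "F7", "F8", "T7", "T8", "P7", "P8")
}

#' Left and right frontal electrode sets
#'
#' Electrode triples used by the frontal laterality index.
#'
#' @return Character vector of 3 electrode labels.
#' @export
frontal_left <- function() c("Fp1", "F3", "F7")

#' @rdname frontal_left
#' @export
frontal_right <- function() c("Fp2", "F4", "F8")

# Hemispheric halves of the frontotemporal set, split into a frontal and a
# temporal group; these are the node sets the synthetic generator couples.
ft_left_frontal <- function() c("Fp1", "F3", "F7", "F9")
ft_left_temporal <- function() c("T7", "T9", "P7", "P9")
ft_right_frontal <- function() c("Fp2", "F4", "F8", "F10")
ft_right_temporal <- function() c("T8", "T10", "P8", "P10")

#' Standard EEG frequency bands
#'
#' The five analysis bands: delta (1-4 Hz), theta (4-7 Hz), alpha (8-13 Hz),
#' beta (14-30 Hz) and gamma (30-45 Hz). Band edges are as conventionally
#' printed; adjacent filters overlap through their transition bands, so the
#' bands are not a strict partition of the spectrum.
#'
#' @return A data.frame with columns `name`, `f_lo`, `f_hi` (Hz).
#' @export
eeg_bands <- function() {
  data.frame(
    name = c("delta", "theta", "alpha", "beta", "gamma"),
    f_lo = c(1, 4, 8, 14, 30),
    f_hi = c(4, 7, 13, 30, 45),
    stringsAsFactors = FALSE
  )
}

# Look up a single band row by name (bands table optional).
band_spec <- function(name, bands = eeg_bands()) {
  i <- match(name, bands$name)
  if (is.na(i)) pg_stop(sprintf("unknown band '%s'", name), "pg_band_error")
  bands[i, , drop = FALSE]
}

# Validate a vector of electrode labels against a montage.
check_labels <- function(labels, montage = ifcn_montage()) {
  bad <- setdiff(labels, montage)
  if (length(bad) > 0) {
    pg_stop(sprintf("unknown electrode label(s): %s", paste(bad, collapse = ", ")),
            "pg_label_error")
  }
  invisible(labels)
}
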