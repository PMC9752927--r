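# Synthetic coupled-oscillator EEG. All generative choices here are
# stand-ins for real scalp EEG: real recordings contain artifacts, volume
# conduction, nonstationarity and spatially structured background that this
# model does not attempt to reproduce.

#' Background channel model for synthetic EEG
#'
#' Each channel is a sum of band-limited Gaussian components (white noise
#' band-pass filtered at the component band, so phase estimation faces
#' realistic jitter rather than the trivial constant phase of a sinusoid)
#' plus 1/f^a noise. Amplitudes are standard deviations in arbitrary units;
#' every generated component is normalized to its exact target SD, so the
#' per-channel variance equals the sum of squared amplitudes.
#'
#' @param band_components data.frame with columns `center_freq` (Hz, in
#'   (0, 45]), `bandwidth` (Hz, > 0), `amplitude` (SD, >= 0). Default: a
#'   single alpha component at 10 Hz, bandwidth 2 Hz, amplitude 1.
#' @param noise_exponent Spectral slope a of the 1/f^a noise (default 1).
#' @param noise_amplitude SD of the 1/f noise component (default 1).
#' @return A `sim_channel_model` list.
#' @export
sim_channel_model <- function(band_components = data.frame(center_freq = 10,
                                                           bandwidth = 2,
                                                           amplitude = 1),
                              noise_exponent = 1, noise_amplitude = 1) {
  bc <- band_components
  if (nrow(bc) > 0) {
    if (any(bc$center_freq <= 0 | bc$center_freq > 45)) {
      pg_stop("component center frequencies must lie in (0, 45] Hz", "pg_sim_error")
    }
    if (any(bc$bandwidth <= 0)) pg_stop("bandwidths must be > 0", "pg_sim_error")
    if (any(bc$amplitude < 0)) pg_stop("amplitudes must be >= 0", "pg_sim_error")
  }
  if (noise_amplitude < 0) pg_stop("noise_amplitude must be >= 0", "pg_sim_error")
  structure(list(band_components = bc, noise_exponent = noise_exponent,
                 noise_amplitude = noise_amplitude),
            class = "sim_channel_model")
}

#' Phase-coupling specification between two electrode sets
#'
#' A shared band-limited oscillator is injected into both node sets; the
#' copy received by `node_set_b` is time-shifted by
#' `phase_lag / (2 pi f_center)` seconds, producing a constant nonzero
#' phase lag between the sets. `strength` is the fraction of channel
#' variance contributed by the shared oscillator.
#'
#' Note that channels within the same set receive identical copies (zero
#' lag), so within-set PLI stays near 0 by the sign convention -- only
#' cross-set pairs acquire high PLI. A zero `phase_lag` yields PLI 0 even
#' between the sets.
#'
#' @param node_set_a,node_set_b Electrode label vectors (montage labels).
#' @param band Band name (resolved via [eeg_bands()]) or `NULL` if `f_lo`,
#'   `f_hi` given explicitly.
#' @param f_lo,f_hi Explicit oscillator band edges in Hz (override `band`).
#' @param phase_lag Constant lag in radians, in `(-pi, pi]` (default pi/4).
#' @param strength Variance fraction in `[0, 1]`.
#' @return A `sim_coupling` list.
#' @export
sim_coupling <- function(node_set_a, node_set_b, band = "theta",
                         f_lo = NULL, f_hi = NULL,
                         phase_lag = pi / 4, strength = 0.5) {
  if (is.null(f_lo) || is.null(f_hi)) {
    b <- band_spec(band)
    f_lo <- b$f_lo
    f_hi <- b$f_hi
  }
  if (strength < 0 || strength > 1) {
    pg_stop("coupling strength must lie in [0, 1]", "pg_sim_error")
  }
  if (phase_lag <= -pi || phase_lag > pi) {
    pg_stop("phase_lag must lie in (-pi, pi]", "pg_sim_error")
  }
  if (length(intersect(node_set_a, node_set_b)) > 0) {
    pg_stop("coupled node sets must be disjoint", "pg_sim_error")
  }
  structure(list(node_set_a = node_set_a, node_set_b = node_set_b,
                 band = band %||% NA_character_, f_lo = f_lo, f_hi = f_hi,
                 phase_lag = phase_lag, strength = strength),
            class = "sim_coupling")
}

# Band-limited unit-SD Gaussian noise, rows = channels.
band_noise_mat <- function(n_ch, n, f_lo, f_hi, fs) {
  X <- matrix(stats::rnorm(n_ch * n), n_ch, n)
  b <- design_bandpass_fir(f_lo, f_hi, fs)
  Y <- fir_zerophase_mat(X, b)
  Y / apply(Y, 1, stats::sd)
}

# 1/f^a unit-SD noise via spectral shaping; flat below f_min to avoid
# unbounded drift (the pipeline high-passes at 0.1 Hz anyway).
one_over_f_mat <- function(n_ch, n, exponent, fs, f_min = 0.1) {
  k <- 0:(n - 1)
  f <- ifelse(k <= n / 2, k, k - n) * fs / n
  shape <- ifelse(abs(f) >= f_min, abs(f)^(-exponent / 2), 0)
  out <- matrix(0, n_ch, n)
  for (ch in seq_len(n_ch)) {
    Z <- stats::fft(stats::rnorm(n))
    y <- Re(stats::fft(Z * shape, inverse = TRUE)) / n
    out[ch, ] <- y / stats::sd(y)
  }
  out
}

# Exact fractional-sample delay via FFT phase rotation.
shift_fft <- function(x, tau, fs) {
  n <- length(x)
  k <- 0:(n - 1)
  f <- ifelse(k <= n / 2, k, k - n) * fs / n
  Re(stats::fft(stats::fft(x) * exp(-2i * pi * f * tau), inverse = TRUE)) / n
}

#' Simulate one multichannel EEG recording
#'
#' Generates a montage-labelled recording in which each channel carries the
#' background of `channel_model` and, for channels named in a coupling, a
#' shared band-limited oscillator contributing `strength` of the channel
#' variance, time-shifted between the two node sets to impose a constant
#' phase lag. Channels may appear in at most one coupling so the variance
#' budget stays exact.
#'
#' @param duration_s Duration in seconds.
#' @param fs Sampling rate in Hz (must exceed twice the highest band edge).
#' @param channel_model A [sim_channel_model()].
#' @param couplings List of [sim_coupling()] objects (possibly empty).
#' @param labels Electrode labels (default the 25-channel IFCN montage).
#' @param seed Integer seed; fixed seed gives bit-reproducible output.
#' @param subject_id Identifier stored on the recording.
#' @return An [eeg_recording()].
#' @export
simulate_recording <- function(duration_s, fs = 500,
                               channel_model = sim_channel_model(),
                               couplings = list(),
                               labels = ifcn_montage(),
                               seed = NULL, subject_id = "sim") {
  if (duration_s <= 0) pg_stop("duration_s must be > 0", "pg_sim_error")
  if (fs <= 2 * 45) pg_stop("fs must exceed twice the highest band edge (45 Hz)",
                            "pg_sim_error")
  for (cp in couplings) {
    bad <- setdiff(c(cp$node_set_a, cp$node_set_b), labels)
    if (length(bad) > 0) {
      pg_stop(sprintf("coupling references unknown electrode(s): %s",
                      paste(bad, collapse = ", ")), "pg_sim_error")
    }
    if (fs <= 2 * cp$f_hi) pg_stop("fs too low for coupling band", "pg_sim_error")
  }
  all_coupled <- unlist(lapply(couplings, function(cp) c(cp$node_set_a, cp$node_set_b)))
  if (anyDuplicated(all_coupled)) {
    pg_stop("a channel may appear in at most one coupling", "pg_sim_error")
  }
  if (!is.null(seed)) set.seed(seed)
  n <- round(duration_s * fs)
  n_ch <- length(labels)
  bc <- channel_model$band_components
  amps <- c(if (nrow(bc) > 0) bc$amplitude else numeric(0),
            channel_model$noise_amplitude)
  total_sd <- sqrt(sum(amps^2))
  if (!(total_sd > 0)) pg_stop("channel model has zero total variance", "pg_sim_error")

  bg <- matrix(0, n_ch, n)
  if (nrow(bc) > 0) {
    for (i in seq_len(nrow(bc))) {
      if (bc$amplitude[i] == 0) next
      comp <- band_noise_mat(n_ch, n,
                             max(0.1, bc$center_freq[i] - bc$bandwidth[i] / 2),
                             bc$center_freq[i] + bc$bandwidth[i] / 2, fs)
      bg <- bg + bc$amplitude[i] * comp
    }
  }
  if (channel_model$noise_amplitude > 0) {
    bg <- bg + channel_model$noise_amplitude *
      one_over_f_mat(n_ch, n, channel_model$noise_exponent, fs)
  }

  data <- bg
  for (cp in couplings) {
    if (cp$strength == 0) next
    osc <- band_noise_mat(1L, n, cp$f_lo, cp$f_hi, fs)[1, ]
    f_center <- (cp$f_lo + cp$f_hi) / 2
    tau <- cp$phase_lag / (2 * pi * f_center)
    osc_b <- shift_fft(osc, tau, fs)
    osc_b <- osc_b / stats::sd(osc_b)
    ia <- match(cp$node_set_a, labels)
    ib <- match(cp$node_set_b, labels)
    s <- cp$strength
    data[ia, ] <- sqrt(1 - s) * bg[ia, ] +
      matrix(sqrt(s) * total_sd * osc, length(ia), n, byrow = TRUE)
    data[ib, ] <- sqrt(1 - s) * bg[ib, ] +
      matrix(sqrt(s) * total_sd * osc_b, length(ib), n, byrow = TRUE)
  }
  eeg_recording(data, fs, labels, subject_id)
}

#' Cohort-level generative specification
#'
#' Parameters of a synthetic case/control cohort emulating a temporal lobe
#' epilepsy study design: patients carry ipsilateral frontotemporal
#' theta-band coupling whose strength is linear in a right-skewed severity
#' score, controls carry bilateral posterior alpha coupling.
#'
#' Severity scores are log-normal with `meanlog = log(40)` and
#' `sdlog = 2.31`, which reproduces a median of 40 and an interquartile
#' range of 182. The severity-to-strength link is
#' `strength = intercept + slope * severity + N(0, noise_sd)`, clamped to
#' `[min, max]`. Patients are assigned left-, right- or bilateral-coupled
#' subgroups with proportions defaulting to 56/55/40.
#'
#' @param n_patients,n_controls Group sizes.
#' @param duration_s Recording length in seconds (default 90).
#' @param fs Sampling rate in Hz (default 500).
#' @param severity_model List with `intercept`, `slope`, `noise_sd`, `min`,
#'   `max` of the linear severity-to-coupling-strength link.
#' @param severity_meanlog,severity_sdlog Log-normal severity parameters.
#' @param base_channel_model Background [sim_channel_model()].
#' @param patient_band Band of the patient coupling (default "theta").
#' @param phase_lag Constant coupling lag in radians (default pi/4).
#' @param control_coupling List of [sim_coupling()] for controls; default a
#'   bilateral occipito-parietal alpha coupling of strength 0.4.
#' @param laterality_props Named weights for left/right/bilateral patient
#'   subgroups.
#' @param seed Root seed; every downstream draw derives from it.
#' @return A `sim_cohort_spec` list.
#' @export
sim_cohort_spec <- function(n_patients, n_controls,
                            duration_s = 90, fs = 500,
                            severity_model = list(intercept = 0.15,
                                                  slope = 0.002,
                                                  noise_sd = 0.03,
                                                  min = 0.02, max = 0.92),
                            severity_meanlog = log(40),
                            severity_sdlog = 2.31,
                            base_channel_model = sim_channel_model(),
                            patient_band = "theta",
                            phase_lag = pi / 4,
                            control_coupling = NULL,
                            laterality_props = c(left = 56, right = 55,
                                                 bilateral = 40),
                            seed = 1L) {
  if (n_patients <= 0 || n_controls < 0) {
    pg_stop("n_patients must be > 0 and n_controls >= 0", "pg_sim_error")
  }
  if (duration_s <= 0) pg_stop("duration_s must be > 0", "pg_sim_error")
  if (is.null(control_coupling)) {
    control_coupling <- list(
      sim_coupling(c("O1", "P3"), c("O2", "P4"), band = "alpha",
                   phase_lag = phase_lag, strength = 0.4)
    )
  }
  structure(list(
    n_patients = n_patients, n_controls = n_controls,
    duration_s = duration_s, fs = fs,
    severity_model = severity_model,
    severity_meanlog = severity_meanlog, severity_sdlog = severity_sdlog,
    base_channel_model = base_channel_model,
    patient_band = patient_band, phase_lag = phase_lag,
    control_coupling = control_coupling,
    laterality_props = laterality_props, seed = as.integer(seed)
  ), class = "sim_cohort_spec")
}

# Couplings for one patient given laterality and strength.
patient_couplings <- function(laterality, band, phase_lag, strength) {
  left <- sim_coupling(ft_left_frontal(), ft_left_temporal(), band = band,
                       phase_lag = phase_lag, strength = strength)
  right <- sim_coupling(ft_right_frontal(), ft_right_temporal(), band = band,
                        phase_lag = phase_lag, strength = strength)
  switch(laterality,
         left = list(left),
         right = list(right),
         bilateral = list(left, right))
}

#' Simulate a full synthetic cohort
#'
#' Draws severity scores, laterality subgroups, clinical covariates and one
#' recording per subject according to a [sim_cohort_spec()]. Identical
#' specs (including seed) produce byte-identical cohorts.
#'
#' The clinical covariates are stand-ins: the seizure-frequency class and
#' drug-resistance flag are deterministic functions of the severity score
#' (fixed cut points at 20/60/365 and > 365 respectively), ASM count grows
#' with severity, and the binary histories are independent Bernoulli draws.
#'
#' @param spec A [sim_cohort_spec()].
#' @return List of subjects, each `list(recording = <eeg_recording>,
#'   record = <one-row data.frame>)`; the record carries `subject_id`,
#'   `group` (control / L-TLE / R-TLE / B-TLE), demographics, severity
#'   (`va2`, `NA` for controls), ordinal `seizure_freq_class`, `dre`,
#'   `n_asm`, history flags and the realized `coupling_strength`.
#' @export
simulate_cohort <- function(spec) {
  set.seed(spec$seed)
  n_p <- spec$n_patients
  n_c <- spec$n_controls
  n_tot <- n_p + n_c
  sub_seeds <- sample.int(2147483646L, n_tot)
  severities <- stats::rlnorm(n_p, spec$severity_meanlog, spec$severity_sdlog)
  sm <- spec$severity_model
  strengths <- pmin(pmax(sm$intercept + sm$slope * severities +
                           stats::rnorm(n_p, 0, sm$noise_sd), sm$min), sm$max)
  lat <- sample(names(spec$laterality_props), n_p, replace = TRUE,
                prob = spec$laterality_props / sum(spec$laterality_props))
  age <- pmin(pmax(round(stats::rnorm(n_tot, 41, 18)), 18), 80)
  sex <- sample(c("M", "F"), n_tot, replace = TRUE)
  onset <- pmin(pmax(round(age[seq_len(n_p)] * stats::runif(n_p, 0.1, 0.9)), 1),
                age[seq_len(n_p)])
  freq_class <- cut(severities, breaks = c(-Inf, 20, 60, 365, Inf),
                    labels = c("lt_1_per_year", "le_1_per_year",
                               "ge_1_per_month", "ge_1_per_week"),
                    ordered_result = TRUE)
  dre <- severities > 365
  n_asm <- 1L + stats::rpois(n_p, pmin(severities / 300, 2))
  febrile <- stats::runif(n_tot) < 0.15
  family <- stats::runif(n_tot) < 0.10
  status_ep <- stats::runif(n_tot) < 0.08

  subjects <- vector("list", n_tot)
  for (i in seq_len(n_tot)) {
    is_patient <- i <= n_p
    sid <- sprintf("%s%03d", if (is_patient) "pat" else "ctl",
                   if (is_patient) i else i - n_p)
    if (is_patient) {
      cps <- patient_couplings(lat[i], spec$patient_band, spec$phase_lag,
                               strengths[i])
      group <- c(left = "L-TLE", right = "R-TLE", bilateral = "B-TLE")[[lat[i]]]
    } else {
      cps <- spec$control_coupling
      group <- "control"
    }
    rec <- simulate_recording(spec$duration_s, spec$fs,
                              spec$base_channel_model, cps,
                              seed = sub_seeds[i], subject_id = sid)
    record <- data.frame(
      subject_id = sid, group = group, age = age[i], sex = sex[i],
      age_of_onset = if (is_patient) onset[i] else NA_real_,
      duration = if (is_patient) age[i] - onset[i] else NA_real_,
      seizure_freq_class = if (is_patient) as.character(freq_class[i]) else NA_character_,
      dre = if (is_patient) dre[i] else NA,
      va2 = if (is_patient) severities[i] else NA_real_,
      n_asm = if (is_patient) n_asm[i] else NA_integer_,
      febrile_history = febrile[i], family_history = family[i],
      status_epilepticus = status_ep[i],
      coupling_strength = if (is_patient) strengths[i] else
        spec$control_coupling[[1]]$strength,
      stringsAsFactors = FALSE
    )
    subjects[[i]] <- list(recording = rec, record = record)
  }
  attr(subjects, "spec") <- spec
  subjects
}

#' Clinical table of a simulated cohort
#'
#' @param cohort Result of [simulate_cohort()].
#' @return data.frame with one row per subject.
#' @export
cohort_records <- function(cohort) {
  do.call(rbind, lapply(cohort, `[[`, "record"))
}
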