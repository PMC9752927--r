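theta_pli_for <- function(rec, total_s, epoch_length_s = 10) {
  ep <- make_epochs(rec, bands = eeg_bands()[2, ], epoch_length_s = epoch_length_s,
                    total_s = total_s)
  pli_connectivity(ep)$theta$pli
}

test_that("uncoupled channels stay at chance-level theta PLI", {
  rec <- simulate_recording(60, 500, seed = 1)
  # single 60-s epoch; bounds frozen from a Monte-Carlo null of this
  # generator (theta phases decorrelate over ~1/bandwidth s, so the null
  # max over 300 pairs sits near 0.2 and the mean near 0.05)
  P <- theta_pli_for(rec, 60, epoch_length_s = 60)
  expect_lt(max(P[upper.tri(P)]), 0.25)
  expect_lt(mean(P[upper.tri(P)]), 0.10)
})

test_that("a strong constant-lag coupling drives cross-set theta PLI near 1", {
  a <- ft_left_frontal()
  b <- ft_left_temporal()
  cp <- sim_coupling(a, b, band = "theta", phase_lag = pi / 4, strength = 0.9)
  rec <- simulate_recording(60, 500, couplings = list(cp), seed = 2)
  P <- theta_pli_for(rec, 60)
  expect_gt(mean(P[a, b]), 0.8)
  # same-set pairs share the oscillator at zero lag: PLI stays low
  expect_lt(mean(P[a, a][upper.tri(P[a, a])]), 0.3)
})

test_that("identical specs with the same seed are bit-reproducible", {
  cp <- sim_coupling(c("F3", "F7"), c("T7", "P7"), strength = 0.5)
  r1 <- simulate_recording(10, 500, couplings = list(cp), seed = 7)
  r2 <- simulate_recording(10, 500, couplings = list(cp), seed = 7)
  expect_identical(r1$data, r2$data)
  spec <- sim_cohort_spec(n_patients = 2, n_controls = 1, duration_s = 5, seed = 3)
  c1 <- simulate_cohort(spec)
  c2 <- simulate_cohort(spec)
  expect_identical(c1[[1]]$recording$data, c2[[1]]$recording$data)
  expect_identical(cohort_records(c1), cohort_records(c2))
})

test_that("per-channel variance matches the component budget within 10%", {
  model <- sim_channel_model(
    band_components = data.frame(center_freq = c(10, 20),
                                 bandwidth = c(2, 4), amplitude = c(2, 1)),
    noise_exponent = 1, noise_amplitude = 1.5
  )
  target_var <- 2^2 + 1^2 + 1.5^2
  rec <- simulate_recording(30, 500, channel_model = model, seed = 4)
  v <- apply(rec$data, 1, var)
  expect_true(all(abs(v - target_var) / target_var < 0.1))
  # coupled channels obey the same budget
  cp <- sim_coupling(c("F3"), c("T7"), strength = 0.6)
  rec2 <- simulate_recording(30, 500, channel_model = model,
                             couplings = list(cp), seed = 4)
  v2 <- apply(rec2$data[c("F3", "T7"), ], 1, var)
  expect_true(all(abs(v2 - target_var) / target_var < 0.1))
})

test_that("estimated PLI is non-decreasing on a coupling-strength grid", {
  a <- c("F3", "F7")
  b <- c("T7", "P7")
  plis <- vapply(c(0, 0.2, 0.4, 0.6, 0.8), function(s) {
    cps <- if (s > 0) list(sim_coupling(a, b, strength = s)) else list()
    rec <- simulate_recording(30, 500, couplings = cps, seed = 11)
    mean(theta_pli_for(rec, 30)[a, b])
  }, numeric(1))
  expect_true(all(diff(plis) >= 0))
})

test_that("simulation rejects invalid specifications", {
  expect_error(simulate_recording(10, 500,
                 couplings = list(sim_coupling(c("XX"), c("T7")))),
               class = "pligraph_error")
  expect_error(sim_coupling(c("F3"), c("T7"), strength = 1.4),
               class = "pligraph_error")
  expect_error(simulate_recording(10, 80), class = "pligraph_error")
  expect_error(sim_cohort_spec(n_patients = 0, n_controls = 3),
               class = "pligraph_error")
})

test_that("cohort generation follows the severity and grouping contracts", {
  spec <- sim_cohort_spec(
    n_patients = 20, n_controls = 10, duration_s = 2, seed = 5,
    severity_model = list(intercept = 0.3, slope = 0, noise_sd = 0,
                          min = 0.02, max = 0.92)
  )
  cohort <- simulate_cohort(spec)
  recs <- cohort_records(cohort)
  expect_equal(nrow(recs), 30)
  pats <- recs[recs$group != "control", ]
  ctls <- recs[recs$group == "control", ]
  # degenerate link: zero slope pins every strength at the intercept
  expect_true(all(pats$coupling_strength == 0.3))
  expect_equal(nrow(ctls), 10)
  expect_true(all(is.na(ctls$va2)))
  expect_true(all(pats$group %in% c("L-TLE", "R-TLE", "B-TLE")))
  expect_true(all(pats$age_of_onset <= pats$age))
  # severity classes are a deterministic function of the severity score
  expect_true(all((pats$va2 > 365) == (pats$seizure_freq_class == "ge_1_per_week")))
})
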