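cfg0 <- small_config(noise = list(sd = 0, alpha = 1))

test_that("template map is frontal-maximal, unit-norm and deterministic", {
  lay <- spiral_layout(32)
  tpl <- build_template(lay, plas_config())
  expect_equal(sum(tpl$weights^2), 1)
  expect_identical(names(which.max(tpl$weights)), "Fz")
  expect_true(all(tpl$frontal_channels %in% lay$name))
  expect_identical(tpl, build_template(lay, plas_config()))
  # posterior channels sit below zero in the centred gradient
  back <- lay$name[which.min(lay$y)]
  expect_lt(tpl$weights[back], 0)
})

test_that("all-zero signals trigger no markers", {
  rec <- make_spaced_night(numeric(0), duration_s = 60)
  tpl <- build_template(rec$layout, cfg0)
  expect_equal(nrow(detect_stream(rec, tpl, detector_params(), "real")), 0)
})

test_that("the polarity gate rejects anticorrelated scalp patterns", {
  # monophasic frontal bumps: with the correct topography both criteria
  # rise into a template-positive map and markers fire; with the inverted
  # topography the map stays anticorrelated so no prediction is scored
  # even while voltage and similarity rise during the decay phase
  lay <- spiral_layout(16)
  topo <- plaslab:::channel_topography(lay, "Fz", 1.0)
  rate <- 200
  nsamp <- 120 * rate
  bump_t <- seq(0, 0.5, by = 1 / rate)
  bump <- 75 * sin(pi * bump_t / 0.5)^2
  onsets <- seq(10, 110, by = 4)
  mk_rec <- function(sign_topo) {
    data <- matrix(0, 16, nsamp)
    for (on in onsets) {
      idx <- round(on * rate) + seq_along(bump)
      data[, idx] <- data[, idx] + sign_topo * tcrossprod(topo, bump)
    }
    structure(list(data = data, rate = rate, channel_names = lay$name,
                   layout = lay, hypnogram = rep("N2", 4),
                   events = data.frame(onset_s = onsets + 0.25,
                                       kind = "sw_peak", amplitude = 75),
                   night = "E1", participant = "T01"),
              class = "plas_recording")
  }
  tpl <- build_template(lay, cfg0)
  n_ok <- nrow(detect_stream(mk_rec(+1), tpl, detector_params(), "real"))
  n_inv <- nrow(detect_stream(mk_rec(-1), tpl, detector_params(), "real"))
  expect_gt(n_ok, length(onsets) * 0.9)
  expect_equal(n_inv, 0)
})

test_that("markers hit true peaks on a noise-free slow-wave train", {
  peaks <- seq(5, 115, by = 4)  # spaced beyond the refractory lockout
  rec <- make_spaced_night(peaks, duration_s = 120)
  tpl <- build_template(rec$layout, cfg0)
  delay <- calibrate_delay(rec, tpl, detector_params())
  mk <- detect_stream(rec, tpl, detector_params(delay_ms = delay), "real")
  met <- evaluate_detection(mk, rec$events, tolerance_ms = 100)
  expect_gte(met$recall, 0.9)
  expect_lte(met$median_abs_error_ms, 30)
  # offline oracle agrees with the ground-truth peaks it was built from
  oracle <- offline_peak_oracle(rec, min_height = 20)
  expect_equal(length(oracle), length(peaks))
  expect_lt(max(abs(oracle - peaks)), 0.02)
})

test_that("detection is causal and honours the refractory lockout", {
  peaks <- seq(5, 115, by = 3)
  rec <- make_spaced_night(peaks, duration_s = 120)
  tpl <- build_template(rec$layout, cfg0)
  prm <- detector_params()
  full <- detect_stream(rec, tpl, prm, "real")
  expect_true(all(diff(full$time_s) >= prm$refractory_s))

  # truncating the recording never changes markers already emitted
  for (cut_s in c(40, 77.3)) {
    k <- round(cut_s * rec$rate)
    trunc <- rec
    trunc$data <- rec$data[, seq_len(k)]
    trunc$hypnogram <- rec$hypnogram[seq_len(ceiling(k / rec$rate / 30))]
    mk_t <- detect_stream(trunc, tpl, prm, "real")
    horizon <- (k - 1) / rec$rate + prm$delay_ms / 1000
    expect_equal(mk_t$time_s, full$time_s[full$time_s <= horizon + 1e-9])
  }
})

test_that("markers respect stage gating and condition/night pairing", {
  rec <- make_spaced_night(seq(5, 55, by = 4), duration_s = 60)
  rec$hypnogram <- rep("W", length(rec$hypnogram))
  tpl <- build_template(rec$layout, cfg0)
  expect_warning(mk <- detect_stream(rec, tpl, detector_params(), "real"),
                 "gated")
  expect_equal(nrow(mk), 0)

  bl <- make_spaced_night(seq(5, 55, by = 4), duration_s = 60, night = "BL")
  expect_error(detect_stream(bl, tpl, detector_params(), "real"),
               "experimental nights")
  expect_error(detect_stream(rec, tpl, detector_params(), "sham"),
               "baseline")
  sham <- detect_stream(bl, tpl, detector_params(), "sham")
  expect_true(all(sham$condition == "sham"))
  expect_gt(nrow(sham), 0)
})

test_that("delay calibration matches an oracle lead-time construction", {
  peaks <- seq(5, 115, by = 4)
  rec <- make_spaced_night(peaks, duration_s = 120)
  tpl <- build_template(rec$layout, cfg0)
  prm0 <- detector_params(delay_ms = 0)
  crossings <- detect_stream(rec, tpl, prm0, "real")$time_s
  oracle_lead <- median(vapply(crossings, function(tc) {
    (peaks[peaks >= tc][1] - tc) * 1000
  }, numeric(1)))
  delay <- calibrate_delay(rec, tpl, detector_params())
  expect_lt(abs(delay - min(oracle_lead, 200)), 10)

  few <- make_spaced_night(c(10, 20), duration_s = 40)
  expect_error(calibrate_delay(few, tpl, detector_params()), "at least 10")

  flat <- make_spaced_night(numeric(0), duration_s = 120)
  flat$events <- data.frame(onset_s = seq(5, 115, by = 10), kind = "sw_peak",
                            amplitude = 75)
  expect_error(calibrate_delay(flat, tpl, detector_params()), "no detections")
})

test_that("detection metrics follow greedy one-to-one matching", {
  truth <- data.frame(onset_s = c(1.01, 2.05), kind = "sw_peak", amplitude = 75)
  mk <- data.frame(time_s = c(1.00, 2.00, 9.00), condition = "real",
                   night = "E1")
  met <- evaluate_detection(mk, truth, tolerance_ms = 100)
  expect_equal(met$precision, 2 / 3)
  expect_equal(met$recall, 1)

  exact <- data.frame(time_s = c(1.01, 2.05), condition = "real", night = "E1")
  met2 <- evaluate_detection(exact, truth, tolerance_ms = 100)
  expect_equal(met2$precision, 1)
  expect_equal(met2$recall, 1)
  expect_equal(met2$phase_error_ms, c(0, 0))

  none <- data.frame(time_s = numeric(), condition = character(),
                     night = character())
  met3 <- evaluate_detection(none, truth, tolerance_ms = 100)
  expect_equal(met3$recall, 0)
  expect_equal(met3$precision, 0)
  expect_true(met3$precision_undefined)
  expect_error(evaluate_detection(mk, truth, tolerance_ms = 0), "positive")
})

test_that("detector keeps useful sensitivity at the default noise level", {
  cfg <- small_config()  # default 20 uV 1/f background
  rec <- generate_night(test_profile(sw_density = 4), "E1", 15, cfg, seed = 7)
  tpl <- build_template(rec$layout, cfg)
  delay <- calibrate_delay(rec, tpl, detector_params())
  mk <- detect_stream(rec, tpl, detector_params(delay_ms = delay), "real")
  met <- evaluate_detection(mk, rec$events, tolerance_ms = 150)
  expect_gte(met$recall, 0.5)
  expect_lte(met$median_abs_error_ms, 50)
})
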