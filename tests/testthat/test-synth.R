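test_that("cohort generation respects sizes, profile rules and reproducibility", {
  cfg <- plas_config()
  cohort <- generate_cohort(18, 16, cfg, seed = 1)
  expect_equal(nrow(cohort), 34)
  expect_equal(sum(cohort$group == "HC"), 18)
  expect_equal(sum(cohort$group == "CI"), 16)
  expect_true(all(cohort$responsiveness >= 0))
  expect_true(all(cohort$sw_density >= 0))
  hc <- cohort[cohort$group == "HC", ]
  expect_true(all(hc$night_gain_1 == 1 & hc$night_gain_2 == 1 & hc$night_gain_3 == 1))
  ci <- cohort[cohort$group == "CI", ]
  expect_true(all(ci$night_gain_1 <= ci$night_gain_2 & ci$night_gain_2 <= ci$night_gain_3))
  expect_identical(cohort, generate_cohort(18, 16, cfg, seed = 1))

  expect_equal(nrow(generate_cohort(0, 0, cfg, seed = 5)), 0)
  expect_error(generate_cohort(-1, 4, cfg), "non-negative")
})

test_that("CI slow-wave density is stochastically lower than HC at large n", {
  cohort <- generate_cohort(100, 100, plas_config(), seed = 7)
  expect_lt(mean(cohort$sw_density[cohort$group == "CI"]),
            mean(cohort$sw_density[cohort$group == "HC"]))
})

test_that("night generation is deterministic with valid hypnogram and events", {
  cfg <- small_config()
  p <- test_profile(sw_density = 3)
  r1 <- generate_night(p, "E1", duration_min = 6, cfg, seed = 11)
  r2 <- generate_night(p, "E1", duration_min = 6, cfg, seed = 11)
  expect_identical(r1$data, r2$data)
  expect_identical(r1$events, r2$events)

  expect_equal(length(r1$hypnogram), floor(6 * 60 / 30))
  expect_equal(nrow(r1$data), 16)
  expect_true(all(r1$events$onset_s >= 0 & r1$events$onset_s < 6 * 60))
  expect_true(all(r1$hypnogram %in% c("W", "N1", "N2", "N3", "REM")))

  # slow-wave peaks only inside N2/N3 epochs
  sw <- r1$events[r1$events$kind == "sw_peak", ]
  ep <- floor(sw$onset_s / 30) + 1
  expect_true(all(r1$hypnogram[ep] %in% c("N2", "N3")))

  expect_error(generate_night(p, "E1", duration_min = 0, cfg), "positive")
})

test_that("zero slow-wave density yields zero ground-truth events", {
  rec <- generate_night(test_profile(sw_density = 0), "BL", 5,
                        small_config(), seed = 2)
  expect_equal(sum(rec$events$kind == "sw_peak"), 0)
})

test_that("slow-wave count follows the Poisson rate over N2/N3 time", {
  # high rate, 60 min, stage mix with a large N2+N3 share
  cfg <- plas_config(n_channels = 8, noise = list(sd = 5, alpha = 1))
  rec <- generate_night(test_profile(sw_density = 10), "BL", 60, cfg, seed = 3)
  n2n3_min <- sum(rec$hypnogram %in% c("N2", "N3")) * 30 / 60
  lambda <- 10 * n2n3_min
  count <- sum(rec$events$kind == "sw_peak")
  expect_lt(abs(count - lambda), 3 * sqrt(lambda))
})

test_that("evoked injection is additive, scaled and marker-validated", {
  cfg <- small_config(noise = list(sd = 0, alpha = 1),
                      spindle = list(density = 0, f_lo = 12, f_hi = 16,
                                     dur = 0.8, amp = 20, topo_sigma = 0.8))
  p <- test_profile(sw_density = 0)
  rec <- generate_night(p, "E1", 4, cfg, seed = 1)

  # empty marker list is a no-op
  none <- data.frame(time_s = numeric(), condition = character(),
                     night = character())
  expect_identical(inject_evoked_response(rec, none, p, cfg)$data, rec$data)

  # sham markers add nothing
  sham <- data.frame(time_s = 30, condition = "sham", night = "E1")
  expect_identical(inject_evoked_response(rec, sham, p, cfg)$data, rec$data)

  # mean Fz voltage over the scoring window equals the configured peak
  mk <- data.frame(time_s = 60, condition = "real", night = "E1")
  out <- inject_evoked_response(rec, mk, p, cfg)
  fz <- match("Fz", out$channel_names)
  idx <- (round(61 * cfg$rate) + 1):(round(61.5 * cfg$rate) + 1)
  expect_equal(mean(out$data[fz, idx]), cfg$evoked$peak_uv,
               tolerance = 0.05)
  # other samples untouched
  pre <- seq_len(round(59 * cfg$rate))
  expect_identical(out$data[, pre], rec$data[, pre])

  expect_error(inject_evoked_response(rec, data.frame(time_s = 1e5,
                                                      condition = "real",
                                                      night = "E1"), p, cfg),
               "outside recording")
  expect_error(inject_evoked_response(rec, data.frame(time_s = 10,
                                                      condition = "real",
                                                      night = "E2"), p, cfg),
               "night")
})

test_that("ramping night gains make the induced second peak grow E1 to E3", {
  cfg <- small_config(noise = list(sd = 0, alpha = 1))
  p <- test_profile(group = "CI", sw_density = 0, night_gain = c(0.4, 0.7, 1.0))
  amp_at <- function(night) {
    rec <- generate_night(p, night, 4, cfg, seed = 9)
    mk <- data.frame(time_s = c(60, 90, 120), condition = "real", night = night)
    out <- inject_evoked_response(rec, mk, p, cfg)
    fz <- match("Fz", out$channel_names)
    idx <- (round(61 * cfg$rate) + 1):(round(61.5 * cfg$rate) + 1)
    mean(out$data[fz, idx])
  }
  expect_gt(amp_at("E3"), amp_at("E1"))
})

test_that("behavioral scores are bounded, consistent and null under zero effects", {
  cfg <- plas_config()
  cfg$memory$noise_sd <- 0
  cfg$abeta$noise_sd <- 0
  p <- test_profile(group = "CI")
  p$memory_slope <- 0
  p$abeta_slope <- 0
  bb <- generate_behavior_and_biomarker(p, response_score = 3, cfg, seed = 4)
  expect_identical(as.integer(bb$behavior$scores),
                   as.integer(pmin(pmax(round(cfg$memory$base$CI), 0), 40)))
  expect_equal(bb$abeta$diff, 0)
  expect_equal(unname(bb$behavior$gains),
               unname(bb$behavior$scores[2:8] - bb$behavior$scores[1]))

  # clipping at the 40-item bound under an extreme effect
  p2 <- test_profile(group = "HC")
  p2$memory_slope <- 100
  bb2 <- generate_behavior_and_biomarker(p2, response_score = 50,
                                         plas_config(), seed = 4)
  expect_true(all(bb2$behavior$scores <= 40 & bb2$behavior$scores >= 0))

  expect_error(generate_behavior_and_biomarker(p, Inf, cfg), "finite")
})

test_that("amyloid slope is recoverable from a large simulated CI cohort", {
  cfg <- plas_config()
  tab <- simulate_participant_table(0, 200, cfg, seed = 21)
  fit <- response_regression(tab, "abeta_diff", subset = "CI")
  expect_lt(abs(fit$coefficients[2] - 0.002), 2 * fit$slope_se)
})
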