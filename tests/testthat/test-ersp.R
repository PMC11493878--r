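make_epochs <- function(fun, n_trials = 3, n_ch = 2, rate = 200,
                        window = c(-1.5, 3)) {
  times <- seq(window[1], window[2], by = 1 / rate)
  ep <- array(0, c(n_trials, n_ch, length(times)))
  for (tr in seq_len(n_trials)) for (ch in seq_len(n_ch))
    ep[tr, ch, ] <- fun(times)
  structure(list(epochs = ep, times = times,
                 channel_names = paste0("E", seq_len(n_ch)),
                 night = "E1", rate = rate, n_stimulations = n_trials),
            class = "plas_epochs")
}

test_that("Morlet power localises oscillations in frequency and time", {
  # pure 10 Hz sinusoid: the 10 Hz bin dominates at every interior time
  ep <- make_epochs(function(t) sin(2 * pi * 10 * t))
  tfr <- morlet_tfr(ep, freqs = seq(2, 18, by = 2))
  interior <- tfr$times > -0.5 & tfr$times < 1.5
  argmax <- apply(tfr$power[1, , interior], 2, which.max)
  expect_true(all(tfr$freqs[argmax] == 10))

  # zero signal gives zero power
  ep0 <- make_epochs(function(t) 0 * t)
  expect_equal(max(morlet_tfr(ep0, freqs = c(5, 10))$power), 0)

  # 13 Hz burst at 1.0-1.4 s on noise: spindle-band peak inside the burst
  set.seed(6)
  epb <- make_epochs(function(t) {
    x <- rnorm(length(t), 0, 0.5)
    on <- t >= 1 & t <= 1.4
    x[on] <- x[on] + 3 * sin(2 * pi * 13 * (t[on] - 1)) *
      sin(pi * (t[on] - 1) / 0.4)^2
    x
  }, n_trials = 10)
  tfrb <- morlet_tfr(epb, freqs = seq(10, 16, by = 1))
  band <- which(tfrb$freqs >= 12 & tfrb$freqs <= 14)
  prof <- colMeans(tfrb$power[1, band, , drop = FALSE][1, , ])
  tpk <- tfrb$times[which.max(prof)]
  expect_gt(tpk, 0.9)
  expect_lt(tpk, 1.5)

  expect_error(morlet_tfr(ep, freqs = c(0.05, 10)), "resolvable")
})

test_that("dB baselining is exact in closed form and scale invariant", {
  freqs <- 1:4
  times <- seq(-1.5, 2.5, by = 0.01)
  p <- array(2, c(3, length(freqs), length(times)))
  p[1, 2, 30] <- 20  # one bin at 10x its baseline mean
  tfr <- fake_tfr(p, freqs, times)
  db <- baseline_db(tfr)
  expect_equal(db$units, "dB")
  expect_equal(db$power[1, 2, 30], 10)
  expect_equal(db$power[2, 3, 100], 0)

  # uniform scaling of the whole epoch cancels
  scaled <- fake_tfr(7 * p, freqs, times)
  expect_equal(baseline_db(scaled)$power, db$power)

  zero <- fake_tfr(array(0, dim(p)), freqs, times)
  expect_error(baseline_db(zero), "zero baseline")
  expect_error(baseline_db(db), "already")
})

test_that("stationary noise baselines to approximately 0 dB", {
  set.seed(7)
  ep <- make_epochs(function(t) rnorm(length(t)), n_trials = 30)
  db <- baseline_db(morlet_tfr(ep, freqs = seq(4, 16, by = 4)))
  interior <- db$times > -0.5 & db$times < 1.8
  expect_lt(max(abs(db$power[, , interior])), 3)
})

test_that("band specifications carry the published limits and electrode sets", {
  lay <- spiral_layout(64)
  sw <- band_spec("sw", lay)
  expect_equal(c(sw$f_lo, sw$f_hi), c(0.75, 1.5))
  expect_equal(length(sw$channel_set), 17)
  expect_true("Fz" %in% sw$channel_set)
  sp <- band_spec("spindle", lay)
  expect_equal(c(sp$f_lo, sp$f_hi), c(12, 16))
  expect_equal(length(sp$channel_set), 13)
  expect_true("Cz" %in% sp$channel_set)
  expect_equal(band_spec("beta", lay)$f_hi, 20)
})

test_that("band response scores use weighted median differences", {
  lay <- spiral_layout(16)
  freqs <- seq(0.5, 20, by = 0.5)
  times <- seq(-1.5, 2.5, by = 0.05)
  base <- array(1, c(16, length(freqs), length(times)))
  mk <- function(level, night, n_stim) {
    p <- base
    p[] <- level
    tfr <- fake_tfr(p, freqs, times, night = night, n_stim = n_stim)
    tfr$channel_names <- lay$name
    tfr$units <- "dB"
    tfr
  }
  band <- band_spec("delta", lay)
  tfrs <- list(BL = mk(0, "BL", 500), E1 = mk(0, "E1", 50),
               E2 = mk(3, "E2", 100), E3 = mk(3, "E3", 150))
  expect_equal(band_response_score(tfrs, band)$value,
               (0 * 50 + 3 * 100 + 3 * 150) / 300)  # 2.5 -> d=(0,3,3)
  same <- list(BL = mk(1, "BL", 10), E1 = mk(1, "E1", 10),
               E2 = mk(1, "E2", 10), E3 = mk(1, "E3", 10))
  expect_equal(band_response_score(same, band)$value, 0)
  const <- list(BL = mk(0, "BL", 10), E1 = mk(1, "E1", 1),
                E2 = mk(1, "E2", 99), E3 = mk(1, "E3", 400))
  expect_equal(band_response_score(const, band)$value, 1)
})

test_that("summed activity reproduces the worked exclusion example exactly", {
  # five masked bins with dB values {1, 1, 1, 1, 12}: mean 3.2, SD 4.92,
  # cutoff 10.58 -> the 12 dB bin is excluded and the sum is 4
  freqs <- c(1, 2, 3, 4, 5)
  times <- c(0.5, 1.0)
  p_bl <- array(1, c(1, 5, 2))
  p_exp <- array(1, c(1, 5, 2))
  vals <- c(1, 1, 1, 1, 12)
  for (i in 1:5) p_exp[1, i, 1] <- 10^(vals[i] / 10)
  mask <- array(FALSE, c(1, 5, 2))
  mask[1, , 1] <- TRUE
  sa <- summed_activity(fake_tfr(p_exp, freqs, times),
                        fake_tfr(p_bl, freqs, times), mask)
  expect_equal(sa$value, 4)
  expect_equal(sa$n_bins_used, 4L)
  expect_equal(sa$n_bins_excluded, 1L)

  # equal maps sum to zero
  sa0 <- summed_activity(fake_tfr(p_bl, freqs, times),
                         fake_tfr(p_bl, freqs, times), mask)
  expect_equal(sa0$value, 0)

  # empty restricted mask warns and returns zero
  off <- array(FALSE, c(1, 5, 2))
  expect_warning(sae <- summed_activity(fake_tfr(p_exp, freqs, times),
                                        fake_tfr(p_bl, freqs, times), off),
                 "empty")
  expect_equal(sae$value, 0)
})

test_that("summed activity matches the brute-force recomputation on random maps", {
  set.seed(8)
  for (rep in 1:20) {
    d <- c(sample(2:4, 1), sample(3:6, 1), sample(4:8, 1))
    freqs <- sort(runif(d[2], 0, 20))
    times <- sort(runif(d[3], -1.5, 2.5))
    p_exp <- array(exp(rnorm(prod(d))), d)
    p_bl <- array(exp(rnorm(prod(d))), d)
    mask <- array(runif(prod(d)) < 0.5, d)
    sa <- summed_activity(fake_tfr(p_exp, freqs, times),
                          fake_tfr(p_bl, freqs, times), mask)
    expect_equal(sa$value,
                 brute_summed_activity(p_exp, p_bl, mask, freqs, times),
                 tolerance = 0)
  }
  # scaling all experimental power shifts every bin identically
  d <- c(2, 4, 6)
  freqs <- seq(1, 16, length.out = 4)
  times <- seq(0, 2.5, length.out = 6)
  p_exp <- array(exp(rnorm(prod(d))), d)
  p_bl <- array(exp(rnorm(prod(d))), d)
  mask <- array(TRUE, d)
  v2 <- summed_activity(fake_tfr(2 * p_exp, freqs, times),
                        fake_tfr(p_bl, freqs, times), mask)
  expect_equal(v2$value,
               brute_summed_activity(2 * p_exp, p_bl, mask, freqs, times),
               tolerance = 0)
})

test_that("a freq x time mask broadcasts across channels", {
  d <- c(3, 4, 5)
  freqs <- seq(1, 10, length.out = 4)
  times <- seq(0, 2, length.out = 5)
  set.seed(9)
  p_exp <- array(exp(rnorm(prod(d))), d)
  p_bl <- array(exp(rnorm(prod(d))), d)
  m2 <- matrix(c(TRUE, FALSE), 4, 5)
  m3 <- aperm(array(m2, c(4, 5, 3)), c(3, 1, 2))
  sa2 <- summed_activity(fake_tfr(p_exp, freqs, times),
                         fake_tfr(p_bl, freqs, times), m2)
  sa3 <- summed_activity(fake_tfr(p_exp, freqs, times),
                         fake_tfr(p_bl, freqs, times), m3)
  expect_equal(sa2$value, sa3$value)
})

test_that("significant-channel fractions count cluster membership per bin", {
  labels <- array(0L, c(8, 3, 10))
  labels[1:2, 2, 4] <- 1L   # significant cluster on 2 of 8 channels
  labels[, 1, 7] <- 2L      # non-significant cluster on all channels
  cl <- structure(list(clusters = data.frame(id = 1:2, mass = c(50, 30),
                                             sign = 1L,
                                             p_value = c(0.004, 0.2),
                                             n_bins = c(2L, 8L),
                                             significant = c(TRUE, FALSE)),
                       labels = labels, alpha = 0.01, n_perm = 500),
                  class = "plas_clusters")
  fr <- significant_channel_fraction(cl)
  expect_equal(fr[2, 4], 0.25)
  expect_equal(fr[1, 7], 0)
  expect_equal(sum(fr), 0.25)
})

test_that("night trends and per-night group tests behave at the limits", {
  tab <- expand.grid(participant_id = sprintf("P%02d", 1:10),
                     night = c("E1", "E2", "E3"),
                     stringsAsFactors = FALSE)
  tab$group <- ifelse(as.integer(sub("P", "", tab$participant_id)) <= 5,
                      "HC", "CI")
  tab$value <- 5
  tr <- night_trend_and_group_tests(tab)
  expect_equal(tr$trend$slope, c(0, 0))
  expect_equal(tr$trend$t, c(0, 0))
  expect_equal(tr$group_tests$mean_diff, c(0, 0, 0))

  # deterministic limit: value = 2 * night + vanishing noise
  set.seed(10)
  tab$value <- 2 * match(tab$night, c("E1", "E2", "E3")) + rnorm(30, 0, 1e-6)
  tr2 <- night_trend_and_group_tests(tab)
  expect_equal(tr2$trend$slope, c(2, 2), tolerance = 1e-4)
  expect_true(all(tr2$trend$p < 1e-10))

  solo <- tab[tab$participant_id %in% c("P01", "P06"), ]
  expect_error(night_trend_and_group_tests(solo), "fewer than 2")
})
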