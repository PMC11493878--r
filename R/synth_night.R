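#' Simulate one night of multichannel sleep EEG
#'
#' Builds a recording for one participant-night: a block-structured
#' hypnogram cycling through W/N1/N2/N3/REM, 1/f background noise on every
#' channel, frontal-maximal slow-wave events placed at a Poisson rate within
#' N2/N3 epochs, and centroparietal 12-16 Hz spindle bursts within N2. The
#' ground-truth event table (slow-wave peak times and amplitudes, spindle
#' centres) is returned with the recording so detector performance can be
#' benchmarked without hand labelling.
#'
#' @param profile a cohort row (see [generate_cohort()]) or an equivalent
#'   list with at least `group` and `sw_density`.
#' @param night one of `"BL"`, `"E1"`, `"E2"`, `"E3"`.
#' @param duration_min night duration in minutes (> 0).
#' @param config configuration from [plas_config()].
#' @param seed integer seed; identical inputs give identical samples.
#' @return A `plas_recording`: list with `data` (channels x samples matrix,
#'   uV), `rate`, `channel_names`, `layout`, `hypnogram` (one stage per 30-s
#'   epoch), `events` (data.frame `onset_s`, `kind`, `amplitude`), `night`.
#' @export
generate_night <- function(profile, night = "BL", duration_min = 480,
                           config = plas_config(), seed = NULL) {
  night <- match.arg(night, NIGHTS)
  if (!is.numeric(duration_min) || length(duration_min) != 1 ||
      is.na(duration_min) || duration_min <= 0)
    stop("duration_min must be a positive number of minutes")
  rate <- config$raw_rate %||% config$rate
  dur_s <- duration_min * 60
  nsamp <- round(dur_s * rate)
  layout <- spiral_layout(config$n_channels)
  nch <- nrow(layout)

  with_seed(seed, {
    hyp <- build_hypnogram(duration_min, config)
    stage_of_sample <- hyp[pmin(length(hyp), floor((seq_len(nsamp) - 1) / (30 * rate)) + 1)]

    data <- pink_noise_matrix(nch, nsamp, rate, config$noise$sd, config$noise$alpha)

    # slow-wave events: Poisson within N2/N3 time
    sw_cfg <- config$sw
    n2n3 <- stage_of_sample %in% c("N2", "N3")
    n2n3_min <- sum(n2n3) / rate / 60
    grp <- profile$group
    events <- data.frame(onset_s = numeric(), kind = character(),
                         amplitude = numeric(), stringsAsFactors = FALSE)
    density <- profile$sw_density %||% sw_cfg$density_mean[grp]
    kern <- sw_kernel(rate, sw_cfg)
    topo <- channel_topography(layout, "Fz", sw_cfg$topo_sigma)
    n_sw <- if (density > 0 && n2n3_min > 0) rpois(1, density * n2n3_min) else 0L
    if (n_sw > 0) {
      allowed <- which(n2n3)
      # peak must leave room for the kernel on both sides
      pre <- attr(kern, "peak_idx") - 1L
      post <- length(kern) - attr(kern, "peak_idx")
      allowed <- allowed[allowed > pre & allowed <= nsamp - post]
      if (length(allowed)) {
        peaks <- sort(sample(allowed, n_sw, replace = TRUE))
        amps <- pmax(10, rnorm(n_sw, sw_cfg$amp_mean[grp], sw_cfg$amp_sd))
        for (k in seq_len(n_sw)) {
          idx <- (peaks[k] - pre):(peaks[k] + post)
          data[, idx] <- data[, idx] + amps[k] * tcrossprod(topo, kern)
        }
        events <- rbind(events,
                        data.frame(onset_s = (peaks - 1) / rate,
                                   kind = "sw_peak", amplitude = amps,
                                   stringsAsFactors = FALSE))
      }
    }

    # spindle bursts in N2
    sp <- config$spindle
    n2_min <- sum(stage_of_sample == "N2") / rate / 60
    n_sp <- if (sp$density > 0 && n2_min > 0) rpois(1, sp$density * n2_min) else 0L
    if (n_sp > 0) {
      lsp <- round(sp$dur * rate)
      allowed <- which(stage_of_sample == "N2")
      allowed <- allowed[allowed <= nsamp - lsp]
      if (length(allowed)) {
        starts <- sort(sample(allowed, n_sp, replace = TRUE))
        cz_topo <- channel_topography(layout, "Cz", sp$topo_sigma)
        tt <- seq_len(lsp) / rate
        for (k in seq_len(n_sp)) {
          f <- runif(1, sp$f_lo, sp$f_hi)
          burst <- sp$amp * sin(2 * pi * f * tt) * sin(pi * tt / sp$dur)^2
          idx <- starts[k]:(starts[k] + lsp - 1)
          data[, idx] <- data[, idx] + tcrossprod(cz_topo, burst)
        }
        events <- rbind(events,
                        data.frame(onset_s = (starts - 1 + lsp / 2) / rate,
                                   kind = "spindle", amplitude = sp$amp,
                                   stringsAsFactors = FALSE))
      }
    }
    events <- events[order(events$onset_s), , drop = FALSE]
    rownames(events) <- NULL

    structure(list(data = data, rate = rate, channel_names = layout$name,
                   layout = layout, hypnogram = hyp, events = events,
                   night = night, participant = profile$id %||% NA_character_),
              class = "plas_recording")
  })
}

#' @export
print.plas_recording <- function(x, ...) {
  cat(sprintf("<plas_recording> %s night %s: %d channels x %d samples @ %g Hz (%.1f min)\n",
              x$participant %||% "?", x$night, nrow(x$data), ncol(x$data),
              x$rate, ncol(x$data) / x$rate / 60))
  cat(sprintf("  hypnogram: %d epochs (%s)\n", length(x$hypnogram),
              paste(sprintf("%s=%d", names(table(x$hypnogram)),
                            as.integer(table(x$hypnogram))), collapse = " ")))
  cat(sprintf("  ground-truth events: %d sw_peak, %d spindle\n",
              sum(x$events$kind == "sw_peak"), sum(x$events$kind == "spindle")))
  invisible(x)
}

# Fixed-proportion block hypnogram: each sleep cycle runs
# W -> N1 -> N2 -> N3 -> N2 -> REM with durations set by the configured
# stage proportions (the N2 share is split around N3).
build_hypnogram <- function(duration_min, config) {
  n_epochs <- floor(duration_min * 60 / 30)
  p <- config$stages$proportions[STAGES]
  p <- p / sum(p)
  cyc_ep <- max(1, min(round(config$stages$cycle_min * 2), n_epochs))
  block <- c(W = p[["W"]], N1 = p[["N1"]], N2a = p[["N2"]] / 2,
             N3 = p[["N3"]], N2b = p[["N2"]] / 2, REM = p[["REM"]])
  counts <- round(block * cyc_ep)
  stages <- c("W", "N1", "N2", "N3", "N2", "REM")
  cycle <- rep(stages, times = counts)
  if (!length(cycle)) cycle <- "N2"
  hyp <- rep(cycle, length.out = max(n_epochs, 0))
  hyp
}

# channels x samples matrix of independent 1/f^alpha noise, scaled to sd uV.
pink_noise_matrix <- function(nch, nsamp, rate, sd_uv, alpha = 1) {
  if (sd_uv <= 0) return(matrix(0, nch, nsamp))
  nfft <- nextn(nsamp, 2)
  freqs <- seq(0, rate / 2, length.out = nfft / 2 + 1)
  shape <- c(0, 1 / freqs[-1]^(alpha / 2))
  out <- matrix(0, nch, nsamp)
  for (ch in seq_len(nch)) {
    half <- complex(real = rnorm(nfft / 2 + 1), imaginary = rnorm(nfft / 2 + 1)) * shape
    half[1] <- 0
    half[nfft / 2 + 1] <- complex(real = Re(half[nfft / 2 + 1]), imaginary = 0)
    spec <- c(half, Conj(rev(half[2:(nfft / 2)])))
    x <- Re(fft(spec, inverse = TRUE))[seq_len(nsamp)]
    out[ch, ] <- x / stats::sd(x) * sd_uv
  }
  out
}

# Asymmetric biphasic slow-wave kernel: slow raised-cosine descent into the
# down-state trough, steep rise to the positive up-state peak, short decay.
# Unit positive peak; the peak sample index is carried as an attribute
# (ground-truth peak time). The short trough-to-peak rise (t_rise) mirrors
# the steep up-slope of real slow oscillations and is what makes a stimulus
# delay of a few tens of ms able to coincide with the predicted peak.
sw_kernel <- function(rate, sw_cfg) {
  dt <- 1 / rate
  t_down <- sw_cfg$t_trough
  t_rise <- sw_cfg$t_rise
  t_fall <- sw_cfg$t_fall
  down <- -sw_cfg$down_frac * sin(pi * seq(dt, t_down, by = dt) / (2 * t_down))^2
  rise_t <- seq(dt, t_rise, by = dt)
  rise <- -sw_cfg$down_frac +
    (1 + sw_cfg$down_frac) * sin(pi * rise_t / (2 * t_rise))^2
  fall <- cos(pi * seq(dt, t_fall, by = dt) / (2 * t_fall))^2
  k <- c(down, rise, fall)
  attr(k, "peak_idx") <- length(down) + length(rise)
  k
}

#' Add stimulation-evoked responses to a recording
#'
#' For every real-condition marker, adds a damped 1-Hz oscillatory response
#' with the frontal slow-wave topography: a negative deflection centred in
#' the 0.5-1 s window and a positive second peak centred in the 1-1.5 s
#' window after the stimulus. The kernel is scaled so that, per unit
#' responsiveness and unit night gain, the mean Fz voltage over the
#' configured scoring window (default 1-1.5 s) equals `config$evoked$peak_uv`.
#' Sham markers add nothing; the addition is purely additive and leaves all
#' other samples untouched.
#'
#' @param rec a `plas_recording`.
#' @param markers marker data.frame (see [detect_stream()]); may be empty.
#' @param profile the participant profile the recording belongs to.
#' @param config configuration from [plas_config()].
#' @return The recording with the evoked responses added.
#' @export
inject_evoked_response <- function(rec, markers, profile,
                                   config = plas_config()) {
  stopifnot(inherits(rec, "plas_recording"))
  if (is.null(markers) || nrow(markers) == 0) return(rec)
  if (!is.null(markers$night) && any(markers$night != rec$night))
    stop("markers belong to night(s) ",
         paste(unique(markers$night[markers$night != rec$night]), collapse = ", "),
         " but the recording is night ", rec$night)
  dur_s <- ncol(rec$data) / rec$rate
  bad <- markers$time_s < 0 | markers$time_s >= dur_s
  if (any(bad))
    stop("marker time(s) outside recording: ",
         paste(sprintf("%.3f", markers$time_s[bad]), collapse = ", "))
  real <- markers[markers$condition == "real", , drop = FALSE]
  if (nrow(real) == 0) return(rec)

  ev <- config$evoked
  kern <- evoked_kernel(rec$rate, ev)
  gain <- night_gain_for(profile, rec$night)
  amp <- (profile$responsiveness %||% 1) * gain
  if (amp == 0) return(rec)
  topo <- channel_topography(rec$layout, "Fz", config$sw$topo_sigma)
  nsamp <- ncol(rec$data)
  for (tm in real$time_s) {
    i0 <- round(tm * rec$rate) + 1L
    idx <- i0:(i0 + length(kern) - 1L)
    keep <- idx >= 1L & idx <= nsamp
    rec$data[, idx[keep]] <- rec$data[, idx[keep]] +
      amp * tcrossprod(topo, kern[keep])
  }
  rec
}

# Damped-oscillation evoked kernel over [0, t_off] s post-stimulus:
# Hann-windowed 1-Hz cosine aligned so the trough falls at 0.75 s and the
# positive peak at 1.25 s. Scaled so the mean over the scoring window is
# exactly peak_uv.
evoked_kernel <- function(rate, ev) {
  tt <- seq(0, ev$t_off, by = 1 / rate)
  w <- ifelse(tt >= ev$t_on & tt <= ev$t_off,
              sin(pi * (tt - ev$t_on) / (ev$t_off - ev$t_on))^2, 0)
  centre <- (ev$score_window[1] + ev$score_window[2]) / 2
  k <- w * cos(2 * pi * ev$f * (tt - centre))
  win <- tt >= ev$score_window[1] & tt <= ev$score_window[2]
  k * ev$peak_uv / mean(k[win])
}
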