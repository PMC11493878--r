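#' Morlet wavelet time-frequency transform
#'
#' Per-trial complex Morlet convolution (FFT-based), power averaged over
#' trials. The wavelet at each frequency has a Gaussian envelope of
#' `cycles/(2*pi*f)` SD, with the cycle count increasing linearly across
#' the frequency grid (default 3 to 7 cycles from the lowest to the
#' highest frequency); each wavelet is normalised to unit gain at its
#' centre frequency. Time bins lying within two envelope SDs of the epoch
#' edges are flagged in the `edge_mask` attribute (freq x time) as
#' contaminated by the wavelet support.
#'
#' @param epochs a `plas_epochs` object whose window covers `t_range`.
#' @param freqs frequency grid in Hz (default 0.5-20 in 0.5 Hz steps).
#' @param cycles two-element range of Morlet cycles mapped linearly onto
#'   `freqs`, or a vector of one cycle count per frequency.
#' @param t_range time range retained in the output (default -1.5 to 2.5 s).
#' @return list of class `plas_tfr`: `power` (channels x frequencies x
#'   times, linear uV^2), `freqs`, `times`, `night`, `n_stimulations`,
#'   `units = "linear"`, and attribute `edge_mask`.
#' @export
morlet_tfr <- function(epochs, freqs = seq(0.5, 20, by = 0.5),
                       cycles = c(3, 7), t_range = c(-1.5, 2.5)) {
  stopifnot(inherits(epochs, "plas_epochs"))
  rate <- epochs$rate
  times <- epochs$times
  if (t_range[1] < times[1] - 1e-9 || t_range[2] > times[length(times)] + 1e-9)
    stop("epoch window does not cover the requested time range")
  if (length(cycles) == 2 && length(freqs) != 2)
    cycles <- cycles[1] + (cycles[2] - cycles[1]) *
      (freqs - min(freqs)) / max(max(freqs) - min(freqs), 1e-12)
  if (length(cycles) != length(freqs))
    stop("cycles must be a range or one value per frequency")

  ntime <- length(times)
  epoch_dur <- (ntime - 1) / rate
  sigmas <- cycles / (2 * pi * freqs)
  if (any(2 * sigmas > epoch_dur))
    stop("frequency below the resolvable limit for this epoch length: ",
         paste(freqs[2 * sigmas > epoch_dur], collapse = ", "), " Hz")

  d <- dim(epochs$epochs)  # trials x channels x time
  nser <- d[1] * d[2]
  X <- matrix(aperm(epochs$epochs, c(3, 1, 2)), ntime, nser)
  nfft <- nextn(2 * ntime, 2)
  FX <- mvfft(rbind(X, matrix(0, nfft - ntime, nser)))

  keep <- times >= t_range[1] - 1e-9 & times <= t_range[2] + 1e-9
  out_times <- times[keep]
  power <- array(0, dim = c(d[2], length(freqs), sum(keep)))
  edge <- matrix(FALSE, length(freqs), sum(keep))
  for (fi in seq_along(freqs)) {
    sig <- sigmas[fi]
    half <- min(floor(4 * sig * rate), floor((nfft - 1) / 2))
    tw <- (-half:half) / rate
    w <- exp(2i * pi * freqs[fi] * tw) * exp(-tw^2 / (2 * sig^2))
    w <- w / sum(exp(-tw^2 / (2 * sig^2)))  # unit gain at centre frequency
    wp <- complex(real = numeric(nfft))
    wp[1:(half + 1)] <- w[(half + 1):(2 * half + 1)]
    wp[(nfft - half + 1):nfft] <- w[1:half]
    conv <- mvfft(FX * as.vector(fft(wp)), inverse = TRUE) / nfft
    p <- Mod(conv[seq_len(ntime), , drop = FALSE])^2
    dim(p) <- c(ntime, d[1], d[2])
    power[, fi, ] <- t(colMeans(aperm(p, c(2, 1, 3)))[keep, , drop = FALSE])
    edge[fi, ] <- out_times - times[1] < 2 * sig |
                  times[ntime] - out_times < 2 * sig
  }
  dimnames(power) <- list(epochs$channel_names, NULL, NULL)
  structure(list(power = power, freqs = freqs, times = out_times,
                 channel_names = epochs$channel_names,
                 night = epochs$night, n_stimulations = epochs$n_stimulations,
                 units = "linear"),
            edge_mask = edge, class = "plas_tfr")
}

#' dB baseline normalisation of a time-frequency map
#'
#' Expresses power relative to the mean power in the baseline window
#' (default 2-2.5 s post-stimulus, the quietest part of the epoch), per
#' channel and frequency: `10*log10(power / baseline mean)`.
#'
#' @param tfr a linear-power `plas_tfr`.
#' @param window baseline window in seconds.
#' @return The `plas_tfr` in dB units.
#' @export
baseline_db <- function(tfr, window = c(2, 2.5)) {
  stopifnot(inherits(tfr, "plas_tfr"))
  if (!identical(tfr$units, "linear")) stop("tfr is already baseline-normalised")
  wi <- tfr$times >= window[1] & tfr$times <= window[2]
  if (!any(wi)) stop("baseline window outside the time axis")
  base <- rowMeans(tfr$power[, , wi, drop = FALSE], dims = 2)
  if (any(base <= 0)) stop("degenerate input: zero baseline power")
  tfr$power <- 10 * log10(tfr$power / as.vector(base))
  tfr$units <- "dB"
  tfr$baseline_window <- window
  tfr
}

#' Cluster permutation over time-frequency maps
#'
#' [cluster_permutation()] specialised to channel x frequency x time grids
#' of per-trial (or per-participant) time-frequency power, with the
#' stricter default alpha used for spectral contrasts.
#'
#' @param a,b arrays of observations x channels x frequencies x times.
#' @param alpha cluster significance level (default 0.01).
#' @param n_perm,adjacency,cf_alpha as in [cluster_permutation()].
#' @return A `plas_clusters` object.
#' @export
tfr_cluster <- function(a, b, alpha = 0.01, n_perm = 1000, adjacency = NULL,
                        cf_alpha = 0.05) {
  cluster_permutation(a, b, alpha = alpha, n_perm = n_perm,
                      adjacency = adjacency, cf_alpha = cf_alpha)
}

#' Proportion of channels inside significant clusters
#'
#' For each time-frequency bin, the fraction of (good) channels that belong
#' to any significant cluster at that bin -- the map used to visualise the
#' spatial extent of spectral perturbations.
#'
#' @param clusters a `plas_clusters` result on a channel x freq x time grid.
#' @param n_channels total number of good channels (defaults to the grid's
#'   channel dimension).
#' @return matrix frequencies x times with values in \[0, 1\].
#' @export
significant_channel_fraction <- function(clusters, n_channels = NULL) {
  stopifnot(inherits(clusters, "plas_clusters"))
  lab <- clusters$labels
  if (length(dim(lab)) != 3) stop("clusters were not computed on a channel x freq x time grid")
  n_channels <- n_channels %||% dim(lab)[1]
  sig_ids <- clusters$clusters$id[clusters$clusters$significant]
  member <- array(lab %in% sig_ids, dim = dim(lab))
  frac <- apply(member, c(2, 3), sum) / n_channels
  frac
}

#' Band specification for spectral response scores
#'
#' The five analysis bands with their frequency limits and electrode
#' subsets: slow waves 0.75-1.5 Hz, delta 1-4 Hz, theta 4-8 Hz, spindle
#' 12-16 Hz, beta 16-20 Hz. The spindle band uses the 13 centroparietal
#' electrodes around Cz; all other bands use the 17 frontal electrodes
#' around Fz. The time window defaults to the induced-second-peak window.
#'
#' @param name one of `"sw"`, `"delta"`, `"theta"`, `"spindle"`, `"beta"`.
#' @param layout electrode layout for the channel subsets.
#' @param window time window in seconds (default `c(1, 1.5)`).
#' @return list of class `plas_band`: `name`, `f_lo`, `f_hi`, `t_lo`,
#'   `t_hi`, `channel_set`.
#' @export
band_spec <- function(name = c("sw", "delta", "theta", "spindle", "beta"),
                      layout, window = c(1, 1.5)) {
  name <- match.arg(name)
  lims <- list(sw = c(0.75, 1.5), delta = c(1, 4), theta = c(4, 8),
               spindle = c(12, 16), beta = c(16, 20))[[name]]
  channels <- if (name == "spindle") nearest_channels(layout, "Cz", 13)
              else nearest_channels(layout, "Fz", 17)
  structure(list(name = name, f_lo = lims[1], f_hi = lims[2],
                 t_lo = window[1], t_hi = window[2], channel_set = channels),
            class = "plas_band")
}

#' Band-specific spectral response score
#'
#' Per experimental night, the median dB power over the band's channels,
#' frequencies and time window minus the same median in the baseline
#' night; nights combined as a stimulation-count-weighted mean.
#'
#' @param tfrs named list of dB-normalised `plas_tfr` objects for `BL`,
#'   `E1`, `E2`, `E3`.
#' @param band a `plas_band` from [band_spec()].
#' @param participant_id optional id.
#' @return list of class `plas_response_score` (value in dB).
#' @export
band_response_score <- function(tfrs, band, participant_id = NA_character_) {
  missing <- setdiff(NIGHTS, names(tfrs))
  if (length(missing)) stop("missing night(s): ", paste(missing, collapse = ", "))
  med <- function(tfr) {
    chi <- match(intersect(band$channel_set, tfr$channel_names), tfr$channel_names)
    fi <- which(tfr$freqs >= band$f_lo & tfr$freqs <= band$f_hi)
    ti <- which(tfr$times >= band$t_lo & tfr$times <= band$t_hi)
    if (!length(chi) || !length(fi) || !length(ti))
      stop("empty band selection for band ", band$name)
    stats::median(tfr$power[chi, fi, ti])
  }
  base <- med(tfrs$BL)
  d <- vapply(c("E1", "E2", "E3"), function(n) med(tfrs[[n]]) - base, numeric(1))
  w <- vapply(c("E1", "E2", "E3"), function(n) as.numeric(tfrs[[n]]$n_stimulations),
              numeric(1))
  if (any(w <= 0)) stop("every experimental night needs a positive stimulation count")
  structure(list(participant_id = participant_id, value = sum(w * d) / sum(w),
                 per_night = d, weights_used = w, band = band$name),
            class = "plas_response_score")
}

#' Summed PLAS-evoked activity
#'
#' The per-participant, per-night statistic capturing both the height and
#' the extent of induced spectral change: the group-level significant
#' cluster mask is restricted to the post-stimulation window (0-2.5 s) and
#' frequencies up to 16 Hz; within the mask each bin contributes the
#' absolute dB power ratio of experimental over baseline night,
#' `|10*log10(P_exp/P_bl)|`; bins more than 1.5 SD above the participant's
#' mean (over masked bins; optionally two-sided) are excluded; the
#' remaining bins are summed.
#'
#' @param tfr_exp,tfr_bl linear-power `plas_tfr` maps on a shared grid.
#' @param mask logical array on the channels x freqs x times grid, or a
#'   freqs x times matrix broadcast over channels (the group-level
#'   significant-cluster mask).
#' @param night night label carried into the result.
#' @param t_lim,f_lim mask restriction (defaults 0-2.5 s, 0-16 Hz).
#' @param outlier_sd SD multiple for bin exclusion (default 1.5).
#' @param two_sided exclude bins on both sides of the mean (default FALSE:
#'   upper tail only, since values are absolute).
#' @param participant_id optional id.
#' @return list of class `plas_summed_activity`: `participant_id`, `night`,
#'   `value` (>= 0), `n_bins_used`, `n_bins_excluded`.
#' @export
summed_activity <- function(tfr_exp, tfr_bl, mask, night = tfr_exp$night,
                            t_lim = c(0, 2.5), f_lim = c(0, 16),
                            outlier_sd = 1.5, two_sided = FALSE,
                            participant_id = NA_character_) {
  stopifnot(identical(dim(tfr_exp$power), dim(tfr_bl$power)))
  d <- dim(tfr_exp$power)
  if (is.matrix(mask)) mask <- aperm(array(mask, dim = d[c(2, 3, 1)]), c(3, 1, 2))
  stopifnot(identical(dim(mask), d))
  fi <- tfr_exp$freqs >= f_lim[1] & tfr_exp$freqs <= f_lim[2]
  ti <- tfr_exp$times >= t_lim[1] & tfr_exp$times <= t_lim[2]
  restricted <- mask
  restricted[, !fi, ] <- FALSE
  restricted[, , !ti] <- FALSE
  if (!any(restricted)) {
    warning("empty restricted mask; summed activity is 0")
    return(structure(list(participant_id = participant_id, night = night,
                          value = 0, n_bins_used = 0L, n_bins_excluded = 0L),
                     class = "plas_summed_activity"))
  }
  v <- abs(10 * log10(tfr_exp$power[restricted] / tfr_bl$power[restricted]))
  mu <- mean(v)
  s <- stats::sd(v)
  excl <- if (is.na(s) || s == 0) rep(FALSE, length(v))
          else if (two_sided) abs(v - mu) > outlier_sd * s
          else v - mu > outlier_sd * s
  structure(list(participant_id = participant_id, night = night,
                 value = sum(v[!excl]),
                 n_bins_used = sum(!excl), n_bins_excluded = sum(excl)),
            class = "plas_summed_activity")
}

#' Night trends and per-night group tests of summed activity
#'
#' Per group, an ordinary least-squares regression of summed activity on
#' the experimental night index (E1=1, E2=2, E3=3) pooling participants,
#' reporting the slope t, adjusted R-squared and p; plus, per night, a
#' pooled-variance two-sample t test between groups.
#'
#' @param summed data.frame with columns `participant_id`, `group`
#'   (`"HC"`/`"CI"`), `night` (`"E1"`..`"E3"`), `value`.
#' @return list of class `plas_night_trends`: `trend` data.frame (per
#'   group: slope, t, adj_r2, p, n) and `group_tests` data.frame (per
#'   night: t, df, p, mean difference HC - CI).
#' @export
night_trend_and_group_tests <- function(summed) {
  need <- c("participant_id", "group", "night", "value")
  if (!all(need %in% names(summed)))
    stop("summed table needs columns: ", paste(need, collapse = ", "))
  summed$night_idx <- match(summed$night, c("E1", "E2", "E3"))
  if (anyNA(summed$night_idx)) stop("nights must be E1, E2 or E3")
  trend <- do.call(rbind, lapply(split(summed, summed$group), function(d) {
    if (length(unique(d$participant_id)) < 2)
      stop("group ", d$group[1], " has fewer than 2 participants")
    if (stats::sd(d$value) == 0)  # zero-variance input carries no trend
      return(data.frame(group = d$group[1], slope = 0, t = 0, adj_r2 = 0,
                        p = 1, n = nrow(d)))
    fit <- lm(value ~ night_idx, data = d)
    s <- summary(fit)
    co <- s$coefficients["night_idx", ]
    tval <- unname(co["t value"])
    pval <- unname(co["Pr(>|t|)"])
    if (!is.finite(tval)) { tval <- 0; pval <- 1 }
    data.frame(group = d$group[1], slope = unname(co["Estimate"]),
               t = tval, adj_r2 = s$adj.r.squared,
               p = pval, n = nrow(d))
  }))
  rownames(trend) <- NULL
  gt <- do.call(rbind, lapply(c("E1", "E2", "E3"), function(n) {
    d <- summed[summed$night == n, ]
    hc <- d$value[d$group == "HC"]
    ci <- d$value[d$group == "CI"]
    if (stats::sd(hc) == 0 && stats::sd(ci) == 0) {
      d0 <- mean(hc) - mean(ci)
      return(data.frame(night = n, t = if (d0 == 0) 0 else sign(d0) * Inf,
                        df = length(hc) + length(ci) - 2,
                        p = if (d0 == 0) 1 else 0, mean_diff = d0))
    }
    tt <- two_sample_t(x = hc, y = ci)
    data.frame(night = n, t = tt$t, df = tt$df, p = tt$p,
               mean_diff = mean(hc) - mean(ci))
  }))
  structure(list(trend = trend, group_tests = gt),
            class = "plas_night_trends")
}
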