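# Shared fixtures, built in code at test time.

# A small configuration for signal-level tests: fewer channels, quiet
# settings left at their defaults unless a test overrides them.
small_config <- function(...) {
  plas_config(n_channels = 16, ...)
}

test_profile <- function(group = "HC", responsiveness = 1, sw_density = 4,
                         night_gain = c(1, 1, 1), id = "T01") {
  list(id = id, group = group, responsiveness = responsiveness,
       sw_density = sw_density, night_gain = night_gain,
       memory_slope = 1.5, abeta_slope = if (group == "CI") 0.002 else 0)
}

# Noise-free recording with slow-wave events at chosen peak times: the
# controlled signal used to benchmark the online detector against the
# offline oracle. All epochs are scored N2.
make_spaced_night <- function(peak_times, duration_s = 120, n_channels = 16,
                              amp = 75, night = "E1", invert_topo = FALSE,
                              config = small_config(noise = list(sd = 0, alpha = 1))) {
  rate <- config$rate
  layout <- spiral_layout(n_channels)
  nsamp <- round(duration_s * rate)
  data <- matrix(0, n_channels, nsamp)
  kern <- plaslab:::sw_kernel(rate, config$sw)
  topo <- plaslab:::channel_topography(layout, "Fz", config$sw$topo_sigma)
  if (invert_topo) topo <- -topo
  pre <- attr(kern, "peak_idx") - 1L
  post <- length(kern) - attr(kern, "peak_idx")
  for (tp in peak_times) {
    i <- round(tp * rate) + 1L
    stopifnot(i > pre, i + post <= nsamp)
    data[, (i - pre):(i + post)] <- data[, (i - pre):(i + post)] +
      amp * tcrossprod(topo, kern)
  }
  structure(list(data = data, rate = rate, channel_names = layout$name,
                 layout = layout,
                 hypnogram = rep("N2", floor(duration_s / 30)),
                 events = data.frame(onset_s = peak_times,
                                     kind = rep("sw_peak", length(peak_times)),
                                     amplitude = rep(amp, length(peak_times))),
                 night = night, participant = "T01"),
            class = "plas_recording")
}

# Brute-force reference for the summed-activity statistic: explicit loop
# over masked bins, the stated exclusion rule, accumulation in bin order.
brute_summed_activity <- function(p_exp, p_bl, mask, freqs, times,
                                  t_lim = c(0, 2.5), f_lim = c(0, 16),
                                  outlier_sd = 1.5) {
  vals <- numeric(0)
  d <- dim(p_exp)
  for (tt in seq_len(d[3])) for (ff in seq_len(d[2])) for (ch in seq_len(d[1])) {
    if (!mask[ch, ff, tt]) next
    if (freqs[ff] < f_lim[1] || freqs[ff] > f_lim[2]) next
    if (times[tt] < t_lim[1] || times[tt] > t_lim[2]) next
    vals <- c(vals, abs(10 * log10(p_exp[ch, ff, tt] / p_bl[ch, ff, tt])))
  }
  if (!length(vals)) return(0)
  keep <- vals <= mean(vals) + outlier_sd * stats::sd(vals)
  if (all(is.na(keep))) keep <- rep(TRUE, length(vals))
  sum(vals[keep])
}

# plas_tfr stand-in built from a raw power array.
fake_tfr <- function(power, freqs, times, night = "E1", n_stim = 100,
                     units = "linear") {
  structure(list(power = power, freqs = freqs, times = times,
                 channel_names = paste0("E", seq_len(dim(power)[1])),
                 night = night, n_stimulations = n_stim, units = units),
            class = "plas_tfr")
}

# simple chain adjacency 1-2-3-...-n
chain_adjacency <- function(n) {
  lapply(seq_len(n), function(i) setdiff(intersect(c(i - 1, i + 1), seq_len(n)), i))
}
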