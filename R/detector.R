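#' Canonical slow-wave peak template
#'
#' Builds the topographic template the online detector correlates against:
#' a frontal-positive, posterior-negative gradient map derived from the
#' layout (Gaussian falloff from Fz, centred across channels, unit L2
#' norm), together with the frontal channel subset used for the rising
#' voltage criterion. Deterministic given the layout.
#'
#' @param layout layout data.frame from [spiral_layout()].
#' @param config configuration (uses `sw$topo_sigma`, `detector$n_frontal`).
#' @return list of class `plas_template`: `weights` (named, unit norm) and
#'   `frontal_channels`.
#' @export
build_template <- function(layout, config = plas_config()) {
  if (!all(c("Fz", "Cz") %in% layout$name))
    stop("layout must contain the Fz and Cz anchor channels")
  topo <- channel_topography(layout, "Fz", config$sw$topo_sigma)
  w <- topo - mean(topo)
  w <- w / sqrt(sum(w^2))
  names(w) <- layout$name
  structure(list(weights = w,
                 frontal_channels = nearest_channels(layout, "Fz",
                                                     config$detector$n_frontal)),
            class = "plas_template")
}

#' Detector parameters
#'
#' @param window_ms trailing analysis window (default 120 ms).
#' @param criterion rising-sign criterion threshold in (0, 1] (default 0.75).
#' @param delay_ms stimulus delay after the criterion crossing, calibrated
#'   to coincide with the predicted slow-wave peak (default 50 ms).
#' @param stimulus_ms stimulus duration (50 ms pink noise burst; logged
#'   only, no audio is synthesised).
#' @param refractory_s lockout after each stimulus (default 2.5 s).
#' @param smooth_ms causal moving-average applied to the voltage and
#'   similarity series before the derivative-sign criterion (default
#'   40 ms). Online slow-wave detection operates on delta-band-limited
#'   data; the trailing average is the causal equivalent and its group
#'   delay is absorbed by the calibrated stimulus delay.
#' @param gating sleep stages in which stimulation is allowed.
#' @param similarity `"covariance"` (centred template projection, default)
#'   or `"pearson"` (spatial correlation coefficient).
#' @return list of class `plas_detector_params`.
#' @export
detector_params <- function(window_ms = 120, criterion = 0.75, delay_ms = 50,
                            stimulus_ms = 50, refractory_s = 2.5,
                            gating = c("N2", "N3"),
                            similarity = c("covariance", "pearson"),
                            smooth_ms = 40) {
  stopifnot(window_ms > 0, criterion > 0, criterion <= 1, refractory_s >= 0,
            smooth_ms >= 0)
  structure(list(window_ms = window_ms, criterion = criterion,
                 delay_ms = delay_ms, stimulus_ms = stimulus_ms,
                 refractory_s = refractory_s, gating = gating,
                 similarity = match.arg(similarity), smooth_ms = smooth_ms),
            class = "plas_detector_params")
}

# Topographic similarity time series between every instantaneous scalp map
# and the template: centred covariance (matched-filter projection) or
# Pearson correlation across channels.
template_similarity <- function(data, weights, method = "covariance") {
  nch <- nrow(data)
  cm <- colMeans(data)
  cent <- as.vector(crossprod(weights, data)) - sum(weights) * cm
  if (method == "pearson") {
    css <- colSums(data^2) - nch * cm^2
    denom <- sqrt(pmax(css, 1e-12) * sum((weights - mean(weights))^2))
    cent / denom
  } else {
    cent / (nch - 1)
  }
}

#' Online slow-wave peak prediction
#'
#' Causal re-implementation of the template-based stimulation algorithm.
#' At every sample it tracks (a) the mean voltage over the frontal channel
#' subset and (b) the topographic similarity of the instantaneous scalp map
#' to the slow-wave template. When, within the trailing 120 ms window, the
#' average sign of the first derivative of *each* series exceeds the
#' criterion (default 0.75) -- i.e. both voltage and template similarity are
#' clearly rising -- and the instantaneous map is positively correlated
#' with the template, a peak prediction is scored and a marker is emitted at
#' the current time plus `delay_ms`. A refractory lockout suppresses
#' retriggering on the stimulation-evoked response, and predictions are only
#' scored in gated sleep stages (N2/N3 by default). No sample after the
#' current one is ever inspected.
#'
#' @param rec a `plas_recording` (or `plas_clean_recording`).
#' @param template template from [build_template()].
#' @param params parameters from [detector_params()].
#' @param condition `"real"` (stimulation nights E1-E3) or `"sham"`
#'   (baseline night: markers are placed but no sound would be played).
#' @param audit keep the triggering 120-ms voltage/similarity traces as an
#'   attribute for inspection.
#' @return data.frame of class `plas_markers` with columns `time_s`
#'   (predicted peak = stimulus onset time), `condition`, `night`,
#'   `delay_ms`. The stimulus descriptor (50 ms pink noise) is carried as
#'   an attribute.
#' @export
detect_stream <- function(rec, template, params = detector_params(),
                          condition = c("real", "sham"), audit = FALSE) {
  condition <- match.arg(condition)
  if (condition == "real" && rec$night == "BL")
    stop("real stimulation markers are only placed on experimental nights (E1-E3)")
  if (condition == "sham" && rec$night != "BL")
    stop("sham markers are only placed on the baseline night")

  rate <- rec$rate
  win <- round(params$window_ms / 1000 * rate)
  if (win < 3) stop("window_ms spans fewer than 3 samples at this rate")
  nsamp <- ncol(rec$data)

  fidx <- match(template$frontal_channels, rec$channel_names)
  if (anyNA(fidx)) stop("frontal channels missing from recording")
  v <- colMeans(rec$data[fidx, , drop = FALSE])
  cc <- template_similarity(rec$data, template$weights[rec$channel_names],
                            params$similarity)
  ksm <- max(1L, round((params$smooth_ms %||% 0) / 1000 * rate))
  if (ksm > 1) {
    pad_idx <- ksm:(nsamp + ksm - 1L)  # windows ending at each original sample
    v <- running_mean(c(rep(v[1], ksm - 1), v), ksm)[pad_idx]
    cc <- running_mean(c(rep(cc[1], ksm - 1), cc), ksm)[pad_idx]
  }

  k <- win - 1L  # number of first differences in the half-open window
  rs_v <- running_mean(sign(diff(v)), k)
  rs_c <- running_mean(sign(diff(cc)), k)
  crit <- rep(FALSE, nsamp)
  full <- win:nsamp  # samples with a complete trailing window
  crit[full] <- rs_v[full - 1L] > params$criterion &
                rs_c[full - 1L] > params$criterion
  # polarity gate: predictions require the current scalp map to match the
  # canonical slow-wave topography (positive template similarity), so an
  # anticorrelated pattern whose projection merely decays back to baseline
  # cannot trigger a stimulus
  crit <- crit & cc > 0

  gate <- stage_mask(rec, params$gating)
  if (!any(gate)) {
    warning("no samples in gated stages (", paste(params$gating, collapse = "/"),
            "); returning no markers")
    return(empty_markers(rec$night))
  }
  crit <- crit & gate

  cand <- which(crit)
  times <- numeric(0)
  trig <- integer(0)
  last <- -Inf
  delay_s <- params$delay_ms / 1000
  for (i in cand) {
    tm <- (i - 1) / rate + delay_s
    if (tm - last >= params$refractory_s) {
      times <- c(times, tm)
      trig <- c(trig, i)
      last <- tm
    }
  }
  out <- data.frame(time_s = times,
                    condition = rep(condition, length(times)),
                    night = rep(rec$night, length(times)),
                    delay_ms = rep(params$delay_ms, length(times)),
                    stringsAsFactors = FALSE)
  class(out) <- c("plas_markers", "data.frame")
  attr(out, "stimulus") <- list(kind = "pink_noise",
                                duration_ms = params$stimulus_ms,
                                level_db = 50)
  if (audit) {
    attr(out, "lead_series") <- lapply(trig, function(i) {
      idx <- max(1, i - win + 1):i
      list(voltage = v[idx], similarity = cc[idx])
    })
  }
  out
}

empty_markers <- function(night) {
  out <- data.frame(time_s = numeric(), condition = character(),
                    night = character(), delay_ms = numeric(),
                    stringsAsFactors = FALSE)
  class(out) <- c("plas_markers", "data.frame")
  out
}

# trailing (causal) running mean over the last k values
running_mean <- function(x, k) {
  cs <- cumsum(x)
  (cs - c(rep(0, k), cs[seq_len(length(x) - k)])) / k
}

# per-sample logical mask of the given sleep stages
stage_mask <- function(rec, stages) {
  if (is.null(rec$hypnogram)) stop("recording has no hypnogram")
  nsamp <- ncol(rec$data)
  ep <- pmin(length(rec$hypnogram), floor((seq_len(nsamp) - 1) / (30 * rec$rate)) + 1)
  rec$hypnogram[ep] %in% stages
}

#' Calibrate the stimulus delay against ground-truth peaks
#'
#' Runs the detector with zero delay and returns the median lead time from
#' criterion crossing to the nearest subsequent true slow-wave peak,
#' clipped to \[0, 200\] ms -- the delay that makes the stimulus coincide
#' with the predicted peak.
#'
#' @param rec recording with >= 10 ground-truth `sw_peak` events.
#' @param template,params as for [detect_stream()].
#' @param truth_events optional event table (defaults to `rec$events`).
#' @param max_lead_s match window for crossing-to-peak pairing (default 1 s).
#' @return calibrated delay in ms.
#' @export
calibrate_delay <- function(rec, template, params = detector_params(),
                            truth_events = NULL, max_lead_s = 1) {
  truth <- truth_events %||% rec$events
  peaks <- truth$onset_s[truth$kind == "sw_peak"]
  if (length(peaks) < 10)
    stop("calibration needs at least 10 ground-truth sw_peak events (have ",
         length(peaks), ")")
  p0 <- params
  p0$delay_ms <- 0
  cond <- if (rec$night == "BL") "sham" else "real"
  crossings <- detect_stream(rec, template, p0, condition = cond)$time_s
  if (!length(crossings)) stop("calibration failed: no detections on this recording")
  leads <- vapply(crossings, function(tc) {
    ahead <- peaks[peaks >= tc & peaks <= tc + max_lead_s]
    if (length(ahead)) (ahead[1] - tc) * 1000 else NA_real_
  }, numeric(1))
  leads <- leads[!is.na(leads)]
  if (!length(leads)) stop("calibration failed: no crossing matched a true peak")
  min(max(stats::median(leads), 0), 200)
}

#' Benchmark markers against ground-truth events
#'
#' Greedy one-to-one matching of markers to the nearest true slow-wave
#' peaks within a tolerance, by increasing absolute offset.
#'
#' @param markers marker table from [detect_stream()].
#' @param truth_events event table with `onset_s` and `kind`.
#' @param tolerance_ms maximum |offset| for a match (> 0).
#' @return list of class `plas_detection_metrics`: `n_markers`, `precision`,
#'   `recall`, `phase_error_ms` (signed marker minus matched peak),
#'   `median_abs_error_ms`, and `precision_undefined` (TRUE when there were
#'   no markers, in which case precision is reported as 0).
#' @export
evaluate_detection <- function(markers, truth_events, tolerance_ms = 100) {
  if (tolerance_ms <= 0) stop("tolerance_ms must be positive")
  peaks <- truth_events$onset_s[truth_events$kind == "sw_peak"]
  mt <- markers$time_s
  n_m <- length(mt)
  n_t <- length(peaks)
  if (n_m == 0 || n_t == 0) {
    return(structure(list(n_markers = n_m,
                          precision = 0, recall = if (n_t == 0) NA_real_ else 0,
                          phase_error_ms = numeric(0),
                          median_abs_error_ms = NA_real_,
                          precision_undefined = n_m == 0),
                     class = "plas_detection_metrics"))
  }
  tol <- tolerance_ms / 1000
  pairs <- expand.grid(m = seq_len(n_m), t = seq_len(n_t))
  pairs$off <- mt[pairs$m] - peaks[pairs$t]
  pairs <- pairs[abs(pairs$off) <= tol, , drop = FALSE]
  pairs <- pairs[order(abs(pairs$off)), , drop = FALSE]
  used_m <- logical(n_m)
  used_t <- logical(n_t)
  err <- numeric(0)
  for (r in seq_len(nrow(pairs))) {
    m <- pairs$m[r]; t <- pairs$t[r]
    if (!used_m[m] && !used_t[t]) {
      used_m[m] <- used_t[t] <- TRUE
      err <- c(err, pairs$off[r] * 1000)
    }
  }
  structure(list(n_markers = n_m,
                 precision = sum(used_m) / n_m,
                 recall = sum(used_t) / n_t,
                 phase_error_ms = err,
                 median_abs_error_ms = if (length(err)) stats::median(abs(err)) else NA_real_,
                 precision_undefined = FALSE),
            class = "plas_detection_metrics")
}

#' Offline argmax peak oracle
#'
#' Non-causal reference detector used to benchmark the online algorithm:
#' finds local maxima of the mean frontal voltage that exceed a threshold
#' and are separated by a minimum distance.
#'
#' @param rec recording.
#' @param frontal_channels channels to average (default the 17 nearest Fz).
#' @param min_height minimum peak height in uV.
#' @param min_dist_s minimum separation between peaks in seconds.
#' @return numeric vector of peak times (s).
#' @export
offline_peak_oracle <- function(rec, frontal_channels = NULL,
                                min_height = 20, min_dist_s = 0.5) {
  fch <- frontal_channels %||% nearest_channels(rec$layout, "Fz", 17)
  v <- colMeans(rec$data[match(fch, rec$channel_names), , drop = FALSE])
  n <- length(v)
  is_peak <- c(FALSE, v[2:(n - 1)] > v[1:(n - 2)] & v[2:(n - 1)] >= v[3:n], FALSE)
  cand <- which(is_peak & v > min_height)
  cand <- cand[order(-v[cand])]
  keep <- numeric(0)
  min_dist <- min_dist_s * rec$rate
  for (i in cand) {
    if (!length(keep) || all(abs(keep - i) >= min_dist)) keep <- c(keep, i)
  }
  sort((keep - 1) / rec$rate)
}
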