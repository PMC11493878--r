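#' Epoch a recording around stimulation markers
#'
#' Cuts one trial per marker over the window (default -1.5 to 3 s relative
#' to the stimulus, endpoints inclusive). Trials whose window extends past
#' the recording edges are dropped, as are trials overlapping any
#' artifact-masked sample when the recording carries an artifact mask. The
#' surviving trial count is the night's stimulation count used later as a
#' regression weight.
#'
#' @param rec a `plas_recording` or `plas_clean_recording`.
#' @param markers marker table (see [detect_stream()]).
#' @param window two-element window in seconds relative to each marker.
#' @return list of class `plas_epochs`: `epochs` (trials x channels x time
#'   array, uV), `times`, `channel_names`, `night`, `rate`,
#'   `n_stimulations`.
#' @export
epoch_recording <- function(rec, markers, window = c(-1.5, 3)) {
  stopifnot(inherits(rec, "plas_recording"), length(window) == 2,
            window[1] < window[2])
  rate <- rec$rate
  nsamp <- ncol(rec$data)
  rel <- round(window[1] * rate):round(window[2] * rate)
  times <- rel / rate
  centers <- round(markers$time_s * rate) + 1L
  lo <- centers + rel[1]
  hi <- centers + rel[length(rel)]
  keep <- lo >= 1L & hi <= nsamp
  if (!is.null(rec$artifact_mask)) {
    for (k in which(keep)) {
      if (any(rec$artifact_mask[lo[k]:hi[k]])) keep[k] <- FALSE
    }
  }
  if (!any(keep))
    stop("no trials survive epoching for night ", rec$night)
  centers <- centers[keep]
  good_ch <- setdiff(rec$channel_names, rec$bad_channels %||% character())
  chi <- match(good_ch, rec$channel_names)
  ep <- array(0, dim = c(length(centers), length(chi), length(rel)))
  for (k in seq_along(centers)) {
    ep[k, , ] <- rec$data[chi, (centers[k] + rel[1]):(centers[k] + rel[length(rel)])]
  }
  structure(list(epochs = ep, times = times, channel_names = good_ch,
                 night = rec$night, rate = rate,
                 n_stimulations = length(centers)),
            class = "plas_epochs")
}

#' Whole-epoch baseline correction
#'
#' Subtracts, per trial and channel, that trial-channel's mean over the
#' full epoch window from every time point, so every trial-channel trace
#' has exactly zero mean.
#'
#' @param epochs a `plas_epochs` object.
#' @return The corrected `plas_epochs`.
#' @export
baseline_correct <- function(epochs) {
  stopifnot(inherits(epochs, "plas_epochs"))
  m <- rowMeans(epochs$epochs, dims = 2)      # trials x channels
  epochs$epochs <- epochs$epochs - as.vector(m)  # recycles over time (3rd dim)
  epochs
}

#' Average epochs into an ERP
#'
#' @param epochs a (baseline-corrected) `plas_epochs` object.
#' @return list of class `plas_erp`: `erp` (channels x time mean voltage),
#'   `times`, `channel_names`, `night`, `n_stimulations`.
#' @export
erp_average <- function(epochs) {
  stopifnot(inherits(epochs, "plas_epochs"))
  erp <- apply(epochs$epochs, c(2, 3), mean)
  rownames(erp) <- epochs$channel_names
  structure(list(erp = erp, times = epochs$times,
                 channel_names = epochs$channel_names,
                 night = epochs$night,
                 n_stimulations = epochs$n_stimulations),
            class = "plas_erp")
}

#' Stimulation-count-weighted ERP response score
#'
#' The individual electrophysiological response: for each experimental
#' night the mean voltage difference (experimental minus baseline night) at
#' Fz over the second-slow-wave-peak window (default 1-1.5 s
#' post-stimulus), combined across nights E1-E3 as a weighted mean with the
#' number of stimulations per night as weights.
#'
#' @param erps named list of `plas_erp` objects for `BL`, `E1`, `E2`, `E3`.
#' @param channel scoring electrode (default `"Fz"`).
#' @param window scoring window in seconds (default `c(1, 1.5)`).
#' @param participant_id optional id carried into the result.
#' @return list of class `plas_response_score`: `participant_id`, `value`
#'   (uV), `per_night` (named differences d_E1..d_E3), `weights_used`.
#' @export
erp_response_score <- function(erps, channel = "Fz", window = c(1, 1.5),
                               participant_id = NA_character_) {
  missing <- setdiff(NIGHTS, names(erps))
  if (length(missing))
    stop("missing night(s): ", paste(missing, collapse = ", "))
  bl <- erps$BL
  if (!(channel %in% bl$channel_names))
    stop("scoring channel ", channel, " not available (bad or absent)")
  sel <- function(e) {
    wi <- e$times >= window[1] & e$times <= window[2]
    mean(e$erp[match(channel, e$channel_names), wi])
  }
  base <- sel(bl)
  d <- vapply(c("E1", "E2", "E3"), function(n) sel(erps[[n]]) - base, numeric(1))
  w <- vapply(c("E1", "E2", "E3"), function(n) as.numeric(erps[[n]]$n_stimulations),
              numeric(1))
  if (any(w <= 0) || sum(w) == 0)
    stop("every experimental night must contribute a positive stimulation count")
  structure(list(participant_id = participant_id,
                 value = sum(w * d) / sum(w),
                 per_night = d, weights_used = w),
            class = "plas_response_score")
}
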