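#' Anti-alias downsampling to the analysis rate
#'
#' Zero-phase low-pass filtering (8th-order Butterworth run forward and
#' backward) followed by decimation. Event and hypnogram timestamps are in
#' seconds and unchanged. Only integer decimation factors are supported;
#' requesting the current rate returns the recording unchanged.
#'
#' @param rec a `plas_recording`.
#' @param target_hz target sampling rate (default 200 Hz; must not exceed
#'   the recording rate).
#' @return The downsampled recording.
#' @export
downsample <- function(rec, target_hz = 200) {
  stopifnot(inherits(rec, "plas_recording"))
  if (target_hz > rec$rate)
    stop("upsampling requested (", rec$rate, " -> ", target_hz, " Hz)")
  if (target_hz == rec$rate) return(rec)
  q <- rec$rate / target_hz
  if (abs(q - round(q)) > 1e-9)
    stop("rate ", rec$rate, " is not an integer multiple of ", target_hz)
  q <- round(q)
  bf <- signal::butter(8, 0.8 / q)
  keep <- seq(1, ncol(rec$data), by = q)
  out <- matrix(0, nrow(rec$data), length(keep))
  for (ch in seq_len(nrow(rec$data))) {
    out[ch, ] <- signal::filtfilt(bf, rec$data[ch, ])[keep]
  }
  rec$data <- out
  rec$rate <- target_hz
  rec
}

#' Simplified artifact and bad-channel rejection
#'
#' A deterministic stand-in for a full preprocessing pipeline: per channel,
#' samples exceeding the amplitude limit or the sample-to-sample jump limit
#' are masked (with padding), and 1-s windows whose high-frequency activity
#' (SD of the first difference) is a z-score outlier for that channel are
#' masked as well. Channels that are flat or have more than `bad_frac` of
#' their samples masked are marked bad and do not contribute to the global
#' artifact mask; remaining per-channel masks are unioned.
#'
#' @param rec a `plas_recording`.
#' @param thresholds list with `amp_uv`, `jump_uv`, `hf_z`, `pad_s`,
#'   `bad_frac` (see [plas_config()]`$artifact`). Use `Inf` limits to
#'   disable a rule.
#' @return A `plas_clean_recording`: the recording plus `bad_channels`,
#'   `artifact_mask` (per sample), and `analysis_mask` (gated N2/N3 and
#'   artifact-free).
#' @export
reject_artifacts <- function(rec, thresholds = plas_config()$artifact) {
  stopifnot(inherits(rec, "plas_recording"))
  nch <- nrow(rec$data)
  nsamp <- ncol(rec$data)
  th <- thresholds
  pad <- round(th$pad_s * rec$rate)
  win <- rec$rate  # 1-s windows for the HF criterion

  ch_masks <- matrix(FALSE, nch, nsamp)
  bad <- logical(nch)
  for (ch in seq_len(nch)) {
    x <- rec$data[ch, ]
    if (stats::sd(x) < 1e-6) { bad[ch] <- TRUE; next }
    m <- abs(x) > th$amp_uv
    m[-1] <- m[-1] | abs(diff(x)) > th$jump_uv
    if (is.finite(th$hf_z)) {
      nwin <- floor(nsamp / win)
      if (nwin >= 3) {
        d <- abs(diff(x))
        hf <- vapply(seq_len(nwin), function(w)
          stats::sd(d[((w - 1) * win + 1):min(w * win, nsamp - 1)]), numeric(1))
        z <- (hf - mean(hf)) / max(stats::sd(hf), 1e-12)
        for (w in which(z > th$hf_z))
          m[((w - 1) * win + 1):min(w * win, nsamp)] <- TRUE
      }
    }
    if (any(m) && pad > 0) m <- pad_mask(m, pad)
    ch_masks[ch, ] <- m
    if (mean(m) > th$bad_frac) bad[ch] <- TRUE
  }
  good <- which(!bad)
  artifact <- if (length(good)) colSums(ch_masks[good, , drop = FALSE]) > 0
              else rep(TRUE, nsamp)

  rec$bad_channels <- rec$channel_names[bad]
  rec$artifact_mask <- artifact
  rec$analysis_mask <- gate_stages(rec)
  class(rec) <- unique(c("plas_clean_recording", class(rec)))
  rec
}

pad_mask <- function(m, pad) {
  idx <- which(m)
  lo <- pmax(1, idx - pad)
  hi <- pmin(length(m), idx + pad)
  out <- logical(length(m))
  for (k in seq_along(idx)) out[lo[k]:hi[k]] <- TRUE
  out
}

#' Sleep-stage gating mask
#'
#' Per-sample mask that is true exactly on samples inside 30-s epochs
#' scored in the requested stages and, when the recording carries an
#' artifact mask, not artifact-masked. All EEG analyses downstream run on
#' N2/N3 (non-REM stage 2 and slow-wave sleep) only.
#'
#' @param rec recording with a hypnogram.
#' @param stages stages to keep (default N2 and N3).
#' @return logical vector, one entry per sample.
#' @export
gate_stages <- function(rec, stages = c("N2", "N3")) {
  if (is.null(rec$hypnogram)) stop("recording has no hypnogram")
  m <- stage_mask(rec, stages)
  if (!is.null(rec$artifact_mask)) m <- m & !rec$artifact_mask
  m
}
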