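#' Measured response scores from latent profiles
#'
#' Cohort-level shortcut used for calibration studies: the measured ERP
#' response score (uV) is the latent responsiveness times the mean night
#' gain, scaled by the configured evoked peak amplitude, plus measurement
#' noise. This is the quantity the full signal-level pipeline (detect ->
#' inject -> epoch -> ERP -> weighted score) estimates.
#'
#' @param cohort a `plas_cohort` data.frame.
#' @param config configuration from [plas_config()].
#' @param seed integer seed.
#' @return numeric vector, one score per participant.
#' @export
simulate_response_scores <- function(cohort, config = plas_config(),
                                     seed = NULL) {
  gain <- rowMeans(cohort[, c("night_gain_1", "night_gain_2", "night_gain_3")])
  with_seed(seed, {
    config$evoked$peak_uv * cohort$responsiveness * gain +
      rnorm(nrow(cohort), 0, config$sim$response_noise_sd)
  })
}

#' Summed-activity table from latent profiles
#'
#' Cohort-level shortcut for the per-night summed-activity statistic:
#' `base + scale * responsiveness * night_gain + noise`, floored at zero.
#' Under the default night gains this produces the delayed-response
#' pattern: constant values across nights for HC, a rising ramp for CI,
#' and a group gap that shrinks from E1 to E3.
#'
#' @param cohort a `plas_cohort` data.frame.
#' @param config configuration.
#' @param seed integer seed.
#' @return data.frame: `participant_id`, `group`, `night` (E1-E3), `value`.
#' @export
simulate_summed_activity <- function(cohort, config = plas_config(),
                                     seed = NULL) {
  sm <- config$sim
  with_seed(seed, {
    rows <- lapply(seq_len(nrow(cohort)), function(i) {
      p <- as_profile(cohort, i)
      vals <- sm$summed_base + sm$summed_scale * p$responsiveness * p$night_gain +
        rnorm(3, 0, sm$summed_noise_sd)
      data.frame(participant_id = p$id, group = p$group,
                 night = c("E1", "E2", "E3"), value = pmax(vals, 0),
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

#' Simulate a complete participant table
#'
#' Generates a cohort and, per participant, the measured response score,
#' the memory trajectory and the amyloid records, assembled into the flat
#' per-participant table consumed by the regression functions.
#'
#' @param n_hc,n_ci group sizes.
#' @param config configuration.
#' @param seed integer seed.
#' @return data.frame, one row per participant: `id`, `group`, `age`,
#'   `gender`, `moca`, `response_score`, `score_t0`..`score_t7`,
#'   `gain_t1`..`gain_t7`, `abeta_pre`, `abeta_post`, `abeta_diff`.
#' @examples
#' tab <- simulate_participant_table(18, 16, seed = 1)
#' response_regression(tab, "abeta_diff", subset = "CI")
#' @export
simulate_participant_table <- function(n_hc, n_ci, config = plas_config(),
                                       seed = NULL) {
  with_seed(seed, {
    cohort <- generate_cohort(n_hc, n_ci, config)
    scores <- simulate_response_scores(cohort, config)
    rows <- lapply(seq_len(nrow(cohort)), function(i) {
      p <- as_profile(cohort, i)
      bb <- generate_behavior_and_biomarker(p, scores[i], config)
      out <- data.frame(id = p$id, group = p$group, age = p$age,
                        gender = p$gender, moca = p$moca,
                        response_score = scores[i], stringsAsFactors = FALSE)
      out[paste0("score_t", 0:7)] <- as.list(as.numeric(bb$behavior$scores))
      out[paste0("gain_t", 1:7)] <- as.list(as.numeric(bb$behavior$gains))
      out$abeta_pre <- bb$abeta$pre_ratio
      out$abeta_post <- bb$abeta$post_ratio
      out$abeta_diff <- bb$abeta$diff
      out
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

#' Full signal-level pipeline for one participant
#'
#' Runs the end-to-end chain for all four nights: simulate the raw night,
#' detect markers online (sham on BL, real on E1-E3), inject the
#' stimulation-evoked response for real markers, reject artifacts, epoch
#' around markers, baseline-correct, average to per-night ERPs, and
#' compute the weighted ERP response score. Intended for moderate problem
#' sizes (reduced channel counts / night durations); the cohort-level
#' shortcut functions cover large replicate studies.
#'
#' @param profile a cohort row or profile list.
#' @param config configuration.
#' @param duration_min night duration in minutes.
#' @param seed integer seed (one independent stream per night is derived
#'   from it).
#' @param ersp also compute dB ERSP maps per night (slower).
#' @return list: `markers`, `epochs`, `erps` (per night), `score`
#'   (`plas_response_score`), and optionally `tfrs`.
#' @export
run_participant_pipeline <- function(profile, config = plas_config(),
                                     duration_min = 20, seed = 1,
                                     ersp = FALSE) {
  template <- NULL
  markers <- list()
  erps <- list()
  epochs_by_night <- list()
  tfrs <- list()
  for (ni in seq_along(NIGHTS)) {
    night <- NIGHTS[ni]
    rec <- generate_night(profile, night, duration_min, config,
                          seed = seed * 13L + ni)
    if (!is.null(config$raw_rate)) rec <- downsample(rec, config$rate)
    if (is.null(template)) template <- build_template(rec$layout, config)
    params <- do.call(detector_params, config$detector[
      intersect(names(config$detector), names(formals(detector_params)))])
    cond <- if (night == "BL") "sham" else "real"
    mk <- detect_stream(rec, template, params, condition = cond)
    if (cond == "real") rec <- inject_evoked_response(rec, mk, profile, config)
    clean <- reject_artifacts(rec, config$artifact)
    ep <- baseline_correct(epoch_recording(clean, mk))
    markers[[night]] <- mk
    epochs_by_night[[night]] <- ep
    erps[[night]] <- erp_average(ep)
    if (ersp) tfrs[[night]] <- baseline_db(
      morlet_tfr(ep, freqs = config$ersp$freqs, cycles = config$ersp$cycles),
      config$ersp$baseline)
  }
  score <- erp_response_score(erps, participant_id = profile$id %||% NA)
  out <- list(markers = markers, epochs = epochs_by_night, erps = erps,
              score = score)
  if (ersp) out$tfrs <- tfrs
  out
}
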