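#' Default simulation and analysis configuration
#'
#' A single nested list drives both the synthetic cohort generator and the
#' analysis defaults. The values below are the package's study conditions:
#' sample means for age and group composition follow the studied cohort
#' (healthy, HC, vs. cognitively impaired, CI, older adults); slow-wave
#' amplitude defaults (75 uV HC / 50 uV CI, SD 15) encode the qualitative
#' finding that impaired individuals produce fewer and smaller slow waves;
#' night gains make the HC evoked response constant across stimulation
#' nights E1-E3 while the CI response ramps up.
#'
#' @param ... named overrides, merged recursively into the defaults
#'   (e.g. `plas_config(n_channels = 16, noise = list(sd = 0))`).
#'
#' @return A named list of class `plas_config`.
#'
#' @details Main entries:
#' \describe{
#'   \item{n_channels, rate}{layout size and sampling rate (Hz). Simulation
#'     runs directly at the 200 Hz analysis rate; `raw_rate` may be set
#'     higher to exercise the anti-alias downsampler.}
#'   \item{stages}{hypnogram stage proportions per sleep cycle and cycle
#'     length in minutes.}
#'   \item{sw}{slow-wave event model: Poisson density (events/min of N2+N3)
#'     and amplitude distributions per group, biphasic kernel segment times
#'     (seconds), frontal topography width (radians).}
#'   \item{spindle}{12-16 Hz burst density (events/min of N2), duration,
#'     amplitude, centroparietal topography width.}
#'   \item{noise}{1/f background: per-channel SD in uV and spectral slope.}
#'   \item{evoked}{stimulation-evoked kernel: active window post-stimulus,
#'     oscillation frequency, and `peak_uv`, the mean Fz voltage over the
#'     1-1.5 s scoring window contributed per unit responsiveness.}
#'   \item{responsiveness, night_gain}{latent per-participant response
#'     magnitude and its per-night scaling (HC constant 1; CI ramp).}
#'   \item{memory, abeta}{behavioral learning curves over sessions t0-t7
#'     (bounded by 40 items) and plasma amyloid-beta 42/40 model.}
#'   \item{detector}{online algorithm parameters: 120 ms window, 0.75
#'     rising-sign criterion, 50 ms default delay, 50 ms stimulus, 2.5 s
#'     refractory lockout, N2/N3 gating.}
#'   \item{artifact}{simplified artifact rejection thresholds.}
#'   \item{ersp}{Morlet grid 0.5-20 Hz, 3 to 7 cycles, 2-2.5 s dB baseline
#'     window, summed-activity mask limits and 1.5-SD outlier rule.}
#'   \item{cluster}{cluster-forming alpha, permutation count, channel
#'     adjacency distance (radians on the unit sphere).}
#'   \item{sim}{cohort-level shortcut model used for calibration studies:
#'     measurement noise of the response score and the linear map from
#'     latent responsiveness x night gain to summed activity.}
#' }
#'
#' @examples
#' cfg <- plas_config(n_channels = 16)
#' cfg$detector$criterion
#' @export
plas_config <- function(...) {
  defaults <- list(
    n_channels = 128L,
    rate = 200,
    raw_rate = NULL,
    stages = list(
      proportions = c(W = 0.08, N1 = 0.08, N2 = 0.45, N3 = 0.22, REM = 0.17),
      cycle_min = 90
    ),
    sw = list(
      density_mean = c(HC = 5, CI = 3),   # events / min of N2+N3
      density_sd   = c(HC = 1.5, CI = 1),
      amp_mean     = c(HC = 75, CI = 50), # uV at the frontal maximum
      amp_sd       = 15,
      t_trough = 0.65,                    # down-state duration before the peak rise
      t_rise   = 0.30,                    # trough-to-peak rise time
      t_fall   = 0.25,                    # peak decay back to baseline
      down_frac = 0.8,                    # trough depth relative to peak
      topo_sigma = 1.0                    # radians, frontal gaussian falloff
    ),
    spindle = list(density = 2, f_lo = 12, f_hi = 16, dur = 0.8, amp = 20,
                   topo_sigma = 0.8),
    noise = list(sd = 20, alpha = 1),
    evoked = list(peak_uv = 5, t_on = 0.25, t_off = 1.75, f = 1,
                  score_window = c(1, 1.5)),
    responsiveness = list(mean = c(HC = 1, CI = 0.8), sd = c(HC = 0.3, CI = 0.4)),
    night_gain = list(HC = c(1, 1, 1), CI = c(0.4, 0.7, 1.0)),
    age = list(mean = c(HC = 68.3, CI = 71.9), sd = c(HC = 5.1, CI = 4.0)),
    p_female = c(HC = 14 / 18, CI = 6 / 16),
    moca = list(mean = c(HC = 27.9, CI = 23.3), sd = c(HC = 1.4, CI = 1.6)),
    memory = list(
      base = list(HC = c(13, 17, 21, 25, 28, 29, 26, 14.5),
                  CI = c(9.4, 11, 13, 15, 17, 18, 13.7, 6.6)),
      slope = c(HC = 1.5, CI = 1.5),      # items per uV of response score
      effect_sessions = list(HC = c("t5", "t6"), CI = "t7"),
      noise_sd = 3,
      n_items = 40
    ),
    abeta = list(pre_mean = 0.0695, pre_sd = 0.008,
                 slope = c(HC = 0, CI = 0.002),  # ratio change per uV
                 noise_sd = 0.005),
    detector = list(window_ms = 120, criterion = 0.75, delay_ms = 50,
                    stimulus_ms = 50, refractory_s = 2.5,
                    gating = c("N2", "N3"), similarity = "covariance",
                    smooth_ms = 40, n_frontal = 17),
    artifact = list(amp_uv = 300, jump_uv = 50, hf_z = 5, pad_s = 0.25,
                    bad_frac = 0.3),
    ersp = list(freqs = seq(0.5, 20, by = 0.5), cycles = c(3, 7),
                baseline = c(2, 2.5), band_window = c(1, 1.5),
                mask_t = c(0, 2.5), mask_f = c(0, 16),
                outlier_sd = 1.5, outlier_two_sided = FALSE),
    cluster = list(cf_alpha = 0.05, n_perm = 1000, adjacency_dist = 0.6),
    sim = list(response_noise_sd = 1, summed_base = 50, summed_scale = 100,
               summed_noise_sd = 25)
  )
  overrides <- list(...)
  if (length(overrides)) {
    if (is.null(names(overrides)) || any(!nzchar(names(overrides))))
      stop("all configuration overrides must be named")
    unknown <- setdiff(names(overrides), names(defaults))
    if (length(unknown))
      stop("unknown configuration entries: ", paste(unknown, collapse = ", "))
    defaults <- modifyList(defaults, overrides)
  }
  structure(defaults, class = c("plas_config", "list"))
}

# Run code under a fixed RNG seed, restoring the caller's RNG state after.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

NIGHTS <- c("BL", "E1", "E2", "E3")
STAGES <- c("W", "N1", "N2", "N3", "REM")
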