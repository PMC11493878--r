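#' Generate a synthetic participant cohort
#'
#' Draws participant profiles for the healthy (HC) and cognitively impaired
#' (CI) groups. Each profile carries the latent quantities the downstream
#' analysis is meant to recover: a non-negative responsiveness (the latent
#' magnitude of the stimulation-evoked second slow-wave peak), a slow-wave
#' event density that is stochastically lower in the CI group, per-night
#' evoked-response gains (constant 1 for HC, non-decreasing ramp for CI),
#' and the slopes linking responsiveness to memory gains and to the change
#' in the plasma amyloid-beta 42/40 ratio (zero for HC by default).
#'
#' @param n_hc,n_ci group sizes (non-negative integers).
#' @param config configuration list from [plas_config()].
#' @param seed integer seed; the draw is fully reproducible given the seed.
#' @return A data.frame of class `plas_cohort`, one row per participant,
#'   with columns `id`, `group`, `age`, `gender`, `moca`, `responsiveness`,
#'   `sw_density`, `night_gain_1..3`, `memory_slope`, `abeta_slope`.
#' @examples
#' cohort <- generate_cohort(18, 16, plas_config(), seed = 1)
#' table(cohort$group)
#' @export
generate_cohort <- function(n_hc, n_ci, config = plas_config(), seed = NULL) {
  if (length(n_hc) != 1 || length(n_ci) != 1 || is.na(n_hc) || is.na(n_ci) ||
      n_hc < 0 || n_ci < 0 || n_hc != floor(n_hc) || n_ci != floor(n_ci))
    stop("n_hc and n_ci must be non-negative integers")
  groups <- rep(c("HC", "CI"), times = c(n_hc, n_ci))
  n <- length(groups)
  with_seed(seed, {
    rows <- lapply(seq_len(n), function(i) {
      g <- groups[i]
      gain <- config$night_gain[[g]]
      if (is.unsorted(gain)) stop("night_gain must be non-decreasing")
      moca <- round(rnorm(1, config$moca$mean[g], config$moca$sd[g]))
      moca <- if (g == "CI") min(moca, 25L) else max(moca, 26L)
      data.frame(
        id = sprintf("P%03d", i),
        group = g,
        age = round(rnorm(1, config$age$mean[g], config$age$sd[g]), 1),
        gender = if (runif(1) < config$p_female[g]) "F" else "M",
        moca = min(max(moca, 0L), 30L),
        responsiveness = max(0, rnorm(1, config$responsiveness$mean[g],
                                      config$responsiveness$sd[g])),
        sw_density = max(0, rnorm(1, config$sw$density_mean[g],
                                  config$sw$density_sd[g])),
        night_gain_1 = gain[1], night_gain_2 = gain[2], night_gain_3 = gain[3],
        memory_slope = unname(config$memory$slope[g]),
        abeta_slope = unname(config$abeta$slope[g]),
        stringsAsFactors = FALSE
      )
    })
    out <- if (n) do.call(rbind, rows) else
      data.frame(id = character(), group = character(), age = numeric(),
                 gender = character(), moca = integer(),
                 responsiveness = numeric(), sw_density = numeric(),
                 night_gain_1 = numeric(), night_gain_2 = numeric(),
                 night_gain_3 = numeric(), memory_slope = numeric(),
                 abeta_slope = numeric(), stringsAsFactors = FALSE)
    rownames(out) <- NULL
    class(out) <- c("plas_cohort", "data.frame")
    out
  })
}

# One cohort row as a plain profile list (night_gain as a vector).
as_profile <- function(cohort, i) {
  row <- as.list(cohort[i, , drop = FALSE])
  row <- lapply(row, function(x) x[[1]])
  row$night_gain <- c(row$night_gain_1, row$night_gain_2, row$night_gain_3)
  row
}

night_gain_for <- function(profile, night) {
  if (night == "BL") return(0)
  gain <- profile$night_gain %||%
    c(profile$night_gain_1, profile$night_gain_2, profile$night_gain_3)
  gain[match(night, c("E1", "E2", "E3"))]
}
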