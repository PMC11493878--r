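#' Simulate memory trajectory and plasma amyloid-beta records
#'
#' Generates the behavioural and biomarker outcomes for one participant
#' given a measured electrophysiological response score (uV). Memory scores
#' over sessions t0-t7 follow the group's saturating learning curve (the
#' cued-recall feedback sessions t1-t4 act as additional learning runs and
#' drive the rise; performance decays toward the follow-ups), plus a
#' response-score effect expressed at group-specific sessions: t5/t6 for
#' the healthy profile, the 3-month follow-up t7 only for the impaired
#' profile (the delayed-effect structure). Scores are integers clipped to
#' the 40-item bound. The amyloid change score is linear in the response
#' score with slope `abeta_slope` (zero for HC by default) plus noise.
#'
#' @param profile cohort row or profile list (`group`, `memory_slope`,
#'   `abeta_slope`, `id`).
#' @param response_score measured evoked-response magnitude in uV (finite).
#' @param config configuration from [plas_config()].
#' @param seed integer seed.
#' @return list with `behavior` (`participant_id`, `scores` t0..t7,
#'   `gains` t1..t7) and `abeta` (`participant_id`, `pre_ratio`,
#'   `post_ratio`, `diff`).
#' @export
generate_behavior_and_biomarker <- function(profile, response_score,
                                            config = plas_config(),
                                            seed = NULL) {
  if (!is.finite(response_score)) stop("response_score must be finite")
  grp <- profile$group
  mem <- config$memory
  base <- mem$base[[grp]]
  sessions <- paste0("t", 0:7)
  effect <- numeric(8)
  names(effect) <- sessions
  slope <- profile$memory_slope %||% unname(mem$slope[grp])
  effect[mem$effect_sessions[[grp]]] <- slope * response_score

  with_seed(seed, {
    scores <- round(base + effect + rnorm(8, 0, mem$noise_sd))
    scores <- pmin(pmax(scores, 0), mem$n_items)
    scores <- as.integer(scores)
    names(scores) <- sessions
    gains <- scores[2:8] - scores[1]
    names(gains) <- sessions[2:8]

    ab <- config$abeta
    pre <- min(max(rnorm(1, ab$pre_mean, ab$pre_sd), 1e-4), 1 - 1e-4)
    aslope <- profile$abeta_slope %||% unname(ab$slope[grp])
    diff <- aslope * response_score + rnorm(1, 0, ab$noise_sd)
    post <- min(max(pre + diff, 1e-4), 1 - 1e-4)
    list(
      behavior = list(participant_id = profile$id %||% NA_character_,
                      scores = scores, gains = gains),
      abeta = list(participant_id = profile$id %||% NA_character_,
                   pre_ratio = pre, post_ratio = post, diff = post - pre)
    )
  })
}
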