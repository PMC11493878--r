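#' Pooled-variance two-sample t test
#'
#' Student's t with pooled variance and `df = n1 + n2 - 2`, accepting
#' either raw vectors or printed summary statistics (mean, SD, n per
#' group), so that group comparisons can be recomputed directly from
#' published tables. Raw-vector and summary inputs give identical results
#' to machine precision.
#'
#' @param x,y raw data vectors (alternative to the summary interface).
#' @param m1,sd1,n1,m2,sd2,n2 summary statistics per group.
#' @param alternative `"two.sided"` (default), `"greater"` or `"less"`.
#' @return list: `t`, `df`, `p`, `mean_diff`, `alternative`.
#' @examples
#' two_sample_t(m1 = 27.94, sd1 = 1.43, n1 = 18,
#'              m2 = 23.25, sd2 = 1.57, n2 = 16)$t
#' @export
two_sample_t <- function(x = NULL, y = NULL, m1 = NULL, sd1 = NULL, n1 = NULL,
                         m2 = NULL, sd2 = NULL, n2 = NULL,
                         alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  if (!is.null(x) || !is.null(y)) {
    if (is.null(x) || is.null(y)) stop("both raw vectors are required")
    n1 <- length(x); n2 <- length(y)
    if (n1 < 2 || n2 < 2) stop("each group needs n >= 2")
    m1 <- mean(x); m2 <- mean(y); sd1 <- stats::sd(x); sd2 <- stats::sd(y)
  }
  if (any(vapply(list(m1, sd1, n1, m2, sd2, n2), is.null, logical(1))))
    stop("supply raw vectors or the full set of summary statistics")
  if (n1 < 2 || n2 < 2) stop("each group needs n >= 2")
  if (sd1 < 0 || sd2 < 0 || (sd1 == 0 && sd2 == 0)) stop("SDs must be positive")
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df
  tval <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  p <- switch(alternative,
              two.sided = 2 * pt(-abs(tval), df),
              greater = pt(tval, df, lower.tail = FALSE),
              less = pt(tval, df))
  list(t = tval, df = df, p = p, mean_diff = m1 - m2, alternative = alternative)
}

#' Yates-corrected chi-square test for a 2x2 table
#'
#' Continuity-corrected chi-square on a 2x2 contingency table (e.g. gender
#' by group), as computed by [stats::chisq.test()] with `correct = TRUE`.
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @return list: `chi2`, `df` (1), `p`.
#' @examples
#' yates_chi2(matrix(c(4, 10, 14, 6), nrow = 2))$chi2
#' @export
yates_chi2 <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == 2)) stop("a 2x2 table is required")
  if (any(table < 0) || any(table != round(table)))
    stop("counts must be non-negative integers")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("zero marginal in the table")
  ct <- stats::chisq.test(table, correct = TRUE)
  list(chi2 = unname(ct$statistic), df = unname(ct$parameter),
       p = ct$p.value)
}

#' Holm-Bonferroni step-down adjustment
#'
#' Order-preserving Holm adjustment of a p-value family (via
#' [stats::p.adjust()]); adjusted values are monotone and never smaller
#' than the input.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return adjusted p-values in the input order.
#' @export
holm_bonferroni <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "holm")
}

#' Sleep-architecture difference-score contrasts
#'
#' For each sleep parameter, computes per participant the difference score
#' `mean(E1, E2, E3) - BL` (experimental nights collapsed minus baseline),
#' then runs Holm-corrected pooled two-sample t tests between groups (one
#' family across parameters) and Holm-corrected one-sample t tests of the
#' difference scores against zero within each group (one family per
#' group). Participants missing any night are excluded with a message.
#'
#' @param table long data.frame: `participant_id`, `group`, `night`
#'   (`BL`/`E1`/`E2`/`E3`) plus one numeric column per sleep parameter.
#' @param parameters parameter columns to test (default: all numeric
#'   columns besides the identifiers).
#' @return list of class `plas_architecture_contrasts`: `diffs` (per
#'   participant x parameter), `between` and `within` result tables with
#'   raw and Holm-adjusted p-values.
#' @export
sleep_architecture_contrasts <- function(table, parameters = NULL) {
  need <- c("participant_id", "group", "night")
  if (!all(need %in% names(table)))
    stop("table needs columns: ", paste(need, collapse = ", "))
  parameters <- parameters %||%
    setdiff(names(table)[vapply(table, is.numeric, logical(1))], need)
  complete <- vapply(split(table$night, table$participant_id),
                     function(n) all(NIGHTS %in% n), logical(1))
  dropped <- names(complete)[!complete]
  if (length(dropped))
    message("excluding participant(s) missing nights: ",
            paste(dropped, collapse = ", "))
  table <- table[table$participant_id %in% names(complete)[complete], ]

  diffs <- do.call(rbind, lapply(split(table, table$participant_id), function(d) {
    e <- d[d$night %in% c("E1", "E2", "E3"), parameters, drop = FALSE]
    b <- d[d$night == "BL", parameters, drop = FALSE]
    out <- data.frame(participant_id = d$participant_id[1], group = d$group[1],
                      stringsAsFactors = FALSE)
    out[parameters] <- as.list(colMeans(e) - unlist(b))
    out
  }))
  rownames(diffs) <- NULL

  # constant difference scores (e.g. all nights identical) carry no
  # evidence either way: report t = 0, p = 1 instead of a 0/0 statistic
  between <- do.call(rbind, lapply(parameters, function(pp) {
    x <- diffs[[pp]][diffs$group == "HC"]
    y <- diffs[[pp]][diffs$group == "CI"]
    if (stats::sd(x) == 0 && stats::sd(y) == 0) {
      d0 <- mean(x) - mean(y)
      data.frame(parameter = pp, t = if (d0 == 0) 0 else sign(d0) * Inf,
                 df = length(x) + length(y) - 2, p = if (d0 == 0) 1 else 0)
    } else {
      tt <- two_sample_t(x = x, y = y)
      data.frame(parameter = pp, t = tt$t, df = tt$df, p = tt$p)
    }
  }))
  between$p_adj <- holm_bonferroni(between$p)

  within <- do.call(rbind, lapply(c("HC", "CI"), function(g) {
    res <- do.call(rbind, lapply(parameters, function(pp) {
      v <- diffs[[pp]][diffs$group == g]
      if (stats::sd(v) == 0) {
        data.frame(group = g, parameter = pp,
                   t = if (mean(v) == 0) 0 else sign(mean(v)) * Inf,
                   df = length(v) - 1, p = if (mean(v) == 0) 1 else 0,
                   mean_diff = mean(v))
      } else {
        tt <- t.test(v, mu = 0)
        data.frame(group = g, parameter = pp, t = unname(tt$statistic),
                   df = unname(tt$parameter), p = tt$p.value,
                   mean_diff = mean(v))
      }
    }))
    res$p_adj <- holm_bonferroni(res$p)
    res
  }))
  rownames(within) <- NULL
  structure(list(diffs = diffs, between = between, within = within),
            class = "plas_architecture_contrasts")
}

#' Regress outcomes on the electrophysiological response score
#'
#' Ordinary least squares of a memory gain (t5, t6 or t7) or of the
#' amyloid-beta 42/40 change score on the stimulation response score, for
#' the whole sample or one group, optionally with age and gender
#' covariates. Both the covariate-adjusted and unadjusted models are
#' reported so they can be compared.
#'
#' @param table participant table (see [simulate_participant_table()]):
#'   one row per participant with `group`, `age`, `gender`, the predictor
#'   column, and outcome columns `gain_t5`, `gain_t6`, `gain_t7`,
#'   `abeta_diff`.
#' @param outcome outcome column name.
#' @param predictor predictor column (default `"response_score"`).
#' @param covariates optional subset of `c("age", "gender")`.
#' @param subset `"all"`, `"HC"` or `"CI"`.
#' @return list of class `plas_regression`: `formula`, `coefficients`,
#'   `F`, `df`, `adj_r2`, `p` (overall F test), `n`, and `unadjusted`
#'   (same fields without covariates) when covariates were requested.
#' @export
response_regression <- function(table, outcome, predictor = "response_score",
                                covariates = NULL,
                                subset = c("all", "HC", "CI")) {
  subset <- match.arg(subset)
  if (subset != "all") table <- table[table$group == subset, , drop = FALSE]
  vars <- c(outcome, predictor, covariates)
  if (!all(vars %in% names(table)))
    stop("missing column(s): ", paste(setdiff(vars, names(table)), collapse = ", "))
  d <- table[complete.cases(table[, vars, drop = FALSE]), , drop = FALSE]
  k <- 1 + length(covariates)
  if (nrow(d) < k + 3) stop("need at least k + 3 complete cases (have ", nrow(d), ")")
  if (!is.null(covariates) && "gender" %in% covariates)
    d$gender <- as.integer(d$gender == "F")
  fml <- stats::reformulate(c(predictor, covariates), response = outcome)
  fit <- lm(fml, data = d)
  if (fit$rank < k + 1) {
    ali <- stats::alias(fit)$Complete
    stop("rank-deficient design; collinear term(s): ",
         paste(rownames(ali) %||% "unknown", collapse = ", "))
  }
  out <- regression_result(fit, fml, nrow(d))
  if (!is.null(covariates)) {
    fml0 <- stats::reformulate(predictor, response = outcome)
    out$unadjusted <- regression_result(lm(fml0, data = d), fml0, nrow(d))
  }
  out
}

regression_result <- function(fit, fml, n) {
  s <- summary(fit)
  fs <- s$fstatistic
  structure(list(formula = deparse(fml),
                 coefficients = coef(fit),
                 F = unname(fs["value"]),
                 df = c(unname(fs["numdf"]), unname(fs["dendf"])),
                 adj_r2 = s$adj.r.squared,
                 p = unname(pf(fs["value"], fs["numdf"], fs["dendf"],
                               lower.tail = FALSE)),
                 n = n,
                 slope_se = s$coefficients[2, "Std. Error"]),
            class = "plas_regression")
}

#' Baseline amyloid independence check
#'
#' Regresses the stimulation response score on the pre-intervention
#' amyloid-beta 42/40 ratio within a group: a non-significant fit
#' indicates the intervention-related change was not driven by baseline
#' amyloid status.
#'
#' @param table participant table with `abeta_pre` and the response column.
#' @param response response column (default `"response_score"`).
#' @param subset `"all"`, `"HC"` or `"CI"`.
#' @return A `plas_regression` result.
#' @export
baseline_independence_check <- function(table, response = "response_score",
                                        subset = c("all", "HC", "CI")) {
  response_regression(table, outcome = response, predictor = "abeta_pre",
                      subset = match.arg(subset))
}

#' @export
print.plas_regression <- function(x, ...) {
  cat(sprintf("<plas_regression> %s\n  F(%d, %d) = %.3f, adj R^2 = %.3f, p = %.4g, n = %d\n",
              x$formula, x$df[1], x$df[2], x$F, x$adj_r2, x$p, x$n))
  invisible(x)
}
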