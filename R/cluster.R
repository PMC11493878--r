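#' Cluster-based permutation test
#'
#' Nonparametric family-wise-error-controlled comparison of two trial sets
#' over a channel (x frequency) x time grid, following the cluster-mass
#' permutation scheme used throughout EEG statistics: bin-wise pooled
#' two-sample t statistics, thresholding at the point-wise two-tailed
#' cluster-forming alpha, grouping of suprathreshold bins into
#' sign-consistent clusters under channel adjacency (plus +-1 neighbourhood
#' along frequency and time), cluster mass as the summed t, and a null
#' distribution of the maximum absolute cluster mass over random trial
#' relabelings. Bins with degenerate variance never enter a cluster.
#'
#' @param a,b trial data for the two conditions: arrays with dimensions
#'   trials x channels x time, or trials x channels x frequency x time.
#'   Also accepts `plas_epochs` objects.
#' @param alpha cluster significance level (default 0.05).
#' @param n_perm number of permutations (default 1000; a warning is issued
#'   below 100). Cluster p-values are floored at `1 / (n_perm + 1)`.
#' @param adjacency channel neighbour list (one integer vector per
#'   channel), e.g. from [channel_adjacency()].
#' @param cf_alpha point-wise two-tailed cluster-forming alpha (default
#'   0.05).
#' @return list of class `plas_clusters`: `clusters` data.frame (`id`,
#'   `mass`, `sign`, `p_value`, `n_bins`, `significant`), `labels` (array
#'   of per-bin cluster ids, 0 = none), `t` (observed t array), `alpha`,
#'   `n_perm`, `null_max`.
#' @export
cluster_permutation <- function(a, b, alpha = 0.05, n_perm = 1000,
                                adjacency = NULL, cf_alpha = 0.05) {
  a <- as_trial_array(a)
  b <- as_trial_array(b)
  da <- dim(a); db <- dim(b)
  if (length(da) != length(db) || any(da[-1] != db[-1]))
    stop("a and b must share the bin grid")
  if (da[1] < 2 || db[1] < 2) stop("each condition needs at least 2 trials")
  if (n_perm < 100) warning("n_perm < 100: cluster p-values will be very coarse")

  grid <- da[-1]
  nchan <- grid[1]
  nfreq <- if (length(grid) == 3) grid[2] else 1L
  ntime <- grid[length(grid)]
  if (is.null(adjacency)) adjacency <- replicate(nchan, integer(0), simplify = FALSE)
  if (length(adjacency) != nchan)
    stop("adjacency must have one entry per channel")

  n1 <- da[1]; n2 <- db[1]
  B <- prod(grid)
  X <- rbind(matrix(a, n1, B), matrix(b, n2, B))
  g <- c(rep(1L, n1), rep(0L, n2))
  tthr <- qt(1 - cf_alpha / 2, df = n1 + n2 - 2)

  res <- .cluster_perm_engine(X, g, as.integer(n_perm), as.integer(nchan),
                              as.integer(nfreq), as.integer(ntime),
                              lapply(adjacency, as.integer), tthr)

  masses <- res$masses
  nclus <- length(masses)
  pvals <- if (nclus) vapply(masses, function(m)
    (1 + sum(res$null_max >= abs(m))) / (n_perm + 1), numeric(1)) else numeric(0)
  clusters <- data.frame(id = seq_len(nclus), mass = masses,
                         sign = ifelse(masses >= 0, 1L, -1L),
                         p_value = pvals,
                         n_bins = if (nclus) tabulate(res$labels[res$labels > 0],
                                                      nclus) else integer(0),
                         significant = pvals < alpha)
  structure(list(clusters = clusters,
                 labels = array(res$labels, dim = grid),
                 t = array(res$t, dim = grid),
                 alpha = alpha, n_perm = n_perm,
                 cf_alpha = cf_alpha, null_max = res$null_max),
            class = "plas_clusters")
}

as_trial_array <- function(x) {
  if (inherits(x, "plas_epochs")) return(x$epochs)
  if (is.array(x) && length(dim(x)) %in% c(3, 4)) return(x)
  stop("expected a plas_epochs object or a trials x channels (x freq) x time array")
}

#' @export
print.plas_clusters <- function(x, ...) {
  sig <- sum(x$clusters$significant)
  cat(sprintf("<plas_clusters> %d cluster(s), %d significant at alpha=%g (%d permutations)\n",
              nrow(x$clusters), sig, x$alpha, x$n_perm))
  if (nrow(x$clusters)) print(x$clusters, ...)
  invisible(x)
}
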