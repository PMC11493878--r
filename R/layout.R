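#' Spherical-spiral electrode layout
#'
#' Places `n_channels` sensors on the upper part of a unit sphere along a
#' golden-angle spiral, approximating a high-density scalp net. The exact
#' coordinates of commercial geodesic nets are proprietary, so the layout is
#' a deterministic stand-in: the two points nearest the canonical midline
#' positions are renamed and snapped to `Fz` (anterior midline, 45 deg
#' elevation) and `Cz` (vertex). Head coordinates: x right, y anterior,
#' z up.
#'
#' @param n_channels number of electrodes (>= 8).
#' @param min_z lowest z covered by the cap (default -0.15, slightly below
#'   the equator, as EEG nets extend below the widest head circumference).
#' @return A data.frame with columns `name`, `x`, `y`, `z` (unit vectors).
#' @examples
#' lay <- spiral_layout(32)
#' subset(lay, name %in% c("Fz", "Cz"))
#' @export
spiral_layout <- function(n_channels = 128L, min_z = -0.15) {
  n <- as.integer(n_channels)
  if (is.na(n) || n < 8) stop("n_channels must be at least 8")
  i <- seq_len(n)
  # evenly spaced heights over the cap, golden-angle azimuths
  z <- seq(1, min_z, length.out = n)
  phi <- i * pi * (3 - sqrt(5))
  r <- sqrt(pmax(0, 1 - z^2))
  lay <- data.frame(name = paste0("E", i),
                    x = r * cos(phi), y = r * sin(phi), z = z,
                    stringsAsFactors = FALSE)
  anchors <- list(Cz = c(0, 0, 1), Fz = c(0, sqrt(0.5), sqrt(0.5)))
  for (nm in names(anchors)) {
    a <- anchors[[nm]]
    d <- (lay$x - a[1])^2 + (lay$y - a[2])^2 + (lay$z - a[3])^2
    d[lay$name %in% names(anchors)] <- Inf
    k <- which.min(d)
    lay$name[k] <- nm
    lay[k, c("x", "y", "z")] <- a
  }
  lay
}

# Great-circle distance (radians) from every channel to a reference channel.
channel_distances <- function(layout, ref) {
  k <- match(ref, layout$name)
  if (is.na(k)) stop("reference channel '", ref, "' not in layout")
  p <- as.matrix(layout[, c("x", "y", "z")])
  dots <- pmin(1, pmax(-1, p %*% p[k, ]))
  acos(as.vector(dots))
}

#' Channels nearest a reference electrode
#'
#' Used for the frontal (around Fz) and centroparietal (around Cz) electrode
#' subsets of the band-specific response scores.
#'
#' @param layout a layout data.frame from [spiral_layout()].
#' @param ref reference channel name (e.g. `"Fz"`).
#' @param k subset size, including the reference itself.
#' @return Character vector of channel names ordered by distance.
#' @export
nearest_channels <- function(layout, ref, k) {
  d <- channel_distances(layout, ref)
  layout$name[order(d)][seq_len(min(k, nrow(layout)))]
}

#' Channel adjacency by spherical distance
#'
#' Neighbour structure used for cluster formation: two channels are adjacent
#' when their great-circle distance is below `max_dist` radians.
#'
#' @param layout layout data.frame.
#' @param max_dist adjacency threshold in radians (default 0.6).
#' @return A list, one integer vector of neighbour indices per channel.
#' @export
channel_adjacency <- function(layout, max_dist = 0.6) {
  p <- as.matrix(layout[, c("x", "y", "z")])
  dots <- pmin(1, pmax(-1, tcrossprod(p)))
  d <- acos(dots)
  lapply(seq_len(nrow(layout)), function(i) {
    nb <- which(d[i, ] <= max_dist)
    nb[nb != i]
  })
}

# Gaussian scalp topography centred on a reference channel, 1 at the centre.
channel_topography <- function(layout, ref, sigma) {
  d <- channel_distances(layout, ref)
  exp(-d^2 / (2 * sigma^2))
}
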