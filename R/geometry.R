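# Spherical geometry helpers and the axis-projection turning-point method.

# forward azimuthal-equidistant projection about (lat0, lon0); returns km
aeqd_forward <- function(lat, lon, lat0, lon0) {
  rlat <- lat * pi / 180; rlon <- lon * pi / 180
  rlat0 <- lat0 * pi / 180; rlon0 <- lon0 * pi / 180
  dlon <- rlon - rlon0
  cosc <- sin(rlat0) * sin(rlat) + cos(rlat0) * cos(rlat) * cos(dlon)
  cosc <- pmin(1, pmax(-1, cosc))
  c_ <- acos(cosc)
  az <- atan2(sin(dlon) * cos(rlat),
              cos(rlat0) * sin(rlat) - sin(rlat0) * cos(rlat) * cos(dlon))
  d <- .EARTH_R * c_
  cbind(x = d * sin(az), y = d * cos(az))
}

# inverse: planar km offsets about (lat0, lon0) back to geographic degrees
aeqd_inverse <- function(x, y, lat0, lon0) {
  d <- sqrt(x^2 + y^2)
  az <- atan2(x, y)
  rlat0 <- lat0 * pi / 180; rlon0 <- lon0 * pi / 180
  delta <- d / .EARTH_R
  lat <- asin(sin(rlat0) * cos(delta) + cos(rlat0) * sin(delta) * cos(az))
  lon <- rlon0 + atan2(sin(az) * sin(delta) * cos(rlat0),
                       cos(delta) - sin(rlat0) * sin(lat))
  cbind(lat = lat * 180 / pi, lon = ((lon * 180 / pi + 180) %% 360) - 180)
}

#' Project a trajectory onto a local plane
#'
#' Azimuthal-equidistant projection about the trajectory centroid, in km.
#' Distances from the centroid are preserved exactly under the spherical
#' Earth model; pairwise distances within the spans typical of foraging trips
#' (under ~1000 km) are preserved to well within 1 percent.
#'
#' @param traj a `betpl_trajectory`.
#' @param max_step_km_per_10min plausibility bound on the implied ground
#'   speed between consecutive fixes; exceeding it is an error (default 200
#'   km per 10-minute gap).
#' @return A `betpl_planar_track`: data frame with columns `x`, `y` (km) and
#'   `time`, plus attributes `id`, `origin` (lat, lon) and `meta`.
#' @export
project_to_plane <- function(traj, max_step_km_per_10min = 200) {
  bad <- which(!is.finite(traj$lat) | !is.finite(traj$lon))
  if (length(bad))
    stop("non-finite coordinates at fix ", bad[1L])
  lon0 <- traj$lon[1L] + atan2(
    mean(sin((traj$lon - traj$lon[1L]) * pi / 180)),
    mean(cos((traj$lon - traj$lon[1L]) * pi / 180))) * 180 / pi
  lat0 <- mean(traj$lat)
  xy <- aeqd_forward(traj$lat, traj$lon, lat0, lon0)
  d <- sqrt(diff(xy[, 1L])^2 + diff(xy[, 2L])^2)
  gap_min <- diff(as.numeric(traj$time)) / 60
  lim <- max_step_km_per_10min * pmax(gap_min, 1e-9) / 10
  if (any(d > lim))
    stop("trajectory '", traj_id(traj), "': implausible displacement of ",
         round(d[which(d > lim)[1L]], 1), " km between fixes ",
         which(d > lim)[1L], " and ", which(d > lim)[1L] + 1L)
  out <- data.frame(x = xy[, 1L], y = xy[, 2L], time = traj$time)
  attr(out, "id") <- traj_id(traj)
  attr(out, "origin") <- c(lat = lat0, lon = lon0)
  attr(out, "meta") <- traj_meta(traj)
  class(out) <- c("betpl_planar_track", "data.frame")
  out
}

#' Rigidly rotate a planar track about its first point
#'
#' @param track a `betpl_planar_track`.
#' @param theta rotation angle, degrees (counter-clockwise).
#' @return the rotated `betpl_planar_track`; all pairwise distances are
#'   preserved to machine precision.
#' @export
rotate_track <- function(track, theta) {
  th <- theta * pi / 180
  x0 <- track$x[1L]; y0 <- track$y[1L]
  dx <- track$x - x0; dy <- track$y - y0
  out <- track
  out$x <- x0 + cos(th) * dx - sin(th) * dy
  out$y <- y0 + sin(th) * dx + cos(th) * dy
  out
}

#' Turning points of a 1-D trajectory
#'
#' A turning point is where the sign of the successive displacement reverses
#' (a nonzero displacement followed, possibly after a run of zero
#' displacements, by a nonzero displacement of opposite sign). Zero
#' displacements never count as direction changes: the previous direction is
#' carried across stationary runs so GPS jitter at rest does not fragment
#' steps. The first and last indices are always included as segment
#' boundaries.
#'
#' @param series numeric vector of 1-D positions (at least 2).
#' @return integer vector of boundary indices (1-based), sorted, including
#'   `1` and `length(series)`.
#' @export
turning_points_1d <- function(series) {
  n <- length(series)
  if (n < 2L) stop("need at least 2 positions")
  d <- diff(series)
  s <- sign(d)
  turns <- integer(0)
  last <- 0
  for (i in seq_len(n - 1L)) {
    if (s[i] == 0) next
    if (last != 0 && s[i] != last) turns <- c(turns, i)
    last <- s[i]
  }
  sort(unique(c(1L, turns, n)))
}

#' Extract a pooled step-length sample from a planar track
#'
#' Implements the axis-projection method: the track is rotated by `theta`
#' about its first point, projected onto the x and y axes, turning points are
#' found on each 1-D projection, and the 1-D distances between consecutive
#' turning points from both axes are pooled into one sample. Lengths below
#' `lim_a` or above `l_max` are discarded.
#'
#' @param track a `betpl_planar_track`.
#' @param theta rotation angle, degrees.
#' @param lim_a lower bound on retained step lengths, km.
#' @param l_max upper bound on step lengths, km (default 600).
#' @param n_min minimum number of surviving steps for the sample to be
#'   flagged sufficient (default 30).
#' @return A `betpl_steps` object: list with `lengths` (km), `lim_a`,
#'   `theta`, `l_max`, `source_id`, `n` and `sufficient`.
#' @export
extract_steps <- function(track, theta = 0, lim_a = 0.1, l_max = 600,
                          n_min = 30) {
  rot <- rotate_track(track, theta)
  lx <- steps_1d(rot$x)
  ly <- steps_1d(rot$y)
  pooled <- c(lx, ly)
  pooled <- pooled[pooled >= lim_a & pooled <= l_max]
  step_sample(pooled, lim_a = lim_a, theta = theta, l_max = l_max,
              source_id = attr(track, "id") %||% "<track>", n_min = n_min)
}

# 1-D step lengths between consecutive turning-point boundaries
steps_1d <- function(series) {
  b <- turning_points_1d(series)
  abs(diff(series[b]))
}

#' Construct a step-length sample
#'
#' @param lengths numeric vector of step lengths, km.
#' @param lim_a,theta,l_max extraction parameters recorded with the sample.
#' @param source_id identifier of the source track.
#' @param n_min sufficiency threshold.
#' @return a `betpl_steps` object.
#' @export
step_sample <- function(lengths, lim_a, theta = 0, l_max = 600,
                        source_id = "<sample>", n_min = 30) {
  lengths <- as.numeric(lengths)
  if (any(lengths < lim_a | lengths > l_max))
    lengths <- lengths[lengths >= lim_a & lengths <= l_max]
  out <- list(lengths = lengths, lim_a = lim_a, theta = theta, l_max = l_max,
              source_id = source_id, n = length(lengths),
              sufficient = length(lengths) >= n_min)
  class(out) <- "betpl_steps"
  out
}

#' @export
print.betpl_steps <- function(x, ...) {
  cat("<betpl_steps>", x$n, "steps from", x$source_id,
      sprintf("(lim_a = %g km, theta = %g deg)%s", x$lim_a, x$theta,
              if (x$sufficient) "" else " [insufficient]"), "\n")
  invisible(x)
}
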