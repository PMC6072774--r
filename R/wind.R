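# Gridded wind fields: container, CSV dialect, trilinear interpolation,
# per-trajectory summaries and head/cross-wind decomposition.

#' Gridded wind field
#'
#' Eastward (`u`) and northward (`v`) wind components at 10 m on a regular
#' latitude-longitude-time grid (the reference resolution is 0.5 degrees and
#' 6 hours). Components, not speeds, are stored and interpolated: speed
#' interpolation is biased low near direction shear.
#'
#' @param lat,lon strictly increasing regular axes, degrees.
#' @param time strictly increasing regular `POSIXct` axis.
#' @param u,v numeric arrays `[time, lat, lon]`, m/s; `NA` marks masked
#'   cells.
#' @return a `betpl_wind_grid` object.
#' @export
wind_grid <- function(lat, lon, time, u, v) {
  if (!inherits(time, "POSIXct")) time <- as.POSIXct(time, tz = "UTC")
  for (ax in list(lat = lat, lon = lon, t = as.numeric(time))) {
    d <- diff(ax)
    if (length(d) && (any(d <= 0) || max(abs(d - d[1L])) > 1e-6 * abs(d[1L])))
      stop("axes must be strictly increasing and regular")
  }
  dims <- c(length(time), length(lat), length(lon))
  if (!identical(dim(u), dims) || !identical(dim(v), dims))
    stop("u and v must be arrays [time, lat, lon] matching the axes")
  structure(list(lat = lat, lon = lon, time = time, u = u, v = v),
            class = "betpl_wind_grid")
}

#' @export
print.betpl_wind_grid <- function(x, ...) {
  cat("<betpl_wind_grid>", length(x$time), "times x", length(x$lat),
      "lat x", length(x$lon), "lon;",
      format(x$time[1L]), "to", format(x$time[length(x$time)]), "\n")
  invisible(x)
}

#' Read a wind grid from long-format CSV
#'
#' One row per (time, lat, lon) cell with columns `time` (ISO 8601), `lat`,
#' `lon`, `u`, `v`. The long table is reshaped to the gridded container; the
#' two dialects (CSV and in-memory arrays) yield identical summaries on
#' identical content.
#'
#' @param path CSV path.
#' @return a [wind_grid()].
#' @export
read_wind_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("time", "lat", "lon", "u", "v")
  if (!all(need %in% names(df)))
    stop("wind CSV must have columns ", paste(need, collapse = ", "))
  tm <- as.POSIXct(df$time, tz = "UTC",
                   tryFormats = c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M:%S"))
  lat <- sort(unique(df$lat)); lon <- sort(unique(df$lon))
  tax <- sort(unique(tm))
  dims <- c(length(tax), length(lat), length(lon))
  if (nrow(df) != prod(dims))
    stop("wind CSV is not a complete regular grid")
  it <- match(as.numeric(tm), as.numeric(tax))
  ila <- match(df$lat, lat); ilo <- match(df$lon, lon)
  idx <- cbind(it, ila, ilo)
  u <- array(NA_real_, dims); v <- array(NA_real_, dims)
  u[idx] <- df$u; v[idx] <- df$v
  wind_grid(lat, lon, tax, u, v)
}

#' Write a wind grid to long-format CSV
#' @param grid a [wind_grid()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_wind_csv <- function(grid, path) {
  g <- expand.grid(time = grid$time, lat = grid$lat, lon = grid$lon,
                   KEEP.OUT.ATTRS = FALSE)
  g$u <- as.vector(grid$u); g$v <- as.vector(grid$v)
  g$time <- format(g$time, "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  write.csv(g, path, row.names = FALSE)
  invisible(path)
}

# locate x on a regular axis; returns lower index and fraction
axis_locate <- function(x, axis, name) {
  if (any(x < axis[1L] - 1e-9 | x > axis[length(axis)] + 1e-9))
    stop("query outside grid hull on the ", name, " axis")
  if (length(axis) == 1L) return(list(i = rep(1L, length(x)),
                                      f = rep(0, length(x))))
  step <- axis[2L] - axis[1L]
  pos <- (x - axis[1L]) / step
  i <- pmin(pmax(floor(pos), 0), length(axis) - 2L)
  list(i = as.integer(i) + 1L, f = pmin(pmax(pos - i, 0), 1))
}

#' Interpolate wind at positions and times
#'
#' Trilinear (linear in latitude, longitude and time) interpolation of each
#' component separately; speed is the magnitude of the interpolated vector.
#' Queries outside the grid hull are an error naming the offending axis.
#' When a corner cell of the enclosing brick is masked (`NA`), the
#' nearest-valid corner value is substituted and the query flagged.
#'
#' @param grid a [wind_grid()].
#' @param lat,lon,time query vectors (recycled to a common length).
#' @return data frame with `u`, `v`, `speed` and logical `filled` (masked
#'   corner encountered).
#' @export
interp_wind <- function(grid, lat, lon, time) {
  if (!inherits(time, "POSIXct")) time <- as.POSIXct(time, tz = "UTC")
  nq <- max(length(lat), length(lon), length(time))
  lat <- rep_len(lat, nq); lon <- rep_len(lon, nq)
  time <- rep_len(time, nq)
  it <- axis_locate(as.numeric(time), as.numeric(grid$time), "time")
  ila <- axis_locate(lat, grid$lat, "latitude")
  ilo <- axis_locate(lon, grid$lon, "longitude")

  interp_one <- function(arr) {
    acc <- numeric(nq); filled <- logical(nq)
    corners <- vector("list", 8L); wts <- vector("list", 8L)
    k <- 0L
    for (dt in 0:1) for (da in 0:1) for (do in 0:1) {
      k <- k + 1L
      i1 <- pmin(it$i + dt, dim(arr)[1L])
      i2 <- pmin(ila$i + da, dim(arr)[2L])
      i3 <- pmin(ilo$i + do, dim(arr)[3L])
      corners[[k]] <- arr[cbind(i1, i2, i3)]
      wts[[k]] <- (if (dt) it$f else 1 - it$f) *
        (if (da) ila$f else 1 - ila$f) * (if (do) ilo$f else 1 - ilo$f)
    }
    cmat <- do.call(cbind, corners)
    wmat <- do.call(cbind, wts)
    bad <- is.na(cmat)
    if (any(bad)) {
      filled <- rowSums(bad & wmat > 0) > 0
      # nearest-valid corner by weight
      for (r in which(rowSums(bad) > 0)) {
        ok <- which(!bad[r, ])
        if (!length(ok)) stop("all corner cells masked for a query")
        cmat[r, is.na(cmat[r, ])] <- cmat[r, ok[which.max(wmat[r, ok])]]
      }
    }
    list(val = rowSums(cmat * wmat), filled = filled)
  }
  iu <- interp_one(grid$u); iv <- interp_one(grid$v)
  data.frame(u = iu$val, v = iv$val, speed = sqrt(iu$val^2 + iv$val^2),
             filled = iu$filled | iv$filled)
}

#' Per-trajectory wind summary
#'
#' Wind speed is evaluated at every usable fix; besides the arithmetic mean
#' the root-mean-square and cubic-mean speeds are reported, which upweight
#' gusts (power-mean ordering `mean <= rms <= cubic` always holds).
#'
#' @param traj a `betpl_trajectory`.
#' @param grid a [wind_grid()].
#' @return a one-row data frame: `id`, `mean_v`, `rms_v`, `cubic_v`,
#'   `n_fixes`.
#' @export
summarize_wind <- function(traj, grid) {
  w <- tryCatch(interp_wind(grid, traj$lat, traj$lon, traj$time),
                error = function(e) NULL)
  if (is.null(w)) {
    inside <- traj$lat >= min(grid$lat) & traj$lat <= max(grid$lat) &
      traj$lon >= min(grid$lon) & traj$lon <= max(grid$lon) &
      as.numeric(traj$time) >= as.numeric(grid$time[1L]) &
      as.numeric(traj$time) <= as.numeric(grid$time[length(grid$time)])
    if (!any(inside))
      stop("trajectory '", traj_id(traj), "' has no fixes inside the wind grid")
    sub <- traj[inside, , drop = FALSE]
    w <- interp_wind(grid, sub$lat, sub$lon, sub$time)
  }
  s <- w$speed
  data.frame(id = traj_id(traj), mean_v = mean(s),
             rms_v = sqrt(mean(s^2)), cubic_v = mean(s^3)^(1 / 3),
             n_fixes = length(s))
}

#' Head- and cross-wind components along a trajectory
#'
#' Flight direction at each fix is the bearing to the next fix. The head
#' component is minus the projection of the wind vector on the flight
#' direction (positive = headwind, negative = tailwind); the cross component
#' is the signed perpendicular part (positive = wind from the left of
#' track). `head^2 + cross^2` equals the interpolated speed squared. Fixes
#' with zero displacement are skipped.
#'
#' @param traj a `betpl_trajectory`.
#' @param grid a [wind_grid()].
#' @return list with `per_fix` (data frame `head`, `cross`, `speed`) and the
#'   trajectory means `mean_head` (mean positive head component over
#'   headwind fixes), `mean_tail` (mean tailwind magnitude) and
#'   `mean_cross_abs`.
#' @export
headtail_components <- function(traj, grid) {
  if (nrow(traj) < 2L) stop("need at least 2 fixes")
  n <- nrow(traj)
  b <- geosphere::bearing(cbind(traj$lon[-n], traj$lat[-n]),
                          cbind(traj$lon[-1L], traj$lat[-1L]))
  d <- geosphere::distHaversine(cbind(traj$lon[-n], traj$lat[-n]),
                                cbind(traj$lon[-1L], traj$lat[-1L]),
                                r = .EARTH_R)
  keep <- d > 0
  if (!any(keep)) stop("all displacements zero")
  w <- interp_wind(grid, traj$lat[-n][keep], traj$lon[-n][keep],
                   traj$time[-n][keep])
  br <- b[keep] * pi / 180
  fe <- sin(br); fn <- cos(br)           # unit flight vector (east, north)
  head <- -(w$u * fe + w$v * fn)
  cross <- w$u * fn - w$v * fe
  per_fix <- data.frame(head = head, cross = cross, speed = w$speed)
  list(per_fix = per_fix,
       mean_head = if (any(head > 0)) mean(head[head > 0]) else 0,
       mean_tail = if (any(head < 0)) mean(-head[head < 0]) else 0,
       mean_cross_abs = mean(abs(cross)))
}
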