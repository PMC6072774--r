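#' Trajectory container
#'
#' A trajectory is an ordered sequence of GPS fixes for one foraging trip,
#' together with per-trip metadata. Fixes are expected at roughly 10-minute
#' cadence; timestamps must be strictly increasing and at least 3 fixes are
#' required.
#'
#' @param id character trip identifier.
#' @param time `POSIXct` vector of fix times (UTC).
#' @param lat,lon numeric vectors, decimal degrees. Longitudes are wrapped to
#'   (-180, 180].
#' @param meta named list of trip metadata; recognised entries are `species`,
#'   `colony`, `sex` (`"male"`, `"female"` or `"unknown"`), `period`
#'   (`"incubation"` or `"chick-rearing"`) and `region` (`"Atlantic"` or
#'   `"Mediterranean"`).
#'
#' @return An object of class `betpl_trajectory`: a data frame with columns
#'   `time`, `lat`, `lon` and attributes `id` and `meta`.
#' @export
trajectory <- function(id, time, lat, lon, meta = list()) {
  if (length(time) != length(lat) || length(lat) != length(lon))
    stop("time, lat and lon must have equal length")
  if (length(time) < 3L)
    stop("trajectory '", id, "' has fewer than 3 fixes")
  bad <- which(!is.finite(lat) | !is.finite(lon))
  if (length(bad))
    stop("trajectory '", id, "': non-finite coordinates at fix ", bad[1L])
  if (any(abs(lat) > 90))
    stop("trajectory '", id, "': |lat| > 90")
  if (!inherits(time, "POSIXct")) time <- as.POSIXct(time, tz = "UTC")
  if (any(diff(as.numeric(time)) <= 0))
    stop("trajectory '", id, "': timestamps not strictly increasing at fix ",
         which(diff(as.numeric(time)) <= 0)[1L] + 1L)
  lon <- ((lon + 180) %% 360) - 180
  lon[lon == -180] <- 180
  out <- data.frame(time = time, lat = lat, lon = lon)
  attr(out, "id") <- as.character(id)
  attr(out, "meta") <- meta
  class(out) <- c("betpl_trajectory", "data.frame")
  out
}

#' @export
print.betpl_trajectory <- function(x, ...) {
  cat("<betpl_trajectory> id:", attr(x, "id"), "-", nrow(x), "fixes,",
      format(x$time[1L]), "to", format(x$time[nrow(x)]), "\n")
  m <- attr(x, "meta")
  if (length(m)) cat("  meta:", paste(names(m), unlist(m), sep = "=",
                                      collapse = ", "), "\n")
  invisible(x)
}

traj_id <- function(traj) attr(traj, "id")
traj_meta <- function(traj) attr(traj, "meta")

#' Trip duration in days
#' @param traj a `betpl_trajectory`.
#' @return numeric, days between first and last fix.
#' @export
trip_duration_days <- function(traj) {
  as.numeric(difftime(traj$time[nrow(traj)], traj$time[1L], units = "days"))
}

#' Maximum displacement from the trip origin
#'
#' Great-circle distance (km) of the farthest fix from the first fix, used as
#' a colony proxy when colony coordinates are not recorded.
#'
#' @param traj a `betpl_trajectory`.
#' @return numeric, km.
#' @export
max_displacement_km <- function(traj) {
  d <- geosphere::distHaversine(cbind(traj$lon[1L], traj$lat[1L]),
                                cbind(traj$lon, traj$lat), r = .EARTH_R)
  max(d)
}

#' Read trajectories from CSV
#'
#' Expects columns `id`, `timestamp` (ISO 8601), `lat`, `lon`, with one row
#' per fix, plus an optional metadata side table with columns `id`, `species`,
#' `colony`, `sex`, `period`, `region`.
#'
#' @param path path to the track CSV.
#' @param meta_path optional path to the metadata CSV.
#' @return list of `betpl_trajectory` objects, named by id.
#' @export
read_tracks <- function(path, meta_path = NULL) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "timestamp", "lat", "lon")
  if (!all(need %in% names(df)))
    stop("track file must have columns ", paste(need, collapse = ", "))
  meta <- NULL
  if (!is.null(meta_path)) {
    meta <- read.csv(meta_path, stringsAsFactors = FALSE)
    rownames(meta) <- meta$id
  }
  bad <- which(!is.finite(df$lat) | !is.finite(df$lon))
  if (length(bad))
    stop("track file row ", bad[1L], " (trajectory '", df$id[bad[1L]],
         "'): non-finite coordinates")
  tm <- as.POSIXct(df$timestamp, tz = "UTC",
                   tryFormats = c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M:%S"))
  if (anyNA(tm))
    stop("track file row ", which(is.na(tm))[1L], " (trajectory '",
         df$id[which(is.na(tm))[1L]], "'): unparseable timestamp")
  out <- lapply(split(seq_len(nrow(df)), df$id), function(i) {
    id <- df$id[i[1L]]
    m <- list()
    if (!is.null(meta) && id %in% rownames(meta))
      m <- as.list(meta[id, setdiff(names(meta), "id"), drop = FALSE])
    trajectory(id, tm[i], df$lat[i], df$lon[i], m)
  })
  out[order(names(out))]
}

#' Write trajectories to CSV
#' @param trajs list of `betpl_trajectory`.
#' @param path output CSV for fixes.
#' @param meta_path optional output CSV for metadata.
#' @return `path`, invisibly.
#' @export
write_tracks <- function(trajs, path, meta_path = NULL) {
  rows <- do.call(rbind, lapply(trajs, function(tr) {
    data.frame(id = traj_id(tr),
               timestamp = format(tr$time, "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
               lat = tr$lat, lon = tr$lon)
  }))
  write.csv(rows, path, row.names = FALSE)
  if (!is.null(meta_path)) {
    md <- do.call(rbind, lapply(trajs, function(tr) {
      m <- traj_meta(tr)
      data.frame(id = traj_id(tr),
                 species = m$species %||% NA, colony = m$colony %||% NA,
                 sex = m$sex %||% NA, period = m$period %||% NA,
                 region = m$region %||% NA)
    }))
    write.csv(md, meta_path, row.names = FALSE)
  }
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Split a trajectory at sampling gaps
#'
#' Gaps longer than `max_gap_min` break the trip into separately processed
#' pieces so that downstream step extraction never spans unsampled intervals.
#' Pieces shorter than 3 fixes are dropped.
#'
#' @param traj a `betpl_trajectory`.
#' @param max_gap_min maximum tolerated gap between fixes, minutes.
#' @return list of `betpl_trajectory` (ids suffixed `.1`, `.2`, ... when
#'   split).
#' @export
split_track_gaps <- function(traj, max_gap_min = 60) {
  gaps <- diff(as.numeric(traj$time)) / 60
  cut <- which(gaps > max_gap_min)
  if (!length(cut)) return(list(traj))
  bounds <- c(0L, cut, nrow(traj))
  pieces <- list()
  for (k in seq_len(length(bounds) - 1L)) {
    i <- (bounds[k] + 1L):bounds[k + 1L]
    if (length(i) < 3L) next
    pieces[[length(pieces) + 1L]] <-
      trajectory(paste0(traj_id(traj), ".", k), traj$time[i], traj$lat[i],
                 traj$lon[i], traj_meta(traj))
  }
  pieces
}

#' Drop fixes within a radius of the trip origin
#'
#' Removes nest-attendance fixes near the colony (trip origin proxy).
#'
#' @param traj a `betpl_trajectory`.
#' @param radius_km removal radius, km; `0` disables the filter.
#' @return a `betpl_trajectory` (unchanged if fewer than 3 fixes would
#'   survive).
#' @export
filter_colony_radius <- function(traj, radius_km = 1) {
  if (radius_km <= 0) return(traj)
  d <- geosphere::distHaversine(cbind(traj$lon[1L], traj$lat[1L]),
                                cbind(traj$lon, traj$lat), r = .EARTH_R)
  keep <- d > radius_km | seq_len(nrow(traj)) == 1L
  if (sum(keep) < 3L) return(traj)
  trajectory(traj_id(traj), traj$time[keep], traj$lat[keep], traj$lon[keep],
             traj_meta(traj))
}
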