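# Shared fixtures and independent oracles for the test suite.

# reference parameter set used across recovery tests
ref_params <- function(lim_a = 0.3) {
  betpl_params(mu = 1.5, lambda1 = 0.02, lambda2 = 0.5, lim_a = lim_a)
}

# coarse grids keep multi-fit tests fast; estimator structure is unchanged
ctl_free_coarse <- function(coarsen = 4L)
  betpl_grid_control("free_mu", coarsen = coarsen)
ctl_fixed_coarse <- function(coarsen = 8L)
  betpl_grid_control("fixed_mu", coarsen = coarsen)

# build a planar track directly from step lengths and headings (radians),
# vertices as fixes (no GPS resampling) -- isolates step extraction from
# sampling-cadence effects
vertex_track <- function(lengths, headings, id = "vtrack") {
  x <- c(0, cumsum(lengths * sin(headings)))
  y <- c(0, cumsum(lengths * cos(headings)))
  out <- data.frame(x = x, y = y,
                    time = as.POSIXct("2015-06-01", tz = "UTC") +
                      600 * seq_along(x))
  attr(out, "id") <- id
  attr(out, "origin") <- c(lat = 36, lon = 12)
  attr(out, "meta") <- list()
  class(out) <- c("betpl_planar_track", "data.frame")
  out
}

# independent brute-force turning-point scan (sign changes with zero carry)
brute_turning_points <- function(s) {
  n <- length(s)
  turns <- integer(0)
  prev <- 0
  for (i in 2:n) {
    d <- s[i] - s[i - 1]
    if (d == 0) next
    cur <- if (d > 0) 1 else -1
    if (prev != 0 && cur != prev) turns <- c(turns, i - 1L)
    prev <- cur
  }
  sort(unique(c(1L, turns, n)))
}

# independent weighted-KS computation by explicit loops
brute_weighted_ks <- function(x, P) {
  x <- sort(x); n <- length(x)
  D <- 0
  for (i in seq_len(n)) {
    if (P[i] <= 0 || P[i] >= 1) next
    w <- sqrt(P[i] * (1 - P[i]))
    D <- max(D, abs(i / n - P[i]) / w, abs((i - 1) / n - P[i]) / w)
  }
  D
}

# independent trilinear interpolation at one query by explicit corner loop
brute_trilinear <- function(grid, la, lo, tm) {
  tq <- as.numeric(tm); tax <- as.numeric(grid$time)
  loc <- function(x, ax) {
    i <- max(1L, min(findInterval(x, ax), length(ax) - 1L))
    f <- (x - ax[i]) / (ax[i + 1L] - ax[i])
    c(i, f)
  }
  lt <- loc(tq, tax); lla <- loc(la, grid$lat); llo <- loc(lo, grid$lon)
  out <- c(u = 0, v = 0)
  for (dt in 0:1) for (da in 0:1) for (do in 0:1) {
    w <- (if (dt) lt[2] else 1 - lt[2]) *
      (if (da) lla[2] else 1 - lla[2]) *
      (if (do) llo[2] else 1 - llo[2])
    out["u"] <- out["u"] + w * grid$u[lt[1] + dt, lla[1] + da, llo[1] + do]
    out["v"] <- out["v"] + w * grid$v[lt[1] + dt, lla[1] + da, llo[1] + do]
  }
  out
}

# small uniform wind grid for interpolation tests
make_test_grid <- function(u_fun = NULL, nt = 4L, nlat = 5L, nlon = 6L) {
  lat <- seq(35, by = 0.5, length.out = nlat)
  lon <- seq(11, by = 0.5, length.out = nlon)
  tm <- as.POSIXct("2015-06-01", tz = "UTC") + (0:(nt - 1)) * 21600
  dims <- c(nt, nlat, nlon)
  if (is.null(u_fun)) {
    u <- array(rnorm(prod(dims)), dims)
    v <- array(rnorm(prod(dims)), dims)
  } else {
    u <- array(0, dims); v <- array(0, dims)
    for (k in seq_len(nt)) for (i in seq_len(nlat)) for (j in seq_len(nlon)) {
      uv <- u_fun(tm[k], lat[i], lon[j])
      u[k, i, j] <- uv[1L]; v[k, i, j] <- uv[2L]
    }
  }
  wind_grid(lat, lon, tm, u, v)
}
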