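# Synthetic data generators: BETPL walks, the mechanistic odor-threshold
# simulator, wind grids and whole cohorts.
#
# The mechanistic simulator embodies the navigation model directly. The
# odor signal s(t) experienced along a flight is a drifting diffusion: on
# acquiring the olfactory map (signal at the detection threshold c_tau) the
# signal decays at the mean dilution rate C/T while fluctuating with
# turbulent diffusivity C^2/T, and the map is lost when the signal is
# exhausted (s = 0). Contact durations are therefore first-passage times of
# a drift-diffusion process: their distribution has an emergent power law
# with exponent 3/2 in the intermediate range, an exponential long-duration
# truncation at rate 1/(4T) from the drift, and a short-duration suppression
# exp(-tau_2 / t) with tau_2 = T c_tau^2 / (4 C^2) from the diffusive
# barrier. None of these three features is an input parameter. Between
# contacts the bird is lost: it reorients uniformly and keeps flying until
# the map is re-acquired after an exponential waiting time.

#' Odor-signal parameters for the mechanistic simulator
#'
#' @param T_corr autocorrelation timescale of the odor signal, seconds: the
#'   typical duration over which experienced concentrations stay correlated.
#' @param C mean odor concentration (arbitrary units); also the scale of the
#'   turbulent fluctuations.
#' @param c_tau detection threshold (same units as `C`): the signal level at
#'   which the olfactory map becomes available.
#' @param flight_speed_kmh cruising ground speed, km/h.
#' @param sim_dt simulation time step, seconds. The default resolves both
#'   the correlation time (`T/100`) and the short-passage scale
#'   `T (c_tau/C)^2 / 4` (32 steps across it), whichever is finer; it is
#'   validated to be at most `T/50`.
#' @param lost_mean mean duration of the lost (map re-acquisition) phase,
#'   seconds; defaults to `T_corr / 20`, so lost-phase displacements are
#'   small-scale flights that the `lim_a` scan is designed to discard.
#' @return an `odor_params` list.
#' @export
odor_params <- function(T_corr, C = 1, c_tau = 0.3, flight_speed_kmh = 40,
                        sim_dt = NULL, lost_mean = NULL) {
  stopifnot(T_corr > 0, C > 0, c_tau > 0, flight_speed_kmh > 0)
  if (c_tau > 6 * C)
    stop("degenerate signal model: c_tau = ", c_tau, " exceeds C + 5 SD = ",
         6 * C, "; the map would essentially never be acquired")
  if (is.null(sim_dt))
    sim_dt <- min(T_corr / 100, T_corr * (c_tau / C)^2 / 32)
  if (sim_dt > T_corr / 50)
    stop("sim_dt must be at most T_corr / 50")
  if (is.null(lost_mean)) lost_mean <- T_corr / 20
  structure(list(T_corr = T_corr, C = C, c_tau = c_tau,
                 flight_speed_kmh = flight_speed_kmh, sim_dt = sim_dt,
                 lost_mean = lost_mean), class = "odor_params")
}

#' Simulate odor-contact durations (flight-segment durations)
#'
#' Direct simulation of the signal-decay first-passage process with a
#' Brownian-bridge correction for within-step boundary crossings. Segments
#' shorter than `2 sim_dt` are discretization artefacts and are discarded
#' when `discard_short = TRUE`.
#'
#' @param odor an [odor_params()].
#' @param n_seg number of contact episodes to simulate.
#' @param seed optional integer seed.
#' @param discard_short drop durations below `2 sim_dt`.
#' @return numeric vector of durations, seconds.
#' @export
sim_odor_segments <- function(odor, n_seg, seed = NULL,
                              discard_short = TRUE) {
  stopifnot(n_seg >= 1)
  dt <- odor$sim_dt
  D <- odor$C^2 / odor$T_corr           # turbulent diffusivity of the signal
  drift <- odor$C / odor$T_corr         # mean dilution rate
  cap_steps <- ceiling(400 * odor$T_corr / dt)  # >> 1/(4T) tail scale
  durations <- with_seed(seed, function() {
    s <- rep(odor$c_tau, n_seg)
    t_ <- numeric(n_seg)
    out <- numeric(n_seg)
    alive <- rep(TRUE, n_seg)
    sq <- sqrt(2 * D * dt)
    step <- 0L
    while (any(alive) && step < cap_steps) {
      step <- step + 1L
      i <- which(alive)
      snew <- s[i] - drift * dt + sq * rnorm(length(i))
      t_[i] <- t_[i] + dt
      hit <- snew <= 0
      pos <- !hit
      if (any(pos))   # bridge probability of an unseen within-step crossing
        hit[pos] <- runif(sum(pos)) < exp(-s[i][pos] * snew[pos] / (D * dt))
      done <- i[hit]
      out[done] <- t_[done]
      alive[done] <- FALSE
      s[i] <- snew
    }
    out[out == 0] <- cap_steps * dt     # censored ultra-long contacts
    out
  })
  if (discard_short) durations <- durations[durations >= 2 * dt]
  durations
}

# von Mises sampler (Best & Fisher 1979 rejection method); mu, output in rad
rvonmises <- function(n, mu = 0, kappa = 0) {
  if (kappa < 1e-8) return((runif(n, -pi, pi) + mu + pi) %% (2 * pi) - pi)
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n); got <- 0L
  while (got < n) {
    m <- n - got
    u1 <- runif(m); u2 <- runif(m); u3 <- runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    ok <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
    th <- sign(u3[ok] - 0.5) * acos(f[ok])
    take <- min(sum(ok), m)
    if (take > 0) {
      out[(got + 1L):(got + take)] <- th[seq_len(take)]
      got <- got + take
    }
  }
  ((out + mu + pi) %% (2 * pi)) - pi
}

# assemble a timed planar polyline from segment (duration s, heading rad)
# pairs, resample at the fix interval and inverse-project about the colony
walk_to_trajectory <- function(durations, headings, speed_kmh, colony,
                               start_time, fix_interval_min, id, meta) {
  v <- speed_kmh / 3600                 # km per second
  tt <- c(0, cumsum(durations))
  dx <- v * durations * sin(headings)
  dy <- v * durations * cos(headings)
  vx <- c(0, cumsum(dx)); vy <- c(0, cumsum(dy))
  fix_dt <- fix_interval_min * 60
  tq <- seq(0, tt[length(tt)], by = fix_dt)
  x <- approx(tt, vx, xout = tq)$y
  y <- approx(tt, vy, xout = tq)$y
  ll <- aeqd_inverse(x, y, colony[1L], colony[2L])
  trajectory(id, start_time + tq, ll[, "lat"], ll[, "lon"], meta)
}

#' Generate a trajectory with BETPL-distributed flight segments
#'
#' Step lengths are drawn from the BETPL; headings are uniform or, with a
#' directional bias, von Mises about a target bearing. The walk is flown at
#' constant speed and resampled to GPS fixes at the recording cadence, then
#' placed on the sphere around a colony.
#'
#' @param params a [betpl_params()] for the step lengths.
#' @param n_steps number of flight segments (>= 50).
#' @param bias optional list `list(bearing = degrees, kappa = concentration)`
#'   for a preferred direction of movement.
#' @param colony `c(lat, lon)` of the trip origin.
#' @param flight_speed_kmh cruising speed.
#' @param fix_interval_min GPS cadence, minutes (default 10).
#' @param start_time first fix time.
#' @param seed optional integer seed.
#' @param id,meta trajectory identity and metadata.
#' @return a `betpl_trajectory`; the drawn headings are attached as
#'   attribute `"headings"` (radians) and step lengths as `"step_lengths"`.
#' @export
gen_betpl_walk <- function(params, n_steps = 200, bias = NULL,
                           colony = c(36, 12), flight_speed_kmh = 40,
                           fix_interval_min = 10,
                           start_time = as.POSIXct("2015-06-01",
                                                   tz = "UTC"),
                           seed = NULL, id = "sim", meta = list()) {
  stopifnot(n_steps >= 50)
  dat <- with_seed(seed, function() {
    lens <- betpl_sample(params, n_steps)
    heads <- if (is.null(bias)) runif(n_steps, -pi, pi) else
      rvonmises(n_steps, bias$bearing * pi / 180, bias$kappa)
    list(lens = lens, heads = heads)
  })
  durations <- dat$lens / (flight_speed_kmh / 3600)
  tr <- walk_to_trajectory(durations, dat$heads, flight_speed_kmh, colony,
                           start_time, fix_interval_min, id, meta)
  attr(tr, "headings") <- dat$heads
  attr(tr, "step_lengths") <- dat$lens
  tr
}

#' Generate a trajectory from the mechanistic odor-threshold simulator
#'
#' Alternates odor-contact flight segments (durations from
#' [sim_odor_segments()], one heading per segment) with lost phases
#' (exponential waiting, uniform reorientation, same flight speed) until the
#' requested trip duration is reached, then resamples to GPS fixes.
#'
#' @param odor an [odor_params()].
#' @param duration_days trip duration.
#' @param bias optional `list(bearing, kappa)` heading bias for contact
#'   segments.
#' @param colony,flight `c(lat, lon)` origin; speed comes from `odor`.
#' @param fix_interval_min GPS cadence, minutes.
#' @param start_time first fix time.
#' @param seed optional integer seed.
#' @param id,meta trajectory identity and metadata.
#' @return a `betpl_trajectory` with attribute `"truth"` recording the
#'   generative parameters and the implied truncation scales (in km):
#'   `lambda1 = 1/(4 T v)` and `lambda2 = T v (c_tau/C)^2 / 4`.
#' @export
gen_odor_walk <- function(odor, duration_days = 4, bias = NULL,
                          colony = c(36, 12), fix_interval_min = 10,
                          start_time = as.POSIXct("2015-06-01", tz = "UTC"),
                          seed = NULL, id = "odor_sim", meta = list()) {
  total <- duration_days * 86400
  v <- odor$flight_speed_kmh / 3600
  sim <- with_seed(seed, function() {
    durs <- numeric(0); heads <- numeric(0); used <- 0
    while (used < total) {
      cycle <- odor$T_corr * (odor$c_tau / odor$C) + odor$lost_mean
      batch <- max(16L, ceiling((total - used) / cycle))
      seg <- sim_odor_segments(odor, batch, discard_short = FALSE)
      lost <- rexp(batch, rate = 1 / odor$lost_mean)
      hc <- if (is.null(bias)) runif(batch, -pi, pi) else
        rvonmises(batch, bias$bearing * pi / 180, bias$kappa)
      hl <- runif(batch, -pi, pi)
      inter <- as.vector(rbind(seg, lost))
      durs <- c(durs, inter)
      heads <- c(heads, as.vector(rbind(hc, hl)))
      used <- used + sum(inter)
    }
    cum <- cumsum(durs)
    k <- which(cum >= total)[1L]
    durs <- durs[seq_len(k)]; durs[k] <- durs[k] - (cum[k] - total)
    list(durs = durs, heads = heads[seq_len(k)])
  })
  tr <- walk_to_trajectory(sim$durs, sim$heads, odor$flight_speed_kmh,
                           colony, start_time, fix_interval_min, id, meta)
  attr(tr, "truth") <- list(
    T_corr = odor$T_corr, C = odor$C, c_tau = odor$c_tau,
    flight_speed_kmh = odor$flight_speed_kmh,
    lambda1 = 1 / (4 * odor$T_corr * v),
    lambda2 = odor$T_corr * v * (odor$c_tau / odor$C)^2 / 4)
  tr
}

#' Generate a gridded wind field consistent with per-trajectory wind speeds
#'
#' Builds a 0.5-degree / 6-hour grid covering all fixes (plus padding).
#' Each trajectory occupies its own time window; within it the field's speed
#' is the trajectory's `U` modulated by a smooth low-amplitude spatial
#' pattern, with a smoothly wandering direction, so that the along-track
#' mean speed matches `U` within a few percent.
#'
#' @param trajs list of `betpl_trajectory` with disjoint time spans.
#' @param U numeric vector of per-trajectory mean wind speeds, m/s.
#' @param seed optional integer seed.
#' @param res_deg,res_hours grid resolution.
#' @param rel_amp relative amplitude of the spatial speed modulation.
#' @return a [wind_grid()].
#' @export
gen_wind_grid <- function(trajs, U, seed = NULL, res_deg = 0.5,
                          res_hours = 6, rel_amp = 0.03) {
  stopifnot(length(trajs) == length(U))
  all_lat <- unlist(lapply(trajs, `[[`, "lat"))
  all_lon <- unlist(lapply(trajs, `[[`, "lon"))
  t0 <- min(vapply(trajs, function(tr) as.numeric(tr$time[1L]), 0))
  t1 <- max(vapply(trajs, function(tr) as.numeric(tr$time[nrow(tr)]), 0))
  step_s <- res_hours * 3600
  lat <- seq(floor((min(all_lat) - 1) / res_deg) * res_deg,
             ceiling((max(all_lat) + 1) / res_deg) * res_deg, by = res_deg)
  lon <- seq(floor((min(all_lon) - 1) / res_deg) * res_deg,
             ceiling((max(all_lon) + 1) / res_deg) * res_deg, by = res_deg)
  tax <- seq(floor(t0 / step_s) * step_s - step_s,
             ceiling(t1 / step_s) * step_s + step_s, by = step_s)
  starts <- vapply(trajs, function(tr) as.numeric(tr$time[1L]), 0)
  # per grid time: wind speed of the trip whose window covers it
  Ut <- U[pmax(findInterval(tax, starts), 1L)]
  ph <- with_seed(seed, function() runif(6, 0, 2 * pi))
  dims <- c(length(tax), length(lat), length(lon))
  u <- array(0, dims); v <- array(0, dims)
  la0 <- mean(lat); lo0 <- mean(lon)
  for (k in seq_along(tax)) {
    spat <- outer(sin(2 * pi * (lat - la0) / 7 + ph[1L]),
                  sin(2 * pi * (lon - lo0) / 7 + ph[2L]))
    spd <- Ut[k] * (1 + rel_amp * spat)
    dir <- ph[3L] + 0.4 * sin(2 * pi * tax[k] / 86400 + ph[4L]) +
      0.2 * outer(sin(2 * pi * (lat - la0) / 11 + ph[5L]),
                  cos(2 * pi * (lon - lo0) / 11 + ph[6L]))
    u[k, , ] <- spd * sin(dir)
    v[k, , ] <- spd * cos(dir)
  }
  wind_grid(lat, lon, as.POSIXct(tax, tz = "UTC",
                                 origin = "1970-01-01"), u, v)
}

# truncated-exponential / bi-exponential step generators for null cohorts
sample_null_steps <- function(n, scenario) {
  if (scenario == "exponential_null") {
    rexp(n, rate = 1 / 20) + 0.2
  } else {
    comp <- runif(n) < 0.5
    ifelse(comp, rexp(n, 1 / 5), rexp(n, 1 / 45)) + 0.2
  }
}

#' Generate a synthetic cohort of trajectories, wind and metadata
#'
#' Scenarios:
#' * `wind_coupled`: per-trip wind speeds `U ~ Uniform(2, 12)` m/s with the
#'   odor-signal parameters coupled to the wind -- `T(U) = T_ref
#'   (U/U_ref)^{3/2}` (so the long-step truncation scales as
#'   `lambda1 ~ U^{-3/2}`, the empirically observed dependence) and mean
#'   concentration `C ~ U^{gamma - 1}` from the wind-driven flux `F ~
#'   U^gamma` (default `gamma = 2.1`), giving `lambda2 ~ U^{1.5 - 2(gamma -
#'   1)}`.
#' * `wind_independent`: same trip construction but `T` and `C` fixed at
#'   their reference values regardless of `U`.
#' * `exponential_null` / `biexponential_null`: walks with single- or
#'   two-scale exponential step lengths, for model-discrimination power
#'   tests.
#'
#' @param n_traj number of trajectories (>= 2).
#' @param scenario one of the four above.
#' @param seed master seed; all randomness flows from it through named
#'   substreams, so regeneration is reproducible.
#' @param gamma wind-flux exponent in \[2, 3\].
#' @param T_ref,U_ref,ratio_ref reference correlation time (s), wind speed
#'   (m/s) and threshold ratio `c_tau/C`.
#' @param duration_range trip durations, days (uniform draw).
#' @param U_range per-trip mean wind speeds, m/s (uniform draw).
#' @param flight_speed_kmh cruising speed.
#' @param colony trip origin `c(lat, lon)`.
#' @param wind generate the wind grid (`TRUE`) or skip it.
#' @return a `betpl_cohort`: list with `trajectories`, `wind`, `truth`
#'   (per-trip generative parameters), `meta`, `scenario`, `seed`.
#' @export
gen_cohort <- function(n_traj = 20, scenario = c("wind_coupled",
                                                 "wind_independent",
                                                 "exponential_null",
                                                 "biexponential_null"),
                       seed = 1L, gamma = 2.1, T_ref = 1125, U_ref = 6,
                       ratio_ref = 0.3, duration_range = c(2, 8),
                       U_range = c(2, 12), flight_speed_kmh = 40,
                       colony = c(36, 12), wind = TRUE) {
  scenario <- match.arg(scenario)
  stopifnot(n_traj >= 2, gamma >= 2, gamma <= 3)
  base_time <- as.POSIXct("2015-05-01", tz = "UTC")
  draws <- with_seed(sub_seed(seed, "cohort"), function() {
    data.frame(
      U = runif(n_traj, U_range[1L], U_range[2L]),
      days = runif(n_traj, duration_range[1L], duration_range[2L]),
      sex = sample(c("male", "female"), n_traj, replace = TRUE),
      period = sample(c("incubation", "chick-rearing"), n_traj,
                      replace = TRUE),
      region = sample(c("Atlantic", "Mediterranean"), n_traj,
                      replace = TRUE))
  })
  trajs <- vector("list", n_traj)
  truth <- vector("list", n_traj)
  start <- base_time
  for (i in seq_len(n_traj)) {
    id <- sprintf("sim%03d", i)
    meta <- list(species = "synthetic_shearwater",
                 colony = ifelse(draws$region[i] == "Atlantic",
                                 "colony_A", "colony_M"),
                 sex = draws$sex[i], period = draws$period[i],
                 region = draws$region[i])
    sseed <- sub_seed(seed, paste0("traj", i))
    if (scenario %in% c("wind_coupled", "wind_independent")) {
      if (scenario == "wind_coupled") {
        T_i <- T_ref * (draws$U[i] / U_ref)^1.5
        C_i <- (draws$U[i] / U_ref)^(gamma - 1)
      } else {
        T_i <- T_ref
        C_i <- 1
      }
      od <- odor_params(T_i, C = C_i, c_tau = ratio_ref,
                        flight_speed_kmh = flight_speed_kmh)
      trajs[[i]] <- gen_odor_walk(od, duration_days = draws$days[i],
                                  colony = colony, start_time = start,
                                  seed = sseed, id = id, meta = meta)
      tru <- attr(trajs[[i]], "truth")
    } else {
      trajs[[i]] <- with_seed(sseed, function() {
        n_steps <- max(60L, ceiling(draws$days[i] * 86400 /
                                      (20 / (flight_speed_kmh / 3600))))
        lens <- sample_null_steps(n_steps, scenario)
        heads <- runif(n_steps, -pi, pi)
        walk_to_trajectory(lens / (flight_speed_kmh / 3600), heads,
                           flight_speed_kmh, colony, start, 10, id, meta)
      })
      tru <- list(T_corr = NA, C = NA, c_tau = NA,
                  flight_speed_kmh = flight_speed_kmh,
                  lambda1 = NA, lambda2 = NA)
    }
    truth[[i]] <- data.frame(id = id, scenario = scenario, U = draws$U[i],
                             days = draws$days[i], T_corr = tru$T_corr,
                             C = tru$C, c_tau = tru$c_tau,
                             lambda1 = tru$lambda1, lambda2 = tru$lambda2)
    start <- start + ceiling(draws$days[i] + 1) * 86400
  }
  wg <- if (wind)
    gen_wind_grid(trajs, draws$U, seed = sub_seed(seed, "wind")) else NULL
  out <- list(trajectories = setNames(trajs, vapply(trajs, traj_id, "")),
              wind = wg, truth = do.call(rbind, truth), meta = draws,
              scenario = scenario, seed = seed)
  class(out) <- "betpl_cohort"
  out
}

#' @export
print.betpl_cohort <- function(x, ...) {
  cat("<betpl_cohort>", length(x$trajectories), "trajectories, scenario",
      x$scenario, "(seed", paste0(x$seed, ")"), "\n")
  invisible(x)
}
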