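test_that("trilinear interpolation is exact at nodes and linear between", {
  set.seed(8)
  g <- make_test_grid()
  # node identity
  w <- interp_wind(g, g$lat[3], g$lon[4], g$time[2])
  expect_equal(w$u, g$u[2, 3, 4], tolerance = 1e-12)
  expect_equal(w$v, g$v[2, 3, 4], tolerance = 1e-12)

  # spatial midpoint of u = 4 and u = 8 gives 6
  g2 <- make_test_grid(u_fun = function(tm, la, lo)
    c(ifelse(lo <= 12, 4, 8), 0))
  # nodes at lon 12 and 12.5 bracket 12.25
  w2 <- interp_wind(g2, g2$lat[2], 12.25, g2$time[1])
  expect_equal(w2$u, 6, tolerance = 1e-12)

  # random queries against the independent corner-loop oracle
  for (r in 1:25) {
    la <- runif(1, min(g$lat), max(g$lat))
    lo <- runif(1, min(g$lon), max(g$lon))
    tm <- g$time[1] + runif(1, 0, as.numeric(diff(range(g$time)),
                                             units = "secs"))
    w <- interp_wind(g, la, lo, tm)
    o <- brute_trilinear(g, la, lo, tm)
    expect_lt(abs(w$u - o[["u"]]), 1e-10)
    expect_lt(abs(w$v - o[["v"]]), 1e-10)
    # bounded by the local corner extremes
    expect_lte(w$u, max(g$u) + 1e-12)
    expect_gte(w$u, min(g$u) - 1e-12)
  }

  # out-of-hull queries name the axis
  expect_error(interp_wind(g, 90, g$lon[1], g$time[1]), "latitude")
  expect_error(interp_wind(g, g$lat[1], g$lon[1], g$time[1] - 86400),
               "time")
})

test_that("wind summaries compute the three power means", {
  tm0 <- as.POSIXct("2015-06-01", tz = "UTC")
  # constant 7 m/s field
  g7 <- make_test_grid(u_fun = function(tm, la, lo) c(7, 0))
  tr <- trajectory("c7", tm0 + c(0, 600, 1200), c(35.5, 35.7, 35.9),
                   c(11.5, 11.6, 11.7))
  s7 <- summarize_wind(tr, g7)
  expect_equal(s7$mean_v, 7, tolerance = 1e-12)
  expect_equal(s7$rms_v, 7, tolerance = 1e-12)
  expect_equal(s7$cubic_v, 7, tolerance = 1e-12)

  # speeds {3, 4}: hand-computed weighted averages
  g34 <- make_test_grid(u_fun = function(tm, la, lo)
    c(ifelse(la < 35.9, 3, 4), 0))
  # third fix outside the hull is dropped; the two usable speeds are {3, 4}
  tr2 <- trajectory("s34", tm0 + c(0, 600, 1200), c(35.5, 36, 80),
                    c(11.5, 11.5, 11.5))
  s34 <- summarize_wind(tr2, g34)
  expect_equal(s34$mean_v, 3.5, tolerance = 1e-12)
  expect_equal(s34$rms_v, sqrt(12.5), tolerance = 1e-12)
  expect_equal(s34$cubic_v, 45.5^(1 / 3), tolerance = 1e-12)

  # power-mean ordering on a random field
  set.seed(10)
  g <- make_test_grid()
  tr3 <- trajectory("rnd", tm0 + 600 * (0:9), runif(10, 35.2, 36.8),
                    runif(10, 11.2, 13.2))
  s <- summarize_wind(tr3, g)
  expect_lte(s$mean_v, s$rms_v + 1e-12)
  expect_lte(s$rms_v, s$cubic_v + 1e-12)
})

test_that("head/cross decomposition follows the sign conventions", {
  tm0 <- as.POSIXct("2015-06-01", tz = "UTC")
  # wind due north 5 m/s, flight due north: pure tailwind
  gn <- make_test_grid(u_fun = function(tm, la, lo) c(0, 5))
  trn <- trajectory("north", tm0 + c(0, 600, 1200), c(35.5, 35.6, 35.7),
                    c(12, 12, 12))
  hn <- headtail_components(trn, gn)
  expect_lt(max(abs(hn$per_fix$head - (-5))), 1e-9)
  expect_lt(max(abs(hn$per_fix$cross)), 1e-9)
  expect_equal(hn$mean_tail, 5, tolerance = 1e-9)

  # wind due east, flight due north: pure crosswind
  ge <- make_test_grid(u_fun = function(tm, la, lo) c(5, 0))
  he <- headtail_components(trn, ge)
  expect_lt(max(abs(he$per_fix$head)), 1e-9)
  expect_lt(max(abs(abs(he$per_fix$cross) - 5)), 1e-9)

  # vector-algebra oracle and the Pythagorean closure on random cases
  set.seed(20)
  g <- make_test_grid()
  tr <- trajectory("rnd", tm0 + 600 * (0:6), 35.3 + cumsum(runif(7, 0, 0.05)),
                   11.3 + cumsum(runif(7, 0, 0.05)))
  h <- headtail_components(tr, g)
  n <- nrow(tr)
  w <- interp_wind(g, tr$lat[-n], tr$lon[-n], tr$time[-n])
  br <- geosphere::bearing(cbind(tr$lon[-n], tr$lat[-n]),
                           cbind(tr$lon[-1], tr$lat[-1])) * pi / 180
  expect_lt(max(abs(h$per_fix$head - (-(w$u * sin(br) + w$v * cos(br))))),
            1e-12)
  expect_lt(max(abs(h$per_fix$cross - (w$u * cos(br) - w$v * sin(br)))),
            1e-12)
  expect_lt(max(abs(h$per_fix$head^2 + h$per_fix$cross^2 -
                      h$per_fix$speed^2)), 1e-9)
})

test_that("the CSV dialect round-trips and matches the in-memory grid", {
  set.seed(30)
  g <- make_test_grid()
  f <- tempfile(fileext = ".csv")
  write_wind_csv(g, f)
  g2 <- read_wind_csv(f)
  expect_equal(g2$u, g$u, tolerance = 1e-12)
  expect_equal(g2$v, g$v, tolerance = 1e-12)
  expect_equal(as.numeric(g2$time), as.numeric(g$time))

  tm0 <- as.POSIXct("2015-06-01", tz = "UTC")
  tr <- trajectory("rt", tm0 + 600 * (0:5), runif(6, 35.2, 36.8),
                   runif(6, 11.2, 13.2))
  expect_equal(summarize_wind(tr, g), summarize_wind(tr, g2),
               tolerance = 1e-12)
  unlink(f)
})

test_that("masked corner cells fall back to the nearest valid value", {
  g <- make_test_grid(u_fun = function(tm, la, lo) c(3, 0))
  g$u[1, 1, 1] <- NA
  w <- interp_wind(g, g$lat[1] + 0.1, g$lon[1] + 0.1, g$time[1])
  expect_true(w$filled)
  expect_equal(w$u, 3, tolerance = 1e-12)
})
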