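test_that("planar projection reproduces geodesic distances", {
  # two fixes half a degree apart in latitude: haversine oracle
  tr <- trajectory("t1", as.POSIXct("2015-06-01", tz = "UTC") + c(0, 600, 1200),
                   lat = c(36, 36.25, 36.5), lon = c(12, 12, 12))
  pt <- project_to_plane(tr)
  sep <- sqrt(diff(pt$x[c(1, 3)])^2 + diff(pt$y[c(1, 3)])^2)
  oracle <- geosphere::distHaversine(c(12, 36), c(12, 36.5), r = 6371.0088)
  expect_lt(abs(sep / oracle - 1), 0.01)

  # identical fixes project to identical points
  tr2 <- trajectory("t2", as.POSIXct("2015-06-01", tz = "UTC") + c(0, 600, 1200),
                    lat = rep(36, 3), lon = rep(12, 3))
  pt2 <- project_to_plane(tr2)
  expect_equal(max(abs(pt2$x)), 0, tolerance = 1e-9)
  expect_equal(max(abs(pt2$y)), 0, tolerance = 1e-9)

  # a 3-4-5 right triangle built by inverse projection keeps its ratios
  ll <- betpl:::aeqd_inverse(c(0, 30, 30), c(0, 0, 40), 36, 12)
  tr3 <- trajectory("t3", as.POSIXct("2015-06-01", tz = "UTC") + c(0, 3600, 7200),
                    lat = ll[, "lat"], lon = ll[, "lon"])
  pt3 <- project_to_plane(tr3, max_step_km_per_10min = 1e6)
  d12 <- sqrt((pt3$x[2] - pt3$x[1])^2 + (pt3$y[2] - pt3$y[1])^2)
  d23 <- sqrt((pt3$x[3] - pt3$x[2])^2 + (pt3$y[3] - pt3$y[2])^2)
  d13 <- sqrt((pt3$x[3] - pt3$x[1])^2 + (pt3$y[3] - pt3$y[1])^2)
  expect_lt(abs(d12 / 30 - 1), 0.01)
  expect_lt(abs(d23 / 40 - 1), 0.01)
  expect_lt(abs(d13 / 50 - 1), 0.01)
})

test_that("projection rejects bad input", {
  expect_error(trajectory("b", Sys.time() + c(0, 600, 1200),
                          c(36, NA, 36.2), c(12, 12, 12)),
               "non-finite")
  # implausible jump flagged with fix index
  tr <- trajectory("b2", as.POSIXct("2015-06-01", tz = "UTC") + c(0, 600, 1200),
                   lat = c(36, 36, 39), lon = c(12, 12, 12))
  expect_error(project_to_plane(tr), "implausible")
})

test_that("rotation is a rigid isometry about the first point", {
  set.seed(7)
  trk <- vertex_track(rexp(40, 1 / 5), runif(40, -pi, pi))
  expect_equal(rotate_track(trk, 0)$x, trk$x)
  expect_equal(rotate_track(trk, 0)$y, trk$y)

  unit <- vertex_track(1, pi / 2)  # offset (1, 0)
  r90 <- rotate_track(unit, 90)
  expect_equal(r90$x[2] - r90$x[1], 0, tolerance = 1e-12)
  expect_equal(r90$y[2] - r90$y[1], 1, tolerance = 1e-12)

  for (th in c(15, 45, 123.4)) {
    rot <- rotate_track(trk, th)
    d0 <- dist(cbind(trk$x, trk$y))
    d1 <- dist(cbind(rot$x, rot$y))
    expect_lt(max(abs(d0 - d1)), 1e-9)
  }
})

test_that("turning points match a brute-force sign-change scan", {
  # worked example: boundaries give 1-D steps {2, 1, 2}
  s <- c(0, 1, 2, 1, 3)
  b <- turning_points_1d(s)
  expect_equal(b, c(1L, 3L, 4L, 5L))
  expect_equal(abs(diff(s[b])), c(2, 1, 2))

  expect_equal(turning_points_1d(c(0, 1, 2, 3)), c(1L, 4L))
  expect_equal(abs(diff(c(0, 3))), 3)

  alt <- c(0, 1, 0, 1)
  expect_equal(turning_points_1d(alt), 1:4)
  expect_equal(abs(diff(alt[1:4])), c(1, 1, 1))

  # property: agreement with the independent scan on random walks with ties
  set.seed(11)
  for (rep in 1:20) {
    s <- cumsum(sample(c(-1L, 0L, 1L), 60, replace = TRUE))
    expect_identical(turning_points_1d(s), brute_turning_points(s))
  }
})

test_that("step extraction pools both axes and filters by lim_a", {
  # axis-aligned unit moves alternating direction: all pooled steps are 1 km
  n <- 40
  trk <- data.frame(x = rep(c(0, 1), n / 2),
                    y = rep(c(0, 0.5, 1, 0.5), n / 4),
                    time = as.POSIXct("2015-06-01", tz = "UTC") +
                      600 * seq_len(n))
  attr(trk, "id") <- "unit"
  class(trk) <- c("betpl_planar_track", "data.frame")
  s <- extract_steps(trk, theta = 0, lim_a = 0.5)
  expect_true(all(s$lengths %in% c(0.5, 1)))
  expect_true(s$sufficient)

  s2 <- extract_steps(trk, theta = 0, lim_a = 2)
  expect_equal(s2$n, 0L)
  expect_false(s2$sufficient)

  # pooling: n equals the sum of per-axis counts after filtering
  set.seed(3)
  trk2 <- vertex_track(rexp(200, 1 / 3), runif(200, -pi, pi))
  lim_a <- 0.4
  s3 <- extract_steps(trk2, theta = 30, lim_a = lim_a)
  rot <- rotate_track(trk2, 30)
  nx <- sum(abs(diff(rot$x[turning_points_1d(rot$x)])) >= lim_a)
  ny <- sum(abs(diff(rot$y[turning_points_1d(rot$y)])) >= lim_a)
  expect_equal(s3$n, nx + ny)

  # monotonicity: raising lim_a never increases the sample size
  ns <- vapply(c(0.1, 0.3, 0.6, 1, 2),
               function(a) extract_steps(trk2, 0, a)$n, integer(1))
  expect_true(all(diff(ns) <= 0))
})

test_that("axis projection preserves a pure power law", {
  # walk with Pareto steps (mu = 2): pooled 1-D steps refit mu within 0.1
  p <- betpl_params(mu = 2, lambda1 = 0, lambda2 = 0, lim_a = 0.1)
  set.seed(42)
  lens <- betpl_sample(p, 10000)
  trk <- vertex_track(lens, runif(10000, -pi, pi))
  # as in the full method, the lower bound is chosen by goodness of fit:
  # the projection distorts only the region near the generative cutoff
  cand <- lapply(c(0.3, 1, 2, 3), function(a) {
    s <- extract_steps(trk, theta = 0, lim_a = a)
    f <- fit_alternative(s, "powerlaw")
    D <- weighted_ks(s, cdf = betpl:::alt_cdf_fun(f))$D_weighted
    list(mu = f$par[["mu"]], D = D)
  })
  best <- cand[[which.min(vapply(cand, `[[`, 0, "D"))]]
  expect_lt(abs(best$mu - 2), 0.1)
})
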