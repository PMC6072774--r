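# builds a records table directly, bypassing the fitting pipeline
fake_records <- function(n, lambda1, mean_v, mu = NULL, lambda2 = NULL,
                         days = NULL, displ = NULL, sex = NULL,
                         period = NULL) {
  out <- data.frame(
    id = sprintf("r%03d", seq_len(n)),
    lambda1 = lambda1, lambda1_fixed = lambda1,
    lambda2 = lambda2 %||% lambda1 * 10,
    lambda2_fixed = lambda2 %||% lambda1 * 10,
    mu = mu %||% rep(1.5, n), mean_v = mean_v,
    rms_v = mean_v, cubic_v = mean_v,
    duration_days = days %||% rep(5, n),
    max_displacement_km = displ %||% rep(200, n),
    sex = sex %||% rep(c("male", "female"), length.out = n),
    period = period %||% rep(c("incubation", "chick-rearing"),
                             length.out = n),
    region = rep(c("Atlantic", "Mediterranean"), length.out = n),
    colony = "c1")
  class(out) <- c("betpl_records", "data.frame")
  out
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("OLS output matches the closed-form normal equations", {
  set.seed(40)
  for (r in 1:5) {
    n <- 30
    v <- exp(runif(n, 0.5, 2.5))
    lam <- exp(-1.2 * log(v) + rnorm(n, 0, 0.3))
    rec <- fake_records(n, lam, v)
    fit <- regress_lambda_on_wind(rec, "lambda1", estimates = "free")
    o <- betpl:::ols_closed_form(log(v), log(lam))
    expect_lt(abs(fit$beta - o$beta), 1e-10)
    expect_lt(abs(fit$se - o$se), 1e-10)
    expect_lt(abs(fit$p - o$p), 1e-10)
    expect_equal(fit$df, o$df)
  }
})

test_that("a noiseless power-law dependence is recovered exactly", {
  v <- seq(2, 12, length.out = 20)
  lam <- 0.3 * v^(-1.5) * exp(rnorm(20, 0, 1e-8))
  rec <- fake_records(20, lam, v)
  fit <- regress_lambda_on_wind(rec, "lambda1", estimates = "free")
  expect_equal(fit$beta, -1.5, tolerance = 1e-6)
  expect_lt(fit$p, 1e-15)
  expect_true(all(fit$bands$logl >= fit$bands$pi_lo &
                    fit$bands$logl <= fit$bands$pi_hi))
})

test_that("noisy slopes are recovered and permuted wind is null", {
  hits_rec <- 0L; null_ok <- 0L
  for (seed in 1:5) {
    set.seed(200 + seed)
    n <- 50
    v <- exp(runif(n, log(2), log(12)))
    lam <- 0.3 * v^(-1.5) * exp(rnorm(n, 0, 0.4))
    rec <- fake_records(n, lam, v)
    fit <- regress_lambda_on_wind(rec, "lambda1", estimates = "free")
    if (abs(fit$beta + 1.5) < 3 * fit$se) hits_rec <- hits_rec + 1L
    rec_perm <- fake_records(n, lam, sample(v))
    fitp <- regress_lambda_on_wind(rec_perm, "lambda1",
                                   estimates = "free")
    if (fitp$p > 0.05) null_ok <- null_ok + 1L
  }
  expect_gte(hits_rec, 4L)
  expect_gte(null_ok, 4L)
})

test_that("subsetting and exclusions are honoured", {
  v <- exp(runif(40, 0.5, 2.5))
  lam <- 0.3 * v^(-1) * exp(rnorm(40, 0, 0.2))
  lam[1:3] <- 0                           # unusable, must be excluded
  rec <- fake_records(40, lam, v, days = rep(c(2, 6), each = 20))
  fit <- regress_lambda_on_wind(rec, "lambda1", estimates = "free",
                                min_days = 4)
  expect_equal(fit$n_used, 20 - sum(lam[rec$duration_days > 4] == 0))
  expect_error(regress_lambda_on_wind(rec[1:12, ], "lambda1",
                                      min_days = 6), "fewer than 10")
})

test_that("exponent-wind correlation behaves at the degenerate extremes", {
  v <- exp(runif(110, 0.5, 2.5))
  rec_const <- fake_records(110, 0.01 * v^0, v, mu = rep(1.5, 110))
  expect_error(mu_wind_independence(rec_const), "degenerate")

  rec_lin <- fake_records(110, 0.01 * v^0, v, mu = 1 + 0.1 * v)
  r_lin <- mu_wind_independence(rec_lin)
  expect_equal(r_lin$r, 1, tolerance = 1e-9)
  expect_equal(r_lin$df, 108)

  ok <- 0L
  for (seed in 1:3) {
    set.seed(seed)
    rec <- fake_records(110, 0.01 * v^0, v,
                        mu = 1.5 + rnorm(110, 0, 0.15))
    if (abs(mu_wind_independence(rec)$r) < 0.3) ok <- ok + 1L
  }
  expect_gte(ok, 3L)
})

test_that("exponent error shrinks with trip extent", {
  # scatter about 3/2 that tightens deterministically with displacement
  displ <- seq(50, 500, length.out = 60)
  err <- 0.4 * (500 / displ)^0.5 * rep(c(1, -1), 30)
  rec <- fake_records(60, rep(0.01, 60), rep(5, 60),
                      mu = 1.5 + err, displ = displ)
  tab <- mu_convergence(rec, thresholds = c(0, 100, 200, 300))
  expect_equal(nrow(tab), 4)
  expect_true(all(diff(tab$mse) < 0))
  expect_lt(attr(tab, "trend_tau"), 0)

  rec2 <- fake_records(20, rep(0.01, 20), rep(5, 20),
                       mu = rep(1.5, 20), displ = seq(50, 500, length.out = 20))
  tab2 <- mu_convergence(rec2, thresholds = c(0, 100))
  expect_true(all(tab2$mse == 0))
  tab3 <- mu_convergence(rec2, thresholds = 0)
  expect_equal(nrow(tab3), 1)
  expect_null(attr(tab3, "trend_tau"))
})

test_that("covariate screening reports null effects and drops confounds", {
  set.seed(77)
  n <- 60
  v <- exp(runif(n, log(2), log(12)))
  lam <- 0.3 * v^(-1.5) * exp(rnorm(n, 0, 0.3))
  rec <- fake_records(n, lam, v,
                      sex = sample(c("male", "female"), n, TRUE),
                      period = sample(c("incubation", "chick-rearing"),
                                      n, TRUE))
  cm <- covariate_models(rec, "lambda1", covariates = c("sex", "period"),
                         estimates = "free")
  ref_row <- cm$table$model == "log(v) [reference]"
  expect_equal(cm$table$delta_aic[ref_row], 0)  # reference vs itself
  added <- cm$table[!ref_row, , drop = FALSE]
  if (nrow(added)) expect_true(all(added$p > 0.05))

  # a two-level covariate aligned with wind is excluded as confounded
  rec$region <- ifelse(v > median(v), "Atlantic", "Mediterranean")
  cm2 <- covariate_models(rec, "lambda1",
                          covariates = c("sex", "region"),
                          estimates = "free")
  expect_match(cm2$excluded$region, "confounded")
  expect_false(any(grepl("region", cm2$table$model)))
})

test_that("head/tail-wind regression recovers a planted effect", {
  n <- 30
  head_w <- runif(n, 0, 6); tail_w <- runif(n, 0, 6)
  lam <- 0.02 * exp(0.3 * head_w) * exp(rnorm(n, 0, 1e-8))
  rec <- fake_records(n, lam, rep(5, n))
  rec$mean_head <- head_w; rec$mean_tail <- tail_w
  ht <- headtail_regression(rec, "lambda1", estimates = "free")
  expect_equal(unname(ht$coef["head", 1]), 0.3, tolerance = 1e-6)
  expect_lt(abs(ht$coef["tail", 1]), 1e-6)

  expect_error(headtail_regression(rec[0, ], "lambda1"), "no usable")
  rec2 <- fake_records(12, rep(0.01, 12), rep(5, 12))
  expect_error(headtail_regression(rec2, "lambda1"), "head/tail")
})
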