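# Hypothesis tests: log-log regressions of the truncation parameters on
# wind speed, exponent universality checks, covariate screening and the
# head/tail-wind decomposition.

#' Assemble per-trip records from pipeline stage results
#'
#' One row per trajectory that survived parametrization scanning (and, when
#' a comparison table is supplied, whose best-supported family is the
#' BETPL).
#'
#' @param trajs list of `betpl_trajectory`.
#' @param scans_free,scans_fixed named lists of `betpl_scan` results in
#'   free-mu and fixed-mu mode (either may be `NULL`).
#' @param windsums data frame from [summarize_wind()] rows (or `NULL`).
#' @param comparisons optional named list of `betpl_comparison`; trips whose
#'   `best_family` is not `"betpl"` are dropped.
#' @param headtails optional named list from [headtail_components()].
#' @return data frame of class `betpl_records`.
#' @export
trip_records <- function(trajs, scans_free = NULL, scans_fixed = NULL,
                         windsums = NULL, comparisons = NULL,
                         headtails = NULL) {
  rows <- lapply(trajs, function(tr) {
    id <- traj_id(tr)
    sf <- scans_free[[id]]; sx <- scans_fixed[[id]]
    if ((!is.null(sf) && is.na(sf$selected)) ||
        (!is.null(sx) && is.na(sx$selected))) return(NULL)
    if (!is.null(comparisons)) {
      cp <- comparisons[[id]]
      if (is.null(cp) || cp$best_family != "betpl") return(NULL)
    }
    m <- traj_meta(tr)
    r <- data.frame(
      id = id,
      duration_days = trip_duration_days(tr),
      max_displacement_km = max_displacement_km(tr),
      sex = m$sex %||% NA, period = m$period %||% NA,
      region = m$region %||% NA, colony = m$colony %||% NA)
    if (!is.null(sf)) {
      p <- sf$fit$params_mean
      r$mu <- p$mu; r$lambda1 <- p$lambda1; r$lambda2 <- p$lambda2
      r$lim_a <- sf$fit$lim_a; r$theta <- sf$fit$theta; r$n_steps <- sf$fit$n
    }
    if (!is.null(sx)) {
      p <- sx$fit$params_mean
      r$lambda1_fixed <- p$lambda1; r$lambda2_fixed <- p$lambda2
    }
    if (!is.null(windsums)) {
      w <- windsums[windsums$id == id, , drop = FALSE]
      if (nrow(w) == 1L) {
        r$mean_v <- w$mean_v; r$rms_v <- w$rms_v; r$cubic_v <- w$cubic_v
      }
    }
    if (!is.null(headtails) && !is.null(headtails[[id]])) {
      r$mean_head <- headtails[[id]]$mean_head
      r$mean_tail <- headtails[[id]]$mean_tail
    }
    r
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("betpl_records", "data.frame")
  out
}

subset_records <- function(records, min_days = NULL, min_displacement = NULL) {
  keep <- rep(TRUE, nrow(records))
  if (!is.null(min_days)) keep <- keep & records$duration_days > min_days
  if (!is.null(min_displacement))
    keep <- keep & records$max_displacement_km >= min_displacement
  records[keep, , drop = FALSE]
}

#' Log-log regression of a truncation parameter on wind speed
#'
#' Ordinary least squares of `log(lambda)` on `log(wind)`. Besides the
#' slope, its standard error, t-test p-value and 95% confidence interval,
#' per-point 95% confidence and prediction bands are returned and records
#' outside the prediction band are flagged as outliers.
#'
#' @param records a [trip_records()] data frame.
#' @param response `"lambda1"` or `"lambda2"`.
#' @param wind `"mean_v"`, `"rms_v"` or `"cubic_v"`.
#' @param estimates `"free"` (free-mu fit) or `"fixed"` (mu pinned at 3/2;
#'   the fixed-mu estimates are the more precise choice for `lambda2`).
#' @param min_days optional trip-duration subsetting (strictly more than
#'   `min_days` days); the reference report uses 4.
#' @param min_displacement optional minimum displacement subsetting, km.
#' @return a `betpl_regression`: list with `beta`, `se`, `p`, `df`, `ci95`,
#'   `bands` (per-record fit/CI/PI/outlier), `n_used`, `n_excluded`,
#'   `model` (the `lm` fit), `response`, `wind`, `estimates`.
#' @export
regress_lambda_on_wind <- function(records, response = c("lambda1",
                                                         "lambda2"),
                                   wind = c("mean_v", "rms_v", "cubic_v"),
                                   estimates = c("free", "fixed"),
                                   min_days = NULL,
                                   min_displacement = NULL) {
  response <- match.arg(response); wind <- match.arg(wind)
  estimates <- match.arg(estimates)
  col <- if (estimates == "fixed") paste0(response, "_fixed") else response
  if (!col %in% names(records))
    stop("records lack column ", col)
  rec <- subset_records(records, min_days, min_displacement)
  y <- rec[[col]]; v <- rec[[wind]]
  ok <- is.finite(y) & is.finite(v) & y > 0 & v > 0
  n_excluded <- sum(!ok)
  rec <- rec[ok, , drop = FALSE]
  if (nrow(rec) < 10L)
    stop("fewer than 10 usable records after subsetting (", nrow(rec), ")")
  d <- data.frame(logl = log(rec[[col]]), logv = log(rec[[wind]]))
  fit <- lm(logl ~ logv, data = d)
  sm <- summary(fit)
  pred_c <- predict(fit, interval = "confidence", level = 0.95)
  pred_p <- suppressWarnings(
    predict(fit, interval = "prediction", level = 0.95))
  bands <- data.frame(id = rec$id, logv = d$logv, logl = d$logl,
                      fit = pred_c[, "fit"],
                      ci_lo = pred_c[, "lwr"], ci_hi = pred_c[, "upr"],
                      pi_lo = pred_p[, "lwr"], pi_hi = pred_p[, "upr"])
  bands$outlier <- bands$logl < bands$pi_lo | bands$logl > bands$pi_hi
  out <- list(beta = unname(coef(fit)[2L]),
              se = sm$coefficients[2L, 2L],
              p = sm$coefficients[2L, 4L],
              df = fit$df.residual,
              ci95 = unname(confint(fit)[2L, ]),
              bands = bands, n_used = nrow(rec), n_excluded = n_excluded,
              model = fit, response = response, wind = wind,
              estimates = estimates, min_days = min_days)
  class(out) <- "betpl_regression"
  out
}

#' @export
print.betpl_regression <- function(x, ...) {
  cat(sprintf(
    "<betpl_regression> log(%s%s) ~ log(%s): beta = %.3f +/- %.3f (p = %.3g, df = %d)\n",
    x$response, if (x$estimates == "fixed") " [mu=3/2]" else "", x$wind,
    x$beta, x$se, x$p, x$df))
  cat(sprintf("  95%% CI [%.3f, %.3f]; n = %d (%d excluded), %d outliers\n",
              x$ci95[1L], x$ci95[2L], x$n_used, x$n_excluded,
              sum(x$bands$outlier)))
  invisible(x)
}

#' Log-log scatter with confidence and prediction bands
#' @param x a `betpl_regression`.
#' @param ... passed to `plot`.
#' @export
plot_regression <- function(x, ...) {
  b <- x$bands[order(x$bands$logv), ]
  plot(b$logv, b$logl, xlab = paste0("log ", x$wind),
       ylab = paste0("log ", x$response), pch = ifelse(b$outlier, 1, 16),
       ...)
  lines(b$logv, b$fit, lwd = 2)
  lines(b$logv, b$ci_lo, col = "blue"); lines(b$logv, b$ci_hi, col = "blue")
  lines(b$logv, b$pi_lo, col = "red3"); lines(b$logv, b$pi_hi, col = "red3")
  legend("topright", c("fit", "95% CI (mean)", "95% PI (individual)"),
         lty = 1, col = c("black", "blue", "red3"), bty = "n")
}

#' Correlation of the fitted exponent with wind speed
#'
#' The theory predicts a universal exponent independent of wind; this is
#' the Pearson correlation of the fitted `mu` with mean wind speed, with
#' the usual t-test (df = n - 2).
#'
#' @param records a [trip_records()] data frame (needs `mu` and `mean_v`).
#' @param min_days optional duration subsetting.
#' @return list with `r`, `p`, `df`, `n`.
#' @export
mu_wind_independence <- function(records, min_days = NULL) {
  rec <- subset_records(records, min_days)
  ok <- is.finite(rec$mu) & is.finite(rec$mean_v)
  rec <- rec[ok, , drop = FALSE]
  if (nrow(rec) < 10L) stop("fewer than 10 usable records")
  if (sd(rec$mu) == 0 || sd(rec$mean_v) == 0)
    stop("degenerate variance: correlation undefined")
  ct <- cor.test(rec$mu, rec$mean_v)
  list(r = unname(ct$estimate), p = ct$p.value,
       df = unname(ct$parameter), n = nrow(rec))
}

#' Convergence of the fitted exponent with trip extent
#'
#' Mean squared error of the fitted `mu` about the predicted 3/2 within
#' cumulative subsets of increasing maximum displacement: longer trips
#' carry more steps, so the error should shrink as the threshold rises.
#'
#' @param records a [trip_records()] data frame.
#' @param thresholds displacement thresholds, km; default quintile-based.
#' @param mu_ref reference exponent (default 3/2).
#' @return data frame (`threshold_km`, `n`, `mse`) with attributes
#'   `trend_tau` and `trend_p` (Kendall rank correlation of MSE with
#'   threshold) when more than one bin is usable.
#' @export
mu_convergence <- function(records, thresholds = NULL, mu_ref = 1.5) {
  ok <- is.finite(records$mu) & is.finite(records$max_displacement_km)
  rec <- records[ok, , drop = FALSE]
  if (is.null(thresholds))
    thresholds <- unname(quantile(rec$max_displacement_km,
                                  c(0, 0.2, 0.4, 0.6, 0.8)))
  rows <- lapply(thresholds, function(d) {
    sub <- rec[rec$max_displacement_km >= d, , drop = FALSE]
    if (!nrow(sub)) return(NULL)
    data.frame(threshold_km = d, n = nrow(sub),
               mse = mean((sub$mu - mu_ref)^2))
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (nrow(out) > 1L && sd(out$mse) > 0) {
    ct <- suppressWarnings(cor.test(out$threshold_km, out$mse,
                                    method = "kendall"))
    attr(out, "trend_tau") <- unname(ct$estimate)
    attr(out, "trend_p") <- ct$p.value
  }
  out
}

#' Screen biological covariates against the wind regression
#'
#' Starting from the reference model `log(lambda) ~ log(mean_v)`, each
#' covariate is added as an interaction with the wind slope
#' (`log(v):cov`) and as interaction plus main effect; models are ranked
#' by the AIC difference to the reference, and only extensions with
#' `delta AIC <= 4` are reported. A covariate that is confounded with wind
#' (two-sample t-test on `log(mean_v)` for two-level covariates, p < 0.05)
#' is excluded up front, as are rank-deficient models.
#'
#' @param records a [trip_records()] data frame.
#' @param response `"lambda1"` or `"lambda2"`.
#' @param covariates character vector of metadata columns.
#' @param estimates `"free"` or `"fixed"`.
#' @param min_days optional duration subsetting.
#' @param delta_aic_max reporting threshold.
#' @return list with `table` (model, delta_aic, added-term t and p),
#'   `reference_aic`, `excluded` (named reasons).
#' @export
covariate_models <- function(records, response = c("lambda1", "lambda2"),
                             covariates = c("sex", "period", "region"),
                             estimates = c("free", "fixed"),
                             min_days = NULL, delta_aic_max = 4) {
  response <- match.arg(response); estimates <- match.arg(estimates)
  col <- if (estimates == "fixed") paste0(response, "_fixed") else response
  rec <- subset_records(records, min_days)
  ok <- is.finite(rec[[col]]) & rec[[col]] > 0 & is.finite(rec$mean_v) &
    rec$mean_v > 0
  rec <- rec[ok, , drop = FALSE]
  d <- data.frame(logl = log(rec[[col]]), logv = log(rec$mean_v))
  excluded <- list()
  use <- character(0)
  for (cv in covariates) {
    x <- rec[[cv]]
    if (is.null(x) || anyNA(x) || length(unique(x)) < 2L) {
      excluded[[cv]] <- "missing or single-level"
      next
    }
    if (length(unique(x)) == 2L) {
      tt <- t.test(d$logv ~ factor(x))
      if (tt$p.value < 0.05) {
        excluded[[cv]] <- sprintf(
          "confounded with wind (t = %.2f, p = %.3g)",
          tt$statistic, tt$p.value)
        next
      }
    }
    d[[cv]] <- factor(x)
    use <- c(use, cv)
  }
  ref <- lm(logl ~ logv, data = d)
  rows <- list(data.frame(model = "log(v) [reference]", delta_aic = 0,
                          t = NA_real_, p = NA_real_))
  for (cv in use) {
    for (form in c(sprintf("logl ~ logv + logv:%s", cv),
                   sprintf("logl ~ logv + logv:%s + %s", cv, cv))) {
      m <- lm(as.formula(form), data = d)
      if (anyNA(coef(m))) {
        excluded[[form]] <- "rank deficient"
        next
      }
      sm <- summary(m)$coefficients
      added <- setdiff(rownames(sm), rownames(summary(ref)$coefficients))
      rows[[length(rows) + 1L]] <- data.frame(
        model = sub("logl ~ ", "", form), delta_aic = AIC(m) - AIC(ref),
        t = sm[added[1L], 3L], p = sm[added[1L], 4L])
    }
  }
  tab <- do.call(rbind, rows)
  tab <- tab[tab$delta_aic <= delta_aic_max, , drop = FALSE]
  tab <- tab[order(tab$delta_aic), , drop = FALSE]
  rownames(tab) <- NULL
  list(table = tab, reference_aic = AIC(ref), excluded = excluded,
       n = nrow(d))
}

#' Regression of a truncation parameter on head- and tail-wind strength
#'
#' OLS of `log(lambda)` on the per-trip mean headwind and mean tailwind
#' components, to probe for a direct mechanical effect of wind on flight
#' independent of odor transport.
#'
#' @param records a [trip_records()] with `mean_head`/`mean_tail` columns.
#' @param response `"lambda1"` or `"lambda2"`.
#' @param estimates `"free"` or `"fixed"`.
#' @param min_days optional duration subsetting.
#' @return list with `coef` (matrix of estimate/se/t/p for head and tail),
#'   `model`, `n`.
#' @export
headtail_regression <- function(records, response = c("lambda1", "lambda2"),
                                estimates = c("free", "fixed"),
                                min_days = NULL) {
  response <- match.arg(response); estimates <- match.arg(estimates)
  col <- if (estimates == "fixed") paste0(response, "_fixed") else response
  rec <- subset_records(records, min_days)
  if (!all(c("mean_head", "mean_tail") %in% names(rec)))
    stop("records lack head/tail wind summaries")
  ok <- is.finite(rec[[col]]) & rec[[col]] > 0 & is.finite(rec$mean_head) &
    is.finite(rec$mean_tail)
  rec <- rec[ok, , drop = FALSE]
  if (!nrow(rec)) stop("no usable records")
  d <- data.frame(logl = log(rec[[col]]), head = rec$mean_head,
                  tail = rec$mean_tail)
  fit <- lm(logl ~ head + tail, data = d)
  sm <- summary(fit)$coefficients
  list(coef = sm[c("head", "tail"), , drop = FALSE], model = fit,
       n = nrow(d))
}

# closed-form OLS (normal equations + t tests); independent cross-check
# used by the test suite, not by the user-facing functions
ols_closed_form <- function(x, y) {
  n <- length(x)
  X <- cbind(1, x)
  XtX <- crossprod(X)
  beta <- solve(XtX, crossprod(X, y))
  res <- y - X %*% beta
  s2 <- sum(res^2) / (n - 2)
  se <- sqrt(diag(solve(XtX)) * s2)
  tv <- beta / se
  p <- 2 * stats::pt(abs(tv), df = n - 2, lower.tail = FALSE)
  list(beta = beta[2L], se = se[2L], p = p[2L], df = n - 2)
}
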