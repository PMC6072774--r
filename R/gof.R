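# Goodness of fit and parametrization selection.

#' Uniform-sensitivity Kolmogorov-Smirnov statistic
#'
#' The classical KS distance is most sensitive near the distribution median;
#' dividing by `sqrt(P (1 - P))` equalizes sensitivity across the whole
#' range, which matters for heavy-tailed step-length data. The statistic is
#' the maximum over the sorted sample of
#' `|S(l) - P(l)| / sqrt(P(l) (1 - P(l)))` where `S` is the empirical CDF
#' (both step sides are examined) and `P` the fitted model CDF; points where
#' `P` is exactly 0 or 1 are excluded.
#'
#' @param sample a `betpl_steps` object.
#' @param params a [betpl_params()] (its support must cover the sample), or
#'   `NULL` when `cdf` is given.
#' @param cdf optional vectorized CDF function, for non-BETPL families.
#' @return list (class `betpl_gof`) with `D_weighted`, `n`, `lim_a`,
#'   `theta`.
#' @export
weighted_ks <- function(sample, params = NULL, cdf = NULL) {
  x <- sort(sample$lengths)
  n <- length(x)
  if (n < 1L) stop("empty sample")
  if (is.null(cdf)) {
    if (x[1L] < params$lim_a || x[n] > params$l_max)
      stop("sample outside model support [", params$lim_a, ", ",
           params$l_max, "]")
    tab <- betpl_cdf_table(params)
    P <- betpl_cdf(x, params, table = tab)
  } else {
    P <- cdf(x)
  }
  S_hi <- seq_len(n) / n
  S_lo <- (seq_len(n) - 1) / n
  keep <- P > 0 & P < 1
  if (!any(keep)) stop("model CDF degenerate on the sample")
  D <- max((pmax(abs(S_hi - P), abs(S_lo - P)) / sqrt(P * (1 - P)))[keep])
  structure(list(D_weighted = D, n = n, lim_a = sample$lim_a,
                 theta = sample$theta), class = "betpl_gof")
}

#' Parametric-bootstrap p-value for the weighted KS statistic
#'
#' Simulates `n_boot` samples of the observed size from the fitted BETPL,
#' refits each and recomputes the weighted KS statistic; the p-value is the
#' fraction of bootstrap statistics at least as large as the observed one.
#' Off by default in the pipeline: the statistic's role there is candidate
#' selection, not significance.
#'
#' @param sample a `betpl_steps`.
#' @param fit a `betpl_fit` of that sample.
#' @param n_boot number of bootstrap replicates (>= 99).
#' @param seed integer seed (bootstrap is fully reproducible under it).
#' @param control fitting control for the refits; defaults to the fit's
#'   mode at default resolution.
#' @return numeric p-value in \[0, 1\].
#' @export
bootstrap_p <- function(sample, fit, n_boot = 199L, seed = 1L,
                        control = NULL) {
  if (n_boot < 99L) stop("n_boot must be at least 99")
  if (is.null(control)) control <- betpl_grid_control(fit$mode)
  D_obs <- if (is.na(fit$gof_D))
    weighted_ks(sample, fit$params_mean)$D_weighted else fit$gof_D
  D_boot <- with_seed(seed, function() {
    vapply(seq_len(n_boot), function(b) {
      xb <- betpl_sample(fit$params_mean, sample$n)
      sb <- step_sample(xb, lim_a = sample$lim_a, theta = sample$theta,
                        l_max = sample$l_max, source_id = sample$source_id,
                        n_min = 1L)
      fb <- fit_betpl(sb, mode = fit$mode, control = control, gof = TRUE)
      fb$gof_D
    }, numeric(1))
  })
  mean(D_boot >= D_obs)
}

#' The 18 reference lower-bound candidates (km)
#' @export
LIM_A_SCAN <- c(0.05, 0.10, 0.20, 0.30, 0.40, 0.50, 0.60, 0.70, 0.80, 0.90,
                1.00, 1.20, 1.40, 1.60, 1.80, 2.00, 2.50, 3.00)

#' The reference rotation angles (degrees)
#' @export
THETA_SCAN <- c(0, 15, 30, 45)

#' Scan step-extraction parametrizations and select the best by GoF
#'
#' For every combination of lower bound `lim_a` (18 reference values by
#' default) and rotation `theta` (0, 15, 30, 45 degrees), extracts the
#' pooled step sample, fits the BETPL and computes the weighted KS
#' statistic; the winning parametrization minimizes the statistic among
#' sufficient samples. Ties are broken deterministically: larger n, then
#' smaller `lim_a`, then smaller `theta`. The per-candidate fit runs in the
#' same mode as the downstream analysis so selection and inference are
#' consistent.
#'
#' @param traj a `betpl_trajectory` (or a `betpl_planar_track`).
#' @param mode fitting mode, `"free_mu"` or `"fixed_mu"`.
#' @param lim_a_list,thetas candidate lists.
#' @param control optional [betpl_grid_control()].
#' @param l_max,n_min passed to [extract_steps()].
#' @param keep_fits retain the per-candidate `betpl_fit` objects.
#' @return A `betpl_scan`: list with `table` (one row per candidate:
#'   `lim_a`, `theta`, `n`, `sufficient`, `mu`, `lambda1`, `lambda2`,
#'   `D_weighted`, `boundary`, `selected`), `selected` (the winning row
#'   index, or `NA` with `reason` when all candidates are insufficient),
#'   `fit` (the winning fit) and `id`.
#' @export
scan_parametrizations <- function(traj, mode = c("free_mu", "fixed_mu"),
                                  lim_a_list = LIM_A_SCAN,
                                  thetas = THETA_SCAN, control = NULL,
                                  l_max = 600, n_min = 30,
                                  keep_fits = FALSE) {
  mode <- match.arg(mode)
  if (is.null(control)) control <- betpl_grid_control(mode)
  track <- if (inherits(traj, "betpl_planar_track")) traj else
    project_to_plane(traj)
  id <- attr(track, "id")

  rows <- list(); fits <- list()
  for (th in thetas) {
    rot <- rotate_track(track, th)
    raw <- c(steps_1d(rot$x), steps_1d(rot$y))
    for (a in lim_a_list) {
      samp <- step_sample(raw, lim_a = a, theta = th, l_max = l_max,
                          source_id = id, n_min = n_min)
      key <- sprintf("%g|%g", a, th)
      if (samp$sufficient) {
        f <- fit_betpl(samp, mode = mode, control = control, gof = TRUE)
        rows[[key]] <- data.frame(
          lim_a = a, theta = th, n = samp$n, sufficient = TRUE,
          mu = f$params_mean$mu, lambda1 = f$params_mean$lambda1,
          lambda2 = f$params_mean$lambda2, D_weighted = f$gof_D,
          boundary = f$boundary)
        if (keep_fits) fits[[key]] <- f
      } else {
        rows[[key]] <- data.frame(
          lim_a = a, theta = th, n = samp$n, sufficient = FALSE,
          mu = NA_real_, lambda1 = NA_real_, lambda2 = NA_real_,
          D_weighted = NA_real_, boundary = NA)
      }
    }
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  tab <- tab[order(tab$theta, tab$lim_a), , drop = FALSE]

  cand <- which(tab$sufficient)
  if (!length(cand)) {
    out <- list(table = tab, selected = NA_integer_,
                reason = "insufficient steps at all parametrizations",
                fit = NULL, id = id, mode = mode)
    class(out) <- "betpl_scan"
    return(out)
  }
  ord <- cand[order(tab$D_weighted[cand], -tab$n[cand], tab$lim_a[cand],
                    tab$theta[cand])]
  sel <- ord[1L]
  tab$selected <- seq_len(nrow(tab)) == sel

  sel_fit <- {
    key <- sprintf("%g|%g", tab$lim_a[sel], tab$theta[sel])
    if (keep_fits) fits[[key]] else {
      rot <- rotate_track(track, tab$theta[sel])
      samp <- step_sample(c(steps_1d(rot$x), steps_1d(rot$y)),
                          lim_a = tab$lim_a[sel], theta = tab$theta[sel],
                          l_max = l_max, source_id = id, n_min = n_min)
      fit_betpl(samp, mode = mode, control = control, gof = TRUE)
    }
  }
  out <- list(table = tab, selected = sel, reason = NULL, fit = sel_fit,
              id = id, mode = mode, fits = if (keep_fits) fits else NULL)
  class(out) <- "betpl_scan"
  out
}

#' @export
print.betpl_scan <- function(x, ...) {
  cat("<betpl_scan>", x$id, "-", nrow(x$table), "candidates,", x$mode, "\n")
  if (is.na(x$selected)) {
    cat("  excluded:", x$reason, "\n")
  } else {
    s <- x$table[x$selected, ]
    cat(sprintf(
      "  selected lim_a = %g km, theta = %g deg (n = %d, D = %.3f)\n",
      s$lim_a, s$theta, s$n, s$D_weighted))
    cat(sprintf("  mu = %.3f, lambda1 = %.4f /km, lambda2 = %.3f km\n",
                s$mu, s$lambda1, s$lambda2))
  }
  invisible(x)
}
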