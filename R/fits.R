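#' Drift-diffusion fit to an msd curve
#'
#' Fits \deqn{\langle r^2 \rangle = 4 D_{eff}\,\delta t + (v_{eff}\,\delta t)^2}
#' by least squares with non-negativity constraints on both parameters. The
#' model is linear in `(4 D_eff, v_eff^2)`, so the bounded problem is solved
#' exactly by an active-set scan of the four sign-constrained candidates --
#' noiseless curves generated from the model are recovered to machine
#' precision.
#'
#' @param curve A tibble with `lag_s` and `msd_um2` (optionally `n_pairs`,
#'   used as weights).
#' @return An object of class `msd_drift_fit` with elements `d_eff`
#'   (um^2/s), `v_eff` (um/s), `residual` (root mean square, um^2), `n_lags`.
#' @export
fit_msd_drift <- function(curve) {
  stopifnot(all(c("lag_s", "msd_um2") %in% names(curve)))
  curve <- curve[is.finite(curve$lag_s) & is.finite(curve$msd_um2), ]
  if (nrow(curve) < 3) {
    abort("need at least 3 lags", class = "asterdrift_insufficient_data")
  }
  x <- curve$lag_s; y <- curve$msd_um2
  w <- if ("n_pairs" %in% names(curve)) curve$n_pairs else rep(1, length(x))
  # candidates: free OLS, a = 0, b = 0, both 0; keep the feasible minimum
  rss <- function(a, b) sum(w * (y - a * x - b * x^2)^2)
  cands <- list(c(0, 0))
  X <- cbind(x, x^2)
  fit2 <- tryCatch(solve(crossprod(X * sqrt(w)), crossprod(X, w * y)),
                   error = function(e) NULL)
  if (!is.null(fit2)) cands <- c(cands, list(as.numeric(fit2)))
  a1 <- sum(w * x * y) / sum(w * x^2)
  b1 <- sum(w * x^2 * y) / sum(w * x^4)
  cands <- c(cands, list(c(max(a1, 0), 0)), list(c(0, max(b1, 0))))
  feas <- Filter(function(p) all(p >= 0), cands)
  best <- feas[[which.min(vapply(feas, function(p) rss(p[1], p[2]), numeric(1)))]]
  structure(list(d_eff = best[1] / 4, v_eff = sqrt(best[2]),
                 residual = sqrt(mean((y - best[1] * x - best[2] * x^2)^2)),
                 n_lags = length(x)),
            class = "msd_drift_fit")
}

#' Anomalous-diffusion fit to an msd curve
#'
#' Fits \deqn{\langle r^2 \rangle = 4 D' t^{\alpha}} with `D' >= 0` and the
#' anomaly exponent constrained to `[0, 2]` (`alpha = 1` free diffusion,
#' `alpha = 2` ballistic, `alpha < 1` sub-diffusive/confined). Initialized by
#' log-log regression and refined by bounded Levenberg-Marquardt.
#'
#' @inheritParams fit_msd_drift
#' @return An object of class `msd_anom_fit` with `d_prime` (um^2/s^alpha),
#'   `alpha`, `residual`, `n_lags`.
#' @export
fit_msd_anomalous <- function(curve) {
  stopifnot(all(c("lag_s", "msd_um2") %in% names(curve)))
  keep <- is.finite(curve$lag_s) & is.finite(curve$msd_um2) &
    curve$lag_s > 0 & curve$msd_um2 > 0
  curve <- curve[keep, ]
  if (nrow(curve) < 3) {
    abort("need at least 3 lags with positive msd",
          class = "asterdrift_fit_error")
  }
  x <- curve$lag_s; y <- curve$msd_um2
  ll <- lm(log(y) ~ log(x))
  alpha0 <- min(max(coef(ll)[[2]], 0), 2)
  d0 <- max(exp(coef(ll)[[1]]) / 4, .Machine$double.xmin)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ 4 * dp * x^alpha,
                      start = list(dp = d0, alpha = alpha0),
                      lower = c(0, 0), upper = c(Inf, 2),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    est <- c(dp = d0, alpha = alpha0)
  } else {
    est <- coef(fit)
  }
  structure(list(d_prime = est[["dp"]], alpha = est[["alpha"]],
                 residual = sqrt(mean((y - 4 * est[["dp"]] * x^est[["alpha"]])^2)),
                 n_lags = length(x)),
            class = "msd_anom_fit")
}

#' Hill-type fit to a distance-travelled profile
#'
#' The distance travelled from the nucleation site,
#' `d(t) = |position(t) - position(0)|`, is fitted to the saturating model
#' with cooperativity
#' \deqn{d(t) = \frac{d_{max} t^n}{T_{half}^n + t^n}}
#' `n > 1` (sigmoid profile) is read as transport dominated by pulling;
#' `n <= 1` (parabolic) as pushing. Fits with `R^2 <= 0.7` are flagged
#' unreliable.
#'
#' @param track A single-track trajectory tibble (>= 4 samples).
#' @return An object of class `distance_time_fit` with `d_max` (um),
#'   `t_half` (s), `n`, `r_squared`, `mode` (`"pulling"`/`"pushing"`),
#'   `reliable`.
#' @export
fit_distance_time <- function(track) {
  check_tracks(track)
  if (dplyr::n_distinct(track$track_id) != 1L) {
    abort("`track` must contain exactly one track", class = "asterdrift_fit_error")
  }
  if (nrow(track) < 4) {
    abort("need at least 4 samples", class = "asterdrift_insufficient_data")
  }
  t <- track$t_s - track$t_s[1]
  d <- sqrt((track$x_um - track$x_um[1])^2 + (track$y_um - track$y_um[1])^2)
  if (all(d == 0)) {
    abort("degenerate distance series (all zero)",
          class = "asterdrift_fit_degenerate")
  }
  d_max0 <- max(d)
  t_half0 <- t[which.min(abs(d - d_max0 / 2))]
  if (t_half0 <= 0) t_half0 <- max(t) / 2
  fit <- tryCatch(
    minpack.lm::nlsLM(d ~ d_max * t^n / (t_half^n + t^n),
                      start = list(d_max = d_max0, t_half = t_half0, n = 1.5),
                      lower = c(1e-6, 1e-6, 0.05), upper = c(Inf, Inf, 20),
                      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) NULL)
  if (is.null(fit)) {
    abort("distance-time fit failed to converge", class = "asterdrift_fit_error")
  }
  est <- coef(fit)
  pred <- est[["d_max"]] * t^est[["n"]] / (est[["t_half"]]^est[["n"]] + t^est[["n"]])
  r2 <- 1 - sum((d - pred)^2) / sum((d - mean(d))^2)
  structure(list(d_max = est[["d_max"]], t_half = est[["t_half"]],
                 n = est[["n"]], r_squared = r2,
                 mode = if (est[["n"]] > 1) "pulling" else "pushing",
                 reliable = r2 > 0.7),
            class = "distance_time_fit")
}

#' @export
print.msd_drift_fit <- function(x, ...) {
  cat(sprintf("<msd_drift_fit> D_eff = %.4g um^2/s, v_eff = %.4g um/s (rms %.3g, %d lags)\n",
              x$d_eff, x$v_eff, x$residual, x$n_lags))
  invisible(x)
}

#' @export
print.msd_anom_fit <- function(x, ...) {
  cat(sprintf("<msd_anom_fit> D' = %.4g um^2/s^a, alpha = %.3f (rms %.3g, %d lags)\n",
              x$d_prime, x$alpha, x$residual, x$n_lags))
  invisible(x)
}

#' @export
print.distance_time_fit <- function(x, ...) {
  cat(sprintf("<distance_time_fit> d_max = %.3g um, T_half = %.3g s, n = %.3g -> %s (R2 = %.3f%s)\n",
              x$d_max, x$t_half, x$n, x$mode, x$r_squared,
              if (x$reliable) "" else ", unreliable"))
  invisible(x)
}
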