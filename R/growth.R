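# Growth-rate prediction from life-history traits, and estimation of
# observed growth rates from growth-assay time series.

#' Predict the viral population growth rate from four life-history traits
#'
#' Solves the lytic-virus Euler-Lotka characteristic equation
#' \deqn{1 = s \, b_r \, \frac{kH}{kH + \lambda} \, e^{-\lambda \mu_l}}
#' for the exponential growth rate \eqn{\lambda}: a virion's lifetime
#' reproduction (specific infectivity times burst size per release),
#' discounted by the race between adsorption at rate \eqn{kH} and loss from
#' the growing cohort, and delayed by the lysis time. The left side being a
#' strictly decreasing function of \eqn{\lambda} on \eqn{(-kH, \infty)}, the
#' root is unique and found by bracketed bisection. Negative rates (declining
#' populations, `s * b_r < 1`) are admitted, with the bracket extended down
#' towards `-k * H`.
#'
#' @param s Specific infectivity, in `[0, 1]`.
#' @param k Adsorption constant, mL/h.
#' @param mu_l Mean lysis time, h.
#' @param b_r Burst size per releasing cell.
#' @param host_density Host density H, cells/mL (default 1e7).
#' @param strain_id Optional label carried into the result.
#' @param tol Residual tolerance enforced at the returned root.
#' @return An object of class `growth_prediction`: `lambda_pred` (per hour),
#'   the `host_density`, the `inputs_used`, the `bracket` searched, a
#'   `converged` flag, and the `residual` of the characteristic equation at
#'   the root. When `s * b_r <= 0` (no viable reproduction) the prediction is
#'   flagged non-converged with `lambda_pred = NA`.
#' @examples
#' predict_growth_rate(s = 0.25, k = 5e-8, mu_l = 10, b_r = 400)
#' @export
predict_growth_rate <- function(s, k, mu_l, b_r, host_density = 1e7,
                                strain_id = NA_character_, tol = 1e-9) {
  if (!is.finite(s) || s < 0 || s > 1) stop_msg("s must lie in [0, 1]")
  if (!is.finite(k) || k < 0) stop_msg("k must be >= 0")
  if (!is.finite(mu_l) || mu_l <= 0) stop_msg("mu_l must be > 0")
  if (!is.finite(b_r) || b_r < 0) stop_msg("b_r must be >= 0")
  if (!is.finite(host_density) || host_density <= 0) stop_msg("host_density must be > 0")

  inputs <- c(s = s, k = k, mu_l = mu_l, b_r = b_r)
  R <- s * b_r           # lifetime reproduction per free virion
  kH <- k * host_density
  out <- list(strain_id = strain_id, lambda_pred = NA_real_,
              host_density = host_density, inputs_used = inputs,
              converged = FALSE, bracket = c(NA_real_, NA_real_),
              residual = NA_real_)
  class(out) <- "growth_prediction"

  if (R <= 0 || kH <= 0) return(out)  # no growth solution exists
  if (R == 1) {
    out$lambda_pred <- 0; out$converged <- TRUE
    out$bracket <- c(0, 0); out$residual <- 0
    return(out)
  }

  # log of the reproduction side; strictly decreasing in lambda on (-kH, Inf)
  g <- function(lam) log(R) + log(kH) - log(kH + lam) - lam * mu_l

  if (R > 1) {
    lo <- 0
    hi <- log(R) / mu_l  # infinite-host limit is an upper bound
    if (g(hi) > 0) {     # guard: expand if the bound is not yet a bracket
      while (g(hi) > 0) hi <- hi * 2
    }
  } else {
    hi <- 0
    eps <- 1e-6
    lo <- -kH * (1 - eps)
    while (g(lo) <= 0 && eps > 1e-300) { eps <- eps * 1e-3; lo <- -kH * (1 - eps) }
    if (g(lo) <= 0) return(out)
  }
  bracket <- c(lo, hi)

  for (i in seq_len(200L)) {
    mid <- (lo + hi) / 2
    if (g(mid) > 0) lo <- mid else hi <- mid
    if (hi - lo < .Machine$double.eps * max(1, abs(lo))) break
  }
  lam <- (lo + hi) / 2
  resid <- abs(exp(g(lam)) - 1)
  out$lambda_pred <- lam
  out$bracket <- bracket
  out$residual <- resid
  out$converged <- is.finite(lam) && resid <= tol
  out
}

#' @export
print.growth_prediction <- function(x, ...) {
  cat(sprintf("lambda = %.6g /h at H = %.3g cells/mL (converged: %s)\n",
              x$lambda_pred, x$host_density, x$converged))
  invisible(x)
}

#' Estimate the observed growth rate from a growth-assay time series
#'
#' Log-linear regression of titer on time over the configured exponential
#' window; the slope is the observed growth rate. Non-positive titers inside
#' the window are dropped with a flag; fewer than 3 usable points is an
#' estimation failure. The CI is a percentile bootstrap over observations
#' resampled within time points.
#'
#' @param growth Rows: `replicate`, `time_h`, `pfu_per_ml`.
#' @param window Optional `c(t_min, t_max)` exponential window, hours;
#'   default uses the full series.
#' @param n_boot Bootstrap replicates for the CI (>= 100; 0 skips the CI).
#' @param seed Integer seed.
#' @param strain_id Optional label.
#' @return An object of class `observed_growth`: `lambda_obs` (per hour),
#'   `ci_low`, `ci_high`, `n_points`, `converged`, `flags`.
#' @export
fit_observed_growth <- function(growth, window = NULL, n_boot = 200L,
                                seed = 1L, strain_id = NA_character_) {
  growth <- check_columns(growth, c("replicate", "time_h", "pfu_per_ml"), "growth")
  flags <- character()
  if (!is.null(window)) {
    keep <- growth$time_h >= window[1] & growth$time_h <= window[2]
    growth <- growth[keep, , drop = FALSE]
  }
  usable <- growth$pfu_per_ml > 0
  if (any(!usable)) flags <- c(flags, "nonpositive_titers_dropped")
  growth <- growth[usable, , drop = FALSE]
  out <- list(strain_id = strain_id, lambda_obs = NA_real_,
              ci_low = NA_real_, ci_high = NA_real_,
              n_points = nrow(growth), converged = FALSE, flags = flags)
  class(out) <- "observed_growth"
  if (length(unique(growth$time_h)) < 3L) {
    out$flags <- c(out$flags, "estimation_failed")
    return(out)
  }
  slope <- function(df) unname(stats::coef(stats::lm(log(pfu_per_ml) ~ time_h, data = df))[2])
  lam <- slope(growth)
  out$lambda_obs <- lam
  out$converged <- TRUE
  if (n_boot >= 100L) {
    set.seed(seed)
    draws <- vapply(seq_len(n_boot), function(b) {
      idx <- resample_cases(nrow(growth))
      tryCatch(slope(growth[idx, , drop = FALSE]), error = function(e) NA_real_)
    }, numeric(1))
    ci <- percentile_ci(draws, lam)
    out$ci_low <- ci$low; out$ci_high <- ci$high
    if (ci$adjusted) out$flags <- c(out$flags, "ci_adjusted")
  } else {
    out$ci_low <- lam; out$ci_high <- lam
  }
  out
}

#' @export
print.observed_growth <- function(x, ...) {
  cat(sprintf("lambda_obs = %.4g /h (95%% CI %.4g-%.4g, %d points)\n",
              x$lambda_obs, x$ci_low, x$ci_high, x$n_points))
  invisible(x)
}
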