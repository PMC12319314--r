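# Trait estimators. Each estimator has a vector-level core (used by the
# bootstrap, which refits thousands of times) and an exported wrapper that
# validates the assay table and returns trait_estimate records.

# Least-squares objective on log scale with the overall scale (log v0)
# profiled out analytically; falls back to Poisson-weighted least squares
# when zero counts are present (no pseudocounts).
profiled_logscale_sse <- function(y, shape) {
  ok <- shape > 0
  if (!any(ok)) return(Inf)
  y <- y[ok]; shape <- shape[ok]
  if (all(y > 0)) {
    z <- log(y) - log(shape)
    sum((z - mean(z))^2)
  } else {
    profiled_logscale_sse_raw(y, shape)
  }
}

# Poisson deviance with the scale profiled at its ML value; tolerates zeros.
profiled_logscale_sse_raw <- function(y, shape) {
  c0 <- sum(y) / sum(shape)
  mu <- c0 * shape
  pos <- y > 0
  2 * (sum(y[pos] * log(y[pos] / mu[pos])) - sum(y - mu))
}

# --- adsorption ---------------------------------------------------------------

fit_adsorption_core <- function(t, y, H) {
  flags <- character()
  if (all(y == 0)) return(list(par = c(a = NA_real_, k = NA_real_),
                               flags = "estimation_failed", converged = FALSE,
                               resid_scale = NA_real_))
  if (length(unique(t)) < 3L) stop_msg("adsorption fit needs >= 3 distinct time points")
  y0 <- mean(y[t == min(t)])
  if (y0 <= 0) y0 <- max(y)
  # constant counts: no adsorption detectable
  if (max(y) > 0 && stats::sd(y / y0) < 1e-12)
    return(list(par = c(a = NA_real_, k = 0), flags = "no_adsorption",
                converged = TRUE, resid_scale = 0))
  plat <- mean(y[t == max(t)])
  a0 <- min(0.99, max(0.05, 1 - plat / y0))
  ok <- y > 0
  any_zero <- !all(ok)
  ly <- log(y[ok]); t_fit <- if (any_zero) t else t[ok]
  obj_shape <- if (!any_zero) {
    function(shape) {
      z <- ly - log(shape)
      sum((z - sum(z) / length(z))^2)
    }
  } else {
    function(shape) profiled_logscale_sse_raw(y, shape)
  }
  obj <- function(par) {
    a <- stats::plogis(par[2])
    obj_shape((1 - a) + a * exp(-exp(par[1]) * t_fit))
  }
  t_half <- stats::median(t[t > 0])
  starts <- cbind(log_kH = log(rep(c(0.2, 1, 5) / t_half, 2)),
                  logit_a = stats::qlogis(rep(c(a0, 0.9), each = 3)))
  vals <- vapply(seq_len(nrow(starts)), function(i) obj(starts[i, ]), numeric(1))
  opt <- stats::optim(starts[which.min(vals), ], obj, method = "Nelder-Mead",
                      control = list(maxit = 400, reltol = 1e-12))
  kH <- unname(exp(opt$par[1])); a <- unname(stats::plogis(opt$par[2]))
  converged <- opt$convergence == 0
  # plateau indistinguishable from complete adsorption: log-linear reduction
  if (a > 0.995) {
    ok <- y > 0
    sl <- stats::coef(stats::lm(log(y[ok]) ~ t[ok]))[2]
    red_kH <- max(0, -sl)
    if (obj(c(log(max(red_kH, 1e-12)), stats::qlogis(1 - 1e-9))) <= opt$value + 1e-9) {
      kH <- red_kH; a <- 1
    }
  }
  n_ok <- sum(y > 0)
  list(par = c(a = a, k = kH / H), flags = flags, converged = converged,
       resid_scale = sqrt(opt$value / max(1, n_ok - 2)))
}

#' Fit the adsorption constant and attaching fraction
#'
#' Nonlinear least squares (log scale, scale profiled out) of the free-virus
#' curve `V(t) = v0 * ((1 - a) + a * exp(-k * H * t))`. When the fitted
#' attaching fraction is indistinguishable from 1 the model reduces to
#' log-linear regression with slope `-k * H`. Zero counts switch the
#' objective to Poisson-weighted least squares (no pseudocounts).
#'
#' @param adsorption Adsorption rows: `replicate`, `time_h`,
#'   `free_pfu_per_ml`, `host_density_per_ml`.
#' @return A list of two [trait_estimate()] records, `k` (mL/h) and `a`.
#' @export
fit_adsorption <- function(adsorption) {
  adsorption <- check_columns(adsorption,
    c("replicate", "time_h", "free_pfu_per_ml", "host_density_per_ml"),
    "adsorption")
  if (any(adsorption$host_density_per_ml <= 0)) stop_msg("host density must be positive")
  if (any(adsorption$free_pfu_per_ml < 0)) stop_msg("free-virus counts must be non-negative")
  H <- adsorption$host_density_per_ml[1]
  core <- fit_adsorption_core(adsorption$time_h, adsorption$free_pfu_per_ml, H)
  mk <- function(nm) {
    est <- clamp_trait(nm, core$par[[nm]])
    fl <- core$flags
    if (!is.finite(core$par[[nm]])) {
      fl <- union(fl, "poorly_resolved")
      est <- NA_real_
    }
    trait_estimate(nm, est, converged = core$converged,
                   resid_scale = core$resid_scale, flags = fl)
  }
  list(k = mk("k"), a = mk("a"))
}

# --- depolarization -----------------------------------------------------------

estimate_depolarization_core <- function(cells_total, cells_depolarized, moi) {
  n <- sum(cells_total); x <- sum(cells_depolarized)
  flags <- character()
  if (x >= n) {
    d <- 1; flags <- "saturated"
  } else {
    f <- x / n
    d <- min(1, max(0, -log(1 - f) / moi))
  }
  list(par = c(d = d), flags = flags)
}

#' Estimate the depolarization probability
#'
#' Inverts the Poisson multiplicity-of-infection model: with pooled
#' depolarized fraction `F` at adsorbed multiplicity `moi`,
#' `d = -log(1 - F) / moi`, clamped to `[0, 1]`. Counts are pooled across
#' replicates before inversion because per-replicate counts may be small.
#'
#' @param depolarization Rows: `replicate`, `cells_total`,
#'   `cells_depolarized`, `adsorbed_moi`.
#' @return A [trait_estimate()] for `d`. A saturated assay (all cells
#'   depolarized) returns the upper bound 1 with a `"saturated"` flag.
#' @export
estimate_depolarization <- function(depolarization) {
  depolarization <- check_columns(depolarization,
    c("replicate", "cells_total", "cells_depolarized", "adsorbed_moi"),
    "depolarization")
  if (any(depolarization$cells_depolarized > depolarization$cells_total))
    stop_msg("cells_depolarized cannot exceed cells_total")
  moi <- depolarization$adsorbed_moi[1]
  if (moi <= 0) stop_msg("adsorbed_moi must be > 0")
  core <- estimate_depolarization_core(depolarization$cells_total,
                                       depolarization$cells_depolarized, moi)
  trait_estimate("d", core$par[["d"]], flags = core$flags)
}

# --- lysis curve --------------------------------------------------------------

fit_lysis_core <- function(t, ic, depol_dens, sigma_min) {
  flags <- character()
  D <- mean(depol_dens)
  if (!is.finite(D) || D <= 0)
    return(list(par = c(r = NA_real_, mu_l = NA_real_, sigma_l = NA_real_,
                        releasing_density = NA_real_, depol_density = D),
                flags = "estimation_failed", converged = FALSE, resid_scale = NA_real_))
  y <- ic / D
  if (all(ic == 0))
    return(list(par = c(r = 0, mu_l = NA_real_, sigma_l = NA_real_,
                        releasing_density = 0, depol_density = D),
                flags = "poorly_resolved", converged = TRUE, resid_scale = 0))
  tu <- sort(unique(t))
  span <- diff(range(tu))
  # starts from the shape of the survival-of-infectious-centers curve
  ybar <- vapply(tu, function(ti) mean(y[t == ti]), numeric(1))
  r0 <- min(1, max(1e-3, max(ybar[seq_len(min(2L, length(ybar)))])))
  below <- tu[ybar <= r0 / 2]
  mu0 <- if (length(below)) below[1] else stats::median(tu)
  sig0 <- max(sigma_min, span / 8)
  obj <- function(par) sum((y - par[1] * (1 - lysis_cdf(t, par[2], par[3])))^2)
  opt <- stats::optim(c(r0, mu0, sig0), obj, method = "L-BFGS-B",
                      lower = c(1e-6, min(tu) + 1e-6, sigma_min),
                      upper = c(1, max(tu) + span, span),
                      control = list(maxit = 500, factr = 1e4))
  par <- opt$par
  if (max(tu) < par[2] + 2 * par[3]) flags <- c(flags, "truncated")
  list(par = c(r = par[1], mu_l = par[2], sigma_l = par[3],
               releasing_density = par[1] * D, depol_density = D),
       flags = flags, converged = opt$convergence == 0,
       resid_scale = sqrt(opt$value / max(1, length(y) - 3)))
}

#' Fit the lysis-time distribution and release probability
#'
#' Infectious centers per depolarized cell decline as releasing cells lyse:
#' `IC(t) / D = r * (1 - Phi((t - mu_l) / sigma_l))` with the lysis-time
#' normal CDF truncated at 0. Least squares gives the release probability
#' `r` (the initial plateau), the mean lysis time `mu_l` (the midpoint), and
#' its spread `sigma_l`, bounded below by half the median sampling interval
#' to prevent degenerate zero-SD fits on coarse grids.
#'
#' @param onestep One-step rows: `replicate`, `time_h`,
#'   `infectious_centers_per_ml`, `free_pfu_per_ml`,
#'   `depolarized_cells_per_ml`.
#' @return A list of [trait_estimate()] records `r`, `mu_l`, `sigma_l`, plus
#'   `releasing_density` and `depol_density` (cells/mL) used downstream by
#'   the burst-size estimator.
#' @export
fit_lysis_curve <- function(onestep) {
  onestep <- check_columns(onestep,
    c("replicate", "time_h", "infectious_centers_per_ml", "free_pfu_per_ml",
      "depolarized_cells_per_ml"), "onestep")
  tu <- sort(unique(onestep$time_h))
  if (length(tu) < 4L) stop_msg("lysis fit needs >= 4 distinct time points")
  sigma_min <- stats::median(diff(tu)) / 2
  core <- fit_lysis_core(onestep$time_h, onestep$infectious_centers_per_ml,
                         onestep$depolarized_cells_per_ml, sigma_min)
  mk <- function(nm) {
    v <- core$par[[nm]]
    fl <- core$flags
    if (!is.finite(v)) { fl <- union(fl, "poorly_resolved"); v <- NA_real_ }
    else v <- clamp_trait(nm, v)
    trait_estimate(nm, v, converged = core$converged,
                   resid_scale = core$resid_scale, flags = fl)
  }
  list(r = mk("r"), mu_l = mk("mu_l"), sigma_l = mk("sigma_l"),
       releasing_density = core$par[["releasing_density"]],
       depol_density = core$par[["depol_density"]])
}

# --- burst sizes --------------------------------------------------------------

estimate_burst_core <- function(t, free, depol_dens, r_hat, mu_l, sigma_l) {
  flags <- character()
  r_hat <- unname(r_hat); mu_l <- unname(mu_l); sigma_l <- unname(sigma_l)
  D <- mean(depol_dens)
  if (!is.finite(D) || D <= 0)
    return(list(par = c(b_d = NA_real_, b_r = NA_real_),
                flags = "estimation_failed"))
  t_early <- max(min(t), if (is.finite(mu_l)) mu_l - 3 * sigma_l else min(t))
  early <- t <= t_early
  if (!any(early)) early <- t == min(t)
  late <- if (is.finite(mu_l)) t >= mu_l + 3 * sigma_l else t == max(t)
  if (!any(late)) {
    late <- if (is.finite(mu_l)) t >= mu_l + 2 * sigma_l else t == max(t)
    flags <- c(flags, "truncated")
  }
  if (!any(late)) { late <- t == max(t); flags <- c(flags, "truncated") }
  inoculum <- mean(free[early])
  yield <- mean(free[late])
  b_d <- (yield - inoculum) / D
  if (b_d < 0) { b_d <- 0; flags <- c(flags, "negative_yield") }
  if (is.finite(r_hat) && r_hat > 0) b_r <- b_d / r_hat
  else { b_r <- NA_real_; flags <- c(flags, "b_r_undefined") }
  list(par = c(b_d = b_d, b_r = b_r), flags = flags)
}

#' Estimate burst sizes per depolarized cell and per release
#'
#' The final free-progeny yield (measured after the release curve plateaus,
#' at `t >= mu_l + 3 * sigma_l`) minus the residual inoculum (measured before
#' the curve rises), divided by the depolarized-cell density, gives the burst
#' size per depolarized cell `b_d`; dividing by the release probability gives
#' the burst size per releasing cell `b_r = b_d / r`.
#'
#' @inheritParams fit_lysis_curve
#' @param r A [trait_estimate()] for the release probability.
#' @param mu_l,sigma_l Lysis-time mean and SD used to place the pre-rise and
#'   post-plateau measurement windows; defaults use the first and last
#'   sampling times.
#' @return A list of [trait_estimate()] records `b_d` and `b_r`.
#' @export
estimate_burst_sizes <- function(onestep, r, mu_l = NULL, sigma_l = NULL) {
  onestep <- check_columns(onestep,
    c("replicate", "time_h", "infectious_centers_per_ml", "free_pfu_per_ml",
      "depolarized_cells_per_ml"), "onestep")
  r_hat <- if (inherits(r, "trait_estimate")) r$estimate else r
  core <- estimate_burst_core(onestep$time_h, onestep$free_pfu_per_ml,
                              onestep$depolarized_cells_per_ml, r_hat,
                              mu_l %||% NA_real_, sigma_l %||% NA_real_)
  mk <- function(nm) {
    v <- core$par[[nm]]
    fl <- core$flags
    if (!is.finite(v)) { fl <- union(fl, "poorly_resolved"); v <- NA_real_ }
    else v <- clamp_trait(nm, v)
    if (inherits(r, "trait_estimate") && is_flagged(r)) fl <- union(fl, "poorly_resolved")
    trait_estimate(nm, v, flags = fl)
  }
  list(b_d = mk("b_d"), b_r = mk("b_r"))
}

# --- specific infectivity -----------------------------------------------------

#' Compose specific infectivity from its component probabilities
#'
#' Specific infectivity is the overall probability that a virion attaches,
#' depolarizes its host, and yields released progeny: `s = a * d * r`. When a
#' matrix of joint bootstrap draws for the components is supplied, the CI is
#' the percentile interval of the per-draw products (never naive interval
#' multiplication).
#'
#' @param a,d,r [trait_estimate()] records for the components.
#' @param joint_draws Optional numeric matrix with columns `a`, `d`, `r`:
#'   joint bootstrap replicates of the components.
#' @return A [trait_estimate()] for `s`; flagged poorly resolved when any
#'   component is.
#' @export
estimate_specific_infectivity <- function(a, d, r, joint_draws = NULL) {
  comps <- list(a = a, d = d, r = r)
  vals <- vapply(comps, function(e) e$estimate, numeric(1))
  flags <- character()
  if (any(vapply(comps, is_flagged, logical(1))) || anyNA(vals))
    flags <- "poorly_resolved"
  s <- if (anyNA(vals)) NA_real_ else clamp_trait("s", prod(vals))
  est <- trait_estimate("s", s, flags = flags)
  if (!is.null(joint_draws) && !anyNA(vals)) {
    prod_draws <- joint_draws[, "a"] * joint_draws[, "d"] * joint_draws[, "r"]
    ci <- stats::quantile(prod_draws, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
    est$ci_low <- clamp_trait("s", min(ci[1], s))
    est$ci_high <- clamp_trait("s", max(ci[2], s))
    est$n_boot <- sum(is.finite(prod_draws))
  }
  est
}

# --- decay --------------------------------------------------------------------

fit_decay_core <- function(t, y, fix_p = NULL) {
  flags <- character()
  if (all(y == 0))
    return(list(par = c(m = NA_real_, p = NA_real_), flags = "estimation_failed",
                converged = FALSE, resid_scale = NA_real_))
  if (stats::sd(y / max(y)) < 1e-12)
    return(list(par = c(m = 0, p = 1), flags = "no_decay",
                converged = TRUE, resid_scale = 0))
  ok <- y > 0
  any_zero <- !all(ok)
  ly <- log(y[ok]); t_ok <- t[ok]
  # log-scale SSE with the scale profiled out; Poisson-weighted when zeros
  # are present (no pseudocounts)
  obj_shape <- if (!any_zero) {
    function(shape) {
      z <- ly - log(shape)
      sum((z - sum(z) / length(z))^2)
    }
  } else {
    function(shape) profiled_logscale_sse_raw(y, shape)
  }
  # pure-exponential candidate: closed-form log-linear slope (p = 0)
  m_fast <- max(1e-8, -sum((t_ok - mean(t_ok)) * ly) / sum((t_ok - mean(t_ok))^2))
  sse_exp <- obj_shape(exp(-m_fast * if (any_zero) t else t_ok))
  if (!is.null(fix_p) && fix_p == 0) {
    # persistent fraction pinned at zero: exactly the log-linear regression
    return(list(par = c(m = m_fast, p = 0), flags = flags, converged = TRUE,
                resid_scale = sqrt(sse_exp / max(1, sum(ok) - 2))))
  }
  # biphasic candidates: multi-start over m and p
  tt <- if (any_zero) t else t_ok
  obj <- function(par) {
    p <- stats::plogis(par[2])
    obj_shape(p + (1 - p) * exp(-exp(par[1]) * tt))
  }
  first <- mean(y[t == min(t)]); last <- mean(y[t == max(t)])
  p_ratio <- min(0.99, max(1e-6, last / max(first, 1e-12)))
  starts <- cbind(log_m = log(c(m_fast, 10 * m_fast, m_fast, 10 * m_fast)),
                  logit_p = stats::qlogis(c(1e-6, 1e-6, p_ratio, p_ratio)))
  fits <- lapply(seq_len(nrow(starts)), function(i)
    stats::optim(starts[i, ], obj, method = "Nelder-Mead",
                 control = list(maxit = 300, reltol = 1e-10)))
  vals <- vapply(fits, `[[`, numeric(1), "value")
  ms <- vapply(fits, function(f) exp(f$par[1]), numeric(1))
  # best SSE wins; near-ties broken by the smaller mortality rate
  tol <- 1e-9 * (1 + min(vals))
  cand <- which(vals <= min(vals) + tol)
  best <- fits[[cand[which.min(ms[cand])]]]
  if (sse_exp <= best$value + tol) {
    par <- c(m = m_fast, p = 0)
    value <- sse_exp; converged <- TRUE
  } else {
    par <- c(m = unname(exp(best$par[1])), p = unname(stats::plogis(best$par[2])))
    value <- best$value; converged <- best$convergence == 0
  }
  n_ok <- sum(ok)
  list(par = par, flags = flags, converged = converged,
       resid_scale = sqrt(value / max(1, n_ok - 2)))
}

#' Fit biphasic decay: mortality rate and persistent fraction
#'
#' Nonlinear least squares on the log surviving titer of
#' `S(t) = S0 * (p + (1 - p) * exp(-m * t))`. Because biphasic fits are
#' multimodal, the optimizer is multi-started over mortality rates (the fast
#' log-linear slope and 10x it) crossed with persistent fractions (near zero
#' and the last/first titer ratio); a pure-exponential candidate with the
#' closed-form slope competes on equal terms, so single-phase data reduce
#' exactly to log-linear regression. Ties go to the smaller mortality rate.
#'
#' @param decay Rows: `replicate`, `time_h`, `pfu_per_ml`.
#' @param fix_p Optionally pin the persistent fraction; `fix_p = 0` reduces
#'   the model to single-exponential decay, whose fit is exactly the
#'   log-linear regression slope.
#' @return A list of [trait_estimate()] records `m` (per hour) and `p`.
#'   Constant titers return `(m, p) = (0, 1)` flagged `"no_decay"`.
#' @export
fit_decay <- function(decay, fix_p = NULL) {
  decay <- check_columns(decay, c("replicate", "time_h", "pfu_per_ml"), "decay")
  if (length(unique(decay$time_h)) < 4L)
    stop_msg("decay fit needs >= 4 distinct time points")
  core <- fit_decay_core(decay$time_h, decay$pfu_per_ml, fix_p = fix_p)
  mk <- function(nm) {
    v <- core$par[[nm]]
    fl <- core$flags
    if (!is.finite(v)) { fl <- union(fl, "poorly_resolved"); v <- NA_real_ }
    else v <- clamp_trait(nm, v)
    trait_estimate(nm, v, converged = core$converged,
                   resid_scale = core$resid_scale, flags = fl)
  }
  list(m = mk("m"), p = mk("p"))
}
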