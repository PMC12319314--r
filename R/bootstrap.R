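# Nonparametric bootstrap over assay rows, and the per-strain orchestration
# that produces a full life-history profile with joint bootstrap CIs.

# Index machinery: the default unit is the individual observation (plain
# case resampling over a table's rows); replicate-level resampling takes
# whole replicate series and is available for data with replicate-level
# correlation. Small-stratum stratified resampling is deliberately avoided:
# with few rows per time point it shrinks the bootstrap variance by the
# within-stratum factor (n-1)/n and the intervals undercover.
resample_cases <- function(n) sample.int(n, n, replace = TRUE)

resample_replicates <- function(replicate) {
  reps <- unique(replicate)
  chosen <- reps[sample.int(length(reps), length(reps), replace = TRUE)]
  unlist(lapply(chosen, function(rp) which(replicate == rp)), use.names = FALSE)
}

percentile_ci <- function(draws, estimate) {
  draws <- draws[is.finite(draws)]
  adjusted <- FALSE
  if (!length(draws)) return(list(low = NA_real_, high = NA_real_, adjusted = FALSE, n = 0L))
  ci <- stats::quantile(draws, c(0.025, 0.975), names = FALSE, type = 7)
  if (is.finite(estimate) && (estimate < ci[1] || estimate > ci[2])) {
    # guarantee the point estimate sits inside its own interval
    ci <- stats::quantile(c(draws, estimate), c(0.025, 0.975), names = FALSE, type = 7)
    ci[1] <- min(ci[1], estimate); ci[2] <- max(ci[2], estimate)
    adjusted <- TRUE
  }
  list(low = ci[1], high = ci[2], adjusted = adjusted, n = length(draws))
}

# Poorly-resolved rule: a trait is excluded from downstream analysis when its
# CI spans more than two orders of magnitude (rates, sizes, times), more than
# 0.8 probability units (probabilities), or when >20% of bootstrap refits fail.
poorly_resolved <- function(trait_name, ci_low, ci_high) {
  if (!is.finite(ci_low) || !is.finite(ci_high)) return(TRUE)
  if (trait_name %in% PROB_TRAITS) return((ci_high - ci_low) > 0.8)
  if (ci_high <= 0) return(FALSE)
  ci_low <= ci_high / 100
}

#' Attach a percentile bootstrap confidence interval to a fit
#'
#' Refits `fit` on `n_boot` resampled copies of the assay rows and attaches
#' the 2.5%/97.5% percentiles of the refitted estimates. The default
#' resampling unit is the individual observation (ordinary case resampling
#' over the table's rows); `"replicate"` resamples whole replicate series
#' instead. The point estimate is guaranteed to lie
#' inside its interval (the original fit joins the percentile set if needed,
#' flagged `"ci_adjusted"`). More than 20% failed refits flags the interval
#' `"ci_unreliable"`.
#'
#' @param fit A function taking a rows `data.frame` and returning a
#'   [trait_estimate()] or a (possibly nested) list of them.
#' @param rows Assay rows accepted by `fit`.
#' @param n_boot Number of bootstrap refits (>= 100).
#' @param seed Integer seed; intervals are reproducible for a fixed seed.
#' @param resample `"observation"` (case resampling, default) or
#'   `"replicate"`.
#' @return The result of `fit(rows)` with `ci_low`, `ci_high`, `n_boot` and
#'   flags filled in on every [trait_estimate()] it contains.
#' @export
bootstrap_ci <- function(fit, rows, n_boot = 1000L, seed = 1L,
                         resample = c("observation", "replicate")) {
  resample <- match.arg(resample)
  if (n_boot < 100L) stop_msg("n_boot must be >= 100")
  point <- fit(rows)
  ests <- flatten_estimates(point)
  if (!length(ests)) stop_msg("fit must return trait_estimate objects")
  set.seed(seed)
  draws <- matrix(NA_real_, n_boot, length(ests),
                  dimnames = list(NULL, names(ests)))
  fails <- 0L
  for (b in seq_len(n_boot)) {
    idx <- if (resample == "observation") resample_cases(nrow(rows))
           else resample_replicates(rows$replicate)
    res <- tryCatch(flatten_estimates(fit(rows[idx, , drop = FALSE])),
                    error = function(e) NULL)
    if (is.null(res)) { fails <- fails + 1L; next }
    draws[b, ] <- vapply(res, function(e) e$estimate, numeric(1))[names(ests)]
  }
  attach_cis(point, draws, fails, n_boot)
}

flatten_estimates <- function(x) {
  if (inherits(x, "trait_estimate")) {
    out <- list(x); names(out) <- x$trait_name; return(out)
  }
  if (is.list(x)) {
    parts <- lapply(unname(x), function(el)
      if (inherits(el, "trait_estimate")) {
        o <- list(el); names(o) <- el$trait_name; o
      } else NULL)
    return(do.call(c, parts[!vapply(parts, is.null, logical(1))]))
  }
  NULL
}

attach_cis <- function(point, draws, fails, n_boot) {
  fill <- function(est) {
    if (!inherits(est, "trait_estimate")) return(est)
    nm <- est$trait_name
    ci <- percentile_ci(draws[, nm], est$estimate)
    est$ci_low <- clamp_trait(nm, ci$low)
    est$ci_high <- clamp_trait(nm, ci$high)
    est$n_boot <- as.integer(n_boot)
    if (ci$adjusted) est <- add_flag(est, "ci_adjusted")
    if (fails > 0.2 * n_boot) est <- add_flag(est, "ci_unreliable")
    if (poorly_resolved(nm, est$ci_low, est$ci_high))
      est <- add_flag(est, "poorly_resolved")
    est
  }
  if (inherits(point, "trait_estimate")) return(fill(point))
  lapply(point, function(el) if (inherits(el, "trait_estimate")) fill(el) else el)
}

# --- full profile -------------------------------------------------------------

TRAIT_ORDER <- c("a", "k", "d", "r", "mu_l", "sigma_l", "b_d", "b_r", "s", "m", "p")

# One pass of all estimators on (possibly resampled) raw vectors.
profile_point <- function(prep, idx = NULL) {
  out <- rep(NA_real_, length(TRAIT_ORDER))
  names(out) <- TRAIT_ORDER
  if (!is.null(prep$ads)) {
    a <- prep$ads
    ix <- if (is.null(idx)) seq_along(a$t) else idx$ads
    core <- fit_adsorption_core(a$t[ix], a$y[ix], a$H)
    out["a"] <- core$par[["a"]]; out["k"] <- core$par[["k"]]
  }
  if (!is.null(prep$dep)) {
    x <- if (is.null(idx)) prep$dep$x else stats::rbinom(1L, prep$dep$n, prep$dep$x / prep$dep$n)
    out["d"] <- estimate_depolarization_core(prep$dep$n, x, prep$dep$moi)$par[["d"]]
  }
  if (!is.null(prep$one)) {
    o <- prep$one
    ix <- if (is.null(idx)) seq_along(o$t) else idx$one
    lys <- fit_lysis_core(o$t[ix], o$ic[ix], o$dd[ix], o$sigma_min)
    out["r"] <- lys$par[["r"]]; out["mu_l"] <- lys$par[["mu_l"]]
    out["sigma_l"] <- lys$par[["sigma_l"]]
    bur <- estimate_burst_core(o$t[ix], o$free[ix], o$dd[ix],
                               out["r"], out["mu_l"], out["sigma_l"])
    out["b_d"] <- bur$par[["b_d"]]; out["b_r"] <- bur$par[["b_r"]]
  }
  out["s"] <- out["a"] * out["d"] * out["r"]
  if (!is.null(prep$dec)) {
    dc <- prep$dec
    ix <- if (is.null(idx)) seq_along(dc$t) else idx$dec
    core <- fit_decay_core(dc$t[ix], dc$y[ix])
    out["m"] <- core$par[["m"]]; out["p"] <- core$par[["p"]]
  }
  out
}

prepare_dataset <- function(dataset) {
  prep <- list()
  has <- function(nm) !is.null(dataset[[nm]]) && nrow(dataset[[nm]]) > 0
  if (has("adsorption")) {
    a <- dataset$adsorption
    prep$ads <- list(t = a$time_h, y = a$free_pfu_per_ml,
                     H = a$host_density_per_ml[1], n = nrow(a))
  }
  if (has("depolarization")) {
    d <- dataset$depolarization
    prep$dep <- list(n = sum(d$cells_total), x = sum(d$cells_depolarized),
                     moi = d$adsorbed_moi[1])
  }
  if (has("onestep")) {
    o <- dataset$onestep
    tu <- sort(unique(o$time_h))
    prep$one <- list(t = o$time_h, ic = o$infectious_centers_per_ml,
                     free = o$free_pfu_per_ml, dd = o$depolarized_cells_per_ml,
                     sigma_min = stats::median(diff(tu)) / 2, n = nrow(o))
  }
  if (has("decay")) {
    dc <- dataset$decay
    prep$dec <- list(t = dc$time_h, y = dc$pfu_per_ml, n = nrow(dc))
  }
  prep
}

#' Estimate a strain's full life-history profile
#'
#' Runs every trait estimator on one strain's assay dataset, then a joint
#' bootstrap: each of the `n_boot` iterations resamples all assay tables at
#' once and refits everything, so derived traits (`s`, `b_d`, `b_r`) get
#' properly propagated intervals. Per-trait estimation failures never abort
#' the profile; the affected traits are flagged. Missing assay tables flag
#' their traits `"missing_data"`.
#'
#' @param dataset An `assay_dataset` (see [build_panel()]) or a plain list
#'   with any of `adsorption`, `depolarization`, `onestep`, `decay` tables
#'   plus `strain_id`.
#' @param n_boot Number of joint bootstrap iterations (>= 100).
#' @param seed Integer seed.
#' @return An object of class `life_history_profile`: per-trait
#'   [trait_estimate()] records for `a, k, d, r, mu_l, sigma_l, b_d, b_r, s,
#'   m, p`. Coerce with `as.data.frame()`.
#' @export
estimate_profile <- function(dataset, n_boot = 1000L, seed = 1L) {
  if (n_boot < 100L) stop_msg("n_boot must be >= 100")
  prep <- prepare_dataset(dataset)
  point <- profile_point(prep)

  set.seed(seed)
  draws <- matrix(NA_real_, n_boot, length(TRAIT_ORDER),
                  dimnames = list(NULL, TRAIT_ORDER))
  fails <- 0L
  for (b in seq_len(n_boot)) {
    idx <- list(
      ads = if (!is.null(prep$ads)) resample_cases(prep$ads$n),
      one = if (!is.null(prep$one)) resample_cases(prep$one$n),
      dec = if (!is.null(prep$dec)) resample_cases(prep$dec$n)
    )
    res <- tryCatch(profile_point(prep, idx), error = function(e) NULL)
    if (is.null(res)) { fails <- fails + 1L; next }
    draws[b, ] <- res
  }

  missing_tables <- c(
    if (is.null(prep$ads)) c("a", "k"),
    if (is.null(prep$dep)) "d",
    if (is.null(prep$one)) c("r", "mu_l", "sigma_l", "b_d", "b_r"),
    if (is.null(prep$dec)) c("m", "p")
  )
  if (any(c("a", "d", "r") %in% missing_tables))
    missing_tables <- c(missing_tables, "s")

  estimates <- lapply(TRAIT_ORDER, function(nm) {
    if (nm %in% missing_tables)
      return(trait_estimate(nm, NA_real_, NA_real_, NA_real_, n_boot,
                            converged = FALSE,
                            flags = c("missing_data", "poorly_resolved")))
    est_val <- if (is.finite(point[nm])) clamp_trait(nm, point[nm]) else NA_real_
    ci <- percentile_ci(draws[, nm], est_val)
    flags <- character()
    if (!is.finite(point[nm])) flags <- c(flags, "poorly_resolved")
    if (ci$adjusted) flags <- c(flags, "ci_adjusted")
    fail_frac <- (fails + sum(!is.finite(draws[, nm]))) / n_boot
    if (fail_frac > 0.2) flags <- c(flags, "ci_unreliable", "poorly_resolved")
    lo <- clamp_trait(nm, ci$low); hi <- clamp_trait(nm, ci$high)
    if (poorly_resolved(nm, lo, hi)) flags <- c(flags, "poorly_resolved")
    trait_estimate(nm, est_val, lo, hi, n_boot, flags = unique(flags))
  })
  names(estimates) <- TRAIT_ORDER

  out <- list(strain_id = dataset$strain_id %||% NA_character_,
              estimates = estimates, n_boot = as.integer(n_boot),
              seed = as.integer(seed))
  class(out) <- "life_history_profile"
  out
}

#' @export
as.data.frame.life_history_profile <- function(x, ...) {
  do.call(rbind, lapply(x$estimates, function(e) {
    data.frame(strain_id = x$strain_id, trait = e$trait_name,
               estimate = e$estimate, ci_low = e$ci_low, ci_high = e$ci_high,
               n_boot = e$n_boot,
               flags = paste(e$diagnostics$flags, collapse = ";"),
               row.names = NULL)
  }))
}

#' @export
print.life_history_profile <- function(x, ...) {
  cat(sprintf("Life-history profile for %s (n_boot = %d)\n", x$strain_id, x$n_boot))
  for (e in x$estimates) print(e)
  invisible(x)
}

#' Tabulate profiles in wide form
#'
#' @param profiles A list of `life_history_profile` objects.
#' @param drop_flagged Replace poorly resolved estimates with `NA`
#'   (mirroring the exclusion of unresolved traits from downstream analysis).
#' @return A `data.frame` with one row per strain and columns
#'   `<trait>`, `<trait>_lo`, `<trait>_hi` for each of the eleven traits.
#' @export
profiles_table <- function(profiles, drop_flagged = TRUE) {
  do.call(rbind, lapply(profiles, function(p) {
    row <- data.frame(strain_id = p$strain_id)
    for (e in p$estimates) {
      bad <- drop_flagged && is_flagged(e)
      row[[e$trait_name]] <- if (bad) NA_real_ else e$estimate
      row[[paste0(e$trait_name, "_lo")]] <- if (bad) NA_real_ else e$ci_low
      row[[paste0(e$trait_name, "_hi")]] <- if (bad) NA_real_ else e$ci_high
    }
    row
  }))
}
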