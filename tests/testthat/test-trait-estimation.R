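test_that("adsorption fit recovers the constant, the plateau, and degenerate cases", {
  t <- c(0, 0.5, 1, 1.5, 2)
  H <- 1e7
  # complete adsorption: log-linear reduction, slope -k*H
  rows <- data.frame(replicate = 1L, time_h = t,
                     free_pfu_per_ml = 1e6 * exp(-0.5 * t),
                     host_density_per_ml = H)
  fit <- fit_adsorption(rows)
  expect_equal(fit$k$estimate, 5e-8, tolerance = 1e-6)
  expect_gt(fit$a$estimate, 0.99)

  # partial attachment: plateau identifies a, decay rate identifies k*H
  t2 <- seq(0, 6, by = 0.5)
  rows2 <- data.frame(replicate = 1L, time_h = t2,
                      free_pfu_per_ml = 1e6 * (0.2 + 0.8 * exp(-t2)),
                      host_density_per_ml = H)
  fit2 <- fit_adsorption(rows2)
  expect_equal(fit2$a$estimate, 0.8, tolerance = 1e-4)
  expect_equal(fit2$k$estimate * H, 1, tolerance = 1e-4)

  # constant counts: no adsorption detectable
  rows3 <- data.frame(replicate = 1L, time_h = t, free_pfu_per_ml = 5e5,
                      host_density_per_ml = H)
  expect_equal(fit_adsorption(rows3)$k$estimate, 0)

  # all-zero counts: flagged failure, never silent
  rows4 <- data.frame(replicate = 1L, time_h = t, free_pfu_per_ml = 0,
                      host_density_per_ml = H)
  fit4 <- fit_adsorption(rows4)
  expect_true(is.na(fit4$k$estimate))
  expect_true("poorly_resolved" %in% fit4$k$diagnostics$flags)
})

test_that("depolarization probability inverts the multiplicity model", {
  mk <- function(x, n, moi) data.frame(replicate = seq_along(x), cells_total = n,
                                       cells_depolarized = x, adsorbed_moi = moi)
  expect_equal(estimate_depolarization(mk(0, 300, 2))$estimate, 0)
  n <- 4e5
  expect_equal(estimate_depolarization(mk(round((1 - exp(-1)) * n), n, 2))$estimate,
               0.5, tolerance = 1e-3)
  expect_equal(estimate_depolarization(mk(round((1 - exp(-0.25)) * n), n, 1))$estimate,
               0.25, tolerance = 1e-3)
  sat <- estimate_depolarization(mk(300, 300, 2))
  expect_equal(sat$estimate, 1)
  expect_true("saturated" %in% sat$diagnostics$flags)
  expect_error(estimate_depolarization(mk(301, 300, 2)), "exceed")
})

test_that("lysis curve fit recovers plateau, midpoint and spread", {
  t <- seq(0, 16, by = 0.5)
  D <- 1e6
  mkrows <- function(y) data.frame(replicate = 1L, time_h = t,
                                   infectious_centers_per_ml = y * D,
                                   free_pfu_per_ml = 0,
                                   depolarized_cells_per_ml = D)
  y <- 0.8 * (1 - pnorm(t, 8, 1.5))
  fit <- fit_lysis_curve(mkrows(y))
  expect_equal(fit$r$estimate, 0.8, tolerance = 1e-3)
  expect_equal(fit$mu_l$estimate, 8, tolerance = 1e-3)
  expect_equal(fit$sigma_l$estimate, 1.5, tolerance = 2e-3)
  expect_equal(fit$depol_density, D)
  expect_equal(fit$releasing_density, 0.8 * D, tolerance = 1e-3)

  # step curve: sigma collapses to its lower bound (half the sampling step)
  stp <- fit_lysis_curve(mkrows(as.numeric(t < 8)))
  expect_equal(stp$r$estimate, 1, tolerance = 0.05)
  expect_equal(stp$mu_l$estimate, 8, tolerance = 0.3)
  expect_equal(stp$sigma_l$estimate, 0.25, tolerance = 0.1)

  # all-zero release: r = 0, timing unresolvable
  zero <- fit_lysis_curve(mkrows(rep(0, length(t))))
  expect_equal(zero$r$estimate, 0)
  expect_true(is.na(zero$mu_l$estimate))
  expect_true("poorly_resolved" %in% zero$mu_l$diagnostics$flags)
})

test_that("burst sizes follow yield arithmetic and the release probability", {
  t <- seq(0, 16, by = 0.5)
  D <- 1e6
  cdf <- pnorm(t, 8, 1)
  rows <- data.frame(replicate = 1L, time_h = t,
                     infectious_centers_per_ml = 0.8 * D * (1 - cdf),
                     free_pfu_per_ml = 0.8 * D * 500 * cdf,
                     depolarized_cells_per_ml = D)
  r <- trait_estimate("r", 0.8)
  fit <- estimate_burst_sizes(rows, r, mu_l = 8, sigma_l = 1)
  expect_equal(fit$b_d$estimate, 400, tolerance = 1e-3)
  expect_equal(fit$b_r$estimate, 500, tolerance = 1e-3)

  # zero yield
  rows0 <- rows; rows0$free_pfu_per_ml <- 0
  fit0 <- estimate_burst_sizes(rows0, r, mu_l = 8, sigma_l = 1)
  expect_equal(fit0$b_d$estimate, 0)
  expect_equal(fit0$b_r$estimate, 0)

  # r = 1 makes the two burst sizes coincide
  fit1 <- estimate_burst_sizes(rows, trait_estimate("r", 1), mu_l = 8, sigma_l = 1)
  expect_equal(fit1$b_d$estimate, fit1$b_r$estimate)

  # r = 0: burst per release undefined, flagged
  fitna <- estimate_burst_sizes(rows, trait_estimate("r", 0), mu_l = 8, sigma_l = 1)
  expect_true(is.na(fitna$b_r$estimate))
  expect_true("b_r_undefined" %in% fitna$b_r$diagnostics$flags)
})

test_that("specific infectivity is the product of its components", {
  te <- function(nm, v) trait_estimate(nm, v)
  expect_equal(estimate_specific_infectivity(te("a", 1), te("d", 1), te("r", 1))$estimate, 1)
  expect_equal(estimate_specific_infectivity(te("a", 0.8), te("d", 0.5), te("r", 0.25))$estimate, 0.1)
  expect_equal(estimate_specific_infectivity(te("a", 0.8), te("d", 0), te("r", 0.25))$estimate, 0)
  flagged <- trait_estimate("d", 0.5, flags = "poorly_resolved")
  s <- estimate_specific_infectivity(te("a", 0.8), flagged, te("r", 0.25))
  expect_true("poorly_resolved" %in% s$diagnostics$flags)
  # CI from joint draws is the percentile of products, not interval arithmetic
  set.seed(1)
  draws <- cbind(a = runif(500, 0.7, 0.9), d = runif(500, 0.4, 0.6),
                 r = runif(500, 0.2, 0.3))
  s2 <- estimate_specific_infectivity(te("a", 0.8), te("d", 0.5), te("r", 0.25),
                                      joint_draws = draws)
  prods <- draws[, 1] * draws[, 2] * draws[, 3]
  expect_equal(s2$ci_low, unname(quantile(prods, 0.025)), tolerance = 1e-10)
  expect_equal(s2$ci_high, unname(quantile(prods, 0.975)), tolerance = 1e-10)
})

test_that("biphasic decay fit recovers (m, p) against a grid-search oracle", {
  t <- seq(0, 200, by = 10)
  y <- 1e6 * (0.01 + 0.99 * exp(-0.05 * t))
  rows <- data.frame(replicate = 1L, time_h = t, pfu_per_ml = y)
  fit <- fit_decay(rows)
  expect_equal(fit$m$estimate, 0.05, tolerance = 1e-4)
  expect_equal(fit$p$estimate, 0.01, tolerance = 1e-4)

  # independent oracle: dense grid search over (m, p) minimizing log-scale SSE
  grid <- expand.grid(m = seq(0.01, 0.1, by = 0.002), p = seq(0.002, 0.03, by = 0.001))
  sse <- vapply(seq_len(nrow(grid)), function(i) {
    pred <- grid$p[i] + (1 - grid$p[i]) * exp(-grid$m[i] * t)
    z <- log(y) - log(pred)
    sum((z - mean(z))^2)
  }, numeric(1))
  best <- grid[which.min(sse), ]
  expect_equal(fit$m$estimate, best$m, tolerance = 0.05)
  expect_equal(fit$p$estimate, best$p, tolerance = 0.1)

  # constant titers: the no-decay convention
  const <- fit_decay(data.frame(replicate = 1L, time_h = t, pfu_per_ml = 1e6))
  expect_equal(const$m$estimate, 0)
  expect_equal(const$p$estimate, 1)
  expect_true("no_decay" %in% const$m$diagnostics$flags)
})

test_that("single-phase decay reduces exactly to log-linear regression", {
  t <- seq(0, 120, by = 8)
  set.seed(31)
  y <- 1e6 * exp(-0.03 * t) * exp(rnorm(length(t), 0, 0.05))
  rows <- data.frame(replicate = 1L, time_h = t, pfu_per_ml = y)
  fit <- fit_decay(rows)
  slope <- -unname(stats::coef(stats::lm(log(y) ~ t))[2])
  expect_equal(fit$m$estimate, slope, tolerance = 1e-6)
  expect_lte(fit$p$estimate, 1e-4)
})

test_that("bootstrap intervals are seeded, degenerate without noise, and validated", {
  t <- seq(0, 200, by = 20)
  y <- 1e6 * (0.02 + 0.98 * exp(-0.04 * t))
  rows <- data.frame(replicate = rep(1:3, each = length(t)),
                     time_h = rep(t, 3), pfu_per_ml = rep(y, 3))
  # zero noise: every resample is identical, interval collapses on the estimate
  ci <- bootstrap_ci(fit_decay, rows, n_boot = 100, seed = 1)
  expect_equal(ci$m$ci_low, ci$m$estimate, tolerance = 1e-4)
  expect_equal(ci$m$ci_high, ci$m$estimate, tolerance = 1e-4)

  set.seed(77)
  noisy <- rows
  noisy$pfu_per_ml <- noisy$pfu_per_ml * exp(rnorm(nrow(noisy), 0, 0.1))
  c1 <- bootstrap_ci(fit_decay, noisy, n_boot = 120, seed = 5)
  c2 <- bootstrap_ci(fit_decay, noisy, n_boot = 120, seed = 5)
  expect_identical(c1$m$ci_low, c2$m$ci_low)
  expect_identical(c1$p$ci_high, c2$p$ci_high)
  expect_lte(c1$m$ci_low, c1$m$estimate)
  expect_gte(c1$m$ci_high, c1$m$estimate)
  # replicate-level resampling is available for correlated replicates
  c3 <- bootstrap_ci(fit_decay, noisy, n_boot = 120, seed = 5, resample = "replicate")
  expect_lte(c3$m$ci_low, c3$m$estimate)
  expect_error(bootstrap_ci(fit_decay, noisy, n_boot = 50), "n_boot")
})

test_that("full profiles recover noise-free truth and tolerate missing assays", {
  tr <- draw_true_traits(1, seed = 21)
  ds <- make_noisefree_dataset(tr)
  prof <- estimate_profile(ds, n_boot = 100, seed = 2)
  df <- as.data.frame(prof)
  truth <- unlist(tr[df$trait])
  rel <- abs(df$estimate - truth) / abs(truth)
  expect_true(all(rel < 0.01), info = paste(df$trait, signif(rel, 3), collapse = "; "))
  # order constraints on output
  est <- setNames(df$estimate, df$trait)
  expect_lte(est["b_d"], est["b_r"] + 1e-9)
  expect_lte(est["s"], min(est["a"], est["d"], est["r"]) + 1e-9)

  # missing decay table: m and p flagged, everything else estimated
  ds2 <- ds; ds2$decay <- NULL
  prof2 <- estimate_profile(ds2, n_boot = 100, seed = 2)
  expect_true(is.na(prof2$estimates$m$estimate))
  expect_true("missing_data" %in% prof2$estimates$m$diagnostics$flags)
  expect_false(is.na(prof2$estimates$k$estimate))
})

test_that("estimators are invariant to row order and replicate relabeling", {
  tr <- draw_true_traits(1, seed = 8)
  des <- assay_design()
  set.seed(15)
  ds <- list(strain_id = "x",
             adsorption = simulate_adsorption_assay(tr, des),
             decay = simulate_decay_assay(tr, des))
  one <- simulate_one_step_assay(tr, des)
  ds$onestep <- one$onestep; ds$depolarization <- one$depolarization

  shuffle <- function(df, seed) { set.seed(seed); df[sample(nrow(df)), ] }
  relabel <- function(df) { df$replicate <- max(df$replicate) + 1 - df$replicate; df }

  f1 <- fit_adsorption(ds$adsorption)
  f2 <- fit_adsorption(relabel(shuffle(ds$adsorption, 1)))
  expect_equal(f1$k$estimate, f2$k$estimate)
  d1 <- fit_decay(ds$decay)
  d2 <- fit_decay(relabel(shuffle(ds$decay, 2)))
  expect_equal(d1$m$estimate, d2$m$estimate)
  l1 <- fit_lysis_curve(ds$onestep)
  l2 <- fit_lysis_curve(relabel(shuffle(ds$onestep, 3)))
  expect_equal(l1$mu_l$estimate, l2$mu_l$estimate)
  p1 <- estimate_depolarization(ds$depolarization)
  p2 <- estimate_depolarization(relabel(shuffle(ds$depolarization, 4)))
  expect_equal(p1$estimate, p2$estimate)
})
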