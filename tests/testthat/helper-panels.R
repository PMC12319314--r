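# Shared fixtures: noise-free designs and datasets built in code.

noisefree_design <- function(...) {
  assay_design(count_noise = FALSE, titer_cv = 0, ...)
}

# A complete noise-free dataset for one strain (no growth table by default).
make_noisefree_dataset <- function(traits, design = noisefree_design()) {
  one <- suppressWarnings(simulate_one_step_assay(traits, design))
  ds <- list(strain_id = traits$strain_id,
             adsorption = simulate_adsorption_assay(traits, design),
             depolarization = one$depolarization,
             onestep = one$onestep,
             decay = simulate_decay_assay(traits, design))
  class(ds) <- "assay_dataset"
  ds
}

# Trait ranges where only specific infectivity varies between strains; the
# other growth inputs are pinned, so observed growth is driven by s alone.
s_dominated_ranges <- function() {
  rng <- default_trait_ranges()
  rng$a <- c(0.4, 0.95)
  rng$d <- c(0.25, 0.9)
  rng$r <- c(0.35, 0.95)
  rng$k <- c(3e-7, 3e-7)
  rng$mu_l <- c(8, 8)
  rng$sigma_l <- c(1, 1)
  rng$b_r <- c(300, 300)
  rng$m <- c(0.03, 0.03)
  rng$p <- c(0.05, 0.05)
  rng
}

# Brute-force all-subsets OLS + AIC oracle, independent of the package path
# (lm + explicit formula per subset).
aic_oracle <- function(y, X) {
  p_all <- names(X)
  subsets <- lapply(0:(2^length(p_all) - 1), function(mask)
    p_all[bitwAnd(mask, 2^(seq_along(p_all) - 1)) > 0])
  n <- length(y)
  rows <- lapply(subsets, function(vars) {
    dat <- cbind(data.frame(y = y), X)
    fm <- if (length(vars)) stats::reformulate(vars, "y") else y ~ 1
    fit <- stats::lm(fm, data = dat)
    rss <- sum(stats::residuals(fit)^2)
    K <- length(stats::coef(fit)) + 1
    data.frame(subset = if (length(vars)) paste(vars, collapse = "+") else "(intercept only)",
               rss = rss, aic = n * log(rss / n) + 2 * K)
  })
  tab <- do.call(rbind, rows)
  tab$delta_aic <- tab$aic - min(tab$aic)
  tab$consensus <- list(Reduce(intersect, subsets[tab$delta_aic <= 2]))
  tab
}
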