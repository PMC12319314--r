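# Observation-noise helpers ---------------------------------------------------

# Plaque/cell-count noise: an idealized serial dilution brings the expected
# plate count to `target`, the count is Poisson, and the titer is read back
# off the dilution. Relative noise ~ 1/sqrt(target) at every titer.
count_noisy_titer <- function(expectation, target) {
  out <- numeric(length(expectation))
  pos <- is.finite(expectation) & expectation > 0
  scale <- expectation[pos] / target
  out[pos] <- stats::rpois(sum(pos), rep(target, sum(pos))) * scale
  out
}

# Multiplicative lognormal titer noise with coefficient of variation cv,
# mean-preserving (E[obs] = expectation).
lognormal_noisy_titer <- function(expectation, cv) {
  if (cv <= 0) return(expectation)
  sdlog <- sqrt(log(1 + cv^2))
  expectation * stats::rlnorm(length(expectation), meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

# Closed-form assay expectations ----------------------------------------------

# Free-virus titer during adsorption: the attaching fraction a is depleted
# exponentially at rate k*H, the rest stays free.
adsorption_expectation <- function(t, v0, a, k, H) {
  v0 * ((1 - a) + a * exp(-k * H * t))
}

# Surviving infectious titer under biphasic decay with persistent fraction p.
decay_expectation <- function(t, v0, m, p) {
  v0 * (p + (1 - p) * exp(-m * t))
}

# Cumulative lysed fraction among releasing cells: normal CDF in time,
# left-truncated at 0 (lysis cannot precede infection).
lysis_cdf <- function(t, mu_l, sigma_l) {
  if (sigma_l <= 0) return(as.numeric(t >= mu_l))
  p0 <- stats::pnorm(0, mu_l, sigma_l)
  pmax(0, (stats::pnorm(t, mu_l, sigma_l) - p0) / (1 - p0))
}

# Simulators -------------------------------------------------------------------

#' Simulate a free-virus adsorption time series
#'
#' Expected free titer is `v0 * ((1 - a) + a * exp(-k * H * t))`: the
#' attaching fraction `a` of virions is depleted exponentially at rate `k * H`
#' while the remainder never adsorbs. With `count_noise` on, observed titers
#' carry Poisson plaque-counting noise.
#'
#' @param traits One row of a true-traits table (see [draw_true_traits()]).
#' @param design An [assay_design()].
#' @return A `data.frame` with columns `replicate`, `time_h`,
#'   `free_pfu_per_ml`, `host_density_per_ml`.
#' @export
simulate_adsorption_assay <- function(traits, design) {
  design <- validate_assay_design(design)
  traits <- validate_true_traits(as.data.frame(traits))
  stopifnot(nrow(traits) == 1L)
  grid <- expand.grid(time_h = design$t_adsorption,
                      replicate = seq_len(design$n_replicates))
  mu <- adsorption_expectation(grid$time_h, design$v0, traits$a, traits$k,
                               design$host_density)
  obs <- if (design$count_noise) count_noisy_titer(mu, design$target_count) else mu
  data.frame(replicate = grid$replicate, time_h = grid$time_h,
             free_pfu_per_ml = obs, host_density_per_ml = design$host_density)
}

#' Simulate a one-step growth assay with its depolarization counts
#'
#' Cells are depolarized with probability `1 - exp(-d * moi)` (Poisson
#' multiplicity statistics); a fraction `r` of depolarized cells goes on to
#' lyse, with lysis times normal `(mu_l, sigma_l)` truncated at 0. Infectious
#' centers count releasing cells that have not yet lysed; free virus is the
#' residual inoculum plus `b_r` progeny per lysed cell.
#'
#' @inheritParams simulate_adsorption_assay
#' @return A list with `onestep` rows (`replicate`, `time_h`,
#'   `infectious_centers_per_ml`, `free_pfu_per_ml`,
#'   `depolarized_cells_per_ml`), `depolarization` rows (`replicate`,
#'   `cells_total`, `cells_depolarized`, `adsorbed_moi`), and a `truncated`
#'   flag set when the sampling grid ends before `mu_l + 3 * sigma_l`.
#' @export
simulate_one_step_assay <- function(traits, design) {
  design <- validate_assay_design(design)
  traits <- validate_true_traits(as.data.frame(traits))
  stopifnot(nrow(traits) == 1L)
  H <- design$host_density
  f_depol <- 1 - exp(-traits$d * design$adsorbed_moi)
  D <- H * f_depol                      # depolarized cells / mL
  f0 <- design$residual_frac * design$v0  # residual free inoculum

  truncated <- max(design$t_onestep) < traits$mu_l + 3 * traits$sigma_l
  if (truncated)
    warning("one-step sampling grid ends before mu_l + 3*sigma_l; lysis curve truncated",
            call. = FALSE)

  grid <- expand.grid(time_h = design$t_onestep,
                      replicate = seq_len(design$n_replicates))
  cdf <- lysis_cdf(grid$time_h, traits$mu_l, traits$sigma_l)
  ic_mu <- traits$r * D * (1 - cdf)
  free_mu <- f0 + traits$b_r * traits$r * D * cdf
  if (design$count_noise) {
    ic <- count_noisy_titer(ic_mu, design$target_count)
    free <- count_noisy_titer(free_mu, design$target_count)
    depol_dens <- count_noisy_titer(rep(D, nrow(grid)), design$target_count)
    cells_dep <- stats::rbinom(design$n_replicates, design$cells_total, f_depol)
  } else {
    ic <- ic_mu; free <- free_mu
    depol_dens <- rep(D, nrow(grid))
    cells_dep <- design$cells_total * f_depol
  }
  onestep <- data.frame(replicate = grid$replicate, time_h = grid$time_h,
                        infectious_centers_per_ml = ic,
                        free_pfu_per_ml = free,
                        depolarized_cells_per_ml = depol_dens)
  depolarization <- data.frame(replicate = seq_len(design$n_replicates),
                               cells_total = design$cells_total,
                               cells_depolarized = cells_dep,
                               adsorbed_moi = design$adsorbed_moi)
  list(onestep = onestep, depolarization = depolarization, truncated = truncated)
}

#' Simulate a survival (decay) assay
#'
#' Expected surviving titer is `v0 * (p + (1 - p) * exp(-m * t))`: most
#' virions decay at mortality rate `m` while a persistent fraction `p`
#' resists decay.
#'
#' @inheritParams simulate_adsorption_assay
#' @return A `data.frame` with columns `replicate`, `time_h`, `pfu_per_ml`.
#' @export
simulate_decay_assay <- function(traits, design) {
  design <- validate_assay_design(design)
  traits <- validate_true_traits(as.data.frame(traits))
  stopifnot(nrow(traits) == 1L)
  grid <- expand.grid(time_h = design$t_decay,
                      replicate = seq_len(design$n_replicates))
  mu <- decay_expectation(grid$time_h, design$v0, traits$m, traits$p)
  obs <- if (design$count_noise) count_noisy_titer(mu, design$target_count) else mu
  data.frame(replicate = grid$replicate, time_h = grid$time_h, pfu_per_ml = obs)
}

#' Simulate a population growth assay
#'
#' Total titer grows (or declines) exponentially at `growth_rate`; observed
#' titers carry multiplicative lognormal noise with the design's `titer_cv`.
#'
#' @inheritParams simulate_adsorption_assay
#' @param growth_rate Exponential growth rate, per hour. Typically the rate
#'   predicted from the same strain's traits by [predict_growth_rate()], so
#'   that end-to-end recovery is testable.
#' @return A `data.frame` with columns `replicate`, `time_h`, `pfu_per_ml`.
#' @export
simulate_growth_assay <- function(traits, design, growth_rate) {
  design <- validate_assay_design(design)
  if (!is.finite(growth_rate)) stop_msg("growth_rate must be finite")
  v0 <- 1e4  # growth assays start from a dilute inoculum
  grid <- expand.grid(time_h = design$t_growth,
                      replicate = seq_len(design$n_replicates))
  mu <- v0 * exp(growth_rate * grid$time_h)
  obs <- if (design$count_noise) lognormal_noisy_titer(mu, design$titer_cv) else mu
  data.frame(replicate = grid$replicate, time_h = grid$time_h, pfu_per_ml = obs)
}

# Panel assembly ----------------------------------------------------------------

# Species/type-host grouping for synthetic panels: contiguous blocks of
# near-equal size (3 groups of {12, 12, 10} for the default 34-strain panel).
# Host and species are deliberately confounded, as in real collections where
# each species is assayed in its type host.
assign_strain_metadata <- function(strain_ids, n_groups = 3L, seed = 1L) {
  n <- length(strain_ids)
  n_groups <- max(1L, min(as.integer(n_groups), n))
  sizes <- rep(ceiling(n / n_groups), n_groups)
  i <- n_groups
  while (sum(sizes) > n) {  # trim from the last group: {12, 12, 10} for 34/3
    sizes[i] <- sizes[i] - 1L
    if (sizes[i] == 1L) i <- i - 1L
  }
  grp <- rep(seq_len(n_groups), sizes)
  set.seed(seed)
  genome <- round(stats::runif(n, 290e3, 370e3))
  data.frame(strain_id = strain_ids,
             species = sprintf("species_%s", LETTERS[grp]),
             type_host = sprintf("host_%s", LETTERS[grp]),
             genome_size_bp = genome)
}

#' Build a complete synthetic assay panel with known ground truth
#'
#' Draws ground-truth traits for `n_strains` strains, predicts each strain's
#' growth rate from its own traits via the Euler-Lotka characteristic
#' equation, and simulates all five assays per strain. Species/type-host
#' labels and genome sizes are assigned by a configurable grouping scheme so
#' that variance-partitioning and within-species analyses are exercisable.
#'
#' @inheritParams draw_true_traits
#' @param design An [assay_design()]; its `seed` is overridden by `seed`.
#' @param n_groups Number of species/type-host groups.
#' @param out_dir Optional directory; when given, all tables are written as
#'   CSV (see [write_panel()]) and the paths recorded in the result.
#' @return An object of class `assay_panel`: a list with `truth` (true-traits
#'   table including the predicted growth rate `lambda_pred`), `metadata`
#'   (strain/species/host/genome table), and `datasets` (named list of
#'   per-strain assay datasets, each holding the five assay tables).
#' @export
build_panel <- function(n_strains = 34L,
                        trait_ranges = default_trait_ranges(),
                        design = assay_design(),
                        n_groups = 3L,
                        seed = 1L,
                        out_dir = NULL) {
  design <- validate_assay_design(design)
  truth <- draw_true_traits(n_strains, trait_ranges, seed = seed)
  metadata <- assign_strain_metadata(truth$strain_id, n_groups = n_groups,
                                     seed = seed + 1L)
  truth$lambda_pred <- vapply(seq_len(nrow(truth)), function(i) {
    predict_growth_rate(truth$s[i], truth$k[i], truth$mu_l[i], truth$b_r[i],
                        host_density = design$host_density)$lambda_pred
  }, numeric(1))

  set.seed(seed + 2L)
  datasets <- lapply(seq_len(nrow(truth)), function(i) {
    tr <- truth[i, ]
    one <- simulate_one_step_assay(tr, design)
    ds <- list(strain_id = tr$strain_id,
               adsorption = simulate_adsorption_assay(tr, design),
               depolarization = one$depolarization,
               onestep = one$onestep,
               decay = simulate_decay_assay(tr, design),
               growth = simulate_growth_assay(tr, design, tr$lambda_pred),
               truncated_onestep = one$truncated)
    class(ds) <- "assay_dataset"
    ds
  })
  names(datasets) <- truth$strain_id

  panel <- list(truth = truth, metadata = metadata, datasets = datasets,
                design = design, seed = as.integer(seed))
  class(panel) <- "assay_panel"
  if (!is.null(out_dir)) panel$paths <- write_panel(panel, out_dir)
  panel
}

#' @export
print.assay_panel <- function(x, ...) {
  cat(sprintf("Synthetic assay panel: %d strains, %d species groups, seed %d\n",
              nrow(x$truth), length(unique(x$metadata$species)), x$seed))
  invisible(x)
}
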