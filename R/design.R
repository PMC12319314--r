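#' Assay design for synthetic panels
#'
#' Bundles the experimental design shared by the five simulated assays:
#' culture conditions, sampling grids, replication, and the observation-noise
#' model. Defaults describe a typical algal-virus assay campaign: a host
#' culture at 1e7 cells/mL, triplicate assays, plaque counts read from plates
#' diluted to roughly `target_count` plaques (Poisson counting noise), and
#' growth-assay titers with ~15% lognormal measurement error.
#'
#' @param host_density Host cell density, cells/mL.
#' @param v0 Initial free-virus titer for the adsorption and decay assays,
#'   PFU/mL.
#' @param adsorbed_moi Mean adsorbed virions per cell in the depolarization
#'   and one-step assays.
#' @param t_adsorption,t_onestep,t_decay,t_growth Strictly increasing
#'   sampling-time grids, hours.
#' @param n_replicates Replicates per assay (>= 1).
#' @param count_noise If `TRUE`, plaque/cell counts are Poisson-distributed
#'   around their expectations; if `FALSE` the expectations are returned
#'   exactly (useful for oracle tests).
#' @param titer_cv Lognormal coefficient of variation for growth-assay titer
#'   measurements (0 disables).
#' @param target_count Expected plaques (or cells) counted per plate after
#'   idealized serial dilution; sets the relative Poisson noise to roughly
#'   `1/sqrt(target_count)`.
#' @param cells_total Cells scored per replicate in the depolarization assay.
#' @param residual_frac Fraction of the one-step inoculum left as residual
#'   free virus after washing, relative to `v0`.
#' @param seed Integer seed consumed by the simulators.
#' @return An object of class `assay_design` (a validated list).
#' @export
assay_design <- function(host_density = 1e7,
                         v0 = 1e6,
                         adsorbed_moi = 2,
                         t_adsorption = c(0, 0.25, 0.5, 0.75, 1, 1.5, 2, 3, 4, 6),
                         t_onestep = seq(0, 18, by = 1),
                         t_decay = c(0, 24, 48, 96, 144, 216, 312, 432, 600),
                         t_growth = seq(0, 24, by = 3),
                         n_replicates = 3L,
                         count_noise = TRUE,
                         titer_cv = 0.15,
                         target_count = 200,
                         cells_total = 300L,
                         residual_frac = 0.02,
                         seed = 1L) {
  des <- list(host_density = host_density, v0 = v0, adsorbed_moi = adsorbed_moi,
              t_adsorption = t_adsorption, t_onestep = t_onestep,
              t_decay = t_decay, t_growth = t_growth,
              n_replicates = as.integer(n_replicates),
              count_noise = isTRUE(count_noise), titer_cv = titer_cv,
              target_count = target_count, cells_total = as.integer(cells_total),
              residual_frac = residual_frac, seed = as.integer(seed))
  class(des) <- "assay_design"
  validate_assay_design(des)
}

validate_assay_design <- function(design) {
  if (!inherits(design, "assay_design")) stop_msg("design must be an assay_design object")
  with(design, {
    if (host_density <= 0) stop_msg("host_density must be > 0")
    if (v0 <= 0) stop_msg("v0 must be > 0")
    if (adsorbed_moi <= 0) stop_msg("adsorbed_moi must be > 0")
    if (n_replicates < 1L) stop_msg("n_replicates must be >= 1")
    if (titer_cv < 0) stop_msg("titer_cv must be >= 0")
    if (target_count <= 0) stop_msg("target_count must be > 0")
    if (cells_total < 1L) stop_msg("cells_total must be >= 1")
    if (residual_frac < 0) stop_msg("residual_frac must be >= 0")
    for (grid in c("t_adsorption", "t_onestep", "t_decay", "t_growth")) {
      g <- design[[grid]]
      if (length(g) < 2L || any(diff(g) <= 0) || any(g < 0))
        stop_msg("%s must be a strictly increasing grid of non-negative times", grid)
    }
  })
  design
}
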