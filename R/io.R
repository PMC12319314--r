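# CSV interchange for assay panels, configuration, and the end-to-end
# pipeline. Units are encoded in column names (time_h, pfu_per_ml, ...).

PANEL_SCHEMAS <- list(
  strains = c("strain_id", "species", "type_host", "genome_size_bp"),
  adsorption = c("strain_id", "replicate", "time_h", "free_pfu_per_ml",
                 "host_density_per_ml"),
  depolarization = c("strain_id", "replicate", "cells_total",
                     "cells_depolarized", "adsorbed_moi"),
  onestep = c("strain_id", "replicate", "time_h", "infectious_centers_per_ml",
              "free_pfu_per_ml", "depolarized_cells_per_ml"),
  decay = c("strain_id", "replicate", "time_h", "pfu_per_ml"),
  growth = c("strain_id", "replicate", "time_h", "pfu_per_ml")
)
ASSAY_TABLES <- setdiff(names(PANEL_SCHEMAS), "strains")

#' Write an assay panel to CSV tables
#'
#' One CSV per table (`strains.csv`, `adsorption.csv`, `depolarization.csv`,
#' `onestep.csv`, `decay.csv`, `growth.csv`, plus `true_traits.csv` when the
#' panel carries ground truth), with documented case-sensitive headers.
#' Output is byte-identical for identical panels.
#'
#' @param panel An `assay_panel` from [build_panel()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of file paths, invisibly.
#' @export
write_panel <- function(panel, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(strains = file.path(dir, "strains.csv"))
  utils::write.csv(panel$metadata, paths["strains"], row.names = FALSE, quote = FALSE)
  for (tb in ASSAY_TABLES) {
    combined <- do.call(rbind, lapply(panel$datasets, function(ds) {
      if (is.null(ds[[tb]])) return(NULL)
      cbind(strain_id = ds$strain_id, ds[[tb]])
    }))
    paths[tb] <- file.path(dir, paste0(tb, ".csv"))
    utils::write.csv(combined, paths[tb], row.names = FALSE, quote = FALSE)
  }
  if (!is.null(panel$truth)) {
    paths["true_traits"] <- file.path(dir, "true_traits.csv")
    utils::write.csv(as.data.frame(panel$truth), paths["true_traits"],
                     row.names = FALSE, quote = FALSE)
  }
  invisible(paths)
}

#' Read an assay panel from CSV tables
#'
#' Loads and validates the panel tables written by [write_panel()] (or
#' prepared externally to the same schemas). Headers must match the
#' documented schemas exactly (case-sensitive); unknown or missing columns
#' are an error naming them. A missing assay file marks that assay absent
#' for every strain, and the downstream traits come back flagged.
#'
#' @param config A [panel_config()] or a directory path.
#' @return An `assay_panel` with `metadata`, `datasets` and, when present,
#'   `truth`.
#' @export
read_panel <- function(config) {
  if (is.character(config)) config <- panel_config(input_dir = config)
  dir <- config$input_dir
  read_tb <- function(tb, required = FALSE) {
    path <- file.path(dir, paste0(tb, ".csv"))
    if (!file.exists(path)) {
      if (required) stop_msg("required table not found: %s", path)
      return(NULL)
    }
    df <- utils::read.csv(path, check.names = FALSE)
    check_columns(df, PANEL_SCHEMAS[[tb]], tb)
  }
  metadata <- read_tb("strains", required = TRUE)
  tables <- lapply(ASSAY_TABLES, read_tb)
  names(tables) <- ASSAY_TABLES
  datasets <- lapply(metadata$strain_id, function(sid) {
    ds <- list(strain_id = sid)
    for (tb in ASSAY_TABLES) {
      if (is.null(tables[[tb]])) { ds[tb] <- list(NULL); next }
      rows <- tables[[tb]][tables[[tb]]$strain_id == sid, , drop = FALSE]
      rows$strain_id <- NULL
      row.names(rows) <- NULL
      ds[[tb]] <- if (nrow(rows)) rows else NULL
    }
    class(ds) <- "assay_dataset"
    ds
  })
  names(datasets) <- metadata$strain_id
  truth_path <- file.path(dir, "true_traits.csv")
  panel <- list(metadata = metadata, datasets = datasets,
                truth = if (file.exists(truth_path)) utils::read.csv(truth_path),
                design = NULL, seed = NA_integer_)
  class(panel) <- "assay_panel"
  panel
}

#' Pipeline configuration
#'
#' Settings for [run_pipeline()], validated at construction. Can be loaded
#' from a YAML file with [load_config()].
#'
#' @param input_dir Directory holding the panel CSVs (must exist).
#' @param out_dir Output directory for result tables and the run log.
#' @param n_boot Bootstrap iterations per strain (>= 100).
#' @param seed Master seed; all pipeline randomness derives from it.
#' @param host_density Host density for growth predictions, cells/mL.
#' @param n_perm Permutations for the comparative tests.
#' @param weight_rule CI-breadth weighting rule, `"product"` or `"sum"`.
#' @param growth_window Optional `c(t_min, t_max)` exponential window for
#'   observed-growth fits; `NULL` uses the full series.
#' @return A validated list of class `panel_config`.
#' @export
panel_config <- function(input_dir, out_dir = NULL, n_boot = 1000L, seed = 1L,
                         host_density = 1e7, n_perm = 999L,
                         weight_rule = c("product", "sum"),
                         growth_window = NULL) {
  weight_rule <- match.arg(weight_rule)
  if (!dir.exists(input_dir)) stop_msg("input_dir does not exist: %s", input_dir)
  if (n_boot < 100L) stop_msg("n_boot must be >= 100")
  if (n_perm < 1L) stop_msg("n_perm must be >= 1")
  if (host_density <= 0) stop_msg("host_density must be > 0")
  if (!is.null(growth_window) &&
      (length(growth_window) != 2L || growth_window[1] >= growth_window[2]))
    stop_msg("growth_window must be c(t_min, t_max) with t_min < t_max")
  structure(list(input_dir = input_dir, out_dir = out_dir,
                 n_boot = as.integer(n_boot), seed = as.integer(seed),
                 host_density = host_density, n_perm = as.integer(n_perm),
                 weight_rule = weight_rule, growth_window = growth_window),
            class = "panel_config")
}

#' Load a pipeline configuration from YAML
#'
#' @param path YAML file whose keys match the arguments of [panel_config()].
#' @return A validated `panel_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop_msg("config file not found: %s", path)
  vals <- yaml::read_yaml(path)
  do.call(panel_config, vals)
}

#' Run the full life-history pipeline on a panel
#'
#' Reads the panel, estimates every strain's life-history profile with joint
#' bootstrap CIs, predicts growth rates from the estimated traits, fits
#' observed growth rates, and runs the comparative analyses (fold-ranges,
#' type-host variance partitioning, predicted-vs-observed correlation,
#' all-subsets AIC selection, and within-species trade-off tests). All
#' randomness derives from the config seed; identical config and seed
#' reproduce byte-identical outputs. Per-strain estimation failures are
#' logged and flagged, never abort the panel.
#'
#' @param config A [panel_config()] (or directory path).
#' @return A results bundle (list) with `profiles`, `predictions`,
#'   `observed_growth`, `fold_ranges`, `variance_partition`,
#'   `model_selection`, `tradeoffs`, `log`, and `config_hash`. When
#'   `config$out_dir` is set, each table is also written as CSV together
#'   with `run_log.txt` and the hashed `config.yaml`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- panel_config(input_dir = config)
  stopifnot(inherits(config, "panel_config"))
  panel <- read_panel(config)
  n <- nrow(panel$metadata)
  log_lines <- c(sprintf("pipeline start: %d strains, seed %d, n_boot %d",
                         n, config$seed, config$n_boot))

  profiles <- vector("list", n)
  for (i in seq_len(n)) {
    ds <- panel$datasets[[i]]
    profiles[[i]] <- estimate_profile(ds, n_boot = config$n_boot,
                                      seed = config$seed + i)
    flagged <- names(Filter(is_flagged, profiles[[i]]$estimates))
    log_lines <- c(log_lines, sprintf(
      "estimate %s: %s", ds$strain_id,
      if (length(flagged)) paste("WARN poorly resolved:", paste(flagged, collapse = ","))
      else "ok"))
  }
  prof_tab <- profiles_table(profiles)
  prof_long <- do.call(rbind, lapply(profiles, as.data.frame))

  predictions <- do.call(rbind, lapply(seq_len(n), function(i) {
    p <- prof_tab[i, ]
    ok <- !anyNA(c(p$s, p$k, p$mu_l, p$b_r))
    gp <- if (ok) predict_growth_rate(p$s, p$k, p$mu_l, p$b_r,
                                      host_density = config$host_density,
                                      strain_id = p$strain_id)
    data.frame(strain_id = p$strain_id,
               lambda_pred = if (ok) gp$lambda_pred else NA_real_,
               host_density = config$host_density,
               converged = if (ok) gp$converged else FALSE)
  }))

  observed <- do.call(rbind, lapply(seq_len(n), function(i) {
    ds <- panel$datasets[[i]]
    if (is.null(ds$growth))
      return(data.frame(strain_id = ds$strain_id, lambda_obs = NA_real_,
                        ci_low = NA_real_, ci_high = NA_real_,
                        n_points = 0L, converged = FALSE))
    og <- fit_observed_growth(ds$growth, window = config$growth_window,
                              n_boot = max(100L, config$n_boot),
                              seed = config$seed + 10000L + i,
                              strain_id = ds$strain_id)
    data.frame(strain_id = og$strain_id, lambda_obs = og$lambda_obs,
               ci_low = og$ci_low, ci_high = og$ci_high,
               n_points = og$n_points, converged = og$converged)
  }))

  # comparative statistics on point estimates; poorly resolved traits are NA
  positive_traits <- c("k", "mu_l", "sigma_l", "b_d", "b_r", "m", "s", "a", "d", "r", "p")
  fold_ranges <- do.call(rbind, lapply(positive_traits, function(tr) {
    v <- prof_tab[[tr]]
    ok <- !is.na(v) & v > 0
    data.frame(trait = tr,
               fold = if (sum(ok) >= 2L) fold_range(v[ok]) else NA_real_,
               n = sum(ok))
  }))

  varpart <- do.call(rbind, lapply(positive_traits, function(tr) {
    v <- prof_tab[[tr]]
    ok <- !is.na(v)
    if (sum(ok) < 3L || length(unique(panel$metadata$type_host[ok])) < 2L)
      return(NULL)
    host_variance_partition(v[ok], panel$metadata$type_host[ok],
                            n_perm = config$n_perm, seed = config$seed,
                            trait_name = tr)
  }))

  pred_obs <- merge(predictions, observed, by = "strain_id")
  usable <- stats::complete.cases(pred_obs$lambda_pred, pred_obs$lambda_obs)
  growth_cor <- if (sum(usable) >= 5L)
    correlate_predicted_observed(pred_obs$lambda_pred[usable],
                                 pred_obs$lambda_obs[usable])
  else list(rho = NA_real_, p_value = NA_real_, n = sum(usable),
            method = "insufficient_data", flag = "n < 5")
  log_lines <- c(log_lines, sprintf(
    "growth correlation: rho = %.3f (P = %.4f, n = %d)",
    growth_cor$rho, growth_cor$p_value, growth_cor$n))

  sel_df <- merge(prof_tab[c("strain_id", "k", "mu_l", "s", "b_r")], observed,
                  by = "strain_id")
  cc <- stats::complete.cases(sel_df[c("k", "mu_l", "s", "b_r", "lambda_obs")])
  model_sel <- if (sum(cc) >= 7L)
    aic_subset_selection(sel_df$lambda_obs[cc],
                         sel_df[cc, c("k", "mu_l", "s", "b_r")])
  else NULL

  tradeoffs <- tradeoff_tests(prof_tab,
                              species = panel$metadata$species,
                              genome_size_bp = panel$metadata$genome_size_bp,
                              growth = observed,
                              n_perm = config$n_perm, seed = config$seed)

  bundle <- list(profiles = prof_long, profiles_wide = prof_tab,
                 predictions = predictions, observed_growth = observed,
                 fold_ranges = fold_ranges, variance_partition = varpart,
                 growth_correlation = growth_cor, model_selection = model_sel,
                 tradeoffs = tradeoffs, log = log_lines)

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    cfg_path <- file.path(config$out_dir, "config.yaml")
    yaml::write_yaml(unclass(config), cfg_path)
    # the hash identifies the analysis settings, not the file locations
    settings <- unclass(config)
    settings$input_dir <- settings$out_dir <- NULL
    hash_path <- tempfile(fileext = ".yaml")
    yaml::write_yaml(settings, hash_path)
    hash <- unname(tools::md5sum(hash_path))
    unlink(hash_path)
    bundle$config_hash <- hash
    wr <- function(df, name) {
      if (is.null(df)) return()
      df <- as.data.frame(df)
      df$config_hash <- hash
      utils::write.csv(df, file.path(config$out_dir, paste0(name, ".csv")),
                       row.names = FALSE, quote = FALSE)
    }
    wr(prof_long, "profiles")
    wr(predictions, "predictions")
    wr(observed, "observed_growth")
    wr(fold_ranges, "fold_ranges")
    wr(varpart, "variance_partition")
    if (!is.null(model_sel))
      wr(cbind(as.data.frame(model_sel),
               consensus = paste(attr(model_sel, "consensus_predictors"),
                                 collapse = "+")), "model_selection")
    wr(tradeoffs, "tradeoffs")
    writeLines(c(log_lines, sprintf("config_hash: %s", hash)),
               file.path(config$out_dir, "run_log.txt"))
  }
  invisible(bundle)
}
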