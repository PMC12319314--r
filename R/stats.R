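# Comparative analyses across strains: fold-ranges, type-host variance
# partitioning, predicted-vs-observed growth correlation, all-subsets AIC
# model selection, and CI-breadth-weighted trade-off correlations.

#' Fold-range of a trait across strains
#'
#' @param estimates Numeric per-strain trait values; `NA`s (poorly resolved
#'   strains) are dropped.
#' @return `max / min` over the non-missing values (>= 1).
#' @export
fold_range <- function(estimates) {
  x <- estimates[!is.na(estimates)]
  if (length(x) < 2L) stop_msg("fold_range needs >= 2 non-missing values")
  if (any(x <= 0)) stop_msg("fold_range is undefined for non-positive values")
  max(x) / min(x)
}

#' Partition trait variance by type host (or any grouping)
#'
#' The fraction of variance explained by the grouping is
#' `R^2 = SS_between / SS_total` on the trait point estimates. Significance
#' is assessed by a permutation test shuffling group labels:
#' `P = (# permuted R^2 >= observed + 1) / (n_perm + 1)`, appropriate for the
#' small, unbalanced group sizes typical of strain collections.
#'
#' @param values Numeric per-strain trait point estimates (`NA` dropped).
#' @param groups Group labels (type host or species), same length.
#' @param n_perm Number of label permutations.
#' @param seed Integer seed.
#' @param trait_name Optional label carried into the result.
#' @return A `data.frame` row with `trait_name`, `r_squared`, `p_value`,
#'   `groups` (count) and `n`.
#' @export
host_variance_partition <- function(values, groups, n_perm = 9999L, seed = 1L,
                                    trait_name = NA_character_) {
  keep <- !is.na(values) & !is.na(groups)
  values <- values[keep]; groups <- as.character(groups[keep])
  n <- length(values)
  if (n < 3L) stop_msg("variance partition needs >= 3 strains")
  if (length(unique(groups)) < 2L) stop_msg("variance partition needs >= 2 groups")
  r2 <- function(v, g) {
    gm <- mean(v)
    sst <- sum((v - gm)^2)
    if (sst == 0) return(NA_real_)
    means <- tapply(v, g, mean)
    ns <- tapply(v, g, length)
    sum(ns * (means[names(ns)] - gm)^2) / sst
  }
  obs <- r2(values, groups)
  if (is.na(obs))
    return(data.frame(trait_name = trait_name, r_squared = NA_real_,
                      p_value = NA_real_, groups = length(unique(groups)),
                      n = n, flag = "zero_variance"))
  set.seed(seed)
  perm <- vapply(seq_len(n_perm), function(i) r2(values, sample(groups)), numeric(1))
  p <- (sum(perm >= obs) + 1) / (n_perm + 1)
  data.frame(trait_name = trait_name, r_squared = obs, p_value = p,
             groups = length(unique(groups)), n = n, flag = "")
}

#' Spearman correlation of predicted and observed growth rates
#'
#' Rank correlation with average-rank ties. The two-sided P-value comes from
#' exact permutation of the ranks when `n <= 10` and from the asymptotic t
#' approximation otherwise.
#'
#' @param predictions,observations Paired numeric vectors; pairs with any
#'   `NA` are dropped.
#' @return A list with `rho`, `p_value`, `n`, `method`.
#' @export
correlate_predicted_observed <- function(predictions, observations) {
  keep <- stats::complete.cases(predictions, observations)
  x <- predictions[keep]; y <- observations[keep]
  n <- length(x)
  if (n < 5L) stop_msg("correlation needs >= 5 paired non-missing values")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(rho = NA_real_, p_value = NA_real_, n = n, method = "undefined",
                flag = "constant_input"))
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  if (n <= 10L) {
    perms <- all_permutations(n)
    ry_perm <- matrix(ry[perms], nrow(perms), n)
    # correlation is monotone in the permuted cross-product
    cross <- as.numeric(ry_perm %*% rx)
    obs_cross <- sum(rx * ry)
    center <- n * mean(rx) * mean(ry)
    p <- mean(abs(cross - center) >= abs(obs_cross - center) - 1e-9)
    method <- "exact_permutation"
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tstat), n - 2)
    method <- "asymptotic_t"
  }
  list(rho = rho, p_value = p, n = n, method = method, flag = "")
}

#' All-subsets regression with AIC and the delta-AIC consensus set
#'
#' Fits ordinary least squares for every subset of the candidate predictors
#' (including the intercept-only model; 16 subsets for the four growth
#' traits). AIC is computed as `n * log(RSS / n) + 2 * K` with `K` the number
#' of coefficients (intercept included) plus one for the error variance.
#' The consensus set is the intersection of predictor sets over all models
#' within 2 AIC units of the best; predictors that survive every competitive
#' model are the ones with robust support.
#'
#' @param lambda_obs Numeric response (observed growth rates per strain).
#' @param predictors `data.frame` of candidate predictors (columns named,
#'   e.g. `k`, `mu_l`, `s`, `b_r`). Only complete cases are used.
#' @return An object of class `model_selection_table`: a `data.frame` with
#'   one row per subset (`subset`, `n_predictors`, `K`, `rss`, `aic`, `delta_aic`,
#'   `collinear`), plus attributes `consensus_predictors`, `coefficients`
#'   (named list) and `n_strains`.
#' @export
aic_subset_selection <- function(lambda_obs, predictors) {
  predictors <- as.data.frame(predictors)
  keep <- stats::complete.cases(lambda_obs, predictors)
  y <- lambda_obs[keep]
  X <- predictors[keep, , drop = FALSE]
  n <- length(y)
  p_all <- names(X)
  if (n < length(p_all) + 3L)
    stop_msg("need n >= number of parameters of the largest subset + 2 (n = %d)", n)

  subsets <- lapply(0:(2^length(p_all) - 1), function(mask)
    p_all[bitwAnd(mask, 2^(seq_along(p_all) - 1)) > 0])
  rows <- vector("list", length(subsets))
  coefs <- vector("list", length(subsets))
  for (i in seq_along(subsets)) {
    vars <- subsets[[i]]
    M <- cbind(`(Intercept)` = 1, as.matrix(X[vars]))
    qr_M <- qr(M)
    collinear <- qr_M$rank < ncol(M)
    if (collinear) {
      rows[[i]] <- data.frame(subset = paste(vars, collapse = "+"),
                              n_predictors = length(vars), K = NA_real_,
                              rss = NA_real_, aic = NA_real_, collinear = TRUE)
      next
    }
    beta <- qr.coef(qr_M, y)
    rss <- sum((y - M %*% beta)^2)
    K <- ncol(M) + 1  # coefficients incl. intercept, plus the error variance
    aic <- n * log(rss / n) + 2 * K
    coefs[[i]] <- stats::setNames(as.numeric(beta), colnames(M))
    rows[[i]] <- data.frame(
      subset = if (length(vars)) paste(vars, collapse = "+") else "(intercept only)",
      n_predictors = length(vars), K = K, rss = rss, aic = aic,
      collinear = FALSE)
  }
  tab <- do.call(rbind, rows)
  tab$delta_aic <- tab$aic - min(tab$aic, na.rm = TRUE)
  if (any(tab$collinear))
    warning("collinear predictor subset(s) excluded from the consensus", call. = FALSE)
  in_band <- which(!tab$collinear & tab$delta_aic <= 2)
  consensus <- Reduce(intersect, subsets[in_band])
  names(coefs) <- tab$subset
  structure(tab, class = c("model_selection_table", "data.frame"),
            consensus_predictors = consensus,
            coefficients = coefs[!tab$collinear],
            n_strains = n)
}

#' @export
print.model_selection_table <- function(x, ...) {
  ord <- order(x$delta_aic)
  print.data.frame(x[ord, ], row.names = FALSE, digits = 4)
  cons <- attr(x, "consensus_predictors")
  cat(sprintf("\nConsensus (predictors in every model with dAIC <= 2): %s\n",
              if (length(cons)) paste(cons, collapse = ", ") else "(none)"))
  invisible(x)
}

#' Confidence-interval-weighted correlation between two traits
#'
#' Weighted Pearson correlation where each strain's weight shrinks with the
#' breadth of its 95% CIs: `w_i` proportional to
#' `1 / (breadth_x_i * breadth_y_i)` (precision-product rule, default) or
#' `1 / (breadth_x_i + breadth_y_i)`, normalized to sum to 1. The P-value is
#' a weight-preserving permutation test: `y` and its breadth are permuted
#' together against `x`, and the weights recomputed each time.
#'
#' @param x,y Trait point estimates (length >= 5 after `NA` removal).
#' @param breadth_x,breadth_y Positive 95% CI breadths for `x` and `y`.
#' @param weight_rule `"product"` (default) or `"sum"`.
#' @param n_perm Number of permutations for the P-value.
#' @param seed Integer seed.
#' @param trait_x,trait_y,species Optional labels carried into the result.
#' @return A `data.frame` row with `trait_x`, `trait_y`, `species`,
#'   `r_weighted`, `p_value`, `n`.
#' @export
weighted_correlation <- function(x, y, breadth_x, breadth_y,
                                 weight_rule = c("product", "sum"),
                                 n_perm = 9999L, seed = 1L,
                                 trait_x = "x", trait_y = "y",
                                 species = NA_character_) {
  weight_rule <- match.arg(weight_rule)
  keep <- stats::complete.cases(x, y, breadth_x, breadth_y)
  x <- x[keep]; y <- y[keep]
  breadth_x <- breadth_x[keep]; breadth_y <- breadth_y[keep]
  n <- length(x)
  if (n < 5L)
    stop_msg("correlations are only tested where n >= 5 (got n = %d)", n)
  if (any(breadth_x <= 0) || any(breadth_y <= 0))
    stop_msg("CI breadths must be strictly positive")

  wcor <- function(x, y, bx, by) {
    w <- if (weight_rule == "product") 1 / (bx * by) else 1 / (bx + by)
    w <- w / sum(w)
    mx <- sum(w * x); my <- sum(w * y)
    cxy <- sum(w * (x - mx) * (y - my))
    vx <- sum(w * (x - mx)^2); vy <- sum(w * (y - my)^2)
    if (vx == 0 || vy == 0) return(NA_real_)
    cxy / sqrt(vx * vy)
  }
  r_obs <- wcor(x, y, breadth_x, breadth_y)
  set.seed(seed)
  perm <- vapply(seq_len(n_perm), function(i) {
    idx <- sample.int(n)
    wcor(x, y[idx], breadth_x, breadth_y[idx])
  }, numeric(1))
  p <- (sum(abs(perm) >= abs(r_obs) - 1e-12, na.rm = TRUE) + 1) / (n_perm + 1)
  data.frame(trait_x = trait_x, trait_y = trait_y, species = species,
             r_weighted = r_obs, p_value = p, n = n)
}

#' Within-species trade-off tests
#'
#' Tests the three trade-offs hypothesized to constrain lytic viruses —
#' growth rate versus mortality rate, burst size versus lysis time, and
#' burst size versus genome size — as CI-weighted correlations, within each
#' species with at least 5 strains carrying both traits. Rates and sizes are
#' log-transformed by default (growth rates, which may be negative, are not).
#' Species below the n >= 5 gate are reported as not tested.
#'
#' @param profiles Wide profile table from [profiles_table()] (poorly
#'   resolved traits already `NA`).
#' @param species Per-strain species labels, aligned with `profiles` rows.
#' @param genome_size_bp Per-strain genome sizes, base pairs (`NA` allowed;
#'   the genome-size test is skipped where missing).
#' @param growth Optional `data.frame` with columns `strain_id`,
#'   `lambda_obs`, `ci_low`, `ci_high` (from [fit_observed_growth()]) for the
#'   growth-mortality test.
#' @param log_sizes Log-transform rates and sizes before correlating.
#' @param n_perm,seed Passed to [weighted_correlation()].
#' @return A `data.frame` with one row per species x trade-off, columns as
#'   [weighted_correlation()] plus `tested` and `note`.
#' @export
tradeoff_tests <- function(profiles, species, genome_size_bp = NULL,
                           growth = NULL, log_sizes = TRUE,
                           n_perm = 9999L, seed = 1L) {
  stopifnot(nrow(profiles) == length(species))
  logt <- function(v, lo, hi) {
    if (!log_sizes) return(list(v = v, b = hi - lo))
    ok <- !is.na(v) & v > 0 & !is.na(lo) & lo > 0
    list(v = ifelse(ok, log(v), NA_real_),
         b = ifelse(ok, log(hi) - log(lo), NA_real_))
  }
  pull <- function(nm) logt(profiles[[nm]], profiles[[paste0(nm, "_lo")]],
                            profiles[[paste0(nm, "_hi")]])
  tests <- list()
  if (!is.null(growth)) {
    g <- growth[match(profiles$strain_id, growth$strain_id), ]
    m <- pull("m")
    tests$growth_vs_mortality <- list(
      x = g$lambda_obs, bx = pmax(g$ci_high - g$ci_low, 1e-12),
      y = m$v, by = m$b, tx = "lambda_obs", ty = "m")
  }
  bd <- pull("b_d"); mu <- pull("mu_l")
  tests$burst_vs_lysis_time <- list(x = bd$v, bx = bd$b, y = mu$v, by = mu$b,
                                    tx = "b_d", ty = "mu_l")
  if (!is.null(genome_size_bp)) {
    gs <- if (log_sizes) log(genome_size_bp) else genome_size_bp
    tests$burst_vs_genome_size <- list(
      x = bd$v, bx = bd$b, y = gs, by = rep(1, length(gs)),
      tx = "b_d", ty = "genome_size")
  }

  out <- list()
  for (nm in names(tests)) {
    te <- tests[[nm]]
    for (sp in sort(unique(species))) {
      sel <- species == sp
      ok <- sel & stats::complete.cases(te$x, te$y, te$bx, te$by)
      if (sum(ok) >= 5L) {
        row <- weighted_correlation(te$x[ok], te$y[ok], te$bx[ok], te$by[ok],
                                    n_perm = n_perm, seed = seed,
                                    trait_x = te$tx, trait_y = te$ty,
                                    species = sp)
        row$tested <- TRUE; row$note <- ""
      } else {
        row <- data.frame(trait_x = te$tx, trait_y = te$ty, species = sp,
                          r_weighted = NA_real_, p_value = NA_real_,
                          n = sum(ok), tested = FALSE,
                          note = "n < 5: not tested")
      }
      row$tradeoff <- nm
      out[[length(out) + 1L]] <- row
    }
  }
  do.call(rbind, out)
}
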