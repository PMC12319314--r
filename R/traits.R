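#' Default ground-truth trait ranges for synthetic panels
#'
#' Per-trait low/high bounds used by [draw_true_traits()]. The spreads emulate
#' the variation reported across chlorovirus strains: burst size per release
#' spans 77-fold, the adsorption constant 20-fold, and the probability traits
#' cover most of the unit interval, while lysis time and mortality are
#' comparatively restricted.
#'
#' @return Named list of `c(low, high)` numeric pairs for traits
#'   `a`, `k`, `d`, `r`, `mu_l`, `sigma_l`, `b_r`, `m`, `p`.
#' @export
default_trait_ranges <- function() {
  list(
    a       = c(0.5, 0.95),    # attaching fraction of virions
    k       = c(5e-8, 1e-6),   # adsorption constant, mL h^-1
    d       = c(0.2, 0.9),     # depolarization probability
    r       = c(0.3, 0.95),    # release probability
    mu_l    = c(5, 12),        # mean lysis time, h
    sigma_l = c(0.6, 2),       # SD of lysis time, h
    b_r     = c(10, 770),      # burst size per releasing cell
    m       = c(0.01, 0.08),   # mortality rate, h^-1
    p       = c(0.01, 0.1)     # persistent fraction
  )
}

# Traits drawn on the log scale (rates, sizes); the rest are uniform.
LOG_DRAWN_TRAITS <- c("k", "b_r", "m")

validate_trait_ranges <- function(trait_ranges) {
  need <- names(default_trait_ranges())
  missing <- setdiff(need, names(trait_ranges))
  if (length(missing))
    stop_msg("trait_ranges is missing bounds for: %s", paste(missing, collapse = ", "))
  for (nm in need) {
    b <- trait_ranges[[nm]]
    if (!is.numeric(b) || length(b) != 2L || anyNA(b))
      stop_msg("trait_ranges$%s must be a numeric c(low, high) pair", nm)
    if (b[1] > b[2])
      stop_msg("trait_ranges$%s has low > high (%g > %g)", nm, b[1], b[2])
    if (nm %in% PROB_TRAITS && (b[1] < 0 || b[2] > 1))
      stop_msg("trait_ranges$%s is a probability: bounds must lie in [0, 1], got [%g, %g]",
               nm, b[1], b[2])
    if (nm %in% c("k", "b_r", "m", "sigma_l") && b[1] < 0)
      stop_msg("trait_ranges$%s must be non-negative", nm)
    if (nm == "mu_l" && b[1] <= 0)
      stop_msg("trait_ranges$mu_l must be strictly positive")
    if (nm %in% LOG_DRAWN_TRAITS && b[1] <= 0 && b[1] < b[2])
      stop_msg("trait_ranges$%s is drawn log-uniformly and needs a positive lower bound", nm)
  }
  trait_ranges[need]
}

#' Draw ground-truth life-history traits for a panel of virus strains
#'
#' Rates and burst sizes (`k`, `b_r`, `m`) are drawn log-uniformly within
#' their bounds; probabilities and times uniformly. The derived traits are
#' filled in: burst size per depolarized cell `b_d = r * b_r` and specific
#' infectivity `s = a * d * r`.
#'
#' @param n_strains Number of strains to draw (>= 1).
#' @param trait_ranges Named list of `c(low, high)` bounds, as
#'   [default_trait_ranges()]. Degenerate bounds (`low == high`) pin a trait.
#' @param seed Integer seed; draws are reproducible for a fixed seed.
#' @return A `data.frame` with one row per strain and columns `strain_id`,
#'   the nine generating traits, and derived `b_d` and `s`.
#' @examples
#' draw_true_traits(3, seed = 1)
#' @export
draw_true_traits <- function(n_strains, trait_ranges = default_trait_ranges(),
                             seed = 1L) {
  if (!is.numeric(n_strains) || length(n_strains) != 1L || n_strains < 1)
    stop_msg("n_strains must be a single integer >= 1")
  n_strains <- as.integer(n_strains)
  trait_ranges <- validate_trait_ranges(trait_ranges)
  set.seed(seed)
  draw1 <- function(nm) {
    b <- trait_ranges[[nm]]
    if (b[1] == b[2]) return(rep(b[1], n_strains))
    if (nm %in% LOG_DRAWN_TRAITS) exp(stats::runif(n_strains, log(b[1]), log(b[2])))
    else stats::runif(n_strains, b[1], b[2])
  }
  out <- data.frame(strain_id = sprintf("strain_%02d", seq_len(n_strains)))
  for (nm in names(trait_ranges)) out[[nm]] <- draw1(nm)
  out$b_d <- out$r * out$b_r
  out$s <- out$a * out$d * out$r
  class(out) <- c("true_traits", "data.frame")
  out
}

validate_true_traits <- function(traits) {
  stopifnot(is.data.frame(traits))
  need <- c("strain_id", names(default_trait_ranges()))
  missing <- setdiff(need, names(traits))
  if (length(missing))
    stop_msg("true traits table is missing: %s", paste(missing, collapse = ", "))
  for (nm in PROB_TRAITS[PROB_TRAITS %in% names(traits)])
    if (any(traits[[nm]] < 0 | traits[[nm]] > 1))
      stop_msg("trait %s has values outside [0, 1]", nm)
  if (any(traits$k < 0) || any(traits$m < 0) || any(traits$b_r < 0))
    stop_msg("k, m and b_r must be non-negative")
  if (any(traits$mu_l <= 0)) stop_msg("mu_l must be strictly positive")
  if (any(traits$sigma_l < 0)) stop_msg("sigma_l must be non-negative")
  if (is.null(traits$b_d)) traits$b_d <- traits$r * traits$b_r
  if (is.null(traits$s)) traits$s <- traits$a * traits$d * traits$r
  traits
}
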