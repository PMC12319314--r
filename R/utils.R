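#' @keywords internal
"_PACKAGE"

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Construct a single trait estimate record
#'
#' A trait estimate carries a point estimate, a percentile 95% confidence
#' interval, the number of bootstrap replicates behind that interval, and
#' fit diagnostics (convergence flag, residual scale, and any quality flags
#' such as `"poorly_resolved"` or `"truncated"`).
#'
#' @param trait_name One of `"a"`, `"k"`, `"d"`, `"r"`, `"mu_l"`, `"sigma_l"`,
#'   `"b_d"`, `"b_r"`, `"s"`, `"m"`, `"p"`.
#' @param estimate Point estimate, in the trait's units.
#' @param ci_low,ci_high 95% confidence bounds. Default to the estimate
#'   (degenerate interval) until a bootstrap attaches real ones.
#' @param n_boot Number of bootstrap replicates behind the interval.
#' @param converged Logical convergence flag from the underlying fit.
#' @param resid_scale Residual standard deviation of the fit, `NA` for
#'   closed-form estimators.
#' @param flags Character vector of quality flags (empty when clean).
#' @return An object of class `trait_estimate`.
#' @export
trait_estimate <- function(trait_name, estimate, ci_low = estimate,
                           ci_high = estimate, n_boot = 0L,
                           converged = TRUE, resid_scale = NA_real_,
                           flags = character()) {
  stopifnot(is.character(trait_name), length(trait_name) == 1L)
  out <- list(
    trait_name = trait_name,
    estimate = estimate,
    ci_low = ci_low,
    ci_high = ci_high,
    n_boot = as.integer(n_boot),
    diagnostics = list(converged = isTRUE(converged),
                       resid_scale = resid_scale,
                       flags = as.character(flags))
  )
  class(out) <- "trait_estimate"
  out
}

#' @export
print.trait_estimate <- function(x, ...) {
  fl <- if (length(x$diagnostics$flags)) paste(" [", paste(x$diagnostics$flags, collapse = ", "), "]") else ""
  cat(sprintf("%s = %.4g  (95%% CI %.4g-%.4g, n_boot = %d)%s\n",
              x$trait_name, x$estimate, x$ci_low, x$ci_high, x$n_boot, fl))
  invisible(x)
}

is_flagged <- function(est, flag = "poorly_resolved") {
  inherits(est, "trait_estimate") && flag %in% est$diagnostics$flags
}

add_flag <- function(est, flag) {
  est$diagnostics$flags <- union(est$diagnostics$flags, flag)
  est
}

# Probability-valued traits are clamped to [0,1]; rates and sizes to >= 0.
PROB_TRAITS <- c("a", "d", "r", "s", "p")
POSITIVE_TRAITS <- c("k", "mu_l", "sigma_l", "b_d", "b_r", "m")

clamp_trait <- function(trait_name, value) {
  if (trait_name %in% PROB_TRAITS) return(pmin(1, pmax(0, value)))
  if (trait_name %in% POSITIVE_TRAITS) return(pmax(0, value))
  value
}

stop_msg <- function(...) stop(sprintf(...), call. = FALSE)

check_columns <- function(df, expected, table_name) {
  got <- names(df)
  unknown <- setdiff(got, expected)
  missing <- setdiff(expected, got)
  if (length(unknown) || length(missing)) {
    parts <- character()
    if (length(missing)) parts <- c(parts, sprintf("missing column(s): %s", paste(missing, collapse = ", ")))
    if (length(unknown)) parts <- c(parts, sprintf("unknown column(s): %s", paste(unknown, collapse = ", ")))
    stop_msg("table '%s' does not match its documented schema (%s)",
             table_name, paste(parts, collapse = "; "))
  }
  df[expected]
}

# All permutations of 1..n as an integer matrix (n! rows); n <= 10 guard lives
# at the call site. Used by the exact Spearman permutation test.
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  r <- 0L
  for (i in seq_len(n)) {
    rest <- seq_len(n)[-i]
    idx <- r + seq_len(nrow(sub))
    out[idx, 1L] <- i
    out[idx, -1L] <- matrix(rest[sub], nrow(sub), n - 1L)
    r <- r + nrow(sub)
  }
  out
}
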