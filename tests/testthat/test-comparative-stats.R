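test_that("fold ranges are max/min over resolved positive estimates", {
  expect_equal(fold_range(c(2, 10)), 5)
  expect_equal(fold_range(c(1, 77)), 77)
  expect_equal(fold_range(c(3, 3, 3)), 1)
  expect_equal(fold_range(c(2, NA, 10)), 5)
  expect_error(fold_range(c(0, 3)), "non-positive")
  expect_error(fold_range(c(3, NA)), ">= 2")
})

test_that("variance partitioning matches hand-computed sums of squares", {
  # no within-group variance: everything explained
  vp1 <- host_variance_partition(c(1, 1, 3, 3), c("A", "A", "B", "B"),
                                 n_perm = 99, seed = 1)
  expect_equal(vp1$r_squared, 1)
  # grand mean 2.5, SS_total 5, SS_between 1
  vp2 <- host_variance_partition(c(1, 3, 2, 4), c("A", "A", "B", "B"),
                                 n_perm = 99, seed = 1)
  expect_equal(vp2$r_squared, 0.2)
  expect_error(host_variance_partition(c(1, 2, 3), c("A", "A", "A"), 99, 1),
               ">= 2 groups")
  # permutation p is seeded and in (0, 1]
  a <- host_variance_partition(rnorm(12), rep(c("A", "B", "C"), 4), 199, 7)
  b <- host_variance_partition(a$r_squared * 0 + rnorm(12), rep(c("A", "B", "C"), 4), 199, 7)
  expect_gt(a$p_value, 0); expect_lte(a$p_value, 1)
  set.seed(50)
  v <- rnorm(10); g <- rep(c("A", "B"), 5)
  p1 <- host_variance_partition(v, g, 499, 3)
  p2 <- host_variance_partition(v, g, 499, 3)
  expect_identical(p1$p_value, p2$p_value)
  # R^2 is invariant to affine transformation of the trait values
  p3 <- host_variance_partition(3 * v - 7, g, 499, 3)
  expect_equal(p1$r_squared, p3$r_squared)
  expect_identical(p1$p_value, p3$p_value)
})

test_that("Spearman correlation handles monotone, reversed and tied inputs", {
  expect_equal(correlate_predicted_observed(1:6, c(2, 5, 7, 8, 20, 21))$rho, 1)
  expect_equal(correlate_predicted_observed(1:6, -(1:6))$rho, -1)
  # rank arithmetic: d^2 = {1,1,1,1,0} -> rho = 1 - 24/120 = 0.8
  res <- correlate_predicted_observed(c(1, 2, 3, 4, 5), c(2, 1, 4, 3, 5))
  expect_equal(res$rho, 0.8)
  expect_equal(res$method, "exact_permutation")
  # exact permutation p agrees with brute force over all 5! orderings
  rho_of <- function(y) cor(rank(c(1, 2, 3, 4, 5)), rank(y))
  perms <- virotraits:::all_permutations(5)
  y <- c(2, 1, 4, 3, 5)
  all_rho <- apply(perms, 1, function(ix) rho_of(y[ix]))
  expect_equal(res$p_value, mean(abs(all_rho) >= 0.8 - 1e-9))
  # asymptotic branch matches cor.test's t approximation
  set.seed(9)
  x <- rnorm(20); y2 <- x + rnorm(20)
  res2 <- correlate_predicted_observed(x, y2)
  ct <- suppressWarnings(cor.test(x, y2, method = "spearman"))
  expect_equal(res2$rho, unname(ct$estimate))
  expect_equal(res2$method, "asymptotic_t")
  # degenerate input is flagged, not a crash
  cst <- correlate_predicted_observed(rep(1, 6), rnorm(6))
  expect_true(is.na(cst$rho))
})

test_that("all-subsets AIC selection matches a brute-force lm oracle", {
  set.seed(4)
  for (i in 1:5) {
    n <- 6 + i
    X <- data.frame(k = rnorm(n), mu_l = rnorm(n), s = rnorm(n), b_r = rnorm(n))
    y <- rnorm(n)
    got <- aic_subset_selection(y, X)
    want <- aic_oracle(y, X)
    expect_equal(nrow(got), 16)
    ord <- match(want$subset, got$subset)
    expect_equal(got$aic[ord], want$aic, tolerance = 1e-8)
    expect_equal(got$delta_aic[ord], want$delta_aic, tolerance = 1e-8)
    expect_setequal(attr(got, "consensus_predictors"), want$consensus[[1]])
  }
})

test_that("AIC consensus isolates a dominant predictor and collapses under noise", {
  set.seed(2)
  n <- 21
  X <- data.frame(k = rnorm(n), mu_l = rnorm(n), s = rnorm(n), b_r = rnorm(n))
  y <- 3 * X$s + rnorm(n, 0, 0.01 * sd(3 * X$s))
  expect_identical(attr(aic_subset_selection(y, X), "consensus_predictors"), "s")

  # pure noise: no predictor survives every competitive model; the consensus
  # is empty for most draws and never substantial
  sizes <- vapply(1:30, function(sd_i) {
    set.seed(100 + sd_i)
    Xn <- data.frame(k = rnorm(n), mu_l = rnorm(n), s = rnorm(n), b_r = rnorm(n))
    length(attr(aic_subset_selection(rnorm(n), Xn), "consensus_predictors"))
  }, integer(1))
  expect_gte(sum(sizes == 0), 15)
  expect_lte(max(sizes), 2)

  # exactly collinear subsets are flagged and excluded with a warning
  Xc <- X; Xc$b_r <- 2 * Xc$s
  expect_warning(selc <- aic_subset_selection(y, Xc), "collinear")
  expect_identical(sum(selc$collinear), 4L)  # every subset holding both s and b_r
  expect_true(all(is.na(selc$aic[selc$collinear])))
})

test_that("weighted correlation reduces, freezes and rescales correctly", {
  x <- c(1, 2, 3, 4, 5); y <- c(2, 2, 3, 5, 4)
  # equal breadths reduce to the unweighted Pearson correlation
  wc <- weighted_correlation(x, y, rep(2, 5), rep(2, 5), n_perm = 99, seed = 1)
  expect_equal(wc$r_weighted, cor(x, y), tolerance = 1e-12)
  # frozen hand-computed weighted-moment value for weights prop {1,1,1,1,4}
  # (breadth products {4,4,4,4,1} under the precision-product rule)
  wc2 <- weighted_correlation(x, y, c(2, 2, 2, 2, 1), c(2, 2, 2, 2, 1),
                              n_perm = 99, seed = 1)
  expect_equal(wc2$r_weighted, 0.845154254729, tolerance = 1e-9)
  # perfect linearity is 1 under any weights
  wc3 <- weighted_correlation(x, 2 * x + 1, c(1, 2, 3, 1, 2), c(2, 1, 1, 3, 1),
                              n_perm = 99, seed = 1)
  expect_equal(wc3$r_weighted, 1, tolerance = 1e-12)
  # invariant to rescaling all breadths by a positive constant
  wc4 <- weighted_correlation(x, y, 10 * c(2, 2, 2, 2, 1), 10 * c(2, 2, 2, 2, 1),
                              n_perm = 99, seed = 1)
  expect_equal(wc4$r_weighted, wc2$r_weighted, tolerance = 1e-12)
  expect_identical(wc4$p_value, wc2$p_value)
  # gates and guards
  expect_error(weighted_correlation(x[1:4], y[1:4], rep(1, 4), rep(1, 4)),
               "n >= 5")
  expect_error(weighted_correlation(x, y, c(0, 1, 1, 1, 1), rep(1, 5)),
               "positive")
})

test_that("trade-off tests run within qualifying species only", {
  set.seed(22)
  n <- 17
  species <- c(rep("sp1", 12), rep("sp2", 4), "sp3")
  mu_l <- runif(n, 5, 12)
  # engineered negative burst-lysis relationship inside sp1
  b_d <- exp(8 - 0.5 * mu_l + rnorm(n, 0, 0.1))
  prof <- data.frame(strain_id = sprintf("s%02d", 1:n),
                     b_d = b_d, b_d_lo = b_d * 0.9, b_d_hi = b_d * 1.1,
                     mu_l = mu_l, mu_l_lo = mu_l * 0.95, mu_l_hi = mu_l * 1.05,
                     m = runif(n, 0.01, 0.08))
  prof$m_lo <- prof$m * 0.9; prof$m_hi <- prof$m * 1.1
  res <- tradeoff_tests(prof, species, genome_size_bp = runif(n, 3e5, 3.6e5),
                        n_perm = 499, seed = 2)
  bl <- res[res$tradeoff == "burst_vs_lysis_time" & res$species == "sp1", ]
  expect_true(bl$tested)
  expect_lt(bl$r_weighted, -0.5)
  expect_lt(bl$p_value, 0.05)
  # species below the n >= 5 gate are reported but not tested
  small <- res[res$species %in% c("sp2", "sp3"), ]
  expect_true(all(!small$tested))
  expect_true(all(is.na(small$r_weighted)))
})
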