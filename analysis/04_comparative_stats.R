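#!/usr/bin/env Rscript
# Comparative analyses over the estimated panel: trait fold-ranges, type-host
# variance partitioning, AIC all-subsets selection of growth predictors, and
# CI-weighted within-species trade-off correlations.

library(virotraits)

panel <- read_panel("results/panel")
wide <- read.csv("results/profiles_wide.csv")
growth <- read.csv("results/growth_rates.csv")

traits <- c("k", "d", "r", "mu_l", "sigma_l", "b_d", "b_r", "s", "m", "p")
folds <- do.call(rbind, lapply(traits, function(tr) {
  v <- wide[[tr]]; v <- v[!is.na(v) & v > 0]
  data.frame(trait = tr, fold = if (length(v) >= 2) fold_range(v) else NA,
             n = length(v))
}))
write.csv(folds, "results/fold_ranges.csv", row.names = FALSE)
cat("Trait fold-ranges across the panel:\n"); print(folds, digits = 3)

vp <- do.call(rbind, lapply(traits, function(tr) {
  v <- wide[[tr]]
  ok <- !is.na(v)
  if (sum(ok) < 3) return(NULL)
  host_variance_partition(v[ok], panel$metadata$type_host[ok],
                          n_perm = 9999, seed = 1, trait_name = tr)
}))
write.csv(vp, "results/variance_partition.csv", row.names = FALSE)
cat("\nType-host variance partitioning (synthetic traits are drawn\n")
cat("independently of host, so R^2 here is the null expectation):\n")
print(vp, digits = 3)

sel_dat <- merge(wide[c("strain_id", "k", "mu_l", "s", "b_r")], growth,
                 by = "strain_id")
cc <- complete.cases(sel_dat[c("k", "mu_l", "s", "b_r", "lambda_obs")])
sel <- aic_subset_selection(sel_dat$lambda_obs[cc],
                            sel_dat[cc, c("k", "mu_l", "s", "b_r")])
write.csv(cbind(as.data.frame(sel),
                consensus = paste(attr(sel, "consensus_predictors"),
                                  collapse = "+")),
          "results/model_selection.csv", row.names = FALSE)
cat("\nAIC all-subsets selection for observed growth:\n")
print(sel)

to <- tradeoff_tests(wide, species = panel$metadata$species,
                     genome_size_bp = panel$metadata$genome_size_bp,
                     growth = growth, n_perm = 9999, seed = 1)
write.csv(to, "results/tradeoffs.csv", row.names = FALSE)
cat("\nWithin-species trade-off tests (n >= 5 gate):\n")
print(to[c("tradeoff", "species", "n", "tested", "r_weighted", "p_value")],
      digits = 3)
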