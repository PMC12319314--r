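#!/usr/bin/env Rscript
# Predict each strain's growth rate from its estimated traits via the lytic
# Euler-Lotka equation, fit the observed growth rates from the growth assays,
# and correlate the two.

library(virotraits)

panel <- read_panel("results/panel")
wide <- read.csv("results/profiles_wide.csv")
n <- nrow(wide)

pred <- do.call(rbind, lapply(seq_len(n), function(i) {
  w <- wide[i, ]
  ok <- !anyNA(c(w$s, w$k, w$mu_l, w$b_r))
  gp <- if (ok) predict_growth_rate(w$s, w$k, w$mu_l, w$b_r, host_density = 1e7,
                                    strain_id = w$strain_id)
  data.frame(strain_id = w$strain_id,
             lambda_pred = if (ok) gp$lambda_pred else NA_real_)
}))

obs <- do.call(rbind, lapply(seq_len(n), function(i) {
  og <- fit_observed_growth(panel$datasets[[i]]$growth, n_boot = 200,
                            seed = 500 + i, strain_id = wide$strain_id[i])
  data.frame(strain_id = og$strain_id, lambda_obs = og$lambda_obs,
             ci_low = og$ci_low, ci_high = og$ci_high)
}))

growth <- merge(pred, obs, by = "strain_id")
write.csv(growth, "results/growth_rates.csv", row.names = FALSE)

keep <- complete.cases(growth$lambda_pred, growth$lambda_obs)
res <- correlate_predicted_observed(growth$lambda_pred[keep],
                                    growth$lambda_obs[keep])
cat(sprintf("Predicted vs observed growth: Spearman rho = %.3f (P = %.3g, n = %d)\n",
            res$rho, res$p_value, res$n))
cat("Growth rates written to results/growth_rates.csv\n")
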