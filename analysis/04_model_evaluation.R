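#!/usr/bin/env Rscript
# Stage 4: internal validation of the fitted model.
#
# Goodness of fit (PRED/IPRED/CWRES), nonparametric bootstrap of subjects
# (200 replicates here; the method's convention is 1000), prediction-
# corrected VPC and NPDE, each on 1000 simulated replicates.

library(remipopk)

master_seed <- 20260926
fit <- readRDS("results/fit.rds")
ds <- fit$data

gof <- cwres(fit)
write.csv(gof, "results/gof_cwres.csv", row.names = FALSE)
cat(sprintf("CWRES: %.1f%% within +/-2 (mean %.3f)\n",
            100 * mean(abs(gof$CWRES) <= 2), mean(gof$CWRES)))

bs <- bootstrap(ds, fit$spec, n_reps = 200, seed = master_seed + 4,
                init = list(theta = fit$theta, omega = fit$omega,
                            sigma_prop = fit$sigma_prop))
write.csv(bs$summary, "results/bootstrap_summary.csv", row.names = FALSE)
cat(sprintf("bootstrap: %d/%d converged; CL median %.1f (95%% CI %.1f-%.1f)\n",
            bs$n_converged, bs$n_reps,
            bs$summary$median[bs$summary$parameter == "CL"],
            bs$summary$lo[bs$summary$parameter == "CL"],
            bs$summary$hi[bs$summary$parameter == "CL"]))

v <- pcvpc(fit, n_sim = 1000, seed = master_seed + 5)
write.csv(v$bins, "results/pcvpc_bins.csv", row.names = FALSE)
cat(sprintf("pcVPC: %.1f%% of observations inside the 90%% prediction interval\n",
            100 * v$coverage90))

nd <- npde(fit, n_sim = 1000, seed = master_seed + 6)
npde_tab <- data.frame(
  statistic = c("mean", "variance", "p_wilcoxon", "p_variance", "p_shapiro",
                "p_global"),
  value = c(nd$mean, nd$variance, nd$p_wilcoxon, nd$p_variance, nd$p_shapiro,
            nd$p_global)
)
write.csv(npde_tab, "results/npde_summary.csv", row.names = FALSE)
cat(sprintf("NPDE: mean %.3f, variance %.3f, global p %.3f\n",
            nd$mean, nd$variance, nd$p_global))
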