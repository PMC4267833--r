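#!/usr/bin/env Rscript

# Stage 4: derived quantities from the selected model: carrying capacity
# over the last six survey years, a counterfactual K at 45,000 sheep, the
# fitted latent trajectory with 95% credible bands, and posterior
# growth-rate curves along temperature and sheep numbers. Runs the
# end-to-end orchestration (which refits the candidates) so this stage is
# reproducible on its own from the dataset CSV. Run 01 first.

library(guanacoSSM)

report <- run_analysis(analysis_config(
  "results/synthetic_study.csv",
  models = c("DD + Temp + Sheep", "DD", "Null"),
  mcmc = mcmc_config(n_chains = 3, n_iter = 30000, burn_in = 6000,
                     thin = 20, seed = 4L),
  M = 10000,
  sheep_counterfactual = 45000
))
write_outputs(report, "results/report")

print(report)
cat("\nFitted trajectory (first and last years):\n")
print(head(report$trajectory, 3), digits = 5)
print(tail(report$trajectory, 3), digits = 5)

truth <- read.csv("results/synthetic_study_truth.csv")
inside <- with(report$trajectory, truth$latent >= n_q2.5 & truth$latent <= n_q97.5)
cat(sprintf("\n95%% latent band covers the true trajectory in %d/%d years\n",
            sum(inside), length(inside)))

cur <- growth_rate_curve(report$best_fit, "Sheep",
                         grid = seq(0.5, 1, length.out = 6))
cat("\nGrowth rate at K versus (rescaled) sheep numbers:\n")
print(cur, digits = 4)
cat("lambda declines as sheep increase: the sheep effect depresses the\n")
cat("equilibrium growth rate, which is what drives the counterfactual K down.\n")
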