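#!/usr/bin/env Rscript
# Step 4: does the pipeline recover known injected biases?
#
# Two experiments on synthetic data with ground truth:
#  (a) a constant -100 gC m-2 y-1 biometric NEP offset, recovered by the
#      paired comparison across 100 replicate datasets;
#  (b) a soil-chamber bias (25% Rsoil underestimate at NSNF sites),
#      detected by the weighted chamber-type screen of the Reco relative
#      difference.

suppressPackageStartupMessages(library(fluxconverge))

dir.create("results", showWarnings = FALSE)

cat("(a) recovery of a -100 gC m-2 y-1 biometric NEP offset\n")
cfg_a <- sim_config(nep_bm_offset = -100, cv_ec = 0.05, cv_bm = 0.05,
                    rleaf_overestimate_no_li = 0,
                    nsnf_rsoil_underestimate = 0, seed = 2001)
rec <- recovery_report(cfg_a, n_replicates = 100)
readr::write_csv(rec, "results/recovery.csv", na = "")
nep <- rec[rec$statistic == "nep_diff_ec_minus_bm", ]
cat(sprintf("    injected %.0f, mean estimate %.1f (bias %.1f, sd %.1f)\n",
            nep$injected, nep$mean_estimate, nep$bias, nep$sd_estimate))
cat(sprintf("    95%% CI coverage across replicates: %.2f\n", nep$coverage))

cat("(b) detection of an NSNF soil-chamber bias\n")
cfg_b <- sim_config(nsnf_rsoil_underestimate = 0.25, cv_ec = 0.03,
                    cv_bm = 0.03, rleaf_overestimate_no_li = 0,
                    seed = 2002)
d <- generate_dataset(cfg_b)
rep <- run_convergence_analysis(d$sites)
row <- rep$table3[rep$table3$flux_kind == "Reco" &
                    rep$table3$variable == "soil_chamber", ]
cat(sprintf("    chamber-type screen: P = %.3g%s, R2 = %.2f (n = %d)\n",
            row$p_value, row$mark, row$r_squared, row$n))
cat("wrote results/recovery.csv\n")
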