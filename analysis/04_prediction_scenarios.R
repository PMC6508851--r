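#!/usr/bin/env Rscript

## Step 4 — the four genomic-prediction scenarios.
##
## A: whole-trajectory prediction for unphenotyped lines, RR vs per-day TP.
## B: forecasting days 11-20 for the same lines from their days 1-10.
## C: forecasting days 11-20 for new lines from training lines' days 1-10.
## D: forecasting new lines in an independent later-window study sharing
##    the same panel (days 8-28, one experiment).
## Two-fold cross-validation with per-experiment Pearson accuracies,
## averaged over experiments and folds; 5 resampling rounds here.

library(rrgrowth)

rec <- read_phenotypes("results/data/phenotypes.tsv")
grm <- vanraden_grm(read_dosage_matrix("results/data/dosages.tsv"))
n_res <- 5L

a_rr <- run_scenario("A", rec, grm, n_resamples = n_res, base_seed = 1)
a_tp <- run_scenario("A", rec, grm, model = "TP", n_resamples = n_res,
                     base_seed = 1)
b <- run_scenario("B", rec, grm, n_resamples = n_res, base_seed = 1)
cc <- run_scenario("C", rec, grm, n_resamples = n_res, base_seed = 1)

two <- simulate_two_studies(sim_config(seed = 14))
d <- run_scenario("D", two$study1$records, two$study1$grm,
                  records2 = two$records2, n_resamples = n_res,
                  base_seed = 1)

cat("scenario A  RR:", round(mean(a_rr$mean_accuracy), 3),
    " TP:", round(mean(a_tp$mean_accuracy), 3),
    " gain:", round(100 * (mean(a_rr$mean_accuracy) /
                             mean(a_tp$mean_accuracy) - 1), 1), "%\n")
cat("scenario B :", round(mean(b$mean_accuracy), 3),
    " range:", round(range(b$mean_accuracy), 3), "\n")
cat("scenario C :", round(mean(cc$mean_accuracy), 3),
    " range:", round(range(cc$mean_accuracy), 3), "\n")
cat("scenario D :", round(mean(d$mean_accuracy), 3),
    " range:", round(range(d$mean_accuracy), 3), "\n")

## relative accuracy r / sqrt(h2): RR's edge in r largely mirrors its edge
## in h2
herit <- read.delim("results/heritability.tsv")
cat("mean relative accuracy  RR:",
    round(mean(relative_accuracy(a_rr$mean_accuracy, herit$h2_rr)), 3),
    " TP:",
    round(mean(relative_accuracy(a_tp$mean_accuracy, herit$h2_tp)), 3),
    "\n")

for (x in list(a_rr, a_tp, b, cc, d)) {
  write.table(summary(x),
              sprintf("results/scenario_%s_%s.tsv", x$scenario, x$model),
              sep = "\t", row.names = FALSE, quote = FALSE)
}
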