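#!/usr/bin/env Rscript
# Figures from the replicated experiment (run 03_experiment.R first):
# imputation accuracy by strategy, gEBV accuracy by strategy, and the
# accuracy-vs-cost trade-off. Written as PDFs under results/figures/.

library(ggplot2)

outcomes <- read.csv("results/outcomes.csv")
dir.create("results/figures", showWarnings = FALSE, recursive = TRUE)

sc_levels <- c("S1", "S2", "S3", "S3_A", "S4", "S5", "S6", "S7", "BLUP")
outcomes$scenario <- factor(outcomes$scenario, levels = sc_levels)

p1 <- ggplot(subset(outcomes, !is.na(mean_ia)),
             aes(scenario, mean_ia, colour = qtn_model)) +
  geom_jitter(width = 0.15, alpha = 0.7) +
  stat_summary(fun = mean, geom = "point", shape = 18, size = 4,
               colour = "black") +
  labs(y = "imputation accuracy (per-individual r, cohort mean)",
       x = NULL, colour = "QTN model") +
  theme_bw()
ggsave("results/figures/imputation_accuracy.pdf", p1, width = 7, height = 4)

p2 <- ggplot(outcomes, aes(scenario, accuracy, colour = qtn_model)) +
  geom_jitter(width = 0.15, alpha = 0.7) +
  stat_summary(fun = mean, geom = "point", shape = 18, size = 4,
               colour = "black") +
  labs(y = "gEBV accuracy r(EBV, TBV) on candidates", x = NULL,
       colour = "QTN model") +
  theme_bw()
ggsave("results/figures/gebv_accuracy.pdf", p2, width = 7, height = 4)

agg <- aggregate(cbind(accuracy, mean_ia) ~ scenario + cost,
                 subset(outcomes, scenario != "BLUP"), mean)
p3 <- ggplot(agg, aes(cost / 1000, accuracy, label = scenario)) +
  geom_point() + geom_text(vjust = -0.8, size = 3) +
  labs(x = "genotyping cost (thousand EUR)",
       y = "mean gEBV accuracy") +
  theme_bw()
ggsave("results/figures/accuracy_vs_cost.pdf", p3, width = 6, height = 4)

cat("wrote results/figures/{imputation_accuracy,gebv_accuracy,",
    "accuracy_vs_cost}.pdf\n", sep = "")
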