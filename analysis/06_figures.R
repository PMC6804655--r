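#!/usr/bin/env Rscript
# Figures from the cohort study tables: apparent vs true risk by planning
# model, the diameter sweep, and the vessel-by-region breakdown of one
# phantom. Requires 05_cohort_study.R output.

suppressPackageStartupMessages({
  library(seegplan)
  library(ggplot2)
})

sdir <- "results/study"
out <- "results/figures"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

ev <- read.csv(file.path(sdir, "evaluation.csv"))
ev$model <- factor(ev$planning_model, levels = c("gold", "mid", "low"))

p1 <- ggplot(ev, aes(model, rs, fill = kind)) +
  geom_boxplot(outlier.size = 0.6) +
  labs(x = "vessel model used for planning", y = "risk score",
       fill = NULL,
       title = "Apparent vs true risk score by vascular-model fidelity") +
  theme_minimal()
ggsave(file.path(out, "risk_by_model.pdf"), p1, width = 6, height = 4)

p2 <- ggplot(ev, aes(model, md, fill = kind)) +
  geom_boxplot(outlier.size = 0.6) +
  labs(x = "vessel model used for planning",
       y = "minimum distance to vessels (mm)", fill = NULL,
       title = "Apparent vs true minimum distance") +
  theme_minimal()
ggsave(file.path(out, "md_by_model.pdf"), p2, width = 6, height = 4)

sw <- read.csv(file.path(sdir, "diameter_sweep.csv"))
p3 <- ggplot(sw, aes(factor(threshold), rs)) +
  geom_boxplot(outlier.size = 0.6) +
  labs(x = "pruning threshold (mm diameter)", y = "risk score",
       title = "Risk of gold-model plans against iteratively pruned vessels") +
  theme_minimal()
ggsave(file.path(out, "diameter_sweep.pdf"), p3, width = 6, height = 4)

# vessel-by-region proportions of one phantom: the gold model classified
# against the 2 mm-visibility reference
ph <- make_phantom(7L)
gold <- truth_vessel_model(ph)
masks <- list(sulcal = sulcal_mask(ph$gm_mask, ph$intracranial_mask, 5),
              gm = ph$gm_mask, intracranial = ph$intracranial_mask)
props <- classify_vessel_regions(gold, masks, prune_by_diameter(gold, 2))
dfp <- data.frame(region = names(props), proportion = as.numeric(props))
p4 <- ggplot(dfp, aes(region, proportion)) +
  geom_col(fill = "steelblue") +
  labs(title = "Gold-model vessel surface by anatomical region",
       subtitle = "reference: vessels visible at the 2 mm cutoff",
       x = NULL, y = "proportion of vertices") +
  theme_minimal() +
  theme(axis.text.x = element_text(angle = 20, hjust = 1))
ggsave(file.path(out, "vessels_by_region.pdf"), p4, width = 6, height = 4)

print(round(props, 3))
cat("wrote", out, "\n")
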