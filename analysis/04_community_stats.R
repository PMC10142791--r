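#!/usr/bin/env Rscript
# Stage 4 — community statistics across cruises.
#
# Kruskal-Wallis contrasts of biovolume between cruises, Shannon
# diversity of morphotype composition per sample, the distribution
# summaries behind bean-style plots, and a PCA ordination of the
# microbiological variables against the environmental covariates
# (log10(x+1)-transformed, correlation matrix).

suppressPackageStartupMessages(library(prokmorph))

cells <- read_cell_table("results/cells_simulated.csv")
summaries <- utils::read.csv("results/summary_by_sample.csv")
env <- utils::read.csv("results/environment.csv",
                       colClasses = c(station = "character"))
cells$VOL_um3 <- cell_volume(cells$L_um, cells$W_um)

# cruise-to-cruise differences in cell volume
groups <- split(cells$VOL_um3, cells$cruise)
kw_all <- kruskal_wallis(groups)
cat(sprintf("Kruskal-Wallis, VOL across the three cruises: H = %.1f (df %d), p %s\n",
            kw_all$statistic, kw_all$df,
            format.pval(kw_all$p_value, digits = 3)))
kw_pair <- kruskal_wallis(groups[c("BANSIC-2012", "NOVESAR-2013")])
cat(sprintf("  summer (BAN-12) vs winter (NOV-13): H = %.1f, p %s\n",
            kw_pair$statistic, format.pval(kw_pair$p_value, digits = 3)))

# Shannon diversity range per cruise
cat("\nShannon H' (bits) over morphotype counts, range across samples:\n")
hr <- tapply(summaries$H_prime, summaries$cruise, range)
for (cr in names(hr))
  cat(sprintf("  %-13s %.2f - %.2f\n", cr, hr[[cr]][1], hr[[cr]][2]))

# distribution summaries (the empirical shapes behind beanplots)
cat("\nVOL distribution by cruise:\n")
for (cr in names(groups)) {
  ds <- distribution_summary(groups[[cr]])
  modes <- sum(diff(sign(diff(ds$density$y))) == -2)
  cat(sprintf("  %-13s mean %.3f sd %.3f median %.3f um^3, %d density mode(s)\n",
              cr, ds$mean, ds$sd, ds$median, modes))
}

# ordination of microbiological vs environmental variables ("T" must be
# selected by name, not through a formula, where it would read as TRUE)
env_vars <- c("T", "S", "DO", "FLUO", "NO3", "PO4", "SiO4")
env_means <- aggregate(env[env_vars],
                       by = env[c("cruise", "station", "depth_m")], mean)
merged <- merge(summaries, env_means,
                by = c("cruise", "station", "depth_m"))
mat <- merged[, c("PA", "PB", "mean_VOL", "T", "S", "DO", "FLUO",
                  "NO3", "PO4", "SiO4", "depth_m")]
pca <- pca_ordination(mat)
cat(sprintf("\nPCA (log10(x+1), correlation matrix): PC1 %.1f%%, PC2 %.1f%% of variance\n",
            pca$variance_explained[1], pca$variance_explained[2]))
top <- sort(pca$cos2[, 1], decreasing = TRUE)[1:4]
cat("  variables best represented on PC1:",
    paste(names(top), collapse = ", "), "\n")

utils::write.csv(round(pca$loadings, 4), "results/pca_loadings.csv")
utils::write.csv(round(pca$scores, 4), "results/pca_scores.csv")
jsonlite::write_json(
  list(kruskal_wallis_VOL = list(statistic = kw_all$statistic,
                                 df = kw_all$df, p_value = kw_all$p_value),
       kruskal_wallis_BAN12_vs_NOV13 = list(statistic = kw_pair$statistic,
                                            p_value = kw_pair$p_value),
       shannon_range = lapply(hr, function(x) list(min = x[1], max = x[2])),
       pca_variance_explained = as.list(pca$variance_explained)),
  "results/community_stats.json", auto_unbox = TRUE, digits = NA,
  pretty = TRUE)
cat("\nwrote results/pca_loadings.csv, results/pca_scores.csv,",
    "results/community_stats.json\n")
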