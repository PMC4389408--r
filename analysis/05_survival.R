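#!/usr/bin/env Rscript
# Survival and clinical-covariate statistics: Kaplan-Meier curves and
# logrank tests by cluster and by immune group, a per-SD Cox model of the
# M2/M1 score, ANOVA of age across clusters and a Fisher test of the
# claudin-low flag against cluster membership.

suppressPackageStartupMessages(library(tnbcsubtyper))

out <- "results/survival"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

cli <- read.delim("results/cohort/clinical.tsv")
labels <- read.delim("results/clustering/cluster_labels.tsv")
imm <- read.delim("results/immune/immune_groups.tsv")
cli$cluster_fitted <- labels$cluster[match(cli$sample_id, labels$sample_id)]

km <- kaplan_meier(cli$efs_time, cli$efs_event, cli$cluster_fitted)
write.table(km, file.path(out, "km_efs_by_cluster.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
lr_cluster <- logrank_test(cli$efs_time, cli$efs_event, cli$cluster_fitted)

idx <- match(imm$sample_id, cli$sample_id)
lr_immune <- logrank_test(cli$efs_time[idx], cli$efs_event[idx], imm$group)

cox_m2m1 <- cox_univariate(cli$efs_time[idx], cli$efs_event[idx],
                           imm$m2m1_score)

age_anova <- group_compare("anova_tukey", values = cli$age,
                           groups = cli$cluster_fitted)
cl_fisher <- group_compare("fisher_exact",
                           table = table(cli$claudin_low,
                                         cli$cluster_fitted == 3))

stats_tab <- data.frame(
  test = c("logrank_efs_by_cluster", "logrank_efs_hir_vs_lir",
           "cox_efs_per_sd_m2m1", "anova_age_by_cluster",
           "fisher_claudin_low_vs_c3"),
  statistic = c(lr_cluster$statistic, lr_immune$statistic,
                cox_m2m1$log_hr, age_anova$f_statistic, NA),
  p_value = c(lr_cluster$p_value, lr_immune$p_value, cox_m2m1$p_value,
              age_anova$p_value, cl_fisher$p_value))
write.table(stats_tab, file.path(out, "survival_statistics.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(age_anova$tukey, file.path(out, "age_tukey.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
print(stats_tab)
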