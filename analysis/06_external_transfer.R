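#!/usr/bin/env Rscript
# Transfer the discovery partition to the external cohort: train a
# nearest-shrunken-centroid classifier on the filtered discovery matrix
# and its fuzzy labels, predict the external samples, and compare the
# predictions with the external cohort's own fuzzy partition.

suppressPackageStartupMessages(library(tnbcsubtyper))

out <- "results/transfer"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

Ef <- read_expression_table("results/clustering/expression_filtered.tsv")
labels <- read.delim("results/clustering/cluster_labels.tsv")
lab <- setNames(labels$cluster, labels$sample_id)[colnames(Ef)]

model <- pam_train(Ef, lab, seed = 2)
print(model)
write_pam_model(model, file.path(out, "pam_model.json"))

E_ext <- read_expression_table("results/external/expression.tsv")
pred <- pam_predict(model, E_ext)
write.table(pred, file.path(out, "external_predictions.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

# independent fuzzy partition of the external cohort for comparison
Ef_ext <- filter_top_variance(E_ext, fraction = 0.05)
fit_ext <- fanny_fit(centred_pearson_dissimilarity(Ef_ext), 3, seed = 1)
lab_ext <- crisp_assign(fit_ext)

# cluster numbers are arbitrary on each cohort: best match over relabellings
perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
              c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
fa <- as.integer(factor(pred$label))
acc <- max(vapply(perms, function(p) mean(p[fa] == lab_ext), numeric(1)))
tab <- table(predicted = pred$label, fuzzy_external = lab_ext)
write.table(as.data.frame(tab), file.path(out, "concordance_table.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat(sprintf("discordance with the external fuzzy partition: %.2f%% (%d/%d)\n",
            100 * (1 - acc), round((1 - acc) * length(lab_ext)),
            length(lab_ext)))
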