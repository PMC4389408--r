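#!/usr/bin/env Rscript
# Dissect the two basal-enriched clusters (canonical C2 and C3) into high
# and low immune response groups by Ward clustering of the seven immune
# metagenes, and score the signed M2/M1 signature per sample.

suppressPackageStartupMessages(library(tnbcsubtyper))

out <- "results/immune"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

E <- read_expression_table("results/cohort/expression.tsv")
ann <- read_probe_annotation("results/cohort/annotation.tsv")
modules <- read_gmt_modules("results/cohort/immune_modules.gmt")
sig <- read_signed_signature("results/macrophage/m2m1_signature.tsv", "m2_m1")
labels <- read.delim("results/clustering/cluster_labels.tsv")

basal <- labels$sample_id[labels$cluster %in% c(2, 3)]
ip <- dissect_immune_response(E, modules, sig, ann, samples = basal)
print(ip)

write.table(data.frame(sample_id = names(ip$group), group = ip$group,
                       m2m1_score = as.numeric(ip$m2m1[names(ip$group)])),
            file.path(out, "immune_groups.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(data.frame(module = rownames(ip$metagene_scores),
                       ip$metagene_scores, check.names = FALSE),
            file.path(out, "metagene_scores.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

cmp <- compare_metagenes_between_clusters(ip$metagene_scores, ip$group)
write.table(cmp, file.path(out, "metagene_comparison.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat(sprintf("M2/M1 mean: HIR %.3f vs LIR %.3f\n",
            mean(ip$m2m1[ip$group == "HIR"]),
            mean(ip$m2m1[ip$group == "LIR"])))
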