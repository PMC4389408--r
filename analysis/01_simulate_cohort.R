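#!/usr/bin/env Rscript
# Simulate the discovery cohort and an independent external cohort from
# the same synthetic platform, and write them as plain-text tables.

suppressPackageStartupMessages(library(tnbcsubtyper))

out <- "results/cohort"
out_ext <- "results/external"
dir.create(out, showWarnings = FALSE, recursive = TRUE)
dir.create(out_ext, showWarnings = FALSE, recursive = TRUE)

coh <- generate_tnbc_cohort(cohort_spec(seed = 11))
write_expression_table(coh$expression, file.path(out, "expression.tsv"))
write.table(coh$annotation, file.path(out, "annotation.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(coh$clinical, file.path(out, "clinical.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(data.frame(sample_id = names(coh$truth), cluster = coh$truth),
            file.path(out, "planted_labels.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write_gmt_modules(coh$modules, file.path(out, "immune_modules.gmt"))

ext <- generate_tnbc_cohort(cohort_spec(seed = 99))
write_expression_table(ext$expression, file.path(out_ext, "expression.tsv"))
write.table(ext$clinical, file.path(out_ext, "clinical.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

cat(sprintf("discovery cohort: %d probes x %d samples, planted sizes %s\n",
            nrow(coh$expression), ncol(coh$expression),
            paste(table(coh$truth), collapse = "/")))
cat(sprintf("external cohort: %d probes x %d samples\n",
            nrow(ext$expression), ncol(ext$expression)))
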