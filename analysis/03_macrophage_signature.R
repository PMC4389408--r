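#!/usr/bin/env Rscript
# Build the signed M2/M1 macrophage signature: SAM on the two-class
# polarized-macrophage reference, keep genes with all probes at q = 0%,
# and weight them +1/-1 by the M2-vs-M1 mean direction.

suppressPackageStartupMessages(library(tnbcsubtyper))

out <- "results/macrophage"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

mac <- generate_macrophage_reference(macrophage_spec(seed = 5))
sam <- sam_two_class(mac$expression, mac$labels, n_perm = 200, seed = 3)
print(sam)

write.table(data.frame(probe_id = sam$probe_ids, d = sam$d, s = sam$s,
                       q_percent = sam$q),
            file.path(out, "sam_statistics.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

sel <- select_q0_genes(sam, mac$annotation)
sig <- build_signed_signature(mac$expression, mac$labels, sel$gene_symbol,
                              name = "m2_m1")
write_signed_signature(sig, file.path(out, "m2m1_signature.tsv"))
cat(sprintf("signature: %d genes (%d up in M2, %d up in M1)\n",
            length(sig$genes), sum(sig$weights > 0), sum(sig$weights < 0)))
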