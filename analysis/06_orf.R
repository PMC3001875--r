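#!/usr/bin/env Rscript
# Six-frame longest-ORF classification of the merged transcripts into the
# four completeness classes, with the 50-aa-binned length histogram.

library(planartx)
library(data.table)

outdir <- "results/orf"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

merged <- read_fasta("results/merge/merged.fa")
res <- classify_orfs(merged)
write_orf_outputs(res, file.path(outdir, "peptides.fa"),
                  file.path(outdir, "orf_calls.tsv"))
fwrite(res$length_histogram, file.path(outdir, "orf_length_histogram.tsv"),
       sep = "\t")
message("ORF completeness classes:")
print(res$class_counts)
message(sprintf("%d of %d transcripts carry a reportable ORF (>= 10 aa)",
                nrow(res$calls), length(merged)))
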