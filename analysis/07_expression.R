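#!/usr/bin/env Rscript
# RNA-seq contrast of intact vs irradiated samples: unique-read counting
# per transcript, RPKM, the RPKM >= 1 detection filter, replicate
# congruency, the weighted proportion test, and the down-regulated call set
# (p < 0.01 and more than 2-fold decrease).  Finishes with the printed
# known-genes fold-change check and truth-based evaluation.

library(planartx)
library(data.table)

sim <- "results/simulation"
outdir <- "results/expression"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

genome <- read_fasta(file.path(sim, "genome.fa"))
truth_tx <- read_gtf(file.path(sim, "truth.gtf"))
tx_seqs <- tx_sequences(truth_tx, genome)
samples <- c("intact_rep1", "intact_rep2", "irradiated_rep1",
             "irradiated_rep2")
read_sets <- lapply(samples, function(s)
    structure(list(reads = fread(file.path(sim, paste0("reads_", s, ".tsv"))),
                   platform = "short"), class = "read_set"))
names(read_sets) <- samples
meta <- data.table(sample_id = samples,
                   condition = sub("_rep\\d+$", "", samples),
                   replicate = as.integer(sub("^.*_rep", "", samples)))

et <- quantify_samples(read_sets, meta, tx_seqs,
                       mapping_params(max_mismatches = 0L))
fwrite(data.table(transcript_id = rownames(et$counts), et$counts),
       file.path(outdir, "counts.tsv"), sep = "\t")
fwrite(data.table(transcript_id = rownames(et$rpkm), round(et$rpkm, 3)),
       file.path(outdir, "rpkm.tsv"), sep = "\t")

etf <- expression_filter(et)
message(sprintf("%d of %d transcripts pass the RPKM >= 1 detection filter",
                nrow(etf$counts), nrow(et$counts)))
cong <- replicate_congruency(etf)
fwrite(cong, file.path(outdir, "replicate_congruency.tsv"), sep = "\t")
message("replicate congruency (Pearson r of log10 RPKM): ",
        paste(sprintf("%s %.3f", cong$condition, cong$r), collapse = ", "))

de <- differential_expression(etf)
fwrite(de, file.path(outdir, "de_results.tsv"), sep = "\t")
message(sprintf("%d transcripts down-regulated (p < 0.01, > 2-fold)",
                sum(de$passes)))

depleted <- readLines(file.path(sim, "depleted_genes.txt"))
called <- unique(sub("\\.\\d+$", "", de[passes == TRUE, transcript_id]))
ev <- evaluate_against_truth(called, depleted, "de")
fwrite(ev, file.path(outdir, "de_evaluation.tsv"), sep = "\t")
message(sprintf("gene-level DE vs truth: precision %.3f, recall %.3f",
                ev$precision, ev$recall))

# the printed known-genes table: recomputed signed fold changes
fc <- fold_change_check()
fwrite(fc, file.path(outdir, "known_genes_fold_change.tsv"), sep = "\t")
message(sprintf("known-genes fold-change check: %d of %d printed rows reproduce to 2 decimals",
                sum(fc$agrees), nrow(fc)))
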