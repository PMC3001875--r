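#!/usr/bin/env Rscript
# Map the intact-condition short reads against the genome and the
# (incomplete) starting annotation, filter on quality, and assemble
# coverage islands + split reads into the first-round transcript set.

library(planartx)
library(data.table)

sim <- "results/simulation"
outdir <- "results/assembly"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

genome <- read_fasta(file.path(sim, "genome.fa"))
ann <- read_gtf(file.path(sim, "annotation_start.gtf"))
reads <- rbindlist(lapply(c("intact_rep1", "intact_rep2"), function(s)
    fread(file.path(sim, paste0("reads_", s, ".tsv")))))

mp <- mapping_params(max_mismatches = 0L)
aln <- map_reads(reads[, .(read_id, seq, read_quality)], genome,
                 annotation = ann, params = mp)
write_sam_like(aln, file.path(outdir, "alignments.tsv"))
status <- aln[, .(u = uniqueness[1]), by = read_id][, table(u)]
message("mapping status: ", paste(names(status), status, collapse = ", "))

filt <- quality_filter(aln, mp)
models <- assemble_transcripts(filt)
write_gtf(models, file.path(outdir, "models_round1.gtf"))
s <- annotate_counts(models)
message(sprintf(
    "round-1 assembly: %d multi-exon and %d single-exon models, mean spliced length %.0f bp",
    s$n_multi_exon, s$n_single_exon, s$mean_length))
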