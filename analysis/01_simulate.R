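#!/usr/bin/env Rscript
# Generate the synthetic study world: a fragmented A/T-rich genome, gene
# models with isoforms, single-exon genes and pseudogene confounders, the
# intact/irradiated expression design, and both read sets.  Everything
# downstream reads from results/simulation/.

library(planartx)
library(data.table)

seed <- 1L
outdir <- "results/simulation"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

genome <- generate_genome(genome_params(
    n_contigs = 50L, contig_length_range = c(5000L, 20000L),
    at_fraction = 0.65, repeat_fraction = 0.1,
    seed = derive_seed(seed, "genome")))
truth <- generate_gene_models(genome, 200L,
                              seed = derive_seed(seed, "genes"),
                              gtf_path = file.path(outdir, "truth.gtf"))
write_fasta(truth$genome, file.path(outdir, "genome.fa"))

at <- mean(strsplit(paste(truth$genome, collapse = ""), "")[[1]] %in%
           c("A", "T"))
message(sprintf("genome: %d contigs, %.0f kb, A+T = %.3f",
                length(truth$genome), sum(nchar(truth$genome)) / 1e3, at))
message(sprintf("genes: %d (%d single-exon, %d pseudogene copies), %d truth junctions",
                nrow(truth$genes), sum(truth$genes$is_single_exon),
                sum(truth$genes$is_pseudogene_copy),
                nrow(truth_junctions(truth))))

expr <- make_expression_truth(truth)
real <- truth$genes[baseline > 0]
set.seed(derive_seed(seed, "depleted"))
depleted <- sample(real$gene_id, round(0.2 * nrow(real)))
expr <- apply_irradiation_effect(expr, depleted, fold = 14.28)
fwrite(expr, file.path(outdir, "expression_truth.tsv"), sep = "\t")
writeLines(depleted, file.path(outdir, "depleted_genes.txt"))
message(length(depleted), " genes depleted 14.28-fold after irradiation")

long_rs <- simulate_long_reads(truth, 1200L, mean_length = 278,
                               error_rate = 0.002,
                               seed = derive_seed(seed, "long"))
write_fasta(setNames(long_rs$reads$seq, long_rs$reads$read_id),
            file.path(outdir, "long_reads.fa"))
message(sprintf("long reads: %d, mean length %.1f bp",
                nrow(long_rs$reads), mean(nchar(long_rs$reads$seq))))

short <- simulate_short_reads(truth, expr, 20000L,
                              seed = derive_seed(seed, "short"))
for (nm in names(short))
    fwrite(short[[nm]]$reads, file.path(outdir, paste0("reads_", nm, ".tsv")),
           sep = "\t")
message("short reads: 4 samples x 20,000 strand-specific 50 bp reads")

# incomplete starting annotation: half of the true junctions withheld
ann <- withhold_junctions(truth$tx, 0.5,
                          seed = derive_seed(seed, "withhold"))
write_gtf(ann$tx, file.path(outdir, "annotation_start.gtf"))
fwrite(ann$withheld, file.path(outdir, "withheld_junctions.tsv"), sep = "\t")
message(nrow(ann$withheld), " of ", nrow(truth_junctions(truth)),
        " junctions withheld from the starting annotation")
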