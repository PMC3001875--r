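#!/usr/bin/env Rscript
# Merge the two platforms: collapse terminal-variant isotigs, homology-
# screen the short-read cDNAs against them (95% identity across >= 50 nt),
# keep unmatched multi-exon models, drop unmatched single-exon ones,
# co-assemble and emit the merged transcript set with provenance.

library(planartx)
library(data.table)

outdir <- "results/merge"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

genome <- read_fasta("results/simulation/genome.fa")
models <- read_gtf("results/rescue/models_round2.gtf")
iso <- fread("results/longread/isotig_groups.tsv")
iso_seq <- read_fasta("results/longread/isotigs.fa")

prm <- merge_params()
col <- collapse_isoforms(iso_seq[iso$isotig_id], groups = iso$isogroup_id,
                         params = prm)
message(sprintf("terminal collapse: %d isotigs -> %d contigs",
                length(iso_seq), length(col$contigs)))

sr_seqs <- tx_sequences(models, genome)
sr_seqs <- sr_seqs[nchar(sr_seqs) >= prm$min_match_length]
ne <- tx_n_exons(models)[names(sr_seqs)]
rep <- merge_datasets(col$contigs, sr_seqs, ne, prm)

write_fasta(rep$final_seqs, file.path(outdir, "merged.fa"))
fwrite(rep$provenance, file.path(outdir, "provenance.tsv"), sep = "\t")
fwrite(rep$log, file.path(outdir, "decision_log.tsv"), sep = "\t")
report <- data.table(metric = c("n_matched_short",
                                "n_unmatched_multi_exon_kept",
                                "n_unmatched_single_exon_dropped",
                                "n_assembled_contigs", "n_singletons_kept",
                                "n_singletons_dropped_single_exon",
                                "final_transcripts"),
                     value = c(rep$n_matched_short,
                               rep$n_unmatched_multi_exon_kept,
                               rep$n_unmatched_single_exon_dropped,
                               rep$n_assembled_contigs, rep$n_singletons_kept,
                               rep$n_singletons_dropped_single_exon,
                               rep$final_transcripts))
fwrite(report, file.path(outdir, "merge_report.tsv"), sep = "\t")
message("merge report:")
print(report)
stopifnot(rep$final_transcripts ==
          rep$n_assembled_contigs + rep$n_singletons_kept)
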