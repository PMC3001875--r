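#' Split-read rescue benchmark on a truth-known fixture
#'
#' Builds the standard rescue study: a fragmented genome, 200 gene loci at
#' uniform expression, error-free strand-specific 50 bp reads at the
#' requested coverage, and a starting annotation from which half of the
#' true junctions have been withheld.  Runs mapping, assembly and one round
#' of super-gene rescue, then scores recovery of the withheld junctions
#' that at least two reads straddle with a mappable stub on each side, and
#' the precision of all newly assembled junctions.
#'
#' @param seed integer seed.
#' @param n_genes gene loci.
#' @param coverage target fold-coverage of expressed transcripts.
#' @param withheld_fraction fraction of true junctions withheld.
#' @param min_stub stub length defining a straddling read (matches the
#'   mapper's partial-alignment stub).
#' @return list with `recovery`, `precision`, `n_withheld_covered`,
#'   `n_recovered`, `multi_exon_round1`, `multi_exon_round2`, `ledger`.
#' @export
rescue_benchmark <- function(seed = 1L, n_genes = 200L, coverage = 25,
                             withheld_fraction = 0.5, min_stub = 15L) {
    g <- generate_genome(genome_params(
        n_contigs = 50L, contig_length_range = c(8000L, 20000L),
        at_fraction = 0.65, repeat_fraction = 0.05,
        seed = derive_seed(seed, "bench_genome")))
    truth <- generate_gene_models(g, n_genes,
                                  seed = derive_seed(seed, "bench_genes"))
    genes <- copy(truth$genes)
    genes[, baseline := ifelse(is_pseudogene_copy, 0, 100)]
    truth$genes <- genes
    expr <- make_expression_truth(truth, conditions = "intact",
                                  replicates = 1L)
    seqs <- tx_sequences(truth$tx, truth$genome)
    iso <- truth$isoforms[truth$genes[, .(gene_id, baseline)],
                          on = "gene_id"][baseline > 0]
    eff_len <- sum(iso$share * nchar(seqs[iso$transcript_id]))
    n_reads <- ceiling(coverage * eff_len / 50)
    srs <- simulate_short_reads(truth, expr, n_reads,
                                seed = derive_seed(seed, "bench_reads"))
    reads <- srs[[1L]]$reads
    wh <- withhold_junctions(truth$tx, withheld_fraction,
                             seed = derive_seed(seed, "bench_withhold"))
    mp <- mapping_params(max_mismatches = 0L)
    aln <- map_reads(reads[, .(read_id, seq, read_quality)], truth$genome,
                     annotation = wh$tx, params = mp)
    out <- iterate_rescue(aln, reads, truth$genome, map_params = mp,
                          max_rounds = 1L)
    jkey <- function(x) sprintf("%s|%s|%d|%d", x$contig, x$strand,
                                as.integer(x$donor), as.integer(x$acceptor))
    # withheld junctions straddled by >= 2 reads with >= min_stub per side
    jp <- junction_spliced_positions(truth$tx)
    jp <- jp[jkey(jp) %in% jkey(wh$withheld)]
    straddle <- merge(reads[, .(isoform, offset)],
                      jp[, .(isoform = transcript_id, tpos, contig, strand,
                             donor, acceptor)],
                      by = "isoform", allow.cartesian = TRUE)
    straddle <- straddle[offset <= tpos - min_stub &
                         offset + 50 >= tpos + min_stub]
    covered <- straddle[, .N, by = .(contig, strand, donor, acceptor)][N >= 2L]
    final_j <- unique(tx_junctions(out$models)[, .(contig, strand, donor,
                                                   acceptor)])
    n_rec <- sum(jkey(covered) %in% jkey(final_j))
    # precision of every junction assembled after rescue
    ev <- evaluate_against_truth(final_j, truth_junctions(truth), "junctions")
    list(recovery = if (nrow(covered)) n_rec / nrow(covered) else NA_real_,
         precision = ev$precision,
         n_withheld_covered = nrow(covered), n_recovered = n_rec,
         multi_exon_round1 = out$ledger$n_multi_exon[1L],
         multi_exon_round2 = out$ledger$n_multi_exon[2L],
         ledger = out$ledger)
}

#' Differential-expression parameter recovery benchmark
#'
#' Simulates the irradiation contrast at count level: gene models with
#' log-uniform baselines, `n_depleted` genes (expected intact RPKM of at
#' least `min_rpkm_baseline`) depleted `fold`-fold in the irradiated
#' condition, 2+2 replicate libraries of `n_reads` reads, then the full
#' quantification, filtering and testing cascade.  Scores gene-level
#' sensitivity and false-discovery proportion of the down-regulated call
#' set.
#'
#' @param seed integer seed.
#' @param n_genes total gene loci.
#' @param n_depleted depleted genes.
#' @param fold depletion factor (the piwi-family exemplar magnitude by
#'   default).
#' @param n_reads reads per sample.
#' @param min_rpkm_baseline eligibility floor for depleted genes.
#' @return list with `sensitivity`, `fdp`, `n_called`, `n_depleted`,
#'   `de_table`.
#' @export
de_benchmark <- function(seed = 1L, n_genes = 400L, n_depleted = 100L,
                         fold = 14.28, n_reads = 1e6,
                         min_rpkm_baseline = 10) {
    g <- generate_genome(genome_params(
        n_contigs = 50L, contig_length_range = c(10000L, 20000L),
        at_fraction = 0.65, repeat_fraction = 0,
        seed = derive_seed(seed, "de_genome")))
    truth <- generate_gene_models(g, n_genes, pseudogene_fraction = 0,
                                  seed = derive_seed(seed, "de_genes"))
    seqs <- tx_sequences(truth$tx, truth$genome)
    iso <- truth$isoforms[truth$genes[, .(gene_id, baseline)], on = "gene_id"]
    iso[, qlen := nchar(seqs[transcript_id])]
    iso[, w := baseline * share * qlen]
    # expected intact RPKM per isoform at depth n_reads
    iso[, exp_rpkm := 1e9 * (w / sum(w)) / qlen]
    eligible <- unique(iso[exp_rpkm >= min_rpkm_baseline, gene_id])
    if (length(eligible) < n_depleted)
        stop("fixture yields too few genes above the RPKM floor")
    depleted <- with_seed(derive_seed(seed, "de_pick"),
                          sample(eligible, n_depleted))
    expr <- make_expression_truth(truth)
    expr <- apply_irradiation_effect(expr, depleted, fold)
    counts <- simulate_sample_counts(truth, expr, n_reads,
                                     seed = derive_seed(seed, "de_counts"))
    samples <- data.table(
        sample_id = colnames(counts),
        condition = sub("_rep\\d+$", "", colnames(counts)),
        replicate = as.integer(sub("^.*_rep", "", colnames(counts))))
    et <- expression_table(counts, nchar(seqs), samples)
    etf <- expression_filter(et)
    de <- differential_expression(etf)
    tx2gene <- setNames(truth$isoforms$gene_id, truth$isoforms$transcript_id)
    called <- unique(tx2gene[de[passes == TRUE, transcript_id]])
    list(sensitivity = mean(depleted %in% called),
         fdp = if (length(called)) mean(!called %in% depleted) else 0,
         n_called = length(called), n_depleted = n_depleted,
         de_table = de)
}

#' Type-I error of the weighted proportion test under a pure-sampling null
#'
#' `n_tx` transcripts at a common proportion, 2+2 replicate libraries of
#' equal size, no between-library variation; reports the rejection rate at
#' `alpha`.
#'
#' @param seed integer seed.
#' @param n_tx transcripts simulated.
#' @param p common true proportion.
#' @param total library size.
#' @param alpha nominal level.
#' @return rejection rate.
#' @export
baggerly_calibration <- function(seed = 1L, n_tx = 10000L, p = 1e-4,
                                 total = 1e6, alpha = 0.05) {
    with_seed(seed, {
        rej <- logical(n_tx)
        for (i in seq_len(n_tx)) {
            xa <- rbinom(2L, total, p)
            xb <- rbinom(2L, total, p)
            rej[i] <- baggerly_test(xa, c(total, total), xb,
                                    c(total, total))$p_value < alpha
        }
        mean(rej)
    })
}

#' Signed fold-change check against a printed reference table
#'
#' Recomputes the signed fold change from the mean intact/irradiated RPKM
#' columns of a known-genes table and compares with the printed values at
#' two decimals.
#'
#' @param path TSV with columns `gene`, `mean_intact_rpkm`,
#'   `mean_irradiated_rpkm`, `printed_fold_change`; defaults to the table
#'   shipped with the package.
#' @return `data.table` with the recomputed fold change and an `agrees`
#'   flag per row.
#' @export
fold_change_check <- function(path = system.file(
        "extdata", "irradiation_rpkm_known_genes.tsv", package = "planartx")) {
    tab <- fread(path)
    tab[, recomputed := round(fold_change(mean_intact_rpkm,
                                          mean_irradiated_rpkm), 2)]
    tab[, agrees := abs(recomputed - printed_fold_change) < 0.005]
    tab[]
}
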