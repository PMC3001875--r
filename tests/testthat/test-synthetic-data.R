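test_that("genome generation honours composition, determinism and edge cases", {
    expect_s3_class(generate_genome(genome_params(n_contigs = 0L)),
                    "genome_set")
    expect_length(generate_genome(genome_params(n_contigs = 0L))$contigs, 0L)
    expect_error(genome_params(at_fraction = 1.4), "proportion")
    expect_error(genome_params(repeat_fraction = 1), "repeat_fraction")

    p <- genome_params(n_contigs = 50L, contig_length_range = c(5000, 20000),
                       at_fraction = 0.65, seed = 7L)
    g1 <- generate_genome(p)
    g2 <- generate_genome(p)
    expect_identical(g1$contigs, g2$contigs)
    all_bases <- strsplit(paste(g1$contigs, collapse = ""), "")[[1]]
    at <- mean(all_bases %in% c("A", "T"))
    expect_lt(abs(at - 0.65), 0.02)
})

test_that("gene placement produces valid, recountable truth models", {
    w <- small_world()
    tr <- w$truth
    expect_equal(nrow(tr$genes), 40L)
    # fractions achieved to within rounding
    expect_equal(sum(tr$genes$is_pseudogene_copy), round(0.05 * 40))
    expect_equal(sum(tr$genes$is_single_exon & !tr$genes$is_pseudogene_copy),
                 round(0.2 * 40))
    # exons sorted, non-overlapping, within contig bounds
    clen <- nchar(tr$genome)
    for (grp in split(tr$tx, by = "transcript_id")) {
        expect_true(all(diff(grp$start) > 0))
        expect_true(all(grp$end[-nrow(grp)] <= grp$start[-1]))
        expect_true(all(grp$start >= 0 & grp$end <= clen[grp$contig[1]]))
    }
    # pseudogene copies carry zero expression
    expect_true(all(tr$genes[is_pseudogene_copy == TRUE, baseline] == 0))
    # truth junction count equals sum(exons - 1) over multi-exon isoforms
    ne <- tx_n_exons(tr$tx)
    expect_equal(nrow(tx_junctions(tr$tx)), sum(pmax(ne - 1L, 0L)))
    # empty annotation case
    g0 <- generate_genome(genome_params(n_contigs = 2L, seed = 1L))
    t0 <- generate_gene_models(g0, 0L, seed = 1L)
    expect_equal(nrow(t0$tx), 0L)
    # single-exon fraction of 1 forces zero junctions
    t1 <- generate_gene_models(g0, 10L, single_exon_fraction = 1,
                               pseudogene_fraction = 0, seed = 2L)
    expect_equal(nrow(truth_junctions(t1)), 0L)
    expect_equal(sum(t1$genes$is_single_exon), 10L)
})

test_that("truth GTF round-trips through disk exactly", {
    tr <- small_world()$truth
    path <- withr::local_tempfile(fileext = ".gtf")
    write_gtf(tr$tx, path)
    back <- read_gtf(path)
    a <- data.table::setorder(tr$tx[, .(transcript_id, gene_id, contig,
                                        strand, start, end)],
                              transcript_id, start)
    b <- data.table::setorder(back[, .(transcript_id, gene_id, contig,
                                       strand, start, end)],
                              transcript_id, start)
    expect_equal(a, b)
})

test_that("long reads have the target length profile and exact origins", {
    tr <- small_world()$truth
    expect_error(simulate_long_reads(
        generate_gene_models(generate_genome(genome_params(n_contigs = 1L)),
                             0L), 10L),
        "expressed")
    empty <- simulate_long_reads(tr, 0L)
    expect_equal(nrow(empty$reads), 0L)

    lr <- simulate_long_reads(tr, 5000L, mean_length = 278, error_rate = 0,
                              seed = 5L)
    m <- mean(nchar(lr$reads$seq))
    expect_gte(m, 250); expect_lte(m, 306)
    # with error_rate = 0 every read is an exact substring of its isoform
    seqs <- tx_sequences(tr$tx, tr$genome)
    sub <- lr$reads[1:200]
    ok <- mapply(function(s, iso, ori) {
        tseq <- seqs[[iso]]
        if (ori == "-") s <- revcomp(s)
        grepl(s, tseq, fixed = TRUE)
    }, sub$seq, sub$isoform, sub$ori)
    expect_true(all(ok))
})

test_that("short reads are 50 bp, origin-consistent, and design-responsive", {
    tr <- small_world()$truth
    ex <- make_expression_truth(tr)
    # all multipliers zero -> empty samples
    ex0 <- copy(ex)[, rate := 0]
    s0 <- simulate_short_reads(tr, ex0, 1000L, seed = 1L)
    expect_true(all(vapply(s0, function(s) nrow(s$reads) == 0L, logical(1))))

    dep <- tr$genes[baseline > 0][order(-baseline)][1:5, gene_id]
    ex2 <- apply_irradiation_effect(ex, dep, fold = 20)
    srs <- simulate_short_reads(tr, ex2, 50000L, seed = 11L)
    expect_named(srs, c("intact_rep1", "intact_rep2",
                        "irradiated_rep1", "irradiated_rep2"))
    expect_true(all(nchar(srs$intact_rep1$reads$seq) == 50L))
    # origin check: read equals the recorded isoform substring
    seqs <- tx_sequences(tr$tx, tr$genome)
    sub <- srs$intact_rep1$reads[1:200]
    expect_true(all(substring(seqs[sub$isoform], sub$offset + 1,
                              sub$offset + 50) == sub$seq))
    # depletion visible in recounted origins (within 2x of the design fold)
    ca <- srs$intact_rep1$reads[gene_id %in% dep, .N, by = gene_id]
    cb <- srs$irradiated_rep1$reads[gene_id %in% dep, .N, by = gene_id]
    ratios <- ca$N / cb[ca, on = "gene_id", N]
    big <- ca$N >= 100
    expect_true(all(ratios[big] > 10 & ratios[big] < 40))
})

test_that("irradiation effect composes and validates", {
    tr <- small_world()$truth
    ex <- make_expression_truth(tr)
    expect_identical(apply_irradiation_effect(ex, character(0), 3), ex)
    expect_error(apply_irradiation_effect(ex, "nope", 3), "unknown gene")
    expect_error(apply_irradiation_effect(ex, tr$genes$gene_id[1], 1),
                 "fold")
    gid <- tr$genes[baseline > 0, gene_id][1]
    e1 <- apply_irradiation_effect(ex, gid, 14.28)
    base <- ex[gene_id == gid & condition == "irradiated", rate]
    expect_equal(e1[gene_id == gid & condition == "irradiated", rate],
                 base / 14.28)
    # the canonical piwi-like depletion magnitude: 275.7 -> 19.3
    expect_equal(round(275.7 / 14.28, 1), 19.3)
    e2 <- apply_irradiation_effect(e1, gid, 2)
    expect_equal(e2[gene_id == gid & condition == "irradiated", rate],
                 base / (14.28 * 2))
    # intact condition untouched throughout
    expect_equal(e2[condition == "intact"], ex[condition == "intact"])
})
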