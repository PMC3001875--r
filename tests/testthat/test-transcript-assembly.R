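mk_aln <- function(read_id, pos, cigar, contig = "c1", strand = "+",
                   uniqueness = "unique") {
    data.table::data.table(read_id = read_id, contig = contig, pos = pos,
                           strand = strand, cigar = cigar, score = 50,
                           uniqueness = uniqueness, read_quality = 30,
                           target_space = "genome", seq = "A")
}

test_that("coverage islands require two unique reads and merge overlaps", {
    p <- assembly_params()
    empty <- coverage_islands(mk_aln(character(0), numeric(0), character(0)),
                              "c1", "+", p)
    expect_equal(nrow(empty), 0L)
    # a single supporting read is below the 2-read floor
    one <- coverage_islands(mk_aln("r1", 0, "50M"), "c1", "+", p)
    expect_equal(nrow(one), 0L)
    # two overlapping reads merge into one island spanning [0, 75)
    two <- coverage_islands(mk_aln(c("r1", "r2"), c(0, 25), c("50M", "50M")),
                            "c1", "+", p)
    expect_equal(nrow(two), 1L)
    expect_equal(c(two$start, two$end, two$support), c(0, 75, 2))
    # brute-force per-base coverage agreement on a random fixture
    set.seed(3)
    pos <- sample(0:2000, 300, TRUE)
    a <- mk_aln(sprintf("r%d", seq_along(pos)), pos, "50M")
    isl <- coverage_islands(a, "c1", "+", p)
    cov <- integer(3000)
    for (s in pos) cov[(s + 1):(s + 50)] <- cov[(s + 1):(s + 50)] + 1L
    r <- rle(cov > 0)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    want <- data.table::data.table(start = starts[r$values] - 1,
                                   end = as.numeric(ends[r$values]))
    want <- want[vapply(seq_len(nrow(want)), function(i)
        sum(pos >= want$start[i] - 49 & pos < want$end[i]) >= 2, logical(1))]
    expect_equal(isl[, .(start, end)], want)
})

test_that("junction graph applies the shared-splice-site fraction rule", {
    p <- assembly_params()
    # single junction, any support >= 1 is kept
    j1 <- junction_graph(mk_aln("r1", 0, "25M100N25M"), p)
    expect_equal(nrow(j1), 1L)
    expect_equal(c(j1$donor, j1$acceptor), c(25, 125))
    # J2 shares the donor with a 100-supported J1 and has 5 < 0.1 * 100
    a <- rbind(
        mk_aln(sprintf("a%d", 1:100), 0, "25M100N25M"),
        mk_aln(sprintf("b%d", 1:5), 0, "25M200N25M"))
    jj <- junction_graph(a, p)
    expect_equal(nrow(jj), 1L)
    expect_equal(jj$acceptor, 125)
    # degenerate threshold keeps all
    jj0 <- junction_graph(a, assembly_params(junction_fraction = 0))
    expect_equal(nrow(jj0), 2L)
})

test_that("transcript calling chains islands and prunes minor isoforms", {
    p <- assembly_params()
    isl <- data.table::data.table(
        contig = "c1", strand = "+",
        start = c(0, 200, 500), end = c(100, 300, 600),
        support = c(90L, 90L, 15L))
    # A-B strong, A-C weak (10 < 0.3 * 90)
    jn <- data.table::data.table(
        contig = "c1", strand = "+",
        donor = c(100, 100), acceptor = c(200, 500),
        support = c(90L, 10L))
    tx <- call_transcripts(isl, jn, p)
    ne <- tx_n_exons(tx)
    multi <- names(ne[ne >= 2])
    expect_length(multi, 1L)
    expect_equal(tx[transcript_id == multi, .(start, end)],
                 data.table::data.table(start = c(0, 200), end = c(100, 300)))
    # the orphaned island C is reported as a single-exon model
    expect_equal(sum(ne == 1), 1L)
    # islands only -> all single-exon
    solo <- call_transcripts(isl, jn[0], p)
    expect_true(all(tx_n_exons(solo) == 1L))
    # 2 islands + 1 junction -> one 2-exon transcript
    duo <- call_transcripts(isl[1:2],
                            jn[1][, support := 5L], p)
    expect_equal(unname(tx_n_exons(duo)), 2L)
})

test_that("summary counts recompute from models and partition them", {
    expect_equal(annotate_counts(
        tx_table(character(0), character(0), character(0), character(0),
                 numeric(0), numeric(0))),
        list(n_multi_exon = 0L, n_single_exon = 0L, mean_length = NaN))
    tx <- rbind(
        tx_table("t1", "g", "c", "+", c(0, 200), c(100, 260)),
        tx_table("t2", "g", "c", "+", c(400, 600), c(500, 640)),
        tx_table("t3", "g", "c", "+", 900, 950))
    s <- annotate_counts(tx)
    expect_equal(s$n_multi_exon, 2L)
    expect_equal(s$n_single_exon, 1L)
    expect_equal(s$mean_length, mean(c(160, 140, 50)))
    expect_equal(s$n_multi_exon + s$n_single_exon,
                 length(unique(tx$transcript_id)))
})

test_that("assembly recovers expressed junctions and is support-monotone", {
    tr <- small_world()$truth
    ex <- make_expression_truth(tr)
    srs <- simulate_short_reads(tr, ex, 30000L, seed = 8L)
    reads <- srs$intact_rep1$reads
    mp <- mapping_params(max_mismatches = 0L)
    aln <- map_reads(reads[, .(read_id, seq, read_quality)], tr$genome,
                     annotation = tr$tx, params = mp)
    filt <- quality_filter(aln, mp)
    models <- assemble_transcripts(filt)
    # every called junction is a truth junction (full annotation, no errors)
    called <- unique(tx_junctions(models)[, .(contig, strand, donor,
                                              acceptor)])
    ev <- evaluate_against_truth(called, truth_junctions(tr), "junctions")
    expect_equal(ev$fp, 0L)
    # junctions of well-covered transcripts are all found:
    # count junction-read support directly
    jg <- junction_graph(filt)
    well <- jg[support >= 2]
    expect_gt(nrow(well), 0)
    expect_true(all(well[, paste(contig, strand, donor, acceptor)] %in%
                    called[, paste(contig, strand, donor, acceptor)]))
    # exons in a model never overlap, spliced length is the exon-length sum
    lens <- tx_spliced_lengths(models)
    expect_true(all(lens > 0))
    # raising the support floor never yields more models
    m3 <- assemble_transcripts(filt, assembly_params(min_unique_reads = 6L))
    expect_lte(length(unique(m3$transcript_id)),
               length(unique(models$transcript_id)))
})
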