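test_that("super-genes union exons per contig strand with exact coord maps", {
    set.seed(13)
    genome <- c(c1 = random_dna_str(2000), c2 = random_dna_str(1500))
    models <- rbind(
        tx_table("t1", "g1", "c1", "+", c(100, 300), c(200, 400)),
        tx_table("t2", "g2", "c1", "+", c(180, 600), c(260, 700)),
        tx_table("t3", "g3", "c1", "-", 800, 950),
        tx_table("t4", "g4", "c2", "+", 10, 200))
    sgs <- build_supergenes(models, genome)
    expect_length(sgs, 3L)  # c1+, c1-, c2+
    sg <- sgs[["sg_c1_plus"]]
    expect_equal(unname(sg$blocks),
                 matrix(c(100, 300, 600, 260, 400, 700), ncol = 2),
                 ignore_attr = TRUE)
    expect_equal(nchar(sg$cdna), sum(sg$blocks[, 2] - sg$blocks[, 1]))
    # bijective coordinate map, verified base by base against brute force
    for (s in names(sgs)) {
        sgx <- sgs[[s]]
        total <- sum(sgx$blocks[, 2] - sgx$blocks[, 1])
        gmap <- unlist(lapply(seq_len(nrow(sgx$blocks)), function(i)
            sgx$blocks[i, 1]:(sgx$blocks[i, 2] - 1)))
        if (sgx$strand == "-") gmap <- rev(gmap)
        expect_equal(sg_cdna_to_genome(sgx, 0:(total - 1)), gmap)
        expect_equal(anyDuplicated(gmap), 0L)
        # cdna sequence equals the base-wise extraction
        base_by_base <- paste(substring(genome[[sgx$contig]],
                                        gmap + 1, gmap + 1), collapse = "")
        if (sgx$strand == "-")
            base_by_base <- chartr("ACGT", "TGCA", base_by_base)
        expect_equal(sgx$cdna, base_by_base)
    }
    # single single-exon model: identity map
    one <- build_supergenes(tx_table("t", "g", "c2", "+", 50, 120), genome)
    expect_equal(sg_cdna_to_genome(one[[1]], 0:69), 50:119)
    expect_error(build_supergenes(tx_table("t", "g", "nope", "+", 0, 10),
                                  genome), "unknown contig")
})

test_that("rescue candidates are the high-quality unmapped/partial reads", {
    reads <- data.table::data.table(
        read_id = c("full", "part", "unm", "lowq"),
        seq = strrep("A", 50),
        read_quality = c(30, 30, 30, 5))
    aln <- data.table::data.table(
        read_id = c("full", "part", "unm", "lowq"),
        contig = "c", pos = 0, strand = "+",
        cigar = c("50M", "20S30M", NA, NA), score = c(50, 24, 0, 0),
        uniqueness = c("unique", "partial", "unmapped", "unmapped"),
        read_quality = c(30, 30, 30, 5), target_space = "genome", seq = "A")
    cand <- select_rescue_candidates(aln, reads, mapping_params())
    expect_setequal(cand$read_id, c("part", "unm"))
})

test_that("split rescue projects through block boundaries with anchors", {
    set.seed(23)
    genome <- c(c1 = random_dna_str(1200))
    models <- tx_table(c("t1", "t1"), "g1", "c1", "+",
                       c(100, 300), c(200, 400))
    sgs <- build_supergenes(models, genome)
    mp <- mapping_params(max_mismatches = 0L)
    # candidate straddling the two blocks 30/20
    straddle <- paste0(substring(genome, 171, 200), substring(genome, 301, 320))
    inside <- substring(genome, 110, 159)
    nowhere <- random_dna_str(50)
    cand <- data.table::data.table(
        read_id = c("straddle", "inside", "nowhere"),
        seq = c(straddle, inside, nowhere), read_quality = 30)
    resc <- rescue_split_reads(cand, sgs, mp, min_anchor = 10L)
    expect_equal(resc[read_id == "straddle", cigar], "30M100N20M")
    expect_equal(resc[read_id == "straddle", pos], 170)
    expect_equal(resc[read_id == "inside", cigar], "50M")
    expect_false("nowhere" %in% resc$read_id)
    # anchors below 10 bp suppress the junction
    thin <- paste0(substring(genome, 156, 200), substring(genome, 301, 305))
    r2 <- rescue_split_reads(data.table::data.table(
        read_id = "thin", seq = thin, read_quality = 30), sgs, mp)
    expect_false("thin" %in% r2$read_id)
})

test_that("alignment merging prefers rescued split placements", {
    orig <- data.table::data.table(
        read_id = c("a", "b"), contig = "c", pos = c(0, 10), strand = "+",
        cigar = c("35M15S", "50M"), score = c(35, 50),
        uniqueness = c("partial", "unique"), read_quality = 30,
        target_space = "genome", seq = "A")
    expect_identical(merge_alignments(orig, orig[0]), orig)
    resc <- data.table::data.table(
        read_id = c("a", "c"), contig = "c", pos = c(0, 99), strand = "+",
        cigar = c("35M100N15M", "50M"), score = c(50, 50),
        uniqueness = "unique", read_quality = 30,
        target_space = "supergene", seq = "A")
    comb <- merge_alignments(orig, resc)
    expect_equal(nrow(comb), 3L)
    expect_equal(comb[read_id == "a", cigar], "35M100N15M")
    # disjoint sets union cleanly
    comb2 <- merge_alignments(orig, resc[read_id == "c"])
    expect_equal(nrow(comb2), 3L)
})

test_that("iterative rescue recovers withheld junctions and is monotone", {
    w <- small_world()
    tr <- w$truth
    genes <- data.table::copy(tr$genes)
    genes[, baseline := ifelse(is_pseudogene_copy, 0, 100)]
    tr$genes <- genes
    ex <- make_expression_truth(tr)
    srs <- simulate_short_reads(tr, ex, 15000L, seed = 11L)
    reads <- srs$intact_rep1$reads
    wh <- withhold_junctions(tr$tx, 0.5, seed = 2L)
    mp <- mapping_params(max_mismatches = 0L)
    aln <- map_reads(reads[, .(read_id, seq, read_quality)], tr$genome,
                     annotation = wh$tx, params = mp)
    out <- iterate_rescue(aln, reads, tr$genome, map_params = mp,
                          max_rounds = 2L)
    led <- out$ledger
    # junction set only ever grows, and rescue found something to add
    expect_true(all(diff(led$n_junctions) >= 0))
    expect_gt(led$n_junctions[2], led$n_junctions[1])
    expect_gt(led$n_rescued_reads[2], 0)
    # fixed point: round 2 adds nothing on this fixture
    expect_equal(led$n_junctions[3], led$n_junctions[2])
    # every junction assembled after rescue is a truth junction
    pj <- unique(tx_junctions(out$models)[, .(contig, strand, donor,
                                              acceptor)])
    ev <- evaluate_against_truth(pj, truth_junctions(tr), "junctions")
    expect_gte(ev$precision, 0.95)
    # data with no partial/unmapped reads: one round, flat ledger
    full_aln <- map_reads(reads[1:2000, .(read_id, seq, read_quality)],
                          tr$genome, annotation = tr$tx, params = mp)
    out2 <- iterate_rescue(full_aln, reads[1:2000], tr$genome,
                           map_params = mp, max_rounds = 3L)
    expect_equal(out2$ledger$n_junctions[2], out2$ledger$n_junctions[1])
    expect_lte(nrow(out2$ledger), 3L)
})
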