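test_that("seed index retrieves every k-mer position", {
    # L - k + 1 entries: 12-mer with k = 8 gives 5 seed positions
    idx <- build_index(c(s = "ACGTACGTACGT"), k = 8)
    expect_equal(nrow(idx$index), 5L)
    expect_error(build_index(c(s = "ACGTACGT"), k = 3), "k")
    expect_error(build_index(c(s = "ACGTA"), k = 8), "shortest")
    expect_equal(nrow(build_index(character(0), 16)$index), 0L)

    set.seed(9)
    ctg <- c(c1 = random_dna_str(10000))
    idx2 <- build_index(ctg, 16)
    starts <- sample(0:(10000 - 16), 50)
    for (s in starts) {
        km <- substr(ctg, s + 1, s + 16)
        hits <- index_lookup(idx2, km)
        # the sampled position is among the retrieved ones
        expect_true(s %in% hits$pos)
        # and every retrieved position really carries that k-mer
        expect_true(all(substring(ctg, hits$pos + 1, hits$pos + 16) == km))
    }
})

test_that("reads map to their true origins; junctions and repeats behave", {
    tr <- small_world()$truth
    ex <- make_expression_truth(tr)
    srs <- simulate_short_reads(tr, ex, 8000L, seed = 21L)
    reads <- srs$intact_rep1$reads
    mp <- mapping_params(max_mismatches = 0L)
    aln <- map_reads(reads[, .(read_id, seq, read_quality)], tr$genome,
                     annotation = tr$tx, params = mp)
    expect_setequal(aln[, unique(uniqueness)],
                    intersect(c("unique", "multi", "partial", "unmapped"),
                              aln$uniqueness))
    # with the full annotation, essentially every read is placed
    st <- aln[, .(u = uniqueness[1]), by = read_id]
    expect_gt(mean(st$u %in% c("unique", "multi")), 0.99)
    # unique full-length genome alignments sit exactly at their origin
    ann <- tx_junctions(tr$tx)
    g <- aln[uniqueness == "unique" & target_space == "genome" &
             !grepl("N|S", cigar)]
    chk <- merge(g, reads, by = "read_id")
    seqs <- tx_sequences(tr$tx, tr$genome)
    # re-derive the genomic substring and compare to the read
    ok <- vapply(seq_len(min(nrow(chk), 300)), function(i) {
        s <- substring(tr$genome[[chk$contig[i]]], chk$pos[i] + 1,
                       chk$pos[i] + 50)
        if (chk$strand[i] == "-") s <- revcomp(s)
        s == chk$seq.y[i] || s == chk$seq.x[i]
    }, logical(1))
    expect_true(all(ok))
    # junction-spanning reads carry an N gap matching a truth intron
    spl <- aln[uniqueness == "unique" & grepl("N", cigar)]
    expect_gt(nrow(spl), 0)
    jb <- planartx:::alignment_blocks(spl[1:min(.N, 200)])
    jt <- truth_junctions(tr)
    two <- jb[, .N, by = read_id][N >= 2, read_id]
    for (rid in head(two, 50)) {
        b <- jb[read_id == rid][order(start)]
        hit <- jt[contig == b$contig[1] & donor == b$end[1] &
                  acceptor == b$start[2]]
        expect_equal(nrow(hit), 1L)
    }
})

test_that("reads from duplicated loci are flagged multi", {
    set.seed(31)
    core <- random_dna_str(600)
    genome <- c(c1 = paste0(random_dna_str(500), core, random_dna_str(500)),
                c2 = paste0(random_dna_str(300), core, random_dna_str(700)))
    read <- substr(core, 101, 150)
    aln <- map_read(list(read_id = "r", seq = read, read_quality = 30),
                    genome, params = mapping_params(max_mismatches = 0L))
    expect_true(all(aln$uniqueness == "multi"))
    expect_setequal(aln$contig, c("c1", "c2"))
})

test_that("projection to genome agrees with per-base brute force", {
    set.seed(17)
    for (rep in 1:40) {
        n_ex <- sample(2:5, 1)
        lens <- sample(80:250, n_ex, TRUE)
        gaps <- sample(50:400, n_ex - 1, TRUE)
        starts <- cumsum(c(sample(100:500, 1), head(lens, -1) + gaps))
        exons <- cbind(starts, starts + lens)
        strand <- sample(c("+", "-"), 1)
        total <- sum(lens)
        s <- sample(0:(total - 30), 1); e <- s + sample(20:min(60, total - s), 1)
        model <- tx_table("t", "g", "c1", strand,
                          exons[, 1], exons[, 2])
        p <- project_to_genome(list(tstart = s, tend = e, read_strand = "+"),
                               model)
        got <- parse_cigar(p$cigar, p$pos)$blocks
        want <- oracle_blocks(exons, strand, s, e)
        expect_equal(unname(got), unname(want))
        expect_equal(p$strand, strand)
    }
    # crossing the transcript end errors
    model <- tx_table("t", "g", "c1", "+", c(0, 300), c(100, 400))
    expect_error(project_to_genome(list(tstart = 150, tend = 260,
                                        read_strand = "+"), model),
                 "outside")
    # worked case: exons [0,100)+[300,400), cDNA hit [90,110)
    p <- project_to_genome(list(tstart = 90, tend = 110, read_strand = "+"),
                           model)
    expect_equal(p$pos, 90)
    expect_equal(p$cigar, "10M200N10M")
})

test_that("quality filter applies both predicates and is idempotent", {
    set.seed(5)
    n <- 1000
    aln <- data.table::data.table(
        read_id = sprintf("r%d", 1:n), contig = "c", pos = 0, strand = "+",
        cigar = "50M", score = sample(10:50, n, TRUE),
        uniqueness = sample(c("unique", "multi", "partial", "unmapped"),
                            n, TRUE),
        read_quality = round(runif(n, 5, 40), 1),
        target_space = "genome", seq = "A")
    p <- mapping_params()
    kept <- quality_filter(aln, p)
    # brute-force recount under the two predicates
    manual <- aln[uniqueness != "unmapped" &
                  read_quality >= p$min_read_quality &
                  score >= p$min_mapping_score]
    expect_equal(kept, manual)
    expect_equal(quality_filter(kept, p), kept)
})
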