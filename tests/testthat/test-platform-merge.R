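test_that("homology screen enforces the 95% / 50 nt rule", {
    set.seed(71)
    subj <- c(s1 = random_dna_str(500), s2 = random_dna_str(450))
    q_100 <- paste0(random_dna_str(40), substr(subj[["s1"]], 201, 300),
                    random_dna_str(40))      # 100 nt exact shared
    q_49 <- paste0(random_dna_str(60), substr(subj[["s2"]], 101, 149),
                   random_dna_str(60))       # 49 nt exact only
    scr <- homology_screen(c(qa = q_100, qb = q_49, qz = random_dna_str(300)),
                           subj)
    expect_setequal(scr$matched, "qa")
    expect_setequal(scr$unmatched, c("qb", "qz"))
    expect_equal(scr$hits[query == "qa", subject], "s1")
    # reverse strand hits count
    scr2 <- homology_screen(c(qr = as.character(revcomp(q_100))), subj)
    expect_equal(scr2$matched, "qr")
    # a 60 nt segment at ~90% identity fails the identity gate
    seg <- substr(subj[["s1"]], 101, 160)
    mut <- strsplit(seg, "")[[1]]
    at <- seq(5, 60, by = 10)
    mut[at] <- vapply(mut[at], function(b)
        sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))
    q_low <- paste0(random_dna_str(100), paste(mut, collapse = ""),
                    random_dna_str(100))
    scr3 <- homology_screen(c(ql = q_low), subj)
    expect_false("ql" %in% scr3$matched)
})

test_that("seeded local alignment agrees with a reference aligner", {
    set.seed(73)
    params <- merge_params()
    n_checked <- 0L
    for (i in 1:200) {
        shared_len <- sample(30:150, 1)
        shared <- random_dna_str(shared_len)
        a <- paste0(random_dna_str(sample(20:120, 1)), shared,
                    random_dna_str(sample(20:120, 1)))
        b <- paste0(random_dna_str(sample(20:120, 1)), shared,
                    random_dna_str(sample(20:120, 1)))
        got <- planartx:::seeded_local_align(a, b, params)
        want <- oracle_local(a, b)
        if (is.null(got)) {
            # seeding can only miss when the shared run is short
            expect_lt(shared_len, params$k + 4)
            next
        }
        n_checked <- n_checked + 1L
        # optimal score must agree exactly; co-optimal tracebacks may
        # differ in length, so length agreement is checked to the slack a
        # score-neutral extension can introduce
        expect_equal(got$score, want$score)
        expect_lte(abs(got$len - want$len), 6)
    }
    expect_gt(n_checked, 150)
})

test_that("homology decisions agree with the reference aligner's decisions", {
    set.seed(74)
    params <- merge_params()
    agree <- 0L; total <- 0L
    for (i in 1:100) {
        # clear positives (>= 70 nt exact) and clear negatives (<= 35 nt)
        shared_len <- sample(c(20:35, 70:150), 1)
        shared <- random_dna_str(shared_len)
        a <- paste0(random_dna_str(60), shared, random_dna_str(60))
        b <- paste0(random_dna_str(60), shared, random_dna_str(60))
        scr <- homology_screen(c(q = a), c(s = b), params)
        want <- oracle_local(a, b)
        o_matched <- want$len >= params$min_match_length &&
            want$matches / want$len >= params$min_identity
        total <- total + 1L
        if (("q" %in% scr$matched) == o_matched) agree <- agree + 1L
    }
    expect_equal(agree, total)
})

test_that("isoform collapse merges terminal variants only", {
    set.seed(79)
    base <- random_dna_str(700)
    ext3 <- paste0(base, random_dna_str(50))
    out <- collapse_isoforms(c(a = base, b = ext3))
    expect_length(out$contigs, 1L)
    expect_equal(nchar(out$contigs[[1]]), 750)
    expect_setequal(out$members[[1]], c("a", "b"))
    # identical duplicates collapse
    out2 <- collapse_isoforms(c(a = base, b = base))
    expect_length(out2$contigs, 1L)
    # an internal cassette keeps the isoforms apart
    cassette <- paste0(substr(base, 1, 350), random_dna_str(120),
                       substr(base, 351, 700))
    out3 <- collapse_isoforms(c(a = base, b = cassette))
    expect_length(out3$contigs, 2L)
    # staggered 5'/3' extensions produce the superstring
    left <- paste0(random_dna_str(60), substr(base, 1, 500))
    right <- substr(base, 1, 700)
    out4 <- collapse_isoforms(c(a = left, b = right))
    expect_length(out4$contigs, 1L)
    expect_equal(nchar(out4$contigs[[1]]), 760)
})

test_that("dataset merging applies the published decision cascade", {
    set.seed(83)
    # empty short-read set: merged set is the long-read set
    L <- c(l1 = random_dna_str(500), l2 = random_dna_str(450),
           l3 = random_dna_str(400))
    m0 <- merge_datasets(L, setNames(character(0), character(0)),
                         setNames(integer(0), character(0)))
    expect_equal(m0$final_transcripts, 3L)
    expect_true(all(m0$provenance$provenance == "longread_only"))

    # 1 matching short (terminal extension of l1), 1 unmatched 2-exon,
    # 2 unmatched 1-exon
    sh <- c(s_match = paste0(substr(L[["l1"]], 51, 500), random_dna_str(60)),
            s_multi = random_dna_str(300),
            s_one1 = random_dna_str(250), s_one2 = random_dna_str(250))
    ne <- c(s_match = 2L, s_multi = 2L, s_one1 = 1L, s_one2 = 1L)
    m <- merge_datasets(L, sh, ne)
    expect_equal(m$n_matched_short, 1L)
    expect_equal(m$n_unmatched_multi_exon_kept, 1L)
    expect_equal(m$n_unmatched_single_exon_dropped, 2L)
    expect_equal(m$n_assembled_contigs, 1L)          # l1 + s_match collapse
    expect_equal(m$n_singletons_kept, 3L)            # l2, l3, s_multi
    expect_equal(m$n_singletons_dropped_single_exon, 0L)
    expect_equal(m$final_transcripts,
                 m$n_assembled_contigs + m$n_singletons_kept)
    expect_true("combined" %in% m$provenance$provenance)
    # decision log covers every dropped id with the single-exon reason
    dropped <- m$log[action == "dropped"]
    expect_setequal(dropped$id, c("s_one1", "s_one2"))
    expect_error(merge_datasets(L, sh, ne[-1]), "exon counts")
    # byte-stable report on a fixed fixture
    m2 <- merge_datasets(L, sh, ne)
    expect_identical(m$log, m2$log)
    expect_identical(m$final_seqs, m2$final_seqs)
})

test_that("merge never drops multi-exon short-read-only transcripts", {
    set.seed(89)
    L <- c(l1 = random_dna_str(600))
    sh <- c(m1 = random_dna_str(320), m2 = random_dna_str(340),
            s1 = random_dna_str(260))
    ne <- c(m1 = 3L, m2 = 2L, s1 = 1L)
    m <- merge_datasets(L, sh, ne)
    # the multi-exon short-read-only transcripts survive into the final set
    expect_true(all(c("m1", "m2") %in% names(m$final_seqs)))
    # every dropped sequence is single-exon and unmatched
    drop <- m$log[action == "dropped", id]
    expect_true(all(ne[drop] == 1L))
    expect_true(all(drop %in% c(m$log[step == "partition" &
                                      action == "dropped", id],
                                m$log[step == "singleton_filter" &
                                      action == "dropped", id])))
})

test_that("reciprocal set comparison quantifies redundancy", {
    set.seed(97)
    x <- random_dna_str(400)
    # a 96%-identical copy of x
    ch <- strsplit(x, "")[[1]]
    at <- sample(400, 16)
    ch[at] <- vapply(ch[at], function(b)
        sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))
    xp <- paste(ch, collapse = "")
    both <- compare_annotation(c(x = x), c(x = x, xp = xp))
    expect_equal(both$a_with_hit_in_b, 1L)
    expect_equal(both$b_with_hit_in_a, 2L)
    none <- compare_annotation(c(a = random_dna_str(300)),
                               c(b = random_dna_str(300)))
    expect_equal(unlist(none), c(a_with_hit_in_b = 0L, b_with_hit_in_a = 0L))
    same <- compare_annotation(c(x = x), c(x = x))
    expect_equal(unlist(same), c(a_with_hit_in_b = 1L, b_with_hit_in_a = 1L))
})
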