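test_that("unique-read counting and RPKM follow their definitions", {
    aln <- data.table::data.table(
        read_id = sprintf("r%d", 1:10),
        contig = c(rep("T1", 7), rep("T2", 3)),
        pos = 0, strand = "+", cigar = "50M", score = 50,
        uniqueness = c(rep("unique", 7), rep("multi", 3)),
        read_quality = 30, target_space = "transcript", seq = "A")
    cnt <- count_unique_reads(aln, c("T1", "T2", "T3"))
    expect_equal(unname(cnt), c(7L, 0L, 0L))
    expect_equal(sum(cnt), nrow(aln[uniqueness == "unique"]))
    expect_equal(count_unique_reads(aln[0], "T1"), c(T1 = 0L))

    expect_equal(rpkm(0, 1e6, 1000), 0)
    expect_equal(rpkm(100, 1e6, 1000), 100)
    expect_equal(rpkm(50, 2e7, 500), 5)
    expect_error(rpkm(1, 0, 10), "positive")
    # linearity: doubling count and total leaves RPKM unchanged;
    # doubling count at fixed total doubles it
    expect_equal(rpkm(20, 2e6, 700), rpkm(40, 4e6, 700))
    expect_equal(rpkm(40, 2e6, 700), 2 * rpkm(20, 2e6, 700))
})

test_that("the low-expression filter keeps any transcript reaching RPKM 1", {
    counts <- matrix(c(5, 8, 2, 9,
                       1, 0, 0, 0,
                       0, 0, 0, 0), nrow = 3, byrow = TRUE,
                     dimnames = list(c("hi", "edge", "zero"), NULL))
    # craft lengths/totals so RPKM of "edge" is exactly >= 1 in sample 1
    samples <- data.table::data.table(
        sample_id = sprintf("s%d", 1:4),
        condition = rep(c("intact", "irradiated"), each = 2),
        replicate = rep(1:2, 2))
    et <- expression_table(counts, c(hi = 1000, edge = 1000, zero = 1000),
                           samples)
    f <- expression_filter(et, de_params(min_rpkm = 1))
    expect_true("hi" %in% rownames(f$counts))
    expect_false("zero" %in% rownames(f$counts))
    # RPKMs below 1 everywhere are removed
    low <- et$rpkm["edge", ]
    expect_equal("edge" %in% rownames(f$counts), any(low >= 1))
    # empty table stays empty
    f0 <- expression_filter(expression_table(
        counts[0, , drop = FALSE], numeric(0), samples))
    expect_equal(nrow(f0$counts), 0L)
})

test_that("signed fold change reproduces the published sign convention", {
    expect_equal(round(fold_change(275.7, 19.3), 2), -14.28)
    expect_equal(round(fold_change(134.7, 0.65), 2), -207.23)
    expect_equal(fold_change(10, 10), 1)
    expect_equal(fold_change(5, 20), 4)
    # antisymmetry and sentinels
    expect_equal(fold_change(7, 3), -fold_change(3, 7))
    expect_equal(fold_change(5, 0), -Inf)
    expect_equal(fold_change(0, 5), Inf)
})

test_that("the weighted proportion test is symmetric, Welch-limiting and calibrated", {
    # identical groups: statistic 0, p = 1
    bt <- baggerly_test(c(100, 120), c(1e6, 1e6), c(100, 120), c(1e6, 1e6))
    expect_equal(bt$statistic, 0)
    expect_equal(bt$p_value, 1)
    expect_error(baggerly_test(1, 0, 1, 10), "total")

    # equal totals with between-replicate variance dominating reduces to
    # Welch's two-sample t-test on the proportions
    ca <- c(5000, 9000, 7000); cb <- c(2000, 2600, 1400)
    n <- rep(1e6, 3)
    bt2 <- baggerly_test(ca, n, cb, n)
    tt <- t.test(ca / n, cb / n)
    expect_equal(bt2$statistic, unname(tt$statistic), tolerance = 1e-9)
    expect_equal(bt2$p_value, tt$p.value, tolerance = 1e-9)

    # type-I error calibration on the null: common proportion 1e-4,
    # totals 1e6, 2+2 replicates, 10,000 transcripts
    set.seed(107)
    n_tx <- 10000
    rej <- logical(n_tx)
    for (i in seq_len(n_tx)) {
        xa <- rbinom(2, 1e6, 1e-4); xb <- rbinom(2, 1e6, 1e-4)
        rej[i] <- baggerly_test(xa, c(1e6, 1e6), xb,
                                c(1e6, 1e6))$p_value < 0.05
    }
    expect_gte(mean(rej), 0.035)
    expect_lte(mean(rej), 0.065)
})

de_gate <- function(p, fc, params = de_params())
    p < params$alpha & fc <= -params$min_fold

test_that("differential expression applies the p and fold gates", {
    set.seed(109)
    n <- 60
    lens <- rep(1000, n)
    names(lens) <- sprintf("T%02d", 1:n)
    base <- 10^runif(n, 1.2, 3)
    dep <- 1:15                     # depleted 14.28-fold
    rate_irr <- base
    rate_irr[dep] <- base[dep] / 14.28
    tot <- 1e6
    counts <- cbind(
        rmultinom(2, tot, base),
        rmultinom(2, tot, rate_irr))
    rownames(counts) <- names(lens)
    samples <- data.table::data.table(
        sample_id = c("i1", "i2", "r1", "r2"),
        condition = c("intact", "intact", "irradiated", "irradiated"),
        replicate = c(1, 2, 1, 2))
    et <- expression_filter(expression_table(counts, lens, samples))
    de <- differential_expression(et)
    expect_true(all(de[passes == TRUE, p_value] < 0.01))
    expect_true(all(de[passes == TRUE, fold_change] <= -2))
    # the strongly depleted transcripts dominate the passing set
    expect_gte(sum(de[passes == TRUE, transcript_id] %in%
                   names(lens)[dep]), 13)
    expect_lte(sum(de[passes == TRUE, !transcript_id %in%
                      names(lens)[dep]]), 2)
    # explicit gate arithmetic
    expect_true(de_gate(0.005, -2.5))
    expect_false(de_gate(0.005, -1.5))
    expect_false(de_gate(0.02, -10))
})

test_that("replicate congruency is high for true replicates, ~0 for noise", {
    set.seed(113)
    n <- 5000
    lens <- setNames(rep(1000, n), sprintf("T%04d", 1:n))
    rates <- 10^runif(n, 0, 3)
    samples <- data.table::data.table(
        sample_id = c("i1", "i2", "r1", "r2"),
        condition = c("intact", "intact", "irradiated", "irradiated"),
        replicate = c(1, 2, 1, 2))
    # proper replicates: shared rates, multinomial noise at depth 1e6
    counts <- cbind(rmultinom(2, 1e6, rates), rmultinom(2, 1e6, rates))
    rownames(counts) <- names(lens)
    rc <- replicate_congruency(expression_table(counts, lens, samples))
    expect_true(all(rc$r > 0.95))
    # independent noise-only tables decorrelate
    counts2 <- cbind(rmultinom(1, 1e6, 10^runif(n, 0, 3)),
                     rmultinom(1, 1e6, 10^runif(n, 0, 3)),
                     rmultinom(1, 1e6, 10^runif(n, 0, 3)),
                     rmultinom(1, 1e6, 10^runif(n, 0, 3)))
    rownames(counts2) <- names(lens)
    rc2 <- replicate_congruency(expression_table(counts2, lens, samples))
    expect_true(all(abs(rc2$r) < 0.1))
    # duplicated replicate: correlation exactly 1
    counts3 <- counts[, c(1, 1, 3, 3)]
    rownames(counts3) <- names(lens)
    rc3 <- replicate_congruency(expression_table(counts3, lens, samples))
    expect_equal(rc3$r, c(1, 1))
})
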