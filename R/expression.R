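#' Differential-expression parameters
#'
#' Defaults mirror the published selection rule: discard transcripts below
#' RPKM 1 in every sample, call significance at raw p < 0.01, and require a
#' fold decrease of more than 2 in the irradiated condition.
#'
#' @param min_rpkm low-expression floor.
#' @param alpha raw p-value threshold.
#' @param min_fold minimum fold decrease.
#' @return object of class `de_params`.
#' @export
de_params <- function(min_rpkm = 1.0, alpha = 0.01, min_fold = 2.0) {
    stopifnot(min_rpkm > 0, alpha > 0, min_fold > 0)
    structure(as.list(environment()), class = "de_params")
}

#' Count uniquely mapped reads per transcript
#'
#' A read increments exactly one transcript: its unique placement.  Multi-
#' mapped and unmapped records contribute nothing.
#'
#' @param alignments transcript-space alignment table (`contig` holds the
#'   transcript id).
#' @param transcript_ids universe of transcripts to report (zero-filled).
#' @return named integer vector of counts.
#' @export
count_unique_reads <- function(alignments, transcript_ids) {
    out <- setNames(integer(length(transcript_ids)), transcript_ids)
    u <- alignments[uniqueness == "unique"]
    if (nrow(u)) {
        # one placement per read (defensive; unique status implies it)
        u <- u[, head(.SD, 1L), by = read_id]
        tab <- u[, .N, by = contig]
        hit <- tab$contig %in% transcript_ids
        out[tab$contig[hit]] <- tab$N[hit]
    }
    out
}

#' Reads per kilobase per million mapped reads
#'
#' @param count unique-read count.
#' @param total_mapped total mapped reads in the sample.
#' @param length_bp transcript length in bp.
#' @return RPKM value(s); `1e9 * count / (total_mapped * length_bp)`.
#' @export
rpkm <- function(count, total_mapped, length_bp) {
    if (any(total_mapped <= 0) || any(length_bp <= 0))
        stop("total_mapped and length_bp must be positive")
    1e9 * count / (total_mapped * length_bp)
}

#' Build an expression table from per-sample counts
#'
#' @param counts matrix (transcripts x samples) of unique-read counts.
#' @param lengths named numeric vector of transcript lengths (bp).
#' @param samples `data.table` with `sample_id`, `condition`, `replicate`
#'   in column order of `counts`.
#' @return list of class `expression_table`: `counts`, `rpkm`, `lengths`,
#'   `samples`, `total_mapped`.
#' @export
expression_table <- function(counts, lengths, samples) {
    stopifnot(ncol(counts) == nrow(samples),
              all(rownames(counts) %in% names(lengths)))
    total <- colSums(counts)
    rp <- sweep(sweep(counts, 2, total, "/"), 1,
                lengths[rownames(counts)], "/") * 1e9
    structure(list(counts = counts, rpkm = rp,
                   lengths = lengths[rownames(counts)],
                   samples = as.data.table(samples), total_mapped = total),
              class = "expression_table")
}

#' Drop transcripts with near-zero expression in every sample
#'
#' A transcript is kept iff its RPKM reaches `min_rpkm` in at least one
#' sample.
#'
#' @param table an `expression_table`.
#' @param params a [de_params()] object.
#' @return filtered `expression_table` (totals are kept from the full
#'   table; filtering is a reporting decision, not a remapping).
#' @export
expression_filter <- function(table, params = de_params()) {
    keep <- apply(table$rpkm, 1L, max) >= params$min_rpkm
    structure(list(counts = table$counts[keep, , drop = FALSE],
                   rpkm = table$rpkm[keep, , drop = FALSE],
                   lengths = table$lengths[keep],
                   samples = table$samples,
                   total_mapped = table$total_mapped),
              class = "expression_table")
}

#' Signed fold change between condition means
#'
#' Ratio convention used throughout the result tables: with ratio
#' `mean_irradiated / mean_intact` called r, returns r when r >= 1, else
#' `-1/r`,
#' so depletion after irradiation is negative.  Rounding happens only at
#' reporting time.
#'
#' @param mean_intact,mean_irradiated condition means (RPKM).
#' @return signed fold change; `-Inf`/`Inf` sentinels when one mean is 0.
#' @export
fold_change <- function(mean_intact, mean_irradiated) {
    ifelse(mean_irradiated == 0 & mean_intact == 0, 1,
    ifelse(mean_irradiated == 0, -Inf,
    ifelse(mean_intact == 0, Inf, {
        r <- mean_irradiated / mean_intact
        ifelse(r >= 1, r, -1 / r)
    })))
}

#' Weighted two-group proportion test with overdispersion guard
#'
#' Baggerly-style test on the difference of per-replicate proportions
#' `p_i = count_i / total_i`.  Within each group the proportions are
#' combined with library-size weights `w_i = n_i / sum(n_i)`; the variance
#' of the group estimate is the weighted binomial (within-library) term
#' unless the weighted empirical between-replicate term exceeds it
#' significantly -- beyond the 95th percentile of its pure-sampling null
#' scale, `qchisq(0.95, k-1)/(k-1)` times the binomial term -- in which
#' case the larger between-replicate estimate is used (the overdispersion
#' guard of the SAGE literature, gated so that pure sampling noise does
#' not inflate the denominator).  The statistic is referred to a t
#' distribution with Satterthwaite effective degrees of freedom, where a
#' group on its binomial term contributes no degrees-of-freedom penalty
#' (that variance is known, not estimated); if both groups are on their
#' binomial terms the test reduces to a z-test, and with strong
#' between-replicate variance it converges to Welch's t-test on the
#' proportions.  With one replicate per group it degenerates to a
#' two-sample binomial proportion z-test.
#'
#' @param counts_a,counts_b per-replicate counts of the transcript.
#' @param totals_a,totals_b per-replicate library sizes.
#' @return list with `statistic`, `p_value`, `df` (Inf for the normal
#'   reference).
#' @export
baggerly_test <- function(counts_a, totals_a, counts_b, totals_b) {
    if (any(totals_a <= 0) || any(totals_b <= 0)) stop("zero library total")
    grp <- function(x, n) {
        w <- n / sum(n)
        p <- x / n
        phat <- sum(w * p)
        vin <- phat * (1 - phat) / sum(n)       # weighted binomial term
        k <- length(x)
        if (k >= 2L) {
            s2 <- sum(w * (p - phat)^2) / (1 - sum(w^2))
            vbet <- s2 * sum(w^2)
            gate <- qchisq(0.95, k - 1L) / (k - 1L)
        } else { vbet <- 0; gate <- Inf }
        between <- vbet > gate * vin
        list(phat = phat, v = if (between) vbet else vin, k = k,
             between = between)
    }
    a <- grp(counts_a, totals_a)
    b <- grp(counts_b, totals_b)
    num <- a$phat - b$phat
    den <- sqrt(a$v + b$v)
    if (den == 0) return(list(statistic = 0, p_value = 1, df = Inf))
    stat <- num / den
    dterm <- 0
    if (a$between && a$k >= 2L) dterm <- dterm + a$v^2 / (a$k - 1L)
    if (b$between && b$k >= 2L) dterm <- dterm + b$v^2 / (b$k - 1L)
    if (dterm == 0) {
        df <- Inf
        p <- 2 * pnorm(-abs(stat))
    } else {
        df <- (a$v + b$v)^2 / dterm
        p <- 2 * pt(-abs(stat), df)
    }
    list(statistic = stat, p_value = p, df = df)
}

#' Irradiated-versus-intact differential expression
#'
#' Per transcript: pooled condition means of replicate RPKMs, a
#' [baggerly_test()] p-value on the raw counts, the signed
#' [fold_change()], and the selection flag `passes` (p < alpha and fold
#' decrease of at least `min_fold`).  A Benjamini-Hochberg column is
#' emitted for reference but not used for selection, mirroring the raw
#' p-value rule of the original analysis.
#'
#' @param table a filtered `expression_table` with conditions `intact` and
#'   `irradiated`, >= 2 replicates each.
#' @param params a [de_params()] object.
#' @return `data.table` with one row per transcript: means, `fold_change`,
#'   `p_value`, `padj`, `passes`; ordered by p-value.
#' @export
differential_expression <- function(table, params = de_params()) {
    sm <- table$samples
    ia <- which(sm$condition == "intact")
    ib <- which(sm$condition == "irradiated")
    stopifnot(length(ia) >= 1L, length(ib) >= 1L)
    tot <- table$total_mapped
    res <- lapply(rownames(table$counts), function(tx) {
        ca <- table$counts[tx, ia]; cb <- table$counts[tx, ib]
        bt <- baggerly_test(ca, tot[ia], cb, tot[ib])
        mi <- mean(table$rpkm[tx, ia]); mr <- mean(table$rpkm[tx, ib])
        data.table(transcript_id = tx, mean_rpkm_intact = mi,
                   mean_rpkm_irradiated = mr,
                   fold_change = fold_change(mi, mr),
                   p_value = bt$p_value)
    })
    out <- rbindlist(res)
    out[, padj := p.adjust(p_value, method = "BH")]
    out[, passes := p_value < params$alpha & fold_change <= -params$min_fold]
    setorder(out, p_value)
    out[]
}

#' Replicate congruency of RPKM values
#'
#' Pearson correlation of log10 RPKM between the two replicates of each
#' condition, over transcripts detected above RPKM 1 in at least one of the
#' two samples (and non-zero in both, so the log is finite) -- the filter
#' used for the published replicate scatter plots.
#'
#' @param table an `expression_table` with two replicates per condition.
#' @return `data.table` with `condition`, `r`, `n_transcripts`.
#' @export
replicate_congruency <- function(table) {
    sm <- table$samples
    rows <- lapply(unique(sm$condition), function(cond) {
        idx <- which(sm$condition == cond)
        stopifnot(length(idx) == 2L)
        x <- table$rpkm[, idx[1L]]; y <- table$rpkm[, idx[2L]]
        keep <- (x >= 1 | y >= 1) & x > 0 & y > 0
        data.table(condition = cond,
                   r = cor(log10(x[keep]), log10(y[keep])),
                   n_transcripts = sum(keep))
    })
    rbindlist(rows)
}

#' Quantify samples against a transcript set
#'
#' Maps each sample's reads to the transcript sequences (full-length,
#' sense strand), counts uniquely placed reads per transcript and builds
#' the expression table.
#'
#' @param read_sets named list of `read_set` objects (one per sample).
#' @param samples `data.table` with `sample_id`, `condition`, `replicate`
#'   matching `names(read_sets)`.
#' @param tx_seqs named character vector of transcript sequences.
#' @param params a [mapping_params()] object.
#' @return an `expression_table`.
#' @export
quantify_samples <- function(read_sets, samples, tx_seqs,
                             params = mapping_params()) {
    idx <- build_index(tx_seqs[nchar(tx_seqs) >= params$k], params$k)
    counts <- sapply(names(read_sets), function(sn) {
        rd <- read_sets[[sn]]$reads
        hits <- match_full_length(data.table(qid = rd$read_id, seq = rd$seq),
                                  idx, tx_seqs, params$max_mismatches)
        if (nrow(hits) == 0L)
            return(setNames(integer(length(tx_seqs)), names(tx_seqs)))
        hits[, best := max(score), by = qid]
        hits <- hits[score == best]
        hits[, n_hits := .N, by = qid]
        uni <- hits[n_hits == 1L]
        out <- setNames(integer(length(tx_seqs)), names(tx_seqs))
        tab <- uni[, .N, by = sid]
        out[tab$sid] <- tab$N
        out
    })
    expression_table(counts, nchar(tx_seqs), samples)
}
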