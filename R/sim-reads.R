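#' Simulate long (454-like) reads from spliced isoforms
#'
#' Read lengths follow a lognormal targeting the requested mean (default
#' 278 bp, the hallmark of 454 transcriptome runs with Titanium chemistry),
#' truncated to the isoform.  Reads are drawn from expressed isoforms
#' weighted by baseline rate and isoform share, in random orientation, with
#' per-base substitution/indel errors at `error_rate`.
#'
#' @param truth a `gene_truth` object.
#' @param n_reads number of reads.
#' @param mean_length target mean read length in bp.
#' @param error_rate per-base error probability (90% substitutions, 5%
#'   insertions, 5% deletions).
#' @param seed integer RNG seed.
#' @return list of class `read_set`: `reads` (`data.table` with `read_id`,
#'   `seq`, `gene_id`, `isoform`, `offset`, `ori`) and `platform = "long"`.
#' @export
simulate_long_reads <- function(truth, n_reads, mean_length = 278,
                                error_rate = 0.005, seed = 1L) {
    iso <- truth$isoforms[truth$genes[, .(gene_id, baseline)], on = "gene_id"]
    iso <- iso[baseline > 0]
    if (n_reads > 0 && nrow(iso) == 0L)
        stop("no expressed isoform to draw long reads from")
    empty <- data.table(read_id = character(0), seq = character(0),
                        gene_id = character(0), isoform = character(0),
                        offset = integer(0), ori = character(0))
    if (n_reads == 0L)
        return(structure(list(reads = empty, platform = "long"),
                         class = "read_set"))
    seqs <- tx_sequences(truth$tx, truth$genome)
    with_seed(seed, {
        w <- iso$baseline * iso$share
        pick <- sample.int(nrow(iso), n_reads, replace = TRUE, prob = w)
        sdlog <- 0.35
        lens <- pmax(60, round(rlnorm(n_reads,
                                      log(mean_length) - sdlog^2 / 2, sdlog)))
        tid <- iso$transcript_id[pick]
        tlen <- nchar(seqs[tid])
        lens <- pmin(lens, tlen)
        offs <- floor(runif(n_reads) * (tlen - lens + 1))
        ori <- sample(c("+", "-"), n_reads, replace = TRUE)
        rseq <- substring(seqs[tid], offs + 1, offs + lens)
        flip <- ori == "-"
        rseq[flip] <- revcomp(rseq[flip])
        if (error_rate > 0)
            rseq <- vapply(rseq, corrupt_read, character(1),
                           error_rate = error_rate, USE.NAMES = FALSE)
        reads <- data.table(read_id = sprintf("L%06d", seq_len(n_reads)),
                            seq = unname(rseq),
                            gene_id = iso$gene_id[pick], isoform = tid,
                            offset = as.integer(offs), ori = ori)
        structure(list(reads = reads, platform = "long"), class = "read_set")
    })
}

# substitution/indel corruption of a single read
corrupt_read <- function(seq, error_rate) {
    ch <- strsplit(seq, "", fixed = TRUE)[[1L]]
    hit <- which(runif(length(ch)) < error_rate)
    if (length(hit) == 0L) return(seq)
    kind <- sample(c("sub", "ins", "del"), length(hit), replace = TRUE,
                   prob = c(0.9, 0.05, 0.05))
    for (j in seq_along(hit)) {
        i <- hit[j]
        if (kind[j] == "sub") {
            ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1L)
        } else if (kind[j] == "ins") {
            ch[i] <- paste0(sample(c("A", "C", "G", "T"), 1L), ch[i])
        } else ch[i] <- ""
    }
    paste(ch, collapse = "")
}

#' Simulate per-transcript read counts for a sample design
#'
#' Count-level shortcut of [simulate_short_reads()]: the same multinomial
#' sampling of reads over isoforms (weights rate x share x spliced length)
#' without materialising read sequences -- the right tool when only the
#' quantification layer is under study.
#'
#' @inheritParams simulate_short_reads
#' @return matrix of counts, transcripts x samples.
#' @export
simulate_sample_counts <- function(truth, condition_design,
                                   n_reads_per_sample, seed = 1L) {
    des <- as.data.table(condition_design)
    if (any(des$rate < 0)) stop("negative expression multipliers")
    samples <- unique(des[, .(condition, replicate)])
    setorder(samples, condition, replicate)
    seqs <- tx_sequences(truth$tx, truth$genome)
    iso <- copy(truth$isoforms)
    iso[, qlen := nchar(seqs[transcript_id])]
    setorder(iso, transcript_id)
    n_per <- rep_len(n_reads_per_sample, nrow(samples))
    counts <- matrix(0L, nrow = nrow(iso), ncol = nrow(samples),
                     dimnames = list(iso$transcript_id,
                                     sprintf("%s_rep%d", samples$condition,
                                             samples$replicate)))
    for (si in seq_len(nrow(samples))) {
        rates <- des[condition == samples$condition[si] &
                     replicate == samples$replicate[si]]
        tab <- iso[rates, on = "gene_id", nomatch = NULL]
        setorder(tab, transcript_id)
        w <- tab$rate * tab$share * tab$qlen
        if (sum(w) == 0 || n_per[si] == 0L) next
        cc <- with_seed(derive_seed(seed, colnames(counts)[si]),
                        as.vector(rmultinom(1, n_per[si], w)))
        counts[tab$transcript_id, si] <- cc
    }
    counts
}

#' Simulate strand-specific 50 bp short reads for a sample design
#'
#' Per sample, per-isoform read counts are multinomial with weights
#' proportional to expression rate x isoform share x spliced length; read
#' start positions are uniform along the isoform.  Reads are emitted on the
#' transcript (sense) strand, emulating a strand-specific library.
#'
#' @param truth a `gene_truth` object.
#' @param condition_design expression truth table
#'   ([make_expression_truth()], optionally after
#'   [apply_irradiation_effect()]).
#' @param n_reads_per_sample reads per sample (scalar, recycled).
#' @param seed integer RNG seed.
#' @param error_rate per-base substitution probability.
#' @param read_length read length in bp (fixed).
#' @param quality_range scalar per-read quality drawn uniformly over this
#'   range.
#' @return named list of `read_set` objects, one per sample
#'   (`<condition>_rep<k>`), each with columns `read_id`, `seq`, `gene_id`,
#'   `isoform`, `offset`, `ori` and `read_quality`.
#' @export
simulate_short_reads <- function(truth, condition_design, n_reads_per_sample,
                                 seed = 1L, error_rate = 0,
                                 read_length = 50L,
                                 quality_range = c(15, 40)) {
    des <- as.data.table(condition_design)
    if (any(des$rate < 0)) stop("negative expression multipliers")
    samples <- unique(des[, .(condition, replicate)])
    setorder(samples, condition, replicate)
    seqs <- tx_sequences(truth$tx, truth$genome)
    iso <- copy(truth$isoforms)
    iso[, qlen := nchar(seqs[transcript_id])]
    out <- vector("list", nrow(samples))
    names(out) <- sprintf("%s_rep%d", samples$condition, samples$replicate)
    n_per <- rep_len(n_reads_per_sample, nrow(samples))
    for (si in seq_len(nrow(samples))) {
        rates <- des[condition == samples$condition[si] &
                     replicate == samples$replicate[si]]
        tab <- iso[rates, on = "gene_id", nomatch = NULL]
        w <- tab$rate * tab$share * tab$qlen
        empty <- data.table(read_id = character(0), seq = character(0),
                            gene_id = character(0), isoform = character(0),
                            offset = integer(0), ori = character(0),
                            read_quality = numeric(0))
        if (sum(w) == 0 || n_per[si] == 0L) {
            out[[si]] <- structure(list(reads = empty, platform = "short"),
                                   class = "read_set")
            next
        }
        keep <- tab$qlen >= read_length & w > 0
        tab <- tab[keep]; w <- w[keep]
        out[[si]] <- with_seed(derive_seed(seed, names(out)[si]), {
            counts <- as.vector(rmultinom(1, n_per[si], w))
            pick <- rep(seq_len(nrow(tab)), counts)
            tid <- tab$transcript_id[pick]
            tlen <- tab$qlen[pick]
            offs <- floor(runif(length(pick)) * (tlen - read_length + 1))
            rseq <- substring(seqs[tid], offs + 1, offs + read_length)
            if (error_rate > 0) {
                nb <- length(rseq) * read_length
                hits <- which(runif(nb) < error_rate)
                for (h in hits) {
                    ri <- (h - 1) %/% read_length + 1
                    pos <- (h - 1) %% read_length + 1
                    b <- substr(rseq[ri], pos, pos)
                    substr(rseq[ri], pos, pos) <-
                        sample(setdiff(c("A", "C", "G", "T"), b), 1L)
                }
            }
            reads <- data.table(
                read_id = sprintf("%s_r%07d", names(out)[si],
                                  seq_along(pick)),
                seq = unname(rseq), gene_id = tab$gene_id[pick],
                isoform = tid, offset = as.integer(offs), ori = "+",
                read_quality = round(runif(length(pick), quality_range[1],
                                           quality_range[2]), 1))
            structure(list(reads = reads, platform = "short"),
                      class = "read_set")
        })
    }
    out
}
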