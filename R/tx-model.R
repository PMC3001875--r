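#' Construct a transcript model table
#'
#' The package-wide currency for transcript models: one row per exon with
#' 0-based half-open genomic coordinates, plus per-transcript provenance and
#' read-support columns.
#'
#' @param transcript_id,gene_id,contig,strand,start,end per-exon vectors.
#' @param provenance one of `"shortread"`, `"longread"`, `"merged"`,
#'   `"truth"` (recycled).
#' @param support unique-read support (recycled).
#' @return a `data.table` of class `tx_table`.
#' @export
tx_table <- function(transcript_id, gene_id, contig, strand, start, end,
                     provenance = "truth", support = NA_real_) {
    dt <- data.table(transcript_id = as.character(transcript_id),
                     gene_id = as.character(gene_id),
                     contig = as.character(contig),
                     strand = as.character(strand),
                     start = as.numeric(start), end = as.numeric(end),
                     provenance = provenance, support = as.numeric(support))
    tx_canonical(dt)
}

# sort exons genomically within transcripts and assign exon_rank
tx_canonical <- function(tx) {
    tx <- as.data.table(tx)
    if (nrow(tx) == 0L) {
        tx[, exon_rank := integer(0)]
        return(tx[])
    }
    if (any(tx$end <= tx$start)) stop("empty or inverted exon interval")
    setorder(tx, transcript_id, start)
    tx[, exon_rank := seq_len(.N), by = transcript_id]
    bad <- tx[, any(start[-1] < end[-.N]), by = transcript_id][V1 == TRUE]
    if (nrow(bad)) stop("overlapping exons within transcript ",
                        bad$transcript_id[1])
    setorder(tx, contig, transcript_id, exon_rank)
    tx[]
}

#' Number of exons per transcript
#' @param tx transcript model table.
#' @return named integer vector.
#' @export
tx_n_exons <- function(tx) {
    if (nrow(tx) == 0L) return(setNames(integer(0), character(0)))
    n <- tx[, .N, by = transcript_id]
    setNames(n$N, n$transcript_id)
}

#' Spliced (exonic) length per transcript
#' @param tx transcript model table.
#' @return named numeric vector of bp.
#' @export
tx_spliced_lengths <- function(tx) {
    if (nrow(tx) == 0L) return(setNames(numeric(0), character(0)))
    s <- tx[, sum(end - start), by = transcript_id]
    setNames(s$V1, s$transcript_id)
}

#' Splice junctions of a transcript model table
#'
#' @param tx transcript model table.
#' @return `data.table` with `contig`, `strand`, `donor` (0-based exclusive
#'   end of the upstream exon), `acceptor` (0-based start of the downstream
#'   exon) and `transcript_id`; one row per junction.
#' @export
tx_junctions <- function(tx) {
    empty <- data.table(contig = character(0), strand = character(0),
                        donor = numeric(0), acceptor = numeric(0),
                        transcript_id = character(0))
    if (nrow(tx) == 0L) return(empty)
    j <- tx[, if (.N >= 2L) .(contig = contig[1L], strand = strand[1L],
                              donor = end[-.N], acceptor = start[-1L]),
            by = transcript_id]
    if (nrow(j) == 0L) return(empty)
    setcolorder(j, c("contig", "strand", "donor", "acceptor", "transcript_id"))
    j[]
}

#' Extract spliced transcript sequences from a genome
#'
#' Concatenates exon substrings in genomic order and reverse-complements
#' minus-strand transcripts, so every returned sequence reads 5'->3' in
#' transcript orientation.
#'
#' @param tx transcript model table.
#' @param genome named character vector of contig sequences.
#' @return named character vector keyed by transcript id.
#' @export
tx_sequences <- function(tx, genome) {
    if (nrow(tx) == 0L) return(setNames(character(0), character(0)))
    pieces <- tx[, {
        s <- substring(genome[[contig[1L]]], start + 1, end)
        seqc <- paste(s, collapse = "")
        .(seq = if (strand[1L] == "-") revcomp(seqc) else seqc)
    }, by = transcript_id]
    setNames(pieces$seq, pieces$transcript_id)
}

#' Summary counts for a transcript model table
#'
#' @param models transcript model table.
#' @return list with `n_multi_exon`, `n_single_exon` and `mean_length`
#'   (mean spliced length in bp, `NaN` when empty).
#' @export
annotate_counts <- function(models) {
    ne <- tx_n_exons(models)
    len <- tx_spliced_lengths(models)
    list(n_multi_exon = sum(ne >= 2L),
         n_single_exon = sum(ne == 1L),
         mean_length = mean(len))
}

#' Spliced-coordinate positions of a transcript's junctions
#'
#' For every junction, the number of transcript bases 5' of the junction in
#' transcript orientation -- the offset at which a read must straddle to
#' provide split evidence.
#'
#' @param tx transcript model table.
#' @return `data.table` with `transcript_id`, `contig`, `strand`, `donor`,
#'   `acceptor`, `tpos`.
#' @export
junction_spliced_positions <- function(tx) {
    j <- tx_junctions(tx)
    if (nrow(j) == 0L) {
        j[, tpos := numeric(0)]
        return(j[])
    }
    rows <- lapply(split(tx_canonical(tx), by = "transcript_id"),
                   function(grp) {
        if (nrow(grp) < 2L) return(NULL)
        lens <- grp$end - grp$start
        cum <- cumsum(lens)
        total <- sum(lens)
        # junction after genomic exon i is crossed at cum[i] on '+', at
        # total - cum[i] in transcript orientation on '-'
        tp <- if (grp$strand[1L] == "+") cum[-length(cum)]
              else total - cum[-length(cum)]
        data.table(transcript_id = grp$transcript_id[1L],
                   contig = grp$contig[1L], strand = grp$strand[1L],
                   donor = grp$end[-nrow(grp)], acceptor = grp$start[-1L],
                   tpos = tp)
    })
    rbindlist(rows[!vapply(rows, is.null, logical(1))])
}

# genome blocks covered by spliced interval [s, e) of one transcript model
# (0-based half-open in transcript orientation); returns genome-ordered
# matrix of half-open intervals
cdna_blocks <- function(exons, strand, s, e) {
    lens <- exons[, 2] - exons[, 1]
    total <- sum(lens)
    if (s < 0 || e > total || s >= e) stop("interval outside spliced transcript")
    if (strand == "-") { tmp <- s; s <- total - e; e <- total - tmp }
    offs <- cumsum(c(0, lens))
    out <- NULL
    for (i in seq_len(nrow(exons))) {
        a <- max(s, offs[i]); b <- min(e, offs[i + 1])
        if (a < b)
            out <- rbind(out, c(exons[i, 1] + (a - offs[i]),
                                exons[i, 1] + (b - offs[i])))
    }
    colnames(out) <- c("start", "end")
    out
}
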