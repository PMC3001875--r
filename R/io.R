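#' Read a FASTA file as a named character vector
#'
#' @param path FASTA file.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
    s <- Biostrings::readDNAStringSet(path)
    ids <- sub("\\s.*$", "", names(s))
    if (anyDuplicated(ids)) stop("duplicate FASTA ids in ", path)
    out <- as.character(s)
    names(out) <- ids
    out
}

#' Write sequences to FASTA
#'
#' @param sequences named character vector.
#' @param path output file.
#' @param width wrapping width in bases.
#' @export
write_fasta <- function(sequences, path, width = 70L) {
    if (anyDuplicated(names(sequences))) stop("duplicate FASTA ids")
    s <- Biostrings::DNAStringSet(unname(as.character(sequences)))
    names(s) <- names(sequences)
    Biostrings::writeXStringSet(s, path, width = width)
    invisible(path)
}

#' Write transcript models to GTF
#'
#' Emits `transcript` and `exon` rows with `gene_id`/`transcript_id`
#' attributes only; internal 0-based half-open coordinates become 1-based
#' inclusive on disk.
#'
#' @param tx transcript model table (see [tx_table()]).
#' @param path output file.
#' @param source source field for column 2.
#' @export
write_gtf <- function(tx, path, source = "planartx") {
    tx <- tx_canonical(tx)
    attr_str <- function(g, t)
        sprintf('gene_id "%s"; transcript_id "%s";', g, t)
    spans <- tx[, .(start = min(start), end = max(end),
                    gene_id = gene_id[1L], contig = contig[1L],
                    strand = strand[1L]), by = transcript_id]
    lines_t <- sprintf("%s\t%s\ttranscript\t%d\t%d\t.\t%s\t.\t%s",
                       spans$contig, source, as.integer(spans$start + 1),
                       as.integer(spans$end), spans$strand,
                       attr_str(spans$gene_id, spans$transcript_id))
    lines_e <- sprintf("%s\t%s\texon\t%d\t%d\t.\t%s\t.\t%s",
                       tx$contig, source, as.integer(tx$start + 1),
                       as.integer(tx$end), tx$strand,
                       attr_str(tx$gene_id, tx$transcript_id))
    # interleave: transcript row first, then its exons, in transcript order
    ord <- order(match(tx$transcript_id, spans$transcript_id), tx$exon_rank)
    out <- character(0)
    j <- 1L
    for (i in seq_len(nrow(spans))) {
        out <- c(out, lines_t[i])
        k <- sum(tx$transcript_id == spans$transcript_id[i])
        out <- c(out, lines_e[ord][j:(j + k - 1L)])
        j <- j + k
    }
    writeLines(out, path)
    invisible(path)
}

#' Read a GTF file into a transcript model table
#'
#' Coordinates are converted from 1-based inclusive to internal 0-based
#' half-open; exons are sorted genomically within each transcript.
#'
#' @param path GTF file.
#' @return transcript model table.
#' @export
read_gtf <- function(path) {
    gr <- rtracklayer::import(path, format = "gtf")
    ex <- gr[gr$type == "exon"]
    if (length(ex) == 0L)
        return(tx_table(character(0), character(0), character(0), character(0),
                        numeric(0), numeric(0)))
    sp <- gr[gr$type == "transcript"]
    if (length(sp)) {
        spans <- data.table(transcript_id = sp$transcript_id,
                            start = GenomicRanges::start(sp) - 1,
                            end = as.numeric(GenomicRanges::end(sp)))
        exdt <- data.table(transcript_id = ex$transcript_id,
                           s = GenomicRanges::start(ex) - 1,
                           e = as.numeric(GenomicRanges::end(ex)))
        chk <- exdt[spans, on = "transcript_id"]
        if (chk[, any(s < start | e > end)])
            stop("exon outside declared transcript span")
    }
    tx <- tx_table(transcript_id = ex$transcript_id,
                   gene_id = ex$gene_id,
                   contig = as.character(GenomicRanges::seqnames(ex)),
                   strand = as.character(GenomicRanges::strand(ex)),
                   start = GenomicRanges::start(ex) - 1,
                   end = as.numeric(GenomicRanges::end(ex)))
    tx_canonical(tx)
}

#' Write alignments to a SAM-like tab-delimited file
#'
#' Single-end subset: columns read_id, mapped flag, contig, 1-based pos,
#' mapping score, cigar, strand, uniqueness, scalar read quality, sequence.
#'
#' @param alignments alignment table.
#' @param path output file.
#' @export
write_sam_like <- function(alignments, path) {
    a <- as.data.table(alignments)
    out <- data.table(
        read_id = a$read_id,
        mapped = ifelse(a$uniqueness == "unmapped", 0L, 1L),
        contig = ifelse(a$uniqueness == "unmapped", "*", a$contig),
        pos = ifelse(a$uniqueness == "unmapped", 0L, as.integer(a$pos + 1)),
        score = a$score,
        cigar = ifelse(a$uniqueness == "unmapped", "*", a$cigar),
        strand = ifelse(a$uniqueness == "unmapped", "*", a$strand),
        uniqueness = a$uniqueness,
        read_quality = a$read_quality,
        seq = if ("seq" %in% names(a)) a$seq else "*")
    fwrite(out, path, sep = "\t")
    invisible(path)
}

#' Read a SAM-like tab-delimited alignment file
#'
#' @param path file written by [write_sam_like()].
#' @return alignment table with internal 0-based positions.
#' @export
read_sam_like <- function(path) {
    a <- fread(path, sep = "\t",
               colClasses = list(character = c("read_id", "contig", "cigar",
                                               "strand", "uniqueness", "seq")))
    a[, pos := ifelse(uniqueness == "unmapped", NA_real_, as.numeric(pos) - 1)]
    a[, mapped := NULL]
    a[]
}
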