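STOP_CODONS <- c("TAA", "TAG", "TGA")

# enumerate candidate ORFs of one frame's codon string; returns data.table
# with codon-index start/end (0-based, half-open, stop excluded) and flags.
# Reading may begin at the sequence edge without ATG and/or run off the
# edge without a stop; internal stop-free segments still need an ATG.
frame_orfs <- function(codons) {
    n <- length(codons)
    empty <- data.table(cstart = integer(0), cend = integer(0),
                        has_start = logical(0), has_stop = logical(0))
    if (n == 0L) return(empty)
    is_stop <- codons %in% STOP_CODONS
    is_atg <- codons == "ATG"
    bounds <- c(0L, which(is_stop), n + 1L)
    rows <- list()
    for (b in seq_len(length(bounds) - 1L)) {
        s <- bounds[b] + 1L           # first codon index of segment (1-based)
        e <- bounds[b + 1L] - 1L      # last codon index of segment
        if (s > e) next
        has_stop <- bounds[b + 1L] <= n
        at_edge <- s == 1L
        anchors <- integer(0)
        if (at_edge) anchors <- s  # reading may begin at the boundary
        atg <- which(is_atg[s:e])
        if (length(atg)) anchors <- unique(c(anchors, s + atg[1L] - 1L))
        for (anchor in anchors)
            rows[[length(rows) + 1L]] <- data.table(
                cstart = anchor - 1L, cend = e,  # 0-based half-open codons
                has_start = is_atg[anchor], has_stop = has_stop)
    }
    if (length(rows) == 0L) return(empty)
    rbindlist(rows)
}

#' Longest open reading frame of a transcript, all six frames
#'
#' Among all six reading frames, returns the maximal-length reading
#' segment, where an ORF may begin at the sequence boundary without an ATG
#' (class `missing_start`) and/or run off the boundary without a stop
#' (`missing_stop`); `complete` requires both anchors.  Readings anchored
#' by at least a start or a stop codon take priority; a boundary-to-
#' boundary reading with neither anchor (`missing_both`) is reported only
#' when no frame offers an anchored reading.  Ties are broken in frame
#' order +1, +2, +3, -1, -2, -3.  Codons containing N match neither start
#' nor stop.
#'
#' @param sequence DNA string over A/C/G/T/N, length >= 3.
#' @param min_aa minimum peptide length to report (0 reports any).
#' @return list with `frame` (+1..+3, -1..-3), `start`, `end` (0-based
#'   half-open on the forward sequence, stop codon excluded), `peptide`,
#'   `class`; or `NULL` when no ORF of the required length exists.
#' @export
longest_orf <- function(sequence, min_aa = 0L) {
    if (is.na(sequence) || nchar(sequence) == 0L) stop("empty sequence")
    L <- nchar(sequence)
    if (L < 3L) return(NULL)
    frames <- list(`1` = sequence, `2` = substr(sequence, 2L, L),
                   `3` = substr(sequence, 3L, L))
    rcseq <- revcomp(sequence)
    frames <- c(frames, list(`-1` = rcseq, `-2` = substr(rcseq, 2L, L),
                             `-3` = substr(rcseq, 3L, L)))
    frame_keys <- c(1L, 2L, 3L, -1L, -2L, -3L)
    best <- NULL
    for (fi in seq_along(frames)) {
        fseq <- frames[[fi]]
        nc <- nchar(fseq) %/% 3L
        if (nc == 0L) next
        codons <- substring(fseq, 3L * (seq_len(nc) - 1L) + 1L,
                            3L * seq_len(nc))
        cands <- frame_orfs(codons)
        if (nrow(cands) == 0L) next
        cands[, len := cend - cstart]
        cands[, anchored := has_start | has_stop]
        setorder(cands, -anchored, -len, cstart)
        top <- cands[1L]
        better <- is.null(best) ||
            (top$anchored && !best$anchored) ||
            (top$anchored == best$anchored && top$len > best$len)
        if (better) {
            best <- top
            best$frame <- frame_keys[fi]
            best$foff <- abs(best$frame) - 1L
        }
    }
    if (is.null(best) || best$len < min_aa) return(NULL)
    fseq <- frames[[which(frame_keys == best$frame)]]
    nt <- substr(fseq, 3L * best$cstart + 1L, 3L * best$cend)
    pep <- as.character(suppressWarnings(Biostrings::translate(
        Biostrings::DNAString(nt), no.init.codon = TRUE,
        if.fuzzy.codon = "solve")))
    # positions on the forward strand, 0-based half-open
    s_in_frame <- best$foff + 3L * best$cstart
    e_in_frame <- best$foff + 3L * best$cend
    if (best$frame > 0L) { start <- s_in_frame; end <- e_in_frame }
    else { start <- L - e_in_frame; end <- L - s_in_frame }
    cls <- if (best$has_start && best$has_stop) "complete"
           else if (!best$has_start && best$has_stop) "missing_start"
           else if (best$has_start && !best$has_stop) "missing_stop"
           else "missing_both"
    list(frame = best$frame, start = start, end = end,
         peptide = pep, class = cls)
}

#' Classify longest ORFs for a set of transcripts
#'
#' One [longest_orf()] call per transcript; counts per completeness class
#' and a peptide-length histogram binned at 50 aa.  The default
#' `min_aa = 10` suppresses the pile of tiny segments that are unlikely to
#' be real proteins.
#'
#' @param transcripts named character vector of transcript sequences.
#' @param min_aa minimum peptide length for a callable ORF.
#' @return list with `calls` (`data.table`: transcript_id, frame, start,
#'   end, orf_class, peptide), `class_counts` (named integer vector over
#'   the four classes) and `length_histogram` (`data.table`: bin_start,
#'   count).
#' @export
classify_orfs <- function(transcripts, min_aa = 10L) {
    classes <- c("complete", "missing_start", "missing_stop", "missing_both")
    rows <- list()
    for (nm in names(transcripts)) {
        if (nchar(transcripts[[nm]]) < 3L) next
        o <- longest_orf(transcripts[[nm]], min_aa = min_aa)
        if (is.null(o)) next
        rows[[length(rows) + 1L]] <- data.table(
            transcript_id = nm, frame = o$frame, start = o$start,
            end = o$end, orf_class = o$class, peptide = o$peptide)
    }
    calls <- if (length(rows)) rbindlist(rows) else
        data.table(transcript_id = character(0), frame = integer(0),
                   start = integer(0), end = integer(0),
                   orf_class = character(0), peptide = character(0))
    cc <- table(factor(calls$orf_class, levels = classes))
    bins <- if (nrow(calls)) {
        pl <- nchar(calls$peptide)
        b <- (pl %/% 50L) * 50L
        as.data.table(table(bin_start = b))[, .(bin_start =
            as.integer(as.character(bin_start)), count = N)]
    } else data.table(bin_start = integer(0), count = integer(0))
    list(calls = calls, class_counts = setNames(as.integer(cc), classes),
         length_histogram = bins)
}

#' Write ORF calls as a peptide FASTA plus coordinates table
#'
#' @param orf_result result of [classify_orfs()].
#' @param fasta_path,tsv_path output paths.
#' @export
write_orf_outputs <- function(orf_result, fasta_path, tsv_path) {
    calls <- orf_result$calls
    fwrite(calls[, .(transcript_id, frame, start, end, orf_class, peptide)],
           tsv_path, sep = "\t")
    if (nrow(calls)) {
        hdr <- sprintf("%s|frame=%d|%d-%d|%s", calls$transcript_id,
                       calls$frame, calls$start, calls$end, calls$orf_class)
        aa <- Biostrings::AAStringSet(calls$peptide)
        names(aa) <- hdr
        Biostrings::writeXStringSet(aa, fasta_path)
    } else writeLines(character(0), fasta_path)
    invisible(NULL)
}
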