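#' Build super-genes from assembled transcript models
#'
#' One super-gene per contig strand with at least one assembled exon: its
#' blocks are the union of all model exons on that strand (overlaps
#' collapsed), and its cDNA is the block sequences laced together in
#' genomic order (reverse-complemented for the minus strand).  A read that
#' maps contiguously across a block boundary of the cDNA is a candidate
#' split read joining two assembled exons.
#'
#' @param models transcript model table.
#' @param genome named character vector of contig sequences.
#' @return list of `supergene` objects: `supergene_id`, `contig`, `strand`,
#'   `blocks` (genome-ordered 0-based half-open matrix), `cdna`.
#' @export
build_supergenes <- function(models, genome) {
    if (nrow(models) == 0L) return(list())
    unknown <- setdiff(unique(models$contig), names(genome))
    if (length(unknown))
        stop("model references unknown contig(s): ",
             paste(unknown, collapse = ", "))
    out <- list()
    for (grp in split(models, by = c("contig", "strand"), sorted = TRUE)) {
        if (nrow(grp) == 0L) next
        ctg <- grp$contig[1L]; str <- grp$strand[1L]
        ir <- IRanges::reduce(IRanges::IRanges(grp$start + 1L, grp$end))
        blocks <- cbind(start = IRanges::start(ir) - 1,
                        end = as.numeric(IRanges::end(ir)))
        pieces <- substring(genome[[ctg]], blocks[, 1] + 1, blocks[, 2])
        cdna <- paste(pieces, collapse = "")
        if (str == "-") cdna <- revcomp(cdna)
        id <- paste0("sg_", ctg, ifelse(str == "+", "_plus", "_minus"))
        out[[id]] <- structure(list(supergene_id = id, contig = ctg,
                                    strand = str, blocks = blocks,
                                    cdna = cdna),
                               class = "supergene")
    }
    out
}

#' Map a cDNA position of a super-gene to its genomic position
#'
#' The coordinate map is a bijection between cDNA offsets and covered
#' genomic bases.
#'
#' @param sg a `supergene`.
#' @param cdna_pos 0-based cDNA offsets (vectorised).
#' @return 0-based genomic positions.
#' @export
sg_cdna_to_genome <- function(sg, cdna_pos) {
    lens <- sg$blocks[, 2] - sg$blocks[, 1]
    total <- sum(lens)
    if (any(cdna_pos < 0 | cdna_pos >= total))
        stop("cDNA position outside super-gene")
    p <- if (sg$strand == "-") total - 1 - cdna_pos else cdna_pos
    offs <- cumsum(c(0, lens))
    i <- findInterval(p, offs, rightmost.closed = FALSE, left.open = FALSE)
    unname(sg$blocks[i, 1] + (p - offs[i]))
}

# genome blocks covered by cDNA interval [s, e) of a super-gene
sg_interval_blocks <- function(sg, s, e) {
    cdna_blocks(sg$blocks, sg$strand, s, e)
}

#' Select rescue candidate reads
#'
#' High-quality reads that previously failed to map or mapped only along
#' part of their length; fully mapped reads are never reselected.
#'
#' @param alignments alignment table from [map_reads()] (unfiltered, so
#'   unmapped/partial records are present).
#' @param reads read table with `read_id`, `seq`, `read_quality`.
#' @param params a [mapping_params()] object.
#' @return subset of `reads` eligible for remapping.
#' @export
select_rescue_candidates <- function(alignments, reads,
                                     params = mapping_params()) {
    status <- alignments[, .(status = uniqueness[1L]), by = read_id]
    cand <- status[status %in% c("unmapped", "partial"), read_id]
    reads[read_id %in% cand & read_quality >= params$min_read_quality]
}

#' Remap candidates against super-genes and harvest new split reads
#'
#' Each candidate that maps contiguously and uniquely (best score) to a
#' super-gene cDNA is projected through the coordinate map; a projection
#' spanning two or more blocks emits an N-gapped genome alignment (a new
#' split read), provided at least `min_anchor` matched bases lie on each
#' outer side of the crossed boundaries.  Projections within one block are
#' returned as plain alignments.  Junctions are only ever emitted between
#' distinct blocks.
#'
#' @param candidates read table from [select_rescue_candidates()].
#' @param supergenes list from [build_supergenes()].
#' @param params a [mapping_params()] object.
#' @param min_anchor minimum matched bases on each side of a crossed block
#'   boundary.
#' @return alignment table of rescued genome-space placements.
#' @export
rescue_split_reads <- function(candidates, supergenes,
                               params = mapping_params(), min_anchor = 10L) {
    if (nrow(candidates) == 0L || length(supergenes) == 0L)
        return(alignment_table())
    cdnas <- vapply(supergenes, function(sg) sg$cdna, character(1))
    cdnas <- cdnas[nchar(cdnas) >= params$k]
    if (length(cdnas) == 0L) return(alignment_table())
    idx <- build_index(cdnas, params$k)
    hits <- match_full_length(
        data.table(qid = candidates$read_id, seq = candidates$seq),
        idx, cdnas, params$max_mismatches)
    if (nrow(hits) == 0L) return(alignment_table())
    # keep only uniquely best-scoring placements
    hits[, best := max(score), by = qid]
    hits <- hits[score == best]
    hits[, n_hits := .N, by = qid]
    hits <- hits[n_hits == 1L]
    if (nrow(hits) == 0L) return(alignment_table())
    qmeta <- candidates[match(hits$qid, read_id)]
    qlen <- nchar(qmeta$seq)
    rows <- vector("list", nrow(hits))
    for (i in seq_len(nrow(hits))) {
        sg <- supergenes[[hits$sid[i]]]
        blocks <- sg_interval_blocks(sg, hits$start[i], hits$start[i] + qlen[i])
        if (nrow(blocks) >= 2L) {
            widths <- blocks[, 2] - blocks[, 1]
            if (widths[1L] < min_anchor || widths[nrow(blocks)] < min_anchor)
                next
            gap <- blocks[-1L, 1] - blocks[-nrow(blocks), 2]
            if (any(gap > params$max_intron)) next
        }
        rows[[i]] <- data.table(
            read_id = hits$qid[i], contig = sg$contig,
            pos = unname(blocks[1L, 1L]), strand = sg$strand,
            cigar = cigar_from_blocks(blocks), score = hits$score[i],
            uniqueness = "unique", read_quality = qmeta$read_quality[i],
            target_space = "supergene", seq = qmeta$seq[i])
    }
    rows <- rows[!vapply(rows, is.null, logical(1))]
    if (length(rows) == 0L) return(alignment_table())
    rbindlist(rows)
}

#' Merge rescued split reads into the original alignment set
#'
#' Duplicates by read id are resolved in favour of the rescued split
#' placement; a conflicting duplicate at equal score without a new junction
#' keeps the original and is logged.
#'
#' @param original_sam original alignment table.
#' @param rescued alignment table from [rescue_split_reads()].
#' @return combined alignment table.
#' @export
merge_alignments <- function(original_sam, rescued) {
    if (nrow(rescued) == 0L) return(copy(original_sam))
    r1 <- rescued[, .(r_split = any(grepl("N", cigar, fixed = TRUE)),
                      r_score = max(score)), by = read_id]
    o1 <- original_sam[, .(o_score = max(score)), by = read_id]
    cmp <- o1[r1, on = "read_id"]
    win <- cmp[is.na(o_score) | r_split | r_score > o_score, read_id]
    lost <- setdiff(r1$read_id, win)
    if (length(lost))
        message(length(lost), " rescued placement(s) did not beat the ",
                "original record; originals kept")
    rbindlist(list(original_sam[!read_id %in% win],
                   rescued[read_id %in% win]),
              use.names = TRUE, fill = TRUE)
}

#' Iterative super-gene rescue
#'
#' Runs the loop assemble -> build super-genes -> remap rescue candidates ->
#' merge alignments -> re-assemble, stopping at a fixed point (no new
#' junctions) or after `max_rounds` rescue rounds.
#'
#' @param alignments initial alignment table (unfiltered output of
#'   [map_reads()]).
#' @param reads read table (`read_id`, `seq`, `read_quality`).
#' @param genome named character vector of contig sequences.
#' @param map_params a [mapping_params()] object.
#' @param asm_params an [assembly_params()] object.
#' @param max_rounds maximum rescue rounds (the original study performed
#'   one).
#' @param min_anchor minimum per-side anchor for a rescued junction.
#' @return list with `models` (final transcript model table), `alignments`
#'   (augmented set) and `ledger` (`data.table` of per-round junction and
#'   multi-exon model counts).
#' @export
iterate_rescue <- function(alignments, reads, genome,
                           map_params = mapping_params(),
                           asm_params = assembly_params(),
                           max_rounds = 1L, min_anchor = 10L) {
    stopifnot(max_rounds >= 1L)
    # partial stubs are kept as coverage evidence for the assembler even
    # though their clipped scores fall below the full-read score floor
    asm_input <- function(a)
        rbind(quality_filter(a, map_params),
              a[uniqueness == "partial" &
                read_quality >= map_params$min_read_quality &
                score < map_params$min_mapping_score])
    aln <- alignments
    models <- assemble_transcripts(asm_input(aln), asm_params)
    jset <- unique(tx_junctions(models)[, .(contig, strand, donor, acceptor)])
    ledger <- data.table(round = 0L, n_junctions = nrow(jset),
                         n_multi_exon = annotate_counts(models)$n_multi_exon,
                         n_rescued_reads = 0L)
    for (r in seq_len(max_rounds)) {
        sgs <- build_supergenes(models, genome)
        cand <- select_rescue_candidates(aln, reads, map_params)
        rescued <- rescue_split_reads(cand, sgs, map_params, min_anchor)
        aln <- merge_alignments(aln, rescued)
        models <- assemble_transcripts(asm_input(aln), asm_params)
        jnew <- unique(tx_junctions(models)[, .(contig, strand, donor, acceptor)])
        ledger <- rbind(ledger, data.table(
            round = r, n_junctions = nrow(jnew),
            n_multi_exon = annotate_counts(models)$n_multi_exon,
            n_rescued_reads = nrow(rescued)))
        if (nrow(jnew) <= nrow(jset) &&
            nrow(data.table::fsetdiff(jnew, jset)) == 0L) break
        jset <- jnew
    }
    list(models = models, alignments = aln, ledger = ledger)
}
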