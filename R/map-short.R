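#' Short-read mapping parameters
#'
#' Scoring is +1 per matched base, -2 per mismatch, 0 for clipped bases; the
#' default `min_mapping_score` of 40 corresponds to at most ~3 mismatches on
#' a 50 bp read.  An alignment is called partial when at least
#' `partial_frac` of the read is clipped while a mappable stub of at least
#' `min_stub` bp remains to seed split-read rescue.
#'
#' @param k seed length (>= 8).
#' @param max_mismatches maximum mismatches for a full-length placement.
#' @param min_mapping_score score threshold used by [quality_filter()].
#' @param min_read_quality scalar read-quality threshold.
#' @param max_intron maximum intron length in bp.
#' @param partial_frac clipped fraction at or above which an alignment is
#'   partial.
#' @param min_stub minimum mappable stub length of a partial alignment.
#' @param max_hits cap on reported placements per multi-mapping read.
#' @return object of class `mapping_params`.
#' @export
mapping_params <- function(k = 16L, max_mismatches = 3L,
                           min_mapping_score = 40, min_read_quality = 20,
                           max_intron = 100000L, partial_frac = 0.3,
                           min_stub = 15L, max_hits = 10L) {
    if (k < 8L) stop("seed length k must be >= 8")
    if (max_intron <= 0) stop("max_intron must be positive")
    structure(as.list(environment()), class = "mapping_params")
}

#' Build a k-mer seed index over reference sequences
#'
#' Every length-`k` substring of every sequence is retrievable with its
#' 0-based position.
#'
#' @param sequences named character vector.
#' @param k seed length (>= 8).
#' @return object of class `seed_index`.
#' @export
build_index <- function(sequences, k) {
    if (k < 8L) stop("seed length k must be >= 8")
    if (length(sequences) == 0L) {
        idx <- data.table(kmer = character(0), sid = character(0),
                          pos = integer(0))
        setkey(idx, kmer)
        return(structure(list(index = idx, k = as.integer(k),
                              seq_lens = setNames(integer(0), character(0))),
                         class = "seed_index"))
    }
    lens <- nchar(sequences)
    if (min(lens) < k)
        stop("k = ", k, " exceeds the shortest sequence (",
             names(sequences)[which.min(lens)], ", ", min(lens), " bp)")
    parts <- lapply(names(sequences), function(nm) {
        s <- sequences[[nm]]
        n <- nchar(s) - k + 1L
        data.table(kmer = substring(s, 1:n, k:(k + n - 1L)), sid = nm,
                   pos = 0:(n - 1L))
    })
    idx <- rbindlist(parts)
    setkey(idx, kmer)
    structure(list(index = idx, k = as.integer(k), seq_lens = lens),
              class = "seed_index")
}

#' Look up all positions of a k-mer in a seed index
#' @param index a `seed_index`.
#' @param kmers character vector of k-mers.
#' @return `data.table` with `kmer`, `sid`, `pos` (0-based).
#' @export
index_lookup <- function(index, kmers) {
    index$index[data.table(kmer = kmers), on = "kmer", nomatch = NULL]
}

# full-length contiguous placements of queries against indexed sequences.
# queries: data.table(qid, seq); seeds are taken at both query ends.
# Returns data.table(qid, sid, start, mm, score), start 0-based, mm <= max_mm.
match_full_length <- function(queries, index, sequences, max_mm) {
    k <- index$k
    empty <- data.table(qid = character(0), sid = character(0),
                        start = numeric(0), mm = integer(0),
                        score = numeric(0))
    if (nrow(queries) == 0L || nrow(index$index) == 0L) return(empty)
    qlen <- nchar(queries$seq)
    keep <- qlen >= k
    q <- queries[keep]; qlen <- qlen[keep]
    if (nrow(q) == 0L) return(empty)
    seeds <- rbindlist(list(
        data.table(qid = q$qid, kmer = substring(q$seq, 1L, k), soff = 0L,
                   qlen = qlen),
        data.table(qid = q$qid, kmer = substring(q$seq, qlen - k + 1L, qlen),
                   soff = qlen - k, qlen = qlen)))
    hits <- index$index[seeds, on = "kmer", nomatch = NULL, allow.cartesian = TRUE]
    if (nrow(hits) == 0L) return(empty)
    hits[, start := pos - soff]
    hits <- unique(hits[, .(qid, sid, start, qlen)])
    hits <- hits[start >= 0 & start + qlen <= index$seq_lens[sid]]
    if (nrow(hits) == 0L) return(empty)
    qseq <- setNames(q$seq, q$qid)
    refsub <- substring(sequences[hits$sid], hits$start + 1L,
                        hits$start + hits$qlen)
    hits[, mm := cpp_hamming(refsub, qseq[qid])]
    hits <- hits[mm <= max_mm]
    hits[, score := qlen - 3 * mm]
    hits[, qlen := NULL]
    hits[]
}

#' Map short reads to genome and annotated transcripts
#'
#' Seed-and-extend, in the pipeline's priority order: (1) contiguous
#' full-length genome placement (both orientations, at most
#' `max_mismatches`); (2) full-length placement on an annotated spliced
#' transcript, projected back to the genome as a split read
#' ([project_to_genome()]); (3) partial placement (clipped stub); else
#' unmapped.  Ties across loci at the best score give `uniqueness =
#' "multi"`.
#'
#' @param reads `data.table` with `read_id`, `seq` and optionally
#'   `read_quality` (defaults to 40).
#' @param genome named character vector of contig sequences.
#' @param annotation optional transcript model table providing the
#'   transcript space for annotation-guided split reads.
#' @param params a [mapping_params()] object.
#' @param genome_index,tx_index optional prebuilt [build_index()] objects.
#' @return alignment `data.table` with one row per retained placement:
#'   `read_id`, `contig`, `pos` (0-based), `strand`, `cigar`, `score`,
#'   `uniqueness` in unique/multi/partial/unmapped, `read_quality`,
#'   `target_space`, `seq`.
#' @export
map_reads <- function(reads, genome, annotation = NULL,
                      params = mapping_params(),
                      genome_index = NULL, tx_index = NULL) {
    reads <- as.data.table(reads)
    if (!"read_quality" %in% names(reads)) reads[, read_quality := 40]
    empty <- alignment_table()
    if (nrow(reads) == 0L) return(empty)
    if (is.null(genome_index)) genome_index <- build_index(genome, params$k)

    qual <- setNames(reads$read_quality, reads$read_id)
    seqs <- setNames(reads$seq, reads$read_id)
    qlen <- setNames(nchar(reads$seq), reads$read_id)

    # orientation-expanded query set for genome space
    q2 <- rbindlist(list(
        data.table(qid = paste0(reads$read_id, "|+"), seq = reads$seq),
        data.table(qid = paste0(reads$read_id, "|-"), seq = revcomp(reads$seq))))
    hits <- match_full_length(q2, genome_index, genome, params$max_mismatches)
    out <- list()
    mapped_ids <- character(0)
    if (nrow(hits)) {
        hits[, read_id := sub("\\|[+-]$", "", qid)]
        hits[, ori := sub("^.*\\|", "", qid)]
        hits[, best := max(score), by = read_id]
        hits <- hits[score == best]
        hits[, n_hits := .N, by = read_id]
        hits <- hits[, head(.SD, params$max_hits), by = read_id]
        g <- data.table(read_id = hits$read_id, contig = hits$sid,
                        pos = hits$start, strand = hits$ori,
                        cigar = paste0(qlen[hits$read_id], "M"),
                        score = hits$score,
                        uniqueness = ifelse(hits$n_hits == 1L, "unique", "multi"),
                        read_quality = qual[hits$read_id],
                        target_space = "genome", seq = seqs[hits$read_id])
        out[[length(out) + 1L]] <- g
        mapped_ids <- unique(hits$read_id)
    }

    # transcript space for the rest (sense strand of the spliced transcript)
    rest <- reads[!read_id %in% mapped_ids]
    if (nrow(rest) && !is.null(annotation) && nrow(annotation)) {
        tx_seqs <- tx_sequences(annotation, genome)
        tx_seqs <- tx_seqs[nchar(tx_seqs) >= params$k]
        if (is.null(tx_index)) tx_index <- build_index(tx_seqs, params$k)
        th <- match_full_length(data.table(qid = rest$read_id, seq = rest$seq),
                                tx_index, tx_seqs, params$max_mismatches)
        if (nrow(th)) {
            ann <- tx_canonical(annotation)
            models <- split(ann, by = "transcript_id", sorted = TRUE)
            proj <- lapply(seq_len(nrow(th)), function(i) {
                p <- project_to_genome(
                    list(tstart = th$start[i],
                         tend = th$start[i] + qlen[[th$qid[i]]],
                         read_strand = "+"),
                    models[[th$sid[i]]])
                data.table(read_id = th$qid[i], contig = p$contig,
                           pos = p$pos, strand = p$strand, cigar = p$cigar,
                           score = th$score[i])
            })
            pj <- unique(rbindlist(proj))
            pj[, best := max(score), by = read_id]
            pj <- pj[score == best]
            pj[, n_hits := .N, by = read_id]
            pj <- pj[, head(.SD, params$max_hits), by = read_id]
            pj[, `:=`(uniqueness = ifelse(n_hits == 1L, "unique", "multi"),
                      read_quality = qual[read_id],
                      target_space = "transcript", seq = seqs[read_id])]
            pj[, c("best", "n_hits") := NULL]
            out[[length(out) + 1L]] <- pj
            mapped_ids <- c(mapped_ids, unique(pj$read_id))
        }
    }

    # partial placements for still-unplaced reads with a genome seed hit
    rest <- reads[!read_id %in% mapped_ids]
    if (nrow(rest)) {
        p <- partial_placements(rest, genome, genome_index, params,
                                qual, seqs)
        if (nrow(p)) {
            out[[length(out) + 1L]] <- p
            mapped_ids <- c(mapped_ids, unique(p$read_id))
        }
    }

    rest <- reads[!read_id %in% mapped_ids]
    if (nrow(rest))
        out[[length(out) + 1L]] <- data.table(
            read_id = rest$read_id, contig = NA_character_, pos = NA_real_,
            strand = NA_character_, cigar = NA_character_, score = 0,
            uniqueness = "unmapped", read_quality = rest$read_quality,
            target_space = NA_character_, seq = rest$seq)
    aln <- rbindlist(out, use.names = TRUE)
    setorder(aln, read_id)
    aln[]
}

# clipped-stub placements flagging possible split-read halves
partial_placements <- function(rest, genome, genome_index, params, qual, seqs) {
    k <- genome_index$k
    qlen <- nchar(rest$seq)
    keep <- qlen >= k
    rest <- rest[keep]; qlen <- qlen[keep]
    if (nrow(rest) == 0L) return(alignment_table())
    q2 <- rbindlist(list(
        data.table(qid = paste0(rest$read_id, "|+"), seq = rest$seq, qlen = qlen),
        data.table(qid = paste0(rest$read_id, "|-"), seq = revcomp(rest$seq),
                   qlen = qlen)))
    seeds <- rbindlist(list(
        data.table(qid = q2$qid, kmer = substring(q2$seq, 1L, k), soff = 0L,
                   qlen = q2$qlen),
        data.table(qid = q2$qid, kmer = substring(q2$seq, q2$qlen - k + 1L,
                                                  q2$qlen),
                   soff = q2$qlen - k, qlen = q2$qlen)))
    hits <- genome_index$index[seeds, on = "kmer", nomatch = NULL,
                               allow.cartesian = TRUE]
    if (nrow(hits) == 0L) return(alignment_table())
    hits[, start := pos - soff]
    hits <- unique(hits[, .(qid, sid, start, qlen)])
    hits <- hits[start >= 0 & start + qlen <= genome_index$seq_lens[sid]]
    if (nrow(hits) == 0L) return(alignment_table())
    qseq <- setNames(q2$seq, q2$qid)
    refsub <- substring(genome[hits$sid], hits$start + 1L,
                        hits$start + hits$qlen)
    stub_mm <- min(1L, params$max_mismatches)
    ps <- cpp_prefix_suffix(refsub, qseq[hits$qid], stub_mm)
    hits[, `:=`(pref = ps[, 1], pref_mm = ps[, 2],
                suf = ps[, 3], suf_mm = ps[, 4])]
    hits[, stub := pmax(pref, suf)]
    hits[, clip := qlen - stub]
    hits <- hits[stub >= params$min_stub &
                 clip >= ceiling(params$partial_frac * qlen) & stub < qlen]
    if (nrow(hits) == 0L) return(alignment_table())
    hits[, read_id := sub("\\|[+-]$", "", qid)]
    hits[, ori := sub("^.*\\|", "", qid)]
    hits[, score := ifelse(pref >= suf, pref - 3 * pref_mm, suf - 3 * suf_mm)]
    setorder(hits, read_id, -score, sid, start)
    hits <- hits[, head(.SD, 1L), by = read_id]
    use_pref <- hits$pref >= hits$suf
    data.table(read_id = hits$read_id, contig = hits$sid,
               pos = ifelse(use_pref, hits$start, hits$start + hits$clip),
               strand = hits$ori,
               cigar = ifelse(use_pref,
                              paste0(hits$stub, "M", hits$clip, "S"),
                              paste0(hits$clip, "S", hits$stub, "M")),
               score = hits$score, uniqueness = "partial",
               read_quality = qual[hits$read_id], target_space = "genome",
               seq = seqs[hits$read_id])
}

alignment_table <- function() {
    data.table(read_id = character(0), contig = character(0),
               pos = numeric(0), strand = character(0), cigar = character(0),
               score = numeric(0), uniqueness = character(0),
               read_quality = numeric(0), target_space = character(0),
               seq = character(0))
}

#' Map a single read
#'
#' Convenience wrapper over [map_reads()] for one read.
#'
#' @param read list or one-row data frame with `read_id`, `seq`, optional
#'   `read_quality`.
#' @inheritParams map_reads
#' @return one-or-more-row alignment table.
#' @export
map_read <- function(read, genome, annotation = NULL,
                     params = mapping_params(),
                     genome_index = NULL, tx_index = NULL) {
    map_reads(as.data.table(read[c("read_id", "seq",
                                   intersect("read_quality", names(read)))]),
              genome, annotation, params, genome_index, tx_index)
}

#' Project a transcript-space alignment to genome coordinates
#'
#' M runs are split at exon boundaries with N gaps of the exact intron
#' lengths; minus-strand transcripts are handled so the emitted record is on
#' genome forward coordinates with the read strand flipped.
#'
#' @param transcript_alignment list with `tstart`, `tend` (0-based half-open
#'   interval on the spliced transcript) and `read_strand` (`"+"` when the
#'   read matches the transcript sense sequence).
#' @param transcript_model exon rows of one transcript (a transcript model
#'   table subset).
#' @return list with `contig`, `pos` (0-based), `cigar`, `strand`.
#' @export
project_to_genome <- function(transcript_alignment, transcript_model) {
    m <- as.data.table(transcript_model)
    setorder(m, start)
    exons <- as.matrix(m[, .(start, end)])
    strand <- m$strand[1L]
    blocks <- cdna_blocks(exons, strand, transcript_alignment$tstart,
                          transcript_alignment$tend)
    rs <- transcript_alignment$read_strand %||% "+"
    gstrand <- if (strand == "+") rs else c("+" = "-", "-" = "+")[[rs]]
    list(contig = m$contig[1L], pos = unname(blocks[1L, 1L]),
         cigar = cigar_from_blocks(blocks), strand = unname(gstrand))
}

#' Filter alignments on read quality and mapping score
#'
#' Keeps mapped records with `read_quality >= min_read_quality` and
#' `score >= min_mapping_score`; unmapped records are always dropped here
#' (they stay available in the rescue candidate pool).  Idempotent.
#'
#' @param alignments alignment table.
#' @param params a [mapping_params()] object.
#' @export
quality_filter <- function(alignments, params = mapping_params()) {
    alignments[uniqueness != "unmapped" &
               read_quality >= params$min_read_quality &
               score >= params$min_mapping_score]
}
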