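#' Transcript assembly parameters
#'
#' Mirrors the thresholded behaviour of a reference-guided assembler run
#' with a minimum of 2 uniquely mapped high-quality reads per transcribed
#' region, a minimum isoform fraction of 0.3 and a minimum junction fraction
#' of 0.1.
#'
#' @param min_unique_reads minimum unique-read support per coverage island.
#' @param isoform_fraction minor-isoform path support threshold, as a
#'   fraction of the best path at the locus.
#' @param junction_fraction junction support threshold, as a fraction of the
#'   best junction sharing a splice site.
#' @param max_intron maximum intron length in bp.
#' @param max_isoforms cap on enumerated isoform paths per locus.
#' @return object of class `assembly_params`.
#' @export
assembly_params <- function(min_unique_reads = 2L, isoform_fraction = 0.3,
                            junction_fraction = 0.1, max_intron = 100000L,
                            max_isoforms = 8L) {
    if (isoform_fraction < 0 || isoform_fraction > 1 ||
        junction_fraction < 0 || junction_fraction > 1)
        stop("fractions must lie in [0, 1]")
    structure(as.list(environment()), class = "assembly_params")
}

# explode alignment cigars into per-block rows (mapped M runs only)
alignment_blocks <- function(alignments) {
    a <- alignments[uniqueness %in% c("unique", "multi", "partial")]
    empty <- data.table(read_id = character(0), contig = character(0),
                        strand = character(0), start = numeric(0),
                        end = numeric(0), uniqueness = character(0))
    if (nrow(a) == 0L) return(empty)
    rl <- GenomicAlignments::cigarRangesAlongReferenceSpace(
        a$cigar, pos = as.integer(a$pos + 1), ops = "M")
    n_per <- S4Vectors::elementNROWS(rl)
    flat <- unlist(rl, use.names = FALSE)
    i <- rep(seq_len(nrow(a)), n_per)
    data.table(read_id = a$read_id[i], contig = a$contig[i],
               strand = a$strand[i], start = IRanges::start(flat) - 1,
               end = as.numeric(IRanges::end(flat)),
               uniqueness = a$uniqueness[i])
}

#' Coverage islands of mapped reads
#'
#' Maximal intervals of non-zero coverage on one contig strand.  Coverage
#' evidence comes from uniquely mapped reads plus the matched stubs of
#' partial (clipped) alignments -- as in a SAM fed to a reference-guided
#' assembler, where soft-clipped records still cover their matched bases --
#' but the support threshold (`min_unique_reads`) counts uniquely mapped
#' reads only; islands below it are discarded.
#'
#' @param alignments alignment table (already quality-filtered/screened).
#' @param contig,strand the contig strand to scan.
#' @param params an [assembly_params()] object.
#' @return `data.table` with `contig`, `strand`, `start`, `end`, `support`.
#' @export
coverage_islands <- function(alignments, contig, strand,
                             params = assembly_params()) {
    ctg <- contig; str <- strand
    blk <- alignment_blocks(alignments[uniqueness %in% c("unique", "partial")])
    blk <- blk[contig == ctg & strand == str]
    empty <- data.table(contig = character(0), strand = character(0),
                        start = numeric(0), end = numeric(0),
                        support = integer(0))
    if (nrow(blk) == 0L) return(empty)
    ir <- IRanges::IRanges(blk$start + 1L, blk$end)  # 1-based closed
    isl <- IRanges::reduce(ir)
    # support: number of distinct uniquely mapped reads within the island
    uq <- which(blk$uniqueness == "unique")
    ov <- IRanges::findOverlaps(ir[uq], isl)
    sup <- data.table(island = S4Vectors::subjectHits(ov),
                      read_id = blk$read_id[uq][S4Vectors::queryHits(ov)])
    sup <- sup[, .(support = length(unique(read_id))), by = island]
    out <- data.table(contig = ctg, strand = str,
                      start = IRanges::start(isl) - 1,
                      end = as.numeric(IRanges::end(isl)),
                      support = 0L)
    out$support[sup$island] <- sup$support
    out <- out[support >= params$min_unique_reads]
    out[]
}

#' Splice junctions supported by split alignments
#'
#' Tallies N gaps of split (N-containing) alignments into junctions and
#' applies the junction-fraction rule: a junction is kept only when its
#' support is at least `junction_fraction` times the support of the best
#' junction sharing either splice site.
#'
#' @param split_alignments alignment table (unique records with N cigars).
#' @param params an [assembly_params()] object.
#' @return `data.table` with `contig`, `strand`, `donor`, `acceptor`,
#'   `support`.
#' @export
junction_graph <- function(split_alignments, params = assembly_params()) {
    empty <- data.table(contig = character(0), strand = character(0),
                        donor = numeric(0), acceptor = numeric(0),
                        support = integer(0))
    a <- split_alignments[uniqueness == "unique" & grepl("N", cigar, fixed = TRUE)]
    if (nrow(a) == 0L) return(empty)
    rl <- GenomicAlignments::cigarRangesAlongReferenceSpace(
        a$cigar, pos = as.integer(a$pos + 1), ops = "N")
    n_per <- S4Vectors::elementNROWS(rl)
    flat <- unlist(rl, use.names = FALSE)
    i <- rep(seq_len(nrow(a)), n_per)
    # an N run over 1-based [s, e] implies donor = s-1, acceptor = e (0-based)
    j <- data.table(contig = a$contig[i], strand = a$strand[i],
                    donor = IRanges::start(flat) - 1,
                    acceptor = as.numeric(IRanges::end(flat)))
    if (nrow(j) == 0L) return(empty)
    j <- j[acceptor - donor <= params$max_intron & acceptor > donor]
    jj <- j[, .(support = .N), by = .(contig, strand, donor, acceptor)]
    # best support among junctions sharing a donor or an acceptor
    jj[, best := support]
    jj[, best := pmax(best, max(support)), by = .(contig, strand, donor)]
    jj[, best := pmax(best, max(support)), by = .(contig, strand, acceptor)]
    jj <- jj[support >= params$junction_fraction * best]
    jj[, best := NULL]
    setorder(jj, contig, strand, donor, acceptor)
    jj[]
}

#' Chain coverage islands and junctions into transcript models
#'
#' Junction-consistent paths are enumerated greedily by descending support;
#' paths below `isoform_fraction` of the best path at the locus are dropped;
#' islands used by no retained multi-exon path become single-exon models.
#' Exon boundaries interior to a path are trimmed to the junction's
#' donor/acceptor coordinates.
#'
#' @param islands table from [coverage_islands()] (any number of contig
#'   strands).
#' @param junctions table from [junction_graph()].
#' @param params an [assembly_params()] object.
#' @return transcript model table with provenance `"shortread"`.
#' @export
call_transcripts <- function(islands, junctions, params = assembly_params()) {
    out <- list()
    tcount <- 0L
    n_orphan <- 0L
    if (nrow(islands) == 0L)
        return(tx_table(character(0), character(0), character(0),
                        character(0), numeric(0), numeric(0)))
    for (grp in split(islands, by = c("contig", "strand"), sorted = TRUE)) {
        if (nrow(grp) == 0L) next
        setorder(grp, start)
        grp[, island_id := seq_len(.N)]
        ctg <- grp$contig[1L]; str <- grp$strand[1L]
        jn <- junctions[contig == ctg & strand == str]
        # attach junction endpoints to islands
        if (nrow(jn)) {
            jn[, from := findInterval(donor, grp$start)]
            jn[, to := findInterval(acceptor, grp$start)]
            # donor must fall inside island 'from'; acceptor inside 'to'
            f <- jn$from; t <- jn$to
            ok <- f >= 1L & f <= nrow(grp) & t >= 1L & t <= nrow(grp)
            iv <- which(ok)
            ok[iv] <- jn$donor[iv] <= grp$end[f[iv]] &
                jn$donor[iv] > grp$start[f[iv]] &
                jn$acceptor[iv] >= grp$start[t[iv]] &
                jn$acceptor[iv] < grp$end[t[iv]]
            n_orphan <- n_orphan + sum(!ok)
            jn <- jn[ok & from < to]
        }
        used <- rep(FALSE, nrow(grp))
        if (nrow(jn)) {
            setorder(jn, from, -support)
            # enumerate junction-consistent paths per connected component
            comp <- island_components(nrow(grp), jn)
            for (cc in unique(comp)) {
                nodes <- which(comp == cc)
                jc <- jn[from %in% nodes]
                if (nrow(jc) == 0L) next
                paths <- enumerate_paths(nodes, jc, params$max_isoforms)
                if (length(paths) == 0L) next
                psup <- vapply(paths, function(p) p$support, numeric(1))
                keep <- psup >= params$isoform_fraction * max(psup)
                paths <- paths[keep][order(-psup[keep])]
                for (p in paths) {
                    tcount <- tcount + 1L
                    ids <- p$nodes
                    ex_start <- grp$start[ids]
                    ex_end <- grp$end[ids]
                    # trim interior boundaries to the junction coordinates
                    ex_end[-length(ids)] <- p$donors
                    ex_start[-1L] <- p$acceptors
                    out[[length(out) + 1L]] <- data.table(
                        transcript_id = sprintf("asm%05d", tcount),
                        gene_id = sprintf("locus_%s%s_%d", ctg, str, cc),
                        contig = ctg, strand = str,
                        start = ex_start, end = ex_end,
                        support = p$support)
                    used[ids] <- TRUE
                }
            }
        }
        for (i in which(!used)) {
            tcount <- tcount + 1L
            out[[length(out) + 1L]] <- data.table(
                transcript_id = sprintf("asm%05d", tcount),
                gene_id = sprintf("locus_%s%s_s%d", ctg, str, i),
                contig = ctg, strand = str,
                start = grp$start[i], end = grp$end[i],
                support = as.numeric(grp$support[i]))
        }
    }
    if (n_orphan > 0L)
        message(n_orphan, " junction(s) with an endpoint in no coverage ",
                "island; ignored")
    if (length(out) == 0L)
        return(tx_table(character(0), character(0), character(0),
                        character(0), numeric(0), numeric(0)))
    e <- rbindlist(out)
    tx_table(e$transcript_id, e$gene_id, e$contig, e$strand, e$start, e$end,
             provenance = "shortread", support = e$support)
}

# connected components of islands under junction edges (union-find)
island_components <- function(n, jn) {
    parent <- seq_len(n)
    find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
    for (i in seq_len(nrow(jn))) {
        a <- find(jn$from[i]); b <- find(jn$to[i])
        if (a != b) parent[b] <- a
    }
    vapply(seq_len(n), find, integer(1))
}

# greedy enumeration of junction-consistent island paths, descending support
enumerate_paths <- function(nodes, jc, max_isoforms) {
    sources <- setdiff(unique(jc$from), unique(jc$to))
    paths <- list()
    walk <- function(node, acc_nodes, donors, acceptors, sup) {
        if (length(paths) >= max_isoforms) return(invisible())
        nxt <- jc[from == node]
        if (nrow(nxt) == 0L) {
            if (length(acc_nodes) >= 2L)
                paths[[length(paths) + 1L]] <<-
                    list(nodes = acc_nodes, donors = donors,
                         acceptors = acceptors, support = sup)
            return(invisible())
        }
        setorder(nxt, -support)
        for (i in seq_len(nrow(nxt))) {
            if (length(paths) >= max_isoforms) break
            walk(nxt$to[i], c(acc_nodes, nxt$to[i]),
                 c(donors, nxt$donor[i]), c(acceptors, nxt$acceptor[i]),
                 min(sup, nxt$support[i]))
        }
    }
    for (s in sources)
        walk(s, s, numeric(0), numeric(0), Inf)
    paths
}

#' Assemble quality-filtered alignments into transcript models
#'
#' Convenience driver: coverage islands per expressed contig strand,
#' junction graph from split reads, then [call_transcripts()].
#'
#' @param alignments quality-filtered alignment table.
#' @param params an [assembly_params()] object.
#' @return transcript model table.
#' @export
assemble_transcripts <- function(alignments, params = assembly_params()) {
    uni <- alignments[uniqueness == "unique"]
    cov <- alignments[uniqueness %in% c("unique", "partial")]
    strata <- unique(uni[, .(contig, strand)])
    isl <- rbindlist(lapply(seq_len(nrow(strata)), function(i)
        coverage_islands(cov, strata$contig[i], strata$strand[i], params)))
    if (length(isl) == 0L || nrow(isl) == 0L)
        return(tx_table(character(0), character(0), character(0),
                        character(0), numeric(0), numeric(0)))
    jn <- junction_graph(uni, params)
    call_transcripts(isl, jn, params)
}
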