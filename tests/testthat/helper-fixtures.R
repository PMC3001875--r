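library(data.table)

## ---- shared small fixtures (built once per test run) --------------------

small_world <- local({
    cache <- NULL
    function() {
        if (is.null(cache)) {
            g <- generate_genome(genome_params(
                n_contigs = 10L, contig_length_range = c(5000L, 12000L),
                at_fraction = 0.65, repeat_fraction = 0.05, seed = 7L))
            tr <- generate_gene_models(g, 40L, seed = 3L)
            cache <<- list(genome = g, truth = tr)
        }
        cache
    }
})

random_dna_str <- function(n, at = 0.5) {
    p <- c(at / 2, (1 - at) / 2, (1 - at) / 2, at / 2)
    paste(sample(c("A", "C", "G", "T"), n, TRUE, prob = p), collapse = "")
}

## ---- independent oracles -------------------------------------------------

# N50 by direct evaluation of the definition over candidate lengths
oracle_n50 <- function(lengths) {
    half <- sum(lengths) / 2
    cand <- sort(unique(lengths), decreasing = TRUE)
    for (L in cand) if (sum(lengths[lengths >= L]) >= half) return(L)
    min(lengths)
}

# exhaustive six-frame ORF enumeration: every boundary/ATG start against
# its first following stop (or the boundary), anchored readings preferred
oracle_orf <- function(seq) {
    L <- nchar(seq)
    if (L < 3) return(NULL)
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
    frames <- list(`1` = seq, `2` = substr(seq, 2, L), `3` = substr(seq, 3, L),
                   `-1` = rc, `-2` = substr(rc, 2, L), `-3` = substr(rc, 3, L))
    stops <- c("TAA", "TAG", "TGA")
    best <- NULL
    all_cands <- list()
    for (fi in seq_along(frames)) {
        f <- frames[[fi]]
        nc <- nchar(f) %/% 3
        if (nc == 0) next
        cod <- substring(f, 3 * (1:nc) - 2, 3 * (1:nc))
        stop_at <- which(cod %in% stops)
        starts <- unique(c(1L, which(cod == "ATG")))
        for (s in starts) {
            if (s != 1L && cod[s] != "ATG") next
            nxt <- stop_at[stop_at >= s]
            e <- if (length(nxt)) nxt[1] - 1L else nc
            if (e < s) next
            # a mid-sequence start must be ATG; reading must not contain a stop
            if (s != 1L && cod[s] != "ATG") next
            has_start <- cod[s] == "ATG"
            has_stop <- length(nxt) > 0
            # boundary start is only legal at codon 1 (checked above)
            len <- e - s + 1L
            cand <- list(len = len, anchored = has_start || has_stop,
                         has_start = has_start, has_stop = has_stop,
                         frame = c(1L, 2L, 3L, -1L, -2L, -3L)[fi], s = s)
            all_cands[[length(all_cands) + 1L]] <- cand
            better <- is.null(best) ||
                (cand$anchored && !best$anchored) ||
                (cand$anchored == best$anchored && cand$len > best$len)
            if (better) best <- cand
        }
    }
    if (is.null(best)) return(NULL)
    cls <- if (best$has_start && best$has_stop) "complete"
           else if (best$has_stop) "missing_start"
           else if (best$has_start) "missing_stop"
           else "missing_both"
    n_top <- sum(vapply(all_cands, function(cc)
        cc$anchored == best$anchored && cc$len == best$len, logical(1)))
    list(len = best$len, class = cls, frame = best$frame, n_top = n_top)
}

# per-base brute-force projection of a spliced interval to the genome
oracle_blocks <- function(exons, strand, s, e) {
    gmap <- unlist(lapply(seq_len(nrow(exons)),
                          function(i) exons[i, 1]:(exons[i, 2] - 1)))
    if (strand == "-") gmap <- rev(gmap)
    pos <- sort(gmap[(s + 1):e])
    brk <- c(0, which(diff(pos) != 1), length(pos))
    t(vapply(seq_len(length(brk) - 1), function(k)
        c(pos[brk[k] + 1], pos[brk[k + 1]] + 1), numeric(2)))
}

# reference local alignment via Biostrings (never used by the package code)
oracle_local <- function(a, b) {
    mat <- Biostrings::nucleotideSubstitutionMatrix(1, -2)
    pa <- Biostrings::pairwiseAlignment(a, b, type = "local",
                                        substitutionMatrix = mat,
                                        gapOpening = 0, gapExtension = 3)
    list(score = Biostrings::score(pa),
         matches = Biostrings::nmatch(pa),
         len = nchar(as.character(Biostrings::alignedPattern(pa))))
}

# error-free reads tiling a transcript end to end with fixed stride
tiling_reads <- function(seq, read_len, stride, prefix = "t") {
    L <- nchar(seq)
    starts <- unique(c(seq(1, L - read_len + 1, by = stride), L - read_len + 1))
    out <- substring(seq, starts, starts + read_len - 1)
    names(out) <- sprintf("%s%04d", prefix, seq_along(out))
    out
}
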