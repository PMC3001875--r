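#' Parameters for cross-platform transcript merging
#'
#' The operative homology filter follows the published rule: a match needs
#' 95% or better identity across 50 nucleotides or more.  `min_score` is a
#' seed-anchored local-alignment score floor standing in for a
#' database-size-dependent E-value cutoff, deliberately set below the
#' score an alignment passing the 95%/50-nt rule must reach.
#'
#' @param min_identity minimum alignment identity.
#' @param min_match_length minimum alignment length in nt.
#' @param min_score minimum local alignment score (+1/-2/-3 scoring).
#' @param k seed k-mer length for candidate pairing.
#' @param collapse_tail_tol maximum unaligned terminal overhang (bp) still
#'   treated as a "terminal difference" during isoform collapse.
#' @return object of class `merge_params`.
#' @export
merge_params <- function(min_identity = 0.95, min_match_length = 50L,
                         min_score = 40, k = 16L, collapse_tail_tol = 5L) {
    if (min_identity <= 0 || min_identity > 1) stop("min_identity in (0,1]")
    if (min_match_length < 1) stop("min_match_length >= 1")
    structure(as.list(environment()), class = "merge_params")
}

# best seeded local alignment of query (both strands) vs subject (forward).
# Returns NULL or list(score, matches, len, identity, strand,
# q_start, q_end, s_start, s_end) with 1-based coordinates on the query
# strand actually aligned.
seeded_local_align <- function(query, subject, params) {
    best <- NULL
    for (str in c("+", "-")) {
        q <- if (str == "-") revcomp(query) else query
        if (nchar(q) < params$k || nchar(subject) < params$k) next
        # quick shared-kmer screen
        nq <- nchar(q) - params$k + 1L
        qk <- substring(q, 1:nq, params$k:nchar(q))
        ns <- nchar(subject) - params$k + 1L
        sk <- substring(subject, 1:ns, params$k:nchar(subject))
        if (!any(qk %chin% sk)) next
        r <- cpp_sw_local(q, subject)
        if (r[1] == 0) next
        cand <- list(score = r[1], matches = r[2], len = r[3],
                     identity = r[2] / r[3], strand = str,
                     q_start = r[4], q_end = r[5],
                     s_start = r[6], s_end = r[7])
        if (is.null(best) || cand$score > best$score) best <- cand
    }
    best
}

#' Homology screen of query transcripts against subject transcripts
#'
#' A query is matched when some local alignment to any subject (either
#' strand) spans at least `min_match_length` nt at identity >=
#' `min_identity`.  The best hit per query is recorded by identity x
#' length.
#'
#' @param queries,subjects named character vectors of sequences.
#' @param params a [merge_params()] object.
#' @return list with `matched`, `unmatched` (query ids) and `hits`
#'   (`data.table`: `query`, `subject`, `identity`, `aln_len`, `score`).
#' @export
homology_screen <- function(queries, subjects, params = merge_params()) {
    hits_empty <- data.table(query = character(0), subject = character(0),
                             identity = numeric(0), aln_len = integer(0),
                             score = numeric(0))
    if (length(queries) == 0L || length(subjects) == 0L)
        return(list(matched = character(0), unmatched = names(queries),
                    hits = hits_empty))
    # k-mer prescreen: candidate query/subject pairs sharing a seed
    k <- params$k
    kmerize <- function(seqs, stride = 1L) {
        rbindlist(lapply(names(seqs), function(nm) {
            L <- nchar(seqs[[nm]])
            if (L < k) return(NULL)
            st <- seq(1L, L - k + 1L, by = stride)
            data.table(kmer = substring(seqs[[nm]], st, st + k - 1L), id = nm)
        }))
    }
    qk <- unique(rbindlist(list(kmerize(queries, 2L),
                                kmerize(setNames(revcomp(queries),
                                                 names(queries)), 2L))))
    sk <- unique(kmerize(subjects))
    setkey(sk, kmer)
    pairs <- unique(sk[qk, on = "kmer", nomatch = NULL,
                       allow.cartesian = TRUE][, .(query = i.id, subject = id)])
    rows <- list()
    for (r in seq_len(nrow(pairs))) {
        al <- seeded_local_align(queries[[pairs$query[r]]],
                                 subjects[[pairs$subject[r]]], params)
        if (is.null(al)) next
        if (al$len >= params$min_match_length &&
            al$identity >= params$min_identity &&
            al$score >= params$min_score)
            rows[[length(rows) + 1L]] <- data.table(
                query = pairs$query[r], subject = pairs$subject[r],
                identity = al$identity, aln_len = as.integer(al$len),
                score = al$score)
    }
    hits <- if (length(rows)) rbindlist(rows) else hits_empty
    if (nrow(hits)) {
        setorder(hits, query, -identity, -aln_len, subject)
        best <- hits[, head(.SD, 1L), by = query]
    } else best <- hits
    matched <- unique(hits$query)
    list(matched = matched,
         unmatched = setdiff(names(queries), matched),
         hits = best, all_hits = hits)
}

# decide whether two sequences differ only terminally; if so return the
# merged superstring, else NULL
terminal_merge <- function(sa, sb, params) {
    al <- seeded_local_align(sa, sb, params)
    if (is.null(al) || al$identity < params$min_identity) return(NULL)
    if (al$strand == "-") sa <- revcomp(sa)  # work on the aligned strand
    la <- nchar(sa); lb <- nchar(sb)
    tol <- params$collapse_tail_tol
    left_a <- al$q_start - 1L; left_b <- al$s_start - 1L
    right_a <- la - al$q_end;  right_b <- lb - al$s_end
    # internal difference: both sequences have residue beyond the alignment
    if (min(left_a, left_b) > tol || min(right_a, right_b) > tol) return(NULL)
    # overlap must cover the shared span substantially
    if (al$len < 0.8 * min(la, lb)) return(NULL)
    left <- if (left_a >= left_b) substr(sa, 1L, left_a) else
        substr(sb, 1L, left_b)
    mid <- substr(sb, al$s_start, al$s_end)
    right <- if (right_a >= right_b) substr(sa, al$q_end + 1L, la) else
        substr(sb, al$s_end + 1L, lb)
    paste0(left, mid, right)
}

#' Collapse isoforms differing only at their termini
#'
#' Within each group (isogroup when given, otherwise k-mer-linked clusters),
#' two sequences merge when one aligns to the other end-to-end over their
#' shared span at >= `min_identity` with differences confined to terminal
#' extensions; the representative is the longest superstring.  Sequences
#' differing internally (e.g. by a cassette exon) stay separate.
#'
#' @param sequences named character vector.
#' @param groups optional grouping factor (e.g. isogroup ids) aligned with
#'   `sequences`; collapse is only attempted within a group.
#' @param params a [merge_params()] object.
#' @return list with `contigs` (named character vector of representatives)
#'   and `members` (list of input ids per representative).
#' @export
collapse_isoforms <- function(sequences, groups = NULL,
                              params = merge_params()) {
    if (length(sequences) == 0L)
        return(list(contigs = sequences, members = list()))
    if (is.null(groups)) groups <- rep("all", length(sequences))
    reps <- character(0); mem <- list()
    for (g in unique(groups)) {
        seqs <- sequences[groups == g]
        ids <- names(seqs)
        cur_seq <- as.list(seqs)
        cur_mem <- as.list(ids)
        repeat {
            merged <- FALSE
            n <- length(cur_seq)
            if (n >= 2L) {
                for (a in seq_len(n - 1L)) {
                    for (b in (a + 1L):n) {
                        m <- terminal_merge(cur_seq[[a]], cur_seq[[b]], params)
                        if (!is.null(m)) {
                            cur_seq[[a]] <- m
                            cur_mem[[a]] <- c(cur_mem[[a]], cur_mem[[b]])
                            cur_seq[[b]] <- NULL
                            cur_mem[[b]] <- NULL
                            merged <- TRUE
                            break
                        }
                    }
                    if (merged) break
                }
            }
            if (!merged) break
        }
        rep_ids <- vapply(cur_mem, function(m) m[1L], character(1))
        reps <- c(reps, setNames(unlist(cur_seq), rep_ids))
        mem <- c(mem, setNames(cur_mem, rep_ids))
    }
    list(contigs = reps, members = mem)
}

#' Merge long-read and short-read transcript sets
#'
#' The published decision cascade: (1) homology-screen short-read cDNAs
#' against the collapsed long-read contigs; (2) of the unmatched, keep
#' multi-exon models (spliced-read evidence) and drop single-exon ones
#' (possible pseudogene/duplication mappings); (3) co-assemble long-read
#' contigs with the retained short-read cDNAs by the terminal-collapse
#' rule; (4) from the resulting singletons drop any supported only by
#' single-exon short-read evidence; (5) emit the merged set with
#' provenance.  Every decision is logged.
#'
#' @param longread_contigs named character vector (already collapsed).
#' @param shortread_seqs named character vector of short-read cDNAs, keyed
#'   by transcript id.
#' @param shortread_n_exons named integer vector of exon counts for every
#'   short-read transcript.
#' @param params a [merge_params()] object.
#' @return list of class `merge_report`: `final_seqs`, `provenance`
#'   (`data.table`: id, provenance), `log` (decision log), and the counts
#'   `n_matched_short`, `n_unmatched_multi_exon_kept`,
#'   `n_unmatched_single_exon_dropped`, `n_assembled_contigs`,
#'   `n_singletons_kept`, `n_singletons_dropped_single_exon`,
#'   `final_transcripts`.
#' @export
merge_datasets <- function(longread_contigs, shortread_seqs,
                           shortread_n_exons, params = merge_params()) {
    miss <- setdiff(names(shortread_seqs), names(shortread_n_exons))
    if (length(miss))
        stop("short-read models lacking exon counts: ",
             paste(head(miss, 5), collapse = ", "))
    log <- list()
    note <- function(id, step, action, reason)
        log[[length(log) + 1L]] <<- data.table(id = id, step = step,
                                               action = action,
                                               reason = reason)
    # step 1: homology screen
    scr <- homology_screen(shortread_seqs, longread_contigs, params)
    if (length(scr$matched))
        note(scr$matched, "screen", "matched", "homology to long-read contig")
    # step 2: partition unmatched by exon count
    unm <- scr$unmatched
    multi <- unm[shortread_n_exons[unm] >= 2L]
    single <- setdiff(unm, multi)
    if (length(multi))
        note(multi, "partition", "kept", "unmatched but multi-exon")
    if (length(single))
        note(single, "partition", "dropped", "unmatched single-exon")
    # step 3: co-assembly by the terminal-collapse rule
    pool <- c(longread_contigs, shortread_seqs[c(scr$matched, multi)])
    src <- c(rep("longread", length(longread_contigs)),
             rep("shortread", length(scr$matched) + length(multi)))
    names(src) <- names(pool)
    co <- collapse_kmer_groups(pool, params)
    n_members <- vapply(co$members, length, integer(1))
    assembled <- names(co$contigs)[n_members >= 2L &
        vapply(co$members, function(m) length(unique(src[m])) >= 1L,
               logical(1))]
    singles <- names(co$contigs)[n_members == 1L]
    # step 4: drop singletons supported only by single-exon short-read data
    drop_single <- singles[vapply(co$members[singles], function(m)
        all(src[m] == "shortread" & shortread_n_exons[m] == 1L),
        logical(1))]
    keep_singles <- setdiff(singles, drop_single)
    if (length(drop_single))
        note(drop_single, "singleton_filter", "dropped",
             "singleton with only single-exon short-read evidence")
    if (length(keep_singles))
        note(keep_singles, "singleton_filter", "kept", "singleton retained")
    if (length(assembled))
        note(assembled, "coassembly", "assembled",
             "collapsed with another transcript")
    final_ids <- c(assembled, keep_singles)
    final_seqs <- co$contigs[final_ids]
    prov <- vapply(co$members[final_ids], function(m) {
        s <- unique(src[m])
        if (length(s) == 2L) "combined"
        else if (s == "longread") "longread_only"
        else "shortread_only_multiexon"
    }, character(1))
    structure(list(
        final_seqs = final_seqs,
        provenance = data.table(id = final_ids, provenance = unname(prov)),
        log = rbindlist(log),
        n_matched_short = length(scr$matched),
        n_unmatched_multi_exon_kept = length(multi),
        n_unmatched_single_exon_dropped = length(single),
        n_assembled_contigs = length(assembled),
        n_singletons_kept = length(keep_singles),
        n_singletons_dropped_single_exon = length(drop_single),
        final_transcripts = length(final_ids)),
        class = "merge_report")
}

# collapse over homology-linked clusters (no isogroup structure available):
# sequences sharing a significant hit are grouped, then collapsed in-group
collapse_kmer_groups <- function(pool, params) {
    if (length(pool) <= 1L)
        return(collapse_isoforms(pool, params = params))
    scr <- homology_screen(pool, pool, params)
    pairs <- scr$all_hits[query != subject, .(query, subject)]
    g <- igraph::graph_from_data_frame(
        d = data.frame(a = character(0), b = character(0)),
        directed = FALSE, vertices = data.frame(name = names(pool)))
    if (nrow(pairs))
        g <- igraph::add_edges(g, as.vector(rbind(pairs$query, pairs$subject)))
    comp <- igraph::components(g)$membership
    collapse_isoforms(pool, groups = comp[names(pool)], params = params)
}

#' Reciprocal comparison of two transcript sets
#'
#' Directional counts under [homology_screen()]: how many members of A have
#' a hit in B, and vice versa; asymmetry quantifies redundancy.
#'
#' @param setA,setB named character vectors of sequences.
#' @param params a [merge_params()] object.
#' @return list with `a_with_hit_in_b` and `b_with_hit_in_a`.
#' @export
compare_annotation <- function(setA, setB, params = merge_params()) {
    ab <- homology_screen(setA, setB, params)
    ba <- homology_screen(setB, setA, params)
    list(a_with_hit_in_b = length(ab$matched),
         b_with_hit_in_a = length(ba$matched))
}
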