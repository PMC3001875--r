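#' Suffix-prefix overlap graph of long reads
#'
#' Candidate pairs are found by shared k-mers (both orientations) and
#' verified by ungapped comparison of the implied overlap; an edge requires
#' an overlap of at least `min_overlap` bp at identity >= `min_identity`.
#' Containments are recorded separately from proper suffix-prefix overlaps.
#'
#' @param reads named character vector of read sequences (or a `read_set`).
#' @param min_overlap minimum overlap length in bp (>= 20).
#' @param min_identity minimum overlap identity, in (0.8, 1].
#' @param k seed k-mer length.
#' @param max_kmer_occ k-mers occurring more often than this (repeats) are
#'   skipped during seeding.
#' @return list of class `overlap_graph`: `edges` (`data.table` with `i`,
#'   `j`, `flip` (is j reverse-complemented relative to i), `d` (0-based
#'   offset of j in i's forward coordinates), `ovl`, `identity`,
#'   `contained` in none/j_in_i/i_in_j) and `reads`.
#' @export
overlap_graph <- function(reads, min_overlap = 40L, min_identity = 0.95,
                          k = 16L, max_kmer_occ = 100L) {
    if (inherits(reads, "read_set"))
        reads <- setNames(reads$reads$seq, reads$reads$read_id)
    stopifnot(min_overlap >= 20L, min_identity > 0.8, min_identity <= 1)
    edges_empty <- data.table(i = character(0), j = character(0),
                              flip = logical(0), d = integer(0),
                              ovl = integer(0), identity = numeric(0),
                              contained = character(0))
    if (length(reads) < 2L)
        return(structure(list(edges = edges_empty, reads = reads),
                         class = "overlap_graph"))
    lens <- nchar(reads)
    ids <- names(reads)
    rc <- revcomp(reads)
    kmerize <- function(seqs, ori) {
        rbindlist(lapply(seq_along(seqs), function(ii) {
            L <- nchar(seqs[[ii]])
            if (L < k) return(NULL)
            st <- seq(1L, L - k + 1L, by = 4L)  # stride keeps the table small
            data.table(kmer = substring(seqs[[ii]], st, st + k - 1L),
                       rid = ids[ii], ori = ori, pos = st - 1L)
        }))
    }
    fw <- kmerize(reads, "+")
    # dense anchor set on the forward strand of the "subject" side
    subj <- rbindlist(lapply(seq_along(reads), function(ii) {
        L <- lens[ii]
        if (L < k) return(NULL)
        data.table(kmer = substring(reads[[ii]], 1:(L - k + 1L), k:L),
                   rid = ids[ii], ori = "+", pos = 0:(L - k))
    }))
    subj_rc <- rbindlist(lapply(seq_along(rc), function(ii) {
        L <- lens[ii]
        if (L < k) return(NULL)
        data.table(kmer = substring(rc[[ii]], 1:(L - k + 1L), k:L),
                   rid = ids[ii], ori = "-", pos = 0:(L - k))
    }))
    subj <- rbind(subj, subj_rc)
    occ <- subj[, .N, by = kmer][N <= max_kmer_occ]
    subj <- subj[kmer %in% occ$kmer]
    setkey(subj, kmer)
    hits <- subj[fw, on = "kmer", nomatch = NULL, allow.cartesian = TRUE]
    hits <- hits[rid != i.rid]
    if (nrow(hits) == 0L)
        return(structure(list(edges = edges_empty, reads = reads),
                         class = "overlap_graph"))
    # i = query read (forward), j = subject read in orientation ori;
    # offset of j's start in i's forward coordinates:
    hits[, d := i.pos - pos]
    cand <- hits[, .N, by = .(i = i.rid, j = rid, ori, d)]
    # canonical i < j; an (i+, j ori, d) pairing seen from j is equivalent
    cand <- cand[i < j]
    setorder(cand, i, j, ori, -N)
    cand <- cand[, head(.SD, 3L), by = .(i, j, ori)]
    # batch verification of the implied ungapped overlaps
    si <- reads[cand$i]
    sj <- ifelse(cand$ori == "-", rc[cand$j], reads[cand$j])
    Li <- lens[cand$i]; Lj <- lens[cand$j]
    a <- pmax(0L, cand$d); b <- pmin(Li, cand$d + Lj)
    len <- b - a
    ok <- len >= min_overlap
    idy <- rep(0, nrow(cand))
    if (any(ok)) {
        mm <- cpp_hamming(substring(si[ok], a[ok] + 1L, b[ok]),
                          substring(sj[ok], a[ok] - cand$d[ok] + 1L,
                                    b[ok] - cand$d[ok]))
        idy[ok] <- 1 - mm / len[ok]
    }
    keep <- ok & idy >= min_identity
    edges <- if (any(keep)) {
        data.table(i = cand$i[keep], j = cand$j[keep],
                   flip = cand$ori[keep] == "-",
                   d = as.integer(cand$d[keep]),
                   ovl = as.integer(len[keep]), identity = idy[keep],
                   contained = ifelse(cand$d[keep] >= 0L &
                                      cand$d[keep] + Lj[keep] <= Li[keep],
                                      "j_in_i",
                               ifelse(cand$d[keep] <= 0L &
                                      cand$d[keep] + Lj[keep] >= Li[keep],
                                      "i_in_j", "none")))
    } else edges_empty
    if (nrow(edges)) {
        setorder(edges, i, j, -ovl)
        edges <- edges[, head(.SD, 1L), by = .(i, j)]  # best overlap per pair
    }
    structure(list(edges = edges, reads = reads), class = "overlap_graph")
}

#' Assemble isotigs from an overlap graph
#'
#' Connected components are isogroups (putative genes); within a component,
#' reads are oriented by breadth-first propagation, proper suffix-prefix
#' overlaps form a DAG (transitively reduced), and every maximal
#' source-to-sink path yields one isotig (putative isoform) whose sequence
#' is the majority-vote consensus of its member reads plus contained reads.
#'
#' @param graph an `overlap_graph`.
#' @param max_paths_per_component cap on enumerated isoform paths.
#' @return `data.table` with `isotig_id`, `isogroup_id`, `sequence`,
#'   `n_reads`, `members` (list column of read ids).
#' @export
assemble_isotigs <- function(graph, max_paths_per_component = 10L) {
    reads <- graph$reads
    ids <- names(reads)
    lens <- nchar(reads)
    names(lens) <- ids
    edges <- graph$edges
    empty <- data.table(isotig_id = character(0), isogroup_id = character(0),
                        sequence = character(0), n_reads = integer(0),
                        members = list())
    if (length(reads) == 0L) return(empty)
    g <- igraph::graph_from_data_frame(
        if (nrow(edges)) edges[, .(i, j)] else data.frame(i = character(0),
                                                          j = character(0)),
        directed = FALSE, vertices = data.frame(name = ids))
    comp <- igraph::components(g)$membership
    out <- list()
    it <- 0L
    for (cc in sort(unique(comp))) {
        members <- ids[comp == cc]
        gid <- sprintf("isogroup%04d", cc)
        if (length(members) == 1L) {
            it <- it + 1L
            out[[length(out) + 1L]] <- data.table(
                isotig_id = sprintf("isotig%05d", it), isogroup_id = gid,
                sequence = unname(reads[[members]]), n_reads = 1L,
                members = list(members))
            next
        }
        ce <- edges[i %in% members & j %in% members]
        # orient reads by BFS; drop orientation-conflicting edges
        ori <- setNames(rep(NA, length(members)), members)
        ori[members[1L]] <- FALSE  # FALSE = forward
        queue <- members[1L]
        adj <- split(seq_len(nrow(ce)), ce$i)
        adj2 <- split(seq_len(nrow(ce)), ce$j)
        while (length(queue)) {
            u <- queue[1L]; queue <- queue[-1L]
            for (ei in c(adj[[u]], adj2[[u]])) {
                other <- if (ce$i[ei] == u) ce$j[ei] else ce$i[ei]
                want <- xor(ori[u], ce$flip[ei])
                if (is.na(ori[other])) {
                    ori[other] <- want
                    queue <- c(queue, other)
                }
            }
        }
        ori[is.na(ori)] <- FALSE
        conflict <- ce[xor(ori[i], flip) != ori[j]]
        ce <- ce[xor(ori[i], flip) == ori[j]]
        oseq <- ifelse(ori[members], revcomp(reads[members]), reads[members])
        names(oseq) <- members
        # directed edges in component-oriented coordinates
        de <- NULL
        cont <- NULL
        if (nrow(ce)) {
            dor <- ifelse(ori[ce$i], lens[ce$i] - (ce$d + lens[ce$j]), ce$d)
            de <- data.table(u = ce$i, v = ce$j, off = as.integer(dor),
                             contained = ce$contained)
            swap <- de$off < 0L
            de[swap, c("u", "v", "off") := .(v, u, -off)]
            cont <- de[contained != "none"]
            de <- de[contained == "none" & off > 0L]
        }
        contained_ids <- if (!is.null(cont) && nrow(cont)) unique(cont$v)
                         else character(0)
        # layout runs over maximal (non-contained) reads only
        if (!is.null(de) && nrow(de) && length(contained_ids))
            de <- de[!u %in% contained_ids & !v %in% contained_ids]
        free <- setdiff(members, contained_ids)
        if (length(free) == 0L)
            free <- members[which.max(lens[members])]
        paths <- if (is.null(de) || nrow(de) == 0L) {
            lapply(free, function(m) list(nodes = m, offs = 0L))
        } else {
            de <- transitive_reduce(de)
            enumerate_layout_paths(de, free, max_paths_per_component)
        }
        for (p in paths) {
            it <- it + 1L
            nodes <- p$nodes; offs <- p$offs
            # attach contained reads whose container (possibly itself
            # attached) lies on the path
            if (!is.null(cont) && nrow(cont)) {
                repeat {
                    extra <- cont[u %in% nodes & !v %in% nodes]
                    if (nrow(extra) == 0L) break
                    extra <- extra[, head(.SD, 1L), by = v]
                    nodes <- c(nodes, extra$v)
                    offs <- c(offs, offs[match(extra$u, nodes)] + extra$off)
                }
            }
            sh <- min(offs)
            cons <- cpp_consensus(unname(oseq[nodes]), as.integer(offs - sh))
            out[[length(out) + 1L]] <- data.table(
                isotig_id = sprintf("isotig%05d", it), isogroup_id = gid,
                sequence = cons, n_reads = length(nodes),
                members = list(nodes))
        }
    }
    rbindlist(out)
}

# remove edges implied by a two-step path
transitive_reduce <- function(de) {
    if (nrow(de) < 2L) return(de)
    succ <- split(de$v, de$u)
    keep <- rep(TRUE, nrow(de))
    for (r in seq_len(nrow(de))) {
        u <- de$u[r]; w <- de$v[r]
        mids <- setdiff(succ[[u]], w)
        if (any(vapply(mids, function(v) w %in% (succ[[v]] %||% character(0)),
                       logical(1))))
            keep[r] <- FALSE
    }
    de[keep]
}

# enumerate maximal source-to-sink paths with cumulative layout offsets
enumerate_layout_paths <- function(de, members, max_paths) {
    touched <- union(de$u, de$v)
    sources <- c(setdiff(de$u, de$v), setdiff(members, touched))
    paths <- list()
    succ <- split(seq_len(nrow(de)), de$u)
    walk <- function(node, nodes, offs, depth) {
        if (length(paths) >= max_paths || depth > 200L) return(invisible())
        nxt <- succ[[node]]
        nxt <- nxt[!de$v[nxt] %in% nodes]
        if (is.null(nxt) || length(nxt) == 0L) {
            paths[[length(paths) + 1L]] <<- list(nodes = nodes, offs = offs)
            return(invisible())
        }
        for (ei in nxt)
            walk(de$v[ei], c(nodes, de$v[ei]),
                 c(offs, offs[length(offs)] + de$off[ei]), depth + 1L)
    }
    for (s in sources) {
        if (length(paths) >= max_paths) break
        walk(s, s, 0L, 1L)
    }
    paths
}

#' N50 of a set of contig lengths
#'
#' The largest length L such that contigs of length >= L together contain
#' at least half the total assembled bases.
#'
#' @param lengths positive contig lengths in bp.
#' @return N50 in bp.
#' @export
n50 <- function(lengths) {
    if (length(lengths) == 0L) stop("empty length list")
    if (any(lengths <= 0)) stop("lengths must be positive")
    s <- sort(lengths, decreasing = TRUE)
    s[which(cumsum(s) >= sum(s) / 2)[1L]]
}

#' Assembly saturation curve
#'
#' Assembles seeded random nested subsets of the reads at increasing sizes
#' and records isogroup/isotig counts, N50 and mean contig length --
#' the rarefaction design used to ask whether deeper sequencing would keep
#' discovering genes and isoforms.
#'
#' @param reads named character vector of read sequences.
#' @param subset_sizes ascending subset sizes, each <= number of reads.
#' @param seed RNG seed for the (single, shared) subsampling permutation.
#' @param ... passed to [overlap_graph()].
#' @return `data.table` with one row per subset size: `n_reads`,
#'   `n_isogroups`, `n_isotigs`, `n50`, `mean_contig_length`.
#' @export
saturation_curve <- function(reads, subset_sizes, seed = 1L, ...) {
    if (any(subset_sizes > length(reads)))
        stop("subset size exceeds number of reads")
    perm <- with_seed(seed, sample(seq_along(reads)))
    rows <- lapply(subset_sizes, function(n) {
        if (n == 0L)
            return(data.table(n_reads = 0L, n_isogroups = 0L, n_isotigs = 0L,
                              n50 = 0, mean_contig_length = 0))
        sub <- reads[sort(perm[seq_len(n)])]
        iso <- assemble_isotigs(overlap_graph(sub, ...))
        data.table(n_reads = n,
                   n_isogroups = length(unique(iso$isogroup_id)),
                   n_isotigs = nrow(iso),
                   n50 = n50(nchar(iso$sequence)),
                   mean_contig_length = mean(nchar(iso$sequence)))
    })
    rbindlist(rows)
}
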