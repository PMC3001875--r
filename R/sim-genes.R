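#' Place synthetic gene models on a genome
#'
#' Genes are placed without overlap (any strand): multi-exon genes with the
#' requested exon-count range and optional cassette-skipping isoforms,
#' single-exon genes, and pseudogene-like confounders.  A pseudogene copy is
#' the spliced sequence of a real multi-exon gene, mutated at 1--3% and
#' written back into the genome as an intronless locus with zero expression
#' -- the classic trap for single-exon short-read transcript calls.
#' Baseline expression rates are drawn log-uniformly over `[1, 1000]`.
#'
#' @param genome a `genome_set` from [generate_genome()].
#' @param n_genes total number of gene loci (including pseudogene copies).
#' @param exon_count_range integer length-2, exons per multi-exon gene.
#' @param isoform_prob probability that a gene with >= 3 exons carries a
#'   second, cassette-skipping isoform.
#' @param single_exon_fraction fraction of genes that are single-exon.
#' @param pseudogene_fraction fraction of genes that are pseudogene copies.
#' @param seed integer RNG seed.
#' @param gtf_path optional path; when given the truth annotation is written
#'   as GTF.
#' @return list of class `gene_truth`: `genome` (named contig sequences,
#'   with pseudogene sequence written in), `genes` (per-gene table),
#'   `tx` (truth transcript model table, one transcript per isoform),
#'   `isoforms` (per-isoform relative abundance within gene).
#' @export
generate_gene_models <- function(genome, n_genes,
                                 exon_count_range = c(2L, 6L),
                                 isoform_prob = 0.3,
                                 single_exon_fraction = 0.2,
                                 pseudogene_fraction = 0.05,
                                 seed = 1L,
                                 gtf_path = NULL) {
    stopifnot(inherits(genome, "genome_set"))
    contigs <- genome$contigs
    if (n_genes > 0 && length(contigs) == 0L)
        stop("cannot place genes on an empty genome")
    with_seed(seed, {
        n_single <- round(single_exon_fraction * n_genes)
        n_pseudo <- round(pseudogene_fraction * n_genes)
        n_multi <- n_genes - n_single - n_pseudo
        if (n_multi < 0) stop("fractions exceed 1")
        kinds <- c(rep("multi", n_multi), rep("single", n_single),
                   rep("pseudo", n_pseudo))
        occupied <- lapply(contigs, function(x) IRanges::IRanges())
        clens <- nchar(contigs)
        find_slot <- function(span) {
            ord <- sample(seq_along(contigs))
            for (ci in ord) {
                free <- IRanges::setdiff(IRanges::IRanges(1L, clens[ci]),
                                         occupied[[ci]])
                free <- free[IRanges::width(free) >= span + 20L]
                if (length(free) == 0L) next
                g <- free[sample.int(length(free), 1L)]
                at <- IRanges::start(g) +
                    sample.int(IRanges::width(g) - span - 19L, 1L) - 1L
                return(list(contig = ci, start = at))  # 1-based genomic start
            }
            stop("insufficient contig space to place a gene of span ", span,
                 " bp (largest contig tried: ",
                 names(contigs)[which.max(clens)], ")")
        }
        gene_rows <- list(); exon_rows <- list(); iso_rows <- list()
        multi_pool <- list()  # spliced seq donors for pseudogenes
        gi <- 0L
        for (kind in kinds) {
            gi <- gi + 1L
            gid <- sprintf("g%04d", gi)
            strand <- sample(c("+", "-"), 1L)
            if (kind == "multi") {
                n_ex <- sample(exon_count_range[1]:exon_count_range[2], 1L)
                ex_len <- sample(100:300, n_ex, replace = TRUE)
                in_len <- if (n_ex > 1L)
                    sample(60:500, n_ex - 1L, replace = TRUE) else integer(0)
                span <- sum(ex_len) + sum(in_len)
                slot <- find_slot(span)
                st <- slot$start - 1L  # 0-based
                starts <- st + cumsum(c(0L, head(ex_len, -1) + in_len))
                ends <- starts + ex_len
                baseline <- 10^runif(1, 0, 3)
                iso <- list(seq_len(n_ex))
                share <- 1
                if (n_ex >= 3L && runif(1) < isoform_prob) {
                    skip <- sample(2:(n_ex - 1L), 1L)
                    iso <- c(iso, list(setdiff(seq_len(n_ex), skip)))
                    share <- c(0.7, 0.3)
                }
                for (ii in seq_along(iso)) {
                    tid <- sprintf("%s.%d", gid, ii)
                    sel <- iso[[ii]]
                    exon_rows[[length(exon_rows) + 1L]] <- data.table(
                        transcript_id = tid, gene_id = gid,
                        contig = names(contigs)[slot$contig], strand = strand,
                        start = starts[sel], end = ends[sel])
                    iso_rows[[length(iso_rows) + 1L]] <- data.table(
                        transcript_id = tid, gene_id = gid, share = share[ii])
                }
                gene_rows[[length(gene_rows) + 1L]] <- data.table(
                    gene_id = gid, contig = names(contigs)[slot$contig],
                    strand = strand, n_exons = n_ex,
                    is_single_exon = FALSE, is_pseudogene_copy = FALSE,
                    baseline = baseline, source_gene = NA_character_)
                # make every junction's genomic placement unique: the first
                # and last intron base must differ from the exon base that a
                # shifted split point would consume (intron bases only, so
                # transcript sequences are untouched)
                juncs <- unique(rbindlist(lapply(iso, function(sel) {
                    if (length(sel) < 2L) return(NULL)
                    data.table(d = ends[sel[-length(sel)]],
                               a = starts[sel[-1L]])
                })))
                if (!is.null(juncs) && nrow(juncs)) {
                    s <- contigs[[slot$contig]]
                    base_at <- function(p0) substr(s, p0 + 1L, p0 + 1L)
                    for (p0 in unique(juncs$d)) {
                        avoid <- vapply(juncs[d == p0, a], base_at,
                                        character(1))
                        if (base_at(p0) %in% avoid)
                            substr(s, p0 + 1L, p0 + 1L) <-
                                sample(setdiff(c("A", "C", "G", "T"), avoid),
                                       1L)
                    }
                    for (p0 in unique(juncs$a - 1L)) {
                        avoid <- vapply(juncs[a - 1L == p0, d] - 1L, base_at,
                                        character(1))
                        if (base_at(p0) %in% avoid)
                            substr(s, p0 + 1L, p0 + 1L) <-
                                sample(setdiff(c("A", "C", "G", "T"), avoid),
                                       1L)
                    }
                    contigs[[slot$contig]] <- s
                }
                spliced <- paste(substring(contigs[[slot$contig]],
                                           starts + 1, ends), collapse = "")
                if (strand == "-") spliced <- revcomp(spliced)
                multi_pool[[gid]] <- spliced
                occupied[[slot$contig]] <- IRanges::union(
                    occupied[[slot$contig]],
                    IRanges::IRanges(st + 1L, st + span))
            } else if (kind == "single") {
                len <- sample(200:800, 1L)
                slot <- find_slot(len)
                st <- slot$start - 1L
                tid <- sprintf("%s.1", gid)
                exon_rows[[length(exon_rows) + 1L]] <- data.table(
                    transcript_id = tid, gene_id = gid,
                    contig = names(contigs)[slot$contig], strand = strand,
                    start = st, end = st + len)
                iso_rows[[length(iso_rows) + 1L]] <- data.table(
                    transcript_id = tid, gene_id = gid, share = 1)
                gene_rows[[length(gene_rows) + 1L]] <- data.table(
                    gene_id = gid, contig = names(contigs)[slot$contig],
                    strand = strand, n_exons = 1L,
                    is_single_exon = TRUE, is_pseudogene_copy = FALSE,
                    baseline = 10^runif(1, 0, 3), source_gene = NA_character_)
                occupied[[slot$contig]] <- IRanges::union(
                    occupied[[slot$contig]],
                    IRanges::IRanges(st + 1L, st + len))
            } else { # pseudogene copy of an already-placed multi-exon gene
                if (length(multi_pool) == 0L) next
                src <- sample(names(multi_pool), 1L)
                pseq <- mutate_sequence(multi_pool[[src]], runif(1, 0.01, 0.03))
                len <- nchar(pseq)
                slot <- find_slot(len)
                st <- slot$start - 1L
                ins <- if (strand == "-") revcomp(pseq) else pseq
                substr(contigs[[slot$contig]], st + 1L, st + len) <- ins
                tid <- sprintf("%s.1", gid)
                exon_rows[[length(exon_rows) + 1L]] <- data.table(
                    transcript_id = tid, gene_id = gid,
                    contig = names(contigs)[slot$contig], strand = strand,
                    start = st, end = st + len)
                iso_rows[[length(iso_rows) + 1L]] <- data.table(
                    transcript_id = tid, gene_id = gid, share = 1)
                gene_rows[[length(gene_rows) + 1L]] <- data.table(
                    gene_id = gid, contig = names(contigs)[slot$contig],
                    strand = strand, n_exons = 1L,
                    is_single_exon = TRUE, is_pseudogene_copy = TRUE,
                    baseline = 0, source_gene = src)
                occupied[[slot$contig]] <- IRanges::union(
                    occupied[[slot$contig]],
                    IRanges::IRanges(st + 1L, st + len))
            }
        }
        genes <- if (length(gene_rows)) rbindlist(gene_rows) else
            data.table(gene_id = character(0), contig = character(0),
                       strand = character(0), n_exons = integer(0),
                       is_single_exon = logical(0),
                       is_pseudogene_copy = logical(0),
                       baseline = numeric(0), source_gene = character(0))
        tx <- if (length(exon_rows)) {
            e <- rbindlist(exon_rows)
            tx_table(e$transcript_id, e$gene_id, e$contig, e$strand,
                     e$start, e$end, provenance = "truth")
        } else tx_table(character(0), character(0), character(0),
                        character(0), numeric(0), numeric(0))
        isoforms <- if (length(iso_rows)) rbindlist(iso_rows) else
            data.table(transcript_id = character(0), gene_id = character(0),
                       share = numeric(0))
        truth <- structure(list(genome = contigs, genes = genes, tx = tx,
                                isoforms = isoforms),
                           class = "gene_truth")
        if (!is.null(gtf_path)) write_gtf(tx, gtf_path)
        truth
    })
}

#' Truth splice junctions of a gene set
#'
#' Unique donor/acceptor pairs over all isoforms (pseudogene copies are
#' intronless and contribute none).
#'
#' @param truth a `gene_truth` object.
#' @return `data.table` with `contig`, `strand`, `donor`, `acceptor`.
#' @export
truth_junctions <- function(truth) {
    unique(tx_junctions(truth$tx)[, .(contig, strand, donor, acceptor)])
}
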