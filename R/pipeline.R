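#' Default end-to-end pipeline configuration
#'
#' Desk-scale study conditions: a 50-contig A/T-rich genome, 200 gene loci
#' with isoforms, single-exon genes and pseudogene copies, an intact vs
#' irradiated 2x2 design with a 14.28-fold depletion of a stem-cell-like
#' gene subset (the canonical depletion magnitude of the piwi-family
#' exemplar), half of the true junctions withheld from the starting
#' annotation, strand-specific 50 bp short reads and ~278 bp long reads.
#'
#' @param seed global seed; every stage derives its own stream from it.
#' @return nested configuration list.
#' @export
default_config <- function(seed = 1L) {
    list(
        seed = as.integer(seed),
        genome = list(n_contigs = 50L, contig_length_range = c(5000L, 20000L),
                      at_fraction = 0.65, repeat_fraction = 0.1),
        genes = list(n_genes = 200L, exon_count_range = c(2L, 6L),
                     isoform_prob = 0.3, single_exon_fraction = 0.2,
                     pseudogene_fraction = 0.05),
        annotation = list(withheld_junction_fraction = 0.5),
        irradiation = list(depleted_fraction = 0.2, fold = 14.28),
        long_reads = list(n_reads = 1200L, mean_length = 278,
                          error_rate = 0.002),
        short_reads = list(n_reads_per_sample = 20000L, error_rate = 0),
        mapping = list(max_mismatches = 0L), assembly = list(),
        rescue = list(max_rounds = 1L, min_anchor = 10L),
        merge = list(), de = list(),
        stages = c("simulate", "map", "assemble", "rescue", "longread",
                   "merge", "orf", "de", "evaluate"))
}

#' Withhold a fraction of true junctions from an annotation
#'
#' Emulates an incomplete starting annotation: the selected junctions are
#' removed by splitting every transcript that uses them into the maximal
#' sub-transcripts not crossing a withheld junction.
#'
#' @param tx transcript model table.
#' @param fraction fraction of distinct junctions to withhold.
#' @param seed RNG seed.
#' @return list with `tx` (the reduced annotation) and `withheld`
#'   (junction table).
#' @export
withhold_junctions <- function(tx, fraction, seed = 1L) {
    jall <- unique(tx_junctions(tx)[, .(contig, strand, donor, acceptor)])
    if (nrow(jall) == 0L || fraction <= 0)
        return(list(tx = copy(tx), withheld = jall[0]))
    wh <- with_seed(seed, jall[sample(.N, round(fraction * .N))])
    rows <- list()
    for (grp in split(tx, by = "transcript_id", sorted = TRUE)) {
        setorder(grp, start)
        n <- nrow(grp)
        piece <- 1L
        cut <- logical(n - 1L)
        if (n >= 2L) {
            for (i in seq_len(n - 1L))
                cut[i] <- nrow(wh[contig == grp$contig[1L] &
                                  strand == grp$strand[1L] &
                                  donor == grp$end[i] &
                                  acceptor == grp$start[i + 1L]]) > 0L
        }
        part <- cumsum(c(0L, cut))
        for (p in unique(part)) {
            sel <- grp[part == p]
            suffix <- if (length(unique(part)) > 1L)
                sprintf("_p%d", p + 1L) else ""
            rows[[length(rows) + 1L]] <- data.table(
                transcript_id = paste0(sel$transcript_id[1L], suffix),
                gene_id = sel$gene_id[1L], contig = sel$contig[1L],
                strand = sel$strand[1L], start = sel$start, end = sel$end)
        }
    }
    e <- rbindlist(rows)
    list(tx = tx_table(e$transcript_id, e$gene_id, e$contig, e$strand,
                       e$start, e$end, provenance = "truth"),
         withheld = wh)
}

#' Run the full desk-scale pipeline
#'
#' Simulate -> map -> assemble -> super-gene rescue -> long-read assembly
#' -> platform merge -> ORF classification -> differential expression ->
#' truth evaluation, writing per-stage outputs and a checksum manifest.
#' Identical config and seed give identical checksums.
#'
#' @param config list from [default_config()].
#' @param outdir output directory (created).
#' @param quiet suppress progress messages.
#' @return list with the main stage objects and `manifest`.
#' @export
run_pipeline <- function(config = default_config(), outdir = tempfile("run"),
                         quiet = FALSE) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    manifest <- list()
    say <- function(...) if (!quiet) message(...)
    emit <- function(stage, file) {
        path <- file.path(outdir, file)
        manifest[[length(manifest) + 1L]] <<- data.table(
            stage = stage, file = file,
            md5 = unname(tools::md5sum(path)))
        invisible(path)
    }
    res <- list()
    st <- config$stages
    if (length(st) == 0L) {
        res$manifest <- data.table(stage = character(0), file = character(0),
                                   md5 = character(0))
        fwrite(res$manifest, file.path(outdir, "manifest.tsv"), sep = "\t")
        return(res)
    }

    ## --- simulate ------------------------------------------------------
    gp <- do.call(genome_params, c(config$genome,
                                   list(seed = derive_seed(config$seed,
                                                           "genome"))))
    genome_set <- generate_genome(gp)
    truth <- do.call(generate_gene_models,
                     c(list(genome = genome_set),
                       config$genes,
                       list(seed = derive_seed(config$seed, "genes"))))
    expr <- make_expression_truth(truth)
    real <- truth$genes[baseline > 0]
    n_dep <- round(config$irradiation$depleted_fraction * nrow(real))
    depleted <- with_seed(derive_seed(config$seed, "depleted"),
                          sample(real$gene_id, n_dep))
    expr <- apply_irradiation_effect(expr, depleted, config$irradiation$fold)
    ann <- withhold_junctions(truth$tx,
                              config$annotation$withheld_junction_fraction,
                              seed = derive_seed(config$seed, "withhold"))
    long_rs <- do.call(simulate_long_reads,
                       c(list(truth = truth), config$long_reads,
                         list(seed = derive_seed(config$seed, "long"))))
    short <- simulate_short_reads(
        truth, expr, config$short_reads$n_reads_per_sample,
        seed = derive_seed(config$seed, "short"),
        error_rate = config$short_reads$error_rate)
    if ("simulate" %in% st) {
        write_fasta(truth$genome, file.path(outdir, "genome.fa"))
        emit("simulate", "genome.fa")
        write_gtf(truth$tx, file.path(outdir, "truth.gtf"))
        emit("simulate", "truth.gtf")
        write_gtf(ann$tx, file.path(outdir, "annotation_start.gtf"))
        emit("simulate", "annotation_start.gtf")
        fwrite(expr, file.path(outdir, "expression_truth.tsv"), sep = "\t")
        emit("simulate", "expression_truth.tsv")
        write_fasta(setNames(long_rs$reads$seq, long_rs$reads$read_id),
                    file.path(outdir, "long_reads.fa"))
        emit("simulate", "long_reads.fa")
    }
    res$truth <- truth; res$expression_truth <- expr
    res$depleted_genes <- depleted; res$annotation <- ann

    ## --- map + assemble + rescue --------------------------------------
    mp <- do.call(mapping_params, config$mapping)
    ap <- do.call(assembly_params, config$assembly)
    if (any(c("map", "assemble", "rescue") %in% st)) {
        say("mapping discovery reads")
        disc <- rbindlist(lapply(short[grep("^intact", names(short))],
                                 function(s) s$reads))
        aln <- map_reads(disc[, .(read_id, seq, read_quality)],
                         truth$genome, annotation = ann$tx, params = mp)
        if ("map" %in% st) {
            write_sam_like(aln, file.path(outdir, "alignments.tsv"))
            emit("map", "alignments.tsv")
        }
        say("assembling + rescuing")
        resc <- iterate_rescue(aln, disc, truth$genome, mp, ap,
                               max_rounds = config$rescue$max_rounds,
                               min_anchor = config$rescue$min_anchor)
        models <- resc$models
        if ("assemble" %in% st || "rescue" %in% st) {
            write_gtf(models, file.path(outdir, "models.gtf"))
            emit("rescue", "models.gtf")
            fwrite(resc$ledger, file.path(outdir, "rescue_ledger.tsv"),
                   sep = "\t")
            emit("rescue", "rescue_ledger.tsv")
            sgs <- build_supergenes(models, truth$genome)
            sg_tab <- rbindlist(lapply(sgs, function(s) data.table(
                supergene_id = s$supergene_id, contig = s$contig,
                strand = s$strand,
                blocks = paste(sprintf("%d-%d", as.integer(s$blocks[, 1]),
                                       as.integer(s$blocks[, 2])),
                               collapse = ";"))))
            fwrite(sg_tab, file.path(outdir, "supergenes.tsv"), sep = "\t")
            emit("rescue", "supergenes.tsv")
        }
        res$models <- models; res$rescue_ledger <- resc$ledger
    }

    ## --- long-read assembly -------------------------------------------
    if ("longread" %in% st) {
        say("assembling long reads")
        lr <- setNames(long_rs$reads$seq, long_rs$reads$read_id)
        iso <- assemble_isotigs(overlap_graph(lr))
        write_fasta(setNames(iso$sequence, iso$isotig_id),
                    file.path(outdir, "isotigs.fa"))
        emit("longread", "isotigs.fa")
        fwrite(iso[, .(isotig_id, isogroup_id, n_reads)],
               file.path(outdir, "isotig_groups.tsv"), sep = "\t")
        emit("longread", "isotig_groups.tsv")
        res$isotigs <- iso
    }

    ## --- merge ---------------------------------------------------------
    if ("merge" %in% st && !is.null(res$models) && !is.null(res$isotigs)) {
        say("merging platforms")
        prm <- do.call(merge_params, config$merge)
        col <- collapse_isoforms(setNames(res$isotigs$sequence,
                                          res$isotigs$isotig_id),
                                 groups = res$isotigs$isogroup_id,
                                 params = prm)
        sr_seqs <- tx_sequences(res$models, truth$genome)
        keepable <- nchar(sr_seqs) >= prm$min_match_length
        sr_seqs <- sr_seqs[keepable]
        ne <- tx_n_exons(res$models)[names(sr_seqs)]
        rep_merge <- merge_datasets(col$contigs, sr_seqs, ne, prm)
        write_fasta(rep_merge$final_seqs, file.path(outdir, "merged.fa"))
        emit("merge", "merged.fa")
        fwrite(rep_merge$provenance, file.path(outdir, "merged_provenance.tsv"),
               sep = "\t")
        emit("merge", "merged_provenance.tsv")
        fwrite(rep_merge$log, file.path(outdir, "merge_log.tsv"), sep = "\t")
        emit("merge", "merge_log.tsv")
        res$merge <- rep_merge
    }

    ## --- orf ------------------------------------------------------------
    if ("orf" %in% st && !is.null(res$merge)) {
        say("classifying ORFs")
        orfs <- classify_orfs(res$merge$final_seqs)
        write_orf_outputs(orfs, file.path(outdir, "peptides.fa"),
                          file.path(outdir, "orf_calls.tsv"))
        emit("orf", "orf_calls.tsv")
        emit("orf", "peptides.fa")
        res$orfs <- orfs
    }

    ## --- de --------------------------------------------------------------
    if ("de" %in% st) {
        say("quantifying and testing differential expression")
        # quantify against the truth transcript set (desk-scale stand-in
        # for the merged reference, which lacks genome coordinates)
        tx_seqs <- tx_sequences(truth$tx, truth$genome)
        samples <- data.table(
            sample_id = names(short),
            condition = sub("_rep\\d+$", "", names(short)),
            replicate = as.integer(sub("^.*_rep", "", names(short))))
        et <- quantify_samples(short, samples, tx_seqs, mp)
        dp <- do.call(de_params, config$de)
        etf <- expression_filter(et, dp)
        de <- differential_expression(etf, dp)
        fwrite(data.table(transcript_id = rownames(et$counts), et$counts),
               file.path(outdir, "counts.tsv"), sep = "\t")
        emit("de", "counts.tsv")
        fwrite(de, file.path(outdir, "de_results.tsv"), sep = "\t")
        emit("de", "de_results.tsv")
        res$expression <- etf; res$de <- de
    }

    ## --- evaluate --------------------------------------------------------
    if ("evaluate" %in% st && !is.null(res$models)) {
        eval_rows <- list()
        pj <- unique(tx_junctions(res$models)[, .(contig, strand, donor,
                                                  acceptor)])
        eval_rows$junctions <- evaluate_against_truth(
            pj, truth_junctions(truth), what = "junctions")
        if (!is.null(res$de)) {
            called <- unique(res$models$gene_id)  # placeholder join not used
            de_genes <- unique(sub("\\.\\d+.*$", "",
                                   res$de[passes == TRUE, transcript_id]))
            eval_rows$de <- evaluate_against_truth(
                de_genes, depleted, what = "de")
        }
        ev <- rbindlist(eval_rows, idcol = "class")
        fwrite(ev, file.path(outdir, "evaluation.tsv"), sep = "\t")
        emit("evaluate", "evaluation.tsv")
        res$evaluation <- ev
    }

    res$manifest <- rbindlist(manifest)
    fwrite(res$manifest, file.path(outdir, "manifest.tsv"), sep = "\t")
    res
}

#' Precision and recall of predictions against synthetic truth
#'
#' Junction match requires exact donor/acceptor coordinates; transcript
#' match an exact exon chain; differential-expression match gene-id
#' membership.
#'
#' @param predicted junction table, transcript model table, or character
#'   vector of gene ids, depending on `what`.
#' @param truth the matching truth object.
#' @param what one of `"junctions"`, `"transcripts"`, `"de"`.
#' @return one-row `data.table`: `tp`, `fp`, `fn`, `precision`, `recall`
#'   (`NA` when undefined).
#' @export
evaluate_against_truth <- function(predicted, truth,
                                   what = c("junctions", "transcripts",
                                            "de")) {
    what <- match.arg(what)
    key <- function(x) switch(
        what,
        junctions = sprintf("%s|%s|%d|%d", x$contig, x$strand,
                            as.integer(x$donor), as.integer(x$acceptor)),
        transcripts = {
            x <- tx_canonical(x)
            ch <- x[, .(sig = paste0(contig[1L], strand[1L], ":",
                                     paste(start, end, sep = "-",
                                           collapse = ","))),
                    by = transcript_id]
            ch$sig
        },
        de = as.character(x))
    p <- unique(key(predicted)); t <- unique(key(truth))
    tp <- length(intersect(p, t))
    fp <- length(setdiff(p, t))
    fn <- length(setdiff(t, p))
    data.table(tp = tp, fp = fp, fn = fn,
               precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
               recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_)
}
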