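#' Expand gene baselines into a per-condition, per-replicate expression truth
#'
#' @param truth a `gene_truth` object.
#' @param conditions character vector of condition names.
#' @param replicates replicates per condition.
#' @return `data.table` with `gene_id`, `condition`, `replicate`, `rate`
#'   (expected relative transcript abundance, arbitrary units).
#' @export
make_expression_truth <- function(truth,
                                  conditions = c("intact", "irradiated"),
                                  replicates = 2L) {
    g <- truth$genes
    out <- data.table(
        gene_id = rep(g$gene_id, times = length(conditions) * replicates),
        condition = rep(rep(conditions, each = nrow(g)), times = replicates),
        replicate = rep(seq_len(replicates), each = nrow(g) * length(conditions)),
        rate = rep(g$baseline, times = length(conditions) * replicates))
    setorder(out, gene_id, condition, replicate)
    out[]
}

#' Deplete a gene set in the irradiated condition
#'
#' Models the loss of stem-cell-associated transcripts after lethal
#' irradiation: rates of the listed genes are divided by `fold` in the
#' target condition only; everything else is untouched.  Applying the
#' effect twice composes multiplicatively.
#'
#' @param expression_truth table from [make_expression_truth()].
#' @param depleted_gene_ids genes to deplete.
#' @param fold depletion factor, must be > 1.
#' @param condition condition in which depletion applies.
#' @return modified copy of the expression truth table.
#' @export
apply_irradiation_effect <- function(expression_truth, depleted_gene_ids,
                                     fold, condition = "irradiated") {
    if (length(depleted_gene_ids) == 0L) return(copy(expression_truth))
    if (fold <= 1) stop("fold must be > 1")
    unknown <- setdiff(depleted_gene_ids, unique(expression_truth$gene_id))
    if (length(unknown))
        stop("unknown gene ids: ", paste(unknown, collapse = ", "))
    out <- copy(expression_truth)
    cond <- condition
    out[gene_id %in% depleted_gene_ids & condition == cond,
        rate := rate / fold]
    out[]
}
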