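#' Decompose a CIGAR string into reference blocks
#'
#' Projects the aligned (M) runs of a CIGAR onto the reference, with N
#' advancing the reference only and S advancing the read only.  Supported
#' operations are M, I, D, N and S, the subset produced by the short-read
#' mapper and split-read rescue.
#'
#' @param cigar CIGAR string, e.g. `"25M200N25M"`.
#' @param pos 0-based leftmost reference position of the alignment.
#' @return list with `blocks` (matrix of 0-based half-open reference
#'   intervals, one row per M/D run merged across D), `clip_left`,
#'   `clip_right` (soft-clipped read bases) and `read_len` (M+I+S total).
#' @export
parse_cigar <- function(cigar, pos) {
    stopifnot(length(cigar) == 1L, is.character(cigar))
    ops  <- GenomicAlignments::explodeCigarOps(cigar)[[1L]]
    lens <- GenomicAlignments::explodeCigarOpLengths(cigar)[[1L]]
    if (length(ops) == 0L || !all(ops %in% c("M", "I", "D", "N", "S")))
        stop("malformed or unsupported cigar: ", cigar)
    ref <- pos
    blocks <- NULL
    cur_start <- NA_real_
    clip_left <- 0L; clip_right <- 0L
    seen_m <- FALSE
    for (k in seq_along(ops)) {
        op <- ops[k]; L <- lens[k]
        if (op == "S") {
            if (!seen_m) clip_left <- clip_left + L else clip_right <- clip_right + L
        } else if (op == "M" || op == "D") {
            if (op == "M") seen_m <- TRUE
            if (is.na(cur_start)) cur_start <- ref
            ref <- ref + L
        } else if (op == "N") {
            if (!is.na(cur_start)) blocks <- rbind(blocks, c(cur_start, ref))
            cur_start <- NA_real_
            ref <- ref + L
        } # I: read only
    }
    if (!is.na(cur_start)) blocks <- rbind(blocks, c(cur_start, ref))
    if (is.null(blocks)) blocks <- matrix(numeric(0), ncol = 2)
    colnames(blocks) <- c("start", "end")
    list(blocks = blocks, clip_left = clip_left, clip_right = clip_right,
         read_len = sum(lens[ops %in% c("M", "I", "S")]))
}

# assemble a cigar from genome-ordered M blocks (+ optional soft clips)
cigar_from_blocks <- function(blocks, clip_left = 0L, clip_right = 0L) {
    n <- nrow(blocks)
    parts <- character(0)
    if (clip_left > 0) parts <- c(parts, paste0(clip_left, "S"))
    for (i in seq_len(n)) {
        parts <- c(parts, paste0(blocks[i, 2] - blocks[i, 1], "M"))
        if (i < n) parts <- c(parts, paste0(blocks[i + 1, 1] - blocks[i, 2], "N"))
    }
    if (clip_right > 0) parts <- c(parts, paste0(clip_right, "S"))
    paste(parts, collapse = "")
}
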