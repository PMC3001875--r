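#' Reverse complement of character sequences
#'
#' Thin wrapper over [Biostrings::reverseComplement()] that keeps plain
#' character vectors as the working currency of the package.
#'
#' @param x character vector of DNA sequences over A/C/G/T/N.
#' @return character vector of reverse complements, names preserved.
#' @export
revcomp <- function(x) {
    if (length(x) == 0L) return(character(0))
    out <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
    names(out) <- names(x)
    out
}

#' Derive a stage-specific RNG seed from a global seed
#'
#' One global seed fans out to per-stage sub-seeds by stable arithmetic
#' hashing of the stage name, so that re-running a single stage in isolation
#' reproduces its stream.
#'
#' @param seed integer global seed.
#' @param stage character stage label.
#' @return integer seed below 2^31.
#' @export
derive_seed <- function(seed, stage) {
    h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
    as.integer((as.numeric(seed) * 1000003 + h * 7919) %% 2147483629)
}

# run code under a local, restored RNG state
with_seed <- function(seed, code) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        old <- get(".Random.seed", envir = globalenv())
        on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
        on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
                add = TRUE)
    }
    set.seed(seed)
    code
}

# random DNA with a given A+T fraction
random_dna <- function(n, at_fraction = 0.5) {
    p <- c(at_fraction / 2, (1 - at_fraction) / 2,
           (1 - at_fraction) / 2, at_fraction / 2)
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = p),
          collapse = "")
}

# substitute a fraction of bases, used for pseudogene divergence
mutate_sequence <- function(seq, rate) {
    n <- nchar(seq)
    k <- round(rate * n)
    if (k == 0L) return(seq)
    idx <- sample.int(n, k)
    ch <- strsplit(seq, "", fixed = TRUE)[[1L]]
    alt <- lapply(ch[idx], function(b) setdiff(c("A", "C", "G", "T"), b))
    ch[idx] <- vapply(alt, function(a) sample(a, 1L), character(1))
    paste(ch, collapse = "")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
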