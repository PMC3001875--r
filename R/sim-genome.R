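#' Parameters for synthetic genome generation
#'
#' Emulates the salient properties of a fragmented, A/T-rich draft assembly:
#' many short contigs, elevated A+T composition, and a shared repeat pool
#' contributing a tunable fraction of bases.
#'
#' @param n_contigs number of contigs.
#' @param contig_length_range numeric length-2 vector, min/max contig bp.
#' @param at_fraction target A+T proportion, default 0.65.
#' @param repeat_fraction proportion of contig bases drawn from a shared
#'   repeat pool, in `[0, 1)`.
#' @param seed integer RNG seed.
#' @return object of class `genome_params`.
#' @export
genome_params <- function(n_contigs = 50L,
                          contig_length_range = c(5000L, 20000L),
                          at_fraction = 0.65,
                          repeat_fraction = 0.1,
                          seed = 1L) {
    if (n_contigs < 0) stop("n_contigs must be >= 0")
    if (at_fraction < 0 || at_fraction > 1)
        stop("at_fraction must be a proportion in [0, 1]")
    if (repeat_fraction < 0 || repeat_fraction >= 1)
        stop("repeat_fraction must be in [0, 1)")
    structure(list(n_contigs = as.integer(n_contigs),
                   contig_length_range = as.numeric(contig_length_range),
                   at_fraction = at_fraction,
                   repeat_fraction = repeat_fraction,
                   seed = as.integer(seed)),
              class = "genome_params")
}

#' Generate a synthetic fragmented genome
#'
#' Contig sequences are i.i.d. draws at the requested A+T composition; when
#' `repeat_fraction > 0`, windows are overwritten with members of a small
#' repeat pool shared across contigs, emulating unresolved repetitive
#' sequence.  Identical parameters and seed give byte-identical output.
#'
#' @param params a [genome_params()] object.
#' @return list of class `genome_set`: `contigs` (named character vector)
#'   and `params`.
#' @export
generate_genome <- function(params) {
    stopifnot(inherits(params, "genome_params"))
    with_seed(params$seed, {
        n <- params$n_contigs
        contigs <- setNames(character(n),
                            if (n) sprintf("contig%04d", seq_len(n)) else NULL)
        rep_len_unit <- 500L
        pool <- if (params$repeat_fraction > 0)
            vapply(1:5, function(i) random_dna(rep_len_unit, params$at_fraction),
                   character(1)) else character(0)
        for (i in seq_len(n)) {
            L <- round(runif(1, params$contig_length_range[1],
                             params$contig_length_range[2]))
            s <- random_dna(L, params$at_fraction)
            if (length(pool) && params$repeat_fraction > 0) {
                k <- floor(params$repeat_fraction * L / rep_len_unit)
                for (j in seq_len(k)) {
                    at <- sample.int(L - rep_len_unit, 1L)
                    substr(s, at, at + rep_len_unit - 1L) <- sample(pool, 1L)
                }
            }
            contigs[i] <- s
        }
        structure(list(contigs = contigs, params = params),
                  class = "genome_set")
    })
}
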