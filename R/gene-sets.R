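#' Construct a GeneSetCollection
#'
#' @param sets named list of character vectors of gene identifiers. Members
#'   are deduplicated (with a warning when duplicates are dropped).
#' @param universe optional character vector of all gene identifiers; defaults
#'   to the union of the members. A supplied universe is extended to cover
#'   the members if needed.
#'
#' @return a \linkS4class{GeneSetCollection}.
#' @examples
#' gsc <- GeneSetCollection(list(apoptosis = c("BAX", "BCL2"),
#'                               glycolysis = c("HK1", "PFKL", "PKM")))
#' setSizes(gsc)
#' @export
GeneSetCollection <- function(sets = list(), universe = NULL) {
    stopifnot(is.list(sets))
    sets <- lapply(sets, function(m) {
        m <- trimws(as.character(m))
        m <- m[nzchar(m)]
        if (anyDuplicated(m)) {
            warning("duplicated members dropped from a gene set",
                    call. = FALSE)
            m <- unique(m)
        }
        m
    })
    members <- unique(unlist(sets, use.names = FALSE))
    universe <- if (is.null(universe)) members
                else unique(c(trimws(as.character(universe)), members))
    new("GeneSetCollection", sets = sets,
        universe = as.character(universe))
}

#' @rdname GeneSetCollection-class
#' @aliases geneSets geneUniverse setSizes
#' @export
setMethod("geneSets", "GeneSetCollection", function(x) x@sets)

#' @rdname GeneSetCollection-class
#' @export
setMethod("geneUniverse", "GeneSetCollection", function(x) x@universe)

#' @rdname GeneSetCollection-class
#' @export
setMethod("setSizes", "GeneSetCollection",
    function(x) vapply(x@sets, length, integer(1)))

#' @rdname GeneSetCollection-class
#' @export
setMethod("names", "GeneSetCollection", function(x) names(x@sets))

#' @rdname GeneSetCollection-class
#' @export
setMethod("length", "GeneSetCollection", function(x) length(x@sets))

setMethod("show", "GeneSetCollection", function(object) {
    cat(sprintf("GeneSetCollection: %d sets over %d genes\n",
                length(object@sets), length(object@universe)))
    if (length(object@sets)) {
        sz <- setSizes(object)
        cat(sprintf("  sizes: %d..%d (median %g)\n",
                    min(sz), max(sz), stats::median(sz)))
    }
})

#' Sample a random gene set from a universe
#'
#' Uniform sample without replacement, used as the reference set against
#' which the hallmark mRNA-protein correlations are contrasted.
#'
#' @param universe character vector of gene identifiers.
#' @param n set size (default 500, the conventional random-reference size).
#' @param seed integer seed; the draw is deterministic given the seed.
#'
#' @return character vector of `n` gene identifiers.
#' @examples
#' sampleRandomSet(sprintf("g%03d", 1:100), n = 10, seed = 1)
#' @export
sampleRandomSet <- function(universe, n = 500L, seed) {
    universe <- as.character(universe)
    if (length(n) != 1L || !is.finite(n) || n < 1L)
        stop("'n' must be a count >= 1", call. = FALSE)
    if (n > length(universe))
        stop(sprintf("'n' (%d) exceeds the universe size (%d)",
                     as.integer(n), length(universe)), call. = FALSE)
    withr::with_seed(as.integer(seed),
        sample(universe, size = as.integer(n), replace = FALSE))
}
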