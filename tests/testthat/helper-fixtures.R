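# Shared fixture builders; everything is generated in code at test time.

makeAbundance <- function(values, modality = "mRNA",
                          genes = NULL, cells = NULL) {
    if (!is.null(genes)) rownames(values) <- genes
    if (!is.null(cells)) colnames(values) <- cells
    AbundanceMatrix(values, modality)
}

makeRanked <- function(scores, genes = paste0("g", seq_along(scores)),
                       cell = "CL01", modality = "mRNA") {
    ord <- order(-scores, genes, method = "radix")
    new("RankedList", cellId = cell, modality = modality,
        genes = genes[ord], scores = scores[ord])
}

smallCohort <- function(seed, nCells = 6L, nGenes = 400L, ...) {
    generateCohort(cohortParams(nCells = nCells, nGenes = nGenes,
                                seed = seed, ...))
}

# random ranked list + member set for property-style enrichment cases
randomCase <- function(n, maxSet = n - 1L) {
    genes <- sprintf("g%03d", seq_len(n))
    scores <- sort(round(stats::runif(n, 0.1, 10), 4), decreasing = TRUE)
    m <- sample(seq_len(min(maxSet, n - 1L)), 1L)
    members <- sample(genes, m)
    list(ranked = new("RankedList", cellId = "c", modality = "mRNA",
                      genes = genes, scores = scores),
         members = members)
}
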