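## Synthetic paired mRNA/protein cohort with the statistical structure the
## decoupling analysis assumes: log-normal-ish abundances, stronger same-cell
## mRNA-protein coupling inside hallmark sets, elevated transcription of
## hallmark genes, translation-selective hallmarks whose transcription boost
## is not propagated to protein, a linear link from the latent decoupling to
## division rate, and drug inhibition independent of all of it.

.hallmarkNames <- c(
    "Activating_Invasion_and_Metastasis",
    "Tumor_Promoting_Inflammation",
    "Inducing_Angiogenesis",
    "Evading_Immune_Destruction",
    "Enabling_Replicative_Immortality",
    "Sustaining_Proliferative_Signaling",
    "Resisting_Cell_Death",
    "Evading_Growth_Suppressors",
    "Genome_Instability_and_Mutation",
    "Reprogramming_Energy_Metabolism")

## curated hallmark list sizes over the ~19,000 protein-coding genes; used to
## scale the default synthetic set sizes to the simulated universe
.hallmarkRefSizes <- c(1150L, 649L, 509L, 610L, 309L, 1314L, 1194L, 710L,
                       232L, 462L)
.hallmarkRefUniverse <- 19000L

#' Parameters of the synthetic paired cohort
#'
#' Defaults mirror the study conditions of the motivating breast-cancer
#' cell-line cohorts: 32 cell lines, ~3,000 genes, ten hallmark tasks with
#' sizes proportional to the curated hallmark lists (232..1314 genes over a
#' ~19,000-gene universe), same-cell mRNA-protein coupling 0.6 inside
#' hallmark sets versus 0.25 outside, a +0.5 log2 transcription boost of
#' hallmark genes, half of the hallmarks translation-selective (their boost
#' is not propagated to protein), a common division-rate effect of -1.88 per
#' unit of hallmark decoupling, and 101 drugs whose inhibition is independent
#' of the decoupling.
#'
#' @param nCells,nGenes,nHallmarks,nDrugs cohort dimensions.
#' @param hallmarkSizes integer vector of set sizes; `NULL` (default) scales
#'   the curated hallmark sizes to `nGenes`.
#' @param couplingHallmark,couplingBackground target same-cell Pearson
#'   correlation (log scale) between mRNA and protein for hallmark /
#'   non-hallmark genes, in \[0, 1\].
#' @param transcriptionOffset mean log2 mRNA boost of hallmark genes.
#' @param offsetSd between-cell SD of the per-(hallmark, cell) boost (log2).
#' @param translationSelectivity fraction of hallmark sets whose boost is NOT
#'   propagated to protein (the decoupled tasks).
#' @param divisionSlope common linear effect on the division rate of each
#'   decoupled hallmark's per-cell offset (additive over decoupled
#'   hallmarks).
#' @param divisionIntercept baseline division rate.
#' @param divisionNoiseSd residual SD of the division rate.
#' @param muMean,muSd mean and between-gene SD of the baseline log2 mRNA
#'   abundance.
#' @param noiseSdRange range of the per-gene between-cell SD of log2 mRNA.
#' @param proteinBaseline additive log2 offset of protein over mRNA.
#' @param seed master integer seed; all randomness derives from it.
#'
#' @return a validated \linkS4class{CohortParams}.
#' @seealso [generateCohort()]
#' @export
cohortParams <- function(nCells = 32L, nGenes = 3000L, nHallmarks = 10L,
                         hallmarkSizes = NULL,
                         couplingHallmark = 0.6, couplingBackground = 0.25,
                         transcriptionOffset = 0.5, offsetSd = 0.15,
                         translationSelectivity = 0.5,
                         divisionSlope = -1.88, divisionIntercept = 5.5,
                         divisionNoiseSd = 0.2,
                         nDrugs = 101L,
                         muMean = 5, muSd = 2, noiseSdRange = c(1.0, 1.4),
                         proteinBaseline = 3, seed = 1L) {
    nHallmarks <- as.integer(nHallmarks)
    nGenes <- as.integer(nGenes)
    if (is.null(hallmarkSizes)) {
        scale <- nGenes / .hallmarkRefUniverse
        ref <- if (nHallmarks == length(.hallmarkRefSizes))
            .hallmarkRefSizes
        else as.integer(round(seq(min(.hallmarkRefSizes),
                                  max(.hallmarkRefSizes),
                                  length.out = nHallmarks)))
        hallmarkSizes <- pmax(5L, pmin(nGenes, as.integer(round(ref * scale))))
    }
    new("CohortParams",
        nCells = as.integer(nCells), nGenes = nGenes,
        nHallmarks = nHallmarks,
        hallmarkSizes = as.integer(hallmarkSizes),
        couplingHallmark = couplingHallmark,
        couplingBackground = couplingBackground,
        transcriptionOffset = transcriptionOffset, offsetSd = offsetSd,
        translationSelectivity = translationSelectivity,
        divisionSlope = divisionSlope,
        divisionIntercept = divisionIntercept,
        divisionNoiseSd = divisionNoiseSd,
        nDrugs = as.integer(nDrugs),
        muMean = muMean, muSd = muSd, noiseSdRange = noiseSdRange,
        proteinBaseline = proteinBaseline, seed = as.integer(seed))
}

#' Generate a synthetic paired mRNA/protein cohort
#'
#' The generative model, on the log2 scale: each gene has a baseline
#' abundance `mu_g ~ N(muMean, muSd^2)` and a per-cell deviation
#' `e_gc ~ N(0, sigma_g^2)` with `sigma_g ~ U(noiseSdRange)`. Genes belonging
#' to hallmark set s additionally receive that set's per-cell transcription
#' offset `o_sc ~ N(transcriptionOffset, offsetSd^2)` on the mRNA side.
#' Protein is `proteinBaseline + mRNA + eps_gc` where the per-gene noise
#' variance of `eps` is solved from the target same-cell Pearson correlation
#' (`couplingHallmark` for genes in any hallmark, `couplingBackground`
#' otherwise) given the across-gene log-mRNA variance `muSd^2 +
#' mean(sigma^2)`. For the translation-selective hallmarks the offset `o_sc`
#' is removed again from the protein side, decoupling transcription from
#' translation for those tasks. The division rate is `divisionIntercept +
#' divisionSlope * sum_s o_sc` over the decoupled hallmarks plus Gaussian
#' noise, and drug inhibition is iid `N(0.5, 0.15^2)`, independent of the
#' decoupling by construction. Abundances are exported on the linear scale
#' (`2^log2`).
#'
#' @param params a \linkS4class{CohortParams} from [cohortParams()].
#'
#' @return a list with elements `mrna` and `protein`
#'   (\linkS4class{AbundanceMatrix}), `geneSets`
#'   (\linkS4class{GeneSetCollection}), `growth`
#'   (\linkS4class{GrowthTable}) and `truth`
#'   (\linkS4class{SyntheticTruth}). Identical `params` (including seed)
#'   yield identical output.
#' @examples
#' cohort <- generateCohort(cohortParams(nCells = 4, nGenes = 300, seed = 7))
#' cohort$mrna
#' @export
generateCohort <- function(params) {
    stopifnot(is(params, "CohortParams"))
    validObject(params)
    p <- params
    withr::with_seed(p@seed, {
        G <- p@nGenes; C <- p@nCells; S <- p@nHallmarks
        genes <- sprintf("G%05d", seq_len(G))
        cells <- sprintf(sprintf("CL%%0%dd", max(2L, nchar(C))), seq_len(C))
        drugs <- sprintf("drug_%03d", seq_len(p@nDrugs))
        setNamesVec <- if (S == length(.hallmarkNames)) .hallmarkNames
                       else sprintf("hallmark_%02d", seq_len(S))

        ## overlapping sets: each sampled independently from the universe
        sets <- lapply(p@hallmarkSizes, function(n) sort(sample(genes, n)))
        names(sets) <- setNamesVec
        M <- matrix(FALSE, G, S, dimnames = list(genes, setNamesVec))
        for (s in seq_len(S)) M[sets[[s]], s] <- TRUE
        inHallmark <- rowSums(M) > 0L

        nAffected <- round(p@translationSelectivity * S)
        affected <- if (nAffected > 0L)
            sort(sample(setNamesVec, nAffected)) else character(0)

        ## per-(set, cell) transcription offsets (log2)
        O <- matrix(rnorm(S * C, p@transcriptionOffset, p@offsetSd), S, C,
                    dimnames = list(setNamesVec, cells))

        mu <- rnorm(G, p@muMean, p@muSd)
        sigma <- runif(G, p@noiseSdRange[1L], p@noiseSdRange[2L])
        eMat <- matrix(rnorm(G * C), G, C) * sigma
        xLog <- mu + (M %*% O) + eMat
        dimnames(xLog) <- list(genes, cells)

        ## protein noise calibrated so the expected same-cell correlation on
        ## the log scale equals the per-gene coupling target
        rTarget <- ifelse(inHallmark, p@couplingHallmark,
                          p@couplingBackground)
        vx <- p@muSd^2 + mean(sigma^2)
        epsSd <- ifelse(rTarget > 0, sqrt(vx * (1 / pmax(rTarget, 1e-12)^2 - 1)), 0)
        epsMat <- matrix(rnorm(G * C), G, C) * epsSd
        decoupled <- if (length(affected))
            M[, affected, drop = FALSE] %*% O[affected, , drop = FALSE]
        else matrix(0, G, C)
        yLog <- p@proteinBaseline + xLog + epsMat - decoupled
        if (any(rTarget == 0)) {
            ## coupling 0: protein carries no mRNA signal at all
            z <- rTarget == 0
            yLog[z, ] <- p@proteinBaseline +
                matrix(rnorm(sum(z) * C, sd = sqrt(vx)), sum(z), C)
        }
        dimnames(yLog) <- list(genes, cells)

        ## division rate: each decoupled hallmark's offset lowers the rate
        ## with the common coefficient divisionSlope
        proxySum <- if (length(affected))
            colSums(O[affected, , drop = FALSE]) else rep(0, C)
        divRate <- p@divisionIntercept + p@divisionSlope * proxySum +
            rnorm(C, 0, p@divisionNoiseSd)
        names(divRate) <- cells

        inh <- matrix(rnorm(C * p@nDrugs, 0.5, 0.15), C, p@nDrugs,
                      dimnames = list(cells, drugs))

        truth <- new("SyntheticTruth",
                     geneCoupling = setNames(rTarget, genes),
                     setOffsets = O, affectedSets = affected,
                     divisionSlope = p@divisionSlope,
                     divisionIntercept = p@divisionIntercept,
                     seed = p@seed)

        list(mrna = AbundanceMatrix(2^xLog, "mRNA"),
             protein = AbundanceMatrix(2^yLog, "protein"),
             geneSets = GeneSetCollection(sets, universe = genes),
             growth = GrowthTable(divRate, inh),
             truth = truth)
    })
}

#' @describeIn SyntheticTruth-class per-(cell, hallmark) latent decoupling
#'   offsets: the transcription offset for translation-selective hallmarks,
#'   0 for fully propagated ones. Returns a data.frame with columns
#'   `cell_id`, `set_name`, `proxy`.
#' @export
setMethod("deltaProxy", "SyntheticTruth", function(x) {
    O <- x@setOffsets
    z <- rownames(O) %in% x@affectedSets
    df <- expand.grid(set_name = rownames(O), cell_id = colnames(O),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    df$proxy <- as.vector(O) * z[match(df$set_name, rownames(O))]
    df[c("cell_id", "set_name", "proxy")]
})

setMethod("show", "SyntheticTruth", function(object) {
    cat(sprintf("SyntheticTruth: %d hallmarks x %d cells (seed %d)\n",
                nrow(object@setOffsets), ncol(object@setOffsets),
                object@seed))
    cat(sprintf("  decoupled hallmarks: %s\n",
                paste(object@affectedSets, collapse = ", ")))
    cat(sprintf("  division rate = %.3g %+.3g x (summed decoupling offsets) + noise\n",
                object@divisionIntercept, object@divisionSlope))
})

#' Write a synthetic cohort to disk
#'
#' Writes `mrna.tsv`, `protein.tsv`, `hallmarks.gmt`, `growth.tsv` and
#' `truth.json` into `dir` using the package's standard formats.
#'
#' @param cohort list from [generateCohort()].
#' @param dir output directory (created if needed).
#' @return named character vector of the written paths, invisibly.
#' @export
writeCohort <- function(cohort, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    paths <- c(mrna = file.path(dir, "mrna.tsv"),
               protein = file.path(dir, "protein.tsv"),
               gene_sets = file.path(dir, "hallmarks.gmt"),
               growth = file.path(dir, "growth.tsv"),
               truth = file.path(dir, "truth.json"))
    writeAbundance(cohort$mrna, paths[["mrna"]])
    writeAbundance(cohort$protein, paths[["protein"]])
    writeGmt(cohort$geneSets, paths[["gene_sets"]])
    writeGrowth(cohort$growth, paths[["growth"]])
    writeTruth(cohort$truth, paths[["truth"]])
    invisible(paths)
}
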