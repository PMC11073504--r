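## End-to-end pipeline: simulate (or read) -> concordance -> enrichment ->
## task statistics -> growth associations, from one declarative config, with
## TSV outputs, a JSON report and a MANIFEST of completed stages. Identical
## configs produce byte-identical outputs.

.pipelineDefaults <- function() {
    list(simulate = NULL, inputs = NULL,
         method = "pearson", transform = "log2p1",
         score_transform = "log2p1", exponent = 1,
         n_perm = 1000L, n_boot = 10000L,
         sign_convention = "mrna_minus_protein",
         fdr_threshold = 0.2, random_set_size = 500L, min_set_size = 5L,
         seed = 42L, output_dir = "hallmarkTasks_results")
}

#' Read and validate a pipeline configuration
#'
#' YAML file with either a `simulate:` block (arguments of [cohortParams()])
#' or an `inputs:` block (paths `mrna`, `protein`, `gene_sets`, `growth`) --
#' exactly one of the two -- plus any of the analysis options (see
#' [runPipeline()]); unspecified options take the package defaults.
#'
#' @param path path to a YAML file.
#' @return a validated config list.
#' @export
readPipelineConfig <- function(path) {
    if (!file.exists(path))
        stop("config file not found: ", path, call. = FALSE)
    validatePipelineConfig(yaml::read_yaml(path))
}

#' @rdname readPipelineConfig
#' @param config a named list of options (as from YAML).
#' @export
validatePipelineConfig <- function(config) {
    stopifnot(is.list(config))
    cfg <- .pipelineDefaults()
    unknown <- setdiff(names(config), names(cfg))
    if (length(unknown))
        stop("unknown config field(s): ", paste(unknown, collapse = ", "),
             call. = FALSE)
    cfg[names(config)] <- config
    if (is.null(cfg$simulate) == is.null(cfg$inputs))
        stop("exactly one of 'simulate' or 'inputs' must be present",
             call. = FALSE)
    if (!is.null(cfg$inputs)) {
        need <- c("mrna", "protein", "gene_sets", "growth")
        if (!all(need %in% names(cfg$inputs)))
            stop("inputs block must name: ", paste(need, collapse = ", "),
                 call. = FALSE)
    }
    for (f in c("n_perm", "n_boot", "seed", "random_set_size",
                "min_set_size"))
        cfg[[f]] <- as.integer(cfg[[f]])
    stopifnot(cfg$method %in% c("pearson", "spearman"),
              cfg$transform %in% c("log2p1", "none"),
              cfg$score_transform %in% c("log2p1", "none"),
              cfg$sign_convention %in% c("mrna_minus_protein",
                                         "protein_minus_mrna"),
              cfg$fdr_threshold > 0, cfg$fdr_threshold <= 1)
    cfg
}

.logStage <- function(...) message("[hallmarkTasks] ", sprintf(...))

.writeManifest <- function(outDir, stages) {
    writeLines(stages, file.path(outDir, "MANIFEST"))
}

#' Run the full decoupling analysis pipeline
#'
#' Executes, in order: input simulation (or reading), mRNA-protein
#' concordance, per-cell hallmark enrichment for both modalities, the delta
#' and range task statistics with their bootstrap tests, and the growth
#' associations. Every stage logs its parameters; all randomness derives from
#' the master seed by fixed offsets, so an identical config yields
#' byte-identical outputs. Outputs written to the config's `output_dir`:
#' `mrna.tsv`/`protein.tsv`/`hallmarks.gmt`/`growth.tsv`/`truth.json` (when
#' simulating), `correlations.tsv`, `setwise_correlations.tsv`,
#' `enrichment.tsv`, `task_delta.tsv`, `task_range.tsv`,
#' `bootstrap_tests.tsv`, `associations.tsv`, `effects.tsv`, `report.json`
#' and a `MANIFEST` of completed stages (preserved on stage failure).
#'
#' @param config path to a YAML config, or a config list (see
#'   [readPipelineConfig()]).
#' @param outputDir optional override of the config's output directory.
#' @return (invisibly) a list with the main in-memory results: the
#'   correlation matrix, enrichment records, \linkS4class{TaskStats},
#'   bootstrap tests, association records, effect estimates and the report.
#' @export
runPipeline <- function(config, outputDir = NULL) {
    cfg <- if (is.character(config)) readPipelineConfig(config)
           else validatePipelineConfig(config)
    if (!is.null(outputDir)) cfg$output_dir <- outputDir
    outDir <- cfg$output_dir
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    done <- character(0)
    report <- list(package = "hallmarkTasks",
                   version = as.character(utils::packageVersion("hallmarkTasks")),
                   config = cfg[setdiff(names(cfg),
                                        c("simulate", "inputs", "output_dir"))],
                   seed = cfg$seed)

    ## ---- stage: inputs -------------------------------------------------
    if (!is.null(cfg$simulate)) {
        .logStage("simulate: seed %d", cfg$seed)
        sim <- cfg$simulate
        if (is.null(sim$seed)) sim$seed <- cfg$seed
        params <- do.call(cohortParams, sim)
        cohort <- generateCohort(params)
        writeCohort(cohort, outDir)
        mrna <- cohort$mrna; protein <- cohort$protein
        sets <- cohort$geneSets; growth <- cohort$growth
        report$simulate <- list(n_cells = params@nCells,
                                n_genes = params@nGenes,
                                n_hallmarks = params@nHallmarks,
                                seed = params@seed)
    } else {
        .logStage("reading inputs")
        ip <- cfg$inputs
        mrna <- readAbundance(ip$mrna, "mRNA")
        protein <- readAbundance(ip$protein, "protein")
        sets <- readGmt(ip$gene_sets)
        growth <- readGrowth(ip$growth)
    }
    done <- c(done, "inputs"); .writeManifest(outDir, done)

    ## ---- stage: concordance --------------------------------------------
    .logStage("concordance: method %s, transform %s", cfg$method,
              cfg$transform)
    cc <- crossCorrelation(mrna, protein, method = cfg$method,
                           transform = cfg$transform)
    svo <- sameVsOther(cc)
    shared <- intersect(geneIds(mrna), geneIds(protein))
    rsize <- min(cfg$random_set_size, length(shared))
    randomSet <- sampleRandomSet(shared, n = rsize, seed = cfg$seed + 1L)
    allSets <- GeneSetCollection(
        c(geneSets(sets), list(random = randomSet)),
        universe = union(geneUniverse(sets), shared))
    setwise <- setwiseCorrelation(mrna, protein, allSets,
                                  method = cfg$method,
                                  transform = cfg$transform)
    randCorrs <- setwise$r[setwise$set_name == "random"]
    hallSetwise <- setwise[setwise$set_name != "random", ]
    hvr <- hallmarkVsRandom(hallSetwise, randCorrs)
    v <- corValues(cc)
    corDf <- data.frame(cell_id = rownames(v), v, check.names = FALSE,
                        stringsAsFactors = FALSE)
    .writeTsv(corDf, file.path(outDir, "correlations.tsv"))
    .writeTsv(setwise, file.path(outDir, "setwise_correlations.tsv"))
    report$concordance <- list(
        n_genes_used = cc@nGenesUsed,
        same_cell_mean = mean(diag(v), na.rm = TRUE),
        other_cell_mean = mean(v[row(v) != col(v)], na.rm = TRUE),
        welch = as.list(svo$welch), ks = as.list(svo$ks),
        anova = as.list(hvr$anova),
        wilcoxon = lapply(split(hvr$wilcoxon, hvr$wilcoxon$set_name),
                          as.list))
    done <- c(done, "concordance"); .writeManifest(outDir, done)

    ## ---- stage: enrichment ---------------------------------------------
    .logStage("enrichment: %d permutations, exponent %g, seed %d",
              cfg$n_perm, cfg$exponent, cfg$seed + 100L)
    records <- enrichAllCells(mrna, protein, sets, nPerm = cfg$n_perm,
                              seed = cfg$seed + 100L,
                              exponent = cfg$exponent,
                              minSize = cfg$min_set_size,
                              scoreTransform = cfg$score_transform)
    .writeTsv(records, file.path(outDir, "enrichment.tsv"))
    recM <- records[records$modality == "mRNA", ]
    recP <- records[records$modality == "protein", ]
    report$enrichment <- list(
        n_records = nrow(records), n_perm = cfg$n_perm,
        min_nes_mrna = min(recM$nes, na.rm = TRUE),
        frac_signif_mrna = mean(recM$fdr_q < cfg$fdr_threshold,
                                na.rm = TRUE))
    done <- c(done, "enrichment"); .writeManifest(outDir, done)

    ## ---- stage: task statistics ----------------------------------------
    .logStage("task statistics: sign convention %s, %d bootstrap draws",
              cfg$sign_convention, cfg$n_boot)
    stats <- taskStatistics(recM, recP, signConvention = cfg$sign_convention)
    dt <- deltaTable(stats)
    boots <- lapply(sort(unique(dt$set_name)), function(nm) {
        g <- dt[dt$set_name == nm, ]
        bt <- bootstrapDeltaTest(g$nes_mrna, g$nes_protein,
                                 nBoot = cfg$n_boot, seed = cfg$seed + 2L)
        data.frame(set_name = nm, observed_md = bt$observed_md,
                   p_value = bt$p_value, n_boot = bt$n_boot,
                   sample_size = bt$sample_size, stringsAsFactors = FALSE)
    })
    boots <- do.call(rbind, boots)
    .writeTsv(dt, file.path(outDir, "task_delta.tsv"))
    .writeTsv(rangeTable(stats), file.path(outDir, "task_range.tsv"))
    .writeTsv(boots, file.path(outDir, "bootstrap_tests.tsv"))
    report$task_statistics <- list(
        sign_convention = cfg$sign_convention,
        n_significant_sets = sum(boots$p_value < 0.05),
        bootstrap = lapply(split(boots, boots$set_name), as.list))
    done <- c(done, "task_statistics"); .writeManifest(outDir, done)

    ## ---- stage: growth associations ------------------------------------
    .logStage("growth associations")
    gcells <- intersect(cellIds(growth), unique(dt$cell_id))
    dtg <- dt[dt$cell_id %in% gcells & !is.na(dt$delta), ]
    div <- divisionRate(growth)[dtg$cell_id]
    assoc <- correlate(dtg$delta, div, "delta", "division_rate")
    inh <- inhibition(growth)
    if (ncol(inh) > 0L) {
        cellDelta <- tapply(dtg$delta, dtg$cell_id, mean)
        icells <- intersect(names(cellDelta), rownames(inh))
        pred <- rep(cellDelta[icells], times = ncol(inh))
        resp <- as.vector(inh[icells, , drop = FALSE])
        assoc <- rbind(assoc,
                       correlate(pred, resp, "delta", "growth_inhibition"))
    }
    perHall <- do.call(rbind, lapply(sort(unique(dtg$set_name)), function(nm) {
        g <- dtg[dtg$set_name == nm, ]
        correlate(g$delta, divisionRate(growth)[g$cell_id],
                  "delta", "division_rate", hallmark = nm)
    }))
    perHall$p_adjusted <- p.adjust(perHall$p_value, method = "BH")
    rt <- rangeTable(stats)
    rt <- rt[rt$cell_id %in% gcells & !is.na(rt$range), ]
    for (mod in unique(rt$modality)) {
        g <- rt[rt$modality == mod, ]
        assoc <- rbind(assoc, correlate(
            g$range, divisionRate(growth)[g$cell_id],
            paste0("range_", tolower(sub("mRNA", "mrna", g$modality[1L]))),
            "division_rate"))
    }
    fe <- fixedEffectModel(dtg, growth)
    ph <- perHallmarkEffects(dtg, growth)
    rangeEcdf <- NULL
    rp <- rt$range[rt$modality == "protein"]
    rm_ <- rt$range[rt$modality == "mRNA"]
    if (length(rp) >= 2L && length(rm_) >= 2L)
        rangeEcdf <- ecdfCompare(rp, rm_, alternative = "greater")
    .writeTsv(rbind(assoc, perHall[names(assoc)]),
              file.path(outDir, "associations.tsv"))
    .writeTsv(rbind(cbind(hallmark = NA_character_, fe),
                    ph[c("hallmark", setdiff(names(ph), "hallmark"))]),
              file.path(outDir, "effects.tsv"))
    report$associations <- list(
        delta_vs_division = as.list(assoc[1L, ]),
        delta_vs_inhibition = if (nrow(assoc) >= 2L &&
                                  assoc$response[2L] == "growth_inhibition")
            as.list(assoc[2L, ]) else NULL,
        fixed_effect = as.list(fe),
        per_hallmark_effects = lapply(split(ph, ph$hallmark), as.list),
        range_protein_vs_mrna = if (!is.null(rangeEcdf)) as.list(rangeEcdf)
                                else NULL)
    done <- c(done, "growth_associations"); .writeManifest(outDir, done)

    jsonlite::write_json(report, file.path(outDir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         null = "null")
    done <- c(done, "report"); .writeManifest(outDir, done)
    .logStage("done: %s", outDir)

    invisible(list(correlation = cc, setwise = setwise, records = records,
                   taskStats = stats, bootstrap = boots,
                   associations = assoc, perHallmarkAssoc = perHall,
                   fixedEffect = fe, perHallmarkEffects = ph,
                   report = report))
}
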