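#' Assemble a pipeline configuration
#'
#' Bundles every tunable of the end-to-end analysis: the synthetic
#' cohort specification, the Bonferroni threshold, the random-network
#' normalization settings, the permutation-inference settings, and the
#' behavioral covariates. All sub-blocks are validated here, before any
#' computation starts. One `masterSeed` deterministically derives every
#' stage seed (see `deriveSeed` in the sources), so a whole run is
#' reproducible from the configuration alone.
#'
#' @param outDir output directory (created if needed).
#' @param spec a [SyntheticSpec-class]; its seed is overridden by
#'   `masterSeed`.
#' @param alpha family-wise Bonferroni level for edge retention.
#' @param nRandom random networks per subject for normalization.
#' @param swapFactor rewiring swaps per edge.
#' @param globTol,locTol small-world tolerances (see [isSmallWorld()]).
#' @param nPerm permutations for all group tests.
#' @param primaryAlpha NBS edge-level threshold.
#' @param positiveFrac NBS positivity-rule fraction.
#' @param q FDR level for the nodal comparison.
#' @param covariateNames covariates controlled in the behavior analysis.
#' @param masterSeed master RNG seed.
#' @param writeSubjectData also write per-subject time-series and motion
#'   TSVs (voluminous; default FALSE).
#' @return a validated configuration list of class `fcnetConfig`.
#' @export
pipelineConfig <- function(outDir, spec = syntheticSpec(),
                           alpha = 0.05, nRandom = 100L, swapFactor = 20,
                           globTol = 0.1, locTol = 0.05,
                           nPerm = 10000L, primaryAlpha = 0.05,
                           positiveFrac = 0.85, q = 0.05,
                           covariateNames = c("age", "sex", "education"),
                           masterSeed = 1L, writeSubjectData = FALSE) {
    validObject(spec)
    if (nPerm < 1L) stop("nPerm must be at least 1")
    if (nRandom < 0L) stop("nRandom must be nonnegative")
    if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
    if (primaryAlpha <= 0 || primaryAlpha >= 1)
        stop("primaryAlpha must lie in (0, 1)")
    if (positiveFrac < 0 || positiveFrac >= 1)
        stop("positiveFrac must lie in [0, 1)")
    if (q <= 0 || q >= 1) stop("q must lie in (0, 1)")
    structure(list(outDir = outDir, spec = spec, alpha = alpha,
                   nRandom = as.integer(nRandom), swapFactor = swapFactor,
                   globTol = globTol, locTol = locTol,
                   nPerm = as.integer(nPerm), primaryAlpha = primaryAlpha,
                   positiveFrac = positiveFrac, q = q,
                   covariateNames = covariateNames,
                   masterSeed = as.integer(masterSeed),
                   writeSubjectData = isTRUE(writeSubjectData)),
              class = "fcnetConfig")
}

stageLog <- function(stage, t0) {
    message(sprintf("[fcnet] stage %-9s done in %.1f s", stage,
                    as.numeric(proc.time()[3L]) - t0))
}

#' Run the full connectome analysis pipeline
#'
#' Executes, in fixed order: cohort simulation, per-subject cleaning
#' (detrend, band-pass, Friston-24 nuisance regression) with motion
#' quality control, Bonferroni network construction, small-world
#' efficiency metrics with random-network normalization, group
#' permutation inference (global metrics, FDR-corrected nodal
#' comparison, NBS in both directions), and the covariate-adjusted
#' brain-behavior correlation table. Stage outputs are written under
#' `config$outDir` as TSV/JSON; the run is a pure function of the
#' configuration (no timestamps enter any payload).
#'
#' @param config a configuration from [pipelineConfig()].
#' @return invisibly, a named list with all stage results.
#' @examples
#' \donttest{
#' cfg <- pipelineConfig(tempfile("run"),
#'     spec = syntheticSpec(nRois = 20, nVolumes = 60, nGroupA = 8,
#'                          nGroupB = 8),
#'     nRandom = 10L, nPerm = 200L, masterSeed = 7L)
#' res <- runPipeline(cfg)
#' names(res)
#' }
#' @export
runPipeline <- function(config) {
    if (!inherits(config, "fcnetConfig"))
        stop("config must come from pipelineConfig()")
    dir.create(config$outDir, recursive = TRUE, showWarnings = FALSE)
    out <- function(...) file.path(config$outDir, ...)

    # --- simulate -------------------------------------------------------
    t0 <- proc.time()[3L]
    spec <- config$spec
    spec@seed <- deriveSeed(config$masterSeed, 11L)
    cohort <- generateCohort(spec)
    tab <- cohortTable(cohort)
    writeCohortTsv(tab, out("cohort.tsv"))
    writeResultsJson(list(
        nRois = spec@nRois, nVolumes = spec@nVolumes,
        trSeconds = spec@trSeconds, nGroupA = spec@nGroupA,
        nGroupB = spec@nGroupB, blockSizes = spec@blockSizes,
        withinBlockCov = spec@withinBlockCov,
        betweenBlockCov = spec@betweenBlockCov,
        nEffectEdges = nrow(spec@effectEdges),
        effectDelta = spec@effectDelta, arCoeff = spec@arCoeff,
        noiseSd = spec@noiseSd, seed = spec@seed), out("spec_echo.json"))
    if (config$writeSubjectData) {
        dir.create(out("subjects"), showWarnings = FALSE)
        for (id in tab$subject_id) {
            writeTimeSeriesTsv(cohort@timeSeries[[id]],
                               out("subjects", paste0(id, "_ts.tsv")))
            writeMotionTsv(cohort@motion[[id]],
                           out("subjects", paste0(id, "_motion.tsv")))
        }
    }
    stageLog("simulate", t0)

    # --- clean ----------------------------------------------------------
    t0 <- proc.time()[3L]
    qc <- lapply(tab$subject_id, function(id) {
        mp <- cohort@motion[[id]]
        fd <- framewiseDisplacement(mp)
        ex <- motionExclusion(mp)
        list(subject_id = id, fd_max = fd$max, fd_mean = fd$mean,
             fd_rms = fd$rms, exclude = ex$exclude, reason = ex$reason)
    })
    names(qc) <- tab$subject_id
    writeResultsJson(qc, out("cleaning_report.json"))
    keep <- tab$subject_id[!vapply(qc, `[[`, TRUE, "exclude")]
    cleaned <- lapply(keep, function(id)
        cleanTimeSeries(cohort@timeSeries[[id]], cohort@motion[[id]]))
    names(cleaned) <- keep
    stageLog("clean", t0)

    # --- build ----------------------------------------------------------
    t0 <- proc.time()[3L]
    conn <- lapply(cleaned, correlationMatrix)
    graphs <- lapply(conn, thresholdBonferroni, alpha = config$alpha)
    census <- lapply(graphs, componentCensus)
    buildSummary <- lapply(keep, function(id) {
        g <- graphs[[id]]
        list(N = nodeCount(g), K = edgeCount(g),
             density = networkDensity(g),
             nComponents = census[[id]]$nComponents,
             nIsolated = length(census[[id]]$isolated))
    })
    names(buildSummary) <- keep
    writeResultsJson(buildSummary, out("graphs.json"))
    stageLog("build", t0)

    # --- metrics --------------------------------------------------------
    t0 <- proc.time()[3L]
    metricSeeds <- subjectSeeds(config$masterSeed, length(keep), 4L)
    gm <- lapply(seq_along(keep), function(i)
        computeGlobalMetrics(graphs[[keep[i]]], nRandom = config$nRandom,
                             seed = metricSeeds[i],
                             swapFactor = config$swapFactor))
    names(gm) <- keep
    nodal <- t(vapply(keep, function(id) nodalEfficiency(graphs[[id]]),
                      numeric(nodeCount(graphs[[1L]]))))
    metricsTab <- data.frame(
        subject_id = keep,
        group = tab$group[match(keep, tab$subject_id)],
        n_edges = vapply(gm, function(m) NA_integer_, NA_integer_),
        stringsAsFactors = FALSE)
    metricsTab$n_edges <- vapply(keep, function(id)
        edgeCount(graphs[[id]]), 0L)
    metricsTab$density <- vapply(gm, slot, 0.0, "density")
    metricsTab$e_glob <- vapply(gm, slot, 0.0, "eGlob")
    metricsTab$e_loc <- vapply(gm, slot, 0.0, "eLoc")
    metricsTab$norm_e_glob <- vapply(gm, slot, 0.0, "normEGlob")
    metricsTab$norm_e_loc <- vapply(gm, slot, 0.0, "normELoc")
    metricsTab$small_world <- vapply(gm, function(m)
        if (is.na(m@normEGlob)) NA else
            isSmallWorld(m, config$globTol, config$locTol), NA)
    writeCohortTsv(metricsTab, out("metrics.tsv"))
    stageLog("metrics", t0)

    # --- compare --------------------------------------------------------
    t0 <- proc.time()[3L]
    grp <- metricsTab$group
    compareSeed <- deriveSeed(config$masterSeed, 21L)
    globalTests <- lapply(
        c("n_edges", "density", "e_glob", "e_loc", "norm_e_glob",
          "norm_e_loc"),
        function(mn) {
            res <- permutationTestMetric(
                metricsTab[[mn]][grp == "A"], metricsTab[[mn]][grp == "B"],
                nPerm = config$nPerm, direction = "greater",
                seed = compareSeed, metricName = mn)
            list(metric = mn, observed_diff = res@observedDiff,
                 p = res@pValue, crit_95 = res@critValue,
                 significant_percentile = res@significantPercentile,
                 n_perm = res@nPerm)
        })
    names(globalTests) <- vapply(globalTests, `[[`, "", "metric")
    nodalRes <- nodalComparison(nodal[grp == "A", , drop = FALSE],
                                nodal[grp == "B", , drop = FALSE],
                                nPerm = config$nPerm, q = config$q,
                                seed = compareSeed)
    writeResultsJson(list(global = globalTests,
                          nodal = list(
                              n_significant = sum(nodalRes$significant),
                              significant_rois =
                                  roiLabels(graphs[[1L]])[nodalRes$significant],
                              p = nodalRes$p)),
                     out("group_comparison.json"))
    stageLog("compare", t0)

    # --- nbs ------------------------------------------------------------
    t0 <- proc.time()[3L]
    nbsSeed <- deriveSeed(config$masterSeed, 31L)
    connA <- conn[grp == "A"]; connB <- conn[grp == "B"]
    nbsUp <- nbs(connA, connB, primaryAlpha = config$primaryAlpha,
                 nPerm = config$nPerm, positiveFrac = config$positiveFrac,
                 direction = "A>B", seed = nbsSeed)
    nbsDown <- nbs(connA, connB, primaryAlpha = config$primaryAlpha,
                   nPerm = config$nPerm,
                   positiveFrac = config$positiveFrac,
                   direction = "B>A", seed = nbsSeed)
    nbsSummary <- function(x) list(
        direction = x@direction,
        component_sizes = x@componentSizes,
        corrected_p = x@correctedP,
        n_included_edges = sum(x@includedEdges) / 2)
    writeResultsJson(list(`A>B` = nbsSummary(nbsUp),
                          `B>A` = nbsSummary(nbsDown)), out("nbs.json"))
    if (length(nbsUp@components))
        utils::write.table(
            cbind(component_id = rep(seq_along(nbsUp@components),
                                     nbsUp@componentSizes),
                  do.call(rbind, nbsUp@components)),
            out("nbs_components.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)
    stageLog("nbs", t0)

    # --- behavior -------------------------------------------------------
    t0 <- proc.time()[3L]
    aIds <- metricsTab$subject_id[grp == "A"]
    aTab <- tab[match(aIds, tab$subject_id), , drop = FALSE]
    scoreCols <- intersect(c("PSQI", "ISI", "SAS", "SDS", "ESS",
                             "duration", "coupled"), names(aTab))
    behav <- behaviorTable(
        metricsTab[grp == "A", c("subject_id", "n_edges", "e_glob",
                                 "e_loc", "norm_e_glob", "norm_e_loc")],
        aTab[, c("subject_id", scoreCols)],
        aTab[, c("subject_id", config$covariateNames)])
    utils::write.table(behav, out("behavior.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    stageLog("behavior", t0)

    # --- report ---------------------------------------------------------
    t0 <- proc.time()[3L]
    groupMeans <- function(col) list(
        A = mean(metricsTab[[col]][grp == "A"]),
        B = mean(metricsTab[[col]][grp == "B"]))
    report <- list(
        n_subjects = nrow(tab), n_analyzed = length(keep),
        n_excluded_motion = nrow(tab) - length(keep),
        density = groupMeans("density"),
        e_glob = groupMeans("e_glob"), e_loc = groupMeans("e_loc"),
        norm_e_glob = groupMeans("norm_e_glob"),
        norm_e_loc = groupMeans("norm_e_loc"),
        small_world_fraction = mean(metricsTab$small_world, na.rm = TRUE),
        global_tests = lapply(globalTests, `[[`, "p"),
        nodal_significant = sum(nodalRes$significant),
        nbs_top_component = if (length(nbsUp@componentSizes))
            list(size = nbsUp@componentSizes[1L],
                 corrected_p = nbsUp@correctedP[1L]) else NULL)
    writeResultsJson(report, out("report.json"))
    stageLog("report", t0)

    invisible(list(cohort = cohort, qc = qc, graphs = graphs,
                   metrics = metricsTab, nodal = nodal,
                   globalTests = globalTests, nodalComparison = nodalRes,
                   nbsUp = nbsUp, nbsDown = nbsDown, behavior = behav,
                   report = report))
}
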