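#' Default run configuration
#'
#' Assembles the full configuration of a pipeline run: simulation
#' parameters, the named pretreatment presets used by each analysis stage
#' (keyed after the corresponding report figures of a typical
#' fermentation-monitoring study), cross-validation settings and the seed.
#' Presets:
#' \describe{
#'   \item{difference}{Savitzky-Golay smoothing 35 points + detrend, for
#'     averaged difference spectra.}
#'   \item{pca}{smoothing 43 points + detrend, for the global PCA.}
#'   \item{lda.BL / lda.LS / lda.MC}{smoothing 21 points / detrend / MSC,
#'     the per-strain classification pretreatments.}
#'   \item{ph.BL / ph.LS / ph.MC}{detrend / SNV / SNV, the per-strain pH
#'     regression pretreatments.}
#'   \item{cellcount}{smoothing 21 points + MSC, then averaging by
#'     culture x time for the log cell count model.}
#'   \item{aquagram}{smoothing 21 points + SNV.}
#' }
#'
#' @param seed integer seed applied to the simulator and stratified folds.
#' @return named list (`params`, `presets`, `cv`, `seed`).
#' @export
defaultRunConfig <- function(seed = 20250405L) {
    list(
        seed = as.integer(seed),
        params = simParams(seed = seed),
        cv = list(nFolds = 3L, maxPcs = 30L, maxLv = 10L),
        presets = list(
            difference = list(list(step = "savgol", window = 35),
                              list(step = "detrend")),
            pca = list(list(step = "savgol", window = 43),
                       list(step = "detrend")),
            lda.BL = list(list(step = "savgol", window = 21)),
            lda.LS = list(list(step = "detrend")),
            lda.MC = list(list(step = "msc")),
            ph.BL = list(list(step = "detrend")),
            ph.LS = list(list(step = "snv")),
            ph.MC = list(list(step = "snv")),
            cellcount = list(list(step = "savgol", window = 21),
                             list(step = "msc")),
            aquagram = list(list(step = "savgol", window = 21),
                            list(step = "snv"))))
}

#' Read a run configuration from YAML
#'
#' Reads `seed`, `cv` settings and pretreatment `presets` from a YAML file
#' and merges them over [defaultRunConfig()]; simulator parameter overrides
#' under a `params` mapping (`wavelengthStart`, `phStart`, noise entries,
#' ...) are applied to [simParams()].
#'
#' @param path YAML file.
#' @return configuration list as from [defaultRunConfig()].
#' @export
readRunConfig <- function(path) {
    y <- yaml::read_yaml(path)
    cfg <- defaultRunConfig(seed = y$seed %||% 20250405L)
    for (nm in names(y$cv %||% list())) cfg$cv[[nm]] <- y$cv[[nm]]
    for (nm in names(y$presets %||% list()))
        cfg$presets[[nm]] <- y$presets[[nm]]
    if (length(y$params)) {
        args <- y$params
        args$seed <- args$seed %||% cfg$seed
        cfg$params <- do.call(simParams, args)
    }
    cfg
}

.preset <- function(config, name) {
    p <- config$presets[[name]]
    if (is.null(p))
        stop("missing pretreatment preset: ", name, call. = FALSE)
    p
}

.writeJSON <- function(x, path) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    path
}

#' Run the full fermentation-monitoring pipeline
#'
#' Executes every stage on a simulated experiment: simulation (design,
#' reference, spectra, written as CSV with a JSON parameter sidecar),
#' averaged difference spectra, global PCA with influential wavelengths,
#' per-strain PCA-LDA classification of fermentation time (principal
#' component selection under the grouped three-fold plan), per-strain PLSR
#' of pH (latent-variable selection by minimal RMSECV), one PLSR of log10
#' cell count on culture-by-time averaged spectra (stratified seeded
#' three-fold), and per-culture difference aquagrams. All metrics and a
#' manifest listing every artifact, the seed and the configuration are
#' written to `outDir`; a rerun with the same configuration produces
#' identical metric files.
#'
#' @param config list from [defaultRunConfig()] or [readRunConfig()].
#' @param outDir output directory (created if needed).
#' @param radarPlots logical, also render radar plot PNGs.
#' @return the manifest list, invisibly.
#' @export
runPipeline <- function(config = defaultRunConfig(), outDir,
                        radarPlots = FALSE) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    art <- character(0)
    put <- function(f) { art[[length(art) + 1L]] <<- f; file.path(outDir, f) }
    stage <- function(name, expr) {
        tryCatch(expr, error = function(e)
            stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
                 call. = FALSE))
    }

    # --- simulate ---------------------------------------------------------
    sim <- stage("simulate", {
        design <- simulateDesign()
        ref <- simulateReference(design, config$params)
        spectra <- simulateSpectra(design, ref, config$params)
        writeSpectra(spectra, put("spectra.csv"))
        writeReferenceTable(ref, put("reference.csv"))
        .writeJSON(simParamsAsList(config$params), put("sim_params.json"))
        list(design = design, ref = ref, spectra = spectra)
    })
    spectra <- sim$spectra
    strains <- sim$design@cultures

    # --- difference spectra ----------------------------------------------
    stage("difference_spectra", {
        d <- differenceSpectra(
            applyPretreatment(spectra, .preset(config, "difference")))
        writeSpectra(d, put("difference_spectra.csv"))
    })

    # --- global PCA -------------------------------------------------------
    pcaReport <- stage("pca", {
        pre <- applyPretreatment(spectra, .preset(config, "pca"))
        m <- fitPCA(pre, min(10L, nScans(pre) - 1L))
        list(explained_variance_pct = 100 * explainedVariance(m),
             pc12_cumulative_pct = 100 * sum(explainedVariance(m)[1:2]),
             top_wavelengths_pc1 = topLoadingWavelengths(m, 1, 3),
             top_wavelengths_pc2 = topLoadingWavelengths(m, 2, 3))
    })
    .writeJSON(pcaReport, put("pca.json"))

    # --- per-strain PCA-LDA ----------------------------------------------
    ldaReports <- lapply(strains, function(st) stage(paste0("lda.", st), {
        sub <- applyPretreatment(subsetSpectra(spectra, culture = st),
                                 .preset(config, paste0("lda.", st)))
        plan <- makeFoldPlan(sub, config$cv$nFolds)
        labels <- factor(scanInfo(sub)$time_h)
        sel <- selectNrPCs(sub, labels, plan, config$cv$maxPcs)
        res <- pcaLdaClassify(sub, labels, sel$nrpcs, plan)
        utils::write.csv(sel$table,
                         put(sprintf("lda_%s_candidates.csv", st)),
                         row.names = FALSE)
        list(strain = st, nrpcs = res@nrpcs,
             calibration_accuracy_pct = res@trainAccuracy,
             cv_accuracy_pct = res@cvAccuracy,
             confusion = as.data.frame(unclass(res@confusion)))
    }))
    names(ldaReports) <- strains
    .writeJSON(ldaReports, put("lda.json"))

    # --- per-strain pH PLSR ----------------------------------------------
    refKey <- paste(sim$ref$culture, sim$ref$time_h, sim$ref$replicate)
    phReports <- lapply(strains, function(st) stage(paste0("ph.", st), {
        sub <- applyPretreatment(subsetSpectra(spectra, culture = st),
                                 .preset(config, paste0("ph.", st)))
        m <- scanInfo(sub)
        y <- sim$ref$pH[match(paste(m$culture, m$time_h, m$replicate),
                              refKey)]
        plan <- makeFoldPlan(sub, config$cv$nFolds)
        sel <- selectNrLVs(sub, y, plan, config$cv$maxLv)
        mod <- evaluatePLSR(sub, y, sel$nrlv, plan)
        utils::write.csv(mod@predictions,
                         put(sprintf("plsr_ph_%s_predictions.csv", st)),
                         row.names = FALSE)
        c(list(strain = st, nrlv = mod@nrlv), mod@metrics,
          list(peak_wavelengths = regressionVectorPeaks(mod, 6)))
    }))
    names(phReports) <- strains
    .writeJSON(phReports, put("plsr_ph.json"))

    # --- cell-count PLSR on averaged spectra ------------------------------
    ccReport <- stage("cellcount", {
        ferm <- subsetSpectra(spectra,
                              times = setdiff(sim$design@times, 0))
        avg <- applyPretreatment(ferm, .preset(config, "cellcount"))
        avg <- averageBy(avg, c("culture", "time_h"))
        m <- scanInfo(avg)
        yTab <- stats::aggregate(logcfu ~ culture + time_h, sim$ref, mean)
        y <- yTab$logcfu[match(paste(m$culture, m$time_h),
                               paste(yTab$culture, yTab$time_h))]
        plan <- makeStratifiedFoldPlan(avg, config$cv$nFolds,
                                       seed = config$seed)
        sel <- selectNrLVs(avg, y, plan, min(config$cv$maxLv,
                                             nScans(avg) - 2L))
        mod <- evaluatePLSR(avg, y, sel$nrlv, plan)
        utils::write.csv(mod@predictions,
                         put("plsr_cellcount_predictions.csv"),
                         row.names = FALSE)
        c(list(n = nScans(avg), nrlv = mod@nrlv), mod@metrics,
          list(peak_wavelengths = regressionVectorPeaks(mod, 6)))
    })
    .writeJSON(ccReport, put("plsr_cellcount.json"))

    # --- aquagrams --------------------------------------------------------
    aqReports <- lapply(strains, function(st) stage(paste0("aquagram.", st), {
        sub <- subsetSpectra(spectra, culture = st)
        aq <- computeAquagram(sub, pretreatment = .preset(config, "aquagram"))
        base <- aq@groupInfo$sample_id[aq@groupInfo$time_h == 0][1]
        daq <- differenceAquagram(aq, base)
        exportRadar(daq, put(sprintf("aquagram_%s.csv", st)),
                    plotPath = if (radarPlots)
                        put(sprintf("aquagram_%s.png", st)))
        daq@values
    }))
    names(aqReports) <- strains

    manifestPath <- put("manifest.json")
    manifest <- list(
        seed = config$seed,
        n_scans = nScans(spectra),
        models = list(lda = length(ldaReports), plsr_ph = length(phReports),
                      plsr_cellcount = 1L, aquagrams = length(aqReports)),
        cv = config$cv,
        presets = config$presets,
        artifacts = unlist(art),
        timestamp = format(Sys.time(), tz = "UTC"))
    .writeJSON(manifest, manifestPath)
    invisible(manifest)
}

# serializable view of SimParams for the JSON sidecar
simParamsAsList <- function(p) {
    list(wavelengthStart = p@wavelengthStart,
         wavelengthEnd = p@wavelengthEnd,
         wavelengthStep = p@wavelengthStep,
         phStart = p@phStart, phEnd = as.list(p@phEnd),
         kPh = as.list(p@kPh), growth = p@growth,
         bands = p@bands, baseline = p@baseline,
         scatter = p@scatter, noise = p@noise, seed = p@seed)
}
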