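#' @import methods
NULL

REQUIRED_META <- c("sample_id", "culture", "time_h", "replicate", "scan")

#' SpectraSet: NIR spectra with per-scan metadata
#'
#' A `SpectraSet` stores a collection of absorbance spectra together with the
#' experimental metadata of every scan. It extends
#' [SummarizedExperiment::SummarizedExperiment] with wavelengths as rows
#' (feature dimension, `rowData(x)$wavelength_nm`) and scans as columns; the
#' single assay `"absorbance"` holds absorbance units. User-facing accessors
#' ([absorbance()], [wavelengths()], [scanInfo()]) present the conventional
#' chemometric orientation (one row per scan, one column per wavelength).
#'
#' Required metadata fields per scan: `sample_id`, `culture`, `time_h`,
#' `replicate`, `scan`. The combination `(sample_id, replicate, scan)` must be
#' unique, and all scans of one `(sample_id, replicate)` block are kept
#' contiguous in column order so that grouped cross-validation folds are
#' reproducible.
#'
#' @seealso [SpectraSet()] for construction from a scans-by-wavelengths
#'   matrix, [readSpectra()]/[writeSpectra()] for CSV I/O.
#' @export
setClass("SpectraSet", contains = "SummarizedExperiment")

.validSpectraSet <- function(object) {
    msg <- character()
    if (!"absorbance" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'absorbance' is required")
    rd <- SummarizedExperiment::rowData(object)
    if (!"wavelength_nm" %in% colnames(rd)) {
        msg <- c(msg, "rowData must contain 'wavelength_nm'")
    } else {
        wl <- rd$wavelength_nm
        if (anyNA(wl) || !is.numeric(wl))
            msg <- c(msg, "wavelengths must be numeric and non-missing")
        else if (any(diff(wl) <= 0))
            msg <- c(msg, "wavelengths must be strictly increasing")
    }
    cd <- SummarizedExperiment::colData(object)
    miss <- setdiff(REQUIRED_META, colnames(cd))
    if (length(miss))
        msg <- c(msg, paste0("missing scan metadata column(s): ",
                             paste(miss, collapse = ", ")))
    if (!length(miss)) {
        key <- paste(cd$sample_id, cd$replicate, cd$scan, sep = "\r")
        if (anyDuplicated(key))
            msg <- c(msg, "(sample_id, replicate, scan) must be unique")
        blk <- paste(cd$sample_id, cd$replicate, sep = "\r")
        if (length(blk) && any(rle(blk)$values |> duplicated()))
            msg <- c(msg, "scans of one (sample_id, replicate) must be contiguous")
    }
    if (length(msg)) msg else TRUE
}
setValidity("SpectraSet", .validSpectraSet)

#' Fermentation experiment design
#'
#' Enumerates the biological sample groups and individual scan rows of a
#' fermentation-monitoring experiment: a set of starter cultures sampled at
#' fixed fermentation times, each sample measured in replicates with several
#' consecutive scans. When `sharedBaseline` is `TRUE` the unfermented 0 h
#' juice is a single group (culture code `"JUICE"`) shared by all cultures,
#' so the default design (3 cultures, 5 times, 3 replicates, 3 scans) has
#' 3*4 + 1 = 13 sample groups and 117 scan rows.
#'
#' @slot cultures character, fermented culture codes (default `BL`, `LS`, `MC`).
#' @slot times numeric, ordered sampling times in hours.
#' @slot nReplicates,nScans integer counts.
#' @slot sharedBaseline logical, single shared unfermented 0 h group.
#' @slot groups data.frame of sample groups (`sample_id`, `culture`, `time_h`).
#' @slot scans data.frame of scan rows (`sample_id`, `culture`, `time_h`,
#'   `replicate`, `scan`).
#' @export
setClass("FermentationDesign", representation(
    cultures = "character", times = "numeric",
    nReplicates = "integer", nScans = "integer",
    sharedBaseline = "logical",
    groups = "data.frame", scans = "data.frame"))

setValidity("FermentationDesign", function(object) {
    msg <- character()
    if (!length(object@cultures)) msg <- c(msg, "at least one culture required")
    if (anyDuplicated(object@cultures)) msg <- c(msg, "duplicate cultures")
    if (!length(object@times)) msg <- c(msg, "at least one sampling time required")
    if (anyDuplicated(object@times)) msg <- c(msg, "duplicate sampling times")
    if (is.unsorted(object@times)) msg <- c(msg, "times must be increasing")
    if (object@nReplicates < 1L || object@nScans < 1L)
        msg <- c(msg, "replicate and scan counts must be >= 1")
    nexp <- nrow(object@groups) * object@nReplicates * object@nScans
    if (nrow(object@scans) != nexp)
        msg <- c(msg, "scan rows must equal groups x replicates x scans")
    if (length(msg)) msg else TRUE
})

#' Simulation parameters for the fermentation spectra generator
#'
#' Bundles every free parameter of the synthetic experiment: the wavelength
#' grid, per-culture pH decay and growth-curve parameters, the water-band
#' table (center, width and the affine coupling of each band amplitude to pH
#' and log10 CFU), the smooth juice baseline, the turbidity scatter model and
#' the replicate/scan noise standard deviations, plus the seed. Construct
#' with [simParams()], which supplies defaults emulating probiotic
#' fruit-juice fermentation over 24 h.
#'
#' @slot wavelengthStart,wavelengthEnd,wavelengthStep numeric, grid in nm.
#' @slot phStart numeric, initial pH shared by all cultures.
#' @slot phEnd,kPh named numeric, per-culture asymptotic pH and decay rate (1/h).
#' @slot growth named list of per-culture growth-curve parameter lists.
#' @slot bands data.frame with columns `label`, `center`, `sigma`, `alpha`,
#'   `betaPh`, `gammaCfu`.
#' @slot baseline,scatter,noise named lists, see [simParams()].
#' @slot seed integer RNG seed.
#' @export
setClass("SimParams", representation(
    wavelengthStart = "numeric", wavelengthEnd = "numeric",
    wavelengthStep = "numeric",
    phStart = "numeric", phEnd = "numeric", kPh = "numeric",
    growth = "list", bands = "data.frame",
    baseline = "list", scatter = "list", noise = "list",
    seed = "integer"))

setValidity("SimParams", function(object) {
    msg <- character()
    if (object@wavelengthStep <= 0) msg <- c(msg, "wavelength step must be > 0")
    if (object@wavelengthStart >= object@wavelengthEnd)
        msg <- c(msg, "wavelength range must be increasing")
    if (any(unlist(object@noise) < 0)) msg <- c(msg, "noise sds must be >= 0")
    if (any(object@kPh < 0)) msg <- c(msg, "pH decay rates must be >= 0")
    if (any(object@phEnd > object@phStart))
        msg <- c(msg, "phEnd must not exceed phStart")
    need <- c("label", "center", "sigma", "alpha", "betaPh", "gammaCfu")
    if (!all(need %in% colnames(object@bands)))
        msg <- c(msg, "bands table lacks required columns")
    if (length(msg)) msg else TRUE
})

#' Principal component model of a spectra set
#'
#' Column-mean-centered PCA of the absorbance matrix. Loadings are
#' orthonormal (wavelengths x components) with a deterministic sign
#' convention: the largest-magnitude element of each loading vector is
#' positive. `varianceRatio` holds the per-component fractions of total
#' variance (non-increasing, summing to at most 1).
#'
#' @slot center numeric mean spectrum.
#' @slot loadings,scores matrices.
#' @slot varianceRatio numeric explained-variance fractions.
#' @slot wavelengths numeric grid the loadings refer to.
#' @seealso [fitPCA()], [topLoadingWavelengths()]
#' @export
setClass("PCAModel", representation(
    center = "numeric", loadings = "matrix", scores = "matrix",
    varianceRatio = "numeric", wavelengths = "numeric"))

setValidity("PCAModel", function(object) {
    msg <- character()
    g <- crossprod(object@loadings)
    if (max(abs(g - diag(ncol(g)))) > 1e-8)
        msg <- c(msg, "loadings must be orthonormal")
    vr <- object@varianceRatio
    if (any(diff(vr) > 1e-12)) msg <- c(msg, "variance ratios must be non-increasing")
    if (sum(vr) > 1 + 1e-8) msg <- c(msg, "variance ratios must sum to <= 1")
    if (length(msg)) msg else TRUE
})

#' Grouped cross-validation fold plan
#'
#' Assigns every scan row to one of `nFolds` folds such that all consecutive
#' scans of one `(sample_id, replicate)` measurement block share a fold. In
#' the canonical three-replicate design the fold index is the replicate
#' index, so each fold holds one full measurement repetition of every sample.
#'
#' @slot fold integer fold index per scan row.
#' @slot block character `(sample_id, replicate)` block id per scan row.
#' @slot nFolds integer.
#' @seealso [makeFoldPlan()]
#' @export
setClass("FoldPlan", representation(
    fold = "integer", block = "character", nFolds = "integer"))

setValidity("FoldPlan", function(object) {
    msg <- character()
    if (length(object@fold) != length(object@block))
        msg <- c(msg, "fold and block must align")
    if (anyNA(object@fold) || any(object@fold < 1L) ||
        any(object@fold > object@nFolds))
        msg <- c(msg, "fold indices out of range")
    split_folds <- tapply(object@fold, object@block,
                          function(f) length(unique(f)))
    if (length(split_folds) && any(split_folds > 1L))
        msg <- c(msg, "a (sample_id, replicate) block spans several folds")
    if (length(msg)) msg else TRUE
})

#' PCA-LDA classification result
#'
#' Result of fermentation-time classification by PCA-compressed linear
#' discriminant analysis under a grouped fold plan: the retained number of
#' principal components, per-fold training/validation accuracies (percent),
#' the pooled validation confusion matrix, cross-validated class predictions
#' and the canonical discriminant scores of the final all-data model.
#'
#' @slot nrpcs integer, principal components retained.
#' @slot trainAccuracy,cvAccuracy numeric percent.
#' @slot foldTable data.frame of per-fold accuracies.
#' @slot confusion matrix (true class x predicted class, validation pooled).
#' @slot cvPredicted factor of held-out predictions per row.
#' @slot labels factor of true classes per row.
#' @slot canonicalScores matrix of discriminant coordinates (all-data model).
#' @seealso [pcaLdaClassify()], [selectNrPCs()]
#' @export
setClass("ClassificationResult", representation(
    nrpcs = "integer", trainAccuracy = "numeric", cvAccuracy = "numeric",
    foldTable = "data.frame", confusion = "matrix",
    cvPredicted = "factor", labels = "factor",
    canonicalScores = "matrix"))

setValidity("ClassificationResult", function(object) {
    msg <- character()
    acc <- c(object@trainAccuracy, object@cvAccuracy)
    if (any(acc < 0 | acc > 100)) msg <- c(msg, "accuracies must be in [0, 100]")
    cls <- table(object@labels)
    rs <- rowSums(object@confusion)
    if (!all(rs == as.integer(cls[names(rs)])))
        msg <- c(msg, "confusion row sums must equal class counts")
    if (length(msg)) msg else TRUE
})

#' Partial least squares regression model
#'
#' Univariate-response NIPALS PLS model: retained latent variables, mean
#' centers, weight/loading matrices, the wavelength-domain regression vector
#' (so that `fitted = centered X %*% coefficients + yCenter`), calibration and
#' cross-validation metrics, and per-row (actual, fitted, cross-validated)
#' target values.
#'
#' @slot nrlv integer latent variables retained.
#' @slot xCenter numeric mean spectrum; `yCenter` numeric mean response.
#' @slot yCenter numeric.
#' @slot weights,xLoadings matrices (wavelengths x LVs).
#' @slot yLoadings numeric per-LV response loadings.
#' @slot coefficients numeric regression vector over wavelengths.
#' @slot metrics list with `R2C`, `RMSEC` and, after [evaluatePLSR()],
#'   `R2CV`, `RMSECV`.
#' @slot predictions data.frame with columns `actual`, `fitted` and
#'   optionally `cv`.
#' @slot wavelengths numeric grid.
#' @seealso [fitPLSR()], [evaluatePLSR()], [selectNrLVs()]
#' @export
setClass("PLSModel", representation(
    nrlv = "integer", xCenter = "numeric", yCenter = "numeric",
    weights = "matrix", xLoadings = "matrix", yLoadings = "numeric",
    coefficients = "numeric", metrics = "list",
    predictions = "data.frame", wavelengths = "numeric"))

setValidity("PLSModel", function(object) {
    msg <- character()
    m <- object@metrics
    rmse <- unlist(m[grep("^RMSE", names(m))])
    if (length(rmse) && any(rmse < 0)) msg <- c(msg, "RMSE must be >= 0")
    r2 <- unlist(m[grep("^R2", names(m))])
    if (length(r2) && any(r2 > 1 + 1e-12)) msg <- c(msg, "R2 must be <= 1")
    if (length(msg)) msg else TRUE
})

#' Water matrix coordinate registry
#'
#' The twelve conventional water matrix coordinates (WAMACs) of the first
#' overtone of water, used as aquagram axes. Labels `C1`..`C12` with strictly
#' increasing nominal wavelengths inside 1300-1600 nm and a closed band range
#' per coordinate.
#'
#' @slot labels character, `C1`..`C12`.
#' @slot wavelength numeric nominal center (nm).
#' @slot bandLow,bandHigh numeric band limits (nm).
#' @seealso [wamacCoordinates()]
#' @export
setClass("WamacSet", representation(
    labels = "character", wavelength = "numeric",
    bandLow = "numeric", bandHigh = "numeric"))

setValidity("WamacSet", function(object) {
    msg <- character()
    n <- length(object@labels)
    if (n != 12L) msg <- c(msg, "exactly 12 coordinates required")
    if (length(object@wavelength) != n) msg <- c(msg, "one wavelength per label")
    if (any(diff(object@wavelength) <= 0))
        msg <- c(msg, "wavelengths must be strictly increasing")
    if (any(object@wavelength < 1300 | object@wavelength > 1600))
        msg <- c(msg, "coordinates must lie within 1300-1600 nm")
    if (any(object@bandLow > object@wavelength) ||
        any(object@bandHigh < object@wavelength))
        msg <- c(msg, "band ranges must contain the nominal wavelengths")
    if (length(msg)) msg else TRUE
})

#' Aquagram values
#'
#' Normalized absorbance values at the water matrix coordinates, one row per
#' display group (typically culture x fermentation time). Under the classic
#' normalization each coordinate is standardized across the displayed groups,
#' so every column has mean 0; a difference aquagram instead stores
#' deviations from a baseline group.
#'
#' @slot values matrix, groups x coordinates.
#' @slot groupInfo data.frame describing each row.
#' @slot wamacs [WamacSet-class] used.
#' @slot resolved numeric, grid wavelengths the coordinates resolved to.
#' @slot normalization character, `"classic"` or `"difference"`.
#' @seealso [computeAquagram()], [differenceAquagram()]
#' @export
setClass("AquagramValues", representation(
    values = "matrix", groupInfo = "data.frame",
    wamacs = "WamacSet", resolved = "numeric",
    normalization = "character"))

setValidity("AquagramValues", function(object) {
    msg <- character()
    if (ncol(object@values) != length(object@wamacs@labels))
        msg <- c(msg, "one value column per coordinate required")
    if (nrow(object@values) != nrow(object@groupInfo))
        msg <- c(msg, "one groupInfo row per value row required")
    if (object@normalization == "classic" &&
        nrow(object@values) > 1 &&
        max(abs(colMeans(object@values))) > 1e-10)
        msg <- c(msg, "classic normalization requires column means of 0")
    if (length(msg)) msg else TRUE
})
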