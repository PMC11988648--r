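#' Construct a SpectraSet
#'
#' Builds a [SpectraSet-class] from a scans-by-wavelengths absorbance matrix
#' and per-scan metadata. Rows of `absorbance` correspond to rows of `meta`;
#' columns correspond to `wavelengths`, which must be strictly increasing.
#'
#' @param absorbance numeric matrix, one row per scan, one column per
#'   wavelength (absorbance units).
#' @param wavelengths numeric vector of wavelengths in nm.
#' @param meta data.frame with columns `sample_id`, `culture`, `time_h`,
#'   `replicate`, `scan` (one row per scan).
#' @return A [SpectraSet-class].
#' @examples
#' s <- SpectraSet(matrix(runif(6), 2), c(1400, 1410, 1420),
#'                 data.frame(sample_id = c("a", "a"), culture = "BL",
#'                            time_h = 4, replicate = 1, scan = 1:2))
#' nScans(s)
#' @export
SpectraSet <- function(absorbance, wavelengths, meta) {
    absorbance <- as.matrix(absorbance)
    if (ncol(absorbance) != length(wavelengths))
        stop("absorbance must have one column per wavelength")
    if (nrow(absorbance) != nrow(meta))
        stop("absorbance must have one row per meta row")
    meta <- as.data.frame(meta)
    ord <- order(wavelengths)
    wavelengths <- wavelengths[ord]
    absorbance <- absorbance[, ord, drop = FALSE]
    a <- t(absorbance)
    dimnames(a) <- list(formatWl(wavelengths),
                        paste(meta$sample_id, meta$replicate, meta$scan,
                              sep = "."))
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(absorbance = a),
        rowData = S4Vectors::DataFrame(wavelength_nm = wavelengths),
        colData = S4Vectors::DataFrame(meta, row.names = colnames(a)))
    methods::new("SpectraSet", se)
}

#' Absorbance matrix of a SpectraSet
#'
#' @param x A [SpectraSet-class].
#' @return Numeric matrix, one row per scan and one column per wavelength
#'   (columns named by nm value).
#' @aliases absorbance
#' @export
setMethod("absorbance", "SpectraSet", function(x)
    t(SummarizedExperiment::assay(x, "absorbance")))

#' Wavelength grid of a SpectraSet
#'
#' @param x A [SpectraSet-class].
#' @return Numeric vector of wavelengths in nm, strictly increasing.
#' @aliases wavelengths
#' @export
setMethod("wavelengths", "SpectraSet", function(x)
    SummarizedExperiment::rowData(x)$wavelength_nm)

#' Per-scan metadata of a SpectraSet
#'
#' @param x A [SpectraSet-class].
#' @return data.frame with one row per scan (`sample_id`, `culture`,
#'   `time_h`, `replicate`, `scan`).
#' @aliases scanInfo
#' @export
setMethod("scanInfo", "SpectraSet", function(x) {
    df <- as.data.frame(SummarizedExperiment::colData(x))
    rownames(df) <- NULL
    df
})

#' Number of scans in a SpectraSet
#' @param x A [SpectraSet-class].
#' @return integer.
#' @aliases nScans
#' @export
setMethod("nScans", "SpectraSet", function(x) ncol(x))

#' Number of wavelengths in a SpectraSet
#' @param x A [SpectraSet-class].
#' @return integer.
#' @aliases nWavelengths
#' @export
setMethod("nWavelengths", "SpectraSet", function(x) nrow(x))

#' Explained-variance fractions of a PCA model
#' @param x A [PCAModel-class].
#' @return numeric vector of per-component variance fractions.
#' @aliases explainedVariance
#' @export
setMethod("explainedVariance", "PCAModel", function(x) x@varianceRatio)

#' @describeIn SpectraSet-class compact display
#' @param object a `SpectraSet`
#' @export
setMethod("show", "SpectraSet", function(object) {
    wl <- wavelengths(object)
    cat(sprintf("SpectraSet: %d scans x %d wavelengths (%.1f-%.1f nm)\n",
                ncol(object), nrow(object), min(wl), max(wl)))
    m <- scanInfo(object)
    cat(sprintf("  cultures: %s | times (h): %s | %d sample groups\n",
                paste(sort(unique(as.character(m$culture))), collapse = ", "),
                paste(sort(unique(m$time_h)), collapse = ", "),
                length(unique(m$sample_id))))
    steps <- S4Vectors::metadata(object)$pretreatments
    if (length(steps))
        cat("  pretreatments:", paste(steps, collapse = " -> "), "\n")
})

setMethod("show", "FermentationDesign", function(object) {
    cat(sprintf(paste0("FermentationDesign: %d culture(s) x %d time(s), ",
                       "%d replicate(s) x %d scan(s)\n"),
                length(object@cultures), length(object@times),
                object@nReplicates, object@nScans))
    cat(sprintf("  %d sample groups, %d scan rows%s\n",
                nrow(object@groups), nrow(object@scans),
                if (object@sharedBaseline) " (shared 0 h JUICE baseline)" else ""))
})

setMethod("show", "PCAModel", function(object) {
    vr <- object@varianceRatio
    cat(sprintf("PCAModel: %d components over %d wavelengths\n",
                ncol(object@loadings), length(object@wavelengths)))
    cat("  explained variance (%):",
        paste(sprintf("%.2f", 100 * utils::head(vr, 5)), collapse = ", "),
        if (length(vr) > 5) "...\n" else "\n")
})

setMethod("show", "ClassificationResult", function(object) {
    cat(sprintf("ClassificationResult: %d PCs, %d classes\n",
                object@nrpcs, nlevels(object@labels)))
    cat(sprintf("  calibration accuracy %.1f%% | cross-validation %.1f%%\n",
                object@trainAccuracy, object@cvAccuracy))
})

setMethod("show", "PLSModel", function(object) {
    m <- object@metrics
    cat(sprintf("PLSModel: %d latent variable(s), %d wavelengths\n",
                object@nrlv, length(object@wavelengths)))
    cat(sprintf("  R2C %.4f RMSEC %.4g", m$R2C, m$RMSEC))
    if (!is.null(m$R2CV))
        cat(sprintf(" | R2CV %.4f RMSECV %.4g", m$R2CV, m$RMSECV))
    cat("\n")
})

setMethod("show", "WamacSet", function(object) {
    cat("WamacSet:",
        paste(sprintf("%s=%g", object@labels, object@wavelength),
              collapse = " "), "\n")
})

setMethod("show", "AquagramValues", function(object) {
    cat(sprintf("AquagramValues (%s): %d group(s) x %d coordinates\n",
                object@normalization, nrow(object@values),
                ncol(object@values)))
})

#' Aquagram values as a data.frame
#' @param x An [AquagramValues-class].
#' @param row.names,optional,... passed for generic compatibility (unused).
#' @return data.frame: group metadata columns followed by the C1..C12 values.
#' @export
as.data.frame.AquagramValues <- function(x, row.names = NULL,
                                         optional = FALSE, ...) {
    cbind(x@groupInfo, as.data.frame(x@values))
}
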