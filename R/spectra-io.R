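SPECTRA_SCHEMA <- "aquaferm_spectra_v1"
REFERENCE_SCHEMA <- "aquaferm_reference_v1"

#' Write a SpectraSet to wide CSV
#'
#' One row per scan: the five metadata columns followed by one absorbance
#' column per wavelength, named by its nm value. A `#` comment line carries
#' the schema version. The file round-trips through [readSpectra()] within
#' float-to-text precision.
#'
#' @param x A [SpectraSet-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeSpectra <- function(x, path) {
    stopIfNot(methods::is(x, "SpectraSet"), "x must be a SpectraSet")
    df <- cbind(scanInfo(x)[REQUIRED_META],
                as.data.frame(absorbance(x), check.names = FALSE))
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste0("#", SPECTRA_SCHEMA), con)
    utils::write.csv(df, con, row.names = FALSE)
    invisible(path)
}

#' Read a SpectraSet from wide CSV
#'
#' Expects the schema written by [writeSpectra()]: metadata columns
#' `sample_id`, `culture`, `time_h`, `replicate`, `scan` plus numeric
#' wavelength-named absorbance columns. Wavelength columns are parsed
#' numerically and sorted; scan rows are canonicalized to
#' `(culture, time_h, replicate, scan)` order so grouped cross-validation
#' folds are reproducible across round trips.
#'
#' @param path CSV file path.
#' @return A [SpectraSet-class].
#' @export
readSpectra <- function(path) {
    df <- utils::read.csv(path, check.names = FALSE, comment.char = "#")
    miss <- setdiff(REQUIRED_META, colnames(df))
    if (length(miss))
        stop("missing metadata column(s): ", paste(miss, collapse = ", "),
             call. = FALSE)
    wlCols <- colnames(df)[!colnames(df) %in% REQUIRED_META]
    if (anyDuplicated(wlCols))
        stop("duplicated wavelength column(s): ",
             paste(unique(wlCols[duplicated(wlCols)]), collapse = ", "),
             call. = FALSE)
    wl <- suppressWarnings(as.numeric(wlCols))
    if (anyNA(wl))
        stop("non-numeric wavelength column header(s): ",
             paste(wlCols[is.na(wl)], collapse = ", "), call. = FALSE)
    mat <- as.matrix(df[wlCols])
    if (!is.numeric(mat)) stop("non-numeric absorbance values", call. = FALSE)
    canonicalize(SpectraSet(mat, wl, df[REQUIRED_META]))
}

#' Write / read a reference table (long CSV)
#'
#' The reference table holds per biological replicate the measured pH and
#' log10 CFU/mL (`sample_id`, `culture`, `time_h`, `replicate`, `pH`,
#' `logcfu`).
#'
#' @param ref data.frame as returned by [simulateReference()].
#' @param path CSV file path.
#' @return `path` (write) or the validated data.frame (read).
#' @export
writeReferenceTable <- function(ref, path) {
    need <- c("sample_id", "culture", "time_h", "replicate", "pH", "logcfu")
    stopIfNot(all(need %in% colnames(ref)), "reference table lacks columns")
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste0("#", REFERENCE_SCHEMA), con)
    utils::write.csv(ref[need], con, row.names = FALSE)
    invisible(path)
}

#' @rdname writeReferenceTable
#' @export
readReferenceTable <- function(path) {
    df <- utils::read.csv(path, comment.char = "#")
    need <- c("sample_id", "culture", "time_h", "replicate", "pH", "logcfu")
    miss <- setdiff(need, colnames(df))
    if (length(miss))
        stop("missing reference column(s): ", paste(miss, collapse = ", "),
             call. = FALSE)
    key <- paste(df$culture, df$time_h, df$replicate)
    if (anyDuplicated(key))
        stop("duplicate (culture, time_h, replicate) rows", call. = FALSE)
    df
}

#' Subset a SpectraSet by metadata and wavelength range
#'
#' Row filters select scans by culture and/or fermentation time; `range`
#' slices the wavelength axis (closed interval). When filtering by fermented
#' culture, the shared unfermented `JUICE` baseline group is included by
#' default so per-strain subsets retain their 0 h class (the default design
#' then yields 45 rows per strain). Scan order within a replicate is never
#' changed, and independent filters commute.
#'
#' @param x A [SpectraSet-class].
#' @param culture optional character, culture code(s) to keep.
#' @param times optional numeric, fermentation times to keep.
#' @param range optional numeric length-2 wavelength window (nm).
#' @param includeBaseline logical, add the shared `JUICE` group when
#'   filtering by culture (default `TRUE`).
#' @return A [SpectraSet-class]; error if the selection is empty.
#' @examples
#' p <- simParams(); d <- simulateDesign()
#' s <- simulateSpectra(d, simulateReference(d, p), p)
#' nScans(subsetSpectra(s, culture = "BL"))  # 45
#' @export
subsetSpectra <- function(x, culture = NULL, times = NULL, range = NULL,
                          includeBaseline = TRUE) {
    stopIfNot(methods::is(x, "SpectraSet"), "x must be a SpectraSet")
    m <- scanInfo(x)
    keep <- rep(TRUE, nrow(m))
    if (!is.null(culture)) {
        want <- as.character(culture)
        unknown <- setdiff(want, unique(as.character(m$culture)))
        if (length(unknown))
            stop("unknown culture(s): ", paste(unknown, collapse = ", "),
                 call. = FALSE)
        if (includeBaseline && "JUICE" %in% m$culture &&
            !all(want == "JUICE"))
            want <- union(want, "JUICE")
        keep <- keep & m$culture %in% want
    }
    if (!is.null(times)) keep <- keep & m$time_h %in% times
    cols <- NULL
    if (!is.null(range)) {
        stopIfNot(length(range) == 2 && range[1] < range[2],
                  "range must be (low, high) with low < high")
        wl <- wavelengths(x)
        cols <- which(wl >= range[1] & wl <= range[2])
        if (!length(cols))
            stop("wavelength range does not overlap the grid", call. = FALSE)
    }
    if (!any(keep)) stop("empty selection", call. = FALSE)
    out <- if (is.null(cols)) x[, keep] else x[cols, keep]
    methods::validObject(out)
    out
}
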