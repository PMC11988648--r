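# internal helpers shared across modules

# wavelength column labels: plain decimal, no trailing zeros
formatWl <- function(wl) {
    sub("\\.?0+$", "", formatC(wl, format = "f", digits = 6))
}

# canonical scan order (culture, time_h, replicate, scan); JUICE sorts first
# through time_h = 0. Returns a permutation of seq_len(nrow(meta)).
canonicalOrder <- function(meta) {
    order(as.character(meta$culture), meta$time_h, meta$replicate, meta$scan)
}

# reorder a SpectraSet's scans into canonical order
canonicalize <- function(x) {
    ord <- canonicalOrder(scanInfo(x))
    x[, ord]
}

# replace the absorbance matrix (scans x wavelengths) of a SpectraSet,
# recording the pretreatment step; optionally slicing the wavelength axis
replaceAbsorbance <- function(x, mat, step = NULL, keepCols = NULL) {
    if (!is.null(keepCols)) x <- x[keepCols, ]
    stopifnot(nrow(mat) == ncol(x), ncol(mat) == nrow(x))
    SummarizedExperiment::assay(x, "absorbance", withDimnames = FALSE) <-
        t(mat)
    if (!is.null(step))
        S4Vectors::metadata(x)$pretreatments <-
            c(S4Vectors::metadata(x)$pretreatments, step)
    methods::validObject(x)
    x
}

# per-row key identifying a (sample_id, replicate) measurement block
blockKey <- function(meta) paste(meta$sample_id, meta$replicate, sep = ":")

# key for arbitrary metadata column combinations
groupKey <- function(meta, keys) {
    do.call(paste, c(lapply(keys, function(k) meta[[k]]), sep = "_"))
}

stopIfNot <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)
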