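#' Principal component analysis of a spectra set
#'
#' Column-mean-centered PCA via singular value decomposition
#' (`stats::prcomp`). Scores are the centered data projected on the
#' loadings; explained-variance ratios are per-component fractions of the
#' total variance. A deterministic sign convention is applied: the
#' largest-magnitude element of every loading vector is positive, so
#' repeated fits are bit-identical.
#'
#' @param x A [SpectraSet-class] (or bare matrix, scans x wavelengths).
#' @param maxPcs number of components to retain; at most
#'   `min(nScans - 1, nWavelengths)`.
#' @return A [PCAModel-class].
#' @examples
#' p <- simParams(); d <- simulateDesign()
#' s <- simulateSpectra(d, simulateReference(d, p), p)
#' m <- fitPCA(s, 5)
#' round(100 * cumsum(explainedVariance(m)), 2)
#' @export
fitPCA <- function(x, maxPcs) {
    A <- if (methods::is(x, "SpectraSet")) absorbance(x) else as.matrix(x)
    wl <- if (methods::is(x, "SpectraSet")) wavelengths(x)
          else as.numeric(colnames(A) %||% seq_len(ncol(A)))
    stopIfNot(nrow(A) >= 2, "PCA needs at least 2 spectra")
    cap <- min(nrow(A) - 1L, ncol(A))
    if (maxPcs > cap)
        stop("maxPcs exceeds min(n_rows - 1, n_wavelengths) = ", cap,
             call. = FALSE)
    pc <- stats::prcomp(A, center = TRUE, scale. = FALSE, rank. = maxPcs)
    L <- pc$rotation
    S <- pc$x
    for (j in seq_len(ncol(L))) {          # sign convention
        i <- which.max(abs(L[, j]))
        if (L[i, j] < 0) { L[, j] <- -L[, j]; S[, j] <- -S[, j] }
    }
    vr <- pc$sdev^2 / sum(pc$sdev^2)
    methods::new("PCAModel", center = pc$center,
                 loadings = unname(L), scores = unname(S),
                 varianceRatio = vr[seq_len(ncol(L))], wavelengths = wl)
}

# project new spectra (rows x wavelengths) into a PCAModel's space
projectPCA <- function(model, A) {
    sweep(A, 2, model@center) %*% model@loadings
}

#' Influential wavelengths of a PCA loading
#'
#' Returns the wavelengths of the `k` largest absolute loading values of one
#' component, augmented with every local maximum of the absolute loading
#' curve above `localFrac` of its global maximum, sorted by loading
#' magnitude (duplicates removed).
#'
#' @param model A [PCAModel-class].
#' @param pc component index.
#' @param k number of top-magnitude wavelengths.
#' @param localFrac fraction of the global |loading| maximum above which
#'   local maxima are also reported (default 0.5).
#' @return numeric vector of wavelengths (nm), magnitude-sorted.
#' @export
topLoadingWavelengths <- function(model, pc, k, localFrac = 0.5) {
    stopIfNot(pc >= 1 && pc <= ncol(model@loadings), "pc out of range")
    stopIfNot(k >= 1, "k must be >= 1")
    v <- abs(model@loadings[, pc])
    if (k > length(v))
        stop("k exceeds the number of wavelengths", call. = FALSE)
    topIdx <- order(v, decreasing = TRUE)[seq_len(k)]
    n <- length(v)
    isLocalMax <- v >= c(-Inf, v[-n]) & v >= c(v[-1], -Inf) &
        v > localFrac * max(v) & v > 0
    idx <- union(topIdx, which(isLocalMax))
    idx <- idx[order(v[idx], decreasing = TRUE)]
    model@wavelengths[idx]
}
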