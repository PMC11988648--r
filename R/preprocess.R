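#' Crop a SpectraSet to a wavelength window
#'
#' Retains the wavelength columns with `low <= lambda <= high` (closed
#' interval). Idempotent: cropping an already-cropped set to the same window
#' is the identity.
#'
#' @param x A [SpectraSet-class].
#' @param range numeric length-2, `(low, high)` in nm.
#' @return A [SpectraSet-class].
#' @export
cropSpectra <- function(x, range = c(1300, 1600)) {
    subsetSpectra(x, range = range)
}

.checkWindow <- function(window, polyorder, n) {
    stopIfNot(length(window) == 1 && window == round(window) && window > 0,
              "window must be a positive integer")
    if (window %% 2 == 0) stop("window must be odd", call. = FALSE)
    if (window <= polyorder)
        stop("window must exceed the polynomial order", call. = FALSE)
    if (window > n)
        stop("window larger than the number of wavelengths", call. = FALSE)
}

#' Savitzky-Golay smoothing
#'
#' Replaces each spectrum by its moving local-polynomial least-squares fit.
#' Boundary points use the polynomial fits of the terminal windows
#' (fit extrapolation), so the output grid equals the input grid. A spectrum
#' that is exactly a polynomial of degree `polyorder` or less is reproduced
#' to machine precision.
#'
#' @param x A [SpectraSet-class].
#' @param window odd integer window length (points); figure presets in this
#'   field typically use 21, 35 or 43 points.
#' @param polyorder polynomial order of the local fit (default 2).
#' @return A [SpectraSet-class].
#' @export
savgolSmooth <- function(x, window, polyorder = 2) {
    .checkWindow(window, polyorder, nWavelengths(x))
    A <- absorbance(x)
    sm <- t(apply(A, 1, signal::sgolayfilt, p = polyorder, n = window))
    replaceAbsorbance(x, sm, sprintf("savgol(%d,%d)", window, polyorder))
}

#' Savitzky-Golay derivative
#'
#' First or second derivative of each spectrum via a Savitzky-Golay
#' differentiation filter, scaled by the wavelength step so units are per nm
#' (per nm^2 for the second order). The first derivative removes constant
#' offsets; the second also removes linear baselines.
#'
#' @param x A [SpectraSet-class].
#' @param order derivative order, 1 or 2.
#' @param window odd integer window length (points).
#' @param polyorder polynomial order (default 2; must be >= `order`).
#' @return A [SpectraSet-class].
#' @export
spectralDerivative <- function(x, order, window, polyorder = 2) {
    stopIfNot(order %in% 1:2, "derivative order must be 1 or 2")
    stopIfNot(polyorder >= order, "polyorder must be >= derivative order")
    .checkWindow(window, polyorder, nWavelengths(x))
    wl <- wavelengths(x)
    step <- diff(wl)
    stopIfNot(max(abs(step - step[1])) < 1e-9,
              "derivative requires an even wavelength grid")
    A <- absorbance(x)
    d <- t(apply(A, 1, signal::sgolayfilt, p = polyorder, n = window,
                 m = order, ts = step[1]))
    replaceAbsorbance(x, d, sprintf("derivative(%d,%d,%d)",
                                    order, window, polyorder))
}

#' Polynomial detrending
#'
#' Subtracts from each spectrum its own least-squares polynomial of the
#' wavelength (default degree 2), eliminating polynomial baseline
#' tendencies. A spectrum that is exactly such a polynomial maps to zero.
#'
#' @param x A [SpectraSet-class].
#' @param degree polynomial degree, `0 <=  degree < nWavelengths(x)`.
#' @return A [SpectraSet-class].
#' @export
detrendSpectra <- function(x, degree = 2) {
    stopIfNot(degree >= 0 && degree < nWavelengths(x),
              "degree must be in [0, nWavelengths)")
    wl <- wavelengths(x)
    z <- (wl - mean(wl)) / max(1, diff(range(wl)) / 2)  # conditioning
    V <- cbind(rep(1, length(wl)))
    if (degree > 0)
        V <- cbind(V, stats::poly(z, degree = degree, raw = FALSE,
                                  simple = TRUE))
    Q <- qr.Q(qr(V))
    A <- absorbance(x)
    res <- A - (A %*% Q) %*% t(Q)
    replaceAbsorbance(x, res, sprintf("detrend(%d)", degree))
}

#' Standard normal variate (SNV)
#'
#' Standardizes each spectrum to mean 0 and standard deviation 1 (n-1
#' denominator), removing per-spectrum offset and scale. Affine transforms
#' `a*x + b` (a > 0) of a spectrum map to the same output.
#'
#' @param x A [SpectraSet-class].
#' @return A [SpectraSet-class]; error naming the scan row if a spectrum is
#'   constant.
#' @export
snvCorrect <- function(x) {
    A <- absorbance(x)
    mu <- rowMeans(A)
    sd <- apply(A, 1, stats::sd)
    bad <- which(sd == 0)
    if (length(bad))
        stop("constant (degenerate) spectrum in scan row(s): ",
             paste(bad, collapse = ", "), call. = FALSE)
    replaceAbsorbance(x, (A - mu) / sd, "snv")
}

#' Multiplicative scatter correction (MSC)
#'
#' Regresses each spectrum on a reference spectrum, `x ~ a + b * ref`, and
#' returns `(x - a) / b`, reducing multiplicative scatter and baseline
#' shifts. The default reference is the mean spectrum of the set.
#'
#' @param x A [SpectraSet-class].
#' @param reference optional numeric reference spectrum (defaults to the set
#'   mean; the set must then contain at least 2 spectra).
#' @return A [SpectraSet-class]; error if a spectrum is orthogonal to the
#'   reference (fitted slope 0) or the reference is constant.
#' @export
mscCorrect <- function(x, reference = NULL) {
    A <- absorbance(x)
    if (is.null(reference)) {
        stopIfNot(nrow(A) >= 2, "MSC needs >= 2 spectra or a reference")
        reference <- colMeans(A)
    }
    stopIfNot(length(reference) == ncol(A),
              "reference length must match the wavelength grid")
    rc <- reference - mean(reference)
    denom <- sum(rc^2)
    if (denom == 0) stop("constant reference spectrum", call. = FALSE)
    b <- as.vector((A %*% rc)) / denom
    a <- rowMeans(A) - b * mean(reference)
    if (any(abs(b) < 1e-12))
        stop("spectrum orthogonal to the MSC reference in row(s): ",
             paste(which(abs(b) < 1e-12), collapse = ", "), call. = FALSE)
    replaceAbsorbance(x, (A - a) / b, "msc")
}

#' Average spectra by metadata keys
#'
#' Arithmetic mean spectrum per combination of the given metadata keys
#' (e.g. `c("culture", "time_h")`). Replicate and scan identity is lost:
#' the collapsed rows carry `replicate = 0`, `scan = 0` and a `sample_id`
#' built from the key values; non-key metadata that is constant within a
#' group is retained, otherwise set to `NA`.
#'
#' @param x A [SpectraSet-class].
#' @param keys non-empty character vector of metadata column names.
#' @return A [SpectraSet-class] with one row per key combination.
#' @examples
#' p <- simParams(); d <- simulateDesign()
#' s <- simulateSpectra(d, simulateReference(d, p), p)
#' ferm <- subsetSpectra(s, times = c(4, 8, 16, 24))
#' nScans(averageBy(ferm, c("culture", "time_h")))  # 12
#' @export
averageBy <- function(x, keys) {
    stopIfNot(is.character(keys) && length(keys) >= 1, "keys required")
    m <- scanInfo(x)
    stopIfNot(all(keys %in% colnames(m)), "unknown metadata key(s)")
    key <- groupKey(m, keys)
    ukey <- unique(key)
    A <- absorbance(x)
    avg <- t(vapply(ukey, function(k)
        colMeans(A[key == k, , drop = FALSE]), numeric(ncol(A))))
    meta <- data.frame(sample_id = ukey)
    for (col in c("culture", "time_h")) {
        vals <- tapply(m[[col]], key, function(v)
            if (length(unique(v)) == 1) v[1] else NA)
        meta[[col]] <- unname(vals[ukey])
    }
    meta$replicate <- 0L
    meta$scan <- 0L
    out <- SpectraSet(avg, wavelengths(x), meta)
    S4Vectors::metadata(out) <- S4Vectors::metadata(x)
    S4Vectors::metadata(out)$pretreatments <-
        c(S4Vectors::metadata(x)$pretreatments,
          sprintf("average_by(%s)", paste(keys, collapse = ",")))
    out
}

#' Difference spectra against the 0 h baseline
#'
#' Averages the spectra per `(culture, time_h)` and subtracts, for each
#' culture separately, the averaged baseline-time spectrum from the
#' later-time averages. A culture without its own baseline group uses the
#' shared unfermented `JUICE` baseline.
#'
#' @param x A [SpectraSet-class].
#' @param baselineTime fermentation time of the baseline group (default 0).
#' @return A [SpectraSet-class] of per-culture averaged difference spectra
#'   (baseline rows excluded).
#' @export
differenceSpectra <- function(x, baselineTime = 0) {
    avg <- averageBy(x, c("culture", "time_h"))
    m <- scanInfo(avg)
    A <- absorbance(avg)
    isBase <- m$time_h == baselineTime
    if (!any(isBase)) stop("missing baseline time group", call. = FALSE)
    sharedBase <- if (any(isBase & m$culture == "JUICE"))
        A[which(isBase & m$culture == "JUICE")[1], ] else NULL
    keep <- which(!isBase)
    if (!length(keep))
        stop("no non-baseline groups to difference", call. = FALSE)
    D <- matrix(0, length(keep), ncol(A))
    for (j in seq_along(keep)) {
        i <- keep[j]
        own <- which(isBase & m$culture == m$culture[i])
        base <- if (length(own)) A[own[1], ] else sharedBase
        if (is.null(base))
            stop("no baseline group for culture ", m$culture[i],
                 call. = FALSE)
        D[j, ] <- A[i, ] - base
    }
    out <- SpectraSet(D, wavelengths(avg), m[keep, , drop = FALSE])
    S4Vectors::metadata(out)$pretreatments <-
        c(S4Vectors::metadata(avg)$pretreatments,
          sprintf("difference(baseline=%gh)", baselineTime))
    out
}

#' Pretreatment specifications
#'
#' A pretreatment spec is an ordered list of steps, each a list with a
#' `step` name and its parameters, drawn from `crop(range)`,
#' `savgol(window, polyorder)`, `detrend(degree)`, `msc`, `snv`,
#' `derivative(order, window, polyorder)` and `average_by(keys)`.
#' `pretreatmentSpec()` validates the list (window constraints; `msc` and
#' `snv` are mutually alternative scatter corrections and cannot both
#' appear); [applyPretreatment()] applies the steps in order.
#'
#' @param steps list of step lists, e.g.
#'   `list(list(step = "savgol", window = 43), list(step = "detrend"))`.
#' @return Validated spec (class `pretreatment_spec`).
#' @export
pretreatmentSpec <- function(steps = list()) {
    known <- c("crop", "savgol", "detrend", "msc", "snv", "derivative",
               "average_by")
    nm <- vapply(steps, function(s) s$step %||% "", "")
    bad <- setdiff(nm, known)
    if (length(bad))
        stop("unknown pretreatment step(s): ", paste(bad, collapse = ", "),
             call. = FALSE)
    if (sum(nm %in% c("msc", "snv")) > 1)
        stop("at most one of msc/snv may appear", call. = FALSE)
    for (s in steps) {
        if (s$step %in% c("savgol", "derivative")) {
            w <- s$window; p <- s$polyorder %||% 2
            stopIfNot(!is.null(w) && w %% 2 == 1 && w > p,
                      "window must be odd and exceed the polynomial order")
        }
        if (s$step == "derivative")
            stopIfNot((s$order %||% 0) %in% 1:2,
                      "derivative order must be 1 or 2")
    }
    structure(steps, class = "pretreatment_spec")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Apply a pretreatment spec
#'
#' @param x A [SpectraSet-class].
#' @param spec a [pretreatmentSpec()] (or bare list of steps).
#' @return The pretreated [SpectraSet-class].
#' @export
applyPretreatment <- function(x, spec) {
    if (!inherits(spec, "pretreatment_spec"))
        spec <- pretreatmentSpec(spec)
    for (s in spec) {
        x <- switch(s$step,
            crop = cropSpectra(x, s$range %||% c(1300, 1600)),
            savgol = savgolSmooth(x, s$window, s$polyorder %||% 2),
            detrend = detrendSpectra(x, s$degree %||% 2),
            msc = mscCorrect(x),
            snv = snvCorrect(x),
            derivative = spectralDerivative(x, s$order, s$window,
                                            s$polyorder %||% 2),
            average_by = averageBy(x, s$keys))
    }
    x
}
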