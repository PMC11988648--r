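#' Water matrix coordinate registry
#'
#' Returns the twelve water matrix coordinates (WAMACs) of the first
#' overtone region of water used as aquagram axes, labelled `C1`..`C12`.
#' The default nominal wavelengths are 1342, 1364, 1374, 1384, 1412, 1426,
#' 1440, 1452, 1462, 1476, 1488 and 1512 nm, each with a conventional band
#' range; the registry is fully overridable since different instruments and
#' conventions shift the coordinates by a few nm.
#'
#' @param wavelength optional numeric length-12 override of the nominal
#'   wavelengths (strictly increasing, inside 1300-1600 nm).
#' @param bandLow,bandHigh optional length-12 band limits; default is
#'   +-6 nm around each nominal wavelength.
#' @return A [WamacSet-class].
#' @examples
#' wamacCoordinates()
#' @export
wamacCoordinates <- function(wavelength = NULL, bandLow = NULL,
                             bandHigh = NULL) {
    nominal <- c(1342, 1364, 1374, 1384, 1412, 1426,
                 1440, 1452, 1462, 1476, 1488, 1512)
    if (is.null(wavelength)) wavelength <- nominal
    if (length(wavelength) != 12L)
        stop("exactly 12 coordinates required", call. = FALSE)
    if (is.null(bandLow)) bandLow <- wavelength - 6
    if (is.null(bandHigh)) bandHigh <- wavelength + 6
    methods::new("WamacSet", labels = paste0("C", 1:12),
                 wavelength = as.numeric(wavelength),
                 bandLow = as.numeric(bandLow),
                 bandHigh = as.numeric(bandHigh))
}

# resolve coordinates on a wavelength grid: nearest grid point (or the
# band-mean column set when bandMean = TRUE)
.resolveWamacs <- function(wamacs, wl, bandMean = FALSE) {
    span <- range(wl)
    out <- lapply(seq_along(wamacs@wavelength), function(i) {
        wc <- wamacs@wavelength[i]
        if (wc < span[1] - 1e-9 || wc > span[2] + 1e-9)
            stop("coordinate ", wamacs@labels[i], " (", wc,
                 " nm) outside the wavelength grid", call. = FALSE)
        if (bandMean) {
            idx <- which(wl >= wamacs@bandLow[i] & wl <= wamacs@bandHigh[i])
            if (!length(idx)) idx <- which.min(abs(wl - wc))
            idx
        } else which.min(abs(wl - wc))
    })
    out
}

#' Compute an aquagram
#'
#' Classic normalized aquagram: (1) apply the pretreatment (default
#' Savitzky-Golay smoothing, 21 points, then SNV), (2) average the spectra
#' per display group (default `culture` x `time_h`), (3) at each water
#' matrix coordinate standardize the group values across the displayed
#' groups, `(A_g - mu) / sigma`. Each coordinate therefore has mean 0
#' across the groups of one aquagram. Coordinates resolve to the nearest
#' grid wavelength (or to the band mean with `bandMean = TRUE`).
#'
#' @param x A [SpectraSet-class] (raw; pretreatment is applied here).
#' @param wamacs A [WamacSet-class] (default [wamacCoordinates()]).
#' @param pretreatment a [pretreatmentSpec()] or bare step list; `NULL`
#'   skips pretreatment.
#' @param groupBy metadata keys defining the display groups.
#' @param bandMean average over the coordinate's band range instead of the
#'   single nearest wavelength.
#' @return An [AquagramValues-class].
#' @export
computeAquagram <- function(x, wamacs = wamacCoordinates(),
                            pretreatment = list(
                                list(step = "savgol", window = 21),
                                list(step = "snv")),
                            groupBy = c("culture", "time_h"),
                            bandMean = FALSE) {
    stopIfNot(methods::is(wamacs, "WamacSet"), "wamacs must be a WamacSet")
    if (!is.null(pretreatment)) x <- applyPretreatment(x, pretreatment)
    avg <- averageBy(x, groupBy)
    stopIfNot(nScans(avg) >= 2, "aquagram needs >= 2 display groups")
    A <- absorbance(avg)
    wl <- wavelengths(avg)
    idx <- .resolveWamacs(wamacs, wl, bandMean)
    vals <- vapply(idx, function(i) rowMeans(A[, i, drop = FALSE]),
                   numeric(nrow(A)))
    sds <- apply(vals, 2, stats::sd)
    if (any(sds == 0))
        stop("zero variance across groups at coordinate(s): ",
             paste(wamacs@labels[sds == 0], collapse = ", "), call. = FALSE)
    norm <- scale(vals, center = TRUE, scale = sds)
    dimnames(norm) <- list(scanInfo(avg)$sample_id, wamacs@labels)
    gi <- scanInfo(avg)[c("sample_id", intersect(groupBy,
                                                 c("culture", "time_h")))]
    methods::new("AquagramValues", values = unclass(norm)[, , drop = FALSE],
                 groupInfo = gi, wamacs = wamacs,
                 resolved = vapply(idx, function(i) mean(wl[i]), 1),
                 normalization = "classic")
}

#' Difference aquagram
#'
#' Subtracts the baseline group's coordinate values from every group; the
#' baseline maps to the zero vector. This is the radar-plot form used to
#' display spectral change relative to the start of fermentation.
#'
#' @param values An [AquagramValues-class].
#' @param baselineGroup `sample_id` of the baseline group (a row name of
#'   `values`), e.g. `"JUICE_0h"`.
#' @return An [AquagramValues-class] with `normalization = "difference"`.
#' @export
differenceAquagram <- function(values, baselineGroup) {
    stopIfNot(methods::is(values, "AquagramValues"),
              "values must be AquagramValues")
    i <- match(baselineGroup, values@groupInfo$sample_id)
    if (is.na(i))
        stop("baseline group not present: ", baselineGroup, call. = FALSE)
    v <- sweep(values@values, 2, values@values[i, ])
    methods::initialize(values, values = v, normalization = "difference")
}

#' Export aquagram values (CSV and optional radar plot)
#'
#' Writes a deterministic CSV of group metadata plus the 12 coordinate
#' values (axis order C1..C12), and optionally renders a radar plot with
#' the coordinates arranged clockwise from the top.
#'
#' @param values An [AquagramValues-class].
#' @param path CSV output path.
#' @param plotPath optional PNG output path for the radar plot.
#' @return `path`, invisibly.
#' @export
exportRadar <- function(values, path, plotPath = NULL) {
    stopIfNot(methods::is(values, "AquagramValues"),
              "values must be AquagramValues")
    if (nrow(values@values) == 0) stop("empty aquagram values", call. = FALSE)
    utils::write.csv(as.data.frame(values), path, row.names = FALSE)
    if (!is.null(plotPath)) {
        grDevices::png(plotPath, width = 720, height = 720)
        on.exit(grDevices::dev.off())
        .radarPlot(values)
    }
    invisible(path)
}

.radarPlot <- function(values) {
    v <- values@values
    k <- ncol(v)
    ang <- pi / 2 - 2 * pi * (seq_len(k) - 1) / k   # clockwise from top
    lim <- max(abs(v)) * 1.15 + 1e-9
    graphics::plot(NA, xlim = c(-lim, lim), ylim = c(-lim, lim), asp = 1,
                   axes = FALSE, xlab = "", ylab = "",
                   main = sprintf("Aquagram (%s)", values@normalization))
    for (r in pretty(c(0, lim), 4)[-1])
        graphics::polygon(r * cos(ang), r * sin(ang), border = "grey80")
    graphics::text(1.08 * lim * cos(ang), 1.08 * lim * sin(ang),
                   sprintf("%s\n%g", values@wamacs@labels,
                           values@wamacs@wavelength), cex = 0.8)
    cols <- grDevices::hcl.colors(nrow(v), "Dark 3")
    for (g in seq_len(nrow(v))) {
        r <- v[g, ] - min(0, min(v))      # shift so radii are non-negative
        graphics::polygon(r * cos(ang), r * sin(ang), border = cols[g],
                          lwd = 2)
    }
    graphics::legend("topleft", legend = rownames(v), col = cols, lwd = 2,
                     bty = "n", cex = 0.8)
}
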