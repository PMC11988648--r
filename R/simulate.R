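#' Enumerate a fermentation experiment design
#'
#' Builds the sample-group and scan-row tables for a fermentation-monitoring
#' experiment in which several starter cultures are sampled at fixed
#' fermentation times, in replicates, with consecutive instrument scans per
#' replicate. With `sharedBaseline = TRUE` the unfermented 0 h juice is a
#' single sample group (culture code `"JUICE"`) shared by all cultures. The
#' defaults reproduce the canonical design: 3 cultures x 4 fermented times
#' + 1 shared baseline = 13 sample groups, and 13 x 3 replicates x 3 scans =
#' 117 scan rows.
#'
#' @param cultures character vector of fermented culture codes.
#' @param times numeric sampling times in hours (must include 0 when
#'   `sharedBaseline`).
#' @param nReplicates,nScans integer counts per sample group / replicate.
#' @param sharedBaseline logical; share one unfermented 0 h group across
#'   cultures.
#' @return A [FermentationDesign-class].
#' @examples
#' d <- simulateDesign()
#' nrow(d@scans)  # 117
#' @export
simulateDesign <- function(cultures = c("BL", "LS", "MC"),
                           times = c(0, 4, 8, 16, 24),
                           nReplicates = 3L, nScans = 3L,
                           sharedBaseline = TRUE) {
    stopIfNot(length(cultures) >= 1L, "at least one culture required")
    stopIfNot(length(times) >= 1L, "at least one sampling time required")
    stopIfNot(!anyDuplicated(times), "duplicate sampling times")
    stopIfNot(!anyDuplicated(cultures), "duplicate cultures")
    stopIfNot(nReplicates >= 1L && nScans >= 1L,
              "replicate and scan counts must be >= 1")
    times <- sort(times)
    if (sharedBaseline)
        stopIfNot(0 %in% times,
                  "sharedBaseline requires a 0 h sampling time")

    groups <- expand.grid(time_h = times, culture = cultures,
                          KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    if (sharedBaseline) {
        groups <- groups[groups$time_h != 0, , drop = FALSE]
        groups <- rbind(data.frame(time_h = 0, culture = "JUICE"), groups)
    }
    groups <- groups[order(groups$culture != "JUICE", groups$culture,
                           groups$time_h), , drop = FALSE]
    groups$sample_id <- paste0(groups$culture, "_",
                               formatC(groups$time_h, format = "g"), "h")
    rownames(groups) <- NULL
    groups <- groups[, c("sample_id", "culture", "time_h")]

    scans <- groups[rep(seq_len(nrow(groups)),
                        each = nReplicates * nScans), , drop = FALSE]
    scans$replicate <- rep(rep(seq_len(nReplicates), each = nScans),
                           times = nrow(groups))
    scans$scan <- rep(seq_len(nScans), times = nrow(groups) * nReplicates)
    rownames(scans) <- NULL

    methods::new("FermentationDesign", cultures = as.character(cultures),
                 times = as.numeric(times),
                 nReplicates = as.integer(nReplicates),
                 nScans = as.integer(nScans),
                 sharedBaseline = isTRUE(sharedBaseline),
                 groups = groups, scans = scans)
}

#' Default simulation parameters
#'
#' Assembles a [SimParams-class] object whose defaults emulate 24 h probiotic
#' fermentation of a blended fruit juice measured in NIR transmission over
#' 1300-1600 nm:
#' \itemize{
#'   \item pH decays exponentially from 6.5 towards 4.0,
#'     \eqn{pH(t) = pH_{end} + (pH_0 - pH_{end}) e^{-k t}}, with a slower
#'     rate for `LS` so its pH keeps falling between 16 and 24 h while `BL`
#'     and `MC` are near-stationary after 16 h.
#'   \item log10 CFU/mL starts at 7.0 for every culture; `BL` rises
#'     logistically into a stationary phase near 9.0, `LS` rises to
#'     log10(2e9) at exactly 8 h and then declines linearly, `MC` shows a
#'     lag, a logistic rise to 9.2 at 16 h and a decline afterwards.
#'   \item absorbance is a smooth juice/water baseline plus 12 Gaussian
#'     water bands at the WAMAC centers whose amplitudes are affine in
#'     (pH, log10 CFU): acidification increases the bands up to 1452 nm
#'     (strongest at 1412-1440 nm) and decreases those above 1462 nm.
#'   \item turbidity adds a multiplicative slope/offset term growing with
#'     log10 CFU; replicate noise (biological) exceeds scan noise
#'     (instrumental).
#' }
#'
#' @param wavelengthStart,wavelengthEnd,wavelengthStep grid in nm
#'   (defaults 1300, 1600, 0.5: 601 points).
#' @param phStart initial pH.
#' @param phEnd,kPh named per-culture asymptotic pH and decay rate (1/h).
#' @param growth named list of per-culture growth parameters; see Details.
#' @param bands data.frame (`label`, `center`, `sigma`, `alpha`, `betaPh`,
#'   `gammaCfu`): Gaussian center/width (nm), baseline amplitude, and the
#'   amplitude sensitivities per unit of acidification (`phStart - pH`) and
#'   of `log10 CFU - 7`.
#' @param baseline list(`offset`, `amp`, `center`, `width`): smooth baseline
#'   `offset + amp * exp(-((lambda - center) / width)^2 / 2)`.
#' @param scatter list(`slopePerLog`, `offsetPerLog`, `scanSlopeSd`,
#'   `scanOffsetSd`): deterministic tilt per unit `log10 CFU - 7` and random
#'   per-scan tilt jitter.
#' @param noise list(`phSd`, `logcfuSd`, `replicateOffsetSd`, `scanSd`):
#'   replicate-level reference noise and absorbance offsets, and per-scan
#'   white noise (absorbance units).
#' @param seed integer RNG seed.
#' @return A [SimParams-class].
#' @export
simParams <- function(wavelengthStart = 1300, wavelengthEnd = 1600,
                      wavelengthStep = 0.5,
                      phStart = 6.5,
                      phEnd = c(BL = 4.0, LS = 4.0, MC = 4.0),
                      kPh = c(BL = 0.20, LS = 0.12, MC = 0.20),
                      growth = defaultGrowthParams(),
                      bands = defaultBandTable(),
                      baseline = list(offset = 0.15, amp = 0.5,
                                      center = 1445, width = 55),
                      scatter = list(slopePerLog = 0.004,
                                     offsetPerLog = 0.010,
                                     scanSlopeSd = 0.002,
                                     scanOffsetSd = 0.002),
                      noise = list(phSd = 0.010, logcfuSd = 0.05,
                                   replicateOffsetSd = 0.002,
                                   scanSd = 0.001),
                      seed = 20250405L) {
    methods::new("SimParams",
                 wavelengthStart = wavelengthStart,
                 wavelengthEnd = wavelengthEnd,
                 wavelengthStep = wavelengthStep,
                 phStart = phStart, phEnd = phEnd, kPh = kPh,
                 growth = growth, bands = bands, baseline = baseline,
                 scatter = scatter, noise = noise, seed = as.integer(seed))
}

#' @rdname simParams
#' @export
defaultGrowthParams <- function() {
    list(
        BL = list(model = "logistic", l0 = 7, lmax = 9.0,
                  rate = 0.5, tmid = 8),
        LS = list(model = "peak_decline", l0 = 7, peak = log10(2e9),
                  tpeak = 8, rate = 0.8, tmid = 4, declineRate = 0.15),
        MC = list(model = "lag_log_decline", l0 = 7, lmax = 9.2,
                  rate = 0.6, tmid = 10, tDecline = 16, declineRate = 0.10),
        JUICE = list(model = "constant", l0 = 7))
}

#' @rdname simParams
#' @export
defaultBandTable <- function() {
    data.frame(
        label  = paste0("C", 1:12),
        center = c(1342, 1364, 1374, 1384, 1412, 1426,
                   1440, 1452, 1462, 1476, 1488, 1512),
        sigma  = c(8, 7, 7, 7, 9, 9, 10, 9, 9, 9, 9, 10),
        alpha  = c(0.010, 0.012, 0.012, 0.012, 0.030, 0.030,
                   0.035, 0.030, 0.030, 0.025, 0.022, 0.020),
        betaPh = c(0.008, 0.009, 0.009, 0.009, 0.016, 0.018,
                   0.020, 0.008, -0.006, -0.008, -0.008, -0.010),
        gammaCfu = c(0, 0, 0, 0, 0.001, 0,
                     0.004, 0, 0, 0.003, 0, 0.003))
}

# noiseless per-culture pH trajectory
phCurve <- function(t, culture, params) {
    if (culture == "JUICE") return(rep(params@phStart, length(t)))
    pe <- params@phEnd[[culture]]
    k <- params@kPh[[culture]]
    pe + (params@phStart - pe) * exp(-k * t)
}

# noiseless per-culture log10 CFU trajectory; every curve passes through
# l0 at t = 0 by normalizing the logistic between g(0) and its target
logcfuCurve <- function(t, culture, params) {
    g <- params@growth[[culture]]
    stopIfNot(!is.null(g), paste0("no growth parameters for ", culture))
    lgs <- function(t, rate, tmid) 1 / (1 + exp(-rate * (t - tmid)))
    switch(g$model,
        constant = rep(g$l0, length(t)),
        logistic = {
            g0 <- lgs(0, g$rate, g$tmid)
            g$l0 + (g$lmax - g$l0) * (lgs(t, g$rate, g$tmid) - g0) / (1 - g0)
        },
        peak_decline = {
            g0 <- lgs(0, g$rate, g$tmid)
            gp <- lgs(g$tpeak, g$rate, g$tmid)
            rise <- g$l0 + (g$peak - g$l0) *
                (lgs(t, g$rate, g$tmid) - g0) / (gp - g0)
            ifelse(t <= g$tpeak, rise,
                   g$peak - g$declineRate * (t - g$tpeak))
        },
        lag_log_decline = {
            g0 <- lgs(0, g$rate, g$tmid)
            gd <- lgs(g$tDecline, g$rate, g$tmid)
            rise <- g$l0 + (g$lmax - g$l0) *
                (lgs(t, g$rate, g$tmid) - g0) / (gd - g0)
            ifelse(t <= g$tDecline, rise,
                   g$lmax - g$declineRate * (t - g$tDecline))
        },
        stop("unknown growth model: ", g$model))
}

#' Simulate the reference table (pH, log cell count)
#'
#' Generates one reference row per `(culture, time_h, replicate)` of the
#' design. Noiseless trajectories follow
#' \eqn{pH(t) = pH_{end} + (pH_0 - pH_{end}) e^{-k t}} and the per-culture
#' parametric growth curves (see [simParams()]); replicate-level Gaussian
#' noise (`noise$phSd`, `noise$logcfuSd`) is then added. Seeded from
#' `params@seed`, so repeated calls are identical.
#'
#' @param design A [FermentationDesign-class].
#' @param params A [SimParams-class].
#' @return data.frame with columns `sample_id`, `culture`, `time_h`,
#'   `replicate`, `pH`, `logcfu`.
#' @examples
#' ref <- simulateReference(simulateDesign(), simParams())
#' subset(ref, culture == "LS" & time_h == 8)  # near log10(2e9)
#' @export
simulateReference <- function(design, params) {
    stopIfNot(methods::is(design, "FermentationDesign"), "design required")
    stopIfNot(methods::is(params, "SimParams"), "params required")
    methods::validObject(params)
    g <- design@groups
    ref <- g[rep(seq_len(nrow(g)), each = design@nReplicates), , drop = FALSE]
    ref$replicate <- rep(seq_len(design@nReplicates), times = nrow(g))
    rownames(ref) <- NULL
    ph <- lcf <- numeric(nrow(ref))
    for (i in seq_len(nrow(ref))) {
        ph[i] <- phCurve(ref$time_h[i], ref$culture[i], params)
        lcf[i] <- logcfuCurve(ref$time_h[i], ref$culture[i], params)
    }
    set.seed(params@seed %% 1000000000L)
    ref$pH <- ph + stats::rnorm(nrow(ref), 0, params@noise$phSd)
    ref$logcfu <- pmax(0, lcf + stats::rnorm(nrow(ref), 0,
                                             params@noise$logcfuSd))
    ref
}

#' Simulate NIR transmission spectra of fermenting juice
#'
#' Builds one absorbance spectrum per scan row of the design:
#' \deqn{A(\lambda) = B(\lambda) + \sum_k a_k G(\lambda; c_k, \sigma_k)
#'   + s(\lambda) + \epsilon}
#' where `B` is the smooth juice baseline, `G` are Gaussian water bands at
#' the WAMAC centers with amplitudes
#' \eqn{a_k = \alpha_k + \beta_k (pH_0 - pH) + \gamma_k (logCFU - 7)}
#' evaluated on the replicate's reference values, `s` is a turbidity tilt
#' (slope/offset linear in `logCFU - 7`, plus per-scan jitter) and
#' \eqn{\epsilon} combines a flat replicate offset (shared by the replicate's
#' consecutive scans) with per-scan white noise. Seeded and fully
#' reproducible; with all couplings, scatter and noise at zero the output is
#' exactly the baseline.
#'
#' @param design A [FermentationDesign-class].
#' @param reference data.frame from [simulateReference()] covering every
#'   `(culture, time_h, replicate)` of the design.
#' @param params A [SimParams-class].
#' @return A [SpectraSet-class] in canonical scan order.
#' @examples
#' p <- simParams()
#' d <- simulateDesign()
#' s <- simulateSpectra(d, simulateReference(d, p), p)
#' s
#' @export
simulateSpectra <- function(design, reference, params) {
    stopIfNot(methods::is(design, "FermentationDesign"), "design required")
    methods::validObject(params)
    wl <- seq(params@wavelengthStart, params@wavelengthEnd,
              by = params@wavelengthStep)
    scans <- design@scans
    refKey <- paste(reference$culture, reference$time_h,
                    reference$replicate, sep = "\r")
    scanRef <- match(paste(scans$culture, scans$time_h, scans$replicate,
                           sep = "\r"), refKey)
    if (anyNA(scanRef))
        stop("reference table does not cover every (culture, time, replicate)",
             call. = FALSE)

    bl <- params@baseline
    base <- bl$offset + bl$amp * exp(-((wl - bl$center) / bl$width)^2 / 2)
    bands <- params@bands
    G <- vapply(seq_len(nrow(bands)), function(k)
        exp(-((wl - bands$center[k]) / bands$sigma[k])^2 / 2),
        numeric(length(wl)))                     # wavelengths x bands
    u <- (wl - mean(range(wl))) / (diff(range(wl)) / 2)  # tilt in [-1, 1]

    nRep <- nrow(reference)
    nRow <- nrow(scans)
    set.seed((params@seed + 1L) %% 1000000000L)
    repOffset <- stats::rnorm(nRep, 0, params@noise$replicateOffsetSd)
    scanSlope <- stats::rnorm(nRow, 0, params@scatter$scanSlopeSd)
    scanOffset <- stats::rnorm(nRow, 0, params@scatter$scanOffsetSd)
    scanNoise <- matrix(stats::rnorm(nRow * length(wl), 0,
                                     params@noise$scanSd),
                        nrow = nRow)

    acid <- params@phStart - reference$pH          # per replicate
    dens <- reference$logcfu - 7
    # band amplitudes per replicate: nRep x nBands
    amps <- outer(rep(1, nRep), bands$alpha) +
        outer(acid, bands$betaPh) + outer(dens, bands$gammaCfu)

    A <- matrix(0, nrow = nRow, ncol = length(wl))
    for (i in seq_len(nRow)) {
        r <- scanRef[i]
        tilt <- dens[r] * (params@scatter$slopePerLog * u +
                               params@scatter$offsetPerLog) +
            scanSlope[i] * u + scanOffset[i]
        A[i, ] <- base + as.vector(G %*% amps[r, ]) + tilt +
            repOffset[r] + scanNoise[i, ]
    }
    out <- SpectraSet(A, wl, scans)
    S4Vectors::metadata(out)$simSeed <- params@seed
    canonicalize(out)
}
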