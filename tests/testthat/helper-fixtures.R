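# shared fixtures; the default simulation is built once per test run
.fixtures <- new.env(parent = emptyenv())

defaultSim <- function() {
    if (is.null(.fixtures$sim)) {
        params <- simParams()
        design <- simulateDesign()
        ref <- simulateReference(design, params)
        .fixtures$sim <- list(params = params, design = design, ref = ref,
                              spectra = simulateSpectra(design, ref, params))
    }
    .fixtures$sim
}

noiselessParams <- function(...) {
    simParams(scatter = list(slopePerLog = 0.004, offsetPerLog = 0.010,
                             scanSlopeSd = 0, scanOffsetSd = 0),
              noise = list(phSd = 0, logcfuSd = 0,
                           replicateOffsetSd = 0, scanSd = 0),
              ...)
}

noiselessSim <- function() {
    if (is.null(.fixtures$noiseless)) {
        params <- noiselessParams()
        design <- simulateDesign()
        ref <- simulateReference(design, params)
        .fixtures$noiseless <- list(params = params, design = design,
                                    ref = ref,
                                    spectra = simulateSpectra(design, ref,
                                                              params))
    }
    .fixtures$noiseless
}

# small random SpectraSet with valid metadata (nGroups groups x nRep x nScan)
randomSpectra <- function(nGroups = 4, nRep = 1, nScan = 1, nWl = 21,
                          wl = seq(1400, by = 2, length.out = nWl),
                          seed = 42) {
    set.seed(seed)
    n <- nGroups * nRep * nScan
    meta <- data.frame(
        sample_id = rep(sprintf("g%02d", seq_len(nGroups)),
                        each = nRep * nScan),
        culture = rep(c("BL", "LS", "MC")[(seq_len(nGroups) - 1) %% 3 + 1],
                      each = nRep * nScan),
        time_h = rep(seq_len(nGroups) * 4, each = nRep * nScan),
        replicate = rep(rep(seq_len(nRep), each = nScan), nGroups),
        scan = rep(seq_len(nScan), nGroups * nRep))
    SpectraSet(matrix(rnorm(n * nWl), n, nWl), wl, meta)
}

# align reference values to the scan rows of a spectra subset
refFor <- function(x, ref, what = "pH") {
    m <- scanInfo(x)
    ref[[what]][match(paste(m$culture, m$time_h, m$replicate),
                      paste(ref$culture, ref$time_h, ref$replicate))]
}

blockOf <- function(x) {
    m <- scanInfo(x)
    paste(m$sample_id, m$replicate, sep = ":")
}
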