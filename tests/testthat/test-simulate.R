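test_that("design enumeration reproduces the sampling plan counts", {
    d <- simulateDesign()
    expect_equal(nrow(d@groups), 13L)          # 3 cultures x 4 times + JUICE
    expect_equal(nrow(d@scans), 117L)
    expect_equal(sum(d@scans$culture == "JUICE"), 9L)

    # identity case
    d1 <- simulateDesign(cultures = "BL", times = 4, nReplicates = 1,
                         nScans = 1, sharedBaseline = FALSE)
    expect_equal(nrow(d1@groups), 1L)
    expect_equal(nrow(d1@scans), 1L)

    # rows = groups x reps x scans over a grid of small configurations
    for (nc in 1:2) for (nt in 1:3) for (nr in 1:2) for (ns in 1:2) {
        d2 <- simulateDesign(cultures = c("BL", "LS")[seq_len(nc)],
                             times = c(0, 4, 8)[seq_len(nt)],
                             nReplicates = nr, nScans = ns,
                             sharedBaseline = FALSE)
        expect_equal(nrow(d2@scans), nc * nt * nr * ns)
    }
})

test_that("design rejects degenerate inputs", {
    expect_error(simulateDesign(times = c(0, 4, 4)), "duplicate")
    expect_error(simulateDesign(nReplicates = 0), ">= 1")
    expect_error(simulateDesign(cultures = character(0)), "culture")
    expect_error(simulateDesign(times = c(4, 8), sharedBaseline = TRUE),
                 "0 h")
})

test_that("reference trajectories hit the anchor points", {
    d <- simulateDesign()
    p <- noiselessParams()
    ref <- simulateReference(d, p)

    # pH starts at 6.5 for every culture (0 h shared juice)
    expect_equal(ref$pH[ref$time_h == 0], rep(6.5, 3))
    # LS reaches log10(2e9) at exactly 8 h before noise
    expect_equal(ref$logcfu[ref$culture == "LS" & ref$time_h == 8],
                 rep(log10(2e9), 3))
    # every culture starts at log10 CFU 7
    expect_true(all(abs(ref$logcfu[ref$time_h == 0] - 7) < 1e-12))
    # one row per (culture, time, replicate); logcfu non-negative
    expect_false(anyDuplicated(
        paste(ref$culture, ref$time_h, ref$replicate)) > 0)
    expect_true(all(ref$logcfu >= 0))
    # noiseless pH is non-increasing in time within each culture
    for (cu in c("BL", "LS", "MC")) {
        r <- ref[ref$culture %in% c(cu, "JUICE"), ]
        r <- r[order(r$time_h), ]
        expect_true(all(diff(r$pH[r$replicate == 1]) <= 1e-12))
    }
    # pH bounded by the design range
    expect_true(all(ref$pH >= 4.0 - 0.5 & ref$pH <= 6.5 + 0.5))
})

test_that("zero pH decay rate keeps pH constant", {
    d <- simulateDesign()
    p <- noiselessParams(kPh = c(BL = 0, LS = 0, MC = 0))
    ref <- simulateReference(d, p)
    expect_equal(ref$pH, rep(6.5, nrow(ref)))
})

test_that("reference rejects inconsistent parameters", {
    d <- simulateDesign()
    expect_error(simParams(kPh = c(BL = -1, LS = 0.1, MC = 0.1)), "rates")
    expect_error(simParams(phEnd = c(BL = 7.5, LS = 4, MC = 4)), "phEnd")
})

test_that("zero couplings and noise reduce spectra to the baseline", {
    d <- simulateDesign(cultures = "BL", times = c(0, 8),
                        nReplicates = 2, nScans = 2)
    bands <- defaultBandTable()
    bands$alpha <- bands$betaPh <- bands$gammaCfu <- 0
    p <- simParams(bands = bands,
                   scatter = list(slopePerLog = 0, offsetPerLog = 0,
                                  scanSlopeSd = 0, scanOffsetSd = 0),
                   noise = list(phSd = 0, logcfuSd = 0,
                                replicateOffsetSd = 0, scanSd = 0))
    s <- simulateSpectra(d, simulateReference(d, p), p)
    wl <- wavelengths(s)
    base <- p@baseline$offset + p@baseline$amp *
        exp(-((wl - p@baseline$center) / p@baseline$width)^2 / 2)
    A <- absorbance(s)
    for (i in seq_len(nrow(A))) expect_equal(unname(A[i, ]), base)
})

test_that("simulation is deterministic under a fixed seed", {
    d <- simulateDesign()
    p <- simParams(seed = 77L)
    s1 <- simulateSpectra(d, simulateReference(d, p), p)
    s2 <- simulateSpectra(d, simulateReference(d, p), p)
    expect_identical(absorbance(s1), absorbance(s2))
    expect_identical(scanInfo(s1), scanInfo(s2))
})

test_that("noiseless output is seed-invariant and replicate rows identical", {
    d <- simulateDesign()
    a <- simulateSpectra(d, simulateReference(d, noiselessParams(seed = 1L)),
                         noiselessParams(seed = 1L))
    b <- simulateSpectra(d, simulateReference(d, noiselessParams(seed = 2L)),
                         noiselessParams(seed = 2L))
    expect_equal(absorbance(a), absorbance(b))
    # replicate/scan rows within one sample group are identical
    A <- absorbance(a)
    m <- scanInfo(a)
    for (sid in unique(m$sample_id)) {
        rows <- A[m$sample_id == sid, , drop = FALSE]
        expect_true(max(abs(sweep(rows, 2, rows[1, ]))) == 0)
    }
})

test_that("acidification drives absorbance up at 1412 nm over time", {
    # positive pH coupling only: cell-count coupling and turbidity scatter
    # off, isolating the acidification effect on the band amplitudes
    bands <- defaultBandTable()
    bands$gammaCfu <- 0
    p <- simParams(bands = bands,
                   scatter = list(slopePerLog = 0, offsetPerLog = 0,
                                  scanSlopeSd = 0, scanOffsetSd = 0),
                   noise = list(phSd = 0, logcfuSd = 0,
                                replicateOffsetSd = 0, scanSd = 0))
    d <- simulateDesign()
    s <- simulateSpectra(d, simulateReference(d, p), p)
    A <- absorbance(s)
    m <- scanInfo(s)
    i1412 <- which.min(abs(wavelengths(s) - 1412))
    for (cu in c("BL", "LS", "MC")) {
        keep <- m$culture %in% c(cu, "JUICE")
        mu <- tapply(A[keep, i1412], m$time_h[keep], mean)
        expect_true(all(diff(mu[order(as.numeric(names(mu)))]) >= 0))
    }
})

test_that("mean 24 h minus 0 h difference peaks in the 1400-1450 nm region", {
    s <- defaultSim()$spectra
    A <- absorbance(s)
    m <- scanInfo(s)
    d24 <- colMeans(A[m$time_h == 24, ]) - colMeans(A[m$time_h == 0, ])
    peak <- wavelengths(s)[which.max(d24)]
    expect_gte(peak, 1400)
    expect_lte(peak, 1450)
})

test_that("OLS of pH on the most pH-coupled band amplitudes recovers the map", {
    sim <- noiselessSim()
    ref <- sim$ref
    bands <- sim$params@bands
    # reconstruct the generating amplitudes independently of the simulator
    acid <- sim$params@phStart - ref$pH
    dens <- ref$logcfu - 7
    top2 <- order(bands$betaPh, decreasing = TRUE)[1:2]
    a1 <- bands$alpha[top2[1]] + bands$betaPh[top2[1]] * acid +
        bands$gammaCfu[top2[1]] * dens
    a2 <- bands$alpha[top2[2]] + bands$betaPh[top2[2]] * acid +
        bands$gammaCfu[top2[2]] * dens
    fit <- lm(ref$pH ~ a1 + a2)
    expect_lt(max(abs(residuals(fit))), 1e-9)
})
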