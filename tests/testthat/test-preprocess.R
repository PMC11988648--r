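# brute-force Savitzky-Golay oracle: local polynomial least squares with
# terminal-window fits at the boundaries
sgOracle <- function(x, window, polyorder, deriv = 0, ts = 1) {
    n <- length(x)
    h <- (window - 1) / 2
    out <- numeric(n)
    for (i in seq_len(n)) {
        if (i <= h) { lo <- 1; at <- i }
        else if (i > n - h) { lo <- n - window + 1; at <- i - (n - window) }
        else { lo <- i - h; at <- h + 1 }
        idx <- lo:(lo + window - 1)
        z <- (seq_len(window) - at) * ts
        co <- stats::coef(stats::lm(x[idx] ~ stats::poly(z, polyorder,
                                                         raw = TRUE)))
        out[i] <- if (deriv == 0) co[1] else
            if (deriv == 1) co[2] else 2 * co[3]
    }
    out
}

toySet <- function(mat, wl) {
    n <- nrow(mat)
    SpectraSet(mat, wl, data.frame(
        sample_id = sprintf("s%02d", seq_len(n)), culture = "BL",
        time_h = seq_len(n), replicate = 1L, scan = 1L))
}

test_that("Savitzky-Golay smoothing reproduces low-order polynomials", {
    wl <- seq(1300, 1340, by = 2)
    quad <- 0.5 + 0.01 * (wl - 1320) + 2e-4 * (wl - 1320)^2
    s <- toySet(rbind(quad, rep(0.3, length(wl))), wl)
    sm <- savgolSmooth(s, window = 7)
    expect_equal(absorbance(sm)[1, ], absorbance(s)[1, ], tolerance = 1e-9)
    expect_equal(absorbance(sm)[2, ], absorbance(s)[2, ], tolerance = 1e-12)
})

test_that("Savitzky-Golay smoothing matches the local-fit oracle", {
    set.seed(7)
    x <- rnorm(21)
    s <- toySet(rbind(x), seq(1400, by = 0.5, length.out = 21))
    got <- absorbance(savgolSmooth(s, window = 5))[1, ]
    expect_equal(unname(got), sgOracle(x, 5, 2), tolerance = 1e-10)
})

test_that("smoothing rejects invalid windows", {
    s <- toySet(matrix(rnorm(42), 2), seq_len(21))
    expect_error(savgolSmooth(s, window = 6), "odd")
    expect_error(savgolSmooth(s, window = 3, polyorder = 3), "exceed")
    expect_error(savgolSmooth(s, window = 23), "larger")
})

test_that("derivatives remove offsets/ramps and match analytic derivatives", {
    wl <- seq(1300, 1320, by = 0.5)
    set.seed(1)
    base <- rnorm(length(wl))
    s0 <- toySet(rbind(base), wl)
    s1 <- toySet(rbind(base + 5), wl)                 # constant offset
    s2 <- toySet(rbind(base + 5 + 0.2 * (wl - 1300)), wl)  # + linear ramp
    d1a <- absorbance(spectralDerivative(s0, 1, 7))[1, ]
    d1b <- absorbance(spectralDerivative(s1, 1, 7))[1, ]
    expect_equal(d1a, d1b, tolerance = 1e-10)
    d2a <- absorbance(spectralDerivative(s0, 2, 7))[1, ]
    d2b <- absorbance(spectralDerivative(s2, 2, 7))[1, ]
    expect_equal(d2a, d2b, tolerance = 1e-10)

    # lambda^2 -> 2 lambda at interior points (per-nm scaling)
    sq <- toySet(rbind((wl - 1300)^2), wl)
    d1 <- absorbance(spectralDerivative(sq, 1, 7))[1, ]
    interior <- 4:(length(wl) - 3)
    expect_equal(unname(d1[interior]), 2 * (wl[interior] - 1300),
                 tolerance = 1e-8)
    # full agreement with the brute-force derivative oracle
    d1o <- sgOracle(base, 7, 2, deriv = 1, ts = 0.5)
    expect_equal(unname(d1a), d1o, tolerance = 1e-9)
})

test_that("detrending annihilates polynomial baselines", {
    wl <- seq(1300, 1360, by = 2)
    poly2 <- 1 + 0.02 * (wl - 1330) - 3e-4 * (wl - 1330)^2
    s <- toySet(rbind(poly2, rep(2, length(wl))), wl)
    dt <- detrendSpectra(s, degree = 2)
    expect_lt(max(abs(absorbance(dt)[1, ])), 1e-10)
    d0 <- detrendSpectra(s, degree = 0)
    expect_lt(max(abs(absorbance(d0)[2, ])), 1e-12)

    # polynomial + Gaussian peak: residual equals the peak minus its own
    # least-squares degree-2 projection (explicit oracle)
    peak <- 0.3 * exp(-((wl - 1335) / 6)^2 / 2)
    sp <- toySet(rbind(poly2 + peak), wl)
    got <- absorbance(detrendSpectra(sp, degree = 2))[1, ]
    z <- wl - mean(wl)
    V <- cbind(1, z, z^2)
    proj <- V %*% solve(crossprod(V), crossprod(V, peak))
    expect_equal(unname(got), as.vector(peak - proj), tolerance = 1e-8)
})

test_that("SNV standardizes spectra and is affine-invariant", {
    set.seed(3)
    x <- rnorm(21)
    s <- toySet(rbind(x, 3 * x + 2), seq_len(21))
    sn <- absorbance(snvCorrect(s))
    expect_equal(unname(rowMeans(sn)), c(0, 0), tolerance = 1e-12)
    expect_equal(unname(apply(sn, 1, sd)), c(1, 1), tolerance = 1e-12)
    expect_equal(sn[1, ], sn[2, ], tolerance = 1e-12)
    expect_error(snvCorrect(toySet(rbind(x, rep(1, 21)), seq_len(21))),
                 "row\\(s\\): 2")
})

test_that("MSC removes affine scatter against the reference", {
    set.seed(4)
    ref <- cumsum(rnorm(21))
    s <- toySet(rbind(ref, 2 * ref + 1, rnorm(21) + ref), seq_len(21))
    out <- absorbance(mscCorrect(s, reference = ref))
    expect_equal(out[1, ], absorbance(s)[1, ], tolerance = 1e-10)  # fixed point
    expect_equal(out[2, ], absorbance(s)[1, ], tolerance = 1e-10)  # affine removal
    # each corrected spectrum regressed on the reference: slope 1, intercept 0
    for (i in 1:3) {
        co <- coef(lm(out[i, ] ~ ref))
        expect_equal(unname(co), c(0, 1), tolerance = 1e-8)
    }
})

test_that("averaging collapses groups correctly", {
    sim <- defaultSim()
    ferm <- subsetSpectra(sim$spectra, times = c(4, 8, 16, 24))
    avg <- averageBy(ferm, c("culture", "time_h"))
    expect_equal(nScans(avg), 12L)

    # single row averages to itself; identical rows to the common row
    one <- toySet(rbind(1:5), seq_len(5))
    expect_equal(absorbance(averageBy(one, "sample_id"))[1, ],
                 absorbance(one)[1, ])
    m3 <- matrix(rep(c(1, 2, 3, 4, 5), 3), 3, byrow = TRUE)
    same <- SpectraSet(m3, seq_len(5), data.frame(
        sample_id = "g", culture = "BL", time_h = 4,
        replicate = 1L, scan = 1:3))
    got <- averageBy(same, "sample_id")
    expect_equal(unname(absorbance(got)[1, ]), c(1, 2, 3, 4, 5))
    expect_error(averageBy(one, character(0)), "keys")
})

test_that("difference spectra subtract the per-culture 0 h baseline", {
    # toy: 0 h all 1.0, 24 h all 1.3 -> difference all 0.3
    toy <- SpectraSet(rbind(rep(1, 5), rep(1.3, 5)), seq_len(5), data.frame(
        sample_id = c("JUICE_0h", "BL_24h"), culture = c("JUICE", "BL"),
        time_h = c(0, 24), replicate = 1L, scan = 1L))
    d <- differenceSpectra(toy)
    expect_equal(unname(absorbance(d)[1, ]), rep(0.3, 5))
    expect_equal(scanInfo(d)$time_h, 24)

    # baseline subtracted from itself is zero (culture with own 0 h group)
    own <- SpectraSet(rbind(rep(2, 4), rep(2, 4)), seq_len(4), data.frame(
        sample_id = c("BL_0h", "BL_0hb"), culture = "BL",
        time_h = c(0, 0), replicate = c(1L, 2L), scan = 1L))
    expect_error(differenceSpectra(own), "no non-baseline")

    noBase <- subsetSpectra(defaultSim()$spectra, times = c(4, 24),
                            includeBaseline = FALSE)
    expect_error(differenceSpectra(noBase), "missing baseline")

    # default simulation: per-culture difference peaks inside 1400-1450 nm
    d2 <- differenceSpectra(defaultSim()$spectra)
    A <- absorbance(d2)
    m <- scanInfo(d2)
    for (i in which(m$time_h == 24)) {
        pk <- wavelengths(d2)[which.max(A[i, ])]
        expect_gte(pk, 1400); expect_lte(pk, 1450)
    }
})

test_that("pretreatment specs validate and compose sequentially", {
    expect_error(pretreatmentSpec(list(list(step = "savgol", window = 6))),
                 "odd")
    expect_error(pretreatmentSpec(list(list(step = "msc"),
                                       list(step = "snv"))),
                 "at most one")
    expect_error(pretreatmentSpec(list(list(step = "wavelet"))), "unknown")
    expect_error(pretreatmentSpec(list(list(step = "derivative",
                                            order = 3, window = 7))),
                 "order")

    s <- randomSpectra(nGroups = 4, nWl = 31, seed = 9)
    spec <- list(list(step = "savgol", window = 5), list(step = "snv"))
    composed <- applyPretreatment(s, spec)
    manual <- snvCorrect(savgolSmooth(s, 5))
    expect_equal(absorbance(composed), absorbance(manual))
})

test_that("operators preserve shape and metadata", {
    s <- randomSpectra(nGroups = 3, nRep = 2, nWl = 25, seed = 11)
    for (f in list(function(x) savgolSmooth(x, 5),
                   function(x) detrendSpectra(x),
                   function(x) snvCorrect(x),
                   function(x) mscCorrect(x),
                   function(x) spectralDerivative(x, 1, 5))) {
        out <- f(s)
        expect_equal(dim(absorbance(out)), dim(absorbance(s)))
        expect_equal(scanInfo(out), scanInfo(s))
        expect_equal(wavelengths(out), wavelengths(s))
    }
})
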