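test_that("PLS fits an exact linear relation perfectly", {
    set.seed(50)
    Q <- qr.Q(qr(matrix(rnorm(15 * 3), 15, 3)))       # 3 orthogonal factors
    scores <- matrix(rnorm(20 * 3), 20, 3)
    X <- scores %*% t(Q)
    y <- drop(scores %*% c(2, -1, 0.5)) + 3
    m <- fitPLSR(X, y, 3)
    expect_lte(m@metrics$RMSEC, 1e-8)
    expect_equal(m@metrics$R2C, 1, tolerance = 1e-10)
    # regression-vector identity: fitted = centered x . b + yCenter
    fitted <- drop(sweep(X, 2, m@xCenter) %*% m@coefficients) + m@yCenter
    expect_equal(fitted, m@predictions$fitted, tolerance = 1e-8)
})

test_that("one latent variable matches its closed-form solution", {
    set.seed(51)
    X <- matrix(rnorm(10 * 15), 10, 15)
    y <- rnorm(10)
    m <- fitPLSR(X, y, 1)
    Xc <- scale(X, center = TRUE, scale = FALSE)
    yc <- y - mean(y)
    w <- drop(crossprod(Xc, yc)); w <- w / sqrt(sum(w^2))
    t1 <- drop(Xc %*% w)
    bclosed <- w * sum(t1 * yc) / sum(t1^2) /
        drop(crossprod(w, crossprod(Xc, t1) / sum(t1^2)))
    expect_equal(m@coefficients, bclosed, tolerance = 1e-8)
    # prediction equals OLS on the single score for rank-1 X
    X1 <- outer(rnorm(8), rnorm(5))
    y1 <- 2 * X1[, 1] + 1
    m1 <- fitPLSR(X1, y1, 1)
    ols <- stats::lm.fit(cbind(1, X1[, 1]), y1)$fitted.values
    expect_equal(m1@predictions$fitted, ols, tolerance = 1e-8)
})

test_that("PLS rejects degenerate inputs", {
    X <- matrix(rnorm(20), 5, 4)
    expect_error(fitPLSR(X, rep(1, 5), 1), "constant")
    expect_error(fitPLSR(X, rnorm(5), 5), "smaller")
    expect_error(fitPLSR(X, rnorm(4), 1), "one value per")
})

test_that("latent-variable selection finds the generating dimension", {
    set.seed(52)
    Q <- qr.Q(qr(matrix(rnorm(20 * 3), 20, 3)))
    n <- 18
    scores <- matrix(rnorm(n * 3), n, 3) %*% diag(c(3, 2, 1))
    X <- scores %*% t(Q)
    y <- drop(scores %*% c(1, -2, 1.5))
    meta <- data.frame(sample_id = rep(sprintf("g%d", 1:6), each = 3),
                       culture = "BL", time_h = rep(1:6, each = 3),
                       replicate = rep(1:3, 6), scan = 1L)
    s <- SpectraSet(X, seq(1300, by = 10, length.out = 20), meta)
    plan <- makeFoldPlan(s)
    sel <- suppressWarnings(selectNrLVs(s, y, plan, maxLv = 8))
    expect_equal(sel$nrlv, 3L)
    # exhaustive-curve re-check: reported minimum is the curve's minimum
    expect_equal(sel$curve$rmsecv[sel$curve$nrlv == sel$nrlv],
                 min(sel$curve$rmsecv))

    expect_equal(suppressWarnings(selectNrLVs(s, y, plan, maxLv = 1))$nrlv,
                 1L)
    # pure-noise response: selection stays within bounds
    set.seed(53)
    selN <- suppressWarnings(selectNrLVs(s, rnorm(n), plan, maxLv = 5))
    expect_gte(selN$nrlv, 1L)
    expect_lte(selN$nrlv, 5L)
})

test_that("calibration and validation metrics follow their definitions", {
    sim <- defaultSim()
    sub <- applyPretreatment(subsetSpectra(sim$spectra, culture = "LS"),
                             list(list(step = "snv")))
    y <- refFor(sub, sim$ref, "pH")
    plan <- makeFoldPlan(sub)
    m <- evaluatePLSR(sub, y, 3L, plan)
    p <- m@predictions
    expect_equal(m@metrics$RMSEC, sqrt(mean((p$actual - p$fitted)^2)))
    expect_equal(m@metrics$R2C,
                 1 - sum((p$actual - p$fitted)^2) /
                     sum((p$actual - mean(p$actual))^2))
    expect_equal(m@metrics$RMSECV, sqrt(mean((p$actual - p$cv)^2)))
    # perfect predictions give R2 = 1, RMSE = 0; the mean predictor gives 0
    expect_equal(aquaferm:::.r2(y, y), 1)
    expect_equal(aquaferm:::.rmse(y, y), 0)
    expect_equal(aquaferm:::.r2(y, rep(mean(y), length(y))), 0)
})

test_that("grouped-CV integrity is enforced inside the PLS loop", {
    s <- randomSpectra(nGroups = 6, nRep = 1, nScan = 1, seed = 54)
    y <- rnorm(6)
    # a corrupt plan that splits a block across folds must be caught
    expect_error(
        methods::new("FoldPlan", fold = c(1L, 2L, 3L, 1L, 2L, 3L),
                     block = rep(c("a", "b"), each = 3), nFolds = 3L),
        "spans")
})

test_that("regression-vector peaks recover generating extrema", {
    # single spike
    m <- methods::new("PLSModel", nrlv = 1L, xCenter = numeric(5),
                      yCenter = 0, weights = matrix(0, 5, 1),
                      xLoadings = matrix(0, 5, 1), yLoadings = 0,
                      coefficients = c(0, 0, 3, 0, 0),
                      metrics = list(R2C = 1, RMSEC = 0),
                      predictions = data.frame(actual = 1, fitted = 1),
                      wavelengths = c(1400, 1410, 1420, 1430, 1440))
    expect_equal(regressionVectorPeaks(m, 3), 1420)
    m@coefficients <- numeric(5)
    expect_length(regressionVectorPeaks(m, 3), 0)

    # known generating vector inside the row space: exact recovery
    set.seed(55)
    wl <- seq(1300, 1600, by = 5)
    n <- 24
    X <- matrix(0, n, length(wl))
    for (i in seq_len(n))
        X[i, ] <- rnorm(1, 1, .2) * exp(-((wl - 1440) / 40)^2 / 2) +
            rnorm(1, 0, .3) * exp(-((wl - 1380) / 15)^2 / 2) +
            rnorm(1, 0, .3) * exp(-((wl - 1500) / 15)^2 / 2)
    Xc <- scale(X, center = TRUE, scale = FALSE)
    bTrue <- drop(crossprod(Xc, rnorm(n)))     # lies in the row space
    bTrue <- bTrue / max(abs(bTrue))
    y <- drop(Xc %*% bTrue) + 2
    sX <- SpectraSet(X, wl, data.frame(
        sample_id = sprintf("s%02d", seq_len(n)), culture = "BL",
        time_h = seq_len(n), replicate = 1L, scan = 1L))
    mf <- suppressWarnings(fitPLSR(sX, y, 6))
    cosine <- sum(mf@coefficients * bTrue) /
        sqrt(sum(mf@coefficients^2) * sum(bTrue^2))
    expect_gt(cosine, 0.99)
    # every reported peak lies within one grid step of a true extremum of
    # comparable magnitude
    v <- abs(bTrue); n <- length(v)
    trueExt <- wl[v >= c(-Inf, v[-n]) & v >= c(v[-1], -Inf) &
                      v > 0.25 * max(v)]
    for (pk in regressionVectorPeaks(mf, 3))
        expect_lte(min(abs(pk - trueExt)), 5)  # within one grid step
})
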