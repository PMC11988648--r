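# NIPALS univariate-response PLS. Returns weights W, x-loadings P,
# y-loadings q and the per-component coefficient matrices; deflation on X
# only (y loadings computed from the current scores). Components whose
# score norm collapses (X exhausted) are dropped with a warning.
plsNipals <- function(X, y, nrlv, tol = 1e-12) {
    Xc <- scale(X, center = TRUE, scale = FALSE)
    xCenter <- attr(Xc, "scaled:center")
    yCenter <- mean(y)
    yc <- y - yCenter
    n <- nrow(X); p <- ncol(X)
    W <- P <- matrix(0, p, nrlv)
    Tm <- matrix(0, n, nrlv)
    q <- numeric(nrlv)
    E <- Xc
    kept <- 0L
    x0 <- sum(Xc^2)
    for (a in seq_len(nrlv)) {
        w <- crossprod(E, yc)               # covariance weight
        wn <- sqrt(sum(w^2))
        if (wn < tol * max(1, sqrt(x0))) break
        w <- w / wn
        t <- E %*% w
        tt <- sum(t^2)
        if (tt < tol^2 * max(1, x0)) break
        pvec <- crossprod(E, t) / tt
        q[a] <- sum(yc * t) / tt
        E <- E - t %*% t(pvec)
        W[, a] <- w; P[, a] <- pvec; Tm[, a] <- t
        kept <- a
    }
    if (kept < nrlv)
        warning("PLS components truncated at ", kept,
                " (X rank exhausted)")
    keep <- seq_len(kept)
    W <- W[, keep, drop = FALSE]; P <- P[, keep, drop = FALSE]
    q <- q[keep]
    # cumulative regression vectors B_a = W_a (P_a' W_a)^-1 q_a
    Bcum <- matrix(0, p, kept)
    for (a in keep) {
        Wa <- W[, seq_len(a), drop = FALSE]
        Pa <- P[, seq_len(a), drop = FALSE]
        Bcum[, a] <- Wa %*% solve(crossprod(Pa, Wa), q[seq_len(a)])
    }
    list(W = W, P = P, q = q, scores = Tm[, keep, drop = FALSE],
         Bcum = Bcum, nrlv = kept, xCenter = xCenter, yCenter = yCenter)
}

.plsXY <- function(x, y) {
    A <- if (methods::is(x, "SpectraSet")) absorbance(x) else as.matrix(x)
    stopIfNot(is.numeric(y) && all(is.finite(y)), "y must be finite numeric")
    stopIfNot(length(y) == nrow(A), "y must have one value per scan row")
    if (stats::sd(y) == 0) stop("constant response y", call. = FALSE)
    A
}

#' Fit a partial least squares regression model
#'
#' Mean-centered univariate-response PLS by NIPALS deflation. The
#' wavelength-domain regression vector is reconstructed so that
#' `fitted = (X - xCenter) %*% coefficients + yCenter` holds exactly.
#'
#' @param x A [SpectraSet-class] (pretreated) or matrix (scans x wavelengths).
#' @param y numeric response per scan row (e.g. pH or log10 CFU/mL).
#' @param nrlv number of latent variables, `1 <= nrlv < nScans`.
#' @return A [PLSModel-class] with calibration metrics `R2C`, `RMSEC`.
#' @export
fitPLSR <- function(x, y, nrlv) {
    A <- .plsXY(x, y)
    stopIfNot(nrlv >= 1, "nrlv must be >= 1")
    if (nrlv >= nrow(A))
        stop("nrlv must be smaller than the number of rows", call. = FALSE)
    fit <- plsNipals(A, y, nrlv)
    B <- fit$Bcum[, fit$nrlv]
    fitted <- as.vector(sweep(A, 2, fit$xCenter) %*% B) + fit$yCenter
    wl <- if (methods::is(x, "SpectraSet")) wavelengths(x)
          else seq_len(ncol(A))
    methods::new("PLSModel", nrlv = as.integer(fit$nrlv),
                 xCenter = fit$xCenter, yCenter = fit$yCenter,
                 weights = fit$W, xLoadings = fit$P, yLoadings = fit$q,
                 coefficients = B,
                 metrics = list(R2C = .r2(y, fitted),
                                RMSEC = .rmse(y, fitted)),
                 predictions = data.frame(actual = y, fitted = fitted),
                 wavelengths = wl)
}

#' Predict from a PLS model
#' @param object A [PLSModel-class].
#' @param newdata A [SpectraSet-class] or matrix on the model's grid.
#' @param ... unused.
#' @return numeric predictions.
#' @export
setMethod("predict", "PLSModel", function(object, newdata, ...) {
    A <- if (methods::is(newdata, "SpectraSet")) absorbance(newdata)
         else as.matrix(newdata)
    as.vector(sweep(A, 2, object@xCenter) %*% object@coefficients) +
        object@yCenter
})

.rmse <- function(y, yhat) sqrt(mean((y - yhat)^2))
.r2 <- function(y, yhat) 1 - sum((y - yhat)^2) / sum((y - mean(y))^2)

# pooled held-out predictions for candidates 1..maxLv under a fold plan;
# returns matrix rows x candidates (NA where a fold could not reach a
# candidate because of rank truncation)
.plsCVPredict <- function(A, y, plan, maxLv) {
    pred <- matrix(NA_real_, nrow(A), maxLv)
    for (f in sort(unique(plan@fold))) {
        tr <- which(plan@fold != f)
        va <- which(plan@fold == f)
        .assertGroupedSplit(plan, tr, va)
        fit <- suppressWarnings(
            plsNipals(A[tr, , drop = FALSE], y[tr],
                      min(maxLv, length(tr) - 1L)))
        Ava <- sweep(A[va, , drop = FALSE], 2, fit$xCenter)
        for (a in seq_len(fit$nrlv))
            pred[va, a] <- as.vector(Ava %*% fit$Bcum[, a]) + fit$yCenter
    }
    pred
}

#' Select the number of latent variables by minimal RMSECV
#'
#' Computes the cross-validated root mean square error for every candidate
#' latent-variable count `1..maxLv` under the grouped fold plan (pooled
#' held-out predictions) and returns the minimizer; ties break towards the
#' smallest count. Candidates beyond the effective rank of a training split
#' are dropped.
#'
#' @param x A [SpectraSet-class] or matrix.
#' @param y numeric response.
#' @param plan A [FoldPlan-class].
#' @param maxLv candidate upper bound (default 20).
#' @return list with `nrlv` and `curve` (data.frame `nrlv`, `rmsecv`).
#' @export
selectNrLVs <- function(x, y, plan, maxLv = 20L) {
    stopIfNot(maxLv >= 1, "maxLv must be >= 1")
    A <- .plsXY(x, y)
    maxLv <- min(maxLv, nrow(A) - 1L, ncol(A))
    pred <- .plsCVPredict(A, y, plan, maxLv)
    ok <- which(colSums(is.na(pred)) == 0)
    stopIfNot(length(ok) >= 1, "no usable latent-variable candidate")
    rmsecv <- vapply(ok, function(a) .rmse(y, pred[, a]), 1)
    curve <- data.frame(nrlv = ok, rmsecv = rmsecv)
    list(nrlv = ok[which.min(rmsecv)], curve = curve)
}

#' Calibration and cross-validation metrics of a PLS model
#'
#' Fits the all-data model (calibration: `R2C`, `RMSEC`) and computes
#' cross-validated metrics (`R2CV`, `RMSECV`) from the pooled held-out
#' predictions under the grouped fold plan, with
#' `R2 = 1 - sum((y - yhat)^2) / sum((y - mean(y))^2)` and
#' `RMSE = sqrt(mean((y - yhat)^2))`.
#'
#' @param x A [SpectraSet-class] or matrix.
#' @param y numeric response.
#' @param nrlv latent-variable count (e.g. from [selectNrLVs()]).
#' @param plan A [FoldPlan-class].
#' @return A [PLSModel-class] with `metrics$R2CV`, `metrics$RMSECV` and a
#'   `cv` column in its predictions.
#' @export
evaluatePLSR <- function(x, y, nrlv, plan) {
    A <- .plsXY(x, y)
    model <- fitPLSR(x, y, nrlv)
    pred <- .plsCVPredict(A, y, plan, model@nrlv)
    cv <- pred[, model@nrlv]
    if (anyNA(cv))
        stop("a training split could not support ", model@nrlv,
             " latent variables", call. = FALSE)
    model@metrics$R2CV <- .r2(y, cv)
    model@metrics$RMSECV <- .rmse(y, cv)
    model@predictions$cv <- cv
    methods::validObject(model)
    model
}

#' Peak wavelengths of a PLS regression vector
#'
#' Local extrema of the absolute regression vector above `localFrac` of its
#' global maximum, sorted by magnitude, truncated to the top `k`.
#'
#' @param model A [PLSModel-class].
#' @param k maximum number of peaks (>= 1).
#' @param localFrac detection threshold as a fraction of the global maximum
#'   (default 0.25).
#' @return numeric vector of wavelengths (possibly empty for an all-zero
#'   vector).
#' @export
regressionVectorPeaks <- function(model, k, localFrac = 0.25) {
    stopIfNot(k >= 1, "k must be >= 1")
    v <- abs(model@coefficients)
    if (max(v) == 0) return(numeric(0))
    n <- length(v)
    isPeak <- v >= c(-Inf, v[-n]) & v >= c(v[-1], -Inf) & v > localFrac * max(v)
    idx <- which(isPeak)
    idx <- idx[order(v[idx], decreasing = TRUE)]
    model@wavelengths[utils::head(idx, k)]
}
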