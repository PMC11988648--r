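#' Grouped three-fold cross-validation plan
#'
#' Assigns each scan row to a fold such that all consecutive scans of one
#' `(sample_id, replicate)` block share a fold. With the canonical three
#' replicates, the fold index is the replicate index, so each fold holds one
#' complete measurement repetition of every sample and no block is ever
#' split between training and validation. Other replicate counts fall back
#' to a round-robin over replicates, with a warning.
#'
#' @param x A [SpectraSet-class].
#' @param nFolds number of folds (default 3).
#' @return A [FoldPlan-class].
#' @export
makeFoldPlan <- function(x, nFolds = 3L) {
    m <- scanInfo(x)
    reps <- sort(unique(m$replicate))
    if (length(reps) != nFolds)
        warning("replicate count (", length(reps), ") != ", nFolds,
                " folds; using round-robin assignment by replicate")
    fold <- (match(m$replicate, reps) - 1L) %% as.integer(nFolds) + 1L
    methods::new("FoldPlan", fold = fold, block = blockKey(m),
                 nFolds = as.integer(nFolds))
}

#' Stratified fold plan for averaged spectra
#'
#' After group averaging, replicate identity is gone; this assigns folds to
#' the averaged rows by shuffling within each stratum (default: culture) so
#' every fold sees every culture. Seeded for reproducibility.
#'
#' @param x A [SpectraSet-class] of averaged rows.
#' @param nFolds number of folds.
#' @param stratifyBy metadata column to stratify on.
#' @param seed integer seed.
#' @return A [FoldPlan-class].
#' @export
makeStratifiedFoldPlan <- function(x, nFolds = 3L, stratifyBy = "culture",
                                   seed = 1L) {
    m <- scanInfo(x)
    stopIfNot(stratifyBy %in% colnames(m), "unknown stratification column")
    set.seed(seed %% 1000000000L)
    fold <- integer(nrow(m))
    for (s in unique(m[[stratifyBy]])) {
        idx <- which(m[[stratifyBy]] == s)
        fold[idx] <- sample(rep_len(seq_len(nFolds), length(idx)))
    }
    methods::new("FoldPlan", fold = fold, block = blockKey(m),
                 nFolds = as.integer(nFolds))
}

# check that no block is split across the train/validation boundary
.assertGroupedSplit <- function(plan, trainIdx, valIdx) {
    shared <- intersect(plan@block[trainIdx], plan@block[valIdx])
    if (length(shared))
        stop("grouped-CV violation: block(s) in both train and validation: ",
             paste(utils::head(shared, 3), collapse = ", "), call. = FALSE)
    invisible(TRUE)
}

# linear discriminant analysis with pooled within-class covariance and
# equal class priors; ridge fallback for singular pooled covariance
ldaTrain <- function(scores, labels, ridgeEps = 1e-8) {
    labels <- droplevels(as.factor(labels))
    g <- nlevels(labels)
    stopIfNot(g >= 2, "LDA needs at least 2 classes")
    X <- as.matrix(scores)
    p <- ncol(X)
    means <- do.call(rbind, lapply(levels(labels), function(l)
        colMeans(X[labels == l, , drop = FALSE])))
    Xc <- X - means[as.integer(labels), , drop = FALSE]
    W <- crossprod(Xc) / (nrow(X) - g)
    ev <- eigen(W, symmetric = TRUE, only.values = TRUE)$values
    ridged <- FALSE
    if (min(ev) <= max(ev) * 1e-10) {
        W <- W + diag(ridgeEps * max(mean(diag(W)), 1e-12), p)
        ridged <- TRUE
    }
    Winv <- solve(W)
    # canonical (discriminant) directions: eigenvectors of W^-1 B via the
    # symmetric whitened between-class scatter
    Bm <- means - matrix(colMeans(X), g, p, byrow = TRUE)
    B <- crossprod(Bm) / max(1, g - 1)
    eW <- eigen(W, symmetric = TRUE)
    Wih <- eW$vectors %*% diag(1 / sqrt(pmax(eW$values, 1e-300)), p) %*%
        t(eW$vectors)
    eC <- eigen(Wih %*% B %*% Wih, symmetric = TRUE)
    ndisc <- min(g - 1, p)
    V <- Wih %*% eC$vectors[, seq_len(ndisc), drop = FALSE]
    for (j in seq_len(ncol(V))) {           # deterministic sign
        i <- which.max(abs(V[, j]))
        if (V[i, j] < 0) V[, j] <- -V[, j]
    }
    structure(list(means = means, Winv = Winv, levels = levels(labels),
                   canonical = V, ridged = ridged),
              class = "aquaferm_lda")
}

# classify rows of `scores`; equal priors -> maximize the linear
# discriminant score delta_c(x) = x' Winv mu_c - mu_c' Winv mu_c / 2
ldaPredict <- function(fit, scores) {
    X <- as.matrix(scores)
    M <- fit$means
    D <- X %*% fit$Winv %*% t(M) -
        matrix(0.5 * rowSums((M %*% fit$Winv) * M),
               nrow(X), nrow(M), byrow = TRUE)
    factor(fit$levels[max.col(D, ties.method = "first")],
           levels = fit$levels)
}

# run one grouped-CV pass of PCA-LDA; returns per-fold accuracies and
# pooled validation predictions for nrpcs components (vectorized over a set
# of candidate nrpcs values to keep NrPC selection cheap)
.pcaLdaCV <- function(A, labels, plan, nrpcsSet, maxRank) {
    folds <- sort(unique(plan@fold))
    res <- lapply(nrpcsSet, function(j)
        list(train = numeric(0), pred = factor(rep(NA, nrow(A)),
                                               levels = levels(labels))))
    names(res) <- as.character(nrpcsSet)
    for (f in folds) {
        tr <- which(plan@fold != f)
        va <- which(plan@fold == f)
        .assertGroupedSplit(plan, tr, va)
        if (!setequal(unique(labels[tr]), levels(labels)))
            stop("every class must be present in every training split",
                 call. = FALSE)
        pcs <- fitPCA(A[tr, , drop = FALSE],
                      min(maxRank, length(tr) - 1L, ncol(A)))
        Str <- pcs@scores
        Sva <- projectPCA(pcs, A[va, , drop = FALSE])
        for (j in nrpcsSet) {
            if (j > ncol(Str)) next
            fit <- ldaTrain(Str[, seq_len(j), drop = FALSE], labels[tr])
            key <- as.character(j)
            res[[key]]$train <- c(res[[key]]$train,
                mean(ldaPredict(fit, Str[, seq_len(j), drop = FALSE]) ==
                         labels[tr]))
            res[[key]]$pred[va] <-
                ldaPredict(fit, Sva[, seq_len(j), drop = FALSE])
        }
    }
    res
}

#' Select the number of principal components for PCA-LDA
#'
#' Runs PCA-LDA classification under the grouped fold plan for every
#' candidate component count `1..maxPcs` (capped, with a warning, at what
#' the training splits support) and records training and validation
#' accuracy. Selection order: (1) highest validation accuracy, (2) smallest
#' absolute gap between training and validation accuracy, (3) smallest
#' component count. The full candidate table is returned for audit.
#'
#' @param x A [SpectraSet-class] (pretreated).
#' @param labels class labels per scan row (e.g. fermentation time), factor
#'   or coercible.
#' @param plan A [FoldPlan-class].
#' @param maxPcs candidate upper bound (default 30).
#' @return list with `nrpcs` (selected count) and `table` (data.frame of
#'   `nrpcs`, `train`, `val`, `gap` in percent).
#' @export
selectNrPCs <- function(x, labels, plan, maxPcs = 30L) {
    stopIfNot(maxPcs >= 1, "maxPcs must be >= 1")
    A <- absorbance(x)
    labels <- as.factor(labels)
    stopIfNot(nlevels(labels) >= 2, "need >= 2 classes")
    minTrain <- min(table(plan@fold))
    cap <- min(nrow(A) - minTrain - 1L, ncol(A))
    if (maxPcs > cap) {
        warning("maxPcs capped at ", cap, " (training-split rank limit)")
        maxPcs <- cap
    }
    cand <- seq_len(maxPcs)
    cv <- .pcaLdaCV(A, labels, plan, cand, maxRank = maxPcs)
    tab <- data.frame(
        nrpcs = cand,
        train = vapply(cv, function(r) 100 * mean(r$train), 1),
        val = vapply(cv, function(r)
            100 * mean(r$pred == labels, na.rm = TRUE), 1))
    tab$gap <- abs(tab$train - tab$val)
    ord <- order(-tab$val, tab$gap, tab$nrpcs)
    list(nrpcs = tab$nrpcs[ord[1]], table = tab)
}

#' PCA-LDA classification of fermentation-time groups
#'
#' Per fold of the grouped plan, PCA is fit on the training rows only, the
#' training scores feed a linear discriminant with pooled within-class
#' covariance and equal priors, and the held-out rows are projected through
#' the training PCA and LDA and assigned to the nearest class. Calibration
#' accuracy is the mean training (resubstitution) accuracy over folds;
#' cross-validation accuracy pools all held-out predictions. A final
#' all-data PCA-LDA model supplies the canonical discriminant scores.
#'
#' @param x A [SpectraSet-class] (pretreated).
#' @param labels class labels per scan row.
#' @param nrpcs number of principal components retained.
#' @param plan A [FoldPlan-class].
#' @return A [ClassificationResult-class].
#' @export
pcaLdaClassify <- function(x, labels, nrpcs, plan) {
    A <- absorbance(x)
    labels <- as.factor(labels)
    stopIfNot(nlevels(labels) >= 2, "need >= 2 classes")
    stopIfNot(nrpcs >= 1, "nrpcs must be >= 1")
    cv <- .pcaLdaCV(A, labels, plan, nrpcs,
                    maxRank = nrpcs)[[as.character(nrpcs)]]
    folds <- sort(unique(plan@fold))
    foldTable <- data.frame(
        fold = folds,
        train = 100 * cv$train,
        val = vapply(folds, function(f)
            100 * mean(cv$pred[plan@fold == f] == labels[plan@fold == f]),
            1))
    confusion <- unclass(table(true = labels, predicted = cv$pred))
    full <- fitPCA(A, min(nrpcs, nrow(A) - 1L, ncol(A)))
    fit <- ldaTrain(full@scores, labels)
    canon <- full@scores %*% fit$canonical
    methods::new("ClassificationResult",
                 nrpcs = as.integer(nrpcs),
                 trainAccuracy = mean(foldTable$train),
                 cvAccuracy = 100 * mean(cv$pred == labels),
                 foldTable = foldTable, confusion = confusion,
                 cvPredicted = cv$pred, labels = labels,
                 canonicalScores = canon)
}
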