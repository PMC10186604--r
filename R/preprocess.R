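#' Fourth-root transform
#'
#' Replaces every non-missing intensity by its principal fourth root, the
#' variance-stabilizing transform of choice for untargeted LC-MS intensities
#' spanning many decades. Missingness is preserved.
#'
#' @param x a [MetaboSet-class] with nonnegative intensities.
#' @return a transformed MetaboSet.
#' @examples
#' sim <- simulateCohort(syntheticSpec(n_samples = 20, n_features = 10, seed = 1))
#' ft <- fourthRoot(sim$table)
#' @export
fourthRoot <- function(x) {
    a <- assay(x, "intensity")
    if (any(a < 0, na.rm = TRUE))
        stop("fourth root requires nonnegative intensities")
    assay(x, "intensity") <- a^0.25
    x
}

#' Remove features with batch-wise missingness above a threshold
#'
#' A feature is removed iff there exists at least one batch in which its
#' fraction of missing values strictly exceeds `threshold`. Features with no
#' missing values are never removed.
#'
#' @param x a [MetaboSet-class] with batch labels.
#' @param threshold maximum tolerated per-batch missing fraction
#'   (default 0.20; removal requires a strict excess).
#' @return list with `table` (filtered MetaboSet) and `removed_ids`.
#' @export
filterBatchMissingness <- function(x, threshold = 0.20) {
    batch <- sampleBatches(x)
    if (anyNA(batch)) stop("batch labels must not be missing")
    a <- assay(x, "intensity")
    miss <- is.na(a)
    worst <- rep(0, nrow(a))
    for (b in unique(batch)) {
        idx <- which(batch == b)
        if (!length(idx)) stop(sprintf("batch '%s' is empty", b))
        worst <- pmax(worst, rowMeans(miss[, idx, drop = FALSE]))
    }
    drop <- worst > threshold
    removed <- rownames(a)[drop]
    message(sprintf("filterBatchMissingness: removed %d of %d features (>%g%% missing in some batch)",
                    sum(drop), nrow(a), 100 * threshold))
    list(table = x[!drop, ], removed_ids = removed)
}

#' Impute missing intensities from batch minima
#'
#' Replaces each missing value by the minimum (or half the minimum) observed
#' value of that feature within the sample's batch, falling back to the
#' feature's global minimum when a whole (feature, batch) cell is missing.
#' Intended to run after [filterBatchMissingness()], mirroring the fill-in
#' step upstream peak-calling pipelines perform.
#'
#' @param x a [MetaboSet-class].
#' @param half logical; use half-minimum imputation.
#' @return a complete MetaboSet.
#' @export
imputeMissing <- function(x, half = FALSE) {
    a <- assay(x, "intensity")
    if (!anyNA(a)) return(x)
    batch <- sampleBatches(x)
    globalMin <- apply(a, 1L, min, na.rm = TRUE)
    if (any(!is.finite(globalMin)))
        stop("features with no observed values cannot be imputed; filter them first")
    for (b in unique(batch)) {
        idx <- which(batch == b)
        sub <- a[, idx, drop = FALSE]
        if (!anyNA(sub)) next
        bmin <- suppressWarnings(apply(sub, 1L, min, na.rm = TRUE))
        bmin[!is.finite(bmin)] <- globalMin[!is.finite(bmin)]
        fill <- if (half) bmin / 2 else bmin
        na <- which(is.na(sub), arr.ind = TRUE)
        sub[na] <- fill[na[, 1L]]
        a[, idx] <- sub
    }
    assay(x, "intensity") <- a
    x
}

#' Remove PCA outlier samples
#'
#' Computes a centered PCA of the samples-by-features matrix and removes, in
#' a single pass, every sample whose score on any of the first
#' `n_components` components deviates from that component's median score by
#' more than `k` times a high quantile of those absolute deviations
#' (`mode = "deviation"`, the default reading of "more than 1.5 * 95th
#' quantile away from the median"). `mode = "score"` instead thresholds at
#' `k` times the distance from the median to the `q` quantile of the scores
#' themselves.
#'
#' @param x a complete [MetaboSet-class] (impute first).
#' @param n_components number of leading components inspected (default 12).
#' @param k deviation multiplier (default 1.5).
#' @param q quantile level (default 0.95).
#' @param mode `"deviation"` or `"score"`; see Details.
#' @return list with `table` (survivors) and `removed_ids`.
#' @export
removePcaOutliers <- function(x, n_components = 12L, k = 1.5, q = 0.95,
                              mode = c("deviation", "score")) {
    mode <- match.arg(mode)
    m <- intensityMatrix(x)
    if (anyNA(m))
        stop("PCA outlier removal requires a complete matrix; impute missing values first")
    n_components <- as.integer(n_components)
    if (ncol(m) < n_components)
        stop("fewer features than requested components")
    if (nrow(m) < n_components + 1L)
        stop("need at least n_components + 1 samples")
    pc <- prcomp(m, center = TRUE, scale. = FALSE, rank. = n_components)
    scores <- pc$x
    out <- rep(FALSE, nrow(m))
    for (j in seq_len(ncol(scores))) {
        s <- scores[, j]
        dev <- abs(s - median(s))
        thr <- switch(mode,
            deviation = k * quantile(dev, q, names = FALSE),
            score = k * (quantile(s, q, names = FALSE) - median(s)))
        out <- out | (dev > thr)
    }
    removed <- rownames(m)[out]
    message(sprintf("removePcaOutliers: removed %d of %d samples", sum(out), nrow(m)))
    list(table = x[, !out], removed_ids = removed)
}

#' Select rank-stable ("robust") features
#'
#' Within each sample, features are ranked by intensity (average ranks on
#' ties, missing values excluded from ranking). A feature is selected iff
#' (a) its median rank across samples lies within the `[lower_q, upper_q]`
#' quantiles of all features' median ranks, and (b) its max-min rank range
#' lies within the same quantiles of all features' ranges; both bounds
#' inclusive, quantiles computed by linear interpolation. With fully tied
#' inputs every feature has an identical (median, range) pair, so all
#' features are selected — the inclusive-bounds policy is the deterministic
#' tie rule.
#'
#' @param x a [MetaboSet-class] with no fully-missing feature.
#' @param lower_q,upper_q quantile bounds (defaults 0.20, 0.80).
#' @return a [RobustFeatureSet-class].
#' @export
selectRobustFeatures <- function(x, lower_q = 0.20, upper_q = 0.80) {
    a <- assay(x, "intensity")
    if (nrow(a) < 5L) stop("need at least 5 features")
    if (any(rowSums(!is.na(a)) == 0L))
        stop("fully-missing features present; filter them first")
    ranks <- apply(a, 2L, rank, ties.method = "average", na.last = "keep")
    med <- apply(ranks, 1L, median, na.rm = TRUE)
    rng <- apply(ranks, 1L, function(r) diff(range(r, na.rm = TRUE)))
    bMed <- quantile(med, c(lower_q, upper_q), names = FALSE)
    bRng <- quantile(rng, c(lower_q, upper_q), names = FALSE)
    sel <- med >= bMed[1L] & med <= bMed[2L] & rng >= bRng[1L] & rng <= bRng[2L]
    new("RobustFeatureSet",
        ids = rownames(a)[sel], median_ranks = med[sel], rank_ranges = rng[sel],
        quantile_bounds = rbind(median = bMed, range = bRng),
        quantiles = c(lower_q, upper_q))
}

setMethod("show", "RobustFeatureSet", function(object) {
    cat(sprintf("RobustFeatureSet: %d features (quantile bounds %.2f-%.2f)\n",
                length(object@ids), object@quantiles[1L], object@quantiles[2L]))
})

#' Robust row normalization
#'
#' Divides each sample's non-missing intensities by that sample's sum over
#' the robust feature subset, cancelling per-sample dilution exactly. After
#' normalization every sample sums to 1 over the robust subset.
#'
#' @param x a [MetaboSet-class].
#' @param robust a [RobustFeatureSet-class] from [selectRobustFeatures()].
#' @return a normalized MetaboSet.
#' @export
rowNormalize <- function(x, robust) {
    a <- assay(x, "intensity")
    ids <- intersect(robust@ids, rownames(a))
    if (!length(ids)) stop("no robust features present in the table")
    sums <- colSums(a[ids, , drop = FALSE], na.rm = TRUE)
    bad <- which(sums <= 0 | !is.finite(sums))
    if (length(bad))
        stop(sprintf("zero robust-feature sum for sample(s): %s",
                     paste(colnames(a)[bad], collapse = ", ")))
    assay(x, "intensity") <- sweep(a, 2L, sums, "/")
    x
}

#' Quantile normalization across samples
#'
#' Forces every sample's intensity distribution to the common distribution of
#' rank means (ties averaged), via [limma::normalizeQuantiles()]. Requires a
#' complete matrix.
#'
#' @param x a complete [MetaboSet-class].
#' @return a normalized MetaboSet.
#' @export
quantileNormalize <- function(x) {
    a <- assay(x, "intensity")
    if (anyNA(a))
        stop("quantile normalization requires a complete matrix; impute first")
    q <- limma::normalizeQuantiles(a, ties = TRUE)
    dimnames(q) <- dimnames(a)
    assay(x, "intensity") <- q
    x
}

#' Random train/development/test partition
#'
#' @param x a [MetaboSet-class] or a character vector of sample ids.
#' @param fractions three fractions summing to 1 (default 0.8/0.1/0.1).
#' @param seed integer seed; the same seed reproduces the split.
#' @return a [SplitSpec-class]; partition sizes are within 1 of
#'   `fractions * n` (largest-remainder apportionment).
#' @export
splitSamples <- function(x, fractions = c(0.8, 0.1, 0.1), seed = 1L) {
    ids <- if (is.character(x)) x else sampleIds(x)
    if (abs(sum(fractions) - 1) > 1e-8)
        stop("'fractions' must sum to 1")
    if (length(fractions) != 3L)
        stop("'fractions' must have length 3 (train, dev, test)")
    n <- length(ids)
    base <- floor(fractions * n)
    rem <- fractions * n - base
    extra <- order(rem, decreasing = TRUE)[seq_len(n - sum(base))]
    sizes <- base
    sizes[extra] <- sizes[extra] + 1L
    set.seed(seed)
    shuffled <- sample(ids)
    new("SplitSpec",
        train_ids = shuffled[seq_len(sizes[1L])],
        dev_ids = shuffled[sizes[1L] + seq_len(sizes[2L])],
        test_ids = shuffled[sizes[1L] + sizes[2L] + seq_len(sizes[3L])],
        fractions = fractions, seed = as.integer(seed))
}

setMethod("show", "SplitSpec", function(object) {
    cat(sprintf("SplitSpec: train %d / dev %d / test %d (seed %d)\n",
                length(object@train_ids), length(object@dev_ids),
                length(object@test_ids), object@seed))
})
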