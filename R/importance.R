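#' Model-agnostic Shapley attributions
#'
#' Estimates, for each (sample, feature), the signed contribution of that
#' feature to the sample's predicted age, relative to the expected
#' prediction over a background set. Two estimators are used: exact subset
#' enumeration for at most `exact_limit` features, and a permutation-walk
#' estimator above that. Both satisfy local additivity — per sample,
#' `baseline + rowSums(values)` equals the model prediction up to floating
#' error (exact) or Monte Carlo pairing error (the permutation walk
#' telescopes exactly, so additivity holds at machine precision there too).
#'
#' Shapley values are linear in the model, so attributing the ensemble-mean
#' predictor (the `EnsembleModel` method) equals averaging per-member
#' attribution matrices computed with the same estimator draws.
#'
#' @param model a fitted [RatioNet-class], an [EnsembleModel-class] (the
#'   ensemble-mean function is attributed), or a plain `function(X)`
#'   returning one prediction per row.
#' @param background a [MetaboSet-class] or matrix of background samples
#'   (typically training data); subsampled to `n_background` rows.
#' @param samples a [MetaboSet-class] or matrix of samples to explain
#'   (typically the test partition).
#' @param n_background background rows used by the estimator (default 100).
#' @param n_perm permutation walks per sample for the sampling estimator.
#' @param exact_limit feature count up to which exact enumeration is used.
#' @param seed seed for background subsampling and permutation draws.
#' @param member_id label stored in the result.
#' @param ... passed through by the generic.
#' @return an [AttributionMatrix-class] (samples x features, years).
#' @export
#' @rdname attributeModel
setMethod("attributeModel", "ANY",
          function(model, background, samples, n_background = 100L,
                   n_perm = 10L, exact_limit = 12L, seed = 1L,
                   member_id = "model", ...) {
    f <- .asPredictFun(model)
    B <- .asXY(background)$X
    X <- .asXY(samples)$X
    if (ncol(B) != ncol(X))
        stop("background and samples must share feature columns")
    if (!is.null(colnames(B)) && !is.null(colnames(X)) &&
        !identical(colnames(B), colnames(X)))
        stop("background and sample feature names disagree")
    if (nrow(B) < 1L) stop("background must be non-empty")
    set.seed(seed)
    if (nrow(B) > n_background)
        B <- B[sample.int(nrow(B), n_background), , drop = FALSE]
    n <- ncol(X)
    vals <- if (n <= exact_limit)
        .shapExact(f, B, X) else .shapPermutation(f, B, X, n_perm)
    dimnames(vals) <- list(rownames(X), colnames(X))
    new("AttributionMatrix", values = vals, baseline = mean(f(B)),
        member_id = member_id)
})

.asPredictFun <- function(model) {
    if (is.function(model)) return(model)
    if (is(model, "RatioNet")) return(function(X) predictRatioNet(model, X))
    if (is(model, "EnsembleModel"))
        return(function(X) rowMeans(vapply(model@members, predictRatioNet,
                                           numeric(nrow(X)), x = X)))
    stop("unsupported model type")
}

# Exact Shapley values by enumeration of all 2^n feature subsets; the value
# of a coalition is the mean prediction over composites that take coalition
# features from the explicand and the rest from each background row.
.shapExact <- function(f, B, X) {
    n <- ncol(X); m <- nrow(B)
    subsets <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), n)))
    nS <- nrow(subsets)
    sizes <- rowSums(subsets)
    id <- as.integer(subsets %*% 2^(seq_len(n) - 1L))
    w <- exp(lfactorial(sizes) + lfactorial(n - 1L - sizes) - lfactorial(n))
    bigMask <- subsets[rep(seq_len(nS), each = m), , drop = FALSE]
    Brep <- B[rep(seq_len(m), nS), , drop = FALSE]
    out <- matrix(0, nrow(X), n)
    for (s in seq_len(nrow(X))) {
        comp <- Brep
        x <- X[s, ]
        for (j in seq_len(n)) comp[bigMask[, j], j] <- x[j]
        vRaw <- colMeans(matrix(f(comp), m, nS))
        v <- numeric(nS)
        v[id + 1L] <- vRaw    # value function indexed by coalition bitmask

        for (i in seq_len(n)) {
            off <- !subsets[, i]
            id0 <- id[off]
            out[s, i] <- sum(w[off] * (v[id0 + 2^(i - 1L) + 1L] - v[id0 + 1L]))
        }
    }
    out
}

# Permutation-walk estimator: for each (permutation, background row) pair,
# features are switched from the background value to the explicand value in
# permutation order and the prediction deltas are credited to the switched
# feature. Each walk telescopes from the background prediction to the
# explicand prediction, so additivity is exact.
.shapPermutation <- function(f, B, X, n_perm) {
    n <- ncol(X); m <- nrow(B)
    out <- matrix(0, nrow(X), n)
    perms <- replicate(n_perm, sample.int(n), simplify = FALSE)
    masks <- lapply(perms, function(p) {
        pos <- match(seq_len(n), p)
        outer(seq_len(n + 1L), pos, ">")      # (n+1) x n inclusion mask
    })
    for (s in seq_len(nrow(X))) {
        x <- X[s, ]
        Xrow <- matrix(x, n + 1L, n, byrow = TRUE)
        blocks <- vector("list", n_perm * m)
        bi <- 1L
        for (pi in seq_len(n_perm)) {
            M <- masks[[pi]]
            for (b in seq_len(m)) {
                comp <- matrix(B[b, ], n + 1L, n, byrow = TRUE)
                comp[M] <- Xrow[M]
                blocks[[bi]] <- comp
                bi <- bi + 1L
            }
        }
        preds <- f(do.call(rbind, blocks))
        acc <- numeric(n)
        bi <- 0L
        for (pi in seq_len(n_perm)) {
            p <- perms[[pi]]
            for (b in seq_len(m)) {
                fw <- preds[bi + seq_len(n + 1L)]
                bi <- bi + n + 1L
                acc[p] <- acc[p] + diff(fw)
            }
        }
        out[s, ] <- acc / (n_perm * m)
    }
    out
}

#' Average attribution matrices
#'
#' Elementwise arithmetic mean of per-member attribution matrices (and
#' baselines), yielding the ensemble attribution.
#'
#' @param matrices list of [AttributionMatrix-class] with identical shapes.
#' @return an [AttributionMatrix-class] labelled `"ensemble-mean"`.
#' @export
averageAttributions <- function(matrices) {
    stopifnot(length(matrices) >= 1L)
    dims <- lapply(matrices, function(m) dim(m@values))
    if (!all(vapply(dims, identical, TRUE, dims[[1L]])))
        stop("attribution matrices must share the same shape")
    vals <- Reduce(`+`, lapply(matrices, slot, "values")) / length(matrices)
    base <- mean(vapply(matrices, slot, 0, "baseline"))
    new("AttributionMatrix", values = vals, baseline = base,
        member_id = "ensemble-mean")
}

#' Variance-based global feature importance
#'
#' A feature whose attribution varies strongly across samples drives
#' predictions; global importance is the per-feature variance of the
#' attribution column (sample variance, n - 1 denominator).
#'
#' @param m an [AttributionMatrix-class] with at least 2 samples.
#' @return data.frame sorted by descending importance: `id`, `importance`,
#'   `rank`.
#' @export
globalImportance <- function(m) {
    v <- m@values
    if (nrow(v) < 2L) stop("need at least 2 samples")
    imp <- apply(v, 2L, var)
    ord <- order(imp, decreasing = TRUE)
    data.frame(id = colnames(v)[ord], importance = imp[ord],
               rank = seq_along(imp), row.names = NULL)
}

#' Concordance of attributions with raw intensity trends
#'
#' The ratio architecture can, in principle, assign importance to
#' normalizing features, or interpret a feature inversely to its raw trend
#' (as reported for cortisol and 17:0 LysoPC). Per feature this diagnostic
#' computes the Spearman correlation of attribution vs intensity and of
#' intensity vs age, and flags features whose two correlation signs
#' disagree while both are clearly non-zero.
#'
#' @param m an [AttributionMatrix-class].
#' @param x the [MetaboSet-class] holding the same samples and features
#'   (ages are taken from its `colData` unless `ages` is given).
#' @param ages optional numeric ages.
#' @param min_abs_rho magnitude below which a correlation is treated as
#'   "no trend" and no flag is raised (default 0.1).
#' @return data.frame per feature: the two correlations, their signs,
#'   `concordant` (TRUE/FALSE/NA when either trend is below threshold) and
#'   `incomputable` for constant columns.
#' @export
shapIntensityConcordance <- function(m, x, ages = NULL, min_abs_rho = 0.1) {
    ids <- colnames(m@values)
    X <- intensityMatrix(x)
    if (!all(ids %in% colnames(X)))
        stop("attribution features missing from the table")
    if (is.null(ages)) ages <- sampleAges(x)
    samp <- rownames(m@values)
    if (!is.null(samp) && all(samp %in% rownames(X))) {
        Xs <- X[samp, ids, drop = FALSE]
    } else {
        if (nrow(X) != nrow(m@values))
            stop("attribution and intensity sample counts disagree")
        Xs <- X[, ids, drop = FALSE]
    }
    res <- lapply(seq_along(ids), function(j) {
        att <- m@values[, j]
        int <- Xs[, j]
        okA <- !is.na(att) & !is.na(int)
        okI <- !is.na(int) & !is.na(ages)
        consA <- sum(okA) < 3L || sd(att[okA]) == 0 || sd(int[okA]) == 0
        consI <- sum(okI) < 3L || sd(int[okI]) == 0 || sd(ages[okI]) == 0
        rAI <- if (consA) NA_real_ else
            cor(att[okA], int[okA], method = "spearman")
        rIA <- if (consI) NA_real_ else
            cor(int[okI], ages[okI], method = "spearman")
        conc <- if (is.na(rAI) || is.na(rIA) || abs(rAI) < min_abs_rho ||
                    abs(rIA) < min_abs_rho) NA else sign(rAI) == sign(rIA)
        data.frame(id = ids[j], rho_attr_intensity = rAI,
                   rho_intensity_age = rIA,
                   sign_attr = sign(rAI), sign_intensity_age = sign(rIA),
                   concordant = conc, incomputable = consA && consI)
    })
    do.call(rbind, res)
}

setMethod("show", "AttributionMatrix", function(object) {
    cat(sprintf("AttributionMatrix [%s]: %d samples x %d features, baseline %.2f years\n",
                object@member_id, nrow(object@values), ncol(object@values),
                object@baseline))
})
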