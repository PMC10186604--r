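# Shared fixtures: tiny feature tables built in code.

# Minimal MetaboSet from a samples x features matrix with given ages/batches.
makeTable <- function(x, ages = NULL, batches = NULL) {
    n <- nrow(x)
    if (is.null(ages)) ages <- seq(20, 60, length.out = n)
    if (is.null(batches)) batches <- rep("b1", n)
    if (is.null(rownames(x))) rownames(x) <- sprintf("s%02d", seq_len(n))
    if (is.null(colnames(x))) colnames(x) <- sprintf("f%02d", seq_len(ncol(x)))
    MetaboSet(x, data.frame(age = ages, batch = batches))
}

# Small clean cohort (no dilution/batch/missingness) with planted signal.
cleanCohort <- function(n_samples = 200, n_features = 30, n_informative = 8,
                        seed = 42, effect = c(0.45, 0.55)) {
    simulateCohort(syntheticSpec(
        n_samples = n_samples, n_features = n_features, n_batches = 4,
        n_informative = n_informative, dilution_cv = 0, batch_shift_sd = 0,
        missing_rate_range = c(0, 0), effect_size_range = effect,
        seed = seed))
}

# Independent step-up BH implementation used as oracle.
bruteForceBH <- function(p) {
    m <- length(p)
    o <- order(p)
    ps <- p[o]
    q <- ps * m / seq_len(m)
    q <- rev(cummin(rev(q)))
    q <- pmin(q, 1)
    out <- numeric(m)
    out[o] <- q
    out
}

# Closed-form Shapley values of a linear model f(x) = b0 + sum(w * x)
# against a background matrix with independent treatment of features.
linearShapley <- function(w, x, B) {
    w * (x - colMeans(B))
}
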