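#' Feature-wise Spearman correlation with age
#'
#' Computes tie-corrected Spearman rho of every feature against age, with a
#' two-sided p-value from the large-sample t approximation
#' (`t = rho * sqrt((n-2)/(1-rho^2))`); for fewer than 10 complete pairs the
#' p-value is computed by exact enumeration of all rank permutations.
#' Missing intensities are excluded pairwise per feature; features with
#' fewer than 3 complete pairs are flagged and get `NA` statistics.
#' Benjamini-Hochberg q-values are attached.
#'
#' @param x a [MetaboSet-class] with `age` in `colData`.
#' @return data.frame with one row per feature: `id`, `n`, `rho`, `p_value`,
#'   `q_value`, `flagged`.
#' @export
spearmanVsAge <- function(x) {
    age <- sampleAges(x)
    if (is.null(age) || all(is.na(age)))
        stop("age metadata is required")
    if (sum(!is.na(age)) < 3L)
        stop("need at least 3 samples with age")
    a <- assay(x, "intensity")
    res <- t(apply(a, 1L, function(v) .spearmanTest(v, age)))
    out <- data.frame(id = rownames(a), n = as.integer(res[, 1L]),
                      rho = res[, 2L], p_value = res[, 3L],
                      flagged = res[, 1L] < 3 | is.na(res[, 2L]),
                      row.names = NULL)
    out$q_value <- bhFdr(out$p_value)
    out[, c("id", "n", "rho", "p_value", "q_value", "flagged")]
}

.spearmanTest <- function(v, age) {
    ok <- !is.na(v) & !is.na(age)
    n <- sum(ok)
    if (n < 3L) return(c(n, NA_real_, NA_real_))
    rx <- rank(v[ok]); ry <- rank(age[ok])
    if (sd(rx) == 0 || sd(ry) == 0) return(c(n, NA_real_, NA_real_))
    rho <- cor(rx, ry)
    if (n < 10L) {
        p <- .spearmanExactP(rx, ry, rho)
    } else {
        r2 <- min(abs(rho), 1 - 1e-12)
        tstat <- r2 * sqrt((n - 2) / (1 - r2^2))
        p <- 2 * pt(tstat, n - 2, lower.tail = FALSE)
    }
    c(n, rho, min(p, 1))
}

# Exact two-sided permutation p-value by full enumeration of rank orders.
.spearmanExactP <- function(rx, ry, rho) {
    n <- length(rx)
    perms <- .allPermsCached(n)
    rxP <- matrix(rx[perms], nrow(perms), n)
    rhos <- (rxP %*% ry - n * mean(rx) * mean(ry)) /
        ((n - 1) * sd(rx) * sd(ry))
    mean(abs(rhos) >= abs(rho) - 1e-12)
}

.permCache <- new.env(parent = emptyenv())

.allPermsCached <- function(n) {
    key <- as.character(n)
    if (is.null(.permCache[[key]])) .permCache[[key]] <- .allPerms(n)
    .permCache[[key]]
}

.allPerms <- function(n) {
    if (n == 1L) return(matrix(1L, 1L, 1L))
    sub <- .allPerms(n - 1L)
    out <- matrix(0L, n * nrow(sub), n)
    r <- 0L
    for (k in seq_len(n)) {
        rows <- r + seq_len(nrow(sub))
        out[rows, 1L] <- k
        out[rows, -1L] <- ifelse(sub >= k, sub + 1L, sub)
        r <- r + nrow(sub)
    }
    out
}

#' Benjamini-Hochberg step-up q-values
#'
#' Step-up adjustment `q_(i) = min_(j >= i) p_(j) * m / j`, capped at 1 and
#' mapped back to the input order (delegates to
#' [stats::p.adjust()][stats::p.adjust], method `"BH"`). `NA` p-values
#' propagate to `NA` q-values without affecting the other adjustments.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return q-values in input order.
#' @examples
#' bhFdr(c(0.01, 0.02, 0.03, 0.04))  # all 0.04
#' @export
bhFdr <- function(p) {
    ok <- !is.na(p)
    if (any(p[ok] < 0 | p[ok] > 1))
        stop("p-values must lie in [0, 1]")
    out <- rep(NA_real_, length(p))
    out[ok] <- p.adjust(p[ok], method = "BH")
    out
}

#' Age-decile intensity profiles
#'
#' Bins samples into age deciles (sample-count quantiles of age), computes
#' each feature's mean intensity per decile, and standardizes the ten means
#' per feature to mean 0, SD 1. A hierarchical ordering of the requested
#' features by profile similarity (Euclidean distance, complete linkage) is
#' returned for display.
#'
#' @param x a [MetaboSet-class] with at least 10 aged samples.
#' @param feature_ids features to profile (default: all).
#' @param n_bins number of age bins (default 10).
#' @return list with `z` (features x deciles matrix of z-scored decile
#'   means; constant features are flagged and zeroed), `flagged` (logical
#'   per feature), and `order` (display order from hierarchical clustering).
#' @export
decileProfile <- function(x, feature_ids = featureIds(x), n_bins = 10L) {
    age <- sampleAges(x)
    if (sum(!is.na(age)) < n_bins)
        stop(sprintf("need at least %d samples with age", n_bins))
    a <- assay(x, "intensity")[feature_ids, , drop = FALSE]
    qs <- quantile(age, probs = seq(0, 1, length.out = n_bins + 1L),
                   na.rm = TRUE, names = FALSE)
    bin <- cut(age, unique(qs), include.lowest = TRUE)
    means <- t(apply(a, 1L, function(v) tapply(v, bin, mean, na.rm = TRUE)))
    zrow <- function(m) {
        s <- sd(m, na.rm = TRUE)
        if (is.na(s) || s == 0) return(rep(0, length(m)))
        (m - mean(m, na.rm = TRUE)) / s
    }
    z <- t(apply(means, 1L, zrow))
    dimnames(z) <- list(feature_ids, levels(bin))
    flagged <- apply(means, 1L, function(m) {
        s <- sd(m, na.rm = TRUE); is.na(s) || s == 0
    })
    ord <- if (nrow(z) > 2L) hclust(dist(z))$order else seq_len(nrow(z))
    list(z = z, flagged = flagged, order = ord)
}
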