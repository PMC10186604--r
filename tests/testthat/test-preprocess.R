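test_that("fourth root transforms values and preserves missingness", {
    x <- matrix(c(16, 0, 81, 256, NA, 1), 2, 3)
    ms <- makeTable(x)
    out <- intensityMatrix(fourthRoot(ms))
    expect_equal(as.numeric(out), c(2, 0, 3, 4, NA, 1))
    neg <- makeTable(matrix(c(1, 2, 3, 4), 2, 2))
    assay(neg, "intensity")[1, 1] <- -1
    expect_error(fourthRoot(neg), "nonnegative")
})

test_that("batch missingness filter removes strictly above threshold per batch", {
    # 10 samples, 2 batches of 5; f1 misses 2/5 in batch 1 (40%) -> removed;
    # f2 misses exactly 1/5 in each batch (20%) -> kept; f3 complete -> kept
    x <- matrix(runif(30, 1, 10), 10, 3,
                dimnames = list(paste0("s", 1:10), c("f1", "f2", "f3")))
    x[1:2, "f1"] <- NA
    x[c(1, 6), "f2"] <- NA
    ms <- makeTable(x, batches = rep(c("b1", "b2"), each = 5))
    res <- suppressMessages(filterBatchMissingness(ms, threshold = 0.20))
    expect_identical(res$removed_ids, "f1")
    expect_identical(featureIds(res$table), c("f2", "f3"))
    # no missing values anywhere -> nothing removed
    clean <- makeTable(matrix(runif(40, 1, 2), 10, 4),
                       batches = rep(c("b1", "b2"), each = 5))
    expect_length(suppressMessages(filterBatchMissingness(clean))$removed_ids, 0L)
})

test_that("PCA outlier rule removes gross outliers and spares clean data", {
    set.seed(1)
    x <- matrix(rlnorm(40 * 20, 5, 0.2), 40, 20)
    x[7, ] <- x[7, ] * 100
    ms <- makeTable(x)
    res <- suppressMessages(removePcaOutliers(ms, n_components = 5))
    expect_true("s07" %in% res$removed_ids)
    # k -> infinity removes nothing
    res2 <- suppressMessages(removePcaOutliers(ms, n_components = 5, k = 1e9))
    expect_length(res2$removed_ids, 0L)
    # single pass is not rerun on survivors: applying again may remove more
    surv <- suppressMessages(removePcaOutliers(res$table, n_components = 5))
    expect_true(is.character(surv$removed_ids))
    expect_error(removePcaOutliers(makeTable(matrix(NA_real_, 20, 15))),
                 "impute")
})

test_that("robust feature selection matches brute-force rank arithmetic", {
    # 4 samples x 6 features, hand-checkable
    x <- rbind(c(1, 2, 3, 4, 5, 6),
               c(2, 1, 3, 4, 6, 5),
               c(1, 3, 2, 4, 5, 6),
               c(2, 1, 4, 3, 5, 6))
    ms <- makeTable(x)
    rob <- selectRobustFeatures(ms)
    ranks <- apply(t(intensityMatrix(ms)), 2, rank)
    med <- apply(ranks, 1, median)
    rng <- apply(ranks, 1, function(r) diff(range(r)))
    bm <- quantile(med, c(0.2, 0.8)); br <- quantile(rng, c(0.2, 0.8))
    manual <- featureIds(ms)[med >= bm[1] & med <= bm[2] &
                             rng >= br[1] & rng <= br[2]]
    expect_identical(rob@ids, manual)
})

test_that("a feature that is always the maximum is excluded by the median criterion", {
    set.seed(2)
    x <- matrix(runif(10 * 8, 1, 5), 10, 8)
    x[, 8] <- 100 + runif(10)    # always rank 8, range 0
    ms <- makeTable(x)
    rob <- selectRobustFeatures(ms)
    expect_false("f08" %in% rob@ids)
})

test_that("fully tied tables select all features (deterministic tie policy)", {
    # every sample has all features tied, so all ranks are the average rank
    x <- matrix(rep(c(1, 2, 3, 4), times = 5), 4, 5)
    ms <- makeTable(x)
    rob <- selectRobustFeatures(ms)
    expect_identical(rob@ids, featureIds(ms))
})

test_that("rank statistics are invariant to the fourth-root transform", {
    set.seed(3)
    x <- matrix(rlnorm(20 * 12, 8, 1), 20, 12)
    ms <- makeTable(x)
    expect_identical(selectRobustFeatures(ms)@ids,
                     selectRobustFeatures(fourthRoot(ms))@ids)
})

test_that("row normalization divides by robust-subset sums exactly", {
    x <- rbind(c(1, 1, 1, 1), c(2, 4, 2, 8), c(3, 6, 3, 12))
    ms <- makeTable(x)
    rob <- new("RobustFeatureSet", ids = c("f01", "f03"),
               median_ranks = c(1, 2), rank_ranges = c(0, 0),
               quantile_bounds = rbind(median = c(0, 1), range = c(0, 1)),
               quantiles = c(0.2, 0.8))
    out <- intensityMatrix(rowNormalize(ms, rob))
    expect_equal(out, x / rowSums(x[, c(1, 3)]), ignore_attr = TRUE)
    expect_equal(unname(rowSums(out[, c(1, 3)])), rep(1, 3))
    # scalar-multiple samples become identical rows
    expect_equal(out[2, ] / out[3, ], rep(1, 4), ignore_attr = TRUE)
})

test_that("row normalization cancels per-sample positive scaling exactly", {
    set.seed(4)
    x <- matrix(rlnorm(15 * 10, 3, 1), 15, 10)
    ms <- makeTable(x)
    rob <- selectRobustFeatures(ms)
    cs <- runif(15, 0.2, 5)
    msScaled <- makeTable(x * cs)
    expect_equal(intensityMatrix(rowNormalize(ms, rob)),
                 intensityMatrix(rowNormalize(msScaled, rob)),
                 tolerance = 1e-12)
    # zero robust sum errors naming the sample
    x2 <- x; x2[3, ] <- 0
    expect_error(rowNormalize(makeTable(x2), rob), "s03")
})

test_that("quantile normalization equalizes row distributions and is idempotent", {
    ms <- makeTable(rbind(c(1, 2, 3), c(4, 5, 6)))
    out <- intensityMatrix(quantileNormalize(ms))
    expect_equal(sort(out[1, ]), c(2.5, 3.5, 4.5), ignore_attr = TRUE)
    expect_equal(sort(out[1, ]), sort(out[2, ]), ignore_attr = TRUE)
    set.seed(5)
    big <- makeTable(matrix(rlnorm(30 * 20), 30, 20))
    q1 <- quantileNormalize(big)
    q2 <- quantileNormalize(q1)
    expect_equal(intensityMatrix(q1), intensityMatrix(q2), tolerance = 1e-12)
    sorted <- apply(intensityMatrix(q1), 1, sort)
    expect_lt(max(sorted - sorted[, 1]), 1e-12)
    # identical samples are unchanged
    same <- makeTable(matrix(rep(c(1, 5, 9, 2), 4), 4, 4, byrow = TRUE))
    expect_equal(intensityMatrix(quantileNormalize(same)),
                 intensityMatrix(same))
})

test_that("splitting is exhaustive, disjoint, sized and seed-reproducible", {
    ms <- makeTable(matrix(runif(100 * 5), 100, 5))
    sp <- splitSamples(ms, seed = 8)
    expect_length(sp@train_ids, 80L)
    expect_length(sp@dev_ids, 10L)
    expect_length(sp@test_ids, 10L)
    all_ids <- c(sp@train_ids, sp@dev_ids, sp@test_ids)
    expect_setequal(all_ids, sampleIds(ms))
    expect_false(anyDuplicated(all_ids) > 0)
    expect_identical(splitSamples(ms, seed = 8)@train_ids, sp@train_ids)
    differs <- vapply(1:10, function(s)
        !identical(splitSamples(ms, seed = s)@train_ids,
                   splitSamples(ms, seed = s + 100)@train_ids), TRUE)
    expect_true(all(differs))
    expect_error(splitSamples(ms, fractions = c(0.7, 0.2, 0.2)), "sum to 1")
})

test_that("imputation fills batch-wise minima and leaves observed values alone", {
    x <- rbind(c(NA, 2, 3), c(4, 5, 6), c(7, 8, NA), c(10, 11, 12))
    ms <- makeTable(x, batches = c("b1", "b1", "b2", "b2"))
    out <- intensityMatrix(imputeMissing(ms))
    expect_equal(out[1, 1], 4)      # batch-1 minimum of f01
    expect_equal(out[3, 3], 12)     # batch-2 minimum of f03
    expect_equal(out[2, ], x[2, ], ignore_attr = TRUE)
    outH <- intensityMatrix(imputeMissing(ms, half = TRUE))
    expect_equal(outH[1, 1], 2)
})

test_that("the alternative quantile-of-scores outlier reading is exposed", {
    set.seed(14)
    x <- matrix(rlnorm(30 * 15, 5, 0.3), 30, 15)
    x[4, ] <- x[4, ] * 50
    ms <- makeTable(x)
    res <- suppressMessages(removePcaOutliers(ms, n_components = 5,
                                              mode = "score"))
    expect_true("s04" %in% res$removed_ids)
})
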