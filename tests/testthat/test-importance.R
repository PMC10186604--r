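test_that("exact Shapley values match the linear-model closed form", {
    set.seed(30)
    w <- rnorm(8)
    f <- function(X) drop(X %*% w) + 5
    B <- matrix(rnorm(40 * 8), 40, 8)
    X <- matrix(rnorm(6 * 8), 6, 8)
    att <- attributeModel(f, B, X, n_background = 40, seed = 1)
    for (s in 1:6)
        expect_equal(unname(att@values[s, ]), linearShapley(w, X[s, ], B),
                     tolerance = 1e-10)
    expect_equal(att@baseline, mean(f(B)), tolerance = 1e-12)
})

test_that("permutation-walk Shapley matches the linear closed form too", {
    set.seed(31)
    w <- rnorm(15)
    f <- function(X) drop(X %*% w)
    B <- matrix(rnorm(30 * 15), 30, 15)
    X <- matrix(rnorm(4 * 15), 4, 15)
    # linear models: every permutation walk gives the exact same credit
    att <- attributeModel(f, B, X, n_background = 30, n_perm = 2,
                          exact_limit = 0, seed = 2)
    for (s in 1:4)
        expect_equal(unname(att@values[s, ]), linearShapley(w, X[s, ], B),
                     tolerance = 1e-10)
})

test_that("attribution additivity holds for nonlinear models", {
    set.seed(32)
    f <- function(X) drop(sin(X[, 1]) + X[, 2] * X[, 3] + exp(X[, 4] / 5))
    B <- matrix(rnorm(25 * 4), 25, 4)
    X <- matrix(rnorm(5 * 4), 5, 4)
    exact <- attributeModel(f, B, X, seed = 3)
    expect_equal(exact@baseline + rowSums(exact@values), f(X),
                 tolerance = 1e-10, ignore_attr = TRUE)
    walk <- attributeModel(f, B, X, exact_limit = 0, n_perm = 3, seed = 3)
    expect_equal(walk@baseline + rowSums(walk@values), f(X),
                 tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("constant and single-feature models attribute accordingly", {
    B <- matrix(runif(20 * 6), 20, 6)
    X <- matrix(runif(4 * 6), 4, 6)
    attC <- attributeModel(function(X) rep(3.3, nrow(X)), B, X, seed = 4)
    expect_true(all(abs(attC@values) < 1e-12))
    att1 <- attributeModel(function(X) X[, 2]^2, B, X, seed = 4)
    expect_true(all(abs(att1@values[, -2]) < 1e-12))
    expect_false(all(abs(att1@values[, 2]) < 1e-12))
})

test_that("averaging attribution matrices is elementwise", {
    mk <- function(v, b) new("AttributionMatrix",
                             values = matrix(v, 2, 2), baseline = b,
                             member_id = "m")
    a <- mk(1:4, 10); b <- mk(5:8, 20); c3 <- mk(9:12, 30)
    avg <- averageAttributions(list(a, b, c3))
    expect_equal(avg@values, matrix(c(5, 6, 7, 8), 2, 2))
    expect_equal(avg@baseline, 20)
    expect_identical(avg@member_id, "ensemble-mean")
    expect_equal(averageAttributions(list(a, a))@values, a@values)
    neg <- mk(-(1:4), -10)
    expect_equal(averageAttributions(list(a, neg))@values, matrix(0, 2, 2))
    expect_error(averageAttributions(list(a, new("AttributionMatrix",
        values = matrix(0, 3, 2), baseline = 0, member_id = "x"))),
        "shape")
})

test_that("global importance is the per-feature attribution variance", {
    m <- new("AttributionMatrix",
             values = cbind(f1 = c(-1, 1), f2 = c(0.5, 0.5), f3 = c(3, -3)),
             baseline = 0, member_id = "m")
    gi <- globalImportance(m)
    expect_equal(gi$importance[gi$id == "f1"], 2)   # var with n-1 denominator
    expect_equal(gi$importance[gi$id == "f2"], 0)
    expect_identical(gi$id, c("f3", "f1", "f2"))
    expect_equal(gi$rank, 1:3)
    expect_error(globalImportance(new("AttributionMatrix",
        values = matrix(1, 1, 2), baseline = 0, member_id = "m")),
        "2 samples")
})

test_that("ranking the average equals ranking of the averaged matrix", {
    set.seed(33)
    mats <- lapply(1:4, function(k) new("AttributionMatrix",
        values = matrix(rnorm(30), 10, 3,
                        dimnames = list(NULL, c("a", "b", "c"))),
        baseline = 0, member_id = as.character(k)))
    avg <- averageAttributions(mats)
    manual <- Reduce(`+`, lapply(mats, slot, "values")) / 4
    expect_identical(globalImportance(avg)$id,
                     colnames(manual)[order(apply(manual, 2, var),
                                            decreasing = TRUE)])
})

test_that("concordance flags follow attribution and intensity trends", {
    set.seed(34)
    n <- 60
    ages <- runif(n, 20, 60)
    up <- ages + rnorm(n, 0, 2)          # intensity rises with age
    noise <- runif(n, 1, 5)
    x <- cbind(conc = up, inv = up, flat = noise, const = rep(1, n))
    ms <- makeTable(x, ages = ages)
    vals <- cbind(conc = up * 0.5,       # attribution follows intensity
                  inv = -up * 0.5,       # inverse interpretation
                  flat = rnorm(n),       # independent attribution
                  const = rnorm(n))
    rownames(vals) <- sampleIds(ms)
    m <- new("AttributionMatrix", values = vals, baseline = 30,
             member_id = "m")
    cc <- shapIntensityConcordance(m, ms)
    expect_true(cc$concordant[cc$id == "conc"])
    expect_false(cc$concordant[cc$id == "inv"])    # the cortisol-like case
    expect_true(is.na(cc$concordant[cc$id == "flat"]))
    expect_true(is.na(cc$rho_intensity_age[cc$id == "const"]))
})

test_that("attributing an ensemble equals averaging member attributions", {
    # two tiny linear 'members' realized as plain functions
    set.seed(35)
    w1 <- rnorm(5); w2 <- rnorm(5)
    B <- matrix(rnorm(20 * 5), 20, 5)
    X <- matrix(rnorm(3 * 5), 3, 5)
    attMean <- attributeModel(function(M) (drop(M %*% w1) + drop(M %*% w2)) / 2,
                              B, X, seed = 5)
    a1 <- attributeModel(function(M) drop(M %*% w1), B, X, seed = 5)
    a2 <- attributeModel(function(M) drop(M %*% w2), B, X, seed = 5)
    expect_equal(attMean@values,
                 averageAttributions(list(a1, a2))@values, tolerance = 1e-10)
})
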