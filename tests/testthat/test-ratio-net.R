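test_that("ratio expansion enumerates lexicographic pairs", {
    expect_length(ratioExpand(rnorm(12)), 66L)
    expect_equal(ratioExpand(c(2, 4, 8)), c(0.5, 0.25, 0.5))
    expect_error(ratioExpand(5), "at least 2")
    for (n in c(2, 5, 9, 20))
        expect_length(ratioExpand(runif(n, 1, 2)), n * (n - 1) / 2)
})

test_that("ratios cancel positive scaling exactly when unstabilized", {
    set.seed(10)
    v <- rnorm(12)
    for (c in c(0.001, 0.5, 3, 1e4))
        expect_equal(ratioExpand(v * c), ratioExpand(v), tolerance = 1e-12)
})

test_that("network construction matches the closed-form parameter count", {
    cfg <- ratioNetConfig(seed = 2)
    net <- buildRatioNet(cfg, n_features = 500)
    # compression + offset, BN after ratios, two hidden (W,b,gamma,beta), out
    expected <- (500 * 12 + 12) + (2 * 66) +
        (66 * 33 + 33 + 2 * 33) + (33 * 33 + 33 + 2 * 33) + (33 * 1 + 1)
    expect_equal(nParameters(net), expected)
    expect_equal(buildRatioNet(cfg, 10)@arch$R, 66L)
    expect_equal(buildRatioNet(ratioNetConfig(n_compress = 2), 10)@arch$R, 1L)
})

test_that("building twice from one seed gives identical initial parameters", {
    cfg <- ratioNetConfig(seed = 77)
    expect_identical(buildRatioNet(cfg, 40)@params,
                     buildRatioNet(cfg, 40)@params)
})

test_that("zero-epoch training returns the initialized network", {
    cfg <- ratioNetConfig(epochs = 0, seed = 3, standardize_targets = FALSE)
    X <- matrix(runif(60 * 10, 1, 5), 60, 10)
    net <- trainRatioNet(X, rnorm(60, 30, 5), config = cfg)
    expect_identical(net@params, buildRatioNet(cfg, 10)@params)
    expect_equal(nrow(net@history), 0L)
})

test_that("training is deterministic given seeds and data", {
    sim <- cleanCohort(n_samples = 120, n_features = 15, n_informative = 5,
                       seed = 6)
    tab <- fourthRoot(sim$table)
    sp <- splitSamples(tab, seed = 1)
    cfg <- ratioNetConfig(epochs = 15, seed = 5, batch_size = 50)
    a <- trainRatioNet(tab[, sp@train_ids], dev_x = tab[, sp@dev_ids],
                       config = cfg)
    b <- trainRatioNet(tab[, sp@train_ids], dev_x = tab[, sp@dev_ids],
                       config = cfg)
    expect_identical(a@history, b@history)
    expect_identical(a@params, b@params)
})

test_that("analytic gradients agree with numerical differentiation", {
    cfg <- ratioNetConfig(n_compress = 3, hidden_sizes = c(4L, 4L),
                          dropout = 0, epochs = 0, seed = 3, batch_size = 8,
                          weight_decays = c(0, 0, 0, 0),
                          standardize_targets = FALSE)
    net <- buildRatioNet(cfg, 5)
    set.seed(11)
    X <- matrix(rnorm(8 * 5, 2, 1), 8, 5)
    y <- rnorm(8, 30, 5)
    params <- net@params; arch <- net@arch; bn <- net@bn_stats
    fw <- ratioAge:::.rnForward(params, arch, cfg, X, TRUE, bn)
    dy <- matrix(2 * (fw$yhat - y) / 8, ncol = 1)
    gr <- ratioAge:::.rnBackward(params, arch, cfg, fw, dy)
    lossAt <- function(pp) {
        f <- ratioAge:::.rnForward(pp, arch, cfg, X, TRUE, bn)
        mean((f$yhat - y)^2)
    }
    h <- 1e-6
    for (nm in names(gr)) {
        for (i in seq_len(min(length(gr[[nm]]), 4))) {
            pp <- params
            pp[[nm]][i] <- pp[[nm]][i] + h; up <- lossAt(pp)
            pp[[nm]][i] <- pp[[nm]][i] - 2 * h; dn <- lossAt(pp)
            num <- (up - dn) / (2 * h)
            expect_equal(gr[[nm]][i], num, tolerance = 1e-4,
                         label = sprintf("grad %s[%d]", nm, i))
        }
    }
})

test_that("a trained network beats the constant-mean predictor on planted signal", {
    sim <- cleanCohort(n_samples = 500, n_features = 50, n_informative = 10,
                       seed = 1, effect = c(0.45, 0.55))
    tab <- fourthRoot(sim$table)
    sp <- splitSamples(tab, seed = 1)
    cfg <- ratioNetConfig(epochs = 300, seed = 1, batch_size = 100,
                          checkpoint_policy = "best_dev")
    net <- trainRatioNet(tab[, sp@train_ids], dev_x = tab[, sp@dev_ids],
                         config = cfg)
    ydev <- sampleAges(tab[, sp@dev_ids])
    ytr <- sampleAges(tab[, sp@train_ids])
    devRmse <- rmse(predictRatioNet(net, tab[, sp@dev_ids]), ydev)
    constRmse <- rmse(rep(mean(ytr), length(ydev)), ydev)
    expect_lt(devRmse, constRmse)
    # dev loss never produced gradients: history tracked it every epoch
    expect_equal(nrow(net@history), 300L)
    expect_true(all(is.finite(net@history$dev_rmse)))
})

test_that("ensemble predictions average members and quantify spread", {
    sim <- cleanCohort(n_samples = 100, n_features = 12, n_informative = 4,
                       seed = 8)
    tab <- fourthRoot(sim$table)
    sp <- splitSamples(tab, seed = 2)
    cfg <- ratioNetConfig(epochs = 10, seed = 4, batch_size = 40)
    ens <- trainEnsemble(tab[, sp@train_ids], dev_x = tab[, sp@dev_ids],
                         config = cfg, K = 3)
    expect_length(unique(ens@member_seeds), 3L)
    ps <- predictEnsemble(ens, tab[, sp@test_ids])
    expect_equal(ps@per_sample$mean, unname(rowMeans(ps@member_predictions)))
    expect_true(all(is.finite(ps@per_sample$se)))
    # permutation invariance of per-sample predictions
    test <- tab[, sp@test_ids]
    shuf <- test[, rev(seq_len(ncol(test)))]
    ps2 <- predictEnsemble(ens, shuf)
    expect_equal(ps2@per_sample$mean[match(ps@per_sample$sample_id,
                                           ps2@per_sample$sample_id)],
                 ps@per_sample$mean)
    # K = 1 equals the single member
    e1 <- new("EnsembleModel", members = ens@members[1],
              member_seeds = ens@member_seeds[1], config = cfg)
    expect_equal(predictEnsemble(e1, test)@per_sample$mean,
                 unname(predictRatioNet(ens@members[[1]], test)))

    expect_error(trainEnsemble(tab, config = cfg, K = 0), "K")
})

test_that("identical members yield zero standard error and trivial averaging", {
    X <- matrix(runif(20 * 8, 1, 5), 20, 8)
    cfg <- ratioNetConfig(epochs = 0, seed = 9)
    net <- trainRatioNet(X, rnorm(20, 30, 2), config = cfg)
    ens <- new("EnsembleModel", members = list(net, net),
               member_seeds = c(1L, 2L), config = cfg)
    ps <- predictEnsemble(ens, X)
    expect_equal(ps@per_sample$se, rep(0, 20))
    # mean of member predictions [20, 30] -> 25
    fake <- new("PredictionSet",
                per_sample = S4Vectors::DataFrame(
                    sample_id = "s1", mean = 25, se = 5),
                member_predictions = matrix(c(20, 30), 1, 2))
    expect_equal(fake@per_sample$mean, 25)
})

test_that("ensemble averaging never increases mean squared error", {
    # algebraic identity: mse(mean) = mean(mse) - mean variance of members
    set.seed(12)
    truth <- rnorm(50, 40, 8)
    members <- sapply(1:6, function(k) truth + rnorm(50, 0, 6))
    mseMean <- mean((rowMeans(members) - truth)^2)
    meanMse <- mean(colMeans((members - truth)^2))
    expect_lte(mseMean, meanMse + 1e-12)
})

test_that("rmse follows its definition", {
    expect_equal(rmse(c(1, 2), c(1, 2)), 0)
    expect_equal(rmse(c(0, 0), c(3, 4)), sqrt(12.5))
    truth <- runif(10, 20, 60)
    expect_equal(rmse(truth + 3, truth), 3)
    expect_error(rmse(numeric(), numeric()), "non-empty")
    expect_error(rmse(1:3, 1:4), "equal length")
})

test_that("age-group bias isolates regression to the mean", {
    truth <- runif(200, 20, 60)
    ag <- ageGroupBias(truth + 5, truth, bin_width = 10)
    expect_true(all(abs(ag$bins$mean_residual - 5) < 1e-9))
    expect_true(all(abs(ag$scores - (truth + 5 -
        ave(truth + 5, cut(truth, seq(20, 70, 10), include.lowest = TRUE,
            right = FALSE)))) < 1e-9))
    unb <- ageGroupBias(truth, truth, bin_width = 10)
    expect_true(all(abs(unb$bins$mean_residual) < 1e-12))
    # shrunken predictor: old bins under-, young bins over-predicted
    shrunk <- mean(truth) + 0.3 * (truth - mean(truth))
    sh <- ageGroupBias(shrunk, truth, bin_width = 10)
    expect_lt(sh$bins$mean_residual[nrow(sh$bins)], 0)
    expect_gt(sh$bins$mean_residual[1], 0)
})

test_that("fast evaluation path matches the reference evaluation graph", {
    set.seed(13)
    X <- matrix(rlnorm(80 * 20, 2, 0.5), 80, 20)
    y <- rnorm(80, 35, 8)
    for (rl in c(TRUE, FALSE)) {
        cfg <- ratioNetConfig(epochs = 5, seed = 6, batch_size = 40,
                              ratio_layer = rl)
        net <- trainRatioNet(X, y, config = cfg)
        fw <- ratioAge:::.rnForward(net@params, net@arch, net@config,
                                    X, FALSE, net@bn_stats)
        ref <- drop(fw$yhat) * net@target_scale + net@target_center
        expect_equal(predictRatioNet(net, X), ref, tolerance = 1e-12)
    }
})
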