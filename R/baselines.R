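#' Off-the-shelf regression learners for the screening harness
#'
#' Builds the pluggable learner lineup of the normalization-by-learner
#' screen: ordinary linear regression (`"lm"`), elastic net (`"enet"`,
#' glmnet, alpha and lambda tuned by k-fold CV over 5 alpha values),
#' principal-component regression as the latent-projection learner
#' (`"pcr"`, component count tuned by k-fold CV over 5 values), random
#' forest (`"rf"`, ranger, mtry tuned by out-of-bag error over 5 values),
#' gradient boosting (`"gbt"`, xgboost, rounds selected by k-fold CV with
#' early stopping), and the constant-mean predictor (`"const"`). Each
#' learner exposes `fit(X, y, folds, seed)` and `predict(model, X)` and
#' tunes internally on the training data only.
#'
#' @param names which learners to build.
#' @return named list of learners.
#' @export
makeLearners <- function(names = c("lm", "enet", "pcr", "rf", "gbt", "const")) {
    all <- list(
        lm = list(
            fit = function(X, y, folds, seed) {
                Xd <- cbind(1, X)
                fit <- lm.fit(Xd, y)
                cf <- fit$coefficients
                cf[is.na(cf)] <- 0
                cf
            },
            predict = function(model, X) drop(cbind(1, X) %*% model)),
        enet = list(
            fit = function(X, y, folds, seed) {
                set.seed(seed)
                foldid <- sample(rep_len(seq_len(folds), length(y)))
                alphas <- seq(0, 1, length.out = 5)
                fits <- lapply(alphas, function(a)
                    glmnet::cv.glmnet(X, y, alpha = a, foldid = foldid))
                best <- which.min(vapply(fits, function(f)
                    min(f$cvm), 0))
                fits[[best]]
            },
            predict = function(model, X)
                drop(predict(model, X, s = "lambda.min"))),
        pcr = list(
            fit = function(X, y, folds, seed) {
                set.seed(seed)
                maxC <- min(ncol(X), nrow(X) - 2L, 50L)
                grid <- unique(pmax(1L, round(seq(2, maxC, length.out = 5))))
                foldid <- sample(rep_len(seq_len(folds), length(y)))
                errs <- sapply(grid, function(nc) {
                    se <- 0
                    for (fd in seq_len(folds)) {
                        tr <- foldid != fd
                        pc <- prcomp(X[tr, , drop = FALSE], center = TRUE,
                                     rank. = nc)
                        Str <- pc$x
                        cf <- lm.fit(cbind(1, Str), y[tr])$coefficients
                        cf[is.na(cf)] <- 0
                        Ste <- scale(X[!tr, , drop = FALSE], pc$center,
                                     FALSE) %*% pc$rotation
                        se <- se + sum((drop(cbind(1, Ste) %*% cf) - y[!tr])^2)
                    }
                    se
                })
                nc <- grid[which.min(errs)]
                pc <- prcomp(X, center = TRUE, rank. = nc)
                cf <- lm.fit(cbind(1, pc$x), y)$coefficients
                cf[is.na(cf)] <- 0
                list(pc = pc, coef = cf)
            },
            predict = function(model, X) {
                S <- scale(X, model$pc$center, FALSE) %*% model$pc$rotation
                drop(cbind(1, S) %*% model$coef)
            }),
        rf = list(
            fit = function(X, y, folds, seed) {
                p <- ncol(X)
                grid <- unique(pmax(1L, round(seq(sqrt(p) / 2, p / 2,
                                                  length.out = 5))))
                fits <- lapply(grid, function(mt)
                    ranger::ranger(x = X, y = y, mtry = mt, num.trees = 300,
                                   seed = seed))
                fits[[which.min(vapply(fits, function(f)
                    f$prediction.error, 0))]]
            },
            predict = function(model, X) predict(model, data = X)$predictions),
        gbt = list(
            fit = function(X, y, folds, seed) {
                dtr <- xgboost::xgb.DMatrix(X, label = y)
                params <- list(objective = "reg:squarederror", eta = 0.1,
                               max_depth = 3, nthread = 1)
                cv <- xgboost::xgb.cv(params, dtr, nrounds = 300,
                                      nfold = folds,
                                      early_stopping_rounds = 20,
                                      verbose = 0, seed = seed)
                xgboost::xgb.train(params, dtr,
                                   nrounds = cv$best_iteration)
            },
            predict = function(model, X)
                predict(model, xgboost::xgb.DMatrix(X))),
        const = list(
            fit = function(X, y, folds, seed) mean(y),
            predict = function(model, X) rep(model, nrow(X))))
    missing <- setdiff(names, names(all))
    if (length(missing))
        stop("unknown learner(s): ", paste(missing, collapse = ", "))
    all[names]
}

#' Normalization-by-learner screening grid
#'
#' Mirrors the published model screen: for every (normalized dataset,
#' learner) cell, the learner is tuned by k-fold cross-validation on the
#' train + development partition, refitted there, and evaluated once on the
#' held-out test partition. Test data never participate in tuning. Learner
#' failures mark the cell `"failed"` and the screen continues.
#'
#' @param datasets named list of [MetaboSet-class] objects sharing samples
#'   (different normalizations of one cohort).
#' @param learners named learner list from [makeLearners()] (or a character
#'   vector of learner names).
#' @param split a [SplitSpec-class] shared by all datasets.
#' @param folds CV folds for tuning (default 5).
#' @param seed integer seed forwarded to each learner.
#' @return a [ScreenResult-class].
#' @export
screenModels <- function(datasets, learners = makeLearners(), split,
                         folds = 5L, seed = 1L) {
    if (is.character(learners)) learners <- makeLearners(learners)
    stopifnot(length(datasets) >= 1L, length(learners) >= 1L)
    if (is.null(names(datasets)))
        names(datasets) <- paste0("data", seq_along(datasets))
    rmseM <- matrix(NA_real_, length(datasets), length(learners),
                    dimnames = list(names(datasets), names(learners)))
    status <- matrix("unavailable", length(datasets), length(learners),
                     dimnames = dimnames(rmseM))
    fitIds <- c(split@train_ids, split@dev_ids)
    for (d in names(datasets)) {
        ms <- datasets[[d]]
        X <- intensityMatrix(ms)
        y <- sampleAges(ms)
        names(y) <- rownames(X)
        if (anyNA(X))
            stop(sprintf("dataset '%s' contains missing values; impute first", d))
        Xtr <- X[fitIds, , drop = FALSE]; ytr <- y[fitIds]
        Xte <- X[split@test_ids, , drop = FALSE]; yte <- y[split@test_ids]
        for (l in names(learners)) {
            cell <- tryCatch({
                fit <- learners[[l]]$fit(Xtr, ytr, folds, seed)
                pred <- learners[[l]]$predict(fit, Xte)
                list(rmse = rmse(pred, yte), status = "ok")
            }, error = function(e) {
                warning(sprintf("learner '%s' failed on '%s': %s",
                                l, d, conditionMessage(e)))
                list(rmse = NA_real_, status = "failed")
            })
            rmseM[d, l] <- cell$rmse
            status[d, l] <- cell$status
        }
    }
    new("ScreenResult", rmse = rmseM, status = status,
        settings = list(folds = folds, seed = seed,
                        tune_breadth = 5L))
}

setMethod("show", "ScreenResult", function(object) {
    cat("ScreenResult (test RMSE, years):\n")
    print(round(object@rmse, 2))
})

#' Bootstrap comparison of two prediction sets
#'
#' Resamples test indices with replacement and summarizes the distribution
#' of `RMSE(a) - RMSE(b)` by its mean and 2.5/97.5 percentiles, the
#' effect-size check used to conclude whether the learner or the
#' normalization drives performance differences.
#'
#' @param pred_a,pred_b predicted ages (numeric or
#'   [PredictionSet-class]).
#' @param truth observed ages.
#' @param n_boot bootstrap resamples (warns below 100).
#' @param seed integer seed.
#' @return list with `mean_delta`, `ci` (percentile interval) and the full
#'   `deltas` vector.
#' @export
bootstrapRmseCompare <- function(pred_a, pred_b, truth, n_boot = 1000L,
                                 seed = 1L) {
    if (is(pred_a, "PredictionSet")) pred_a <- pred_a@per_sample$mean
    if (is(pred_b, "PredictionSet")) pred_b <- pred_b@per_sample$mean
    stopifnot(length(pred_a) == length(truth),
              length(pred_b) == length(truth))
    if (n_boot < 100L) warning("fewer than 100 bootstrap resamples")
    set.seed(seed)
    n <- length(truth)
    deltas <- vapply(seq_len(n_boot), function(i) {
        idx <- sample.int(n, replace = TRUE)
        rmse(pred_a[idx], truth[idx]) - rmse(pred_b[idx], truth[idx])
    }, 0)
    list(mean_delta = mean(deltas),
         ci = quantile(deltas, c(0.025, 0.975), names = FALSE),
         deltas = deltas)
}
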