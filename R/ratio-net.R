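#' Configure a ratio network
#'
#' See [RatioNetConfig-class] for the meaning of every field; defaults are
#' the published architecture (12-node compression, 66 ratios, two 33-node
#' hidden layers, dropout 0.1 outside the ratio layer, per-layer weight
#' decays 0.5/0.1/0.01/0, Adam at 3e-4 on batches of 500).
#'
#' @param n_compress,hidden_sizes,dropout,weight_decays,learning_rate
#'   architecture and optimizer settings.
#' @param batch_size,epochs,seed training settings. The published fits used
#'   1000 epochs; pick the budget to match your cohort size.
#' @param ratio_epsilon denominator floor of the ratio layer.
#' @param checkpoint_policy `"final_epoch"` or `"best_dev"`.
#' @param use_bias keep the compression-layer offset (disable together with
#'   `ratio_epsilon = 0` for exact scale invariance).
#' @param ratio_layer `FALSE` builds the architecture-matched plain dense
#'   comparator (a learned linear layer of the same width replaces the ratio
#'   operation).
#' @param standardize_targets fit on standardized ages (inverted at
#'   prediction).
#' @return a validated [RatioNetConfig-class].
#' @examples
#' cfg <- ratioNetConfig(epochs = 50, seed = 1)
#' @export
ratioNetConfig <- function(n_compress = 12L, hidden_sizes = c(33L, 33L),
                           dropout = 0.1,
                           weight_decays = c(0.5, 0.1, 0.01, 0),
                           learning_rate = 3e-4, batch_size = 500L,
                           epochs = 1000L, seed = 1L, ratio_epsilon = 1e-6,
                           checkpoint_policy = c("final_epoch", "best_dev"),
                           use_bias = TRUE, ratio_layer = TRUE,
                           standardize_targets = TRUE) {
    new("RatioNetConfig",
        n_compress = as.integer(n_compress),
        hidden_sizes = as.integer(hidden_sizes), dropout = dropout,
        weight_decays = as.numeric(weight_decays),
        learning_rate = learning_rate, batch_size = as.integer(batch_size),
        epochs = as.integer(epochs), seed = as.integer(seed),
        ratio_epsilon = ratio_epsilon,
        checkpoint_policy = match.arg(checkpoint_policy),
        use_bias = use_bias, ratio_layer = ratio_layer,
        standardize_targets = standardize_targets)
}

#' All unique pairwise ratios of a vector
#'
#' The scale-cancelling primitive of the ratio layer: for input of length
#' `n`, returns the `n(n-1)/2` quotients `v[i]/v[j]` over pairs `i < j` in
#' lexicographic order. Denominators are stabilized as
#' `sign(d) * max(|d|, epsilon)`.
#'
#' @param v numeric vector (or matrix, rows expanded independently) of length
#'   (width) at least 2.
#' @param epsilon denominator floor; `0` gives the exact quotient.
#' @return numeric vector (matrix) of width `n(n-1)/2`.
#' @examples
#' ratioExpand(c(2, 4, 8))   # pairs (1,2), (1,3), (2,3)
#' length(ratioExpand(rnorm(12)))  # 66
#' @export
ratioExpand <- function(v, epsilon = 0) {
    vec <- is.null(dim(v))
    if (vec) v <- matrix(v, nrow = 1L)
    if (ncol(v) < 2L) stop("need at least 2 values to form ratios")
    pr <- .ratioPairs(ncol(v))
    out <- .ratioForward(v, pr$I, pr$J, epsilon)$R
    if (vec) drop(out) else out
}

.makeArch <- function(config, n_features) {
    C <- config@n_compress
    pr <- .ratioPairs(C)
    R <- length(pr$I)
    Pi <- matrix(0, R, C); Pj <- matrix(0, R, C)
    Pi[cbind(seq_len(R), pr$I)] <- 1
    Pj[cbind(seq_len(R), pr$J)] <- 1
    list(n_in = as.integer(n_features), C = C, R = R,
         hidden = config@hidden_sizes, I = pr$I, J = pr$J, Pi = Pi, Pj = Pj,
         ratio = config@ratio_layer)
}

#' Build an untrained ratio network
#'
#' Layer sequence: linear(`n_features` -> `n_compress`, no activation, no
#' normalization) -> all unique pairwise ratios -> batch normalization +
#' ReLU -> dense hidden layers (batch normalization + ReLU each) -> linear
#' output node. Initialization is seeded from the config.
#'
#' @param config a [RatioNetConfig-class].
#' @param n_features input width.
#' @return an untrained [RatioNet-class].
#' @examples
#' net <- buildRatioNet(ratioNetConfig(seed = 2), n_features = 100)
#' nParameters(net)
#' @export
buildRatioNet <- function(config, n_features) {
    validObject(config)
    n_features <- as.integer(n_features)
    if (n_features < 1L) stop("'n_features' must be >= 1")
    set.seed(config@seed)
    arch <- .makeArch(config, n_features)
    new("RatioNet",
        params = .initRatioParams(config, n_features),
        bn_stats = .initBnStats(config), arch = arch, config = config,
        history = data.frame(epoch = integer(), train_rmse = numeric(),
                             dev_rmse = numeric()),
        feature_ids = character(), target_center = 0, target_scale = 1,
        trained = FALSE)
}

#' Number of trainable parameters
#' @param net a [RatioNet-class].
#' @return integer count over all weights, offsets and normalization params.
#' @export
nParameters <- function(net) {
    sum(vapply(net@params, length, 0L))
}

.asXY <- function(x, y = NULL) {
    if (is(x, "MetaboSet")) {
        list(X = intensityMatrix(x), y = if (is.null(y)) sampleAges(x) else y)
    } else {
        list(X = as.matrix(x), y = y)
    }
}

#' Train a single ratio network
#'
#' Minimizes mean squared error with Adam on shuffled minibatches; the
#' development set is only ever evaluated (never contributes gradients) and
#' is recorded per epoch in the training history together with the train
#' loss. Both are reported as RMSE in years. With
#' `checkpoint_policy = "best_dev"` the parameters at the best development
#' epoch are returned; the default returns the final epoch. Training is
#' fully deterministic given the config seed.
#'
#' @param x training [MetaboSet-class], or a samples x features matrix.
#' @param y training ages (taken from `colData` when `x` is a MetaboSet).
#' @param dev_x,dev_y optional development data, same feature columns.
#' @param config a [RatioNetConfig-class].
#' @return a fitted [RatioNet-class].
#' @export
trainRatioNet <- function(x, y = NULL, dev_x = NULL, dev_y = NULL, config) {
    tr <- .asXY(x, y)
    X <- tr$X; yr <- as.numeric(tr$y)
    if (is.null(yr) || anyNA(yr)) stop("training ages are required")
    if (anyNA(X)) stop("training matrix must be complete; impute first")
    hasDev <- !is.null(dev_x)
    if (hasDev) {
        dv <- .asXY(dev_x, dev_y)
        if (ncol(dv$X) != ncol(X) ||
            !identical(colnames(dv$X), colnames(X)))
            stop("train and development feature columns must be identical")
        Xd <- dv$X; yd <- as.numeric(dv$y)
    }
    net <- buildRatioNet(config, ncol(X))
    net@feature_ids <- colnames(X) %||% character()

    tc <- 0; ts <- 1
    if (config@standardize_targets) {
        tc <- mean(yr); ts <- sd(yr)
        if (!is.finite(ts) || ts == 0) ts <- 1
    }
    yS <- (yr - tc) / ts
    ydS <- if (hasDev) (yd - tc) / ts else NULL

    params <- net@params
    bnStats <- net@bn_stats
    arch <- net@arch
    decay <- .decayMap(config, params)
    opt <- .adamInit(params)
    n <- nrow(X)
    bs <- min(config@batch_size, n)
    hist <- vector("list", config@epochs)
    best <- list(dev = Inf, params = params, bn = bnStats)

    set.seed(config@seed + 1L)   # training stream, distinct from init
    for (ep in seq_len(config@epochs)) {
        perm <- sample.int(n)
        losses <- c()
        i <- 1L
        while (i <= n) {
            idx <- perm[i:min(i + bs - 1L, n)]
            i <- i + bs
            if (length(idx) < 2L) next   # batch normalization needs > 1
            Xb <- X[idx, , drop = FALSE]
            yb <- yS[idx]
            fw <- .rnForward(params, arch, config, Xb, TRUE, bnStats)
            bnStats <- fw$bnStats
            res <- fw$yhat - yb
            losses <- c(losses, mean(res^2))
            dy <- matrix(2 * res / length(res), ncol = 1L)
            grads <- .rnBackward(params, arch, config, fw, dy)
            st <- .adamStep(params, grads, opt, config@learning_rate, decay)
            params <- st$params
            opt <- st$state
        }
        devMse <- if (hasDev)
            .evalMse(params, arch, config, bnStats, Xd, ydS) else NA_real_
        hist[[ep]] <- c(ep, sqrt(mean(losses)) * ts, sqrt(devMse) * ts)
        if (hasDev && config@checkpoint_policy == "best_dev" &&
            is.finite(devMse) && devMse < best$dev) {
            best <- list(dev = devMse, params = params, bn = bnStats)
        }
    }
    if (hasDev && config@checkpoint_policy == "best_dev" &&
        is.finite(best$dev)) {
        params <- best$params
        bnStats <- best$bn
    }
    h <- do.call(rbind, hist)
    net@params <- params
    net@bn_stats <- bnStats
    net@history <- if (is.null(h)) net@history else
        data.frame(epoch = h[, 1L], train_rmse = h[, 2L], dev_rmse = h[, 3L])
    net@target_center <- tc
    net@target_scale <- ts
    net@trained <- TRUE
    net
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Predict ages with a single network
#'
#' Evaluation mode: dropout off, batch-normalization running statistics
#' frozen.
#'
#' @param net a [RatioNet-class].
#' @param x a [MetaboSet-class] or samples x features matrix with the
#'   training feature columns.
#' @return numeric vector of predicted ages (years).
#' @export
predictRatioNet <- function(net, x) {
    X <- .asXY(x)$X
    if (ncol(X) != net@arch$n_in)
        stop("feature count does not match the training features")
    if (length(net@feature_ids) && !is.null(colnames(X)) &&
        !identical(colnames(X), net@feature_ids))
        stop("feature columns do not match the training features")
    pre <- .foldEval(net@params, net@arch, net@config, net@bn_stats)
    .rnEvalFast(pre, net@arch, net@config, X) * net@target_scale +
        net@target_center
}

#' Train an ensemble of ratio networks
#'
#' Refits the same architecture `K` times with distinct member seeds derived
#' deterministically from the ensemble seed; predictions are later averaged
#' across members ([predictEnsemble()]). The published analysis used
#' K = 1000; a desk-scale K of 25 already realizes most of the variance
#' reduction.
#'
#' @param x,y,dev_x,dev_y as in [trainRatioNet()].
#' @param config shared [RatioNetConfig-class]; its `seed` seeds the member
#'   seed sequence.
#' @param K number of members (>= 1).
#' @return an [EnsembleModel-class].
#' @export
trainEnsemble <- function(x, y = NULL, dev_x = NULL, dev_y = NULL, config,
                          K = 25L) {
    K <- as.integer(K)
    if (K < 1L) stop("'K' must be >= 1")
    set.seed(config@seed)
    seeds <- sample.int(.Machine$integer.max - 1L, K)
    members <- vector("list", K)
    for (k in seq_len(K)) {
        cfg <- config
        cfg@seed <- seeds[k]
        members[[k]] <- trainRatioNet(x, y, dev_x, dev_y, cfg)
    }
    new("EnsembleModel", members = members, member_seeds = seeds,
        config = config)
}

#' Averaged ensemble predictions
#'
#' @param model an [EnsembleModel-class].
#' @param x a [MetaboSet-class] or matrix matching the training features.
#' @return a [PredictionSet-class]: per-sample mean predicted age, standard
#'   error across members, and the full member prediction matrix.
#' @export
predictEnsemble <- function(model, x) {
    X <- .asXY(x)$X
    preds <- vapply(model@members, predictRatioNet, numeric(nrow(X)), x = X)
    preds <- matrix(preds, nrow = nrow(X))
    K <- ncol(preds)
    mu <- rowMeans(preds)
    se <- if (K > 1) apply(preds, 1L, sd) / sqrt(K) else rep(0, nrow(preds))
    ids <- rownames(X) %||% sprintf("sample_%04d", seq_len(nrow(X)))
    rownames(preds) <- ids
    new("PredictionSet",
        per_sample = DataFrame(sample_id = ids, mean = mu, se = se),
        member_predictions = preds)
}

#' Root mean squared error
#'
#' @param pred predicted ages (numeric or [PredictionSet-class], in which
#'   case the ensemble means are used).
#' @param truth observed ages.
#' @return RMSE in years.
#' @examples
#' rmse(c(0, 0), c(3, 4))  # sqrt(12.5)
#' @export
rmse <- function(pred, truth) {
    if (is(pred, "PredictionSet")) pred <- pred@per_sample$mean
    if (length(pred) == 0L || length(pred) != length(truth))
        stop("'pred' and 'truth' must be non-empty and of equal length")
    sqrt(mean((pred - truth)^2))
}

#' Age-group prediction bias and accelerated-aging scores
#'
#' Regression to the mean makes age predictions biased within age groups
#' (old individuals predicted young and vice versa), so accelerated aging
#' must be read as the deviation from the mean prediction of one's own age
#' group, not from chronological age. Bins ages at `bin_width` years,
#' reports the mean residual (prediction - truth) per bin, and returns the
#' per-sample score prediction - (bin mean prediction).
#'
#' @param pred predicted ages (numeric or [PredictionSet-class]).
#' @param truth observed ages.
#' @param bin_width bin width in years (default 5).
#' @return list with `bins` (data.frame: bin, n, mean_age, mean_residual)
#'   and `scores` (per-sample accelerated-aging score, years). Empty bins
#'   are omitted with a warning.
#' @export
ageGroupBias <- function(pred, truth, bin_width = 5) {
    if (is(pred, "PredictionSet")) pred <- pred@per_sample$mean
    stopifnot(length(pred) == length(truth), length(pred) > 0)
    breaks <- seq(floor(min(truth)), max(truth) + bin_width, by = bin_width)
    bin <- cut(truth, breaks, include.lowest = TRUE, right = FALSE)
    if (any(table(bin) == 0L)) {
        warning("empty age bins omitted")
        bin <- droplevels(bin)
    }
    binMeanPred <- tapply(pred, bin, mean)
    bins <- data.frame(
        bin = names(binMeanPred),
        n = as.integer(table(bin)),
        mean_age = as.numeric(tapply(truth, bin, mean)),
        mean_residual = as.numeric(tapply(pred - truth, bin, mean)))
    list(bins = bins, scores = pred - as.numeric(binMeanPred[bin]))
}

setMethod("show", "RatioNet", function(object) {
    a <- object@arch
    cat(sprintf("RatioNet: %d -> %d -> %s(%d) -> %s -> 1 [%s]\n",
                a$n_in, a$C, if (a$ratio) "ratios" else "dense", a$R,
                paste(a$hidden, collapse = " -> "),
                if (object@trained) "trained" else "untrained"))
    if (nrow(object@history)) {
        last <- object@history[nrow(object@history), ]
        cat(sprintf("  %d epochs; final train RMSE %.2f, dev RMSE %.2f years\n",
                    nrow(object@history), last$train_rmse, last$dev_rmse))
    }
})

setMethod("show", "EnsembleModel", function(object) {
    cat(sprintf("EnsembleModel: %d ratio-network members (seed %d)\n",
                length(object@members), object@config@seed))
})

setMethod("show", "PredictionSet", function(object) {
    cat(sprintf("PredictionSet: %d samples x %d members\n",
                nrow(object@member_predictions),
                ncol(object@member_predictions)))
    print(utils::head(as.data.frame(object@per_sample), 5L))
})
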