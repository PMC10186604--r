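#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @import SummarizedExperiment
NULL

#' MetaboSet: an untargeted LC-MS feature table
#'
#' `MetaboSet` extends [SummarizedExperiment::SummarizedExperiment] and is the
#' universal currency of the pipeline: a single `"intensity"` assay holding
#' nonnegative peak intensities (features as rows, samples as columns; missing
#' measurements are `NA`, never 0), per-sample metadata in `colData` (at least
#' `age` in years and `batch`), and per-feature metadata in `rowData`
#' (`mz`, `rt`).
#'
#' @slot .. see [SummarizedExperiment::SummarizedExperiment].
#'
#' @seealso [MetaboSet()] for construction from a samples-by-features matrix,
#'   [intensityMatrix()], [readFeatureTable()].
#' @export
setClass("MetaboSet", contains = "SummarizedExperiment")

.validMetaboSet <- function(object) {
    msg <- character()
    if (!"intensity" %in% assayNames(object))
        msg <- c(msg, "assay 'intensity' is required")
    else {
        x <- assay(object, "intensity")
        if (any(x < 0, na.rm = TRUE))
            msg <- c(msg, "intensities must be nonnegative")
    }
    cd <- colData(object)
    for (f in c("age", "batch"))
        if (!f %in% colnames(cd))
            msg <- c(msg, sprintf("colData must contain '%s'", f))
    if (anyDuplicated(colnames(object)))
        msg <- c(msg, "sample ids must be unique")
    if (anyDuplicated(rownames(object)))
        msg <- c(msg, "feature ids must be unique")
    if (length(msg)) msg else TRUE
}
setValidity("MetaboSet", .validMetaboSet)

#' Generative description of a simulated cohort
#'
#' Holds every parameter of the synthetic-cohort generator: cohort size,
#' feature panel size, batch structure, the right-skewed age distribution
#' (shifted log-normal truncated to [15, 95]), the number, strength and sign
#' mix of age-informative features, per-sample dilution noise, per-(feature,
#' batch) multiplicative offsets, and batch-wise missingness.
#'
#' @slot n_samples,n_features,n_batches,n_informative integer counts.
#' @slot age_mean,age_sd target age moments in years.
#' @slot age_skew dimensionless skewness of the age distribution.
#' @slot effect_size_range length-2 numeric, target |Spearman rho| range of
#'   planted features against age.
#' @slot dilution_cv coefficient of variation of the per-sample multiplicative
#'   dilution factor (log-normal, mean 1).
#' @slot batch_shift_sd log-scale SD of per-(feature, batch) multiplicative
#'   offsets.
#' @slot missing_rate_range length-2 probabilities; each (feature, batch) cell
#'   draws its missingness rate uniformly from this range.
#' @slot inverse_fraction fraction of informative features with negative age
#'   association.
#' @slot noise_sd log-scale SD of per-measurement noise.
#' @slot baseline_log_mean,baseline_log_sd log-normal parameters of feature
#'   baseline intensities.
#' @slot seed integer RNG seed; identical spec implies bit-identical cohort.
#'
#' @seealso [syntheticSpec()], [simulateCohort()].
#' @export
setClass("SyntheticSpec", representation(
    n_samples = "integer", n_features = "integer", n_batches = "integer",
    n_informative = "integer",
    age_mean = "numeric", age_sd = "numeric", age_skew = "numeric",
    effect_size_range = "numeric", dilution_cv = "numeric",
    batch_shift_sd = "numeric", missing_rate_range = "numeric",
    inverse_fraction = "numeric", noise_sd = "numeric",
    baseline_log_mean = "numeric", baseline_log_sd = "numeric",
    seed = "integer"))

.validSyntheticSpec <- function(object) {
    msg <- character()
    chkcount <- function(nm, min = 0L) {
        if (length(slot(object, nm)) != 1L || is.na(slot(object, nm)) ||
            slot(object, nm) < min)
            sprintf("'%s' must be a single integer >= %d", nm, min) else NULL
    }
    msg <- c(msg,
        chkcount("n_samples", 1L), chkcount("n_features", 1L),
        chkcount("n_batches", 1L), chkcount("n_informative", 0L))
    if (object@n_informative > object@n_features)
        msg <- c(msg, "'n_informative' must not exceed 'n_features'")
    if (object@dilution_cv < 0)
        msg <- c(msg, "'dilution_cv' must be >= 0")
    if (object@batch_shift_sd < 0)
        msg <- c(msg, "'batch_shift_sd' must be >= 0")
    if (length(object@missing_rate_range) != 2L ||
        any(object@missing_rate_range < 0) || any(object@missing_rate_range > 1) ||
        diff(object@missing_rate_range) < 0)
        msg <- c(msg, "'missing_rate_range' must be two increasing probabilities in [0,1]")
    if (object@inverse_fraction < 0 || object@inverse_fraction > 1)
        msg <- c(msg, "'inverse_fraction' must be in [0,1]")
    if (length(object@effect_size_range) != 2L ||
        any(object@effect_size_range < 0) || any(object@effect_size_range >= 1) ||
        diff(object@effect_size_range) < 0)
        msg <- c(msg, "'effect_size_range' must be two increasing values in [0,1)")
    if (object@age_sd <= 0) msg <- c(msg, "'age_sd' must be > 0")
    if (object@age_skew <= 0) msg <- c(msg, "'age_skew' must be > 0")
    if (object@noise_sd < 0) msg <- c(msg, "'noise_sd' must be >= 0")
    if (length(msg)) msg else TRUE
}
setValidity("SyntheticSpec", .validSyntheticSpec)

#' Ground truth of a simulated cohort
#'
#' One row per planted age-informative feature: its identifier, the sign of
#' its age association, and the target |Spearman rho| it was calibrated to.
#'
#' @slot table a [S4Vectors::DataFrame] with columns `id`, `sign`, `effect`.
#' @seealso [simulateCohort()], [describeTruth()].
#' @export
setClass("PlantedTruth", representation(table = "DataFrame"))

.validPlantedTruth <- function(object) {
    tb <- object@table
    msg <- character()
    if (!all(c("id", "sign", "effect") %in% colnames(tb)))
        msg <- c(msg, "truth table needs columns id, sign, effect")
    else if (nrow(tb) && !all(tb$sign %in% c(-1, 1)))
        msg <- c(msg, "signs must be +1 or -1")
    if (length(msg)) msg else TRUE
}
setValidity("PlantedTruth", .validPlantedTruth)

#' Robust feature subset used for row normalization
#'
#' Features whose within-sample intensity rank is stable: the median rank
#' across samples lies between the lower and upper quantiles of all features'
#' median ranks, and the max-min rank range lies between the same quantiles of
#' all features' ranges.
#'
#' @slot ids selected feature identifiers.
#' @slot median_ranks,rank_ranges the two statistics for the selected features.
#' @slot quantile_bounds 2x2 matrix: rows median/range, columns lower/upper
#'   cutoff values actually used.
#' @slot quantiles the (lower, upper) quantile levels requested.
#' @seealso [selectRobustFeatures()], [rowNormalize()].
#' @export
setClass("RobustFeatureSet", representation(
    ids = "character", median_ranks = "numeric", rank_ranges = "numeric",
    quantile_bounds = "matrix", quantiles = "numeric"))

#' Train/development/test partition of a cohort
#'
#' @slot train_ids,dev_ids,test_ids disjoint, exhaustive sample-id sets.
#' @slot fractions the requested fractions (sum to 1).
#' @slot seed integer seed that reproduces the split.
#' @seealso [splitSamples()].
#' @export
setClass("SplitSpec", representation(
    train_ids = "character", dev_ids = "character", test_ids = "character",
    fractions = "numeric", seed = "integer"))

.validSplitSpec <- function(object) {
    msg <- character()
    ids <- c(object@train_ids, object@dev_ids, object@test_ids)
    if (anyDuplicated(ids))
        msg <- c(msg, "partitions must be pairwise disjoint")
    if (length(object@fractions) != 3L ||
        abs(sum(object@fractions) - 1) > 1e-8)
        msg <- c(msg, "fractions must be three values summing to 1")
    if (length(msg)) msg else TRUE
}
setValidity("SplitSpec", .validSplitSpec)

#' Architecture and training hyperparameters of the ratio network
#'
#' Defaults follow the published architecture: a 12-node linear compression
#' layer (no activation, no batch normalization, weight decay 0.5), a ratio
#' layer emitting all 66 unique pairwise quotients of the compression outputs
#' (batch-normalized, ReLU, no weights), two 33-node hidden layers (batch
#' normalization, ReLU, weight decays 0.1 and 0.01) and a single linear output
#' node (default, i.e. zero, decay). Adam with learning rate 3e-4 on batches
#' of 500; dropout 0.1 on all layers except the ratio layer.
#'
#' @slot n_compress first-layer width; the ratio layer has
#'   `n_compress*(n_compress-1)/2` outputs.
#' @slot hidden_sizes widths of the dense hidden layers.
#' @slot dropout dropout probability (input and hidden activations; never the
#'   ratio outputs).
#' @slot weight_decays L2 coefficients, one per weighted layer: compression,
#'   each hidden layer, output.
#' @slot learning_rate,batch_size,epochs Adam step size, minibatch size,
#'   training epochs.
#' @slot seed integer seed controlling initialization, shuffling and dropout.
#' @slot ratio_epsilon denominator floor of the ratio layer;
#'   denominators are replaced by `sign(d) * max(|d|, ratio_epsilon)`.
#' @slot checkpoint_policy `"final_epoch"` (default) or `"best_dev"`.
#' @slot use_bias logical; disable the compression-layer offset to obtain
#'   exact scale invariance of the ratio activations.
#' @slot ratio_layer logical; `FALSE` swaps the ratio operation for a learned
#'   dense layer of identical width (architecture-matched comparator).
#' @slot standardize_targets logical; fit on standardized ages and invert the
#'   transform at prediction time.
#' @seealso [ratioNetConfig()], [buildRatioNet()], [trainRatioNet()].
#' @export
setClass("RatioNetConfig", representation(
    n_compress = "integer", hidden_sizes = "integer", dropout = "numeric",
    weight_decays = "numeric", learning_rate = "numeric",
    batch_size = "integer", epochs = "integer", seed = "integer",
    ratio_epsilon = "numeric", checkpoint_policy = "character",
    use_bias = "logical", ratio_layer = "logical",
    standardize_targets = "logical"))

.validRatioNetConfig <- function(object) {
    msg <- character()
    if (object@n_compress < 2L)
        msg <- c(msg, "'n_compress' must be >= 2")
    if (object@dropout < 0 || object@dropout >= 1)
        msg <- c(msg, "'dropout' must be in [0, 1)")
    if (any(object@weight_decays < 0))
        msg <- c(msg, "'weight_decays' must be >= 0")
    if (length(object@weight_decays) != length(object@hidden_sizes) + 2L)
        msg <- c(msg, "need one weight decay per weighted layer (compression, each hidden, output)")
    if (object@ratio_epsilon < 0)
        msg <- c(msg, "'ratio_epsilon' must be >= 0")
    if (!object@checkpoint_policy %in% c("final_epoch", "best_dev"))
        msg <- c(msg, "'checkpoint_policy' must be 'final_epoch' or 'best_dev'")
    if (object@learning_rate <= 0)
        msg <- c(msg, "'learning_rate' must be > 0")
    if (object@batch_size < 2L)
        msg <- c(msg, "'batch_size' must be >= 2 (batch normalization needs > 1 sample)")
    if (object@epochs < 0L)
        msg <- c(msg, "'epochs' must be >= 0")
    if (length(msg)) msg else TRUE
}
setValidity("RatioNetConfig", .validRatioNetConfig)

#' A single (possibly fitted) ratio network
#'
#' @slot params named list of weight matrices, offsets and batch-normalization
#'   scale/shift parameters.
#' @slot bn_stats running means and variances of the batch-normalization
#'   layers, frozen at prediction time.
#' @slot arch internal architecture description (layer dimensions, ratio pair
#'   index maps).
#' @slot config the [RatioNetConfig-class] used to build the network.
#' @slot history data.frame with per-epoch train and development loss (RMSE,
#'   years); zero rows for an untrained network.
#' @slot feature_ids training feature names; enforced at prediction.
#' @slot target_center,target_scale affine target transform fitted on training
#'   ages.
#' @slot trained logical.
#' @seealso [buildRatioNet()], [trainRatioNet()], [predictRatioNet()].
#' @export
setClass("RatioNet", representation(
    params = "list", bn_stats = "list", arch = "list",
    config = "RatioNetConfig", history = "data.frame",
    feature_ids = "character", target_center = "numeric",
    target_scale = "numeric", trained = "logical"))

#' An ensemble of independently fitted ratio networks
#'
#' @slot members list of fitted [RatioNet-class] objects.
#' @slot member_seeds the per-member seeds derived from the ensemble seed.
#' @slot config the shared [RatioNetConfig-class].
#' @seealso [trainEnsemble()], [predictEnsemble()].
#' @export
setClass("EnsembleModel", representation(
    members = "list", member_seeds = "integer", config = "RatioNetConfig"))

.validEnsembleModel <- function(object) {
    msg <- character()
    if (length(object@members) < 1L)
        msg <- c(msg, "ensemble needs at least one member")
    if (length(object@member_seeds) != length(object@members))
        msg <- c(msg, "one seed per member required")
    if (length(msg)) msg else TRUE
}
setValidity("EnsembleModel", .validEnsembleModel)

#' Ensemble predictions with per-member detail
#'
#' @slot per_sample DataFrame with `sample_id`, `mean` (average predicted age,
#'   years) and `se` (standard error across members).
#' @slot member_predictions samples x members matrix of raw member
#'   predictions.
#' @seealso [predictEnsemble()].
#' @export
setClass("PredictionSet", representation(
    per_sample = "DataFrame", member_predictions = "matrix"))

.validPredictionSet <- function(object) {
    mp <- object@member_predictions
    mu <- object@per_sample$mean
    if (nrow(mp) != length(mu))
        return("per-sample table and member matrix disagree on sample count")
    if (nrow(mp) && max(abs(rowMeans(mp) - mu)) > 1e-8 * (1 + max(abs(mu))))
        return("'mean' must equal the arithmetic mean of member predictions")
    TRUE
}
setValidity("PredictionSet", .validPredictionSet)

#' Samples-by-features local attribution matrix
#'
#' Signed Shapley-style attributions in years of predicted-age shift; per
#' sample, `baseline + rowSums(values)` reproduces the model prediction up to
#' the estimator tolerance.
#'
#' @slot values samples x features numeric matrix.
#' @slot baseline expected model prediction over the background set.
#' @slot member_id member label or `"ensemble-mean"`.
#' @seealso [attributeModel()], [averageAttributions()], [globalImportance()].
#' @export
setClass("AttributionMatrix", representation(
    values = "matrix", baseline = "numeric", member_id = "character"))

#' Normalization-by-learner screening grid
#'
#' @slot rmse matrix of held-out test RMSEs (years), normalizations as rows,
#'   learners as columns; `NA` marks a failed or unavailable cell.
#' @slot status character matrix of cell statuses (`"ok"`, `"failed"`,
#'   `"unavailable"`).
#' @slot settings list with folds, tuning breadth and seed.
#' @seealso [screenModels()].
#' @export
setClass("ScreenResult", representation(
    rmse = "matrix", status = "matrix", settings = "list"))
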