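#' Specify a synthetic untargeted LC-MS cohort
#'
#' Builds the generative description of a simulated cohort that mirrors the
#' statistical structure of large uncontrolled toxicology-screening data:
#' hundreds of analytical batches with multiplicative per-(feature, batch)
#' offsets, per-sample dilution factors, batch-wise missingness, a
#' right-skewed age distribution, and a small minority of features whose
#' intensity depends monotonically (either direction) on age. Because such
#' cohorts cannot be shared, the generator provides planted ground truth for
#' end-to-end validation of the modeling pipeline.
#'
#' Defaults reflect the screening-data setting the method targets: ages with
#' mean 28.9 years, SD 9.2 and positive skew; batch effects strong enough to
#' dominate sample-level variance; dilution with a CV of 0.3; planted
#' age-effect sizes of |Spearman rho| 0.3-0.6 with an even sign mix.
#'
#' @param n_samples,n_features,n_batches,n_informative cohort dimensions.
#' @param age_mean,age_sd,age_skew target moments of the age distribution
#'   (shifted log-normal, truncated to [15, 95], moment-matched).
#' @param effect_size_range target |Spearman rho| range for planted features.
#' @param dilution_cv CV of the per-sample multiplicative dilution factor.
#' @param batch_shift_sd log-scale SD of per-(feature, batch) offsets.
#' @param missing_rate_range per-(feature, batch) missingness rate range.
#' @param inverse_fraction fraction of planted features with negative sign.
#' @param noise_sd log-scale SD of per-measurement noise.
#' @param baseline_log_mean,baseline_log_sd log-normal parameters of feature
#'   baseline intensities (wide dynamic range typical of untargeted panels).
#' @param seed integer RNG seed.
#' @return a validated [SyntheticSpec-class].
#' @examples
#' spec <- syntheticSpec(n_samples = 100, n_features = 50, seed = 7)
#' @export
syntheticSpec <- function(n_samples = 500L, n_features = 300L,
                          n_batches = 20L, n_informative = 20L,
                          age_mean = 28.9, age_sd = 9.2, age_skew = 1.5,
                          effect_size_range = c(0.3, 0.6),
                          dilution_cv = 0.3, batch_shift_sd = 0.3,
                          missing_rate_range = c(0, 0.10),
                          inverse_fraction = 0.5, noise_sd = 0.3,
                          baseline_log_mean = log(1e5), baseline_log_sd = 1.2,
                          seed = 1L) {
    new("SyntheticSpec",
        n_samples = as.integer(n_samples), n_features = as.integer(n_features),
        n_batches = as.integer(n_batches),
        n_informative = as.integer(n_informative),
        age_mean = age_mean, age_sd = age_sd, age_skew = age_skew,
        effect_size_range = as.numeric(effect_size_range),
        dilution_cv = dilution_cv, batch_shift_sd = batch_shift_sd,
        missing_rate_range = as.numeric(missing_rate_range),
        inverse_fraction = inverse_fraction, noise_sd = noise_sd,
        baseline_log_mean = baseline_log_mean,
        baseline_log_sd = baseline_log_sd,
        seed = as.integer(seed))
}

# Shifted log-normal parameters matched to (mean, sd, skew):
# skew fixes sigma, sd fixes the log-normal mean, the shift absorbs the rest.
.ageDistParams <- function(mean, sd, skew) {
    f <- function(s2) {
        w <- exp(s2)
        (w + 2) * sqrt(w - 1) - skew
    }
    s2 <- uniroot(f, c(1e-8, 10), tol = 1e-12)$root
    sigma <- sqrt(s2)
    lnMean <- sd / sqrt(exp(s2) - 1)          # mean of the log-normal part
    mu <- log(lnMean) - s2 / 2
    list(mu = mu, sigma = sigma, shift = mean - lnMean)
}

.sampleAges <- function(n, mean, sd, skew, lower = 15, upper = 95) {
    p <- .ageDistParams(mean, sd, skew)
    ages <- p$shift + rlnorm(n, p$mu, p$sigma)
    bad <- which(ages < lower | ages > upper)
    while (length(bad)) {
        ages[bad] <- p$shift + rlnorm(length(bad), p$mu, p$sigma)
        bad <- bad[ages[bad] < lower | ages[bad] > upper]
    }
    ages
}

#' Simulate a cohort with planted ground truth
#'
#' Draws ages from a truncated shifted log-normal matched to the spec's
#' moments, assigns samples to batches, and builds intensities as
#' \deqn{I_{ij} = b_j \exp(\beta_j z_i) \exp(\epsilon_{ij}) \, d_i \, o_{b(i)j}}
#' with feature baselines \eqn{b_j}, standardized age \eqn{z_i}, measurement
#' noise \eqn{\epsilon}, per-sample dilution \eqn{d_i} and per-(feature,
#' batch) offsets \eqn{o}. Planted coefficients \eqn{\beta_j} are calibrated
#' analytically so the noise-free Spearman correlation against age hits the
#' spec's effect-size targets; signs follow `inverse_fraction`. Missing
#' entries are set `NA` per (feature, batch) at a rate drawn from
#' `missing_rate_range` (missing at random).
#'
#' The same spec (including seed) regenerates a bit-identical cohort, and the
#' dilution factors are drawn after all other randomness, so respecifying
#' only `dilution_cv` rescales rows without disturbing anything else.
#'
#' @param spec a [SyntheticSpec-class].
#' @return list with `table` (a [MetaboSet-class]; `colData` carries `age`,
#'   `batch`, `sex`, `date` and the true `dilution`) and `truth`
#'   (a [PlantedTruth-class]).
#' @examples
#' sim <- simulateCohort(syntheticSpec(n_samples = 60, n_features = 30, seed = 3))
#' sim$table
#' describeTruth(sim$truth)
#' @export
simulateCohort <- function(spec) {
    validObject(spec)
    set.seed(spec@seed)
    n <- spec@n_samples; p <- spec@n_features; B <- spec@n_batches

    ages <- .sampleAges(n, spec@age_mean, spec@age_sd, spec@age_skew)
    z <- (ages - mean(ages)) / sd(ages)

    batch <- sample(rep_len(sprintf("batch_%03d", seq_len(B)), n))
    sex <- ifelse(runif(n) < 0.93, "male", "female")
    batchIdx <- as.integer(factor(batch, levels = sprintf("batch_%03d", seq_len(B))))
    date <- as.Date("2017-01-01") + (batchIdx - 1L) * 3L + sample(0:2, n, TRUE)

    baselines <- exp(rnorm(p, spec@baseline_log_mean, spec@baseline_log_sd))

    k <- spec@n_informative
    informative <- sort(sample.int(p, k))
    nNeg <- round(spec@inverse_fraction * k)
    signs <- rep(1, k)
    if (k > 0 && nNeg > 0) signs[sample.int(k, nNeg)] <- -1
    effects <- if (k > 0)
        runif(k, spec@effect_size_range[1L], spec@effect_size_range[2L]) else numeric()
    # target Spearman rho -> Pearson rho on the latent Gaussian scale
    # (rho_S = (6/pi) asin(r/2)), then beta from the noise SD
    rPearson <- 2 * sin(pi * effects / 6)
    beta <- if (spec@noise_sd > 0) {
        spec@noise_sd * rPearson / sqrt(pmax(1 - rPearson^2, 1e-12))
    } else rPearson          # noiseless: any beta gives |rho| = 1
    beta <- beta * signs

    logI <- matrix(rnorm(n * p, 0, spec@noise_sd), n, p)
    logI <- sweep(logI, 2L, log(baselines), "+")
    if (k > 0)
        logI[, informative] <- logI[, informative] + outer(z, beta)

    offsets <- matrix(rnorm(B * p, 0, spec@batch_shift_sd), B, p)
    logI <- logI + offsets[batchIdx, , drop = FALSE]

    rates <- matrix(runif(B * p, spec@missing_rate_range[1L],
                          spec@missing_rate_range[2L]), B, p)
    missMask <- matrix(runif(n * p), n, p) < rates[batchIdx, , drop = FALSE]

    fids <- sprintf("M%dT%d", sample(60:1000, p, TRUE), sample(20:900, p, TRUE))
    fids <- make.unique(fids, sep = "_")

    # dilution drawn last from a fixed-size draw, so respecifying only
    # dilution_cv rescales rows without disturbing any other randomness
    sdD <- sqrt(log(1 + spec@dilution_cv^2))
    dilution <- exp(-sdD^2 / 2 + sdD * rnorm(n))

    x <- exp(logI) * dilution
    x[missMask] <- NA_real_
    dimnames(x) <- list(sprintf("sample_%05d", seq_len(n)), fids)

    tab <- MetaboSet(x,
        data.frame(age = ages, batch = batch, sex = sex, date = date,
                   dilution = dilution))
    truth <- new("PlantedTruth", table = DataFrame(
        id = fids[informative], sign = signs, effect = effects))
    metadata(tab)$spec_seed <- spec@seed
    list(table = tab, truth = truth)
}

#' Summarize planted ground truth
#'
#' @param truth a [PlantedTruth-class].
#' @param ... unused.
#' @return data.frame with one row per planted feature: `id`, `sign`,
#'   `effect`.
#' @export
#' @rdname describeTruth
setMethod("describeTruth", "PlantedTruth", function(truth, ...) {
    as.data.frame(truth@table)
})

#' Read/write planted truth as a sidecar CSV
#'
#' @param truth a [PlantedTruth-class].
#' @param path file path.
#' @return `readTruth()` returns a [PlantedTruth-class];
#'   `writeTruth()` its path, invisibly.
#' @export
writeTruth <- function(truth, path) {
    utils::write.csv(describeTruth(truth), path, row.names = FALSE)
    invisible(path)
}

#' @rdname writeTruth
#' @export
readTruth <- function(path) {
    df <- utils::read.csv(path, colClasses = c("character", "numeric", "numeric"))
    new("PlantedTruth", table = DataFrame(df))
}

setMethod("show", "PlantedTruth", function(object) {
    cat(sprintf("PlantedTruth: %d informative features (%d negative)\n",
                nrow(object@table), sum(object@table$sign < 0)))
})

setMethod("show", "SyntheticSpec", function(object) {
    cat(sprintf(paste0(
        "SyntheticSpec: %d samples x %d features, %d batches, seed %d\n",
        "  informative: %d (inverse fraction %.2f, |rho| in [%.2f, %.2f])\n",
        "  age ~ %.1f +- %.1f (skew %.2f); dilution CV %.2f; batch shift SD %.2f\n"),
        object@n_samples, object@n_features, object@n_batches, object@seed,
        object@n_informative, object@inverse_fraction,
        object@effect_size_range[1L], object@effect_size_range[2L],
        object@age_mean, object@age_sd, object@age_skew,
        object@dilution_cv, object@batch_shift_sd))
})
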