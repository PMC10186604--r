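#' Construct a MetaboSet from a samples-by-features intensity matrix
#'
#' The on-disk and user-facing orientation of untargeted feature tables is
#' samples as rows and features (`M<mz>T<rt>` identifiers) as columns; the
#' container stores the assay transposed, in the features-by-samples
#' orientation of [SummarizedExperiment::SummarizedExperiment].
#'
#' @param intensities numeric matrix, samples x features, nonnegative, `NA`
#'   for missing measurements. Row names are sample ids, column names feature
#'   ids (generated when absent).
#' @param sampleData data.frame (or DataFrame) of per-sample metadata; must
#'   contain `age` (years) and `batch`. A `sample_id` column, when present,
#'   overrides row names.
#' @param featureData optional data.frame of per-feature metadata (`mz`,
#'   `rt`); parsed from `M<mz>T<rt>` identifiers when omitted.
#'
#' @return a [MetaboSet-class].
#' @examples
#' x <- matrix(runif(20, 1, 10), 4, 5,
#'             dimnames = list(paste0("s", 1:4), paste0("M", 100:104, "T", 60)))
#' ms <- MetaboSet(x, data.frame(age = c(20, 30, 40, 50), batch = "b1"))
#' dim(ms)
#' @export
MetaboSet <- function(intensities, sampleData, featureData = NULL) {
    intensities <- as.matrix(intensities)
    if (is.null(rownames(intensities)))
        rownames(intensities) <- sprintf("sample_%04d", seq_len(nrow(intensities)))
    if (is.null(colnames(intensities)))
        colnames(intensities) <- sprintf("F%04d", seq_len(ncol(intensities)))
    sampleData <- as.data.frame(sampleData)
    if ("sample_id" %in% colnames(sampleData)) {
        rownames(sampleData) <- sampleData$sample_id
        sampleData$sample_id <- NULL
    } else if (is.null(rownames(sampleData)) ||
               identical(rownames(sampleData), as.character(seq_len(nrow(sampleData))))) {
        rownames(sampleData) <- rownames(intensities)
    }
    if (nrow(sampleData) != nrow(intensities))
        stop("'sampleData' must have one row per sample")
    sampleData <- sampleData[rownames(intensities), , drop = FALSE]
    if (is.null(featureData))
        featureData <- parseFeatureIds(colnames(intensities))
    featureData <- as.data.frame(featureData)
    if (nrow(featureData) != ncol(intensities))
        stop("'featureData' must have one row per feature")
    rownames(featureData) <- colnames(intensities)
    se <- SummarizedExperiment(
        assays = list(intensity = t(intensities)),
        colData = DataFrame(sampleData),
        rowData = DataFrame(featureData))
    new("MetaboSet", se)
}

#' Parse M<mz>T<rt> feature identifiers
#'
#' @param ids character vector of feature identifiers.
#' @return data.frame with `mz` and `rt` columns (`NA` where the identifier
#'   does not follow the convention).
#' @examples
#' parseFeatureIds(c("M250T142", "M87.05T30.2"))
#' @export
parseFeatureIds <- function(ids) {
    m <- regmatches(ids, regexec("^M([0-9.]+)T([0-9.]+)$", ids))
    mz <- vapply(m, function(g) if (length(g) == 3L) as.numeric(g[2L]) else NA_real_, 0)
    rt <- vapply(m, function(g) if (length(g) == 3L) as.numeric(g[3L]) else NA_real_, 0)
    data.frame(mz = mz, rt = rt, row.names = ids)
}

#' Intensity matrix in samples-by-features orientation
#'
#' @param x a [MetaboSet-class].
#' @param ... unused.
#' @return numeric matrix, samples as rows.
#' @export
#' @rdname intensityMatrix
setMethod("intensityMatrix", "MetaboSet", function(x, ...) {
    t(assay(x, "intensity"))
})

#' Sample and feature accessors
#'
#' Convenience accessors over the colData/rowData of a [MetaboSet-class].
#'
#' @param x a MetaboSet.
#' @return `sampleAges()` numeric years; `sampleBatches()` character;
#'   `sampleIds()`/`featureIds()` character vectors.
#' @export
sampleAges <- function(x) as.numeric(colData(x)$age)

#' @rdname sampleAges
#' @export
sampleBatches <- function(x) as.character(colData(x)$batch)

#' @rdname sampleAges
#' @export
sampleIds <- function(x) colnames(x)

#' @rdname sampleAges
#' @export
featureIds <- function(x) rownames(x)

#' Replace the intensity assay, keeping metadata
#'
#' @param x a [MetaboSet-class].
#' @param intensities samples x features matrix aligned with `x`.
#' @return a MetaboSet with the new assay.
#' @export
setIntensities <- function(x, intensities) {
    stopifnot(nrow(intensities) == ncol(x), ncol(intensities) == nrow(x))
    assay(x, "intensity") <- t(intensities)
    validObject(x)
    x
}

setMethod("show", "MetaboSet", function(object) {
    x <- assay(object, "intensity")
    cat(sprintf("MetaboSet: %d samples x %d features\n", ncol(x), nrow(x)))
    cat(sprintf("  batches: %d | missing: %.2f%% | age range: %s\n",
                length(unique(colData(object)$batch)),
                100 * mean(is.na(x)),
                paste(round(range(colData(object)$age), 1), collapse = "-")))
    callNextMethod()
})
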