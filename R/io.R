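#' Read/write the feature-table CSV dialect
#'
#' Samples as rows; leading metadata columns `sample_id`, `age`, `batch`,
#' `sex`, `date` (extra metadata columns are kept), then one numeric column
#' per feature. Missing measurements are the literal `NA`, never 0, and
#' round-trip losslessly.
#'
#' @param path CSV/TSV file path (delimiter auto-detected on read; chosen
#'   by extension on write).
#' @return `readFeatureTable()` a [MetaboSet-class]; `writeFeatureTable()`
#'   its path, invisibly.
#' @export
readFeatureTable <- function(path) {
    dt <- data.table::fread(path, na.strings = c("NA", ""), data.table = FALSE)
    need <- c("sample_id", "age", "batch")
    miss <- setdiff(need, colnames(dt))
    if (length(miss))
        stop("malformed header: missing column(s) ", paste(miss, collapse = ", "))
    metaCols <- intersect(c("sample_id", "age", "batch", "sex", "date",
                            "dilution"), colnames(dt))
    featCols <- setdiff(colnames(dt), metaCols)
    if (!length(featCols)) stop("no feature columns found")
    if (anyDuplicated(dt$sample_id))
        stop("duplicate sample ids: ",
             paste(unique(dt$sample_id[duplicated(dt$sample_id)]), collapse = ", "))
    bad <- featCols[!vapply(dt[featCols], is.numeric, TRUE)]
    if (length(bad))
        stop("non-numeric intensities in column(s): ", paste(bad, collapse = ", "))
    x <- as.matrix(dt[featCols])
    rownames(x) <- dt$sample_id
    MetaboSet(x, dt[metaCols])
}

#' @param x a [MetaboSet-class].
#' @rdname readFeatureTable
#' @export
writeFeatureTable <- function(x, path) {
    df <- cbind(data.frame(sample_id = sampleIds(x)),
                as.data.frame(colData(x)),
                as.data.frame(intensityMatrix(x)))
    rownames(df) <- NULL
    sep <- if (grepl("\\.tsv$", path)) "\t" else ","
    data.table::fwrite(df, path, sep = sep, na = "NA", quote = FALSE)
    invisible(path)
}

#' Serialize split and robust-feature objects as JSON
#'
#' @param split a [SplitSpec-class]; `robust` a [RobustFeatureSet-class].
#' @param path file path.
#' @return read functions return the object; write functions the path,
#'   invisibly.
#' @export
writeSplit <- function(split, path) {
    jsonlite::write_json(list(
        train_ids = split@train_ids, dev_ids = split@dev_ids,
        test_ids = split@test_ids, fractions = split@fractions,
        seed = split@seed), path, auto_unbox = FALSE, digits = NA)
    invisible(path)
}

#' @rdname writeSplit
#' @export
readSplit <- function(path) {
    j <- jsonlite::read_json(path, simplifyVector = TRUE)
    new("SplitSpec", train_ids = as.character(j$train_ids),
        dev_ids = as.character(j$dev_ids),
        test_ids = as.character(j$test_ids),
        fractions = as.numeric(j$fractions), seed = as.integer(j$seed))
}

#' @param robust a [RobustFeatureSet-class].
#' @rdname writeSplit
#' @export
writeRobustFeatures <- function(robust, path) {
    jsonlite::write_json(list(
        ids = robust@ids, median_ranks = robust@median_ranks,
        rank_ranges = robust@rank_ranges,
        quantile_bounds = robust@quantile_bounds,
        quantiles = robust@quantiles), path, auto_unbox = FALSE, digits = NA)
    invisible(path)
}

#' @rdname writeSplit
#' @export
readRobustFeatures <- function(path) {
    j <- jsonlite::read_json(path, simplifyVector = TRUE)
    qb <- matrix(as.numeric(j$quantile_bounds), 2L, 2L)
    rownames(qb) <- c("median", "range")
    new("RobustFeatureSet", ids = as.character(j$ids),
        median_ranks = as.numeric(j$median_ranks),
        rank_ranges = as.numeric(j$rank_ranges),
        quantile_bounds = qb, quantiles = as.numeric(j$quantiles))
}

#' Write an attribution matrix as CSV with JSON metadata
#'
#' @param m an [AttributionMatrix-class].
#' @param path CSV path; metadata goes to `<path>.json`.
#' @return the path, invisibly.
#' @export
writeAttributions <- function(m, path) {
    df <- cbind(data.frame(sample_id = rownames(m@values)),
                as.data.frame(m@values))
    data.table::fwrite(df, path, na = "NA", quote = FALSE)
    jsonlite::write_json(list(baseline = m@baseline,
                              member_id = m@member_id),
                         paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
    invisible(path)
}
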