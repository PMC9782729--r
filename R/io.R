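#' Read a per-modality feature table
#'
#' Loads a comma-separated feature table (header row mandatory, UTF-8): one
#' row per sample, with a subject-id column, an integer 0/1 label column, an
#' optional replicate-id column, and one column per feature. Feature order is
#' preserved from the file header. Loading is strict: any missing or
#' non-numeric feature cell, any label outside \{0, 1\}, and any missing or
#' duplicated schema column is an error naming the offending row/column —
#' silent coercion would risk miscoding clinical labels.
#'
#' @param path path to the CSV file.
#' @param modality modality tag, \code{"language"} or \code{"imaging"}
#'   (recorded in the metadata; the data model is modality-symmetric).
#' @param schema named list mapping the roles \code{subject_id},
#'   \code{label}, \code{replicate_id} to column names in the file.
#' @return \code{SummarizedExperiment} with assay \code{"features"}
#'   (features x samples) and colData \code{subject_id}, \code{label},
#'   \code{replicate_id}.
#' @seealso \code{\link{writeFeatureTable}} for the inverse; the round trip
#'   is the identity up to numeric text formatting (15 significant digits).
#' @export
readFeatureTable <- function(path,
                             modality = c("language", "imaging"),
                             schema = list(subject_id = "subject_id",
                                           label = "label",
                                           replicate_id = "replicate_id")) {
    modality <- match.arg(modality)
    if (!file.exists(path))
        stop("file not found: ", path)
    header <- strsplit(readLines(path, n = 1L), ",", fixed = TRUE)[[1]]
    if (anyDuplicated(header))
        stop("schema error: duplicated column name(s): ",
             paste(unique(header[duplicated(header)]), collapse = ", "))
    df <- utils::read.csv(path, check.names = FALSE,
                          stringsAsFactors = FALSE, fileEncoding = "UTF-8")
    idCol <- schema$subject_id %||% "subject_id"
    labCol <- schema$label %||% "label"
    repCol <- schema$replicate_id %||% "replicate_id"
    for (col in c(idCol, labCol))
        if (!col %in% names(df))
            stop("schema error: missing required column '", col, "'")
    meta <- intersect(c(idCol, labCol, repCol), names(df))
    featNames <- setdiff(names(df), meta)
    if (!length(featNames))
        stop("schema error: no feature columns found")
    lab <- df[[labCol]]
    if (anyNA(lab) || !all(lab %in% c(0, 1)) ||
        !isTRUE(all.equal(lab, round(lab))))
        stop("data error: label column '", labCol,
             "' must be integer-coded 0/1; offending row(s): ",
             paste(utils::head(which(!(lab %in% c(0, 1))), 5),
                   collapse = ", "))
    feat <- df[featNames]
    for (fn in featNames) {
        v <- feat[[fn]]
        if (!is.numeric(v)) {
            suppressWarnings(v <- as.numeric(v))
            feat[[fn]] <- v
        }
        if (anyNA(v))
            stop("data error: missing or non-numeric value in column '", fn,
                 "', row ", which(is.na(v))[1])
    }
    m <- as.matrix(feat)
    repl <- if (repCol %in% names(df)) as.integer(df[[repCol]])
            else rep(1L, nrow(df))
    if (anyNA(repl) || any(repl < 0))
        stop("data error: replicate ids must be non-negative integers")
    se <- makeModality(m, subject = as.character(df[[idCol]]),
                       label = as.integer(lab), replicate = repl,
                       modality = modality)
    S4Vectors::metadata(se)$source <- path
    se
}

#' Write a per-modality feature table
#'
#' Inverse of \code{\link{readFeatureTable}}: writes one CSV row per sample
#' with columns \code{subject_id}, \code{label}, \code{replicate_id} followed
#' by the features in assay order. Numeric values are written at 15
#' significant digits, so a write/read round trip reproduces the data to
#' that precision.
#'
#' @param se \code{SummarizedExperiment} as built by \code{makeModality}.
#' @param path output CSV path.
#' @param sidecar if TRUE, also write \code{<path>.json} recording modality,
#'   feature names and sample count.
#' @return \code{path}, invisibly.
#' @export
writeFeatureTable <- function(se, path, sidecar = FALSE) {
    cd <- SummarizedExperiment::colData(se)
    df <- data.frame(subject_id = as.character(cd$subject_id),
                     label = as.integer(cd$label),
                     replicate_id = as.integer(cd$replicate_id),
                     check.names = FALSE)
    df <- cbind(df, as.data.frame(featureMatrix(se), check.names = FALSE))
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE,
                     fileEncoding = "UTF-8")
    if (sidecar) {
        info <- list(modality = S4Vectors::metadata(se)$modality,
                     feature_names = rownames(se),
                     n_samples = ncol(se))
        jsonlite::write_json(info, paste0(path, ".json"),
                             auto_unbox = TRUE, digits = NA, pretty = TRUE)
    }
    invisible(path)
}
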