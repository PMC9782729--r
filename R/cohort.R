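#' Build a partially aligned two-modality cohort
#'
#' Combines a language modality and an imaging modality (each a
#' \code{SummarizedExperiment} as produced by \code{\link{readFeatureTable}}
#' or \code{\link{makeModality}}) into a \linkS4class{MultimodalCohort}.
#' Subjects are matched across modalities by exact string equality of
#' \code{subject_id}; subjects present in both modalities form the aligned
#' partition. A subject carrying different clinical labels in the two
#' modalities is a consistency error.
#'
#' @param lang \code{SummarizedExperiment} of language samples.
#' @param img \code{SummarizedExperiment} of imaging samples.
#' @param metadata optional list of provenance.
#' @return a validated \linkS4class{MultimodalCohort}.
#' @examples
#' lang <- makeModality(matrix(rnorm(12), 4, 3,
#'                             dimnames = list(NULL, c("f1", "f2", "f3"))),
#'                      subject = c("a", "a", "b", "c"),
#'                      label = c(1, 1, 0, 1),
#'                      replicate = c(1, 2, 1, 1))
#' img <- makeModality(matrix(rnorm(4), 2, 2,
#'                            dimnames = list(NULL, c("g1", "g2"))),
#'                     subject = c("b", "d"), label = c(0, 1))
#' cohort <- MultimodalCohort(lang, img)
#' alignedIds(cohort)
#' @export
MultimodalCohort <- function(lang, img, metadata = list()) {
    obj <- new("MultimodalCohort", lang = lang, img = img,
               metadata = metadata)
    validObject(obj)
    obj
}

#' Assemble one modality from a samples-by-features matrix
#'
#' Convenience constructor wrapping a plain matrix into the
#' \code{SummarizedExperiment} layout the package uses (features in rows,
#' samples in columns, subject/label/replicate in the column data).
#'
#' @param x samples-by-features numeric matrix with feature column names.
#' @param subject character vector of subject ids, one per row of \code{x}.
#' @param label binary clinical labels (1 = MCI, 0 = NL), one per row.
#' @param replicate integer replicate (transcript) index per row; defaults
#'   to 1 for single-observation modalities.
#' @param modality optional modality tag stored in the metadata.
#' @return \code{SummarizedExperiment}.
#' @export
makeModality <- function(x, subject, label, replicate = rep(1L, nrow(x)),
                         modality = NA_character_) {
    x <- as.matrix(x)
    if (is.null(colnames(x)))
        colnames(x) <- paste0("V", seq_len(ncol(x)))
    stopifnot(length(subject) == nrow(x), length(label) == nrow(x),
              length(replicate) == nrow(x))
    cd <- S4Vectors::DataFrame(subject_id = as.character(subject),
                               label = as.integer(label),
                               replicate_id = as.integer(replicate))
    a <- t(x)
    colnames(a) <- make.unique(paste(subject, replicate, sep = "."))
    SummarizedExperiment::SummarizedExperiment(
        assays = list(features = a), colData = cd,
        metadata = list(modality = modality))
}

#' @rdname accessors
#' @export
setGeneric("langData", function(x) standardGeneric("langData"))
#' @rdname accessors
#' @export
setGeneric("imgData", function(x) standardGeneric("imgData"))
#' @rdname accessors
#' @export
setGeneric("alignedIds", function(x) standardGeneric("alignedIds"))
#' @rdname accessors
#' @export
setGeneric("langOnlyIds", function(x) standardGeneric("langOnlyIds"))
#' @rdname accessors
#' @export
setGeneric("imgOnlyIds", function(x) standardGeneric("imgOnlyIds"))
#' @rdname accessors
#' @export
setGeneric("subjectLabels", function(x) standardGeneric("subjectLabels"))
#' @rdname accessors
#' @export
setGeneric("cohortMetadata", function(x) standardGeneric("cohortMetadata"))

#' Cohort accessors
#'
#' @param x a \linkS4class{MultimodalCohort}.
#' @return \code{langData}/\code{imgData} return the modality
#'   \code{SummarizedExperiment}s; \code{alignedIds}, \code{langOnlyIds} and
#'   \code{imgOnlyIds} the (sorted) subject-id partitions;
#'   \code{subjectLabels} a named integer vector of clinical labels over all
#'   subjects; \code{cohortMetadata} the provenance list.
#' @name accessors
NULL

#' @rdname accessors
setMethod("langData", "MultimodalCohort", function(x) x@lang)
#' @rdname accessors
setMethod("imgData", "MultimodalCohort", function(x) x@img)

#' @rdname accessors
setMethod("alignedIds", "MultimodalCohort", function(x)
    sort(intersect(sampleSubjects(x@lang), sampleSubjects(x@img))))

#' @rdname accessors
setMethod("langOnlyIds", "MultimodalCohort", function(x)
    sort(setdiff(sampleSubjects(x@lang), sampleSubjects(x@img))))

#' @rdname accessors
setMethod("imgOnlyIds", "MultimodalCohort", function(x)
    sort(setdiff(sampleSubjects(x@img), sampleSubjects(x@lang))))

#' @rdname accessors
setMethod("subjectLabels", "MultimodalCohort", function(x) {
    subj <- c(sampleSubjects(x@lang), sampleSubjects(x@img))
    lab <- c(sampleLabels(x@lang), sampleLabels(x@img))
    keep <- !duplicated(subj)
    out <- lab[keep]
    names(out) <- subj[keep]
    out[sort(names(out))]
})

#' @rdname accessors
setMethod("cohortMetadata", "MultimodalCohort", function(x) x@metadata)

#' Subset a cohort by subject
#'
#' Keeps every sample (all transcript replicates and both modality vectors)
#' of the requested subjects and drops everything else. Used by the split
#' protocol so that held-out subjects leave no trace in any training
#' structure.
#'
#' @param x a \linkS4class{MultimodalCohort}.
#' @param subjects character vector of subject ids to keep.
#' @return a \linkS4class{MultimodalCohort}.
#' @export
subsetCohort <- function(x, subjects) {
    keepL <- sampleSubjects(x@lang) %in% subjects
    keepI <- sampleSubjects(x@img) %in% subjects
    MultimodalCohort(x@lang[, keepL], x@img[, keepI],
                     metadata = x@metadata)
}

setMethod("show", "MultimodalCohort", function(object) {
    nl <- length(unique(sampleSubjects(object@lang)))
    ni <- length(unique(sampleSubjects(object@img)))
    na <- length(alignedIds(object))
    cat("MultimodalCohort\n")
    cat(sprintf("  language: %d subjects, %d samples, %d features\n",
                nl, ncol(object@lang), nrow(object@lang)))
    cat(sprintf("  imaging : %d subjects, %d samples, %d features\n",
                ni, ncol(object@img), nrow(object@img)))
    cat(sprintf("  partitions: %d aligned / %d language-only / %d imaging-only\n",
                na, nl - na, ni - na))
    lab <- subjectLabels(object)
    cat(sprintf("  labels: %d MCI / %d NL\n", sum(lab == 1L),
                sum(lab == 0L)))
})
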