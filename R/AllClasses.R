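#' @import methods
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom S4Vectors DataFrame metadata
NULL

#' Partially aligned two-modality cohort
#'
#' Container for a clinical cohort observed through two feature modalities —
#' canonically per-transcript language markers and per-subject neuroimaging
#' markers — where only a subset of subjects is present in both. Each modality
#' is held as a \linkS4class{SummarizedExperiment} whose assay
#' \code{"features"} is a features-by-samples matrix and whose column data
#' carries \code{subject_id}, \code{label} (1 = MCI, 0 = NL) and
#' \code{replicate_id} (transcript index; 1 for single-observation
#' modalities).
#'
#' The three subject partitions are derived, not stored: aligned subjects are
#' those with at least one sample in both modalities; the language-only and
#' imaging-only partitions are the complements. Validity enforces complete
#' (no-missing) numeric features, binary labels, and label agreement for every
#' subject across all of its samples and modalities.
#'
#' @slot lang \code{SummarizedExperiment} of language samples.
#' @slot img \code{SummarizedExperiment} of imaging samples.
#' @slot metadata list of free-form provenance (generator truth, configs).
#'
#' @seealso \code{\link{MultimodalCohort}} (constructor),
#'   \code{\link{alignedIds}}, \code{\link{simulateCohort}}
#' @export
setClass("MultimodalCohort",
    representation(lang = "SummarizedExperiment",
                   img = "SummarizedExperiment",
                   metadata = "list"))

validModality <- function(se, what) {
    msgs <- character()
    cd <- SummarizedExperiment::colData(se)
    need <- c("subject_id", "label", "replicate_id")
    miss <- setdiff(need, colnames(cd))
    if (length(miss))
        return(sprintf("%s: missing colData column(s): %s", what,
                       paste(miss, collapse = ", ")))
    a <- SummarizedExperiment::assay(se, "features")
    if (!is.numeric(a))
        msgs <- c(msgs, sprintf("%s: features must be numeric", what))
    if (anyNA(a))
        msgs <- c(msgs, sprintf("%s: features contain missing values", what))
    lab <- cd$label
    if (ncol(se) && (anyNA(lab) || !all(lab %in% c(0L, 1L))))
        msgs <- c(msgs, sprintf("%s: labels must be 0 or 1", what))
    if (ncol(se)) {
        perSubj <- tapply(as.integer(lab), as.character(cd$subject_id),
                          function(v) length(unique(v)))
        if (any(perSubj > 1))
            msgs <- c(msgs, sprintf(
                "%s: conflicting labels within subject(s): %s", what,
                paste(names(perSubj)[perSubj > 1], collapse = ", ")))
    }
    msgs
}

setValidity("MultimodalCohort", function(object) {
    msgs <- c(validModality(object@lang, "language"),
              validModality(object@img, "imaging"))
    ## cross-modality label agreement
    ls <- SummarizedExperiment::colData(object@lang)
    is <- SummarizedExperiment::colData(object@img)
    if (nrow(ls) && nrow(is)) {
        ll <- tapply(as.integer(ls$label), as.character(ls$subject_id), max)
        il <- tapply(as.integer(is$label), as.character(is$subject_id), max)
        shared <- intersect(names(ll), names(il))
        bad <- shared[ll[shared] != il[shared]]
        if (length(bad))
            msgs <- c(msgs, sprintf(
                "conflicting labels across modalities for subject(s): %s",
                paste(bad, collapse = ", ")))
    }
    if (length(msgs)) msgs else TRUE
})

#' Fitted pairwise alignment model
#'
#' A probabilistic binary classifier over concatenated (language, imaging)
#' feature pairs, scoring how likely the two vectors belong together. Trained
#' with \code{\link{trainAlignmentModel}}; scores are produced by
#' \code{\link{scoreAlignment}} and drive the top-k synthesis in
#' \code{\link{augmentOne}}.
#'
#' @slot fit the fitted backend model (gradient-boosted trees or a penalized
#'   linear model).
#' @slot method character, backend identifier.
#' @slot langNames,imgNames feature names the model was trained on, fixing
#'   both dimensions and order for later scoring.
#' @slot params list of backend hyperparameters actually used.
#' @slot seed integer seed used for fitting.
#' @slot fitted logical.
#' @export
setClass("AlignmentModel",
    representation(fit = "ANY", method = "character",
                   langNames = "character", imgNames = "character",
                   params = "list", seed = "integer", fitted = "logical"),
    prototype(fitted = FALSE, method = NA_character_, seed = NA_integer_))

#' Elastic-net detection model
#'
#' Penalized logistic regression (mixed L1/L2) over a named feature space,
#' with the training-set standardization statistics stored so that held-out
#' samples are scored leak-free. One coefficient per input feature.
#'
#' @slot coefficients named numeric vector of per-feature coefficients on the
#'   standardized scale.
#' @slot intercept numeric intercept.
#' @slot center,scale named standardization statistics from the training set.
#' @slot alpha elastic-net mixing parameter (1 = lasso, 0 = ridge).
#' @slot lambda regularization strength at which coefficients were extracted.
#' @slot fitted logical.
#' @export
setClass("DetectionModel",
    representation(coefficients = "numeric", intercept = "numeric",
                   center = "numeric", scale = "numeric",
                   alpha = "numeric", lambda = "numeric", fitted = "logical"),
    prototype(fitted = FALSE))

#' Pairwise alignment training set
#'
#' Constructed pairs for the alignment model: each row couples one language
#' vector with one imaging vector, labelled 1 (aligned: clinical labels agree
#' by construction) or 0 (not aligned: labels differ).
#'
#' @slot lang pairs-by-features language matrix.
#' @slot img pairs-by-features imaging matrix.
#' @slot aligned integer vector of alignment labels in \{0, 1\}.
#' @slot langLabel,imgLabel clinical labels of the two sides of each pair.
#' @export
setClass("PairSet",
    representation(lang = "matrix", img = "matrix", aligned = "integer",
                   langLabel = "integer", imgLabel = "integer"))

setValidity("PairSet", function(object) {
    n <- nrow(object@lang)
    if (nrow(object@img) != n || length(object@aligned) != n)
        return("lang, img and aligned must have one entry per pair")
    if (!all(object@aligned %in% c(0L, 1L)))
        return("alignment labels must be 0 or 1")
    TRUE
})

#' Repeated random-split experiment report
#'
#' Per-split AUC / Accuracy / F1 for every evaluated model plus their
#' mean and standard deviation across splits.
#'
#' @slot perSplit data.frame with columns split, model, auc, accuracy, f1.
#' @slot summary data.frame with per-model mean and sd of each metric.
#' @slot config list echoing the experiment configuration and seeds.
#' @export
setClass("ExperimentReport",
    representation(perSplit = "data.frame", summary = "data.frame",
                   config = "list"))
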