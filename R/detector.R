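#' Train the elastic-net detection model
#'
#' Fits an elastic-net regularized logistic regression on z-scored features
#' (standardization statistics estimated on the training set and stored in
#' the model, so held-out samples are transformed leak-free). The
#' regularization strength is chosen by internal stratified k-fold
#' cross-validation on the training split; the penalty mix defaults to an
#' equal L1/L2 blend.
#'
#' @param x samples-by-features numeric matrix, or a modality
#'   \code{SummarizedExperiment} (labels then come from its colData).
#' @param y binary labels (1 = MCI, 0 = NL); ignored when \code{x} is a
#'   \code{SummarizedExperiment}.
#' @param alpha elastic-net mixing parameter in [0, 1] (default 0.5).
#' @param nfolds cross-validation folds for the penalty search; capped at
#'   the minority-class count and at least 3.
#' @param seed integer seed controlling the fold assignment.
#' @return a fitted \linkS4class{DetectionModel}.
#' @export
trainDetector <- function(x, y = NULL, alpha = 0.5, nfolds = 5, seed = 1) {
    if (methods::is(x, "SummarizedExperiment")) {
        y <- sampleLabels(x)
        x <- featureMatrix(x)
    }
    x <- as.matrix(x)
    y <- as.integer(y)
    if (anyNA(x))
        stop("data error: feature matrix contains missing values")
    if (length(unique(y)) < 2)
        stop("degenerate input: training labels contain a single class")
    if (is.null(colnames(x)))
        colnames(x) <- paste0("V", seq_len(ncol(x)))
    st <- standardizeFit(x)
    xs <- standardizeApply(x, st)
    ## glmnet needs >= 2 columns; pad single-feature problems with a
    ## zero column whose coefficient is necessarily 0
    pad <- ncol(xs) == 1
    if (pad)
        xs <- cbind(xs, `..pad..` = 0)

    nf <- min(as.integer(nfolds), min(table(y)))
    if (nf >= 3) {
        foldid <- integer(length(y))
        withSeed(seed, {
            for (cls in c(0L, 1L)) {
                idx <- which(y == cls)
                foldid[idx] <- sample(rep_len(seq_len(nf), length(idx)))
            }
        })
        cv <- quietGlmnet(
            glmnet::cv.glmnet(xs, y, family = "binomial", alpha = alpha,
                              foldid = foldid, standardize = FALSE,
                              grouped = length(y) >= 3 * nf))
        lambda <- cv$lambda.min
        cf <- as.numeric(stats::coef(cv, s = "lambda.min"))
    } else {
        ## too few samples per class for stratified CV: fit the path and
        ## take a mid-path penalty (deterministic, mildly regularized)
        fit <- quietGlmnet(
            glmnet::glmnet(xs, y, family = "binomial", alpha = alpha,
                           standardize = FALSE))
        lambda <- fit$lambda[max(1L, ceiling(length(fit$lambda) / 2))]
        cf <- as.numeric(stats::coef(fit, s = lambda))
    }
    beta <- cf[-1]
    if (pad)
        beta <- beta[-length(beta)]
    names(beta) <- colnames(x)
    new("DetectionModel", coefficients = beta, intercept = cf[1],
        center = st$center, scale = st$scale, alpha = alpha,
        lambda = lambda, fitted = TRUE)
}

setMethod("show", "DetectionModel", function(object) {
    cat(sprintf(
        "DetectionModel (elastic net, alpha = %.2f)%s: %d features, %d nonzero\n",
        object@alpha, if (object@fitted) "" else " [unfitted]",
        length(object@coefficients), sum(object@coefficients != 0)))
})

#' Predict class probabilities
#'
#' Applies the stored training standardization and the fitted linear score,
#' returning the logistic probability of the positive (MCI) class per
#' sample. Thresholding at 0.5 yields the class predictions used for
#' Accuracy and F1.
#'
#' @param model fitted \linkS4class{DetectionModel}.
#' @param x samples-by-features matrix or \code{SummarizedExperiment};
#'   feature names must match the training feature space exactly.
#' @return numeric vector of probabilities in [0, 1].
#' @export
predictScores <- function(model, x) {
    if (!is(model, "DetectionModel") || !model@fitted)
        stop("state error: detection model is not fitted")
    if (methods::is(x, "SummarizedExperiment"))
        x <- featureMatrix(x)
    x <- as.matrix(x)
    want <- names(model@coefficients)
    have <- colnames(x) %||% character()
    if (!identical(sort(want), sort(have))) {
        stop("data error: feature mismatch; missing: [",
             paste(utils::head(setdiff(want, have), 5), collapse = ", "),
             "], unexpected: [",
             paste(utils::head(setdiff(have, want), 5), collapse = ", "),
             "]")
    }
    x <- x[, want, drop = FALSE]
    xs <- standardizeApply(x, list(center = model@center,
                                   scale = model@scale))
    as.numeric(stats::plogis(model@intercept +
                             xs %*% model@coefficients))
}

#' Coefficient-based feature importance
#'
#' Ranks features by the absolute value of their fitted coefficients,
#' descending, with ties broken alphabetically by feature name.
#'
#' @param model fitted \linkS4class{DetectionModel}, or a named numeric
#'   coefficient vector.
#' @return data.frame with columns \code{feature}, \code{coefficient},
#'   \code{importance}, sorted by importance.
#' @export
featureImportance <- function(model) {
    beta <- if (is.numeric(model) && !is.null(names(model))) {
        model
    } else {
        if (!is(model, "DetectionModel") || !model@fitted)
            stop("state error: detection model is not fitted")
        model@coefficients
    }
    out <- data.frame(feature = names(beta),
                      coefficient = as.numeric(beta),
                      importance = abs(as.numeric(beta)),
                      stringsAsFactors = FALSE)
    out <- out[order(-out$importance, out$feature), ]
    rownames(out) <- NULL
    out
}
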