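#' Stability selection for per-modality feature filtering
#'
#' Repeatedly subsamples half of the samples (without replacement, stratified
#' by class so every subsample contains both labels), fits an L1-penalized
#' logistic regression over a grid of penalties on within-subsample z-scored
#' features, and records for each feature the fraction of subsamples in which
#' it receives a nonzero coefficient. The per-feature selection frequency is
#' the maximum of that fraction over the penalty grid (the stability-path
#' maximum); the selected set contains the features whose frequency reaches
#' the threshold.
#'
#' Defaults (100 subsamples of fraction 0.5, threshold 0.6) are the canonical
#' stability-selection settings; the penalty grid defaults to eight
#' log-spaced values between the full-data \eqn{\lambda_{max}} (smallest
#' penalty with an empty model) and \eqn{\lambda_{max}/10} — staying in the
#' sparse upper part of the path, where selection frequencies are
#' informative.
#'
#' @param x samples-by-features numeric matrix (or a modality
#'   \code{SummarizedExperiment}, from which labels are taken).
#' @param y binary labels, one per sample; ignored when \code{x} is a
#'   \code{SummarizedExperiment}.
#' @param nSubsamples number of subsampling repeats.
#' @param fraction fraction of samples per draw, in (0, 1).
#' @param lambdaGrid decreasing vector of L1 penalties; NULL for the default
#'   data-driven grid.
#' @param threshold selection-frequency cutoff in (0, 1].
#' @param seed integer RNG seed; the whole procedure is deterministic given
#'   it.
#' @return list with \code{frequency} (named numeric vector in [0, 1]),
#'   \code{selected} (character vector of feature names with frequency >=
#'   threshold), \code{threshold} and \code{lambdaGrid}.
#' @examples
#' set.seed(7)
#' x <- matrix(rnorm(100 * 10), 100, 10,
#'             dimnames = list(NULL, paste0("f", 1:10)))
#' y <- rbinom(100, 1, plogis(3 * x[, 1]))
#' sel <- stabilitySelect(x, y, nSubsamples = 25, seed = 1)
#' sel$selected
#' @export
stabilitySelect <- function(x, y = NULL, nSubsamples = 100, fraction = 0.5,
                            lambdaGrid = NULL, threshold = 0.6, seed = 1) {
    if (methods::is(x, "SummarizedExperiment")) {
        y <- sampleLabels(x)
        x <- featureMatrix(x)
    }
    x <- as.matrix(x)
    y <- as.integer(y)
    if (anyNA(x))
        stop("data error: feature matrix contains missing values")
    if (length(unique(y)) < 2)
        stop("degenerate input: labels contain a single class")
    if (min(table(y)) < 2)
        stop("degenerate input: need at least 2 samples per class")
    if (fraction <= 0 || fraction >= 1)
        stop("config error: fraction must be in (0, 1)")
    if (threshold <= 0 || threshold > 1)
        stop("config error: threshold must be in (0, 1]")
    if (is.null(colnames(x)))
        colnames(x) <- paste0("V", seq_len(ncol(x)))
    p <- ncol(x)

    if (is.null(lambdaGrid)) {
        ## lambda_max from the z-scored full data, as in the glmnet path
        st <- standardizeFit(x)
        xs <- standardizeApply(x, st)
        lmax <- max(abs(crossprod(xs, y - mean(y)))) / length(y)
        lmax <- max(lmax, .Machine$double.eps)
        ## stay within one decade of lambda_max: far smaller penalties let
        ## every feature enter and saturate all selection frequencies
        lambdaGrid <- exp(seq(log(lmax), log(lmax / 10), length.out = 8))
    }
    lambdaGrid <- sort(lambdaGrid, decreasing = TRUE)

    counts <- matrix(0L, p, length(lambdaGrid),
                     dimnames = list(colnames(x), NULL))
    withSeed(seed, {
        idx0 <- which(y == 0L)
        idx1 <- which(y == 1L)
        n0 <- max(1L, round(length(idx0) * fraction))
        n1 <- max(1L, round(length(idx1) * fraction))
        for (b in seq_len(nSubsamples)) {
            take <- c(sample(idx0, n0), sample(idx1, n1))
            xb <- x[take, , drop = FALSE]
            st <- standardizeFit(xb)
            xb <- standardizeApply(xb, st)
            fit <- quietGlmnet(
                glmnet::glmnet(xb, y[take], family = "binomial",
                               alpha = 1, lambda = lambdaGrid,
                               standardize = FALSE))
            beta <- as.matrix(fit$beta)
            ## glmnet may stop early on the path; align by column count
            sel <- beta != 0
            counts[, seq_len(ncol(sel))] <-
                counts[, seq_len(ncol(sel)), drop = FALSE] + sel
        }
    })
    freqPath <- counts / nSubsamples
    frequency <- apply(freqPath, 1, max)
    list(frequency = frequency,
         selected = names(frequency)[frequency >= threshold],
         threshold = threshold, lambdaGrid = lambdaGrid)
}
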