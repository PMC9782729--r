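#' Straightforward multimodal fusion baselines
#'
#' Four fusion strategies usable only on fully aligned samples: feature
#' concatenation (\code{conFusion}), flattened outer product
#' (\code{interFusion}), outer product concatenated with the original
#' vectors (\code{interConFusion}), and prediction-score averaging
#' (\code{votingAvgFusion}). Output dimensions are, respectively,
#' \eqn{d_{lang} + d_{img}}, \eqn{d_{lang} \cdot d_{img}} and their sum.
#' The outer product is flattened language-major (row-major with the
#' language vector indexing rows): element \eqn{(i - 1) d_{img} + j} equals
#' \eqn{x^{lang}_i x^{img}_j}. The flattening order is a fixed convention so
#' runs are reproducible; downstream linear models are permutation
#' invariant.
#'
#' @param xLang,xImg numeric feature vectors (any dimensions; named output
#'   when inputs are named).
#' @return numeric fused feature vector.
#' @examples
#' conFusion(c(1, 2), 3)            # 1 2 3
#' interFusion(c(1, 2), c(3, 4))    # 3 4 6 8
#' interConFusion(1, 2)             # 2 1 2
#' votingAvgFusion(0.2, 0.8)        # 0.5
#' @name fusion
NULL

fuseNames <- function(xLang, xImg) {
    ln <- names(xLang) %||% paste0("lang", seq_along(xLang))
    im <- names(xImg) %||% paste0("img", seq_along(xImg))
    list(lang = ln, img = im,
         inter = as.vector(t(outer(ln, im, paste, sep = "*"))))
}

#' @rdname fusion
#' @export
conFusion <- function(xLang, xImg) {
    nm <- fuseNames(xLang, xImg)
    stats::setNames(c(as.numeric(xLang), as.numeric(xImg)),
                    c(nm$lang, nm$img))
}

#' @rdname fusion
#' @export
interFusion <- function(xLang, xImg) {
    nm <- fuseNames(xLang, xImg)
    stats::setNames(as.vector(t(outer(as.numeric(xLang),
                                      as.numeric(xImg)))), nm$inter)
}

#' @rdname fusion
#' @export
interConFusion <- function(xLang, xImg) {
    c(interFusion(xLang, xImg), conFusion(xLang, xImg))
}

#' @rdname fusion
#' @param scoreLang,scoreImg prediction scores in [0, 1] from the two
#'   unimodal classifiers (vectorized).
#' @export
votingAvgFusion <- function(scoreLang, scoreImg) {
    if (any(scoreLang < 0 | scoreLang > 1) ||
        any(scoreImg < 0 | scoreImg > 1))
        stop("data error: scores must lie in [0, 1]")
    (scoreLang + scoreImg) / 2
}
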