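# Internal helpers shared across modules.

#' Evaluate code under a temporary RNG seed
#'
#' Runs \code{code} with the global random-number stream set from \code{seed},
#' restoring the caller's stream afterwards so that seeded package functions
#' never clobber user-level reproducibility.
#'
#' @param seed integer seed, or NULL to leave the stream untouched.
#' @param code expression to evaluate.
#' @return the value of \code{code}.
#' @keywords internal
#' @noRd
withSeed <- function(seed, code) {
    if (!is.null(seed)) {
        had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
        old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
        set.seed(seed)
        on.exit({
            if (had) {
                assign(".Random.seed", old, envir = globalenv())
            } else if (exists(".Random.seed", envir = globalenv(),
                              inherits = FALSE)) {
                rm(".Random.seed", envir = globalenv())
            }
        }, add = TRUE)
    }
    force(code)
}

# Deterministic child seed: keeps derived seeds inside the 32-bit integer
# range so they remain valid set.seed() arguments.
childSeed <- function(seed, index) {
    s <- (abs(as.numeric(seed)) * 7919 + as.numeric(index) * 104729) %%
        2147483647
    as.integer(s)
}

# samples-by-features matrix view of a modality assay
featureMatrix <- function(se) {
    m <- t(SummarizedExperiment::assay(se, "features"))
    rownames(m) <- colnames(se)
    m
}

sampleLabels <- function(se) {
    as.integer(SummarizedExperiment::colData(se)$label)
}

sampleSubjects <- function(se) {
    as.character(SummarizedExperiment::colData(se)$subject_id)
}

sampleReplicates <- function(se) {
    as.integer(SummarizedExperiment::colData(se)$replicate_id)
}

# z-scoring with train statistics; constant columns get unit scale so they
# map to zero rather than NaN
standardizeFit <- function(x) {
    ctr <- colMeans(x)
    scl <- apply(x, 2, stats::sd)
    scl[!is.finite(scl) | scl < .Machine$double.eps] <- 1
    list(center = ctr, scale = scl)
}

standardizeApply <- function(x, stats) {
    sweep(sweep(x, 2, stats$center, "-"), 2, stats$scale, "/")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# glmnet advises whenever a class has < 8 observations; routine at the
# aligned-only and subsampled training sizes this package works with
quietGlmnet <- function(expr) {
    withCallingHandlers(expr, warning = function(w) {
        if (grepl("fewer than 8[ ]+observations", conditionMessage(w)))
            invokeRestart("muffleWarning")
    })
}
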