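#' Construct the pairwise alignment training set
#'
#' For each sample of the primary modality belonging to an aligned subject,
#' two training pairs are emitted for the alignment model: a positive pair
#' (alignment label 1) whose bank-side vector carries the same clinical
#' label, and a negative pair (alignment label 0) whose bank-side vector is
#' drawn from the bank under the constraint that its clinical label differs.
#' The resulting pair set is exactly class-balanced 1:1 and its size is twice
#' the number of input samples (four per sample under
#' \code{positiveMode = "both"}).
#'
#' Under \code{positiveMode = "own_image"} the positive partner is the
#' subject's own bank vector (its first bank sample, by replicate order);
#' under \code{"same_label_sampled"} it is a uniformly drawn bank vector with
#' matching label; \code{"both"} emits one of each (with two independent
#' negatives to preserve balance). Sampling is a pure function of
#' \code{seed}.
#'
#' The two modalities play symmetric roles: pass language samples with an
#' imaging bank to augment language, or the reverse to augment imaging.
#'
#' @param lang \code{SummarizedExperiment} of aligned subjects' samples in
#'   the modality to be augmented (conventionally language transcripts).
#' @param bank \code{SummarizedExperiment} of all available samples in the
#'   auxiliary modality (conventionally one imaging vector per training
#'   subject).
#' @param positiveMode how the positive partner is chosen; see Details.
#' @param seed integer RNG seed.
#' @return a \linkS4class{PairSet}.
#' @export
buildPairSet <- function(lang, bank,
                         positiveMode = c("same_label_sampled", "own_image",
                                          "both"),
                         seed = 1) {
    positiveMode <- match.arg(positiveMode)
    if (ncol(lang) < 1)
        stop("pair construction requires at least one aligned sample")
    langM <- featureMatrix(lang)
    bankM <- featureMatrix(bank)
    langLab <- sampleLabels(lang)
    bankLab <- sampleLabels(bank)
    langSubj <- sampleSubjects(lang)
    bankSubj <- sampleSubjects(bank)
    bankRep <- sampleReplicates(bank)
    bankOrd <- order(bankSubj, bankRep)

    needOwn <- positiveMode %in% c("own_image", "both")
    if (needOwn && !all(langSubj %in% bankSubj))
        stop("pair construction error: subject(s) without a bank vector: ",
             paste(utils::head(setdiff(langSubj, bankSubj), 5),
                   collapse = ", "))

    withSeed(seed, {
        li <- ii <- al <- list()
        for (i in seq_len(ncol(lang))) {
            y <- langLab[i]
            same <- which(bankLab == y)
            diff <- which(bankLab != y)
            if (!length(diff))
                stop("pair construction error: bank has no sample with ",
                     "label != ", y)
            pos <- integer()
            if (needOwn) {
                own <- bankOrd[bankSubj[bankOrd] == langSubj[i]][1]
                pos <- c(pos, own)
            }
            if (positiveMode %in% c("same_label_sampled", "both")) {
                if (!length(same))
                    stop("pair construction error: bank has no sample with ",
                         "label == ", y)
                pos <- c(pos, same[sample.int(length(same), 1)])
            }
            neg <- diff[sample.int(length(diff), length(pos),
                                   replace = length(diff) < length(pos))]
            li[[i]] <- rep(i, 2 * length(pos))
            ii[[i]] <- c(pos, neg)
            al[[i]] <- c(rep(1L, length(pos)), rep(0L, length(neg)))
        }
        li <- unlist(li); ii <- unlist(ii); al <- unlist(al)
        new("PairSet",
            lang = langM[li, , drop = FALSE],
            img = bankM[ii, , drop = FALSE],
            aligned = al,
            langLabel = langLab[li],
            imgLabel = bankLab[ii])
    })
}

setMethod("show", "PairSet", function(object) {
    cat(sprintf(
        "PairSet: %d pairs (%d aligned / %d not), dims %d + %d\n",
        length(object@aligned), sum(object@aligned == 1L),
        sum(object@aligned == 0L), ncol(object@lang), ncol(object@img)))
})

pairFeatures <- function(lang, img) {
    x <- cbind(lang, img)
    colnames(x) <- c(paste0("a|", colnames(lang)),
                     paste0("b|", colnames(img)))
    x
}

#' Train the crossmodal alignment model
#'
#' Fits a probabilistic binary classifier on constructed pairs (features:
#' the concatenation of the two modality vectors) that scores how likely a
#' (language, imaging) pair is aligned. The default backend is a
#' gradient-boosted decision-tree ensemble; a ridge-penalized logistic
#' regression backend is available for quick linear baselines. Fitting is
#' deterministic given the seed (single-threaded boosting).
#'
#' @param pairs a \linkS4class{PairSet} containing both alignment labels.
#' @param method \code{"xgboost"} (gradient boosting, default) or
#'   \code{"glmnet"} (ridge logistic regression).
#' @param params backend hyperparameters. For xgboost: \code{nrounds} (50),
#'   \code{max_depth} (3), \code{eta} (0.3). For glmnet: \code{lambda}
#'   (0.05).
#' @param seed integer seed.
#' @return an \linkS4class{AlignmentModel}.
#' @export
trainAlignmentModel <- function(pairs, method = c("xgboost", "glmnet"),
                                params = list(), seed = 1) {
    method <- match.arg(method)
    stopifnot(is(pairs, "PairSet"))
    if (length(unique(pairs@aligned)) < 2)
        stop("degenerate input: pair set contains a single alignment class")
    x <- pairFeatures(pairs@lang, pairs@img)
    y <- pairs@aligned
    if (method == "xgboost") {
        p <- list(nrounds = params$nrounds %||% 50,
                  max_depth = params$max_depth %||% 3,
                  eta = params$eta %||% 0.3)
        dtrain <- xgboost::xgb.DMatrix(x, label = y, nthread = 1)
        fit <- withSeed(seed, xgboost::xgb.train(
            params = list(objective = "binary:logistic",
                          max_depth = p$max_depth, eta = p$eta,
                          nthread = 1, seed = seed),
            data = dtrain, nrounds = p$nrounds, verbose = 0))
    } else {
        p <- list(lambda = params$lambda %||% 0.05)
        st <- standardizeFit(x)
        xs <- standardizeApply(x, st)
        fit <- list(glmnet = glmnet::glmnet(xs, y, family = "binomial",
                                            alpha = 0, lambda = p$lambda,
                                            standardize = FALSE),
                    stats = st, lambda = p$lambda)
    }
    new("AlignmentModel", fit = fit, method = method,
        langNames = colnames(pairs@lang), imgNames = colnames(pairs@img),
        params = p, seed = as.integer(seed), fitted = TRUE)
}

setMethod("show", "AlignmentModel", function(object) {
    cat(sprintf("AlignmentModel (%s)%s: %d + %d features\n", object@method,
                if (object@fitted) "" else " [unfitted]",
                length(object@langNames), length(object@imgNames)))
})

#' Score (language, imaging) pairs with a fitted alignment model
#'
#' @param model a fitted \linkS4class{AlignmentModel}.
#' @param lang numeric vector, or a pairs-by-features matrix.
#' @param img numeric vector or matrix with the same number of rows as
#'   \code{lang}.
#' @return numeric vector of alignment probabilities in [0, 1], one per
#'   pair; scoring is deterministic.
#' @export
scoreAlignment <- function(model, lang, img) {
    if (!is(model, "AlignmentModel") || !model@fitted)
        stop("state error: alignment model is not fitted")
    if (is.null(dim(lang))) lang <- matrix(lang, nrow = 1)
    if (is.null(dim(img))) img <- matrix(img, nrow = 1)
    if (ncol(lang) != length(model@langNames))
        stop("data error: language dimension ", ncol(lang),
             " does not match the model's ", length(model@langNames))
    if (ncol(img) != length(model@imgNames))
        stop("data error: imaging dimension ", ncol(img),
             " does not match the model's ", length(model@imgNames))
    if (nrow(lang) != nrow(img))
        stop("data error: lang and img must pair row-wise")
    colnames(lang) <- model@langNames
    colnames(img) <- model@imgNames
    x <- pairFeatures(lang, img)
    s <- if (model@method == "xgboost") {
        stats::predict(model@fit, xgboost::xgb.DMatrix(x, nthread = 1))
    } else {
        xs <- standardizeApply(x, model@fit$stats)
        as.numeric(stats::predict(model@fit$glmnet, xs, type = "response",
                                  s = model@fit$lambda))
    }
    pmin(pmax(as.numeric(s), 0), 1)
}

#' Weighted combination of the top-k bank vectors
#'
#' The synthesis primitive: given one alignment score per bank vector,
#' selects the k highest-scoring vectors (ties broken by the supplied
#' deterministic ordering key, ascending) and returns their weighted sum.
#' Under \code{"score_normalized"} weighting the selected scores are
#' normalized to sum to one (falling back to uniform weights when all
#' selected scores are zero); \code{"uniform"} averages the selected
#' vectors. Weights are non-negative and sum to 1, so the output always lies
#' in the convex hull of the selected vectors.
#'
#' @param bank bank-by-features numeric matrix.
#' @param scores numeric vector of scores in [0, 1], one per bank row.
#' @param k number of vectors to combine, \code{1 <= k <= nrow(bank)}.
#' @param weighting \code{"score_normalized"} or \code{"uniform"}.
#' @param tieOrder integer ordering key per bank row used to break score
#'   ties deterministically (default: row position).
#' @return numeric feature vector of length \code{ncol(bank)}.
#' @examples
#' bank <- rbind(c(1, 0), c(0, 1), c(2, 2))
#' combineBank(bank, scores = c(0.5, 0.3, 0.2), k = 2)  # [0.625, 0.375]
#' @export
combineBank <- function(bank, scores,
                        k, weighting = c("score_normalized", "uniform"),
                        tieOrder = seq_len(nrow(bank))) {
    weighting <- match.arg(weighting)
    bank <- as.matrix(bank)
    if (k < 1 || k > nrow(bank))
        stop("config error: k must satisfy 1 <= k <= ", nrow(bank),
             " (bank size); got ", k)
    if (length(scores) != nrow(bank))
        stop("data error: one score per bank vector required")
    if (any(scores < 0 | scores > 1))
        stop("data error: scores must lie in [0, 1]")
    sel <- order(-scores, tieOrder)[seq_len(k)]
    w <- if (weighting == "uniform" || sum(scores[sel]) <= 0)
        rep(1 / k, k)
    else
        scores[sel] / sum(scores[sel])
    out <- as.numeric(colSums(bank[sel, , drop = FALSE] * w))
    names(out) <- colnames(bank)
    out
}

orderedBank <- function(bank) {
    ord <- order(sampleSubjects(bank), sampleReplicates(bank))
    bank[, ord]
}

#' Synthesize one auxiliary vector for a single sample
#'
#' Scores every bank vector against \code{xLang} with the alignment model
#' and returns the weighted combination of the k highest-scoring ones (see
#' \code{\link{combineBank}}). Ties are broken by ascending subject id, then
#' replicate order.
#'
#' @param model fitted \linkS4class{AlignmentModel}.
#' @param xLang numeric vector in the augmented modality's feature space.
#' @param bank \code{SummarizedExperiment} of auxiliary-modality samples.
#' @param k number of bank vectors combined (default 15).
#' @param weighting see \code{\link{combineBank}}.
#' @return named numeric vector in the bank's feature space.
#' @export
augmentOne <- function(model, xLang, bank, k = 15,
                       weighting = c("score_normalized", "uniform")) {
    weighting <- match.arg(weighting)
    bank <- orderedBank(bank)
    if (k > ncol(bank))
        stop("config error: k = ", k, " exceeds bank size ", ncol(bank))
    bankM <- featureMatrix(bank)
    n <- nrow(bankM)
    scores <- scoreAlignment(model,
                             matrix(xLang, n, length(xLang), byrow = TRUE),
                             bankM)
    combineBank(bankM, scores, k, weighting)
}

#' Augment every sample of a modality
#'
#' Applies the top-k synthesis to each column of \code{lang}, preserving
#' sample order and clinical labels, and returns samples in the concatenated
#' feature space [original features, synthesized auxiliary features]; the
#' synthesized block's feature names carry an \code{AUG:} prefix. By default
#' every sample receives a synthesized vector, including samples of aligned
#' subjects; with \code{useTrueAux = TRUE} an aligned subject's own bank
#' vector is substituted instead.
#'
#' All pairwise scores are computed in one backend call, so the result is
#' identical to column-wise \code{\link{augmentOne}} but considerably
#' faster.
#'
#' @param model fitted \linkS4class{AlignmentModel}.
#' @param lang \code{SummarizedExperiment} of samples to augment.
#' @param bank \code{SummarizedExperiment} auxiliary bank.
#' @param k,weighting see \code{\link{augmentOne}}.
#' @param useTrueAux substitute an aligned subject's true auxiliary vector
#'   for the synthesized one.
#' @return \code{SummarizedExperiment} with
#'   \code{nrow(lang) + nrow(bank)} features and the colData of
#'   \code{lang}.
#' @export
augmentSamples <- function(model, lang, bank, k = 15,
                           weighting = c("score_normalized", "uniform"),
                           useTrueAux = FALSE) {
    weighting <- match.arg(weighting)
    bank <- orderedBank(bank)
    if (k > ncol(bank))
        stop("config error: k = ", k, " exceeds bank size ", ncol(bank))
    langM <- featureMatrix(lang)
    bankM <- featureMatrix(bank)
    nL <- nrow(langM); nB <- nrow(bankM)
    ## one scoring call over the full lang x bank grid
    scores <- scoreAlignment(model,
                             langM[rep(seq_len(nL), each = nB), ,
                                   drop = FALSE],
                             bankM[rep(seq_len(nB), times = nL), ,
                                   drop = FALSE])
    scores <- matrix(scores, nB, nL)
    aug <- vapply(seq_len(nL), function(i)
        combineBank(bankM, scores[, i], k, weighting),
        numeric(ncol(bankM)))
    aug <- t(aug)
    if (useTrueAux) {
        bankSubj <- sampleSubjects(bank)
        langSubj <- sampleSubjects(lang)
        hit <- match(langSubj, bankSubj)
        has <- !is.na(hit)
        aug[has, ] <- bankM[hit[has], , drop = FALSE]
    }
    colnames(aug) <- paste0("AUG:", colnames(bankM))
    full <- cbind(langM, aug)
    makeModality(full, subject = sampleSubjects(lang),
                 label = sampleLabels(lang),
                 replicate = sampleReplicates(lang),
                 modality = "augmented")
}
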