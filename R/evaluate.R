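#' Classification metrics
#'
#' AUC is the probability that a uniformly drawn positive sample outscores a
#' uniformly drawn negative one, ties counted one half (computed by the
#' midrank / Mann-Whitney identity). Accuracy and F1 are evaluated at the
#' 0.5 threshold (score >= 0.5 predicts the positive class); F1 takes MCI
#' (label 1) as the positive class and is 0 when no true positive is
#' recovered.
#'
#' @param scores numeric vector of prediction scores.
#' @param labels binary labels of the same length.
#' @return named numeric vector \code{c(auc, accuracy, f1)}; with
#'   single-class labels AUC is NA (with a warning) while Accuracy and F1
#'   are still returned.
#' @export
computeMetrics <- function(scores, labels) {
    if (length(scores) != length(labels))
        stop("data error: scores and labels must have equal length")
    labels <- as.integer(labels)
    if (!all(labels %in% c(0L, 1L)))
        stop("data error: labels must be 0 or 1")
    nPos <- sum(labels == 1L)
    nNeg <- sum(labels == 0L)
    auc <- if (nPos == 0L || nNeg == 0L) {
        warning("AUC undefined: labels contain a single class")
        NA_real_
    } else {
        r <- rank(scores)  # midranks handle ties
        (sum(r[labels == 1L]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
    }
    pred <- as.integer(scores >= 0.5)
    accuracy <- mean(pred == labels)
    tp <- sum(pred == 1L & labels == 1L)
    fp <- sum(pred == 1L & labels == 0L)
    fn <- sum(pred == 0L & labels == 1L)
    f1 <- if (tp == 0) 0 else 2 * tp / (2 * tp + fp + fn)
    c(auc = auc, accuracy = accuracy, f1 = f1)
}

#' Draw one train/test split of the repeated-split protocol
#'
#' Samples \code{nTestPerClass} MCI and \code{nTestPerClass} NL subjects
#' from the aligned partition as the test set; everything else is training.
#' The draw is a pure function of \code{(seed, splitIndex)}, so every model
#' evaluated under the same master seed sees identical splits.
#'
#' @param cohort a \linkS4class{MultimodalCohort}.
#' @param nTestPerClass held-out subjects per class (default 4).
#' @param seed master seed.
#' @param splitIndex 1-based split number.
#' @return list with sorted character vectors \code{testIds} and
#'   \code{trainIds} (all remaining subjects) plus the derived
#'   \code{splitSeed}.
#' @export
makeSplit <- function(cohort, nTestPerClass = 4, seed = 1, splitIndex = 1) {
    lab <- subjectLabels(cohort)
    pool <- alignedIds(cohort)
    pos <- pool[lab[pool] == 1L]
    neg <- pool[lab[pool] == 0L]
    if (length(pos) < nTestPerClass || length(neg) < nTestPerClass)
        stop("config error: aligned partition has ", length(pos), " MCI / ",
             length(neg), " NL subjects; need ", nTestPerClass,
             " of each for the test set")
    sSeed <- childSeed(seed, splitIndex)
    test <- withSeed(sSeed, c(sample(pos, nTestPerClass),
                              sample(neg, nTestPerClass)))
    list(testIds = sort(test),
         trainIds = sort(setdiff(names(lab), test)),
         splitSeed = sSeed)
}

#' Partition a cohort into train and test cohorts
#'
#' All samples of a test subject — every transcript replicate and both
#' modality vectors — move to the test side, so no training structure
#' (detector, pair set, imaging bank, feature selection) can see them.
#'
#' @param cohort a \linkS4class{MultimodalCohort}.
#' @param testIds character vector of held-out subject ids.
#' @return list of two \linkS4class{MultimodalCohort}s, \code{train} and
#'   \code{test}.
#' @export
splitCohort <- function(cohort, testIds) {
    lab <- subjectLabels(cohort)
    list(train = subsetCohort(cohort, setdiff(names(lab), testIds)),
         test = subsetCohort(cohort, testIds))
}

## ---- per-split model fitting ------------------------------------------

restrictFeatures <- function(se, keep) {
    se[rownames(se) %in% keep, ]
}

alignedModality <- function(se, alignedSubjects) {
    se[, sampleSubjects(se) %in% alignedSubjects]
}

fuseModality <- function(lang, img, fuse) {
    ## one fused sample per language transcript, paired with the same
    ## subject's imaging vector
    langM <- featureMatrix(lang)
    imgM <- featureMatrix(img)
    imgSubj <- sampleSubjects(img)
    hit <- match(sampleSubjects(lang), imgSubj)
    if (anyNA(hit))
        stop("fusion requires fully aligned samples")
    rows <- lapply(seq_len(nrow(langM)), function(i)
        fuse(langM[i, ], imgM[hit[i], ]))
    fused <- do.call(rbind, rows)
    makeModality(fused, subject = sampleSubjects(lang),
                 label = sampleLabels(lang),
                 replicate = sampleReplicates(lang),
                 modality = "fused")
}

scoreOneModel <- function(name, train, test, k, weighting, positiveMode,
                          alignMethod, alignParams, alpha, sSeed) {
    trL <- langData(train); trI <- imgData(train)
    teL <- langData(test); teI <- imgData(test)
    alignedTrain <- alignedIds(train)
    detSeed <- childSeed(sSeed, 11)
    pairSeed <- childSeed(sSeed, 12)

    fitAug <- function(primary, bank, tePrimary) {
        alig <- alignedModality(primary, alignedIds(train))
        pairs <- buildPairSet(alig, bank, positiveMode = positiveMode,
                              seed = pairSeed)
        am <- trainAlignmentModel(pairs, method = alignMethod,
                                  params = alignParams,
                                  seed = childSeed(sSeed, 13))
        augTr <- augmentSamples(am, primary, bank, k = k,
                                weighting = weighting)
        augTe <- augmentSamples(am, tePrimary, bank, k = k,
                                weighting = weighting)
        det <- trainDetector(augTr, alpha = alpha, seed = detSeed)
        list(scores = predictScores(det, augTe),
             labels = sampleLabels(augTe))
    }

    switch(name,
        lang = {
            det <- trainDetector(trL, alpha = alpha, seed = detSeed)
            list(scores = predictScores(det, teL),
                 labels = sampleLabels(teL))
        },
        img = {
            det <- trainDetector(trI, alpha = alpha, seed = detSeed)
            list(scores = predictScores(det, teI),
                 labels = sampleLabels(teI))
        },
        lang_aug_img = fitAug(trL, trI, teL),
        img_aug_lang = fitAug(trI, trL, teI),
        con = ,
        inter = ,
        intercon = {
            fuse <- switch(name, con = conFusion, inter = interFusion,
                           intercon = interConFusion)
            aTrL <- alignedModality(trL, alignedTrain)
            aTrI <- alignedModality(trI, alignedTrain)
            fTr <- fuseModality(aTrL, aTrI, fuse)
            fTe <- fuseModality(teL, teI, fuse)
            det <- trainDetector(fTr, alpha = alpha, seed = detSeed)
            list(scores = predictScores(det, fTe),
                 labels = sampleLabels(fTe))
        },
        voting = {
            aTrL <- alignedModality(trL, alignedTrain)
            aTrI <- alignedModality(trI, alignedTrain)
            detL <- trainDetector(aTrL, alpha = alpha, seed = detSeed)
            detI <- trainDetector(aTrI, alpha = alpha,
                                  seed = childSeed(detSeed, 1))
            sL <- predictScores(detL, teL)
            ## broadcast each subject's imaging score to its transcripts
            sI <- predictScores(detI, teI)
            hit <- match(sampleSubjects(teL), sampleSubjects(teI))
            list(scores = votingAvgFusion(sL, sI[hit]),
                 labels = sampleLabels(teL))
        },
        stop("unknown model: ", name))
}

#' Run the repeated random-split experiment
#'
#' For each split: draws the test set (4 MCI + 4 NL aligned subjects by
#' default), removes every sample of the test subjects from all training
#' structures, optionally runs stability selection per modality on the
#' training data, then fits and scores every model in the roster on
#' identical partitions. Available models: \code{"lang"} and \code{"img"}
#' (unimodal elastic-net detectors), \code{"lang_aug_img"} and
#' \code{"img_aug_lang"} (crossmodal augmentation in either direction), and
#' the aligned-only fusion baselines \code{"con"}, \code{"voting"},
#' \code{"inter"}, \code{"intercon"}.
#'
#' Metrics are computed at transcript level (each language replicate scored
#' independently; imaging models score one vector per subject);
#' \code{subjectLevel = TRUE} averages scores within subject first.
#'
#' @param cohort a \linkS4class{MultimodalCohort}.
#' @param models character vector of model names (see Details).
#' @param nSplits number of random splits (default 100).
#' @param nTestPerClass held-out subjects per class per split (default 4).
#' @param k bank vectors combined per synthesized feature (default 15).
#' @param seed master seed; per-split seeds are derived from it, so adding
#'   a model to the roster never changes the splits.
#' @param select run stability selection per modality on each training
#'   split before modeling (default FALSE).
#' @param selectionControl arguments for \code{\link{stabilitySelect}} when
#'   \code{select = TRUE}.
#' @param weighting,positiveMode see \code{\link{augmentSamples}} and
#'   \code{\link{buildPairSet}}.
#' @param alignMethod,alignParams alignment-model backend, see
#'   \code{\link{trainAlignmentModel}}.
#' @param alpha elastic-net mixing for all detectors.
#' @param subjectLevel aggregate scores per subject before computing
#'   metrics.
#' @return an \linkS4class{ExperimentReport}.
#' @export
runExperiment <- function(cohort,
                          models = c("lang", "img", "lang_aug_img",
                                     "img_aug_lang"),
                          nSplits = 100, nTestPerClass = 4, k = 15,
                          seed = 1, select = FALSE,
                          selectionControl = list(),
                          weighting = "score_normalized",
                          positiveMode = "same_label_sampled",
                          alignMethod = "xgboost", alignParams = list(),
                          alpha = 0.5, subjectLevel = FALSE) {
    known <- c("lang", "img", "lang_aug_img", "img_aug_lang", "con",
               "voting", "inter", "intercon")
    bad <- setdiff(models, known)
    if (length(bad))
        stop("unknown model(s): ", paste(bad, collapse = ", "))
    rows <- vector("list", nSplits * length(models))
    ri <- 0L
    for (s in seq_len(nSplits)) {
        split <- makeSplit(cohort, nTestPerClass, seed, s)
        parts <- splitCohort(cohort, split$testIds)
        train <- parts$train; test <- parts$test
        if (select) {
            selSeed <- childSeed(split$splitSeed, 21)
            keepL <- do.call(stabilitySelect,
                             c(list(x = langData(train), seed = selSeed),
                               selectionControl))$selected
            keepI <- do.call(stabilitySelect,
                             c(list(x = imgData(train),
                                    seed = childSeed(selSeed, 1)),
                               selectionControl))$selected
            if (length(keepL) >= 2) {
                train <- MultimodalCohort(
                    restrictFeatures(langData(train), keepL),
                    imgData(train), metadata = train@metadata)
                test <- MultimodalCohort(
                    restrictFeatures(langData(test), keepL),
                    imgData(test), metadata = test@metadata)
            }
            if (length(keepI) >= 2) {
                train <- MultimodalCohort(
                    langData(train),
                    restrictFeatures(imgData(train), keepI),
                    metadata = train@metadata)
                test <- MultimodalCohort(
                    langData(test),
                    restrictFeatures(imgData(test), keepI),
                    metadata = test@metadata)
            }
        }
        for (m in models) {
            res <- tryCatch(
                scoreOneModel(m, train, test, k, weighting, positiveMode,
                              alignMethod, alignParams, alpha,
                              split$splitSeed),
                error = function(e)
                    stop("split ", s, ", model '", m, "': ",
                         conditionMessage(e), call. = FALSE))
            sc <- res$scores; lb <- res$labels
            if (subjectLevel) {
                subj <- sampleSubjects(
                    if (m == "img") imgData(test) else langData(test))
                sc <- tapply(sc, subj, mean)
                lb <- tapply(lb, subj, max)
            }
            met <- computeMetrics(sc, lb)
            ri <- ri + 1L
            rows[[ri]] <- data.frame(split = s, model = m,
                                     auc = met[["auc"]],
                                     accuracy = met[["accuracy"]],
                                     f1 = met[["f1"]])
        }
    }
    perSplit <- do.call(rbind, rows)
    agg <- do.call(rbind, lapply(split(perSplit, perSplit$model),
        function(d) data.frame(
            model = d$model[1], n_splits = nrow(d),
            auc_mean = mean(d$auc), auc_sd = stats::sd(d$auc),
            accuracy_mean = mean(d$accuracy),
            accuracy_sd = stats::sd(d$accuracy),
            f1_mean = mean(d$f1), f1_sd = stats::sd(d$f1))))
    agg <- agg[match(intersect(models, agg$model), agg$model), ]
    rownames(agg) <- NULL
    new("ExperimentReport", perSplit = perSplit, summary = agg,
        config = list(models = models, nSplits = nSplits,
                      nTestPerClass = nTestPerClass, k = k, seed = seed,
                      select = select, weighting = weighting,
                      positiveMode = positiveMode,
                      alignMethod = alignMethod, alignParams = alignParams,
                      alpha = alpha, subjectLevel = subjectLevel))
}

#' @rdname reportAccessors
#' @export
setGeneric("reportSummary", function(x) standardGeneric("reportSummary"))
#' @rdname reportAccessors
#' @export
setGeneric("reportSplits", function(x) standardGeneric("reportSplits"))

#' Experiment-report accessors
#'
#' @param x an \linkS4class{ExperimentReport}.
#' @return \code{reportSummary}: per-model mean and sd of each metric;
#'   \code{reportSplits}: the per-split metric table.
#' @name reportAccessors
NULL

#' @rdname reportAccessors
setMethod("reportSummary", "ExperimentReport", function(x) x@summary)
#' @rdname reportAccessors
setMethod("reportSplits", "ExperimentReport", function(x) x@perSplit)

setMethod("show", "ExperimentReport", function(object) {
    cat(sprintf("ExperimentReport: %d models x %d splits\n",
                length(unique(object@perSplit$model)),
                object@config$nSplits))
    s <- object@summary
    for (i in seq_len(nrow(s)))
        cat(sprintf("  %-14s AUC %.3f +/- %.3f  Acc %.3f  F1 %.3f\n",
                    s$model[i], s$auc_mean[i], s$auc_sd[i],
                    s$accuracy_mean[i], s$f1_mean[i]))
})
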