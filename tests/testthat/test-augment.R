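test_that("pair construction balances classes and respects label constraints", {
    co <- tinyCohort(nAlign = 4, nLangOnly = 0, nImgOnly = 2,
                     replicates = 2)
    alig <- langData(co)
    for (mode in c("same_label_sampled", "own_image")) {
        pr <- buildPairSet(alig, imgData(co), positiveMode = mode,
                           seed = 1)
        expect_equal(length(pr@aligned), 2L * ncol(alig))
        expect_equal(sum(pr@aligned == 1L), ncol(alig))
        expect_true(all(pr@langLabel[pr@aligned == 1L] ==
                        pr@imgLabel[pr@aligned == 1L]))
        expect_true(all(pr@langLabel[pr@aligned == 0L] !=
                        pr@imgLabel[pr@aligned == 0L]))
    }
    prB <- buildPairSet(alig, imgData(co), positiveMode = "both", seed = 1)
    expect_equal(length(prB@aligned), 4L * ncol(alig))
    expect_equal(sum(prB@aligned == 1L), 2L * ncol(alig))
})

test_that("pair construction errors are informative", {
    co <- tinyCohort(nAlign = 2, nLangOnly = 0, nImgOnly = 0)
    empty <- langData(co)[, FALSE]
    expect_error(buildPairSet(empty, imgData(co)), "at least one")
    ## single-label bank cannot supply negatives
    oneClass <- imgData(co)[, SummarizedExperiment::colData(
        imgData(co))$label == 1L]
    expect_error(buildPairSet(langData(co), oneClass, seed = 1),
                 "label != 1")
})

test_that("a separable pair set is fit perfectly and scored sensibly", {
    pr <- separablePairs()
    am <- trainAlignmentModel(pr, seed = 1)
    s <- scoreAlignment(am, pr@lang, pr@img)
    expect_true(all(s >= 0 & s <= 1))
    expect_equal(mean((s >= 0.5) == (pr@aligned == 1L)), 1.0)
    expect_gt(mean(s[pr@aligned == 1L]), mean(s[pr@aligned == 0L]))
    ## determinism: refit and rescore a probe pair
    am2 <- trainAlignmentModel(pr, seed = 1)
    probe <- scoreAlignment(am, pr@lang[1, ], pr@img[1, ])
    expect_identical(probe, scoreAlignment(am2, pr@lang[1, ], pr@img[1, ]))
    expect_identical(probe, scoreAlignment(am, pr@lang[1, ], pr@img[1, ]))
})

test_that("null pairs give chance-level held-out scores", {
    pr <- nullPairs(n = 400)
    half <- seq_len(200)
    trainPr <- new("PairSet", lang = pr@lang[half, ], img = pr@img[half, ],
                   aligned = pr@aligned[half],
                   langLabel = pr@langLabel[half],
                   imgLabel = pr@imgLabel[half])
    am <- trainAlignmentModel(trainPr, seed = 2)
    s <- scoreAlignment(am, pr@lang[-half, ], pr@img[-half, ])
    auc <- computeMetrics(s, pr@aligned[-half])[["auc"]]
    expect_lt(abs(auc - 0.5), 0.1)
})

test_that("alignment model input contracts are enforced", {
    pr <- separablePairs()
    am <- trainAlignmentModel(pr, seed = 1)
    expect_error(scoreAlignment(am, pr@lang[1, 1:2], pr@img[1, ]),
                 "language dimension")
    expect_error(scoreAlignment(am, pr@lang[1, ], pr@img[1, 1:2]),
                 "imaging dimension")
    expect_error(scoreAlignment(new("AlignmentModel"), pr@lang, pr@img),
                 "not fitted")
    oneSided <- new("PairSet", lang = pr@lang, img = pr@img,
                    aligned = rep(1L, nrow(pr@lang)),
                    langLabel = pr@langLabel, imgLabel = pr@imgLabel)
    expect_error(trainAlignmentModel(oneSided), "single alignment class")
})

test_that("combineBank reproduces hand-computed weights and edge cases", {
    bank <- rbind(c(1, 0), c(0, 1), c(2, 2))
    ## stubbed scores 0.5, 0.3, 0.2 with k = 2: weights 0.625 / 0.375
    expect_equal(unname(combineBank(bank, c(0.5, 0.3, 0.2), k = 2)),
                 c(0.625, 0.375))
    ## k = 1: exactly the argmax vector
    expect_identical(unname(combineBank(bank, c(0.2, 0.9, 0.1), k = 1)),
                     c(0, 1))
    ## k = |bank| with uniform weighting: component-wise mean
    expect_equal(unname(combineBank(bank, c(0.9, 0.5, 0.1), k = 3,
                                    weighting = "uniform")),
                 colMeans(bank))
    ## all-zero scores fall back to uniform over the tie-broken top k
    expect_equal(unname(combineBank(bank, c(0, 0, 0), k = 2)),
                 colMeans(bank[1:2, ]))
    ## appending a zero-score vector leaves the output unchanged
    bank2 <- rbind(bank, c(99, 99))
    expect_equal(combineBank(bank2, c(0.5, 0.3, 0.2, 0), k = 3),
                 combineBank(bank, c(0.5, 0.3, 0.2), k = 3))
    expect_error(combineBank(bank, c(0.5, 0.3, 0.2), k = 4), "config error")
    expect_error(combineBank(bank, c(0.5, 1.3, 0.2), k = 2), "0, 1")
})

test_that("score ties are broken by the deterministic ordering key", {
    bank <- rbind(a = c(1, 0), b = c(0, 1), c = c(5, 5))
    tied <- c(0.4, 0.4, 0.4)
    expect_equal(unname(combineBank(bank, tied, k = 2)),
                 colMeans(bank[1:2, ]))
    ## reversing the key reverses the preference
    expect_equal(unname(combineBank(bank, tied, k = 2, tieOrder = 3:1)),
                 colMeans(bank[3:2, ]))
})

test_that("augmented vectors stay in the bank's convex hull", {
    co <- tinyCohort(nAlign = 4, nLangOnly = 1, nImgOnly = 2)
    pr <- buildPairSet(langData(co), imgData(co), seed = 1)
    am <- trainAlignmentModel(pr, seed = 1)
    bankM <- t(SummarizedExperiment::assay(imgData(co)))
    lo <- apply(bankM, 2, min); hi <- apply(bankM, 2, max)
    lm <- t(SummarizedExperiment::assay(langData(co)))
    for (i in seq_len(nrow(lm))) {
        v <- augmentOne(am, lm[i, ], imgData(co), k = 3)
        expect_true(all(v >= lo - 1e-9 & v <= hi + 1e-9))
    }
})

test_that("augmenting a dataset preserves order, labels and dimensions", {
    co <- simulateCohort(nLangOnly = 2, nImgOnly = 2, nAlign = 4,
                         dLang = 112, dImg = 56, replicates = 2, seed = 4)
    alig <- langData(co)[, SummarizedExperiment::colData(
        langData(co))$subject_id %in% alignedIds(co)]
    pr <- buildPairSet(alig, imgData(co), seed = 2)
    am <- trainAlignmentModel(pr, params = list(nrounds = 5), seed = 2)
    aug <- augmentSamples(am, langData(co), imgData(co), k = 3)
    expect_equal(ncol(aug), ncol(langData(co)))          # n in -> n out
    expect_equal(nrow(aug), 112L + 56L)                  # concatenated dims
    expect_identical(SummarizedExperiment::colData(aug)$label,
                     SummarizedExperiment::colData(langData(co))$label)
    expect_identical(SummarizedExperiment::colData(aug)$subject_id,
                     SummarizedExperiment::colData(langData(co))$subject_id)
    expect_equal(sum(startsWith(rownames(aug), "AUG:")), 56L)
    ## matches per-sample augmentation
    lm <- t(SummarizedExperiment::assay(langData(co)))
    v1 <- augmentOne(am, lm[1, ], imgData(co), k = 3)
    expect_equal(unname(
        SummarizedExperiment::assay(aug)[startsWith(rownames(aug), "AUG:"),
                                         1]),
        unname(v1))
    ## substituting the true auxiliary vector for aligned subjects
    augT <- augmentSamples(am, langData(co), imgData(co), k = 3,
                           useTrueAux = TRUE)
    subj1 <- SummarizedExperiment::colData(langData(co))$subject_id[1]
    own <- SummarizedExperiment::assay(imgData(co))[,
        SummarizedExperiment::colData(imgData(co))$subject_id == subj1]
    expect_equal(unname(SummarizedExperiment::assay(augT)[
        startsWith(rownames(augT), "AUG:"), 1]), unname(own))
})
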