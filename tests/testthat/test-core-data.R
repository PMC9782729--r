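test_that("feature tables round-trip through CSV and reject bad cells", {
    tmp <- withr::local_tempfile(fileext = ".csv")
    writeLines(c("subject_id,label,replicate_id,f1,f2",
                 "s1,1,1,0.5,1.25",
                 "s1,1,2,0.75,2.5",
                 "s2,0,1,-1.5,0.125"), tmp)
    se <- readFeatureTable(tmp, "language")
    expect_equal(ncol(se), 3L)           # row count preserved
    expect_equal(nrow(se), 2L)
    expect_equal(rownames(se), c("f1", "f2"))  # header order preserved
    expect_identical(readFeatureTable(tmp, "language"), se)  # deterministic

    out <- withr::local_tempfile(fileext = ".csv")
    writeFeatureTable(se, out, sidecar = TRUE)
    back <- readFeatureTable(out, "language")
    expect_equal(SummarizedExperiment::assay(back),
                 SummarizedExperiment::assay(se))
    expect_identical(SummarizedExperiment::colData(back)$subject_id,
                     SummarizedExperiment::colData(se)$subject_id)
    expect_true(file.exists(paste0(out, ".json")))

    ## a noisier table still round-trips at text precision
    set.seed(3)
    se2 <- makeModality(matrix(rnorm(40), 8, 5,
                               dimnames = list(NULL, paste0("g", 1:5))),
                        subject = rep(c("a", "b"), 4),
                        label = rep(c(1, 0), 4),
                        replicate = rep(1:4, each = 2))
    writeFeatureTable(se2, out)
    expect_equal(SummarizedExperiment::assay(readFeatureTable(out,
                                                              "imaging")),
                 SummarizedExperiment::assay(se2), tolerance = 1e-12)
})

test_that("loading rejects missing cells, bad labels and broken schemas", {
    tmp <- withr::local_tempfile(fileext = ".csv")
    writeLines(c("subject_id,label,f1,f2",
                 "s1,1,0.5,",
                 "s2,0,1.0,2.0"), tmp)
    expect_error(readFeatureTable(tmp, "language"), "f2.*row 1")

    writeLines(c("subject_id,label,f1", "s1,2,0.5"), tmp)
    expect_error(readFeatureTable(tmp, "language"), "0/1")

    writeLines(c("subject_id,f1", "s1,0.5"), tmp)
    expect_error(readFeatureTable(tmp, "language"), "missing required")

    writeLines(c("subject_id,label,f1,f1", "s1,1,0.5,0.6"), tmp)
    expect_error(readFeatureTable(tmp, "language"), "duplicated")

    expect_error(readFeatureTable(file.path(tempdir(), "nope.csv"),
                                  "language"), "not found")
})

test_that("cohort partitions are disjoint, exhaustive and correctly sized", {
    co <- tinyCohort(nAlign = 4, nLangOnly = 2, nImgOnly = 3)
    expect_equal(length(alignedIds(co)), 4L)
    expect_equal(length(langOnlyIds(co)), 2L)
    expect_equal(length(imgOnlyIds(co)), 3L)
    ## |lang-only| + |aligned| = distinct language subjects, same for imaging
    langSubj <- unique(SummarizedExperiment::colData(langData(co))$subject_id)
    imgSubj <- unique(SummarizedExperiment::colData(imgData(co))$subject_id)
    expect_equal(length(langOnlyIds(co)) + length(alignedIds(co)),
                 length(langSubj))
    expect_equal(length(imgOnlyIds(co)) + length(alignedIds(co)),
                 length(imgSubj))
    expect_length(intersect(alignedIds(co), langOnlyIds(co)), 0L)
    expect_length(intersect(alignedIds(co), imgOnlyIds(co)), 0L)

    ## the study-shaped overlap: 40 language, 43 imaging, 16 shared
    big <- simulateCohort(nLangOnly = 24, nImgOnly = 27, nAlign = 16,
                          dLang = 4, dImg = 3, replicates = 2, seed = 1)
    expect_equal(length(alignedIds(big)), 16L)
    expect_equal(length(langOnlyIds(big)) + 16L, 40L)
    expect_equal(length(imgOnlyIds(big)) + 16L, 43L)
})

test_that("disjoint subject sets give an empty aligned partition", {
    lang <- makeModality(matrix(1:4, 2, 2,
                                dimnames = list(NULL, c("f1", "f2"))),
                         subject = c("a", "b"), label = c(1, 0))
    img <- makeModality(matrix(1:4, 2, 2,
                               dimnames = list(NULL, c("g1", "g2"))),
                        subject = c("c", "d"), label = c(1, 0))
    co <- MultimodalCohort(lang, img)
    expect_length(alignedIds(co), 0L)
})

test_that("conflicting labels across modalities are rejected", {
    lang <- makeModality(matrix(1:2, 1, 2,
                                dimnames = list(NULL, c("f1", "f2"))),
                         subject = "a", label = 1)
    img <- makeModality(matrix(1:2, 1, 2,
                               dimnames = list(NULL, c("g1", "g2"))),
                        subject = "a", label = 0)
    expect_error(MultimodalCohort(lang, img), "conflicting labels")
})

test_that("subject labels are consistent and subsetting keeps whole subjects", {
    co <- tinyCohort()
    lab <- subjectLabels(co)
    expect_true(all(lab %in% c(0L, 1L)))
    keep <- c("A01", "A02", "L01")
    sub <- subsetCohort(co, keep)
    expect_setequal(unique(
        SummarizedExperiment::colData(langData(sub))$subject_id), keep)
    expect_setequal(unique(
        SummarizedExperiment::colData(imgData(sub))$subject_id),
        c("A01", "A02"))
})
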