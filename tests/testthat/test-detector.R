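sigmoidOracle <- function(model, x) {
    xs <- sweep(sweep(x, 2, model@center, "-"), 2, model@scale, "/")
    1 / (1 + exp(-(model@intercept + as.numeric(xs %*% model@coefficients))))
}

test_that("a separable one-feature problem is classified perfectly", {
    set.seed(1)
    n <- 80
    y <- rep(c(0L, 1L), n / 2)
    x <- matrix(y + rnorm(n, sd = 0.01), ncol = 1,
                dimnames = list(NULL, "f"))
    det <- trainDetector(x, y, seed = 1)
    xt <- matrix(rep(c(0L, 1L), 10) + rnorm(20, sd = 0.01), ncol = 1,
                 dimnames = list(NULL, "f"))
    s <- predictScores(det, xt)
    expect_equal(mean((s >= 0.5) == rep(c(0L, 1L), 10)), 1.0)
})

test_that("pure-noise features give chance-level held-out AUC", {
    set.seed(2)
    x <- matrix(rnorm(400 * 6), 400, 6,
                dimnames = list(NULL, paste0("f", 1:6)))
    y <- rbinom(400, 1, 0.5)
    det <- trainDetector(x[1:200, ], y[1:200], seed = 2)
    auc <- computeMetrics(predictScores(det, x[201:400, ]),
                          y[201:400])[["auc"]]
    expect_lt(abs(auc - 0.5), 0.1)
})

test_that("L1-dominant fits concentrate weight on the informative feature", {
    set.seed(3)
    n <- 200
    y <- rbinom(n, 1, 0.5)
    x <- matrix(rnorm(n * 8), n, 8, dimnames = list(NULL, paste0("f", 1:8)))
    x[, 1] <- x[, 1] + 2 * y
    det <- trainDetector(x, y, alpha = 0.95, seed = 3)
    expect_equal(which.max(abs(det@coefficients)), c(f1 = 1L))
})

test_that("scores match the closed-form standardized sigmoid", {
    set.seed(4)
    x <- matrix(rnorm(60 * 4), 60, 4, dimnames = list(NULL, paste0("f", 1:4)))
    y <- as.integer(x[, 2] + rnorm(60, sd = 0.5) > 0)
    det <- trainDetector(x, y, seed = 4)
    probe <- matrix(rnorm(5 * 4), 5, 4, dimnames = list(NULL, paste0("f", 1:4)))
    expect_equal(predictScores(det, probe), sigmoidOracle(det, probe),
                 tolerance = 1e-12)
    expect_length(predictScores(det, probe), 5L)
})

test_that("an all-zero coefficient model scores the intercept's sigmoid", {
    det <- new("DetectionModel",
               coefficients = c(f1 = 0, f2 = 0), intercept = 0.4,
               center = c(f1 = 0, f2 = 0), scale = c(f1 = 1, f2 = 1),
               alpha = 0.5, lambda = 1, fitted = TRUE)
    s <- predictScores(det, matrix(rnorm(10), 5, 2,
                                   dimnames = list(NULL, c("f1", "f2"))))
    expect_equal(s, rep(plogis(0.4), 5))
})

test_that("input contracts: feature mismatch, single class, unfitted state", {
    set.seed(5)
    x <- matrix(rnorm(40), 20, 2, dimnames = list(NULL, c("f1", "f2")))
    det <- trainDetector(x, rep(c(0, 1), 10), seed = 5)
    bad <- matrix(rnorm(4), 2, 2, dimnames = list(NULL, c("f1", "g9")))
    expect_error(predictScores(det, bad), "missing: \\[f2\\]")
    expect_error(trainDetector(x, rep(1, 20)), "single class")
    expect_error(predictScores(new("DetectionModel"), x), "not fitted")
    expect_error(featureImportance(new("DetectionModel")), "not fitted")
})

test_that("importance ranks the published language coefficients correctly", {
    cf <- c("coexistence of adverb phrase, verb phrase and noun phrase" = -2.04,
            "word length in letters" = -1.05,
            "LIWC word category of nonfluencies" = -0.91,
            "LIWC word category of we" = 0.85)
    imp <- featureImportance(cf[c(4, 2, 1, 3)])  # scrambled input order
    expect_equal(imp$feature[1],
                 "coexistence of adverb phrase, verb phrase and noun phrase")
    expect_equal(imp$feature[2], "word length in letters")
    expect_equal(imp$feature[3], "LIWC word category of nonfluencies")
    expect_equal(imp$feature[4], "LIWC word category of we")
    expect_equal(imp$importance, c(2.04, 1.05, 0.91, 0.85))
})

test_that("importance ties break alphabetically and ignore signs", {
    zero <- featureImportance(c(b = 0, c = 0, a = 0))
    expect_equal(zero$feature, c("a", "b", "c"))
    cf <- c(x = 1.5, y = -2, z = 0.5)
    expect_equal(featureImportance(cf)$feature,
                 featureImportance(-cf)$feature)
})

test_that("rescaling a raw feature leaves predictions unchanged", {
    set.seed(6)
    x <- matrix(rnorm(200 * 3), 200, 3,
                dimnames = list(NULL, paste0("f", 1:3)))
    y <- as.integer(x[, 1] - x[, 3] + rnorm(200, sd = 0.8) > 0)
    x2 <- x; x2[, 1] <- x2[, 1] * 100
    det1 <- trainDetector(x, y, seed = 6)
    det2 <- trainDetector(x2, y, seed = 6)
    probe <- x[1:10, ]; probe2 <- x2[1:10, ]
    expect_equal(predictScores(det1, probe), predictScores(det2, probe2),
                 tolerance = 1e-6)
})
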