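# Deterministic miniature fixtures built in code.

# A small fully deterministic cohort: nAlign aligned subjects plus
# modality-only subjects, tiny dimensions, alternating labels.
tinyCohort <- function(nAlign = 4, nLangOnly = 2, nImgOnly = 2,
                       dLang = 3, dImg = 2, replicates = 2) {
    nL <- nAlign + nLangOnly
    nI <- nAlign + nImgOnly
    langSubj <- c(sprintf("A%02d", seq_len(nAlign)),
                  sprintf("L%02d", seq_len(nLangOnly)))
    imgSubj <- c(sprintf("A%02d", seq_len(nAlign)),
                 sprintf("I%02d", seq_len(nImgOnly)))
    langLab <- rep_len(c(1L, 0L), nL)
    imgLab <- c(langLab[seq_len(nAlign)], rep_len(c(1L, 0L), nImgOnly))
    langRows <- matrix(seq_len(nL * replicates * dLang) / 10,
                       nL * replicates, dLang,
                       dimnames = list(NULL, paste0("lf", seq_len(dLang))))
    imgRows <- matrix(as.numeric(seq_len(nI * dImg)), nI, dImg,
                      dimnames = list(NULL, paste0("if", seq_len(dImg))))
    lang <- makeModality(langRows,
                         subject = rep(langSubj, each = replicates),
                         label = rep(langLab, each = replicates),
                         replicate = rep(seq_len(replicates), nL),
                         modality = "language")
    img <- makeModality(imgRows, subject = imgSubj, label = imgLab,
                        modality = "imaging")
    MultimodalCohort(lang, img)
}

# Linearly separable pair set: the sign of the first coordinate encodes the
# clinical label on both sides, so alignment (label agreement) is the sign
# product — separable with a two-level interaction.
separablePairs <- function(n = 60, d = 4, seed = 42) {
    set.seed(seed)
    yl <- rep_len(c(1L, 0L), n)
    yi <- ifelse(seq_len(n) <= n / 2, yl, 1L - yl)  # half aligned
    lang <- matrix(rnorm(n * d, sd = 0.1), n, d,
                   dimnames = list(NULL, paste0("l", seq_len(d))))
    img <- matrix(rnorm(n * d, sd = 0.1), n, d,
                  dimnames = list(NULL, paste0("i", seq_len(d))))
    lang[, 1] <- lang[, 1] + ifelse(yl == 1L, 3, -3)
    img[, 1] <- img[, 1] + ifelse(yi == 1L, 3, -3)
    new("PairSet", lang = lang, img = img,
        aligned = as.integer(yl == yi), langLabel = yl, imgLabel = yi)
}

# Random-feature pair set whose alignment labels are independent coin flips.
nullPairs <- function(n = 400, d = 4, seed = 7) {
    set.seed(seed)
    new("PairSet",
        lang = matrix(rnorm(n * d), n, d,
                      dimnames = list(NULL, paste0("l", seq_len(d)))),
        img = matrix(rnorm(n * d), n, d,
                     dimnames = list(NULL, paste0("i", seq_len(d)))),
        aligned = rbinom(n, 1L, 0.5),
        langLabel = rbinom(n, 1L, 0.5), imgLabel = rbinom(n, 1L, 0.5))
}

# O(n^2) pairwise concordance AUC, ties counted one half.
bruteForceAUC <- function(scores, labels) {
    pos <- scores[labels == 1]
    neg <- scores[labels == 0]
    tot <- 0
    for (p in pos) for (q in neg)
        tot <- tot + (p > q) + 0.5 * (p == q)
    tot / (length(pos) * length(neg))
}
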