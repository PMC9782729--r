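#' Simulate a partially aligned two-modality cohort
#'
#' Generates a synthetic cohort with the statistical structure the
#' crossmodal-augmentation method assumes: every subject carries a shared
#' latent vector \eqn{z} that both modalities load on linearly, plus a
#' class-dependent mean shift and modality-specific Gaussian noise. Language
#' is observed as several per-transcript replicates around a subject-level
#' random effect; imaging is one vector per subject. Only a configurable
#' subset of subjects is observed in both modalities.
#'
#' Per subject \eqn{s} with label \eqn{y_s}: latent
#' \eqn{z_s \sim N(0, I_q)}; imaging vector
#' \eqn{x^{img}_s = A_{img} z_s + (y_s - 1/2)\,\delta_{img} u_{img} + \epsilon_s};
#' language replicate \eqn{r}
#' \eqn{x^{lang}_{sr} = A_{lang} z_s + (y_s - 1/2)\,\delta_{lang} u_{lang} + b_s + e_{sr}},
#' with loading matrices \eqn{A} (entries \eqn{N(0, \ell^2/q)} at
#' per-modality loading scale \eqn{\ell}), unit class directions \eqn{u},
#' subject effect \eqn{b_s \sim N(0, \sigma_b^2 I)} and noise
#' \eqn{\epsilon_s, e_{sr}} of standard deviation \eqn{\sigma_b},
#' \eqn{\sigma_w}.
#'
#' In addition to the mean shifts, the language modality carries a
#' class-conditional dispersion signal: on a fixed random subset of
#' \code{dispFeatures} features, MCI transcripts draw their within-subject
#' noise with sd \code{withinNoise * dispRatio}. This emulates the
#' well-documented increased variability of speech in cognitive impairment
#' and gives the language-label relationship a component that linear
#' detectors cannot exploit but flexible alignment models can — the regime
#' the crossmodal augmentation method targets. The default effect sizes
#' make imaging the markedly stronger modality, mirroring the study setting
#' the generator emulates (held-out AUC near 0.97 for imaging and near 0.8
#' for language at the default cohort shape).
#'
#' Labels of aligned subjects are balanced deterministically at
#' \code{round(nAlign * classBalance)} positives so the repeated-split
#' protocol (which draws its test set from the aligned partition) is always
#' feasible; the remaining subjects draw
#' \eqn{y \sim \mathrm{Bernoulli}(\code{classBalance})}.
#'
#' Generation is a pure function of the arguments: the same seed gives a
#' bit-identical cohort. Loading matrices, class directions, latents and the
#' full configuration are stored in \code{cohortMetadata(x)$truth} for
#' inspection.
#'
#' @param nLangOnly,nImgOnly,nAlign subject counts per partition (defaults
#'   give the 40-language / 43-imaging / 16-aligned cohort shape).
#' @param dLang,dImg feature dimensions (defaults 112 and 56).
#' @param replicates transcripts per language subject (default 15).
#' @param latentDim shared latent dimension \eqn{q}.
#' @param loadLang,loadImg per-modality latent loading scales \eqn{\ell};
#'   the language default is deliberately below the imaging one so that
#'   subject-level latent nuisance does not swamp the transcript-level class
#'   signal available to the alignment model.
#' @param effectLang,effectImg class-separation magnitudes
#'   \eqn{\delta_{lang}, \delta_{img} \ge 0}.
#' @param withinNoise within-subject (per-transcript) noise sd
#'   \eqn{\sigma_w}.
#' @param betweenNoise between-subject noise sd \eqn{\sigma_b}.
#' @param dispFeatures number of language features whose within-subject
#'   noise is inflated for MCI subjects (class-conditional dispersion;
#'   0 disables). Default \code{NULL} means \code{min(40, dLang)}.
#' @param dispRatio within-subject noise sd multiplier for MCI transcripts
#'   on the dispersion feature subset (1 = no dispersion signal).
#' @param classBalance probability of label 1, in (0, 1).
#' @param seed integer RNG seed.
#' @return a \linkS4class{MultimodalCohort}.
#' @examples
#' cohort <- simulateCohort(nLangOnly = 4, nImgOnly = 4, nAlign = 4,
#'                          dLang = 6, dImg = 3, replicates = 2, seed = 1)
#' cohort
#' @export
simulateCohort <- function(nLangOnly = 24, nImgOnly = 27, nAlign = 16,
                           dLang = 112, dImg = 56, replicates = 15,
                           latentDim = 6, loadLang = 0.4, loadImg = 1,
                           effectLang = 2.5, effectImg = 2.2,
                           withinNoise = 0.6, betweenNoise = 0.4,
                           dispFeatures = NULL, dispRatio = 5,
                           classBalance = 0.5, seed = 1) {
    if (any(c(nLangOnly, nImgOnly, nAlign) < 0))
        stop("config error: subject counts must be >= 0")
    if (dLang < 1 || dImg < 1 || latentDim < 1 || replicates < 1)
        stop("config error: dimensions and replicate count must be >= 1")
    if (effectLang < 0 || effectImg < 0 || withinNoise < 0 ||
        betweenNoise < 0 || loadLang < 0 || loadImg < 0)
        stop("config error: effect sizes, loadings and noise sds must be >= 0")
    if (is.null(dispFeatures))
        dispFeatures <- min(40L, dLang)
    if (dispFeatures < 0 || dispFeatures > dLang || dispRatio < 1)
        stop("config error: need 0 <= dispFeatures <= dLang and ",
             "dispRatio >= 1")
    if (classBalance <= 0 || classBalance >= 1)
        stop("config error: classBalance must be in (0, 1)")
    if (nAlign + nLangOnly < 1 || nAlign + nImgOnly < 1)
        stop("config error: each modality needs at least one subject")

    nTotal <- nLangOnly + nImgOnly + nAlign
    ids <- sprintf("S%04d", seq_len(nTotal))
    alignedSet <- ids[seq_len(nAlign)]
    langSet <- c(alignedSet, ids[nAlign + seq_len(nLangOnly)])
    imgSet <- c(alignedSet, ids[nAlign + nLangOnly + seq_len(nImgOnly)])

    cohort <- withSeed(seed, {
        ## labels: aligned partition balanced exactly, rest Bernoulli
        lab <- integer(nTotal)
        names(lab) <- ids
        nPos <- round(nAlign * classBalance)
        if (nAlign > 0)
            lab[sample(alignedSet, nPos)] <- 1L
        rest <- if (nAlign > 0) ids[-seq_len(nAlign)] else ids
        if (length(rest))
            lab[rest] <- stats::rbinom(length(rest), 1L, classBalance)

        q <- latentDim
        Alang <- matrix(stats::rnorm(dLang * q, sd = loadLang / sqrt(q)),
                        dLang, q)
        Aimg <- matrix(stats::rnorm(dImg * q, sd = loadImg / sqrt(q)),
                       dImg, q)
        uLang <- stats::rnorm(dLang); uLang <- uLang / sqrt(sum(uLang^2))
        uImg <- stats::rnorm(dImg); uImg <- uImg / sqrt(sum(uImg^2))
        z <- matrix(stats::rnorm(q * nTotal), q, nTotal,
                    dimnames = list(NULL, ids))

        langFeat <- paste0("lang_", sprintf("%03d", seq_len(dLang)))
        imgFeat <- paste0("img_", sprintf("%03d", seq_len(dImg)))

        imgM <- t(Aimg %*% z[, imgSet, drop = FALSE]) +
            outer(lab[imgSet] - 0.5, effectImg * uImg) +
            matrix(stats::rnorm(length(imgSet) * dImg, sd = betweenNoise),
                   length(imgSet), dImg)
        colnames(imgM) <- imgFeat

        nLangSamp <- length(langSet) * replicates
        langSubj <- rep(langSet, each = replicates)
        langRep <- rep(seq_len(replicates), times = length(langSet))
        bSubj <- matrix(stats::rnorm(length(langSet) * dLang,
                                     sd = betweenNoise),
                        length(langSet), dLang,
                        dimnames = list(langSet, NULL))
        ## within-subject noise, with class-conditional dispersion: MCI
        ## transcripts are more variable on a fixed feature subset
        dispIdx <- sort(sample.int(dLang, dispFeatures))
        sdMat <- matrix(withinNoise, nLangSamp, dLang)
        if (dispFeatures > 0)
            sdMat[lab[langSubj] == 1L, dispIdx] <- withinNoise * dispRatio
        langM <- t(Alang %*% z[, langSubj, drop = FALSE]) +
            outer(lab[langSubj] - 0.5, effectLang * uLang) +
            bSubj[langSubj, , drop = FALSE] +
            matrix(stats::rnorm(nLangSamp * dLang), nLangSamp, dLang) * sdMat
        colnames(langM) <- langFeat
        rownames(langM) <- NULL

        lang <- makeModality(langM, subject = langSubj,
                             label = lab[langSubj], replicate = langRep,
                             modality = "language")
        img <- makeModality(imgM, subject = imgSet, label = lab[imgSet],
                            modality = "imaging")
        truth <- list(config = list(nLangOnly = nLangOnly,
                                    nImgOnly = nImgOnly, nAlign = nAlign,
                                    dLang = dLang, dImg = dImg,
                                    replicates = replicates,
                                    latentDim = latentDim,
                                    loadLang = loadLang, loadImg = loadImg,
                                    effectLang = effectLang,
                                    effectImg = effectImg,
                                    withinNoise = withinNoise,
                                    betweenNoise = betweenNoise,
                                    dispFeatures = dispFeatures,
                                    dispRatio = dispRatio,
                                    classBalance = classBalance,
                                    seed = seed),
                      dispIdx = dispIdx, labels = lab, latents = z,
                      loadings = list(lang = Alang, img = Aimg),
                      classDirections = list(lang = uLang, img = uImg))
        MultimodalCohort(lang, img, metadata = list(truth = truth))
    })
    cohort
}
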