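#' Run the full analysis pipeline on a cohort
#'
#' Fits multivariate and univariate signature weights for every aberration
#' event, scores every sample (signature scores from the multivariate
#' weights, immune scores from reference profiles when available),
#' classifies good versus poor prognosis with random forests over the
#' signature (Sig), immune (Imm), clinical (Clin) and combined feature
#' blocks, optionally runs backward feature elimination, and fits Cox
#' models (per-feature univariate and clinically adjusted, stepwise
#' selection, cross-validated concordance, tertile risk groups). Reports are
#' written under \code{outDir}.
#'
#' @param cohort a \linkS4class{ProgCohort} with aberration matrix, clinical
#'   and survival data (e.g. from \code{\link{simulateCohort}} or
#'   \code{\link{readCohortBundle}}).
#' @param outDir output directory for the weights/scores TSVs and JSON
#'   reports.
#' @param immuneReference optional cell types x genes reference matrix; for
#'   simulated cohorts it defaults to the cohort's ground-truth reference.
#' @param nPerm permutations per score.
#' @param seed master seed.
#' @param horizon prognosis horizon (years) for classification labels.
#' @param kFolds cross-validation folds.
#' @param immuneTopK markers per cell type for the immune weight sets.
#' @param optimize if TRUE, run backward feature elimination on the combined
#'   block (slower).
#' @param ntree forest size.
#' @return invisibly, a list with \code{scores}, \code{weights},
#'   \code{classification}, \code{survival} and the report paths.
#' @export
runAll <- function(cohort, outDir, immuneReference = NULL, nPerm = 1000L,
                   seed = 1L, horizon = 10, kFolds = 10L, optimize = FALSE,
                   immuneTopK = 100L, ntree = 500L) {
    if (!dir.exists(outDir) &&
        !dir.create(outDir, recursive = TRUE, showWarnings = FALSE))
        stop("cannot create output directory: ", outDir, call. = FALSE)
    ab <- aberrations(cohort)
    stopIfNot(!is.null(ab), "cohort has no aberration matrix")

    .msg("fitting multivariate and univariate signature weights")
    multi <- fitSignatures(cohort, mode = "multivariate")
    uni <- fitSignatures(cohort, mode = "univariate")
    writeWeightsTsv(multi$weights,
                    file.path(outDir, "weights_multivariate.tsv"))
    writeWeightsTsv(uni$weights,
                    file.path(outDir, "weights_univariate.tsv"))

    if (is.null(immuneReference)) {
        truth <- groundTruth(cohort)
        if (!is.null(truth)) immuneReference <- truth$reference
    }
    immuneWeights <- NULL
    if (!is.null(immuneReference))
        immuneWeights <- deriveImmuneWeights(immuneReference, topK = immuneTopK)

    .msg("scoring ", ncol(cohort), " samples x ",
         length(multi$weights) + length(immuneWeights), " weight sets")
    sigScores <- scoreCohort(cohort, multi$weights, nPerm = nPerm,
                             seed = subSeed(seed, "scoring", 1L))
    immScores <- NULL
    scores <- sigScores
    if (!is.null(immuneWeights)) {
        immScores <- scoreCohort(cohort, immuneWeights, nPerm = nPerm,
                                 seed = subSeed(seed, "scoring", 2L))
        scores <- cbind(sigScores, immScores)
    }
    writeScoresTsv(scores, file.path(outDir, "scores.tsv"))

    clin <- clinicalData(cohort)
    surv <- survivalData(cohort)

    # ---- classification -------------------------------------------------
    labels <- labelPrognosis(surv, horizon = horizon)
    blocks <- list(Sig = as.data.frame(sigScores))
    if (!is.null(immScores)) blocks$Imm <- as.data.frame(immScores)
    if (ncol(clin)) blocks$Clin <- clin
    combined <- do.call(cbind, unname(blocks))
    blocks$All <- combined
    classReport <- list(horizon = horizon, k = kFolds, seed = seed,
                        nGood = sum(labels == "good", na.rm = TRUE),
                        nPoor = sum(labels == "poor", na.rm = TRUE))
    .msg("cross-validated classification over ", length(blocks), " blocks")
    for (bl in names(blocks)) {
        cv <- crossValidatedProbabilities(blocks[[bl]], labels, k = kFolds,
                                          seed = seed, ntree = ntree)
        classReport$auc[[bl]] <- cv$auc
    }
    classReport$importance <- rfImportance(combined, labels, seed = seed,
                                           ntree = ntree)
    if (optimize) {
        .msg("backward feature elimination")
        opt <- backwardSelection(combined, labels, k = kFolds, seed = seed,
                                 ntree = ntree)
        classReport$optimized <- list(selected = opt$selected,
                                      trajectory = opt$trajectory)
    }
    jsonlite::write_json(classReport,
                         file.path(outDir, "classification_report.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")

    # ---- survival models ------------------------------------------------
    .msg("Cox models")
    univarTab <- do.call(rbind, lapply(colnames(scores), function(f) {
        m <- coxFit(data.frame(score = scores[, f]), surv$time, surv$event)
        data.frame(feature = f, coef = m$coef["score", "coef"],
                   hr = m$coef["score", "hr"], p = m$coef["score", "p"])
    }))
    adjTab <- NULL
    if (ncol(clin)) {
        adjTab <- do.call(rbind, lapply(colnames(scores), function(f) {
            m <- coxFit(cbind(data.frame(score = scores[, f]), clin),
                        surv$time, surv$event)
            data.frame(feature = f, coef = m$coef["score", "coef"],
                       hr = m$coef["score", "hr"], p = m$coef["score", "p"])
        }))
    }
    sw <- stepwiseCox(as.data.frame(scores), surv$time, surv$event,
                      forced = if (ncol(clin)) clin else NULL)
    cvci <- crossValidatedConcordance(
        cbind(as.data.frame(scores)[, sw$selected, drop = FALSE],
              if (ncol(clin)) clin), surv$time, surv$event, k = kFolds,
        seed = seed)
    groups <- predictRiskGroups(sw, cbind(as.data.frame(scores),
                                          if (ncol(clin)) clin))
    km <- kmLogrank(groups$group, surv$time, surv$event)
    survReport <- list(
        univariate = univarTab, adjusted = adjTab,
        stepwise = list(selected = sw$selected,
                        coef = data.frame(covariate = rownames(sw$coef),
                                          sw$coef)),
        cvConcordance = cvci$ci,
        riskGroups = list(sizes = as.list(table(groups$group)),
                          logrankP = km$p))
    jsonlite::write_json(survReport,
                         file.path(outDir, "survival_report.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
    utils::write.table(km$curves, file.path(outDir, "km_curves.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)

    invisible(list(scores = scores,
                   weights = list(multivariate = multi$weights,
                                  univariate = uni$weights,
                                  immune = immuneWeights),
                   classification = classReport,
                   survival = survReport,
                   outDir = outDir))
}
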