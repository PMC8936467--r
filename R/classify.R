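#' Dichotomize survival into good and poor prognosis at a horizon
#'
#' Poor prognosis: the event occurred within the horizon. Good prognosis:
#' followed beyond the horizon without an event (or the event occurred after
#' it). Samples censored before the horizon carry no label and are excluded.
#'
#' @param survivalTable data.frame with \code{time} (nonnegative) and
#'   \code{event} (1 = observed) columns, rownames = samples.
#' @param horizon follow-up horizon in the time unit of the table
#'   (default 10 years).
#' @return factor with levels \code{good}, \code{poor} and NA for excluded
#'   samples, named by sample.
#' @export
labelPrognosis <- function(survivalTable, horizon = 10) {
    t <- survivalTable$time
    e <- as.integer(survivalTable$event)
    stopIfNot(all(t >= 0), "negative survival time")
    lab <- ifelse(e == 1L & t <= horizon, "poor",
                  ifelse(t >= horizon, "good", NA))
    factor(setNames(lab, rownames(survivalTable)),
           levels = c("good", "poor"))
}

# Stratified k-fold assignment over a canonical (lexicographic) sample
# ordering; the seed controls the within-class shuffle only, so fold
# membership is invariant to the input row order.
.stratifiedFolds <- function(labels, k, seed) {
    folds <- integer(length(labels))
    names(folds) <- names(labels)
    canon <- order(names(labels))
    set.seed(seed)
    for (cl in levels(labels)) {
        idx <- canon[labels[canon] == cl]
        idx <- idx[sample.int(length(idx))]
        folds[idx] <- rep_len(seq_len(k), length(idx))
    }
    folds
}

.dropIncomplete <- function(features, labels) {
    keep <- !is.na(labels) & complete.cases(features)
    if (sum(!is.na(labels)) - sum(keep) > 0)
        .msg("dropped ", sum(!is.na(labels)) - sum(keep),
             " labeled sample(s) with missing feature values")
    features <- features[keep, , drop = FALSE]
    labels <- droplevels(labels[keep])
    # canonical sample order, so results do not depend on input row order
    if (!is.null(rownames(features)) && !anyDuplicated(rownames(features))) {
        ord <- order(rownames(features))
        features <- features[ord, , drop = FALSE]
        labels <- labels[ord]
        names(labels) <- rownames(features)
    }
    list(features = features, labels = labels)
}

#' Pooled cross-validated class probabilities from a random forest
#'
#' Stratified k-fold cross-validation: a forest (500 trees, sqrt(p) features
#' per split) is trained on k-1 folds and class probabilities are predicted
#' on the held-out fold; the pooled out-of-fold probabilities are scored once
#' for a single AUC.
#'
#' @param features samples x features numeric data.frame or matrix (rownames
#'   = samples; rows with missing values are dropped with a message).
#' @param labels factor with two levels (\code{good}/\code{poor} from
#'   \code{\link{labelPrognosis}}, or any binary factor); NA = excluded.
#' @param k number of folds (default 10).
#' @param seed controls fold assignment and forest randomness.
#' @param ntree forest size.
#' @return list with \code{prob} (pooled probability of the second level, per
#'   sample), \code{labels}, \code{auc}, \code{folds} and \code{seed}.
#' @export
crossValidatedProbabilities <- function(features, labels, k = 10L, seed = 1L,
                                        ntree = 500L) {
    stopIfNot(k >= 2L, "k must be >= 2")
    features <- as.data.frame(features)
    d <- .dropIncomplete(features, labels)
    stopIfNot(nlevels(d$labels) == 2L, "labels must have exactly two classes")
    stopIfNot(min(table(d$labels)) >= k,
              "need at least k samples in each class")
    folds <- .stratifiedFolds(d$labels, k, subSeed(seed, "folds"))
    prob <- setNames(rep(NA_real_, length(d$labels)), names(d$labels))
    pos <- levels(d$labels)[2L]
    for (f in seq_len(k)) {
        train <- folds != f
        set.seed(subSeed(seed, "forest", index = f))
        rf <- randomForest::randomForest(
            x = d$features[train, , drop = FALSE], y = d$labels[train],
            ntree = ntree)
        prob[!train] <- predict(rf, d$features[!train, , drop = FALSE],
                                type = "prob")[, pos]
    }
    list(prob = prob, labels = d$labels,
         auc = aucScore(prob, as.integer(d$labels == pos)),
         folds = folds, seed = seed)
}

#' DeLong test for two correlated ROC curves
#'
#' Two-sided test of equal AUC for two probability vectors scored on the same
#' samples, using the structural-components estimate of the variance of the
#' paired AUC difference and its asymptotic normal distribution.
#'
#' @param probsA,probsB numeric score vectors on the same samples.
#' @param labels binary vector (1 = positive class).
#' @return list with \code{aucA}, \code{aucB}, \code{diff}, \code{z} and
#'   \code{p}.
#' @export
delongTest <- function(probsA, probsB, labels) {
    stopIfNot(length(probsA) == length(probsB) &&
              length(probsA) == length(labels),
              "score vectors and labels must be aligned")
    y <- as.integer(labels)
    xA <- probsA[y == 1L]; yA <- probsA[y == 0L]
    xB <- probsB[y == 1L]; yB <- probsB[y == 0L]
    m <- length(xA); n <- length(yA)
    stopIfNot(m > 1 && n > 1, "need both classes with >= 2 samples")
    psi <- function(x, y) {
        d <- outer(x, y, "-")
        (d > 0) + 0.5 * (d == 0)
    }
    compute <- function(x, y) {
        P <- psi(x, y)
        list(auc = mean(P), v10 = rowMeans(P), v01 = colMeans(P))
    }
    a <- compute(xA, yA); b <- compute(xB, yB)
    s10 <- cov(cbind(a$v10, b$v10))
    s01 <- cov(cbind(a$v01, b$v01))
    varDiff <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / m +
               (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n
    d <- a$auc - b$auc
    if (varDiff <= 0) {
        if (d != 0)
            warning("zero estimated variance with unequal AUCs")
        else warning("identical predictors; p = 1")
        return(list(aucA = a$auc, aucB = b$auc, diff = d, z = 0, p = 1))
    }
    z <- d / sqrt(varDiff)
    list(aucA = a$auc, aucB = b$auc, diff = d, z = z,
         p = 2 * pnorm(-abs(z)))
}

#' Random-forest feature importance ranking
#'
#' Importance from a forest trained on all included samples (mean decrease in
#' Gini impurity by default, permutation importance optionally); ranking ties
#' are broken alphabetically.
#'
#' @inheritParams crossValidatedProbabilities
#' @param type \code{"gini"} or \code{"permutation"}.
#' @return data.frame (feature, importance) sorted by decreasing importance.
#' @export
rfImportance <- function(features, labels, seed = 1L, ntree = 500L,
                         type = c("gini", "permutation")) {
    type <- match.arg(type)
    features <- as.data.frame(features)
    d <- .dropIncomplete(features, labels)
    stopIfNot(nlevels(d$labels) == 2L, "labels must have exactly two classes")
    set.seed(subSeed(seed, "forest"))
    rf <- randomForest::randomForest(
        x = d$features, y = d$labels, ntree = ntree,
        importance = type == "permutation")
    imp <- randomForest::importance(
        rf, type = if (type == "permutation") 1L else 2L)[, 1L]
    out <- data.frame(feature = names(imp), importance = unname(imp),
                      stringsAsFactors = FALSE)
    out[order(-out$importance, out$feature), , drop = FALSE]
}

#' Backward feature elimination for the random-forest classifier
#'
#' Starting from the full feature set, repeatedly record the pooled k-fold CV
#' AUC of the current set, then remove the single least-important feature,
#' until one feature remains. The selected set is the one with the highest
#' AUC at the smallest number of features (AUC compared at 1e-4 resolution,
#' ties broken toward fewer features).
#'
#' @inheritParams crossValidatedProbabilities
#' @return list with \code{selected} (character vector), \code{trajectory}
#'   (data.frame: nFeatures, auc, removed) and \code{sets} (feature sets per
#'   step).
#' @export
backwardSelection <- function(features, labels, k = 10L, seed = 1L,
                              ntree = 500L) {
    features <- as.data.frame(features)
    stopIfNot(ncol(features) >= 2L, "need at least two features")
    current <- colnames(features)
    steps <- list()
    sets <- list()
    i <- 1L
    while (length(current) >= 1L) {
        cv <- crossValidatedProbabilities(
            features[, current, drop = FALSE], labels, k = k,
            seed = subSeed(seed, "folds", index = i), ntree = ntree)
        removed <- NA_character_
        if (length(current) > 1L) {
            imp <- rfImportance(features[, current, drop = FALSE], labels,
                                seed = subSeed(seed, "forest", index = i),
                                ntree = ntree)
            removed <- imp$feature[nrow(imp)]  # least important, ties
        }                                      # resolved alphabetically
        steps[[i]] <- data.frame(nFeatures = length(current), auc = cv$auc,
                                 removed = removed,
                                 stringsAsFactors = FALSE)
        sets[[i]] <- current
        if (length(current) == 1L) break
        current <- setdiff(current, removed)
        i <- i + 1L
    }
    trajectory <- do.call(rbind, steps)
    aucRes <- round(trajectory$auc, 4L)
    best <- which(aucRes == max(aucRes))
    pick <- best[which.min(trajectory$nFeatures[best])]
    list(selected = sets[[pick]], trajectory = trajectory, sets = sets)
}

#' Train on one cohort, evaluate on another
#'
#' A forest is fit on all included training samples and its probabilities are
#' scored on the test cohort (labels computed per cohort at the same
#' horizon).
#'
#' @param trainFeatures,testFeatures samples x features tables exposing the
#'   same feature names.
#' @param trainLabels,testLabels binary factors (NA = excluded).
#' @param featureSet features to use (default: all shared).
#' @param seed forest seed.
#' @param ntree forest size.
#' @return list with \code{auc}, \code{roc}, \code{prob}.
#' @export
externalValidation <- function(trainFeatures, trainLabels, testFeatures,
                               testLabels, featureSet = NULL, seed = 1L,
                               ntree = 500L) {
    trainFeatures <- as.data.frame(trainFeatures)
    testFeatures <- as.data.frame(testFeatures)
    if (is.null(featureSet)) featureSet <- colnames(trainFeatures)
    missing <- setdiff(featureSet, colnames(testFeatures))
    if (length(missing))
        stop("feature(s) missing in test cohort: ",
             paste(missing, collapse = ", "), call. = FALSE)
    trainD <- .dropIncomplete(trainFeatures[, featureSet, drop = FALSE],
                              trainLabels)
    testD <- .dropIncomplete(testFeatures[, featureSet, drop = FALSE],
                             testLabels)
    pos <- levels(trainD$labels)[2L]
    set.seed(subSeed(seed, "forest"))
    rf <- randomForest::randomForest(x = trainD$features, y = trainD$labels,
                                     ntree = ntree)
    prob <- predict(rf, testD$features, type = "prob")[, pos]
    v <- validateSignature(prob, as.integer(testD$labels == pos))
    list(auc = v$auc, roc = v$roc, prob = prob)
}
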