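#' @importFrom survival coxph Surv survfit survdiff coxph.control
NULL

#' Fit a Cox proportional-hazards model
#'
#' Maximum partial-likelihood fit (Efron ties by default) serving both the
#' univariate use (a single score) and the clinically adjusted use (score
#' plus age, stage, lymph-node status, grade and size). Rows with missing
#' covariates are dropped with a message.
#'
#' @param covariates data.frame of covariates, one row per sample.
#' @param time,event survival time and event indicator (1 = event), aligned
#'   with \code{covariates} rows.
#' @param ties tie-handling method (\code{"efron"} default).
#' @return list of class \code{CoxModelResult} with elements \code{coef}
#'   (data.frame: coef, hr, se, z, p per covariate), \code{loglik},
#'   \code{concordance} (on the fitting data), \code{n}, \code{nEvents} and
#'   \code{fit} (the underlying \code{coxph} object).
#' @export
coxFit <- function(covariates, time, event, ties = "efron") {
    covariates <- as.data.frame(covariates)
    stopIfNot(nrow(covariates) == length(time) &&
              length(time) == length(event),
              "covariates, time and event must be aligned")
    keep <- complete.cases(covariates) & !is.na(time) & !is.na(event)
    if (any(!keep))
        .msg("dropped ", sum(!keep), " sample(s) with missing values")
    covariates <- covariates[keep, , drop = FALSE]
    time <- time[keep]; event <- event[keep]
    stopIfNot(sum(event) >= 1, "no events in the data")
    dat <- cbind(data.frame(.time = time, .event = event), covariates)
    fit <- withCallingHandlers(
        coxph(Surv(.time, .event) ~ ., data = dat, ties = ties),
        warning = function(w) {
            if (grepl("coefficient may be infinite", conditionMessage(w)))
                warning("monotone likelihood (near-perfect separation); ",
                        "estimates are at the iteration bound",
                        call. = FALSE)
            invokeRestart("muffleWarning")
        })
    s <- summary(fit)
    coefTab <- data.frame(
        coef = s$coefficients[, "coef"],
        hr = s$coefficients[, "exp(coef)"],
        se = s$coefficients[, "se(coef)"],
        z = s$coefficients[, "z"],
        p = s$coefficients[, "Pr(>|z|)"],
        row.names = rownames(s$coefficients))
    out <- list(coef = coefTab, loglik = fit$loglik[2L],
                concordance = unname(s$concordance[1L]),
                n = s$n, nEvents = s$nevent, fit = fit)
    class(out) <- "CoxModelResult"
    out
}

#' @export
print.CoxModelResult <- function(x, ...) {
    cat("Cox model:", x$n, "samples,", x$nEvents, "events; concordance =",
        format(x$concordance, digits = 3), "\n")
    print(format(x$coef, digits = 3))
    invisible(x)
}

#' Kaplan-Meier curves and log-rank test across groups
#'
#' @param groups factor or vector of group labels (>= 2 non-empty groups).
#' @param time,event survival data aligned with \code{groups}.
#' @return list with \code{curves} (data.frame of per-group product-limit
#'   curve points: group, time, surv, nRisk, nEvent), \code{chisq},
#'   \code{df} and \code{p} from the log-rank test.
#' @export
kmLogrank <- function(groups, time, event) {
    groups <- droplevels(as.factor(groups))
    stopIfNot(nlevels(groups) >= 2L, "need at least two non-empty groups")
    dat <- data.frame(time = time, event = event, group = groups)
    sf <- survfit(Surv(time, event) ~ group, data = dat)
    strata <- rep(names(sf$strata), sf$strata)
    curves <- data.frame(group = sub("^group=", "", strata),
                         time = sf$time, surv = sf$surv,
                         nRisk = sf$n.risk, nEvent = sf$n.event)
    sd <- survdiff(Surv(time, event) ~ group, data = dat)
    df <- length(sd$n) - 1L
    p <- stats::pchisq(sd$chisq, df = df, lower.tail = FALSE)
    list(curves = curves, chisq = unname(sd$chisq), df = df, p = p)
}

#' Split samples at the median score
#'
#' Scores at or below the median go to the \code{"low"} group, scores above
#' it to \code{"high"}; the grouping depends only on ranks.
#'
#' @param score numeric vector with >= 2 distinct values.
#' @return factor with levels low, high, named like \code{score}.
#' @export
dichotomizeMedian <- function(score) {
    stopIfNot(length(unique(score)) >= 2L,
              "score is constant; cannot dichotomize")
    m <- median(score)
    factor(ifelse(score <= m, "low", "high"), levels = c("low", "high"))
}

#' Concordance index of a risk score against survival
#'
#' The fraction of comparable pairs ordered consistently: a pair is
#' comparable when both members had events (at different times) or when one
#' had an event before the other was censored; it is concordant when the
#' higher predicted risk had the shorter survival, and tied risks count 1/2.
#'
#' @param risk numeric predicted risks (higher = worse).
#' @param time,event survival data aligned with \code{risk}.
#' @return concordance index in [0, 1].
#' @export
concordanceIndex <- function(risk, time, event) {
    stopIfNot(length(risk) == length(time) && length(time) == length(event),
              "inputs must be aligned")
    event <- as.integer(event)
    n <- length(risk)
    # pair (i, j) comparable iff the earlier time is an event time and the
    # times differ (i counted as the earlier member)
    ti <- matrix(time, n, n)
    ei <- matrix(event, n, n)
    comp <- (ti < t(ti)) & (ei == 1L)          # i fails first
    ri <- matrix(risk, n, n)
    conc <- sum(comp & (ri > t(ri)))
    ties <- sum(comp & (ri == t(ri)))
    nComp <- sum(comp)
    stopIfNot(nComp > 0, "no comparable pairs")
    (conc + 0.5 * ties) / nComp
}

#' Stepwise Cox model selection
#'
#' Forward selection with backward checks on Wald p-values: at each step the
#' candidate with the smallest p below \code{enterP} enters; any included
#' non-forced covariate whose p rises above \code{stayP} is dropped.
#' Covariates in \code{forced} (e.g. the clinical block) are always kept.
#'
#' @param candidates data.frame of candidate covariates.
#' @param time,event survival data aligned with \code{candidates}.
#' @param enterP,stayP entry and stay thresholds (defaults 0.15).
#' @param forced data.frame of covariates kept in every model, or NULL.
#' @param maxIter safety bound on add/drop cycles.
#' @return \code{CoxModelResult} of the final model, with an extra
#'   \code{selected} element (candidate names retained) and \code{trace}
#'   (character log of the steps).
#' @export
stepwiseCox <- function(candidates, time, event, enterP = 0.15,
                        stayP = 0.15, forced = NULL, maxIter = 100L) {
    candidates <- as.data.frame(candidates)
    stopIfNot(ncol(candidates) >= 1L, "no candidate covariates")
    forcedNames <- character()
    if (!is.null(forced)) {
        forced <- as.data.frame(forced)
        forcedNames <- colnames(forced)
    }
    inModel <- character()
    pool <- colnames(candidates)
    trace <- character()
    fitWith <- function(vars) {
        parts <- list()
        if (!is.null(forced)) parts <- c(parts, list(forced))
        if (length(vars))
            parts <- c(parts, list(candidates[, vars, drop = FALSE]))
        coxFit(do.call(cbind, parts), time, event)
    }
    for (it in seq_len(maxIter)) {
        changed <- FALSE
        # forward step
        avail <- setdiff(pool, inModel)
        if (length(avail)) {
            ps <- vapply(avail, function(v) {
                f <- fitWith(c(inModel, v))
                f$coef[v, "p"]
            }, numeric(1))
            if (min(ps) < enterP) {
                add <- avail[which.min(ps)]
                inModel <- c(inModel, add)
                trace <- c(trace, paste0("+", add, " (p=",
                                         format(min(ps), digits = 3), ")"))
                changed <- TRUE
            }
        }
        # backward check
        if (length(inModel)) {
            f <- fitWith(inModel)
            ps <- f$coef[inModel, "p"]
            worst <- which.max(ps)
            if (ps[worst] > stayP) {
                drop <- inModel[worst]
                inModel <- setdiff(inModel, drop)
                trace <- c(trace, paste0("-", drop, " (p=",
                                         format(ps[worst], digits = 3), ")"))
                changed <- TRUE
            }
        }
        if (!changed) {
            final <- if (length(inModel) || length(forcedNames))
                fitWith(inModel)
            else NULL
            if (is.null(final))
                stop("no candidate met the entry threshold", call. = FALSE)
            final$selected <- inModel
            final$trace <- trace
            return(final)
        }
    }
    stop("stepwise selection did not converge after ", maxIter,
         " iterations; trace: ", paste(trace, collapse = " "),
         call. = FALSE)
}

#' Linear predictor of a fitted Cox model on new data
#'
#' Centered linear predictor using the fitted coefficients; covariates named
#' in \code{exclude} have their terms zeroed (used to remove e.g. the
#' clinical block from an already-fitted model without refitting).
#'
#' @param model a \code{CoxModelResult}.
#' @param newdata data.frame containing the model covariates.
#' @param exclude covariate names whose coefficients are zeroed.
#' @return numeric linear predictor per row of \code{newdata}.
#' @export
riskLinearPredictor <- function(model, newdata, exclude = character()) {
    vars <- rownames(model$coef)
    missing <- setdiff(vars, colnames(newdata))
    if (length(missing))
        stop("covariate(s) missing in new data: ",
             paste(missing, collapse = ", "), call. = FALSE)
    beta <- model$coef$coef
    names(beta) <- vars
    beta[intersect(exclude, vars)] <- 0
    X <- as.matrix(newdata[, vars, drop = FALSE])
    drop(X %*% beta)
}

#' Rank-based risk groups from a fitted Cox model
#'
#' Computes the linear predictor for every new sample, ranks the samples and
#' cuts them into \code{nGroups} roughly equal groups of increasing risk
#' (remainder samples go to the lower groups).
#'
#' @param model a \code{CoxModelResult}.
#' @param newdata data.frame with the model covariates.
#' @param nGroups number of groups (default 3: low/intermediate/high).
#' @param exclude covariates zeroed before prediction (see
#'   \code{\link{riskLinearPredictor}}).
#' @return list with \code{group} (ordered factor), \code{risk} (linear
#'   predictor) and \code{cutRanks}.
#' @export
predictRiskGroups <- function(model, newdata, nGroups = 3L,
                              exclude = character()) {
    risk <- riskLinearPredictor(model, newdata, exclude = exclude)
    n <- length(risk)
    base <- n %/% nGroups
    rem <- n %% nGroups
    sizes <- rep(base, nGroups) + c(rep(1L, rem), rep(0L, nGroups - rem))
    labels <- if (nGroups == 3L) c("low", "intermediate", "high")
              else paste0("G", seq_len(nGroups))
    grp <- rep(labels, sizes)
    out <- factor(character(n), levels = labels, ordered = TRUE)
    out[order(risk)] <- grp
    names(out) <- rownames(newdata)
    list(group = out, risk = risk,
         cutRanks = cumsum(sizes)[-nGroups])
}

#' Cross-validated concordance of a Cox model
#'
#' k-fold cross-validation: the model is fit on the training folds and the
#' linear predictor is computed on the held-out fold; the pooled out-of-fold
#' predictors are scored once with \code{\link{concordanceIndex}}. Folds
#' without events are re-randomized up to 10 times.
#'
#' @param features samples x covariates data.frame.
#' @param time,event survival data aligned with \code{features}.
#' @param k folds (default 10).
#' @param seed fold seed.
#' @return list with \code{ci}, \code{risk} (pooled linear predictors) and
#'   \code{folds}.
#' @export
crossValidatedConcordance <- function(features, time, event, k = 10L,
                                      seed = 1L) {
    features <- as.data.frame(features)
    n <- nrow(features)
    ids <- rownames(features)
    if (is.null(ids)) ids <- as.character(seq_len(n))
    for (try in 1:10) {
        set.seed(subSeed(seed, "folds", index = try))
        folds <- setNames(sample(rep_len(seq_len(k), n)), ids)
        eventsPerFold <- tapply(event, folds, sum)
        trainOk <- vapply(seq_len(k), function(f)
            sum(event[folds != f]) >= 1, logical(1))
        if (all(trainOk)) break
        if (try == 10)
            stop("could not build folds with events in every training set",
                 call. = FALSE)
    }
    risk <- rep(NA_real_, n)
    for (f in seq_len(k)) {
        train <- folds != f
        m <- coxFit(features[train, , drop = FALSE], time[train],
                    event[train])
        risk[!train] <- riskLinearPredictor(m, features[!train, ,
                                                        drop = FALSE])
    }
    list(ci = concordanceIndex(risk, time, event), risk = setNames(risk, ids),
         folds = folds)
}
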