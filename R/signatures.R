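#' Fit per-gene linear models of expression on aberration status
#'
#' For every gene, ordinary least squares of log2 expression on the binary
#' event indicators, all events jointly in one design (the multivariate
#' model). Coefficient p-values are two-sided t-tests on the OLS estimates
#' with the usual residual degrees of freedom; the design is shared across
#' genes so a single QR decomposition serves all fits. Genes with zero
#' expression variance get beta = 0, p = 1 for every event.
#'
#' @param expr genes x samples matrix, log2 scale.
#' @param aberrationMatrix samples x events binary matrix; zero-variance
#'   event columns must be excluded beforehand (an error names them).
#' @param dropCollinear if TRUE, drop columns that make the design
#'   rank-deficient (with a message) instead of erroring.
#' @return An \linkS4class{AberrationFit}.
#' @export
fitMultivariate <- function(expr, aberrationMatrix, dropCollinear = FALSE) {
    stopIfNot(ncol(expr) == nrow(aberrationMatrix),
              "expr samples and aberrationMatrix rows must match")
    X <- as.matrix(aberrationMatrix)
    storage.mode(X) <- "double"
    constCols <- which(apply(X, 2L, var) == 0)
    if (length(constCols))
        stop("zero-variance event column(s): ",
             paste(colnames(X)[constCols], collapse = ", "),
             "; exclude them before fitting", call. = FALSE)
    design <- cbind(`(Intercept)` = 1, X)
    qrd <- qr(design)
    if (qrd$rank < ncol(design)) {
        bad <- colnames(design)[qrd$pivot[-seq_len(qrd$rank)]]
        if (!dropCollinear)
            stop("rank-deficient design; collinear column(s): ",
                 paste(bad, collapse = ", "),
                 " (set dropCollinear = TRUE to drop automatically)",
                 call. = FALSE)
        .msg("dropping collinear column(s): ", paste(bad, collapse = ", "))
        design <- design[, setdiff(colnames(design), bad), drop = FALSE]
        qrd <- qr(design)
    }
    n <- nrow(design); p <- ncol(design)
    stopIfNot(n >= p + 2L, "need at least 2 more samples than coefficients")
    Y <- t(expr)                                  # samples x genes
    coefs <- qr.coef(qrd, Y)                      # p x genes
    res <- Y - design %*% coefs
    df <- n - p
    sigma2 <- colSums(res^2) / df
    xtxInv <- chol2inv(chol(crossprod(design)))
    se <- sqrt(outer(diag(xtxInv), sigma2))       # p x genes
    tstat <- coefs / se
    pval <- 2 * pt(-abs(tstat), df)

    beta <- t(coefs[-1L, , drop = FALSE])
    pv <- t(pval[-1L, , drop = FALSE])
    intercept <- coefs[1L, ]
    # degenerate genes: constant expression -> no information
    flat <- apply(expr, 1L, var) == 0
    if (any(flat)) {
        beta[flat, ] <- 0
        pv[flat, ] <- 1
    }
    pv[is.na(pv)] <- 1
    beta[is.na(beta)] <- 0
    dimnames(beta) <- dimnames(pv) <-
        list(rownames(expr), colnames(design)[-1L])
    methods::new("AberrationFit", beta = beta, pvalue = pv,
                 intercept = setNames(as.numeric(intercept), rownames(expr)),
                 df = as.numeric(df), mode = "multivariate")
}

#' @describeIn fitMultivariate one event at a time: for each event column a
#'   separate single-indicator regression, equivalent to a pooled-variance
#'   two-sample t-test per gene.
#' @param eventIndicator samples x events matrix or a single indicator vector.
#' @export
fitUnivariate <- function(expr, eventIndicator) {
    if (is.null(dim(eventIndicator)))
        eventIndicator <- matrix(eventIndicator, ncol = 1L,
                                 dimnames = list(names(eventIndicator),
                                                 "event"))
    fits <- lapply(colnames(eventIndicator), function(l)
        fitMultivariate(expr, eventIndicator[, l, drop = FALSE]))
    beta <- do.call(cbind, lapply(fits, function(f) f@beta))
    pv <- do.call(cbind, lapply(fits, function(f) f@pvalue))
    colnames(beta) <- colnames(pv) <- colnames(eventIndicator)
    methods::new("AberrationFit", beta = beta, pvalue = pv,
                 intercept = fits[[1L]]@intercept, df = fits[[1L]]@df,
                 mode = "univariate")
}

#' Derive sign-split normalized signature weights from a fit
#'
#' For each event, the raw weight of a gene is \code{-log10(p)}; genes with a
#' positive coefficient contribute it to the up-weight vector wPlus, genes
#' with a negative coefficient to the down-weight vector wMinus (the other
#' side is zero). Raw weights are capped at \code{cap} and divided by the
#' range over the union of both capped vectors, so all weights lie in [0, 1]
#' and a p-value at or below 10^-cap maps to weight 1.
#'
#' @param fit An \linkS4class{AberrationFit}.
#' @param cap maximum raw weight before normalization (default 10).
#' @param logBase base of the -log transform (default 10).
#' @param events which events to derive (default: all in the fit).
#' @return named list of \linkS4class{SignatureWeightSet}, one per event.
#' @export
deriveWeights <- function(fit, cap = 10, logBase = 10, events = NULL) {
    if (is.null(events)) events <- colnames(fit@beta)
    out <- lapply(events, function(ev) {
        beta <- fit@beta[, ev]
        p <- pmax(fit@pvalue[, ev], 1e-300)
        raw <- pmin(-log(p, base = logBase), cap)
        wPlus <- ifelse(beta > 0, raw, 0)
        wMinus <- ifelse(beta < 0, raw, 0)
        rng <- max(wPlus, wMinus) - min(wPlus, wMinus)  # min is 0 by split
        if (rng == 0) {
            warning("all p-values are 1 for event ", ev,
                    "; weights are all zero")
        } else {
            wPlus <- wPlus / rng
            wMinus <- wMinus / rng
        }
        SignatureWeightSet(
            event = ev, gene = rownames(fit@beta),
            wPlus = wPlus, wMinus = wMinus,
            stats = S4Vectors::DataFrame(beta = beta, p = fit@pvalue[, ev]))
    })
    setNames(out, events)
}

#' Fit signatures and derive weights for all events of a cohort
#'
#' @param cohort a \linkS4class{ProgCohort} with an aberration matrix.
#' @param mode \code{"multivariate"} (all events jointly, the default used
#'   for prognostic models) or \code{"univariate"} (one event at a time,
#'   used to show that scores recapitulate aberration status).
#' @param cap,logBase passed to \code{\link{deriveWeights}}.
#' @param dropCollinear passed to \code{\link{fitMultivariate}}.
#' @return list with \code{fit} (\linkS4class{AberrationFit}) and
#'   \code{weights} (list of \linkS4class{SignatureWeightSet}).
#' @export
fitSignatures <- function(cohort, mode = c("multivariate", "univariate"),
                          cap = 10, logBase = 10, dropCollinear = FALSE) {
    mode <- match.arg(mode)
    ab <- aberrations(cohort)
    stopIfNot(!is.null(ab), "cohort has no aberration matrix")
    fit <- if (mode == "multivariate")
        fitMultivariate(exprs(cohort), ab, dropCollinear = dropCollinear)
    else fitUnivariate(exprs(cohort), ab)
    list(fit = fit, weights = deriveWeights(fit, cap = cap,
                                            logBase = logBase))
}
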