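#' @import methods
#' @importFrom S4Vectors DataFrame SimpleList metadata metadata<-
#' @importClassesFrom S4Vectors DataFrame
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

#' SignatureWeightSet: sign-split gene weights for one event
#'
#' Holds the up-regulation (\code{wPlus}) and down-regulation (\code{wMinus})
#' weight vectors for a single genomic event or immune cell type, both indexed
#' by gene and normalized to [0, 1]. At most one of the two weights is nonzero
#' for any gene: a gene whose expression rises in event carriers contributes to
#' \code{wPlus}, a gene whose expression falls contributes to \code{wMinus}.
#' The \code{stats} slot optionally keeps the regression coefficient and
#' p-value each weight was derived from.
#'
#' @slot event single event label, e.g. \code{"TP53_mut"} or \code{"MemB"}.
#' @slot gene character vector of gene identifiers.
#' @slot wPlus,wMinus numeric weights in [0, 1], parallel to \code{gene}.
#' @slot stats \code{DataFrame} with optional columns \code{beta}, \code{p}.
#'
#' @aliases SignatureWeightSet-class
#' @exportClass SignatureWeightSet
setClass("SignatureWeightSet",
    representation(
        event  = "character",
        gene   = "character",
        wPlus  = "numeric",
        wMinus = "numeric",
        stats  = "DataFrame"
    )
)

setValidity("SignatureWeightSet", function(object) {
    msg <- NULL
    n <- length(object@gene)
    if (length(object@event) != 1L || !nzchar(object@event))
        msg <- c(msg, "'event' must be a single non-empty label")
    if (length(object@wPlus) != n || length(object@wMinus) != n)
        msg <- c(msg, "weight vectors must be parallel to 'gene'")
    if (anyDuplicated(object@gene))
        msg <- c(msg, "duplicated gene identifiers")
    if (n > 0L) {
        if (any(!is.finite(object@wPlus)) || any(!is.finite(object@wMinus)))
            msg <- c(msg, "weights must be finite")
        else {
            if (min(object@wPlus, object@wMinus) < 0 ||
                max(object@wPlus, object@wMinus) > 1 + 1e-12)
                msg <- c(msg, "weights must lie in [0, 1]")
            if (any(object@wPlus * object@wMinus > 0))
                msg <- c(msg, "a gene may not carry both a wPlus and a wMinus")
        }
    }
    if (is.null(msg)) TRUE else msg
})

#' AberrationFit: per-gene linear-model fits on aberration status
#'
#' Result of regressing log2 expression of every gene on binary aberration
#' indicators, either jointly (all events in one design) or one event at a
#' time. Coefficient and p-value matrices are genes x events; p-values are
#' two-sided ordinary t-tests on the OLS coefficients.
#'
#' @slot beta,pvalue numeric genes x events matrices.
#' @slot intercept per-gene intercepts.
#' @slot df residual degrees of freedom of each fit.
#' @slot mode \code{"multivariate"} or \code{"univariate"}.
#'
#' @aliases AberrationFit-class
#' @exportClass AberrationFit
setClass("AberrationFit",
    representation(
        beta      = "matrix",
        pvalue    = "matrix",
        intercept = "numeric",
        df        = "numeric",
        mode      = "character"
    )
)

setValidity("AberrationFit", function(object) {
    msg <- NULL
    if (!identical(dim(object@beta), dim(object@pvalue)))
        msg <- c(msg, "'beta' and 'pvalue' must have identical dimensions")
    if (length(object@intercept) != nrow(object@beta))
        msg <- c(msg, "'intercept' must have one entry per gene")
    pv <- object@pvalue
    if (length(pv) && (min(pv) < 0 || max(pv) > 1))
        msg <- c(msg, "p-values must lie in [0, 1]")
    if (length(object@beta) && any(!is.finite(object@beta)))
        msg <- c(msg, "coefficients must be finite")
    if (is.null(msg)) TRUE else msg
})

#' BaseScoreResult: one sample-level enrichment score with its permutation null
#'
#' The statistic contrasts a weighted foreground cumulative curve f(i) against
#' a complementary background curve b(i) over the sample's ranked expression
#' profile; the signed maximum deviation of f - b is computed separately for
#' the wPlus and wMinus weights, each is normalized against a permutation null
#' (gene order shuffled, weights fixed), and the final score is the difference
#' of the two normalized deviations.
#'
#' @slot score final normalized score.
#' @slot scorePlus,scoreMinus raw signed maximum deviations.
#' @slot nullPlus,nullMinus permutation-null deviations (length nPerm).
#' @slot trace optional list with the f and b curves for inspection.
#'
#' @aliases BaseScoreResult-class
#' @exportClass BaseScoreResult
setClass("BaseScoreResult",
    representation(
        score      = "numeric",
        scorePlus  = "numeric",
        scoreMinus = "numeric",
        nullPlus   = "numeric",
        nullMinus  = "numeric",
        trace      = "list"
    )
)

setValidity("BaseScoreResult", function(object) {
    msg <- NULL
    if (length(object@score) != 1L || !is.finite(object@score))
        msg <- c(msg, "'score' must be a single finite value")
    if (length(object@nullPlus) != length(object@nullMinus))
        msg <- c(msg, "null vectors must have equal length")
    if (is.null(msg)) TRUE else msg
})

#' ProgCohort: expression, aberrations, clinical and survival data for a cohort
#'
#' A \linkS4class{SummarizedExperiment} with one \code{"exprs"} assay (genes x
#' samples, log2 scale), clinical and survival variables in \code{colData},
#' and, when available, the binary samples x events aberration matrix and
#' simulation ground truth in \code{metadata}. Construct with
#' \code{\link{ProgCohort}} or \code{\link{readCohortBundle}}.
#'
#' @aliases ProgCohort-class
#' @exportClass ProgCohort
setClass("ProgCohort", contains = "SummarizedExperiment")

setValidity("ProgCohort", function(object) {
    msg <- NULL
    if (!"exprs" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'exprs' is required")
    ab <- metadata(object)$aberrations
    if (!is.null(ab)) {
        if (!is.matrix(ab) || !setequal(rownames(ab), colnames(object)))
            msg <- c(msg, "aberration matrix rows must match cohort samples")
        else if (length(ab) && !all(ab %in% c(0, 1)))
            msg <- c(msg, "aberration matrix must be binary")
    }
    if (is.null(msg)) TRUE else msg
})
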