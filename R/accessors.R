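#' Construct a ProgCohort
#'
#' @param exprs genes x samples numeric matrix on the log2 scale, with row and
#'   column names.
#' @param clinical data.frame of clinical covariates, one row per sample
#'   (rownames = sample identifiers). May be missing columns; only the columns
#'   present are carried.
#' @param survival data.frame with columns \code{time} and \code{event}
#'   (1 = event observed, 0 = censored), rownames = sample identifiers.
#' @param aberrations optional samples x events binary matrix.
#' @param comparator optional numeric vector of comparator recurrence scores
#'   on the 0-100 scale (one per sample); the low/intermediate/high class is
#'   derived from it.
#' @param truth optional list of simulation ground truth.
#'
#' @return A \linkS4class{ProgCohort}.
#' @export
ProgCohort <- function(exprs, clinical = NULL, survival = NULL,
                       aberrations = NULL, comparator = NULL, truth = NULL) {
    if (is.null(rownames(exprs)) || is.null(colnames(exprs)))
        stop("'exprs' must have gene rownames and sample colnames")
    samples <- colnames(exprs)
    cd <- S4Vectors::DataFrame(row.names = samples)
    addCols <- function(cd, tab) {
        if (is.null(tab)) return(cd)
        tab <- tab[samples, , drop = FALSE]
        for (nm in colnames(tab)) cd[[nm]] <- tab[[nm]]
        cd
    }
    cd <- addCols(cd, clinical)
    cd <- addCols(cd, survival)
    if (!is.null(comparator)) {
        stopifnot(length(comparator) == length(samples))
        cd$oncoScore <- as.numeric(comparator)
        cd$oncoClass <- oncoClass(cd$oncoScore)
    }
    md <- list()
    if (!is.null(aberrations))
        md$aberrations <- aberrations[samples, , drop = FALSE]
    if (!is.null(truth)) md$truth <- truth
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(exprs = exprs), colData = cd, metadata = md)
    methods::new("ProgCohort", se)
}

#' Comparator recurrence class from a 0-100 score
#'
#' Scores 0-17 map to \code{"low"}, 18-30 to \code{"intermediate"} and
#' 31-100 to \code{"high"}; the class is a pure function of the score.
#'
#' @param score numeric vector in [0, 100].
#' @return factor with levels low < intermediate < high.
#' @export
oncoClass <- function(score) {
    stopifnot(all(is.na(score) | (score >= 0 & score <= 100)))
    cut(score, breaks = c(-Inf, 17.5, 30.5, Inf),
        labels = c("low", "intermediate", "high"), ordered_result = TRUE)
}

#' @describeIn ProgCohort the expression assay (genes x samples).
#' @param object,x a \code{ProgCohort}.
#' @param ... unused.
#' @export
setMethod("exprs", "ProgCohort", function(object, ...)
    SummarizedExperiment::assay(object, "exprs"))

#' @describeIn ProgCohort samples x events binary aberration matrix (or NULL).
#' @export
setMethod("aberrations", "ProgCohort", function(object, ...)
    metadata(object)$aberrations)

#' @describeIn ProgCohort set the aberration matrix.
#' @param value samples x events binary matrix.
#' @export
setMethod("aberrations<-", "ProgCohort", function(object, value) {
    metadata(object)$aberrations <- value
    methods::validObject(object)
    object
})

.CLINICAL_VARS <- c("age", "stage", "grade", "size", "nodes")

#' @describeIn ProgCohort clinical covariates as a data.frame.
#' @export
setMethod("clinicalData", "ProgCohort", function(object, ...) {
    cd <- SummarizedExperiment::colData(object)
    keep <- intersect(.CLINICAL_VARS, colnames(cd))
    as.data.frame(cd[, keep, drop = FALSE])
})

#' @describeIn ProgCohort data.frame with \code{time} and \code{event}.
#' @export
setMethod("survivalData", "ProgCohort", function(object, ...) {
    cd <- SummarizedExperiment::colData(object)
    if (!all(c("time", "event") %in% colnames(cd)))
        stop("cohort has no survival data")
    data.frame(time = cd$time, event = cd$event,
               row.names = rownames(cd))
})

#' @describeIn ProgCohort simulation ground truth list (or NULL).
#' @export
setMethod("groundTruth", "ProgCohort", function(object, ...)
    metadata(object)$truth)

setMethod("show", "ProgCohort", function(object) {
    cat("ProgCohort:", nrow(object), "genes x", ncol(object), "samples\n")
    ab <- aberrations(object)
    if (!is.null(ab))
        cat("  aberration events:", ncol(ab), "\n")
    cd <- colnames(SummarizedExperiment::colData(object))
    if (length(cd)) cat("  colData:", paste(cd, collapse = ", "), "\n")
    if (!is.null(groundTruth(object))) cat("  with simulation ground truth\n")
})

#' Construct a SignatureWeightSet
#'
#' @param event single event label.
#' @param gene gene identifiers.
#' @param wPlus,wMinus weights in [0, 1], parallel to \code{gene}; at most one
#'   of the two may be nonzero for a gene.
#' @param stats optional \code{DataFrame} of per-gene fit statistics.
#' @return A \linkS4class{SignatureWeightSet}.
#' @export
SignatureWeightSet <- function(event, gene, wPlus, wMinus,
                               stats = S4Vectors::DataFrame()) {
    methods::new("SignatureWeightSet", event = event, gene = gene,
                 wPlus = as.numeric(wPlus), wMinus = as.numeric(wMinus),
                 stats = stats)
}

#' @describeIn SignatureWeightSet event label.
#' @param object a \code{SignatureWeightSet}.
#' @export
setMethod("eventLabel", "SignatureWeightSet", function(object) object@event)

#' @describeIn SignatureWeightSet named up-regulation weights.
#' @export
setMethod("weightPlus", "SignatureWeightSet", function(object)
    stats::setNames(object@wPlus, object@gene))

#' @describeIn SignatureWeightSet named down-regulation weights.
#' @export
setMethod("weightMinus", "SignatureWeightSet", function(object)
    stats::setNames(object@wMinus, object@gene))

setMethod("show", "SignatureWeightSet", function(object) {
    cat("SignatureWeightSet '", object@event, "': ",
        length(object@gene), " genes, ",
        sum(object@wPlus > 0), " up / ", sum(object@wMinus > 0),
        " down weights\n", sep = "")
})

#' @describeIn BaseScoreResult permutation-null deviations as a two-column
#'   matrix (plus, minus).
#' @param object a \code{BaseScoreResult}.
#' @export
setMethod("baseNull", "BaseScoreResult", function(object)
    cbind(plus = object@nullPlus, minus = object@nullMinus))

setMethod("show", "BaseScoreResult", function(object) {
    cat("BaseScoreResult: score =", format(object@score, digits = 4),
        "(raw +", format(object@scorePlus, digits = 3),
        "/ -", format(object@scoreMinus, digits = 3), ",",
        length(object@nullPlus), "permutations)\n")
})

#' Final score of a BaseScoreResult
#' @param x a \code{BaseScoreResult}.
#' @return single numeric score.
#' @export
baseScoreValue <- function(x) x@score
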