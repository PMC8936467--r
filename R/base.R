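#' @useDynLib PrognoSig, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Prepare a sample's ranked profile for scoring
#'
#' Every gene is centered by its cohort median, the sample's genes are ordered
#' by decreasing signed centered value (so the most up-regulated genes rank
#' first and the most down-regulated last), and the magnitude of each ranked
#' gene is its absolute centered value. Ranking by deregulation rather than by
#' raw expression makes the score reflect sample-specific departures from the
#' cohort, not baseline transcript abundance.
#'
#' @param expr genes x samples matrix on the log2 scale (>= 2 samples, needed
#'   for gene-wise centering).
#' @param sample sample identifier or column index.
#' @return named numeric vector \code{g} of magnitudes in rank order.
#' @export
prepareProfile <- function(expr, sample) {
    stopIfNot(ncol(expr) >= 2L,
              paste("gene-wise median centering needs >= 2 samples;",
                    "provide an external reference median for",
                    "single-sample use"))
    centered <- expr[, sample] - rowMedians(expr)
    ord <- order(centered, decreasing = TRUE)
    setNames(abs(centered[ord]), rownames(expr)[ord])
}

.alignWeights <- function(g, ws) {
    w <- setNames(numeric(length(g)), names(g))
    knownPlus <- weightPlus(ws)
    knownMinus <- weightMinus(ws)
    missing <- setdiff(ws@gene[ws@wPlus > 0 | ws@wMinus > 0], names(g))
    if (length(missing))
        .msg(length(missing), " weighted gene(s) of '", ws@event,
             "' absent from the expression profile; dropped")
    common <- intersect(ws@gene, names(g))
    wp <- w; wp[common] <- knownPlus[common]
    wm <- w; wm[common] <- knownMinus[common]
    list(plus = unname(wp), minus = unname(wm))
}

.normalizeDev <- function(score, nulls, nullNorm) {
    if (nullNorm == "mean_abs") {
        denom <- mean(abs(nulls))
        if (denom == 0) 0 else score / denom
    } else {
        s <- sd(nulls)
        if (s == 0) 0 else (score - mean(nulls)) / s
    }
}

#' Sample-specific enrichment score for one weight set
#'
#' Computes the foreground/background cumulative curves over the ranked
#' profile \code{g}, takes the signed maximum deviation separately for the
#' wPlus and wMinus weights, normalizes each against a permutation null
#' (random orderings of \code{g} with the weights fixed), and returns
#' normalized(Score+) - normalized(Score-). Constant weight vectors carry no
#' information (f and b coincide algebraically) and contribute exactly 0.
#'
#' @param g ranked magnitudes from \code{\link{prepareProfile}}.
#' @param weightSet a \linkS4class{SignatureWeightSet}.
#' @param nPerm number of permutations for the null (default 1000).
#' @param seed integer seed for the permutation stream.
#' @param nullNorm \code{"mean_abs"} (default): divide each deviation by the
#'   mean absolute null deviation; \code{"zscore"}: center and scale by the
#'   null instead.
#' @param perms optional explicit permutation matrix (genes x nPerm, 1-based)
#'   overriding the internal stream; used for tracing and validation.
#' @param trace if TRUE, keep the observed f and b curves in the result.
#' @return A \linkS4class{BaseScoreResult}.
#' @export
baseScore <- function(g, weightSet, nPerm = 1000L, seed = 1L,
                      nullNorm = c("mean_abs", "zscore"), perms = NULL,
                      trace = FALSE) {
    nullNorm <- match.arg(nullNorm)
    stopIfNot(nPerm >= 1L, "nPerm must be >= 1")
    w <- .alignWeights(g, weightSet)
    gv <- unname(g)

    constant <- function(x) max(x) == min(x)
    degenerate <- c(plus = constant(w$plus) || sum(gv * w$plus) == 0,
                    minus = constant(w$minus) || sum(gv * w$minus) == 0)
    if (all(degenerate) && all(w$plus == 0) && all(w$minus == 0))
        warning("all weights are zero for event '", weightSet@event,
                "'; score is 0")

    devPlus <- if (degenerate["plus"]) 0 else cppBaseDev(gv, w$plus)
    devMinus <- if (degenerate["minus"]) 0 else cppBaseDev(gv, w$minus)

    if (is.null(perms))
        perms <- matrix(integer(), nrow = 0L, ncol = 0L)
    nulls <- cppBaseNull(gv, w$plus, w$minus, as.integer(nPerm),
                         as.integer(seed), perms)
    if (degenerate["plus"]) nulls[, 1L] <- 0
    if (degenerate["minus"]) nulls[, 2L] <- 0

    normPlus <- if (degenerate["plus"]) 0 else
        .normalizeDev(devPlus, nulls[, 1L], nullNorm)
    normMinus <- if (degenerate["minus"]) 0 else
        .normalizeDev(devMinus, nulls[, 2L], nullNorm)

    tr <- list()
    if (trace) {
        curves <- function(wv) {
            s1 <- sum(gv * wv); s0 <- sum(gv * (1 - wv))
            list(f = if (s1 > 0) cumsum(gv * wv) / s1 else rep(0, length(gv)),
                 b = if (s0 > 0) cumsum(gv * (1 - wv)) / s0
                     else rep(0, length(gv)))
        }
        tr <- list(plus = curves(w$plus), minus = curves(w$minus),
                   gene = names(g))
    }
    methods::new("BaseScoreResult",
                 score = normPlus - normMinus,
                 scorePlus = devPlus, scoreMinus = devMinus,
                 nullPlus = nulls[, 1L], nullMinus = nulls[, 2L],
                 trace = tr)
}

#' Score every sample of a cohort against a list of weight sets
#'
#' One permutation substream per (sample, weight set), derived from the master
#' seed, so scores are deterministic and independent across cells of the
#' result.
#'
#' @param x a \linkS4class{ProgCohort} or a genes x samples matrix (log2).
#' @param weightSets named list of \linkS4class{SignatureWeightSet}.
#' @param nPerm permutations per score (default 1000).
#' @param seed master seed.
#' @param nullNorm passed to \code{\link{baseScore}}.
#' @param sharePerms if TRUE (default), the permutation stream of a sample is
#'   shared by all weight sets, so identical weight sets always receive
#'   identical scores (and the stream is generated once per sample); set
#'   FALSE for a fully independent substream per (sample, weight set).
#' @return samples x weight-sets numeric score matrix.
#' @export
scoreCohort <- function(x, weightSets, nPerm = 1000L, seed = 1L,
                        nullNorm = c("mean_abs", "zscore"),
                        sharePerms = TRUE) {
    nullNorm <- match.arg(nullNorm)
    expr <- if (methods::is(x, "ProgCohort")) exprs(x) else x
    stopIfNot(length(weightSets) >= 1L, "need at least one weight set")
    if (is.null(names(weightSets)))
        names(weightSets) <- vapply(weightSets, eventLabel, character(1))
    for (ws in weightSets) {
        if (!any(ws@gene %in% rownames(expr)))
            stop("weight set '", ws@event,
                 "' shares no genes with the expression matrix",
                 call. = FALSE)
    }
    med <- rowMedians(expr)
    nSets <- length(weightSets)
    out <- matrix(NA_real_, nrow = ncol(expr), ncol = nSets,
                  dimnames = list(colnames(expr), names(weightSets)))
    # pre-align weight vectors to the gene universe once
    universe <- rownames(expr)
    wp <- wm <- matrix(0, nrow = length(universe), ncol = nSets)
    for (k in seq_len(nSets)) {
        ws <- weightSets[[k]]
        common <- intersect(ws@gene, universe)
        wp[match(common, universe), k] <- weightPlus(ws)[common]
        wm[match(common, universe), k] <- weightMinus(ws)[common]
    }
    noPerms <- matrix(integer(), 0L, 0L)
    for (si in seq_len(ncol(expr))) {
        centered <- expr[, si] - med
        ord <- order(centered, decreasing = TRUE)
        gv <- abs(centered[ord])
        sharedPerms <- if (sharePerms)
            cppGenPerms(length(gv), as.integer(nPerm),
                        subSeed(seed, "scoring", index = si))
        for (k in seq_len(nSets)) {
            wpk <- wp[ord, k]; wmk <- wm[ord, k]
            cellSeed <- subSeed(seed, "scoring",
                                index = (si - 1L) * nSets + k)
            degenerate <- c(max(wpk) == min(wpk) || sum(gv * wpk) == 0,
                            max(wmk) == min(wmk) || sum(gv * wmk) == 0)
            devPlus <- if (degenerate[1L]) 0 else cppBaseDev(gv, wpk)
            devMinus <- if (degenerate[2L]) 0 else cppBaseDev(gv, wmk)
            nulls <- cppBaseNull(gv, wpk, wmk, as.integer(nPerm),
                                 cellSeed,
                                 if (sharePerms) sharedPerms else noPerms)
            np <- if (degenerate[1L]) 0 else
                .normalizeDev(devPlus, nulls[, 1L], nullNorm)
            nm <- if (degenerate[2L]) 0 else
                .normalizeDev(devMinus, nulls[, 2L], nullNorm)
            out[si, k] <- np - nm
        }
    }
    out
}

#' Derive immune-cell weight sets from reference expression profiles
#'
#' The specificity of gene i for cell type c is its reference expression in c
#' minus the maximum over all other types (log scale). The \code{topK} genes
#' with positive specificity receive up-weights proportional to specificity
#' (scaled so the best marker has weight 1); all other weights are zero, and
#' no down-weights are used.
#'
#' @param reference cell types x genes matrix (log2 scale), >= 2 types.
#' @param topK markers retained per cell type (default 100); if fewer genes
#'   have positive specificity, all of them are used with a warning.
#' @return named list of \linkS4class{SignatureWeightSet}, one per cell type.
#' @export
deriveImmuneWeights <- function(reference, topK = 100L) {
    stopIfNot(nrow(reference) >= 2L, "need at least two cell types")
    genes <- colnames(reference)
    out <- lapply(rownames(reference), function(ct) {
        others <- reference[setdiff(rownames(reference), ct), , drop = FALSE]
        spec <- reference[ct, ] - apply(others, 2L, max)
        pos <- which(spec > 0)
        if (length(pos) < topK)
            warning("only ", length(pos), " gene(s) with positive ",
                    "specificity for ", ct, " (requested ", topK, ")")
        top <- pos[order(spec[pos], decreasing = TRUE)][
            seq_len(min(topK, length(pos)))]
        wPlus <- setNames(numeric(length(genes)), genes)
        if (length(top)) wPlus[top] <- spec[top] / max(spec[top])
        SignatureWeightSet(event = ct, gene = genes, wPlus = wPlus,
                           wMinus = numeric(length(genes)))
    })
    setNames(out, rownames(reference))
}

#' Area under the ROC curve by rank statistics
#'
#' AUC as the Mann-Whitney probability that a positive sample outscores a
#' negative one, with ties counted 1/2 (midranks).
#'
#' @param scores numeric vector.
#' @param status binary vector (1 = positive class), both classes present.
#' @return AUC in [0, 1].
#' @export
aucScore <- function(scores, status) {
    status <- as.integer(status)
    n1 <- sum(status == 1L); n0 <- sum(status == 0L)
    stopIfNot(n1 > 0 && n0 > 0, "both classes must be present")
    r <- rank(scores)
    (sum(r[status == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC curve and AUC of a score against a binary status
#'
#' @param scores numeric vector (higher = more likely positive).
#' @param status binary vector (1 = positive class).
#' @return list with \code{auc} and a data.frame \code{roc} of (fpr, tpr)
#'   points at every distinct threshold.
#' @export
validateSignature <- function(scores, status) {
    auc <- aucScore(scores, status)
    ord <- order(scores, decreasing = TRUE)
    st <- as.integer(status)[ord]
    tpr <- c(0, cumsum(st) / sum(st))
    fpr <- c(0, cumsum(1L - st) / sum(1L - st))
    s <- scores[ord]
    keep <- c(TRUE, if (length(s) > 1) c(diff(s) != 0, TRUE) else TRUE)
    list(auc = auc, roc = data.frame(fpr = fpr[keep], tpr = tpr[keep]))
}
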