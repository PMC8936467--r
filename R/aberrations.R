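#' Default copy-number calling thresholds (log2 copy-ratio scale)
#'
#' A gene is called amplified when its log2 copy ratio exceeds
#' \code{log2(2.82)} and deleted when it falls below \code{-log2(1.32)}.
#' @export
AMP_THRESHOLD <- log2(2.82)

#' @rdname AMP_THRESHOLD
#' @export
DEL_THRESHOLD <- -log2(1.32)

#' Call recurrently mutated genes from MAF records
#'
#' A sample carries a gene-level mutation event when it has at least one
#' variant of a qualifying class in that gene; multiple rows for the same
#' gene-sample pair count once. Events are retained when the carrier fraction
#' over \emph{all} cohort samples (including samples absent from the MAF)
#' is at least \code{minFraction}.
#'
#' @param mafRecords data.frame as returned by \code{\link{readMaf}}.
#' @param sampleIds character vector defining the cohort denominator.
#' @param minFraction minimum carrier fraction (inclusive; "at least 10
#'   percent" means a fraction of exactly \code{minFraction} is kept).
#' @param classes qualifying variant classifications.
#' @param includeIndels also count frameshift/in-frame indel classes.
#' @return list with \code{events} (data.frame: label, gene, kind, fraction)
#'   and \code{indicator} (samples x events binary matrix).
#' @export
callRecurrentMutations <- function(mafRecords, sampleIds,
                                   minFraction = 0.10,
                                   classes = NONSYNONYMOUS_CLASSES,
                                   includeIndels = TRUE) {
    stopIfNot(length(sampleIds) > 0, "sampleIds must be non-empty")
    stopIfNot(!anyDuplicated(sampleIds), "duplicate sample identifiers")
    if (includeIndels) classes <- union(classes, INDEL_CLASSES)
    rec <- mafRecords[mafRecords$variant_classification %in% classes, ,
                      drop = FALSE]
    unknown <- setdiff(unique(rec$sample_barcode), sampleIds)
    if (length(unknown)) {
        .msg("ignoring ", length(unknown),
             " MAF sample(s) not in the cohort")
        rec <- rec[rec$sample_barcode %in% sampleIds, , drop = FALSE]
    }
    genes <- sort(unique(rec$hugo_symbol))
    ind <- matrix(0L, nrow = length(sampleIds), ncol = length(genes),
                  dimnames = list(sampleIds, genes))
    if (nrow(rec))
        ind[cbind(match(rec$sample_barcode, sampleIds),
                  match(rec$hugo_symbol, genes))] <- 1L
    frac <- colMeans(ind)
    keep <- frac >= minFraction
    ind <- ind[, keep, drop = FALSE]
    frac <- frac[keep]
    if (ncol(ind)) colnames(ind) <- paste0(colnames(ind), "_mut")
    events <- data.frame(label = colnames(ind), gene = genes[keep],
                         kind = rep("mut", sum(keep)),
                         fraction = unname(frac),
                         stringsAsFactors = FALSE, row.names = NULL)
    list(events = events, indicator = ind)
}

#' Gene-level copy number from segments
#'
#' Each gene's value in a sample is the overlap-length-weighted mean of the
#' log2 copy ratios of the segments overlapping its interval; genes with no
#' overlapping segment are copy-neutral (0).
#'
#' @param segRecords data.frame as returned by \code{\link{readSeg}}.
#' @param annotation named \link[GenomicRanges]{GRanges} of gene intervals
#'   (see \code{\link{readGeneAnnotation}}).
#' @param sampleIds optional cohort samples; defaults to the samples present
#'   in the segments.
#' @return genes x samples numeric matrix of log2 copy ratios.
#' @export
geneLevelCopyNumber <- function(segRecords, annotation, sampleIds = NULL) {
    if (is.null(sampleIds)) sampleIds <- sort(unique(segRecords$sample_barcode))
    genes <- names(annotation)
    stopIfNot(!is.null(genes), "annotation must be a named GRanges")
    cn <- matrix(0, nrow = length(genes), ncol = length(sampleIds),
                 dimnames = list(genes, sampleIds))
    segChroms <- unique(segRecords$chrom)
    missingChrom <- setdiff(
        unique(as.character(GenomicRanges::seqnames(annotation))), segChroms)
    if (length(missingChrom))
        .msg("no segments on chromosome(s) ",
             paste(missingChrom, collapse = ", "),
             "; genes there are copy-neutral")
    for (s in sampleIds) {
        segs <- segRecords[segRecords$sample_barcode == s, , drop = FALSE]
        if (!nrow(segs)) next
        segGr <- GenomicRanges::GRanges(
            seqnames = segs$chrom,
            ranges = IRanges::IRanges(start = segs$start, end = segs$end))
        ov <- GenomicRanges::findOverlaps(annotation, segGr)
        if (!length(ov)) next
        w <- GenomicRanges::width(IRanges::pintersect(
            GenomicRanges::ranges(annotation)[S4Vectors::queryHits(ov)],
            GenomicRanges::ranges(segGr)[S4Vectors::subjectHits(ov)]))
        v <- segs$value[S4Vectors::subjectHits(ov)]
        num <- tapply(w * v, S4Vectors::queryHits(ov), sum)
        den <- tapply(w, S4Vectors::queryHits(ov), sum)
        cn[as.integer(names(num)), s] <- num / den
    }
    cn
}

#' Call recurrent amplifications and deletions
#'
#' A gene is amplified in a sample when its log2 copy ratio exceeds
#' \code{ampThreshold} and deleted when it falls below \code{delThreshold};
#' a gene may yield both an amplification and a deletion event. Events are
#' retained when their carrier fraction is at least \code{minFraction}.
#'
#' @param cnMatrix genes x samples matrix of gene-level log2 copy ratios.
#' @param ampThreshold,delThreshold calling bounds (log2 copy-ratio units).
#' @param minFraction minimum carrier fraction (inclusive).
#' @return list with \code{events} and \code{indicator} as in
#'   \code{\link{callRecurrentMutations}}.
#' @export
callRecurrentCnv <- function(cnMatrix, ampThreshold = AMP_THRESHOLD,
                             delThreshold = DEL_THRESHOLD,
                             minFraction = 0.10) {
    stopIfNot(ampThreshold > delThreshold,
              "ampThreshold must exceed delThreshold")
    samples <- colnames(cnMatrix)
    build <- function(indic, kind) {
        frac <- rowMeans(indic)
        keep <- frac >= minFraction
        ind <- t(indic[keep, , drop = FALSE])
        storage.mode(ind) <- "integer"
        if (ncol(ind))
            colnames(ind) <- paste0(rownames(cnMatrix)[keep], "_", kind)
        list(ind = ind,
             events = data.frame(label = colnames(ind),
                                 gene = rownames(cnMatrix)[keep],
                                 kind = rep(kind, sum(keep)),
                                 fraction = unname(frac[keep]),
                                 stringsAsFactors = FALSE, row.names = NULL))
    }
    amp <- build(cnMatrix > ampThreshold, "amp")
    del <- build(cnMatrix < delThreshold, "del")
    ind <- cbind(amp$ind, del$ind)
    rownames(ind) <- samples
    list(events = rbind(amp$events, del$events), indicator = ind)
}

#' Assemble the binary aberration matrix
#'
#' Binds mutation and copy-number indicator columns into one samples x events
#' matrix, ordered mutation events first, then amplifications, then
#' deletions, alphabetically within each kind.
#'
#' @param mutationCalls,cnvCalls results of the calling functions (either may
#'   be NULL).
#' @param sampleIds cohort samples (row order of the result).
#' @return samples x events binary integer matrix.
#' @export
assembleAberrationMatrix <- function(mutationCalls = NULL, cnvCalls = NULL,
                                     sampleIds) {
    parts <- list()
    if (!is.null(mutationCalls)) parts$mut <- mutationCalls$indicator
    if (!is.null(cnvCalls)) parts$cnv <- cnvCalls$indicator
    ind <- do.call(cbind, c(lapply(parts, function(m)
        m[sampleIds, , drop = FALSE]),
        list(matrix(0L, nrow = length(sampleIds), ncol = 0L))))
    rownames(ind) <- sampleIds
    if (anyDuplicated(colnames(ind)))
        stop("duplicate event labels across mutation and CNV calls",
             call. = FALSE)
    kind <- .eventKind(colnames(ind))
    ord <- order(match(kind, c("mut", "amp", "del")), colnames(ind))
    ind[, ord, drop = FALSE]
}

#' Run the full aberration-calling pipeline on files
#'
#' @param mafPath,segPath,bedPath input files.
#' @param sampleIds cohort sample identifiers.
#' @param minFraction recurrence threshold applied to both mutation and
#'   copy-number events.
#' @param ampThreshold,delThreshold copy-number calling bounds.
#' @param ... passed to \code{\link{callRecurrentMutations}}.
#' @return list with \code{matrix} (samples x events), \code{events}
#'   (combined events table) and \code{copyNumber} (gene-level matrix).
#' @export
callAberrations <- function(mafPath, segPath, bedPath, sampleIds,
                            minFraction = 0.10,
                            ampThreshold = AMP_THRESHOLD,
                            delThreshold = DEL_THRESHOLD, ...) {
    maf <- readMaf(mafPath)
    seg <- readSeg(segPath)
    anno <- readGeneAnnotation(bedPath)
    mut <- callRecurrentMutations(maf, sampleIds, minFraction = minFraction,
                                  ...)
    cn <- geneLevelCopyNumber(seg, anno, sampleIds)
    cnv <- callRecurrentCnv(cn, ampThreshold = ampThreshold,
                            delThreshold = delThreshold,
                            minFraction = minFraction)
    list(matrix = assembleAberrationMatrix(mut, cnv, sampleIds),
         events = rbind(mut$events, cnv$events),
         copyNumber = cn)
}
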