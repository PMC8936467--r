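#' Genomic layout for a simulated cohort
#'
#' Places the expression genes and the aberration-event genes on 22
#' chromosomes as non-overlapping 10 kb intervals separated by 5 kb gaps.
#'
#' @param cohort a simulated \linkS4class{ProgCohort}.
#' @return named \link[GenomicRanges]{GRanges}, one range per gene.
#' @export
simulatedGeneAnnotation <- function(cohort) {
    truth <- groundTruth(cohort)
    stopIfNot(!is.null(truth), "cohort has no simulation ground truth")
    eventGenes <- unique(vapply(strsplit(colnames(aberrations(cohort)), "_"),
                                `[`, character(1), 1L))
    genes <- unique(c(rownames(cohort), eventGenes))
    nChrom <- 22L
    perChrom <- ceiling(length(genes) / nChrom)
    chromIdx <- rep(seq_len(nChrom), each = perChrom)[seq_along(genes)]
    posInChrom <- sequence(tabulate(chromIdx))
    width <- 10000L
    gap <- 5000L
    start <- (posInChrom - 1L) * (width + gap) + 1L
    GenomicRanges::GRanges(
        seqnames = paste0("chr", chromIdx),
        ranges = IRanges::IRanges(start = start, width = width,
                                  names = genes),
        name = genes)
}

.eventGene <- function(label) vapply(strsplit(label, "_"), `[`,
                                     character(1), 1L)
.eventKind <- function(label) vapply(strsplit(label, "_"), `[`,
                                     character(1), 2L)

#' Write MAF, SEG and BED files matching a simulated cohort
#'
#' MAF rows exist exactly for the carriers of each mutation event (one
#' nonsynonymous row per carrier); SEG segments over the gene interval of each
#' copy-number event exceed the calling thresholds for carriers and stay in a
#' narrow neutral band otherwise, so that re-running the aberration callers on
#' these files recovers the ground-truth aberration matrix exactly.
#'
#' @param cohort a simulated \linkS4class{ProgCohort}.
#' @param outDir output directory (created if needed).
#' @param ampValue,delValue log2 copy-ratio written for amplification and
#'   deletion carriers; must exceed the default calling thresholds.
#' @param neutralSd standard deviation of the neutral-segment jitter
#'   (truncated at +/- 0.2, well inside the calling thresholds).
#' @return invisibly, a named list of the file paths written
#'   (\code{maf}, \code{seg}, \code{bed}).
#' @export
simulateGenomicFiles <- function(cohort, outDir, ampValue = 2.0,
                                 delValue = -1.0, neutralSd = 0.05) {
    truth <- groundTruth(cohort)
    stopIfNot(!is.null(truth), "cohort has no simulation ground truth")
    if (!dir.exists(outDir) &&
        !dir.create(outDir, recursive = TRUE, showWarnings = FALSE))
        stop("cannot create output directory: ", outDir, call. = FALSE)

    anno <- simulatedGeneAnnotation(cohort)
    ab <- aberrations(cohort)
    samples <- rownames(ab)
    labels <- colnames(ab)
    kinds <- .eventKind(labels)
    genesOf <- .eventGene(labels)

    # ---- MAF: one Missense_Mutation row per mutation-event carrier
    mutLabels <- labels[kinds == "mut"]
    mafRows <- do.call(rbind, lapply(mutLabels, function(l) {
        carriers <- samples[ab[, l] == 1L]
        if (!length(carriers)) return(NULL)
        data.frame(Hugo_Symbol = .eventGene(l),
                   Tumor_Sample_Barcode = carriers,
                   Variant_Classification = "Missense_Mutation",
                   Variant_Type = "SNP", stringsAsFactors = FALSE)
    }))
    if (is.null(mafRows))
        mafRows <- data.frame(Hugo_Symbol = character(),
                              Tumor_Sample_Barcode = character(),
                              Variant_Classification = character(),
                              Variant_Type = character())
    mafPath <- file.path(outDir, "mutations.maf")
    write.table(mafRows, mafPath, sep = "\t", quote = FALSE,
                row.names = FALSE)

    # ---- SEG: per sample, chromosomes split around copy-number event genes
    cnvLabels <- labels[kinds %in% c("amp", "del")]
    cnvGenes <- genesOf[kinds %in% c("amp", "del")]
    set.seed(subSeed(truth$config$seed, "files"))
    jitter <- function(k) pmax(pmin(rnorm(k, 0, neutralSd), 0.2), -0.2)

    chromEnd <- tapply(GenomicRanges::end(anno),
                       as.character(GenomicRanges::seqnames(anno)), max)
    segList <- vector("list", length(samples))
    cnvAnno <- anno[unique(cnvGenes)]
    cnvChrom <- as.character(GenomicRanges::seqnames(cnvAnno))
    for (si in seq_along(samples)) {
        s <- samples[si]
        rows <- list()
        for (ch in names(chromEnd)) {
            onChrom <- which(cnvChrom == ch)
            cuts <- sort(unique(c(1L, chromEnd[[ch]] + 1L,
                                  GenomicRanges::start(cnvAnno)[onChrom],
                                  GenomicRanges::end(cnvAnno)[onChrom] + 1L)))
            segStart <- cuts[-length(cuts)]
            segEnd <- cuts[-1L] - 1L
            vals <- jitter(length(segStart))
            for (gi in onChrom) {
                g <- names(cnvAnno)[gi]
                hit <- which(segStart == GenomicRanges::start(cnvAnno)[gi])
                lab <- cnvLabels[cnvGenes == g]
                for (l in lab) {
                    if (ab[s, l] == 1L)
                        vals[hit] <- if (.eventKind(l) == "amp") ampValue
                                     else delValue
                }
            }
            rows[[ch]] <- data.frame(Sample = s, Chromosome = ch,
                                     Start = segStart, End = segEnd,
                                     Segment_Mean = vals)
        }
        segList[[si]] <- do.call(rbind, rows)
    }
    seg <- do.call(rbind, segList)
    segPath <- file.path(outDir, "copynumber.seg")
    write.table(seg, segPath, sep = "\t", quote = FALSE, row.names = FALSE)

    # ---- BED (0-based half-open on disk, handled by rtracklayer)
    bedPath <- file.path(outDir, "genes.bed")
    rtracklayer::export(anno, bedPath, format = "BED")

    invisible(list(maf = mafPath, seg = segPath, bed = bedPath))
}

#' Write a complete cohort bundle directory
#'
#' Writes expression, clinical, survival, aberration TSVs plus
#' \code{truth.json} (ground truth without the bulky reference matrix) and a
#' \code{config.yaml} that \code{\link{readCohortBundle}} can consume.
#'
#' @param cohort a \linkS4class{ProgCohort} (simulated or real).
#' @param outDir output directory.
#' @return invisibly, the path to the config file.
#' @export
writeCohortBundle <- function(cohort, outDir) {
    if (!dir.exists(outDir) &&
        !dir.create(outDir, recursive = TRUE, showWarnings = FALSE))
        stop("cannot create output directory: ", outDir, call. = FALSE)
    paths <- list(expression = file.path(outDir, "expression.tsv"))
    writeMatrixTsv(exprs(cohort), paths$expression)
    cd <- SummarizedExperiment::colData(cohort)
    clin <- clinicalData(cohort)
    if (ncol(clin)) {
        paths$clinical <- file.path(outDir, "clinical.tsv")
        write.table(data.frame(sample = rownames(clin), clin),
                    paths$clinical, sep = "\t", quote = FALSE,
                    row.names = FALSE)
    }
    if (all(c("time", "event") %in% colnames(cd))) {
        sv <- survivalData(cohort)
        paths$survival <- file.path(outDir, "survival.tsv")
        write.table(data.frame(sample = rownames(sv),
                               format(sv, digits = 17, trim = TRUE)),
                    paths$survival, sep = "\t", quote = FALSE,
                    row.names = FALSE)
    }
    ab <- aberrations(cohort)
    if (!is.null(ab)) {
        paths$aberrations <- file.path(outDir, "aberrations.tsv")
        write.table(data.frame(sample = rownames(ab), ab, check.names = FALSE),
                    paths$aberrations, sep = "\t", quote = FALSE,
                    row.names = FALSE)
    }
    truth <- groundTruth(cohort)
    if (!is.null(truth)) {
        tr <- truth[c("carriers", "signatureGenes", "directions")]
        tr$immuneFractions <- as.data.frame(truth$immuneFractions)
        tr$linearRisk <- truth$linearRisk
        jsonlite::write_json(tr, file.path(outDir, "truth.json"),
                             auto_unbox = TRUE, digits = NA)
    }
    cfgPath <- file.path(outDir, "config.yaml")
    yaml::write_yaml(c(paths, list(expression_scale = "log2")), cfgPath)
    invisible(cfgPath)
}
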