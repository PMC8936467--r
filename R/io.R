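#' Controlled vocabulary of MAF variant classifications
#'
#' The classification values accepted by \code{\link{readMaf}}, following the
#' standard Mutation Annotation Format vocabulary.
#' @export
MAF_CLASSES <- c(
    "Missense_Mutation", "Nonsense_Mutation", "Nonstop_Mutation",
    "Splice_Site", "Translation_Start_Site", "Frame_Shift_Del",
    "Frame_Shift_Ins", "In_Frame_Del", "In_Frame_Ins", "Silent",
    "3'UTR", "5'UTR", "3'Flank", "5'Flank", "Intron", "IGR", "RNA",
    "Targeted_Region")

#' Default qualifying (nonsynonymous) variant classes for mutation calling
#'
#' Point-mutation classes that alter the protein product; with
#' \code{includeIndels = TRUE} (the default of
#' \code{\link{callRecurrentMutations}}) frameshift and in-frame indels
#' qualify as well.
#' @export
NONSYNONYMOUS_CLASSES <- c(
    "Missense_Mutation", "Nonsense_Mutation", "Nonstop_Mutation",
    "Splice_Site", "Translation_Start_Site")

#' @rdname NONSYNONYMOUS_CLASSES
#' @export
INDEL_CLASSES <- c("Frame_Shift_Del", "Frame_Shift_Ins",
                   "In_Frame_Del", "In_Frame_Ins")

.readTsv <- function(path, what) {
    if (!file.exists(path))
        stop("cannot read ", what, " file: ", path, call. = FALSE)
    data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE,
                      check.names = FALSE)
}

.requireCols <- function(df, cols, what, path) {
    miss <- setdiff(cols, colnames(df))
    if (length(miss))
        stop(what, " file ", path, " lacks required column(s): ",
             paste(miss, collapse = ", "), call. = FALSE)
}

#' Read a Mutation Annotation Format (MAF) file
#'
#' Tab-delimited with a header; \code{#} comment lines are skipped, column
#' order is free and unknown columns are ignored.
#'
#' @param path file path.
#' @return data.frame with columns \code{hugo_symbol}, \code{sample_barcode},
#'   \code{variant_classification}, \code{variant_type}, one row per variant.
#' @export
readMaf <- function(path) {
    if (!file.exists(path)) stop("cannot read MAF file: ", path, call. = FALSE)
    df <- data.table::fread(path, sep = "\t", header = TRUE,
                            data.table = FALSE, check.names = FALSE)
    cmap <- c(hugo_symbol = "Hugo_Symbol",
              sample_barcode = "Tumor_Sample_Barcode",
              variant_classification = "Variant_Classification",
              variant_type = "Variant_Type")
    .requireCols(df, unname(cmap), "MAF", path)
    out <- data.frame(
        hugo_symbol = as.character(df[[cmap["hugo_symbol"]]]),
        sample_barcode = as.character(df[[cmap["sample_barcode"]]]),
        variant_classification = as.character(df[[cmap["variant_classification"]]]),
        variant_type = as.character(df[[cmap["variant_type"]]]),
        stringsAsFactors = FALSE)
    if (nrow(out)) {
        if (any(!nzchar(out$hugo_symbol)) || any(!nzchar(out$sample_barcode)))
            stop("MAF file ", path, " has empty gene or sample identifiers",
                 call. = FALSE)
        bad <- setdiff(unique(out$variant_classification), MAF_CLASSES)
        if (length(bad))
            warning("MAF file ", path, " uses classifications outside the ",
                    "known vocabulary: ", paste(bad, collapse = ", "))
    }
    out
}

#' Read a segmented copy-number (SEG) file
#'
#' Tab-delimited with columns Sample, Chromosome, Start, End, Segment_Mean
#' (1-based inclusive coordinates, log2 copy ratio values).
#'
#' @param path file path.
#' @return data.frame with columns \code{sample_barcode}, \code{chrom},
#'   \code{start}, \code{end}, \code{value}.
#' @export
readSeg <- function(path) {
    df <- .readTsv(path, "SEG")
    cmap <- c(sample_barcode = "Sample", chrom = "Chromosome",
              start = "Start", end = "End", value = "Segment_Mean")
    .requireCols(df, unname(cmap), "SEG", path)
    out <- data.frame(
        sample_barcode = as.character(df[[cmap["sample_barcode"]]]),
        chrom = as.character(df[[cmap["chrom"]]]),
        start = suppressWarnings(as.integer(df[[cmap["start"]]])),
        end = suppressWarnings(as.integer(df[[cmap["end"]]])),
        value = suppressWarnings(as.numeric(df[[cmap["value"]]])),
        stringsAsFactors = FALSE)
    if (nrow(out)) {
        if (anyNA(out$value) || anyNA(out$start) || anyNA(out$end))
            stop("SEG file ", path, " has non-numeric coordinates or values ",
                 "at row(s) ",
                 paste(head(which(is.na(out$value) | is.na(out$start) |
                                  is.na(out$end))), collapse = ", "),
                 call. = FALSE)
        bad <- which(out$start > out$end)
        if (length(bad))
            stop("SEG file ", path, ": start > end at row(s) ",
                 paste(head(bad), collapse = ", "), call. = FALSE)
    }
    out
}

#' Read gene annotation intervals from a BED file
#'
#' BED input is 0-based half-open on disk; the returned
#' \link[GenomicRanges]{GRanges} uses the usual 1-based closed convention,
#' with one interval per gene (the BED name column).
#'
#' @param path BED file path.
#' @return named \code{GRanges}, one range per gene.
#' @export
readGeneAnnotation <- function(path) {
    gr <- rtracklayer::import(path, format = "BED")
    if (is.null(gr$name) || any(!nzchar(gr$name)))
        stop("BED file ", path, " must carry gene identifiers in the name ",
             "column", call. = FALSE)
    if (anyDuplicated(gr$name))
        stop("BED file ", path, " has more than one interval per gene",
             call. = FALSE)
    names(gr) <- gr$name
    gr
}

#' Read an expression matrix TSV (genes x samples)
#'
#' @param path file path; first column = gene identifiers, remaining columns
#'   samples.
#' @param scale \code{"log2"} if values are already log-scale, \code{"raw"}
#'   to apply log2(x + 1) at load.
#' @return numeric matrix, genes x samples.
#' @export
readExpressionMatrix <- function(path, scale = c("log2", "raw")) {
    scale <- match.arg(scale)
    df <- .readTsv(path, "expression")
    genes <- as.character(df[[1L]])
    m <- as.matrix(df[, -1L, drop = FALSE])
    storage.mode(m) <- "double"
    rownames(m) <- genes
    if (anyDuplicated(genes))
        stop("duplicate gene identifiers in ", path, call. = FALSE)
    if (scale == "raw") m <- log2(m + 1)
    m
}

.readSampleTable <- function(path, what) {
    df <- .readTsv(path, what)
    .requireCols(df, "sample", what, path)
    if (anyDuplicated(df$sample))
        stop("duplicate sample identifiers in ", what, " file ", path,
             call. = FALSE)
    rownames(df) <- df$sample
    df[, setdiff(colnames(df), "sample"), drop = FALSE]
}

#' Read a cohort bundle from a config
#'
#' Assembles a \linkS4class{ProgCohort} from a set of TSV files. The sample
#' sets of all components are intersected; samples dropped from any component
#' are reported, and samples are ordered lexicographically.
#'
#' @param config either the path to a YAML file or a named list with entries
#'   \code{expression} (required), \code{clinical}, \code{survival},
#'   \code{aberrations}, \code{comparator} (paths), and optional
#'   \code{expression_scale} ("log2" or "raw", default "log2").
#' @return A \linkS4class{ProgCohort}.
#' @export
readCohortBundle <- function(config) {
    if (is.character(config) && length(config) == 1L)
        config <- yaml::read_yaml(config)
    stopIfNot(!is.null(config$expression),
              "config must name an 'expression' file")
    scale <- if (is.null(config$expression_scale)) "log2"
             else config$expression_scale
    expr <- readExpressionMatrix(config$expression, scale = scale)
    if (anyDuplicated(colnames(expr)))
        stop("duplicate sample identifiers in expression matrix",
             call. = FALSE)
    sampleSets <- list(expression = colnames(expr))

    clinical <- survivalTab <- comparatorTab <- NULL
    if (!is.null(config$clinical)) {
        clinical <- .readSampleTable(config$clinical, "clinical")
        sampleSets$clinical <- rownames(clinical)
    }
    if (!is.null(config$survival)) {
        survivalTab <- .readSampleTable(config$survival, "survival")
        .requireCols(survivalTab, c("time", "event"), "survival",
                     config$survival)
        sampleSets$survival <- rownames(survivalTab)
    }
    if (!is.null(config$comparator)) {
        comparatorTab <- .readSampleTable(config$comparator, "comparator")
        sampleSets$comparator <- rownames(comparatorTab)
    }
    ab <- NULL
    if (!is.null(config$aberrations)) {
        abDf <- .readSampleTable(config$aberrations, "aberrations")
        ab <- as.matrix(abDf)
        storage.mode(ab) <- "integer"
        sampleSets$aberrations <- rownames(ab)
    }

    common <- sort(Reduce(intersect, sampleSets))
    if (!length(common))
        stop("no samples shared by all bundle components", call. = FALSE)
    for (nm in names(sampleSets)) {
        dropped <- length(sampleSets[[nm]]) - length(common)
        if (dropped > 0)
            .msg("dropped ", dropped, " sample(s) from '", nm,
                 "' not shared by all components")
    }
    ProgCohort(
        exprs = expr[, common, drop = FALSE],
        clinical = if (!is.null(clinical)) clinical[common, , drop = FALSE],
        survival = if (!is.null(survivalTab))
            survivalTab[common, , drop = FALSE],
        aberrations = if (!is.null(ab)) ab[common, , drop = FALSE],
        comparator = if (!is.null(comparatorTab))
            comparatorTab[common, "score"])
}

#' Write signature weight sets as a TSV
#'
#' One row per (gene, event): columns gene, event, w_plus, w_minus and, when
#' available, beta and p.
#'
#' @param weightSets list of \linkS4class{SignatureWeightSet}.
#' @param path output path.
#' @return invisibly, the path.
#' @export
writeWeightsTsv <- function(weightSets, path) {
    rows <- lapply(weightSets, function(ws) {
        df <- data.frame(gene = ws@gene, event = ws@event,
                         w_plus = ws@wPlus, w_minus = ws@wMinus,
                         stringsAsFactors = FALSE)
        if ("beta" %in% colnames(ws@stats)) df$beta <- ws@stats$beta
        if ("p" %in% colnames(ws@stats)) df$p <- ws@stats$p
        df
    })
    out <- do.call(rbind, rows)
    write.table(format(out, digits = 17, trim = TRUE, scientific = NA),
                path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Write a samples x features score matrix as a TSV
#' @param scores numeric matrix with sample rownames.
#' @param path output path.
#' @return invisibly, the path.
#' @export
writeScoresTsv <- function(scores, path) {
    df <- data.frame(sample = rownames(scores), scores, check.names = FALSE)
    write.table(format(df, digits = 17, trim = TRUE, scientific = NA),
                path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Write a matrix as a gene x sample TSV
#' @param m numeric matrix with rownames.
#' @param path output path.
#' @param idCol name of the identifier column.
#' @return invisibly, the path.
#' @export
writeMatrixTsv <- function(m, path, idCol = "gene") {
    df <- data.frame(rownames(m), m, check.names = FALSE,
                     stringsAsFactors = FALSE)
    colnames(df)[1L] <- idCol
    write.table(format(df, digits = 17, trim = TRUE, scientific = NA),
                path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
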