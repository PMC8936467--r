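test_that("the recurrence threshold is inclusive at exactly 10 percent", {
    samples <- sprintf("S%03d", 1:100)
    rows <- c(lapply(samples[1:10], function(s)
                  list("GENEA", s, "Missense_Mutation")),
              lapply(samples[1:9], function(s)
                  list("GENEB", s, "Nonsense_Mutation")))
    maf <- readMaf(toyMaf(rows))
    res <- callRecurrentMutations(maf, samples, minFraction = 0.10)
    expect_equal(colnames(res$indicator), "GENEA_mut")
    expect_equal(res$events$fraction, 0.10)
    expect_equal(sum(res$indicator), 10L)
})

test_that("silent-only variants never qualify and duplicates count once", {
    samples <- paste0("S", 1:10)
    rows <- c(lapply(samples[1:3], function(s) list("GENEA", s, "Silent")),
              list(list("GENEB", "S1", "Missense_Mutation"),
                   list("GENEB", "S1", "Nonsense_Mutation"),
                   list("GENEB", "S2", "Missense_Mutation")))
    maf <- readMaf(toyMaf(rows))
    res <- callRecurrentMutations(maf, samples, minFraction = 0.1)
    expect_false("GENEA_mut" %in% colnames(res$indicator))
    expect_equal(unname(res$indicator[c("S1", "S2"), "GENEB_mut"]), c(1L, 1L))
    expect_equal(res$events$fraction[res$events$label == "GENEB_mut"], 0.2)
})

test_that("indel classes are controlled by the includeIndels switch", {
    samples <- paste0("S", 1:10)
    rows <- lapply(samples[1:2], function(s)
        list("GENEC", s, "Frame_Shift_Del", "DEL"))
    maf <- readMaf(toyMaf(rows))
    with_ind <- callRecurrentMutations(maf, samples, minFraction = 0.1)
    expect_true("GENEC_mut" %in% colnames(with_ind$indicator))
    without <- callRecurrentMutations(maf, samples, minFraction = 0.1,
                                      includeIndels = FALSE)
    expect_false("GENEC_mut" %in% colnames(without$indicator))
})

test_that("gene-level copy number is the overlap-weighted segment mean", {
    anno <- GenomicRanges::GRanges("chr1",
        IRanges::IRanges(start = c(101, 301), end = c(200, 400),
                         names = c("GA", "GB")))
    seg <- data.frame(
        sample_barcode = "S1",
        chrom = "chr1",
        start = c(1L, 151L),
        end = c(150L, 1000L),
        value = c(1.0, 0.0))
    cn <- geneLevelCopyNumber(seg, anno, "S1")
    expect_equal(cn["GA", "S1"], 0.5)    # 50/50 split between 1.0 and 0.0
    expect_equal(cn["GB", "S1"], 0.0)    # fully inside the second segment

    seg2 <- data.frame(sample_barcode = "S1", chrom = "chr1",
                       start = 90L, end = 500L, value = 0.8)
    cn2 <- geneLevelCopyNumber(seg2, anno, "S1")
    expect_equal(unname(cn2[, "S1"]), c(0.8, 0.8))
})

test_that("gene copy number equals a per-base averaging oracle", {
    set.seed(13)
    anno <- GenomicRanges::GRanges("chr1",
        IRanges::IRanges(start = c(11, 61, 131), width = c(30, 40, 25),
                         names = c("GA", "GB", "GC")))
    # random tiling of [1, 300] into segments
    cuts <- sort(sample(2:299, 6))
    starts <- c(1L, cuts)
    ends <- c(cuts - 1L, 300L)
    vals <- round(rnorm(length(starts)), 3)
    seg <- data.frame(sample_barcode = "S1", chrom = "chr1",
                      start = starts, end = ends, value = vals)
    cn <- geneLevelCopyNumber(seg, anno, "S1")
    # oracle: average the segment value over every base of the gene
    baseVal <- rep(NA_real_, 300)
    for (i in seq_along(starts)) baseVal[starts[i]:ends[i]] <- vals[i]
    for (g in names(anno)) {
        span <- GenomicRanges::start(anno[g]):GenomicRanges::end(anno[g])
        expect_equal(cn[g, "S1"], mean(baseVal[span]), tolerance = 1e-12)
    }
})

test_that("copy-number calling applies literal log2-ratio bounds", {
    cn <- matrix(c(log2(3.0), 0, -0.5, log2(2.82)), nrow = 4,
                 dimnames = list(c("GA", "GB", "GC", "GD"), "S1"))
    cn <- cbind(cn, S2 = c(log2(3.0), 0, -0.5, 0))
    res <- callRecurrentCnv(cn, minFraction = 0.5)
    expect_true("GA_amp" %in% colnames(res$indicator))   # log2(3) > log2(2.82)
    expect_false("GB_amp" %in% colnames(res$indicator))  # 0 is neutral
    expect_true("GC_del" %in% colnames(res$indicator))   # -0.5 < -log2(1.32)
    # boundary: exactly log2(2.82) is NOT an amplification (strict >)
    expect_false("GD_amp" %in% colnames(res$indicator))
    expect_equal(unname(res$indicator[, "GA_amp"]), c(1L, 1L))
    expect_error(callRecurrentCnv(cn, ampThreshold = -1, delThreshold = 1),
                 "exceed")
})

test_that("aberration matrix assembly orders mut, amp, del and keeps zeros", {
    samples <- paste0("S", 1:4)
    mut <- list(indicator = matrix(c(1L, 0L, 0L, 0L, 0L, 1L, 0L, 0L),
                                   nrow = 4,
                                   dimnames = list(samples,
                                                   c("ZZZ_mut", "AAA_mut"))))
    cnv <- list(indicator = matrix(c(0L, 1L, 0L, 0L), nrow = 4,
                                   dimnames = list(samples, "BBB_amp")))
    m <- assembleAberrationMatrix(mut, cnv, samples)
    expect_equal(colnames(m), c("AAA_mut", "ZZZ_mut", "BBB_amp"))
    expect_equal(unname(m["S4", ]), c(0L, 0L, 0L))  # all-zero row retained
    dup <- list(indicator = matrix(0L, nrow = 4,
                                   dimnames = list(samples, "AAA_mut")))
    expect_error(assembleAberrationMatrix(mut, dup, samples), "duplicate")
})

test_that("calling is invariant to input row order", {
    coh <- simulateCohort(smallConfig(seed = 101, nSamples = 40,
                                      nGenes = 250))
    d <- withr::local_tempdir()
    files <- simulateGenomicFiles(coh, d)
    maf <- readMaf(files$maf)
    seg <- readSeg(files$seg)
    anno <- readGeneAnnotation(files$bed)
    samples <- colnames(coh)
    set.seed(1)
    mafShuf <- maf[sample(nrow(maf)), ]
    segShuf <- seg[sample(nrow(seg)), ]
    expect_identical(callRecurrentMutations(maf, samples)$indicator,
                     callRecurrentMutations(mafShuf, samples)$indicator)
    expect_identical(geneLevelCopyNumber(seg, anno, samples),
                     geneLevelCopyNumber(segShuf, anno, samples))
})

test_that("every retained event meets the recurrence threshold", {
    coh <- simulateCohort(smallConfig(seed = 111, nSamples = 50,
                                      nGenes = 250))
    d <- withr::local_tempdir()
    files <- simulateGenomicFiles(coh, d)
    res <- callAberrations(files$maf, files$seg, files$bed,
                           sampleIds = colnames(coh), minFraction = 0.10)
    expect_true(all(res$events$fraction >= 0.10))
    expect_true(all(colMeans(res$matrix) >= 0.10))
})
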