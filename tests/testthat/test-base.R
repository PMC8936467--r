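test_that("profile preparation centers by cohort median and ranks signed", {
    expr <- rbind(G1 = c(5, 5, 5),    # at the median -> magnitude 0
                  G2 = c(9, 7, 7),    # +2 in S1
                  G3 = c(1, 4, 4))    # -3 in S1
    colnames(expr) <- c("S1", "S2", "S3")
    g <- prepareProfile(expr, "S1")
    # signed ordering: +2 ranks before 0 before -3 (despite |.|)
    expect_equal(names(g), c("G2", "G1", "G3"))
    expect_equal(unname(g), c(2, 0, 3))
    # permuting the cohort's sample order leaves g unchanged
    g2 <- prepareProfile(expr[, c(3, 1, 2)], "S1")
    expect_identical(g, g2)
    expect_error(prepareProfile(expr[, 1, drop = FALSE], "S1"),
                 ">= 2 samples")
})

test_that("the fast scorer equals the naive cumulative-sum oracle", {
    set.seed(17)
    for (i in 1:100) {
        n <- 50
        g <- sort(abs(rnorm(n)), decreasing = sample(c(TRUE, FALSE), 1))
        names(g) <- paste0("G", 1:n)
        ws <- randomWeightSet(names(g), seed = 1000 + i)
        perms <- replicate(20, sample.int(n))
        fast <- baseScore(g, ws, seed = 1, perms = perms)
        naive <- naiveBaseScore(g, ws, perms)
        expect_equal(fast@score, naive$score, tolerance = 1e-12)
        expect_equal(fast@scorePlus, naive$plus, tolerance = 1e-12)
        expect_equal(fast@scoreMinus, naive$minus, tolerance = 1e-12)
        expect_equal(unname(baseNull(fast)[, "plus"]), naive$nullPlus,
                     tolerance = 1e-12)
    }
})

test_that("constant and all-zero weight vectors give exactly zero", {
    g <- setNames(abs(rnorm(30)), paste0("G", 1:30))
    const <- SignatureWeightSet("const", names(g),
                                wPlus = rep(0.4, 30),
                                wMinus = numeric(30))
    r <- baseScore(g, const, nPerm = 10, seed = 1)
    expect_identical(r@scorePlus, 0)
    expect_identical(r@score, 0)

    zero <- SignatureWeightSet("zero", names(g), numeric(30), numeric(30))
    expect_warning(r0 <- baseScore(g, zero, nPerm = 10, seed = 1),
                   "all weights are zero")
    expect_identical(r0@score, 0)
})

test_that("the deviation is invariant to rescaling the magnitudes", {
    set.seed(19)
    g <- setNames(abs(rnorm(40)), paste0("G", 1:40))
    ws <- randomWeightSet(names(g), seed = 5)
    perms <- replicate(15, sample.int(40))
    a <- baseScore(g, ws, perms = perms)
    b <- baseScore(g * 7.3, ws, perms = perms)
    expect_equal(a@score, b@score, tolerance = 1e-12)
    expect_equal(a@scorePlus, b@scorePlus, tolerance = 1e-12)
})

test_that("weight mass on top ranks gives positive deviation, bottom negative", {
    n <- 60
    g <- setNames(seq(3, 0.05, length.out = n), paste0("G", 1:n))
    top <- SignatureWeightSet("top", names(g),
                              wPlus = c(rep(1, 10), rep(0, n - 10)),
                              wMinus = numeric(n))
    bottom <- SignatureWeightSet("bottom", names(g),
                                 wPlus = c(rep(0, n - 10), rep(1, 10)),
                                 wMinus = numeric(n))
    expect_gt(baseScore(g, top, nPerm = 10, seed = 1)@scorePlus, 0)
    expect_lt(baseScore(g, bottom, nPerm = 10, seed = 1)@scorePlus, 0)
})

test_that("internal permutation streams are deterministic and per-cell", {
    coh <- simulateCohort(smallConfig(seed = 131, nSamples = 30,
                                      nGenes = 250))
    ws <- fitSignatures(coh, mode = "univariate")$weights
    s1 <- scoreCohort(coh, ws["TP53_mut"], nPerm = 50, seed = 9)
    s2 <- scoreCohort(coh, ws["TP53_mut"], nPerm = 50, seed = 9)
    expect_identical(s1, s2)
    s3 <- scoreCohort(coh, ws["TP53_mut"], nPerm = 50, seed = 10)
    expect_false(identical(s1, s3))
})

test_that("duplicated weight sets under different labels score identically", {
    coh <- simulateCohort(smallConfig(seed = 141, nSamples = 25,
                                      nGenes = 250))
    ws <- fitSignatures(coh, mode = "univariate")$weights[["TP53_mut"]]
    dup <- ws; dup@event <- "copy"
    sc <- scoreCohort(coh, list(a = ws, b = dup), nPerm = 50, seed = 3)
    expect_identical(unname(sc[, "a"]), unname(sc[, "b"]))
})

test_that("random weight sets are calibrated around zero", {
    coh <- simulateCohort(smallConfig(seed = 151, nSamples = 200,
                                      nGenes = 300, effect = 0))
    ws <- randomWeightSet(rownames(coh), seed = 6)
    sc <- scoreCohort(coh, list(rnd = ws), nPerm = 200, seed = 4)
    se <- sd(sc[, 1]) / sqrt(nrow(sc))
    expect_lt(abs(mean(sc[, 1])), 3 * se)
})

test_that("immune weights pick planted markers and only positive specificity", {
    cfg <- smallConfig(seed = 161, nSamples = 30, nGenes = 300)
    prof <- simulateReferenceProfiles(cfg)
    ws <- deriveImmuneWeights(prof$reference, topK = 15)
    expect_named(ws, IMMUNE_CELL_TYPES)
    memb <- ws$MemB
    wp <- weightPlus(memb)
    expect_setequal(names(wp[wp > 0]), prof$markers$MemB)
    expect_true(all(weightMinus(memb) == 0))
    # a gene expressed equally in all types gets zero weight
    flat <- matrix(1, nrow = 2, ncol = 5,
                   dimnames = list(c("A", "B"), paste0("G", 1:5)))
    flat["A", 1:2] <- 3
    expect_warning(expect_warning(
        wsFlat <- deriveImmuneWeights(flat, topK = 3),
        "positive specificity"), "positive specificity")
    expect_equal(unname(weightPlus(wsFlat$B)), rep(0, 5))
})

test_that("AUC equals brute-force pair counting with half-weight ties", {
    set.seed(23)
    for (i in 1:10) {
        n <- 40
        sc <- sample(1:8, n, replace = TRUE)  # force ties
        st <- rbinom(n, 1, 0.4)
        if (length(unique(st)) < 2) next
        brute <- 0
        pos <- which(st == 1); neg <- which(st == 0)
        for (p in pos) for (q in neg)
            brute <- brute + (sc[p] > sc[q]) + 0.5 * (sc[p] == sc[q])
        brute <- brute / (length(pos) * length(neg))
        expect_equal(aucScore(sc, st), brute, tolerance = 1e-12)
    }
    expect_equal(aucScore(c(1, 2, 3, 4), c(0, 0, 1, 1)), 1.0)
    expect_error(aucScore(1:4, c(1, 1, 1, 1)), "both classes")
})

test_that("ROC curve endpoints and null behavior are sane", {
    set.seed(29)
    v <- validateSignature(rnorm(1000), rbinom(1000, 1, 0.5))
    expect_gt(v$auc, 0.45); expect_lt(v$auc, 0.55)
    expect_equal(v$roc$fpr[1], 0)
    expect_equal(v$roc$tpr[nrow(v$roc)], 1)
})
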