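# Shared fixtures: everything is generated in code at test time.

smallConfig <- function(seed = 11L, nSamples = 60L, nGenes = 300L,
                        effect = 1.0, ...) {
    simulationConfig(
        nSamples = nSamples, nGenes = nGenes,
        events = data.frame(
            label = c("TP53_mut", "CCND1_amp", "ATM_del"),
            fraction = c(0.20, 0.15, 0.10),
            setSize = 40L, effect = effect),
        immune = data.frame(cellType = IMMUNE_CELL_TYPES,
                            meanFraction = rep(0.04, 6), markerSize = 15L),
        seed = seed, ...)
}

writeTempTsv <- function(df, ext = ".tsv") {
    path <- tempfile(fileext = ext)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    path
}

toyMaf <- function(rows) {
    df <- do.call(rbind, lapply(rows, function(r)
        data.frame(Hugo_Symbol = r[[1]], Tumor_Sample_Barcode = r[[2]],
                   Variant_Classification = r[[3]],
                   Variant_Type = if (length(r) > 3) r[[4]] else "SNP")))
    writeTempTsv(df)
}

# Independent reference implementation of the enrichment deviation: explicit
# cumulative sums, no shortcuts. Shares an explicit permutation matrix with
# the fast path when comparing.
naiveDev <- function(g, w) {
    s1 <- sum(g * w); s0 <- sum(g * (1 - w))
    if (s1 <= 0 || s0 <= 0) return(0)
    d <- cumsum(g * w) / s1 - cumsum(g * (1 - w)) / s0
    d[which.max(abs(d))]
}

naiveBaseScore <- function(g, ws, perms, nullNorm = "mean_abs") {
    wp <- wm <- setNames(numeric(length(g)), names(g))
    common <- intersect(ws@gene, names(g))
    wp[common] <- PrognoSig::weightPlus(ws)[common]
    wm[common] <- PrognoSig::weightMinus(ws)[common]
    gv <- unname(g)
    devP <- if (max(wp) == min(wp)) 0 else naiveDev(gv, unname(wp))
    devM <- if (max(wm) == min(wm)) 0 else naiveDev(gv, unname(wm))
    nullP <- apply(perms, 2, function(ix) naiveDev(gv[ix], unname(wp)))
    nullM <- apply(perms, 2, function(ix) naiveDev(gv[ix], unname(wm)))
    if (max(wp) == min(wp)) nullP <- rep(0, ncol(perms))
    if (max(wm) == min(wm)) nullM <- rep(0, ncol(perms))
    norm <- function(s, nulls) {
        d <- mean(abs(nulls)); if (d == 0) 0 else s / d
    }
    np <- if (max(wp) == min(wp)) 0 else norm(devP, nullP)
    nm <- if (max(wm) == min(wm)) 0 else norm(devM, nullM)
    list(score = np - nm, plus = devP, minus = devM,
         nullPlus = nullP, nullMinus = nullM)
}

randomWeightSet <- function(genes, seed, label = "rnd") {
    set.seed(seed)
    n <- length(genes)
    raw <- runif(n)
    sign <- sample(c(1, -1, 0), n, replace = TRUE, prob = c(.3, .3, .4))
    SignatureWeightSet(event = label, gene = genes,
                       wPlus = ifelse(sign > 0, raw, 0),
                       wMinus = ifelse(sign < 0, raw, 0))
}

# Simple exponential survival generator for model-recovery checks.
simSurv <- function(n, beta, score, h0 = 0.1, cmax = 30, seed = 1) {
    set.seed(seed)
    t <- rexp(n, rate = h0 * exp(beta * score))
    cens <- runif(n, 0, cmax)
    data.frame(time = pmin(t, cens), event = as.integer(t <= cens))
}
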