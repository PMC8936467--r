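#' Default immune cell types
#' @export
IMMUNE_CELL_TYPES <- c("NavB", "MemB", "CD4T", "CD8T", "NKcell", "Monocytes")

#' Build a simulation configuration
#'
#' Describes a synthetic ER+ breast-cancer-like cohort: binary genomic events
#' with planted expression signatures, immune cell admixture from reference
#' profiles, clinical covariates, and right-censored survival whose hazard
#' depends on planted event status and clinical variables.
#'
#' Defaults describe the regime the downstream models are designed for:
#' moderately sized cohorts (hundreds of samples), 10-25\% carrier
#' fractions, 150-gene signatures shifted by 1 log2 unit in carriers, six
#' admixed immune cell types, exponential survival with uniform censoring.
#'
#' @param nSamples number of samples (>= 20).
#' @param nGenes total genes in the expression matrix.
#' @param events data.frame with columns \code{label} (e.g. "TP53_mut"),
#'   \code{fraction} (carrier fraction in (0,1)), \code{setSize} (signature
#'   gene-set size) and \code{effect} (log2 shift in carriers; half the set
#'   is shifted up, half down).
#' @param immune data.frame with columns \code{cellType}, \code{meanFraction},
#'   \code{markerSize}.
#' @param baselineHazard events per time unit (years) at linear risk 0.
#' @param hazardCoefs named log-hazard coefficients; names refer to event
#'   labels (carrier status), immune cell types (planted fraction, per 0.1),
#'   or clinical variables \code{age}, \code{size}, \code{nodes} (per unit,
#'   centered). Default: the first two events carry log-hazards 1.0 and 0.7,
#'   MemB is protective (-0.5 per 0.1 fraction), and age/size/nodes
#'   contribute 0.02/0.15/0.15.
#' @param censoringRate approximate target fraction censored before an event;
#'   censoring times are uniform on (0, horizon / censoringRate).
#' @param horizon follow-up horizon in years.
#' @param noiseSd expression noise standard deviation (log2 units).
#' @param immuneScale multiplier on the immune admixture contribution.
#' @param eventCorrelation optional pairwise correlation in (0, 1) between
#'   consecutive event pairs (shared-carrier overlap); 0 = independent.
#' @param seed master seed; all randomness flows from named substreams.
#' @return list of class \code{SimulationConfig}.
#' @export
simulationConfig <- function(
        nSamples = 400L,
        nGenes = 2000L,
        events = data.frame(
            label = c("TP53_mut", "PIK3CA_mut", "CCND1_amp", "ERBB2_amp",
                      "MYC_amp", "FGFR1_amp", "COX6C_amp", "TNFRSF17_amp",
                      "ATM_del", "MAP2K4_del"),
            fraction = c(0.20, 0.25, 0.15, 0.12, 0.18, 0.12, 0.15, 0.10,
                         0.12, 0.10),
            setSize = 150L,
            effect = 1.0),
        immune = data.frame(
            cellType = IMMUNE_CELL_TYPES,
            meanFraction = c(0.03, 0.05, 0.08, 0.06, 0.03, 0.05),
            markerSize = 60L),
        baselineHazard = 0.04,
        hazardCoefs = NULL,
        censoringRate = 0.3,
        horizon = 15,
        noiseSd = 0.5,
        immuneScale = 1.0,
        eventCorrelation = 0,
        seed = 1L) {
    if (is.null(hazardCoefs)) {
        # default prognostic structure: the first two events carry hazard,
        # memory-B infiltration is protective, clinical factors contribute
        nEv <- min(2L, nrow(events))
        hazardCoefs <- c(
            setNames(c(1.0, 0.7)[seq_len(nEv)], events$label[seq_len(nEv)]),
            if ("MemB" %in% immune$cellType) c(MemB = -0.5),
            c(age = 0.02, size = 0.15, nodes = 0.15))
    }
    cfg <- list(nSamples = as.integer(nSamples), nGenes = as.integer(nGenes),
                events = events, immune = immune,
                baselineHazard = baselineHazard, hazardCoefs = hazardCoefs,
                censoringRate = censoringRate, horizon = horizon,
                noiseSd = noiseSd, immuneScale = immuneScale,
                eventCorrelation = eventCorrelation, seed = as.integer(seed))
    class(cfg) <- "SimulationConfig"
    validateSimulationConfig(cfg)
    cfg
}

#' @rdname simulationConfig
#' @param config a \code{SimulationConfig}.
#' @export
validateSimulationConfig <- function(config) {
    with(config, {
        stopIfNot(nSamples >= 20L, "nSamples must be >= 20")
        stopIfNot(all(events$fraction > 0 & events$fraction < 1),
                  "carrier fractions must lie in (0, 1)")
        stopIfNot(all(events$setSize <= nGenes),
                  "signature gene-set sizes must not exceed nGenes")
        stopIfNot(!anyDuplicated(events$label), "duplicate event labels")
        stopIfNot(all(round(events$fraction * nSamples) >= 2),
                  "infeasible config: a carrier fraction yields < 2 carriers")
        stopIfNot(all(immune$meanFraction > 0 & immune$meanFraction < 1),
                  "immune mean fractions must lie in (0, 1)")
        stopIfNot(sum(immune$meanFraction) < 1,
                  "immune mean fractions must sum to < 1")
        stopIfNot(censoringRate > 0 & censoringRate < 1,
                  "censoringRate must lie in (0, 1)")
    })
    invisible(config)
}

# Disjoint gene index blocks: immune marker sets first, then one signature
# block per event (cycled if the universe is exhausted), remainder background.
.assignGeneSets <- function(config) {
    nGenes <- config$nGenes
    genes <- sprintf("G%04d", seq_len(nGenes))
    cursor <- 1L
    take <- function(k) {
        stopIfNot(cursor + k - 1L <= nGenes,
                  "gene universe too small for the configured gene sets")
        idx <- seq.int(cursor, cursor + k - 1L)
        cursor <<- cursor + k
        idx
    }
    markerIdx <- lapply(config$immune$markerSize, take)
    names(markerIdx) <- config$immune$cellType
    sigIdx <- lapply(config$events$setSize, take)
    names(sigIdx) <- config$events$label
    list(genes = genes, markers = markerIdx, signatures = sigIdx)
}

#' Simulate immune reference profiles and per-sample fractions
#'
#' Each of the configured cell types gets a disjoint planted marker gene set
#' expressed high in that type only (log2 scale). Per-sample fractions of the
#' six cell types (plus an implicit tumor compartment) are drawn from a
#' Dirichlet distribution with means proportional to the configured mean
#' fractions, so the immune fractions of a sample always sum to < 1.
#'
#' @param config a \code{SimulationConfig}.
#' @param markerHigh log2 expression of a marker in its own cell type.
#' @param markerLow log2 expression elsewhere.
#' @return list with \code{reference} (cell types x genes matrix),
#'   \code{fractions} (samples x cell types), and \code{markers} (named list
#'   of marker gene vectors).
#' @export
simulateReferenceProfiles <- function(config, markerHigh = 6, markerLow = 0.5) {
    sets <- .assignGeneSets(config)
    cellTypes <- config$immune$cellType
    stopIfNot(length(cellTypes) >= 2L, "need at least two immune cell types")
    nGenes <- config$nGenes
    ref <- matrix(markerLow, nrow = length(cellTypes), ncol = nGenes,
                  dimnames = list(cellTypes, sets$genes))
    for (ct in cellTypes)
        ref[ct, sets$markers[[ct]]] <- markerHigh

    set.seed(subSeed(config$seed, "immune"))
    # Dirichlet via normalized gammas; concentration 50 keeps fractions
    # realistically dispersed around their means.
    alpha <- c(config$immune$meanFraction,
               1 - sum(config$immune$meanFraction)) * 50
    n <- config$nSamples
    g <- matrix(rgamma(n * length(alpha), shape = rep(alpha, each = n)),
                nrow = n)
    frac <- g / rowSums(g)
    fractions <- frac[, seq_along(cellTypes), drop = FALSE]
    dimnames(fractions) <- list(sprintf("S%04d", seq_len(n)), cellTypes)
    list(reference = ref, fractions = fractions,
         markers = lapply(sets$markers, function(i) sets$genes[i]))
}

#' Simulate a cohort with planted ground truth
#'
#' Expression is baseline + sum of event effects in carriers + immune
#' admixture + Gaussian noise, all on the log2 scale:
#' \deqn{Y_{is} = \mu_i + \sum_j \delta_{ij} X_{js} +
#'       \phi \sum_c f_{cs}\,ref_{ic} + \epsilon_{is}}
#' with \eqn{\delta} nonzero only on each event's planted gene set (half the
#' set shifted up, half down). Survival times are exponential with hazard
#' \eqn{h_0 \exp(\mathrm{risk})} and independent uniform censoring.
#'
#' @param config a \code{SimulationConfig}.
#' @return A \linkS4class{ProgCohort} whose \code{\link{groundTruth}} lists
#'   carriers, signature gene sets with effect directions, immune fractions,
#'   markers and the true per-sample linear risk.
#' @export
simulateCohort <- function(config) {
    validateSimulationConfig(config)
    n <- config$nSamples
    nGenes <- config$nGenes
    sets <- .assignGeneSets(config)
    genes <- sets$genes
    samples <- sprintf("S%04d", seq_len(n))
    events <- config$events

    # --- event carriers (exact carrier counts for sharp recurrence tests)
    set.seed(subSeed(config$seed, "events"))
    X <- matrix(0L, nrow = n, ncol = nrow(events),
                dimnames = list(samples, events$label))
    prevCarriers <- NULL
    for (j in seq_len(nrow(events))) {
        k <- as.integer(round(events$fraction[j] * n))
        if (config$eventCorrelation > 0 && !is.null(prevCarriers)) {
            nShared <- min(length(prevCarriers),
                           as.integer(round(config$eventCorrelation * k)))
            shared <- sample(prevCarriers, nShared)
            rest <- sample(setdiff(seq_len(n), shared), k - nShared)
            carriers <- c(shared, rest)
        } else {
            carriers <- sample.int(n, k)
        }
        X[carriers, j] <- 1L
        prevCarriers <- carriers
    }

    # --- signature gene sets with signed effects
    delta <- matrix(0, nrow = nGenes, ncol = nrow(events),
                    dimnames = list(genes, events$label))
    directions <- list()
    for (j in seq_len(nrow(events))) {
        idx <- sets$signatures[[events$label[j]]]
        nUp <- ceiling(length(idx) / 2)
        dir <- rep(c(1, -1), c(nUp, length(idx) - nUp))
        delta[idx, j] <- dir * events$effect[j]
        directions[[events$label[j]]] <-
            setNames(dir, genes[idx])
    }

    # --- immune admixture
    profiles <- simulateReferenceProfiles(config)
    admix <- config$immuneScale *
        t(profiles$reference) %*% t(profiles$fractions)  # genes x samples

    # --- expression
    set.seed(subSeed(config$seed, "expression"))
    mu <- rnorm(nGenes, mean = 7, sd = 1.5)
    noise <- matrix(rnorm(nGenes * n, sd = config$noiseSd), nrow = nGenes)
    expr <- mu + delta %*% t(X) + admix + noise
    dimnames(expr) <- list(genes, samples)

    # --- clinical covariates
    set.seed(subSeed(config$seed, "clinical"))
    clinical <- data.frame(
        age = rnorm(n, 60, 10),
        stage = sample(1:4, n, replace = TRUE,
                       prob = c(0.35, 0.40, 0.18, 0.07)),
        grade = sample(1:3, n, replace = TRUE, prob = c(0.25, 0.45, 0.30)),
        size = rlnorm(n, meanlog = 0.8, sdlog = 0.5),
        nodes = rpois(n, 1.2),
        row.names = samples)

    # --- survival
    risk <- rep(0, n)
    hc <- config$hazardCoefs
    for (nm in names(hc)) {
        if (nm %in% colnames(X)) {
            risk <- risk + hc[[nm]] * X[, nm]
        } else if (nm %in% colnames(profiles$fractions)) {
            risk <- risk + hc[[nm]] * profiles$fractions[, nm] / 0.1
        } else if (nm %in% colnames(clinical)) {
            v <- clinical[[nm]]
            risk <- risk + hc[[nm]] * (v - mean(v))
        } else {
            stop("hazard coefficient refers to unknown feature: ", nm)
        }
    }
    set.seed(subSeed(config$seed, "survival"))
    eventTime <- rexp(n, rate = config$baselineHazard * exp(risk))
    set.seed(subSeed(config$seed, "censoring"))
    censTime <- runif(n, 0, config$horizon / config$censoringRate)
    time <- pmin(eventTime, censTime)
    status <- as.integer(eventTime <= censTime)
    survTab <- data.frame(time = time, event = status, row.names = samples)

    truth <- list(
        config = config,
        carriers = lapply(colnames(X), function(l)
            samples[X[, l] == 1L]),
        signatureGenes = lapply(sets$signatures, function(i) genes[i]),
        directions = directions,
        immuneFractions = profiles$fractions,
        immuneMarkers = profiles$markers,
        reference = profiles$reference,
        linearRisk = setNames(risk, samples))
    names(truth$carriers) <- colnames(X)

    ProgCohort(exprs = expr, clinical = clinical, survival = survTab,
               aberrations = X, truth = truth)
}
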