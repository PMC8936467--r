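test_that("Cox fits recover null and planted coefficients", {
    set.seed(61)
    score <- rnorm(1000)
    null <- simSurv(1000, 0, score, seed = 62)
    m0 <- coxFit(data.frame(score = score), null$time, null$event)
    expect_lt(abs(m0$coef["score", "coef"]), 3 * m0$coef["score", "se"])

    planted <- simSurv(1000, 1.0, score, seed = 63)
    m1 <- coxFit(data.frame(score = score), planted$time, planted$event)
    expect_lt(abs(m1$coef["score", "coef"] - 1.0), 3 * m1$coef["score", "se"])

    # per-unit convention: doubling the covariate halves the coefficient
    m2 <- coxFit(data.frame(score = 2 * score), planted$time, planted$event)
    expect_equal(m2$coef["score", "coef"], m1$coef["score", "coef"] / 2,
                 tolerance = 1e-6)
    expect_equal(m1$coef["score", "hr"], exp(m1$coef["score", "coef"]))
    expect_error(coxFit(data.frame(score = score), planted$time,
                        rep(0, 1000)), "no events")
})

test_that("Cox estimation is consistent with correct Wald coverage", {
    hits <- 0; cover <- 0; total <- 0; est <- c()
    truths <- rep(c(0, 0.5, 1.0), length.out = 50)
    for (i in seq_along(truths)) {
        set.seed(700 + i)
        sc <- rnorm(500)
        d <- simSurv(500, truths[i], sc, seed = 800 + i)
        m <- coxFit(data.frame(score = sc), d$time, d$event)
        b <- m$coef["score", "coef"]; se <- m$coef["score", "se"]
        est <- c(est, b - truths[i])
        cover <- cover + (truths[i] >= b - 1.96 * se &
                          truths[i] <= b + 1.96 * se)
        total <- total + 1
    }
    expect_lt(abs(mean(est)), 0.05)
    expect_gte(cover / total, 0.90)
    expect_lte(cover / total, 0.99)
})

test_that("log-rank test is calibrated and powered", {
    # identical survival in both groups -> statistic 0, p = 1
    time <- c(1, 2, 3, 4, 5, 1, 2, 3, 4, 5)
    ev <- rep(1, 10)
    grp <- rep(c("a", "b"), each = 5)
    res <- kmLogrank(grp, time, ev)
    expect_equal(res$chisq, 0, tolerance = 1e-12)
    expect_equal(res$p, 1, tolerance = 1e-12)
    expect_error(kmLogrank(rep("a", 10), time, ev), "two non-empty")

    # planted hazard ratio 3 at n = 400
    set.seed(67)
    grp2 <- rep(c(0, 1), each = 200)
    d <- simSurv(400, log(3), grp2, seed = 68)
    res2 <- kmLogrank(factor(grp2), d$time, d$event)
    expect_lt(res2$p, 1e-4)

    # agreement with the Cox score test on a 2-group comparison
    m <- coxFit(data.frame(g = grp2), d$time, d$event)
    scoreP <- unname(summary(m$fit)$sctest["pvalue"])
    expect_equal(signif(res2$p, 2), signif(scoreP, 2), tolerance = 0.1)
})

test_that("log-rank null p-values are approximately uniform", {
    ps <- vapply(1:400, function(i) {
        set.seed(900 + i)
        n <- 60
        t <- rexp(n, 0.1); e <- rbinom(n, 1, 0.8)
        g <- rep(c("a", "b"), each = n / 2)  # labels independent of survival
        kmLogrank(g, t, e)$p
    }, numeric(1))
    expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("median dichotomization is rank-based with ties to low", {
    g <- dichotomizeMedian(1:10)
    expect_equal(as.vector(table(g)), c(5L, 5L))
    s <- c(1, 2, 3, 3, 9)           # odd n, ties at the median
    g2 <- dichotomizeMedian(s)
    expect_equal(as.character(g2), c("low", "low", "low", "low", "high"))
    g3 <- dichotomizeMedian(exp(s)) # monotone transform, same grouping
    expect_identical(g2, g3)
    expect_error(dichotomizeMedian(rep(2, 5)), "constant")
})

test_that("concordance matches the brute-force pair oracle", {
    bruteCI <- function(risk, time, event) {
        conc <- ties <- comp <- 0
        n <- length(risk)
        for (i in 1:n) for (j in 1:n) {
            if (i == j) next
            if (event[i] == 1 && time[i] < time[j]) {
                comp <- comp + 1
                if (risk[i] > risk[j]) conc <- conc + 1
                else if (risk[i] == risk[j]) ties <- ties + 1
            }
        }
        (conc + 0.5 * ties) / comp
    }
    set.seed(71)
    for (i in 1:5) {
        n <- 60
        risk <- sample(1:10, n, replace = TRUE)
        time <- rexp(n); ev <- rbinom(n, 1, 0.7)
        expect_equal(concordanceIndex(risk, time, ev),
                     bruteCI(risk, time, ev), tolerance = 1e-12)
    }
    # perfect concordance and the random-risk null
    t0 <- sort(rexp(100))
    expect_equal(concordanceIndex(-t0, t0, rep(1, 100)), 1.0)
    set.seed(72)
    ci <- concordanceIndex(rnorm(1000), rexp(1000), rep(1, 1000))
    expect_gt(ci, 0.47); expect_lt(ci, 0.53)
    expect_error(concordanceIndex(1, 5, 0), "no comparable")
})

test_that("concordance agrees with the survival package on tie-free data", {
    set.seed(73)
    n <- 150
    risk <- rnorm(n); time <- rexp(n); ev <- rbinom(n, 1, 0.6)
    ours <- concordanceIndex(risk, time, ev)
    ref <- survival::concordance(survival::Surv(time, ev) ~ risk,
                                 reverse = TRUE)$concordance
    expect_equal(ours, unname(ref), tolerance = 1e-10)
})

test_that("stepwise Cox selects planted features and respects forcing", {
    set.seed(79)
    n <- 600
    feats <- data.frame(matrix(rnorm(n * 20), nrow = n))
    colnames(feats) <- sprintf("noise%02d", 1:20)
    feats$sigA <- rnorm(n); feats$sigB <- rnorm(n)
    lp <- 1.2 * feats$sigA + 1.0 * feats$sigB
    t <- rexp(n, 0.1 * exp(lp)); cens <- runif(n, 0, 25)
    time <- pmin(t, cens); ev <- as.integer(t <= cens)
    sel <- stepwiseCox(feats, time, ev)
    expect_true(all(c("sigA", "sigB") %in% sel$selected))
    sel2 <- stepwiseCox(feats, time, ev)
    expect_identical(sel$selected, sel2$selected)

    clin <- data.frame(age = rnorm(n, 60, 10))
    self <- stepwiseCox(feats[, 1:5], time, ev, forced = clin)
    expect_true("age" %in% rownames(self$coef))
})

test_that("stepwise entry rate on pure noise is near the threshold", {
    picks <- 0; cands <- 0
    for (i in 1:15) {
        set.seed(1000 + i)
        n <- 150
        feats <- data.frame(matrix(rnorm(n * 6), nrow = n))
        t <- rexp(n, 0.1); cens <- runif(n, 0, 25)
        time <- pmin(t, cens); ev <- as.integer(t <= cens)
        sel <- tryCatch(stepwiseCox(feats, time, ev),
                        error = function(e) list(selected = character()))
        picks <- picks + length(sel$selected)
        cands <- cands + ncol(feats)
    }
    # with enter_p = stay_p = 0.15, false selections stay a modest fraction
    expect_lt(picks / cands, 0.35)
})

test_that("risk groups are tertiles with remainder to the lowest group", {
    set.seed(83)
    n <- 9
    covs <- data.frame(score = rnorm(n))
    d <- simSurv(n, 1, covs$score, seed = 84)
    m <- coxFit(covs, d$time, d$event)
    rg <- predictRiskGroups(m, covs)
    expect_equal(as.vector(table(rg$group)), c(3L, 3L, 3L))

    covs10 <- data.frame(score = rnorm(10))
    rg10 <- predictRiskGroups(m, covs10)
    expect_equal(as.vector(table(rg10$group)), c(4L, 3L, 3L))
    # group order tracks risk
    expect_true(max(rg10$risk[rg10$group == "low"]) <=
                min(rg10$risk[rg10$group == "high"]))
    expect_error(predictRiskGroups(m, data.frame(other = 1:5)),
                 "missing in new data")
})

test_that("risk groups from a planted model separate survival", {
    set.seed(87)
    n <- 600
    covs <- data.frame(score = rnorm(n))
    d <- simSurv(n, 1.2, covs$score, h0 = 0.05, seed = 88)
    half <- seq_len(n / 2)
    m <- coxFit(covs[half, , drop = FALSE], d$time[half], d$event[half])
    rg <- predictRiskGroups(m, covs[-half, , drop = FALSE])
    km <- kmLogrank(rg$group, d$time[-half], d$event[-half])
    expect_lt(km$p, 1e-3)
    hl <- rg$group %in% c("low", "high")
    mHL <- coxFit(data.frame(high = as.integer(rg$group[hl] == "high")),
                  d$time[-half][hl], d$event[-half][hl])
    expect_gt(mHL$coef["high", "hr"], 1)

    # zeroing a covariate block removes its contribution
    covs2 <- data.frame(score = covs$score[-half], age = rnorm(n / 2))
    m2 <- coxFit(data.frame(score = covs$score[half],
                            age = rnorm(length(half))),
                 d$time[half], d$event[half])
    lpFull <- riskLinearPredictor(m2, covs2)
    lpNoAge <- riskLinearPredictor(m2, covs2, exclude = "age")
    expect_equal(lpNoAge, covs2$score * m2$coef["score", "coef"])
    expect_false(isTRUE(all.equal(lpFull, lpNoAge)))
})

test_that("cross-validated concordance is honest and deterministic", {
    set.seed(89)
    n <- 300
    feats <- data.frame(score = rnorm(n), junk = rnorm(n))
    d <- simSurv(n, 1.0, feats$score, h0 = 0.05, seed = 90)
    cv <- crossValidatedConcordance(feats, d$time, d$event, k = 5, seed = 7)
    resub <- coxFit(feats, d$time, d$event)$concordance
    expect_gt(cv$ci, 0.5)
    expect_lte(cv$ci, resub + 0.02)
    cv2 <- crossValidatedConcordance(feats, d$time, d$event, k = 5, seed = 7)
    expect_identical(cv$ci, cv2$ci)

    noise <- data.frame(a = rnorm(n), b = rnorm(n))
    cvN <- crossValidatedConcordance(noise, d$time, d$event, k = 5, seed = 7)
    expect_gt(cvN$ci, 0.44); expect_lt(cvN$ci, 0.56)
})
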