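# A hand-made cohort with one group whose tertile labels we supply directly,
# so the low/high contrast is fully controlled.
makeLfcFixture <- function(values, nLow, nHigh) {
    cohort <- tinyCohort(values)
    ids <- colnames(values)
    tert <- factor(c(rep("low", nLow), rep("high", nHigh)),
                   levels = c("low", "mid", "high"))
    names(tert) <- ids
    list(cohort = cohort, tert = tert)
}

test_that("lfc is high-minus-low and degenerate genes behave as promised", {
    v <- rbind(flat = rep(2, 8),                       # identical tertiles
               sep = c(rep(1, 4), rep(3, 4)),          # constant within each
               noisy = c(1, 2, 1, 2, 3, 4, 3, 4))
    colnames(v) <- paste0("s", 1:8)
    fx <- makeLfcFixture(v, 4, 4)
    de <- differentialLfc(fx$cohort, fx$tert, "A")
    expect_equal(de$lfc[de$gene == "flat"], 0)
    expect_equal(de$p_lfc[de$gene == "flat"], 1)
    expect_equal(de$lfc[de$gene == "sep"], 2)
    # zero residual variance but finite p thanks to the variance prior
    expect_true(is.finite(de$p_lfc[de$gene == "sep"]))
    expect_lt(de$p_lfc[de$gene == "sep"], 0.05)
})

test_that("with prior df 0 the moderated t reduces to the plain pooled t", {
    set.seed(21)
    v <- matrix(rnorm(50 * 12, 5), 50, 12,
                dimnames = list(sprintf("g%02d", 1:50), paste0("s", 1:12)))
    fx <- makeLfcFixture(v, 6, 6)
    de <- differentialLfc(fx$cohort, fx$tert, "A", priorDf = 0)
    for (i in c(1, 17, 50)) {
        tt <- t.test(v[i, 7:12], v[i, 1:6], var.equal = TRUE)
        expect_equal(de$t_mod[i], unname(tt$statistic), tolerance = 1e-8)
        expect_equal(de$p_lfc[i], tt$p.value, tolerance = 1e-8)
    }
})

test_that("the moderated t agrees with the limma empirical-Bayes fit", {
    skip_if_not_installed("limma")
    set.seed(22)
    v <- matrix(rnorm(200 * 16, 6, sqrt(rchisq(200, 4) / 4)), 200, 16,
                dimnames = list(sprintf("g%03d", 1:200), paste0("s", 1:16)))
    fx <- makeLfcFixture(v, 8, 8)
    de <- differentialLfc(fx$cohort, fx$tert, "A")
    design <- cbind(low = rep(c(1, 0), each = 8),
                    high = rep(c(0, 1), each = 8))
    fit <- limma::eBayes(limma::contrasts.fit(
        limma::lmFit(v, design),
        contrasts = c(-1, 1)))
    expect_equal(de$lfc, unname(fit$coefficients[, 1]), tolerance = 1e-10)
    expect_equal(de$t_mod, unname(fit$t[, 1]), tolerance = 1e-6)
    expect_equal(de$p_lfc, unname(fit$p.value[, 1]), tolerance = 1e-6)
})

test_that("spearmanAssoc recovers exact and hand-computed correlations", {
    score <- setNames(c(3, 1, 2, 5, 4), paste0("s", 1:5))
    v <- rbind(up = score,                 # equal to the score
               down = 10 - score,          # strictly decreasing in score
               hand = c(3, 1, 2, 5, 4) * 0 + 1:5)  # ranks 1..5 vs 3,1,2,5,4
    colnames(v) <- names(score)
    cohort <- tinyCohort(v)
    res <- spearmanAssoc(cohort, score, "A")
    expect_equal(res$rho[res$gene == "up"], 1)
    expect_equal(res$rho[res$gene == "down"], -1)
    expect_equal(res$rho[res$gene == "hand"], 0.6)  # rank covariance by hand
})

test_that("spearmanAssoc equals Pearson on ranks and flags constant genes", {
    set.seed(23)
    v <- matrix(runif(20 * 30), 20, 30,
                dimnames = list(sprintf("g%02d", 1:20), paste0("s", 1:30)))
    v["g05", ] <- 3  # constant
    score <- setNames(runif(30), colnames(v))
    cohort <- tinyCohort(v)
    res <- spearmanAssoc(cohort, score, "A")
    for (i in c(1, 9, 20)) {
        oracle <- cor.test(rank(v[i, ]), rank(score))  # Pearson on ranks
        expect_equal(res$rho[i], unname(oracle$estimate), tolerance = 1e-10)
        expect_equal(res$p_sc[i], oracle$p.value, tolerance = 1e-8)
    }
    expect_true(res$flagged[res$gene == "g05"])
    expect_equal(res$rho[res$gene == "g05"], 0)
    expect_equal(res$p_sc[res$gene == "g05"], 1)
})

test_that("percentile ranks follow the closed formula with orientation", {
    pr <- percentileRanks(c(a = -2, b = -1, c = 0, d = 3))
    expect_equal(unname(pr[c("a", "b", "c", "d")]), c(100, 75, 50, 25))
    stat <- setNames(rnorm(10), letters[1:10])
    pr10 <- percentileRanks(stat)
    expect_equal(unname(pr10[which.min(stat)]), 100)
    expect_equal(unname(pr10[which.max(stat)]), 10)
})

test_that("percentile ranks are a bijection and idempotent on ordering", {
    set.seed(24)
    stat <- setNames(rnorm(57), sprintf("g%02d", 1:57))
    pr <- percentileRanks(stat)
    expect_setequal(pr, 100 * (1:57) / 57)
    # ranking the ranks (higher pr = top) reproduces the same pr
    pr2 <- percentileRanks(pr, moreNegativeIsTop = FALSE)
    expect_equal(pr2, pr)
})

test_that("flagged genes and q tie-breaks order deterministically", {
    stat <- c(a = 0, b = 0, c = -1, d = 2)
    q <- c(a = 0.5, b = 0.1, c = 0.9, d = 0.2)
    pr <- percentileRanks(stat, q = q)
    expect_gt(pr[["b"]], pr[["a"]])  # tie at 0 broken by smaller q
    prf <- percentileRanks(stat, q = q, flagged = c(FALSE, FALSE, TRUE,
                                                    FALSE))
    expect_equal(unname(prf[["c"]]), 25)  # flagged forced to the bottom
})

test_that("top-percentile set has floor(f * G) genes", {
    prBig <- percentileRanks(setNames(seq_len(20501) * -1,
                                      sprintf("g%05d", 1:20501)))
    expect_length(topPercentileSet(prBig), 205)
    pr100 <- percentileRanks(setNames(-(1:100), sprintf("g%03d", 1:100)))
    expect_identical(topPercentileSet(pr100), "g100")  # most negative
    pr250 <- percentileRanks(setNames(-(1:250), sprintf("g%03d", 1:250)))
    expect_length(topPercentileSet(pr250), 2)
    expect_error(topPercentileSet(pr100, analysisParams(topFraction = 1e-3)),
                 class = "invalidValueError")
})

test_that("a planted -1 shift is recovered by the lfc estimate", {
    set.seed(25)
    G <- 2000
    v <- matrix(rnorm(G * 60, 5, 0.5), G, 60,
                dimnames = list(sprintf("g%04d", 1:G), paste0("s", 1:60)))
    shifted <- 1:100
    v[shifted, 31:60] <- v[shifted, 31:60] - 1  # lower in the high block
    fx <- makeLfcFixture(v, 30, 30)
    de <- differentialLfc(fx$cohort, fx$tert, "A")
    expect_lt(abs(mean(de$lfc[shifted]) - (-1)), 0.1)
})

test_that("planted culprits reach the top percentile ranks in affected groups", {
    sim <- generatePanTumor(generatorConfig(nGroups = 4, samplesPerGroup = 60,
        nGenes = 500, nCulprits = 20, culpritGroups = 1:4, seed = 31))
    rt <- rankGenes(sim$cohort, sim$signature,
                    analysisParams(universeSize = 500))
    culprits <- names(plantedRoles(sim$truth))[
        plantedRoles(sim$truth) == "culprit"]
    sub <- rt[rt$gene %in% culprits, ]
    expect_gt(median(sub$pr_lfc), 95)
    expect_gt(median(sub$pr_sc), 95)
})
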