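# Cohort with one group whose four samples are all labeled low-tertile, so
# binarization is exercised directly.
allLowFixture <- function(values) {
    cohort <- tinyCohort(values)
    tert <- factor(rep("low", ncol(values)), levels = c("low", "mid",
                                                        "high"))
    names(tert) <- colnames(values)
    list(cohort = cohort, tert = tert)
}

test_that("binarization thresholds strictly above the within-group mean", {
    v <- rbind(const = c(2, 2, 2, 2),
               pair = c(1, 3, 1, 3),
               skew = c(1, 2, 3, 6))
    colnames(v) <- paste0("s", 1:4)
    fx <- allLowFixture(v)
    bin <- binarizeWithinGroup(fx$cohort, fx$tert)
    b <- binaryValues(bin)
    expect_equal(unname(b["const", ]), c(0, 0, 0, 0))  # nothing above mean
    expect_equal(unname(b["pair", ]), c(0, 1, 0, 1))
    expect_equal(unname(b["skew", ]), c(0, 0, 0, 1))   # mean 3, only 6 above
})

test_that("binarization is invariant to per-group affine rescaling", {
    set.seed(61)
    v <- matrix(runif(5 * 12, 1, 9), 5, 12,
                dimnames = list(paste0("g", 1:5), paste0("s", 1:12)))
    grp <- rep(c("A", "B"), each = 6)
    tert <- setNames(factor(rep("low", 12), levels = c("low", "mid",
                                                       "high")),
                     colnames(v))
    c1 <- ExpressionCohort(v, grp)
    v2 <- v
    v2[, 1:6] <- v[, 1:6] * 3 + 1       # affine, positive scale, per group
    v2[, 7:12] <- v[, 7:12] * 0.5 + 2
    c2 <- ExpressionCohort(v2, grp)
    expect_identical(binaryValues(binarizeWithinGroup(c1, tert)),
                     binaryValues(binarizeWithinGroup(c2, tert)))
})

test_that("binarization means are taken per group before concatenation", {
    v <- rbind(g1 = c(1, 2, 11, 12))
    colnames(v) <- paste0("s", 1:4)
    tert <- setNames(factor(rep("low", 4), levels = c("low", "mid",
                                                      "high")),
                     colnames(v))
    cohort <- ExpressionCohort(v, rep(c("A", "B"), each = 2))
    b <- binaryValues(binarizeWithinGroup(cohort, tert))
    # each group centered on its own mean: (1,2 | 11,12) -> (0,1 | 0,1)
    expect_equal(unname(b["g1", ]), c(0, 1, 0, 1))
    v2 <- rbind(g1 = c(1, 2, 3, 4))
    colnames(v2) <- paste0("s", 1:4)
    expect_error(binarizeWithinGroup(
        ExpressionCohort(v2, c("A", "A", "B", "B")),
        setNames(factor(c("low", "low", "low", "mid"),
                        levels = c("low", "mid", "high")),
                 paste0("s", 1:4))),
        class = "smallContextError")
})

# Wrap an explicit 0/1 pattern as a BinaryMatrix.
mkBinary <- function(m, group = rep("A", ncol(m))) {
    methods::new("BinaryMatrix", values = m, group = factor(group))
}

test_that("pairwise Fisher log2 ORs hit the worked values", {
    m <- rbind(gi = c(rep(1L, 10), rep(0L, 10)),
               gj = c(rep(0L, 10), rep(1L, 10)))
    colnames(m) <- paste0("s", 1:20)
    res <- pairwiseFisher(mkBinary(m))
    # perfect exclusion: Haldane OR = 0.25/110.25, p by enumeration
    expect_equal(log2OddsRatios(res)["gi", "gj"], log2(0.25 / 110.25),
                 tolerance = 1e-9)
    expect_equal(pValues(res)["gi", "gj"], fisherEnumP(0, 10, 10, 0),
                 tolerance = 1e-10)
    expect_equal(pValues(res)["gi", "gj"], 1.082508e-05, tolerance = 1e-4)

    mCo <- rbind(gi = m["gi", ], gj = m["gi", ])  # perfect co-occurrence
    resCo <- pairwiseFisher(mkBinary(mCo))
    expect_equal(log2OddsRatios(resCo)["gi", "gj"], log2(110.25 / 0.25),
                 tolerance = 1e-9)
    expect_equal(pValues(resCo)["gi", "gj"], pValues(res)["gi", "gj"],
                 tolerance = 1e-12)  # symmetry of the enumeration

    mInd <- rbind(gi = rep(c(1L, 0L), each = 10),
                  gj = rep(c(1L, 0L), 10))        # [[5,5],[5,5]]
    resInd <- pairwiseFisher(mkBinary(mInd))
    expect_equal(log2OddsRatios(resInd)["gi", "gj"], 0)
})

test_that("Fisher p equals hypergeometric enumeration on random tables", {
    set.seed(62)
    for (i in 1:25) {
        n <- sample(8:24, 1)
        x <- matrix(rbinom(2 * n, 1, runif(1, 0.2, 0.8)), 2, n,
                    dimnames = list(c("gi", "gj"), paste0("s", 1:n)))
        rs <- rowSums(x)
        if (any(rs == 0 | rs == n)) next  # degenerate margins excluded
        res <- pairwiseFisher(mkBinary(x))
        a <- sum(x[1, ] == 1 & x[2, ] == 1)
        b <- sum(x[1, ] == 1 & x[2, ] == 0)
        c2 <- sum(x[1, ] == 0 & x[2, ] == 1)
        d <- n - a - b - c2
        expect_equal(pValues(res)["gi", "gj"], fisherEnumP(a, b, c2, d),
                     tolerance = 1e-10)
    }
})

test_that("mutex matrices are symmetric, permute and sign-flip correctly", {
    set.seed(63)
    m <- matrix(rbinom(4 * 30, 1, 0.5), 4, 30,
                dimnames = list(paste0("g", 1:4), paste0("s", 1:30)))
    res <- pairwiseFisher(mkBinary(m))
    expect_identical(log2OddsRatios(res), t(log2OddsRatios(res)))
    expect_identical(qValues(res), t(qValues(res)))

    perm <- c(3, 1, 4, 2)
    resPerm <- pairwiseFisher(mkBinary(m[perm, ]))
    expect_equal(log2OddsRatios(resPerm),
                 log2OddsRatios(res)[perm, perm], tolerance = 1e-12)

    mFlip <- m; mFlip["g2", ] <- 1L - m["g2", ]
    resFlip <- pairwiseFisher(mkBinary(mFlip))
    keep <- setdiff(rownames(m), "g2")
    expect_equal(log2OddsRatios(resFlip)["g2", keep],
                 -log2OddsRatios(res)["g2", keep], tolerance = 1e-9)
})

test_that("degenerate genes are flagged and excluded from q computation", {
    m <- rbind(g1 = rep(1L, 12), g2 = rbinom(12, 1, 0.5),
               g3 = c(rep(0L, 6), rep(1L, 6)))
    colnames(m) <- paste0("s", 1:12)
    expect_warning(res <- pairwiseFisher(mkBinary(m)), "degenerate")
    expect_true(is.na(pValues(res)["g1", "g2"]))
    expect_true(is.na(qValues(res)["g1", "g3"]))
    expect_false(is.na(qValues(res)["g2", "g3"]))
})

test_that("threshold selection returns genes of passing pairs only", {
    set.seed(64)
    m <- matrix(rbinom(3 * 20, 1, 0.5), 3, 20,
                dimnames = list(paste0("g", 1:3), paste0("s", 1:20)))
    res <- pairwiseFisher(mkBinary(m))
    expect_identical(thresholdMutexGenes(res, orCutoff = -50,
                                         qCutoff = 1e-300),
                     character(0))
    # force exactly one passing pair via a custom result object
    lor <- matrix(c(NA, -2, 0, -2, NA, 0, 0, 0, NA), 3, 3,
                  dimnames = list(paste0("g", 1:3), paste0("g", 1:3)))
    q <- matrix(c(NA, 1e-40, 1, 1e-40, NA, 1, 1, 1, NA), 3, 3,
                dimnames = dimnames(lor))
    one <- methods::new("MutexResult", log2or = lor, p = q, q = q)
    expect_setequal(thresholdMutexGenes(one, orCutoff = -1,
                                        qCutoff = 1e-30),
                    c("g1", "g2"))
})

test_that("complete-linkage Spearman clustering separates planted blocks", {
    set.seed(65)
    base <- rnorm(40)
    feats <- rbind(
        t(replicate(5, base + rnorm(40, sd = 0.3))),       # block 1
        t(replicate(5, -base + rnorm(40, sd = 0.3))))      # anti-block
    rownames(feats) <- paste0("g", 1:10)
    cl <- clusterGenes(feats)
    lab <- clusterLabels(cl)
    expect_length(unique(lab[1:5]), 1)
    expect_length(unique(lab[6:10]), 1)
    expect_false(lab[1] == lab[6])
    # identical vectors merge at height 0
    two <- rbind(a = base, b = base, c = -base)
    cl2 <- clusterGenes(two)
    expect_equal(min(clusterTree(cl2)$height), 0, tolerance = 1e-12)
    # constant vectors are excluded with a warning
    expect_warning(clusterGenes(rbind(feats, flat = rep(1, 40))),
                   "constant")
})

test_that("cluster labels C1/C2 are ordered by descending size", {
    set.seed(66)
    base <- rnorm(30)
    feats <- rbind(t(replicate(7, base + rnorm(30, sd = 0.2))),
                   t(replicate(3, -base + rnorm(30, sd = 0.2))))
    rownames(feats) <- paste0("g", 1:10)
    lab <- clusterLabels(clusterGenes(feats))
    expect_equal(sum(lab == "C1"), 7)
    expect_equal(sum(lab == "C2"), 3)
})

test_that("synexpression groups are maximal correlated subtrees", {
    set.seed(67)
    # three planted blocks, within-rho ~0.35, between ~0; the threshold sits
    # between the within-block mean and the diluted two-block mean, so the
    # root-to-leaf scan must descend exactly to the single blocks
    nPer <- 5; len <- 300
    mk <- function() {
        shared <- rnorm(len)
        t(replicate(nPer, 0.733 * shared + rnorm(len, sd = 1)))
    }
    feats <- rbind(mk(), mk(), mk())
    rownames(feats) <- sprintf("g%02d", 1:15)
    rho <- cor(t(feats), method = "spearman")
    tree <- clusterTree(clusterGenes(feats))
    groups <- synexpressionGroups(rho, tree, minAvgCorr = 0.2)
    expect_length(groups, 3)
    truth <- rep(1:3, each = nPer)
    for (g in groups)
        expect_length(unique(truth[match(g, rownames(feats))]), 1)

    # fully correlated genes: one cluster containing everything
    allCor <- matrix(0.9, 6, 6,
                     dimnames = list(paste0("g", 1:6), paste0("g", 1:6)))
    diag(allCor) <- 1
    feats2 <- t(replicate(6, rnorm(20))) * 0 +
        matrix(rep(rnorm(20), each = 6), 6) +
        matrix(rnorm(120, sd = 0.1), 6)
    rownames(feats2) <- paste0("g", 1:6)
    tree2 <- clusterTree(clusterGenes(feats2))
    g2 <- synexpressionGroups(allCor, tree2, minAvgCorr = 0.15)
    expect_length(g2, 1)
    expect_setequal(g2[[1]], paste0("g", 1:6))

    # fully uncorrelated: nothing qualifies
    noCor <- diag(6); dimnames(noCor) <- dimnames(allCor)
    expect_length(synexpressionGroups(noCor, tree2, minAvgCorr = 0.15), 0)
})
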