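# Independent oracles used to check the package's statistics, plus small
# fixture builders. These deliberately avoid the code paths they verify.

# Small deterministic cohort: g genes x n samples, one group unless given.
tinyCohort <- function(values, group = rep("A", ncol(values))) {
    if (is.null(rownames(values)))
        rownames(values) <- sprintf("g%02d", seq_len(nrow(values)))
    if (is.null(colnames(values)))
        colnames(values) <- sprintf("s%02d", seq_len(ncol(values)))
    ExpressionCohort(values, group = group)
}

# Two-sided Fisher exact p by full hypergeometric enumeration over all
# tables with the observed margins (minimum-likelihood rule).
fisherEnumP <- function(a, b, c, d) {
    r1 <- a + b; r2 <- c + d; c1 <- a + c
    support <- max(0, c1 - r2):min(r1, c1)
    probs <- dhyper(support, r1, r2, c1)
    pObs <- dhyper(a, r1, r2, c1)
    sum(probs[probs <= pObs * (1 + 1e-7)])
}

# Yates-corrected chi-square of a 2x2 table, closed form.
yatesChi2 <- function(a, b, c, d) {
    a <- as.numeric(a); b <- as.numeric(b)
    c <- as.numeric(c); d <- as.numeric(d)
    N <- a + b + c + d
    num <- max(0, abs(a * d - b * c) - N / 2)
    N * num^2 / ((a + b) * (c + d) * (a + c) * (b + d))
}

# Two-group log-rank statistic from the observed-minus-expected event sums.
logrankOracle <- function(time, event, group) {
    g1 <- levels(factor(group))[1]
    O1 <- E1 <- V1 <- 0
    for (tj in sort(unique(time[event == 1]))) {
        atRisk <- time >= tj
        nj <- sum(atRisk)
        n1j <- sum(atRisk & group == g1)
        dj <- sum(time == tj & event == 1)
        d1j <- sum(time == tj & event == 1 & group == g1)
        O1 <- O1 + d1j
        E1 <- E1 + dj * n1j / nj
        if (nj > 1)
            V1 <- V1 + dj * (n1j / nj) * (1 - n1j / nj) * (nj - dj) / (nj - 1)
    }
    chisq <- (O1 - E1)^2 / V1
    list(chisq = chisq, p = pchisq(chisq, df = 1, lower.tail = FALSE))
}

# Permutation p-value for a Spearman correlation (two-sided).
spearmanPermP <- function(x, y, nPerm = 1000, seed = 1) {
    set.seed(seed)
    obs <- abs(cor(x, y, method = "spearman"))
    hits <- replicate(nPerm,
        abs(cor(x, sample(y), method = "spearman")) >= obs - 1e-12)
    (sum(hits) + 1) / (nPerm + 1)
}
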