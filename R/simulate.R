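## Seeded synthetic-cohort generators with planted ground truth. A single
## latent infiltration factor z per sample drives every planted signal, so
## downstream recovery of signature, culprit and program genes can be scored
## exactly.

.geneRoles <- function(config) {
    G <- config@nGenes
    ids <- sprintf("gene%0*d", nchar(as.character(G)), seq_len(G))
    role <- rep("null", G)
    i <- 0L
    take <- function(n) {
        idx <- i + seq_len(n); i <<- i + n; idx
    }
    role[take(config@nSignature)] <- "signature"
    role[take(config@nCulprits)] <- "culprit"
    role[take(config@programSizeA)] <- "programA"
    role[take(config@programSizeB)] <- "programB"
    stats::setNames(role, ids)
}

## Core expression simulator shared by the pan-tumor and treatment
## generators. Assumes the RNG seed has been set by the caller.
.simulateExpression <- function(config) {
    T <- config@nGroups
    npg <- rep_len(config@samplesPerGroup, T)
    roleOf <- .geneRoles(config)
    G <- length(roleOf)
    N <- sum(npg)
    groupNames <- sprintf("grp%02d", seq_len(T))
    group <- rep(groupNames, times = npg)
    sid <- sprintf("%s_s%03d", group,
                   unlist(lapply(npg, seq_len), use.names = FALSE))
    mu <- stats::rnorm(T)                      # per-group infiltration mean
    z <- stats::rnorm(N, mean = rep(mu, times = npg), sd = 1)
    names(z) <- sid
    X <- matrix(stats::rnorm(G * N, mean = config@baseline,
                             sd = config@noiseSd),
                G, N, dimnames = list(names(roleOf), sid))
    sigRows <- roleOf == "signature"
    X[sigRows, ] <- X[sigRows, ] +
        rep(config@signatureEffect * z, each = sum(sigRows))
    culRows <- roleOf == "culprit"
    if (any(culRows) && config@culpritEffect > 0) {
        affected <- group %in% groupNames[config@culpritGroups]
        X[culRows, affected] <- X[culRows, affected] -
            rep(config@culpritEffect * z[affected], each = sum(culRows))
    }
    ## program activation in cold (lower z tertile within group) samples
    programOf <- stats::setNames(rep("none", N), sid)
    for (g in groupNames) {
        idx <- which(group == g)
        tert <- .balancedPartition(z[idx], sid[idx], 3L,
                                   c("low", "mid", "high"))
        cold <- sid[idx][tert == "low"]
        pick <- stats::runif(length(cold)) < config@programProb
        programOf[cold] <- ifelse(pick, "A", "B")
    }
    if (config@programEffect != 0) {
        aRows <- roleOf == "programA"; bRows <- roleOf == "programB"
        aOn <- programOf == "A"; bOn <- programOf == "B"
        X[aRows, aOn] <- X[aRows, aOn] + config@programEffect
        X[bRows, bOn] <- X[bRows, bOn] + config@programEffect
    }
    X <- pmax(X, 0)                            # log2(x+1) floor
    truth <- methods::new("PlantedTruth", z = z, roleOf = roleOf,
        programOf = programOf,
        effects = list(baseline = config@baseline,
                       signatureEffect = config@signatureEffect,
                       culpritEffect = config@culpritEffect,
                       programEffect = config@programEffect,
                       programProb = config@programProb,
                       noiseSd = config@noiseSd, groupMeans = mu))
    list(cohort = ExpressionCohort(X, group = group), truth = truth)
}

#' Generate a pan-tumor expression cohort with planted structure
#'
#' Per sample s in group t, a latent infiltration factor
#' \code{z_s ~ N(mu_t, 1)} (group means \code{mu_t ~ N(0, 1)}) drives:
#' signature genes \code{alpha + beta z + noise}; culprit genes
#' \code{alpha - gamma z + noise} in the affected groups (baseline
#' elsewhere); two mutually exclusive programs A/B that add \code{delta} in
#' cold samples (lower z tertile within group; program A with probability
#' pi, else B); null genes \code{alpha + noise}. Values are clipped at 0.
#' Deterministic given \code{config@seed}.
#'
#' @param config A [GeneratorConfig-class].
#' @return List: \code{cohort} ([ExpressionCohort-class]), \code{truth}
#'   ([PlantedTruth-class]), \code{signature} (the planted signature genes
#'   as a [GeneSignature-class]).
#' @examples
#' sim <- generatePanTumor(generatorConfig(nGroups = 3, samplesPerGroup = 30,
#'                                         nGenes = 200, seed = 7))
#' table(plantedRoles(sim$truth))
#' @export
generatePanTumor <- function(config) {
    methods::validObject(config)
    set.seed(config@seed)
    sim <- .simulateExpression(config)
    sig <- GeneSignature("TSIG_sim",
        names(plantedRoles(sim$truth))[plantedRoles(sim$truth) ==
                                       "signature"])
    c(sim, list(signature = sig))
}

#' Generate a treatment cohort with score-dependent response and survival
#'
#' Expression is simulated as in [generatePanTumor()] but as a single group
#' of \code{nSamples} biopsies. The standardized metagene score of
#' \code{signature} then drives the clinical outcomes: responder probability
#' \code{plogis(intercept - responseSlope * score_std)} (responders labeled
#' CR/PR 1:2, non-responders SD/PD 1:2), and overall survival
#' \code{Exponential(baselineHazard * exp(hazardSlope * score_std))} with
#' independent exponential right-censoring. Biopsy timing (pre/on) and
#' treatment cohort labels are assigned round-robin.
#'
#' @param config A [GeneratorConfig-class]; its group geometry is overridden
#'   to a single group of \code{nSamples}.
#' @param signature Signature to score; \code{NULL} uses the planted
#'   signature genes.
#' @param responseSlope Log-odds decrease in response per SD of score
#'   (b > 0 concentrates responders at low scores).
#' @param hazardSlope Log-hazard increase per SD of score.
#' @param nSamples Number of samples (>= 8 so quartiles are defined).
#' @param intercept Logistic intercept; default \code{qlogis(1/3)}, a
#'   one-third baseline response rate.
#' @param baselineHazard Baseline event rate per day (default 1/365).
#' @param censorRate Independent censoring rate (default baselineHazard/3).
#' @return List: \code{cohort}, \code{clinical} ([ClinicalTable-class]),
#'   \code{truth}, \code{signature}, \code{scores}.
#' @export
generateTreatmentCohort <- function(config, signature = NULL,
        responseSlope = 3, hazardSlope = 0.5, nSamples = 96,
        intercept = stats::qlogis(1 / 3), baselineHazard = 1 / 365,
        censorRate = baselineHazard / 3) {
    if (nSamples < 8L)
        .err("invalidValueError",
             "nSamples must be >= 8 (quartiles per timing stratum)")
    cfg <- config
    cfg@nGroups <- 1
    cfg@samplesPerGroup <- nSamples
    cfg@culpritGroups <- 1
    methods::validObject(cfg)
    set.seed(cfg@seed)
    sim <- .simulateExpression(cfg)
    roles <- plantedRoles(sim$truth)
    if (is.null(signature))
        signature <- GeneSignature("TSIG_sim",
                                   names(roles)[roles == "signature"])
    if (!all(signatureMembers(signature) %in% geneIds(sim$cohort)))
        .err("invalidValueError", "signature members not all generated")
    score <- metageneScore(sim$cohort, signature)
    std <- as.vector(scale(score))
    n <- length(std)
    pResp <- stats::plogis(intercept - responseSlope * std)
    isResp <- stats::runif(n) < pResp
    response <- character(n)
    response[isResp] <- sample(c("CR", "PR"), sum(isResp), replace = TRUE,
                               prob = c(1, 2))
    response[!isResp] <- sample(c("SD", "PD"), sum(!isResp),
                                replace = TRUE, prob = c(1, 2))
    rate <- baselineHazard * exp(hazardSlope * std)
    tEvent <- stats::rexp(n, rate = 1) / rate
    tCens <- stats::rexp(n, rate = 1) / censorRate
    clinical <- ClinicalTable(data.frame(
        sample_id = sampleIds(sim$cohort),
        cohort = rep(c("Ipi-Naive", "Ipi-Naive", "Ipi-Prog", "Ipi-Prog"),
                     length.out = n),
        timing = rep(c("pre", "on"), length.out = n),
        response = response,
        os_time = pmin(tEvent, tCens),
        os_event = as.integer(tEvent <= tCens)))
    list(cohort = sim$cohort, clinical = clinical, truth = sim$truth,
         signature = signature, scores = score)
}
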