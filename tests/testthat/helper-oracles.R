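# Independent brute-force oracles and small fixture builders used across
# the suite. These deliberately re-derive each quantity from its
# definition, by a different route than the package implementation.

# Holm step-down from the definition: sort ascending, running maximum of
# (m - j + 1) * p_(j), capped at 1, back in the original order.
bruteHolm <- function(p) {
    m <- length(p)
    o <- order(p)
    adj <- numeric(m)
    run <- 0
    for (j in seq_len(m)) {
        run <- max(run, min(1, (m - j + 1) * p[o[j]]))
        adj[o[j]] <- run
    }
    adj
}

# Exact two-sided Mann-Whitney p by direct enumeration of every subset of
# pooled positions assigned to the first sample, two-sided via the
# symmetric deviation of U from its mean.
bruteMWU <- function(x, y) {
    n1 <- length(x); n2 <- length(y)
    r <- rank(c(x, y))
    uOf <- function(ix) sum(r[ix]) - n1 * (n1 + 1) / 2
    uObs <- uOf(seq_len(n1))
    mid <- n1 * n2 / 2
    dev <- abs(uObs - mid)
    sets <- utils::combn(n1 + n2, n1)
    hits <- sum(apply(sets, 2L, function(ix)
        abs(uOf(ix) - mid) >= dev - 1e-9))
    list(U = min(uObs, n1 * n2 - uObs), p = hits / ncol(sets))
}

# O(n^3) UPGMA from the definition: at each step merge the pair of
# clusters with smallest average inter-cluster Euclidean distance.
bruteUPGMA <- function(m) {
    n <- nrow(m)
    d <- as.matrix(stats::dist(m))
    clusters <- as.list(seq_len(n))
    heights <- numeric(n - 1L)
    for (s in seq_len(n - 1L)) {
        best <- Inf; bi <- bj <- NA
        for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
            if (j <= i) next
            avg <- mean(d[clusters[[i]], clusters[[j]]])
            if (avg < best - 1e-12) { best <- avg; bi <- i; bj <- j }
        }
        heights[s] <- best
        clusters[[bi]] <- c(clusters[[bi]], clusters[[bj]])
        clusters[[bj]] <- NULL
    }
    heights
}

# Friedman chi-squared from the rank-sum formula (untied data).
bruteFriedman <- function(blocks) {
    r <- t(apply(blocks, 1L, rank))
    n <- nrow(blocks); k <- ncol(blocks)
    12 / (n * k * (k + 1)) * sum(colSums(r)^2) - 3 * n * (k + 1)
}

# Small default synthetic cohort shared by module tests.
smallCohort <- function(seed = 42L, ...) {
    simulateCohort(cohortConfig(nGenes = 300L, nSubjectsPerGroup = 4L,
                                coreD2N = 15L, sharedD6N = 15L,
                                distinctD6N = 15L, seed = seed, ...))
}

# A purely null cohort (no planted effects).
nullCohort <- function(nGenes = 300L, nSubjectsPerGroup = 4L, seed = 1L,
                       ...) {
    simulateCohort(cohortConfig(nGenes = nGenes,
                                nSubjectsPerGroup = nSubjectsPerGroup,
                                coreD2N = 0L, sharedD6N = 0L,
                                distinctD6N = 0L, seed = seed, ...))
}

# Clinical series built by hand to hit one adjudicator branch at a time.
handSeries <- function(group = "AsmEx",
                       symptomDelta = 0, symptomDays = 0L,
                       extraPuffs = 0, puffDays = 0L,
                       fev1Drop = 0, pefDrop = 0, pefDays = 0L,
                       careSeeking = FALSE) {
    nb <- 7L; ni <- 10L
    baseline <- data.frame(day = 1:nb, symptom = rep(10, nb),
                           puffs = rep(2, nb), pef = rep(400, nb))
    illness <- data.frame(day = 1:ni, symptom = rep(10, ni),
                          puffs = rep(2, ni), pef = rep(400, ni))
    if (symptomDays > 0L)
        illness$symptom[seq_len(symptomDays)] <- 10 + symptomDelta
    if (puffDays > 0L)
        illness$puffs[seq_len(puffDays)] <- 2 + extraPuffs
    if (pefDays > 0L)
        illness$pef[seq_len(pefDays)] <- 400 * (1 - pefDrop)
    visits <- data.frame(visit = c("BL", "D2", "D6"),
                         fev1 = c(100, 100 * (1 - fev1Drop), 100),
                         eno = c(20, 30, 25))
    new("ClinicalSeries", subject = "S1", group = group,
        baseline = baseline, illness = illness, visits = visits,
        careSeeking = careSeeking, planted = NA)
}
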