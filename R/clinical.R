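## Clinical statistics: the a priori exacerbation adjudicator, the rank
## tests used throughout the study, and two-reference-gene qPCR
## normalization.

#' Thresholds of the a priori asthma-exacerbation definition
#'
#' Defaults are exactly the printed criteria: symptom-score increase >= 10
#' points for >= 2 days over the baseline-week average, plus at least one
#' objective change — albuterol use >= 4 puffs/day above the baseline
#' average for >= 2 days, FEV1 decline >= 10\% at an illness visit versus
#' baseline, or PEF decline >= 20\% versus the best baseline-week PEF for
#' >= 2 days.
#'
#' @param symptomDelta,symptomDays symptom criterion thresholds.
#' @param albuterolExtraPuffs,albuterolDays albuterol criterion thresholds.
#' @param fev1DeclineFrac fractional FEV1 decline (0.10 = 10\%).
#' @param pefDeclineFrac,pefDays PEF criterion thresholds.
#' @return a named list of thresholds.
#' @export
exacerbationCriteria <- function(symptomDelta = 10, symptomDays = 2L,
                                 albuterolExtraPuffs = 4,
                                 albuterolDays = 2L,
                                 fev1DeclineFrac = 0.10,
                                 pefDeclineFrac = 0.20, pefDays = 2L) {
    crit <- list(symptomDelta = symptomDelta,
                 symptomDays = as.integer(symptomDays),
                 albuterolExtraPuffs = albuterolExtraPuffs,
                 albuterolDays = as.integer(albuterolDays),
                 fev1DeclineFrac = fev1DeclineFrac,
                 pefDeclineFrac = pefDeclineFrac,
                 pefDays = as.integer(pefDays))
    if (any(unlist(crit) <= 0))
        stop("all exacerbation thresholds must be > 0")
    crit
}

#' Adjudicate asthma exacerbation during ARI
#'
#' Applies the a priori definition: criterion 1 is care-seeking or
#' corticosteroid escalation; criterion 2 is a symptom-score increase of at
#' least \code{symptomDelta} points over the baseline-week daily average on
#' at least \code{symptomDays} illness days, plus at least one objective
#' change (albuterol, FEV1 or PEF, see
#' \code{\link{exacerbationCriteria}}). The verdict is criterion 1 OR
#' criterion 2; a full per-day evidence trace is returned. Non-asthmatic
#' subjects are trivially negative (with a note in the evidence).
#'
#' @param series a \linkS4class{ClinicalSeries}.
#' @param criteria thresholds from \code{\link{exacerbationCriteria}}.
#' @return an \linkS4class{ExacerbationCall}.
#' @export
classifyExacerbation <- function(series,
                                 criteria = exacerbationCriteria()) {
    validObject(series)
    if (nrow(series@baseline) < 2L)
        stop("insufficient data: baseline diary needs >= 2 days")
    asthmatic <- grepl("Asm", series@group, ignore.case = TRUE) ||
        grepl("asthma", series@group, ignore.case = TRUE)
    if (!asthmatic) {
        return(new("ExacerbationCall", verdict = FALSE,
                   criterion1 = FALSE, criterion2 = FALSE,
                   objectiveChanges = character(0),
                   evidence = list(note = paste0(
                       "non-asthmatic group '", series@group,
                       "': exacerbation not applicable"))))
    }

    baseSym <- mean(series@baseline$symptom)
    basePuffs <- mean(series@baseline$puffs)
    bestPef <- max(series@baseline$pef)

    symHit <- series@illness$symptom >= baseSym + criteria$symptomDelta
    symptomMet <- sum(symHit) >= criteria$symptomDays

    puffHit <- series@illness$puffs >=
        basePuffs + criteria$albuterolExtraPuffs
    albuterolMet <- sum(puffHit) >= criteria$albuterolDays

    v <- series@visits
    blFev1 <- v$fev1[v$visit == "BL"]
    illFev1 <- v$fev1[v$visit != "BL"]
    fev1Met <- length(blFev1) == 1L && length(illFev1) >= 1L &&
        any(illFev1 <= (1 - criteria$fev1DeclineFrac) * blFev1,
            na.rm = TRUE)

    pefHit <- series@illness$pef <= (1 - criteria$pefDeclineFrac) * bestPef
    pefMet <- sum(pefHit) >= criteria$pefDays

    objective <- c("albuterol", "fev1", "pef")[
        c(albuterolMet, isTRUE(fev1Met), pefMet)]
    criterion1 <- isTRUE(series@careSeeking)
    criterion2 <- symptomMet && length(objective) >= 1L

    new("ExacerbationCall",
        verdict = criterion1 || criterion2,
        criterion1 = criterion1, criterion2 = criterion2,
        objectiveChanges = objective,
        evidence = list(
            baselineSymptomMean = baseSym,
            baselinePuffsMean = basePuffs,
            bestBaselinePef = bestPef,
            symptomDaysOver = sum(symHit), symptomHit = symHit,
            albuterolDaysOver = sum(puffHit), albuterolHit = puffHit,
            fev1Baseline = if (length(blFev1)) blFev1 else NA_real_,
            fev1IllnessMin = if (length(illFev1)) min(illFev1)
                             else NA_real_,
            pefDaysUnder = sum(pefHit), pefHit = pefHit))
}

#' Friedman repeated-measures rank test
#'
#' Within-block midranks across the time points, tie-corrected chi-squared
#' statistic on k - 1 degrees of freedom. Incomplete blocks are dropped
#' with a warning. The fully tied table (all values equal within every
#' block) is the degenerate case: the statistic is 0 and p = 1.
#'
#' @param blocks numeric matrix, one row per subject (block), one column
#'   per time point.
#' @return an object of class \code{htest} with the chi-squared statistic.
#' @examples
#' friedmanRankTest(rbind(c(1, 2, 3), c(2, 4, 6), c(0, 1, 2)))$statistic
#' @export
friedmanRankTest <- function(blocks) {
    blocks <- as.matrix(blocks)
    complete <- stats::complete.cases(blocks)
    if (any(!complete)) {
        warning(sum(!complete), " incomplete block(s) dropped")
        blocks <- blocks[complete, , drop = FALSE]
    }
    if (nrow(blocks) < 2L)
        stop("need >= 2 complete blocks")
    k <- ncol(blocks)
    n <- nrow(blocks)
    if (all(apply(blocks, 1L, function(r) length(unique(r)) == 1L))) {
        out <- list(statistic = c("Friedman chi-squared" = 0),
                    parameter = c(df = k - 1), p.value = 1,
                    method = "Friedman rank sum test",
                    data.name = "blocks")
        class(out) <- "htest"
        return(out)
    }
    out <- stats::friedman.test(blocks)
    out$n <- n
    out
}

## exact two-sided Mann-Whitney p by enumeration of all C(n1+n2, n1)
## assignments of the pooled midranks; symmetric tail in U
.mwuExactP <- function(ranks, n1, uObs) {
    n <- length(ranks)
    n2 <- n - n1
    mid <- n1 * n2 / 2
    dev <- abs(uObs - mid)
    hits <- 0L
    total <- 0L
    cmb <- utils::combn(n, n1)
    for (j in seq_len(ncol(cmb))) {
        u <- sum(ranks[cmb[, j]]) - n1 * (n1 + 1) / 2
        total <- total + 1L
        if (abs(u - mid) >= dev - 1e-9) hits <- hits + 1L
    }
    hits / total
}

#' Mann-Whitney U test
#'
#' Reports U = min(U_x, U_y). The two-sided p-value is exact — enumeration
#' of all label assignments of the pooled midranks — when both samples have
#' at most \code{exactLimit} observations, and a tie-corrected normal
#' approximation with continuity correction otherwise.
#'
#' @param x,y numeric samples (each >= 2 observations, >= 1 for the
#'   statistic).
#' @param exactLimit per-sample size limit for exact enumeration
#'   (default 8).
#' @return an object of class \code{htest} with statistic \code{U}.
#' @examples
#' mannWhitneyU(1:3, 4:6)   # U = 0, exact two-sided p = 0.1
#' @export
mannWhitneyU <- function(x, y, exactLimit = 8L) {
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
    if (length(x) < 1L || length(y) < 1L)
        stop("both samples must be non-empty")
    n1 <- length(x); n2 <- length(y)
    ranks <- rank(c(x, y))
    r1 <- sum(ranks[seq_len(n1)])
    ux <- r1 - n1 * (n1 + 1) / 2
    uy <- n1 * n2 - ux
    u <- min(ux, uy)

    if (n1 <= exactLimit && n2 <= exactLimit) {
        p <- .mwuExactP(ranks, n1, ux)
        method <- "Mann-Whitney U test (exact enumeration)"
    } else {
        mu <- n1 * n2 / 2
        ties <- table(ranks)
        tieTerm <- sum(ties^3 - ties) /
            ((n1 + n2) * (n1 + n2 - 1))
        sigma <- sqrt(n1 * n2 / 12 * (n1 + n2 + 1 - tieTerm))
        if (sigma == 0) {
            p <- 1
        } else {
            z <- (abs(ux - mu) - 0.5) / sigma
            p <- 2 * stats::pnorm(-max(z, 0))
        }
        method <- "Mann-Whitney U test (tie-corrected normal approximation)"
    }
    out <- list(statistic = c(U = u), p.value = min(p, 1),
                method = method,
                data.name = paste(deparse(substitute(x)), "vs",
                                  deparse(substitute(y))),
                n = c(n1 = n1, n2 = n2))
    class(out) <- "htest"
    out
}

#' Spearman rank correlation
#'
#' Pearson correlation of midranks. The p-value is exact — enumeration of
#' all permutations — for n <= 7, and a t approximation on n - 2 degrees
#' of freedom otherwise.
#'
#' @param x,y numeric vectors (n >= 3, neither constant).
#' @return an object of class \code{htest} with estimate \code{rho}.
#' @examples
#' spearmanRank(c(1, 2, 3), c(1, 1, 2))$estimate  # ~0.866
#' @export
spearmanRank <- function(x, y) {
    ok <- !is.na(x) & !is.na(y)
    x <- x[ok]; y <- y[ok]
    n <- length(x)
    if (n < 3L) stop("need n >= 3")
    if (stats::sd(x) == 0 || stats::sd(y) == 0)
        stop("undefined correlation: an input vector is constant")
    rx <- rank(x); ry <- rank(y)
    rho <- stats::cor(rx, ry)
    if (n <= 7L) {
        perms <- .permutations(n)
        cnt <- 0L
        for (j in seq_len(nrow(perms))) {
            r <- stats::cor(rx, ry[perms[j, ]])
            if (abs(r) >= abs(rho) - 1e-12) cnt <- cnt + 1L
        }
        p <- cnt / nrow(perms)
        method <- "Spearman rank correlation (exact permutation)"
    } else {
        tstat <- rho * sqrt((n - 2) / (1 - rho^2))
        p <- 2 * stats::pt(-abs(tstat), df = n - 2)
        method <- "Spearman rank correlation (t approximation)"
    }
    out <- list(estimate = c(rho = rho), p.value = min(p, 1),
                method = method, n = n,
                data.name = paste(deparse(substitute(x)), "and",
                                  deparse(substitute(y))))
    class(out) <- "htest"
    out
}

.permutations <- function(n) {
    if (n == 1L) return(matrix(1L, 1L, 1L))
    sub <- .permutations(n - 1L)
    out <- matrix(0L, n * nrow(sub), n)
    row <- 1L
    for (i in seq_len(n)) {
        rest <- setdiff(seq_len(n), i)
        for (j in seq_len(nrow(sub))) {
            out[row, ] <- c(i, rest[sub[j, ]])
            row <- row + 1L
        }
    }
    out
}

#' Two-reference-gene qPCR normalization
#'
#' The reference Ct is the arithmetic mean of the two housekeeping-gene
#' Cts (equivalent to the geometric mean of their abundances); the
#' normalized copy number is \code{2^-(Ct_target - Ct_ref)}. Fold change
#' between conditions is the ratio of normalized values.
#'
#' @param targetCt target-gene threshold cycle.
#' @param referenceCts numeric vector of the two housekeeping Cts.
#' @return normalized copy number (dimensionless).
#' @examples
#' normalizeQpcr(25, c(20, 22))  # 2^-4 = 0.0625
#' @export
normalizeQpcr <- function(targetCt, referenceCts) {
    cts <- c(targetCt, referenceCts)
    if (any(cts <= 0 | cts >= 45))
        stop("Ct values must lie in (0, 45)")
    2^-(targetCt - mean(referenceCts))
}
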