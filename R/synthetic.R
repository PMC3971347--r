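## Synthetic longitudinal cohort generator: expression + clinical diaries
## with planted ground truth, emulating a 4-group x 3-visit nasal-mucosa
## ARI time course.

#' Construct a synthetic-cohort configuration
#'
#' Defaults reproduce the validation conditions used throughout the package:
#' 4 groups x 8 subjects x 3 visits, 5,000 gene probes, a core-D2 set
#' up-regulated (+1.5 log2) at day 2 in every group, a shared-D6 set
#' up-regulated at day 6 in the three non-exacerbation groups, a distinct-D6
#' set down-regulated (-1.5 log2) at day 6 in the exacerbation group only,
#' residual noise 0.5 log2 and within-subject correlation 0.3.
#'
#' @param nGenes number of gene probes.
#' @param nSubjectsPerGroup subjects per group.
#' @param groupNames four ordered group labels; the fourth is the
#'   exacerbation group.
#' @param timepoints three ordered visit labels.
#' @param coreD2N,coreD2Effect planted core-D2 set size and log2 effect.
#' @param sharedD6N,sharedD6Effect planted shared-D6 set size and effect.
#' @param sharedD6Groups groups carrying the shared-D6 signature
#'   (default: the first three).
#' @param distinctD6N,distinctD6Effect planted exacerbation-only set size
#'   and effect.
#' @param noiseSd residual log2 SD (> 0).
#' @param withinSubjectRho within-subject equicorrelation in [0, 1).
#' @param missingVisitProb probability a subject-visit sample is dropped.
#' @param seed integer seed.
#' @return a validated \linkS4class{CohortConfig}.
#' @examples
#' cfg <- cohortConfig(nGenes = 200, nSubjectsPerGroup = 4, seed = 7)
#' cfg
#' @export
cohortConfig <- function(nGenes = 5000L, nSubjectsPerGroup = 8L,
                         groupNames = c("Healthy", "AllrgRhin",
                                        "AsmNoEx", "AsmEx"),
                         timepoints = c("BL", "D2", "D6"),
                         coreD2N = 60L, coreD2Effect = 1.5,
                         sharedD6N = 70L, sharedD6Effect = 1.5,
                         sharedD6Groups = groupNames[1:3],
                         distinctD6N = 90L, distinctD6Effect = -1.5,
                         noiseSd = 0.5, withinSubjectRho = 0.3,
                         missingVisitProb = 0, seed = 1L) {
    new("CohortConfig",
        nGenes = as.integer(nGenes),
        nSubjectsPerGroup = as.integer(nSubjectsPerGroup),
        groupNames = as.character(groupNames),
        timepoints = as.character(timepoints),
        coreD2N = as.integer(coreD2N), coreD2Effect = coreD2Effect,
        sharedD6N = as.integer(sharedD6N), sharedD6Effect = sharedD6Effect,
        sharedD6Groups = as.character(sharedD6Groups),
        distinctD6N = as.integer(distinctD6N),
        distinctD6Effect = distinctD6Effect,
        noiseSd = noiseSd, withinSubjectRho = withinSubjectRho,
        missingVisitProb = missingVisitProb, seed = as.integer(seed))
}

## Deterministic sub-seed per generator stage, kept below 2^31.
.subSeed <- function(seed, stage)
    as.integer((as.numeric(seed) * 48271 + stage * 9973) %% 2147483647)

#' Simulate a longitudinal expression cohort with planted signatures
#'
#' Each observation is baseline mean (uniform in [4, 14] log2 units, fixed
#' per gene) + planted group x timepoint offset + subject random intercept
#' + residual noise. The subject intercept variance is
#' \code{rho/(1-rho) * noiseSd^2}, which induces the exact equicorrelation
#' \code{rho} among a subject's samples — the covariance structure the
#' differential-expression stage assumes. Missing visits are dropped whole
#' sample (all genes at once). Identical seeds give bit-identical output.
#'
#' @param config a \linkS4class{CohortConfig}.
#' @return an \linkS4class{AriCohort}; planted truth in
#'   \code{\link{plantedTruth}} / \code{\link{plantedOffsets}}.
#' @examples
#' cohort <- simulateCohort(cohortConfig(nGenes = 100,
#'                                       nSubjectsPerGroup = 3))
#' dim(cohort)
#' table(plantedTruth(cohort)$class)
#' @export
simulateCohort <- function(config) {
    validObject(config)
    grp <- config@groupNames
    tps <- config@timepoints
    ns <- config@nSubjectsPerGroup
    nG <- config@nGenes

    classes <- rep("null", nG)
    idx <- 0L
    coreIdx <- seq_len(config@coreD2N)
    classes[coreIdx] <- "core_d2"
    idx <- config@coreD2N
    sharedIdx <- idx + seq_len(config@sharedD6N)
    classes[sharedIdx] <- "shared_d6"
    idx <- idx + config@sharedD6N
    distinctIdx <- idx + seq_len(config@distinctD6N)
    classes[distinctIdx] <- "distinct_d6"

    cells <- as.vector(outer(grp, tps, paste, sep = "."))
    offsets <- matrix(0, nG, length(cells), dimnames = list(NULL, cells))
    offsets[coreIdx, paste(grp, tps[2L], sep = ".")] <- config@coreD2Effect
    offsets[sharedIdx, paste(config@sharedD6Groups, tps[3L], sep = ".")] <-
        config@sharedD6Effect
    offsets[distinctIdx, paste(grp[4L], tps[3L], sep = ".")] <-
        config@distinctD6Effect

    subjects <- as.vector(vapply(seq_along(grp), function(g)
        sprintf("%s_S%02d", grp[g], seq_len(ns)), character(ns)))
    subjGroup <- rep(grp, each = ns)
    ann <- data.frame(
        sample_id = as.vector(vapply(subjects, function(s)
            paste(s, tps, sep = "."), character(length(tps)))),
        subject = rep(subjects, each = length(tps)),
        group = rep(subjGroup, each = length(tps)),
        timepoint = rep(tps, times = length(subjects)),
        stringsAsFactors = FALSE)
    ann$cell <- paste(ann$group, ann$timepoint, sep = ".")

    geneIds <- sprintf("G%05d", seq_len(nG))

    set.seed(.subSeed(config@seed, 1L))
    mu <- stats::runif(nG, 4, 14)
    sb <- sqrt(config@withinSubjectRho / (1 - config@withinSubjectRho)) *
        config@noiseSd
    ## subject random intercepts: genes x subjects
    B <- matrix(stats::rnorm(nG * length(subjects), 0, sb),
                nG, length(subjects), dimnames = list(NULL, subjects))
    E <- matrix(stats::rnorm(nG * nrow(ann), 0, config@noiseSd),
                nG, nrow(ann))
    Y <- mu + offsets[, ann$cell, drop = FALSE] +
        B[, ann$subject, drop = FALSE] + E
    dimnames(Y) <- list(geneIds, ann$sample_id)

    if (config@missingVisitProb > 0) {
        set.seed(.subSeed(config@seed, 2L))
        keep <- stats::runif(nrow(ann)) >= config@missingVisitProb
        if (!any(keep))
            stop("all samples dropped by missingness; lower missingVisitProb")
        Y <- Y[, keep, drop = FALSE]
        ann <- ann[keep, , drop = FALSE]
    }
    rownames(ann) <- ann$sample_id

    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(log2 = Y),
        colData = S4Vectors::DataFrame(ann[, c("sample_id", "subject",
                                               "group", "timepoint")]),
        rowData = S4Vectors::DataFrame(gene_id = geneIds, class = classes))
    out <- new("AriCohort", se)
    S4Vectors::metadata(out)$offsets <- offsets
    S4Vectors::metadata(out)$config <- config
    out
}

#' Construct a clinical-simulation configuration
#'
#' @param baselineDays length of the asymptomatic baseline diary week
#'   (>= 2 days).
#' @param illnessDays length of the illness diary window; must cover the
#'   day-2 and day-6 visits (>= 7 days).
#' @param symptomScale typical baseline daily symptom score (points).
#' @param seed integer seed.
#' @return a list of class \code{ClinicalSimConfig}.
#' @export
clinicalSimConfig <- function(baselineDays = 7L, illnessDays = 10L,
                              symptomScale = 10, seed = 1L) {
    baselineDays <- as.integer(baselineDays)
    illnessDays <- as.integer(illnessDays)
    if (baselineDays < 2L)
        stop("baseline week must have >= 2 days")
    if (illnessDays < 7L)
        stop("illness window must cover the D2 and D6 visits")
    structure(list(baselineDays = baselineDays, illnessDays = illnessDays,
                   symptomScale = symptomScale, seed = as.integer(seed)),
              class = "ClinicalSimConfig")
}

#' Simulate per-subject clinical series with planted exacerbations
#'
#' Builds symptom/albuterol/PEF diaries and visit spirometry for every
#' subject of a cohort. Subjects flagged in \code{plantedExacerbation}
#' satisfy criterion 2 of the a priori exacerbation definition by
#' construction (symptom score >= baseline mean + 15 points on three illness
#' days, plus albuterol use >= baseline mean + 6 puffs on two days); all
#' other subjects are built to satisfy neither criterion (their illness
#' fluctuations stay strictly inside every threshold). Care-seeking flags
#' are FALSE unless supplied via \code{careSeeking}.
#'
#' @param config a \code{\link{clinicalSimConfig}}.
#' @param annotation a sample-annotation data.frame (columns subject,
#'   group) or an \linkS4class{AriCohort}.
#' @param plantedExacerbation named logical vector over asthmatic subjects;
#'   defaults to TRUE for every subject of the exacerbation (fourth) group.
#' @param careSeeking optional named logical vector setting criterion 1.
#' @return named list of \linkS4class{ClinicalSeries}, one per subject.
#' @export
simulateClinical <- function(config, annotation,
                             plantedExacerbation = NULL,
                             careSeeking = NULL) {
    if (is(annotation, "AriCohort"))
        annotation <- sampleAnnotation(annotation)
    subj <- unique(annotation[, c("subject", "group")])
    groups <- unique(subj$group)
    exGroup <- groups[length(groups)]
    if (is.null(plantedExacerbation)) {
        plantedExacerbation <-
            stats::setNames(subj$group == exGroup, subj$subject)
    }
    unknown <- setdiff(names(plantedExacerbation), subj$subject)
    if (length(unknown))
        stop("unknown subject identifier(s): ",
             paste(unknown, collapse = ", "))

    set.seed(.subSeed(config$seed, 3L))
    out <- vector("list", nrow(subj))
    names(out) <- subj$subject
    for (i in seq_len(nrow(subj))) {
        sid <- subj$subject[i]
        planted <- isTRUE(plantedExacerbation[sid])
        care <- isTRUE(careSeeking[sid])
        out[[i]] <- .simulateOneSeries(config, sid, subj$group[i],
                                       planted, care)
    }
    out
}

.simulateOneSeries <- function(config, subject, group, planted, care) {
    nb <- config$baselineDays
    ni <- config$illnessDays
    asthmatic <- group %in% c("AsmNoEx", "AsmEx") || grepl("Asm", group)

    baseSym <- config$symptomScale
    basePuffs <- if (asthmatic) 2 else 0
    basePef <- 420 + stats::rnorm(1, 0, 15)

    baseline <- data.frame(
        day = seq_len(nb),
        symptom = pmax(0, baseSym + stats::runif(nb, -1, 1)),
        puffs = rep(basePuffs, nb),
        pef = basePef + stats::runif(nb, -8, 8))
    mBaseSym <- mean(baseline$symptom)
    mBasePuffs <- mean(baseline$puffs)
    bestPef <- max(baseline$pef)

    ## non-exacerbating illness stays strictly inside every threshold:
    ## symptoms < mean+10, puffs < mean+4, PEF > 0.8*best
    illness <- data.frame(
        day = seq_len(ni),
        symptom = mBaseSym + stats::runif(ni, 1, 6),
        puffs = mBasePuffs + sample(0:2, ni, replace = TRUE),
        pef = bestPef * stats::runif(ni, 0.88, 0.99))
    baseFev1 <- if (asthmatic) 92 + stats::rnorm(1, 0, 4)
                else 100 + stats::rnorm(1, 0, 4)
    visits <- data.frame(
        visit = c("BL", "D2", "D6"),
        fev1 = c(baseFev1,
                 baseFev1 * stats::runif(2, 0.93, 1.0)),
        eno = c(20, 35, 30) + stats::rnorm(3, 0, 2))

    if (planted) {
        ## criterion 2 by construction: symptom spike on 3 days + extra
        ## albuterol on 2 days (the objective change)
        illness$symptom[2:4] <- mBaseSym + 15
        illness$puffs[c(2L, 3L)] <- mBasePuffs + 6
    }
    new("ClinicalSeries", subject = subject, group = group,
        baseline = baseline, illness = illness, visits = visits,
        careSeeking = isTRUE(care), planted = planted)
}
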