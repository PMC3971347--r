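## End-to-end orchestration of the stage sequence: consensus correlation ->
## GLS fits -> moderation/Holm -> ARI gene set -> transition PCAs ->
## profiles -> membership -> kinetics -> clinical association.

#' Pipeline configuration
#'
#' @param alpha Holm family-wise significance level for ARI gene selection
#'   (default 0.05).
#' @param nTop signature profile size per group and focal time point
#'   (default 100).
#' @param trim two-sided trim fraction of the consensus correlation.
#' @param bProportion prior DE proportion for the reported B statistic.
#' @param transitions which transitions to run; the three stages are
#'   peak (BL to D2, focal D2), reduction (D2 to D6, focal D2 and D6) and
#'   resolution (D6 to BL, focal D6).
#' @return a named list.
#' @export
pipelineConfig <- function(alpha = 0.05, nTop = 100L, trim = 0.15,
                           bProportion = 0.01,
                           transitions = c("peak", "reduction",
                                           "resolution")) {
    stopifnot(alpha > 0, alpha < 1, nTop >= 1)
    list(alpha = alpha, nTop = as.integer(nTop), trim = trim,
         bProportion = bProportion,
         transitions = match.arg(transitions,
                                 c("peak", "reduction", "resolution"),
                                 several.ok = TRUE))
}

## transition layout: time-point pair, symptomatic reference and focal
## time points, in terms of the ordered visit labels (t1, t2, t3)
.transitionSpec <- function(tps) {
    list(peak = list(pair = c(tps[1L], tps[2L]), reference = tps[2L],
                     focal = tps[2L]),
         reduction = list(pair = c(tps[2L], tps[3L]), reference = tps[2L],
                          focal = c(tps[2L], tps[3L])),
         resolution = list(pair = c(tps[3L], tps[1L]), reference = tps[3L],
                           focal = tps[3L]))
}

## group-transition PCA with orientation and separation test
.groupTransitionPCA <- function(cohort, genes, group, pair, reference) {
    ann <- sampleAnnotation(cohort)
    sel <- ann$group == group & ann$timepoint %in% pair
    samples <- ann$sample_id[sel]
    pca <- covariancePCA(cohort, genes = genes, samples = samples)
    refSamples <- ann$sample_id[ann$group == group &
                                ann$timepoint == reference]
    pca <- orientPC1(pca, refSamples)

    annT <- ann[sel, , drop = FALSE]
    sA <- pcaScores(pca)[annT$sample_id[annT$timepoint == pair[1L]], 1L]
    sB <- pcaScores(pca)[annT$sample_id[annT$timepoint == pair[2L]], 1L]
    subA <- annT$subject[annT$timepoint == pair[1L]]
    subB <- annT$subject[annT$timepoint == pair[2L]]
    common <- intersect(subA, subB)
    sep <- tryCatch({
        if (length(common) >= 2L && setequal(subA, subB)) {
            pairing <- cbind(names(sA)[match(common, subA)],
                             names(sB)[match(common, subB)])
            testPC1Separation(sA, sB, pairing)
        } else testPC1Separation(sA, sB)
    }, error = function(e) e$message)
    list(pca = pca, separation = sep, samples = samples)
}

#' Run the full ARI profile-extraction pipeline
#'
#' Executes, in order: consensus within-subject correlation, per-gene GLS
#' fits, empirical-Bayes moderation with Holm adjustment, selection of the
#' ARI gene set (union over the three time contrasts), an all-sample PCA of
#' the ARI genes, per-group transition PCAs with PC1 orientation and
#' cluster-separation tests, sign-directed top-N loading profiles at each
#' focal time point, core/shared/distinct membership classification,
#' kinetics min-max scaling plus average-linkage clustering of the core
#' signature fold changes, and (when clinical series are supplied) the
#' exacerbation adjudication and a Spearman association between
#' signature-gene expression change and airway-obstruction change. An empty
#' ARI set skips the downstream stages with a notice.
#'
#' @param cohort an \linkS4class{AriCohort} (e.g. from
#'   \code{\link{simulateCohort}} or \code{\link{readExpressionTable}}).
#' @param clinical optional named list of \linkS4class{ClinicalSeries}.
#' @param config a \code{\link{pipelineConfig}}.
#' @param outDir optional output directory; when given, every stage's
#'   tables are written there and registered in the manifest.
#' @param verbose log stage progress to standard error.
#' @return a \linkS4class{RunManifest}; in-memory results are in
#'   \code{\link{stageResults}}.
#' @export
runPipeline <- function(cohort, clinical = NULL,
                        config = pipelineConfig(), outDir = NULL,
                        verbose = FALSE) {
    logv <- function(...) if (verbose) message("[ariprofiles] ", ...)
    res <- list()
    stages <- c(correlation = FALSE, fits = FALSE, moderation = FALSE,
                selection = FALSE, pca = FALSE, profiles = FALSE,
                membership = FALSE, kinetics = FALSE, clinical = FALSE)
    files <- character(0)
    notes <- character(0)
    if (!is.null(outDir) && !dir.exists(outDir))
        dir.create(outDir, recursive = TRUE)
    reg <- function(path) files <<- c(files, path)

    ann <- sampleAnnotation(cohort)
    tps <- unique(ann$timepoint)
    groups <- unique(ann$group)

    logv("estimating consensus within-subject correlation")
    rho <- consensusCorrelation(cohort, trim = config$trim)
    res$correlation <- rho
    stages["correlation"] <- TRUE

    logv("fitting per-gene GLS models (rho = ",
         sprintf("%.3f", consensus(rho)), ")")
    fits <- fitGeneModels(cohort, rho)
    res$fits <- fits
    stages["fits"] <- TRUE

    logv("moderating statistics")
    de <- moderateStatistics(fits, bProportion = config$bProportion)
    res$de <- de
    stages["moderation"] <- TRUE
    if (!is.null(outDir)) {
        p <- file.path(outDir, "contrast_table.tsv")
        writeContrastTable(de, p); reg(p)
    }

    ariGenes <- selectAriGenes(de, alpha = config$alpha)
    res$ariGenes <- ariGenes
    stages["selection"] <- TRUE
    logv(length(ariGenes), " ARI genes selected at Holm alpha ",
         config$alpha)
    if (!is.null(outDir)) {
        p <- file.path(outDir, "ari_genes.txt")
        writeLines(ariGenes, p); reg(p)
    }
    if (length(ariGenes) < 2L) {
        notes <- c(notes, paste0(
            "ARI gene set has ", length(ariGenes),
            " gene(s); PCA and downstream stages skipped"))
        logv(notes[length(notes)])
        return(.finishManifest(config, stages, files, res, notes, outDir))
    }

    logv("all-sample covariance PCA of the ARI genes")
    res$allPCA <- covariancePCA(cohort, genes = ariGenes)
    stages["pca"] <- TRUE

    trSpec <- .transitionSpec(tps)[config$transitions]
    profiles <- list()
    separations <- list()
    membershipTables <- list()
    for (trName in names(trSpec)) {
        tr <- trSpec[[trName]]
        logv("transition ", trName, ": ", tr$pair[1L], " to ", tr$pair[2L])
        perGroup <- lapply(groups, function(g)
            .groupTransitionPCA(cohort, ariGenes, g, tr$pair,
                                tr$reference))
        names(perGroup) <- groups
        separations[[trName]] <- lapply(perGroup, `[[`, "separation")
        for (focal in tr$focal) {
            key <- paste0(trName, ".", focal)
            prof <- lapply(groups, function(g) {
                focalSamples <- ann$sample_id[ann$group == g &
                                              ann$timepoint == focal]
                selectLoadingProfile(perGroup[[g]]$pca, focalSamples,
                                     n = config$nTop, group = g,
                                     timepoint = focal)
            })
            names(prof) <- groups
            profiles[[key]] <- prof
            membershipTables[[key]] <- classifyMembership(prof)
            if (!is.null(outDir)) {
                for (g in groups) {
                    p <- file.path(outDir, sprintf("profile_%s_%s.tsv",
                                                   key, g))
                    writeProfile(prof[[g]], p); reg(p)
                }
                p <- file.path(outDir,
                               sprintf("membership_%s.tsv", key))
                writeMembership(mem = membershipTables[[key]], path = p)
                reg(p); reg(paste0(p, ".regions.tsv"))
            }
        }
    }
    res$profiles <- profiles
    res$separations <- separations
    res$membership <- membershipTables
    stages["profiles"] <- TRUE
    stages["membership"] <- TRUE

    ## kinetics on the peak core signature (falling back to the first
    ## non-empty membership class available)
    coreGenes <- character(0)
    if (length(membershipTables)) {
        firstKey <- names(membershipTables)[1L]
        coreGenes <- classGenes(membershipTables[[firstKey]], "core")
        if (!length(coreGenes))
            coreGenes <- membership(membershipTables[[firstKey]])$gene_id
    }
    if (length(coreGenes) >= 2L) {
        traj <- trajectoryMeans(cohort, genes = coreGenes)
        scaled <- minmaxScaleTrajectories(traj)
        fcs <- do.call(cbind, lapply(groups, function(g)
            computeFoldChange(cohort, c(tps[2L], tps[3L]), group = g,
                              genes = coreGenes)))
        colnames(fcs) <- groups
        dendro <- averageLinkageCluster(fcs)
        res$kinetics <- list(trajectories = traj, scaled = scaled,
                             foldChanges = fcs, dendrogram = dendro)
        stages["kinetics"] <- TRUE
        if (!is.null(outDir)) {
            p <- file.path(outDir, "kinetics_scaled.tsv")
            long <- data.frame(
                gene_id = rep(rownames(scaled), ncol(scaled)),
                cell = rep(colnames(scaled), each = nrow(scaled)),
                scaled_value = as.vector(scaled))
            utils::write.table(long, p, sep = "\t", quote = FALSE,
                               row.names = FALSE); reg(p)
            p <- file.path(outDir, "kinetics_dendrogram.tsv")
            utils::write.table(dendroMerges(dendro), p, sep = "\t",
                               quote = FALSE, row.names = FALSE); reg(p)
        }
    } else {
        notes <- c(notes, "kinetics skipped: fewer than 2 signature genes")
    }

    if (!is.null(clinical)) {
        logv("adjudicating exacerbations and clinical association")
        calls <- lapply(clinical, classifyExacerbation)
        assoc <- .clinicalAssociation(cohort, clinical, membershipTables,
                                      tps)
        res$clinical <- list(calls = calls, association = assoc)
        stages["clinical"] <- TRUE
        if (!is.null(outDir)) {
            p <- file.path(outDir, "exacerbation_calls.tsv")
            df <- data.frame(
                subject_id = names(calls),
                verdict = vapply(calls, verdict, logical(1)),
                criterion1 = vapply(calls, slot, logical(1), "criterion1"),
                criterion2 = vapply(calls, slot, logical(1), "criterion2"),
                objective = vapply(calls, function(cc)
                    paste(cc@objectiveChanges, collapse = ","),
                    character(1)))
            utils::write.table(df, p, sep = "\t", quote = FALSE,
                               row.names = FALSE); reg(p)
        }
    } else {
        notes <- c(notes, "no clinical series supplied; clinical stage",
                   " not run")
    }
    .finishManifest(config, stages, files, res, notes, outDir)
}

## Spearman association between signature-gene expression change (later vs
## mid time point) and airway-obstruction change (illness PEF drop versus
## best baseline PEF) across subjects, per group
.clinicalAssociation <- function(cohort, clinical, membershipTables, tps) {
    key <- grep("reduction", names(membershipTables), value = TRUE)
    key <- if (length(key)) key[length(key)] else names(membershipTables)[1L]
    if (is.null(key) || is.na(key)) return(NULL)
    mem <- membershipTables[[key]]
    distinctClass <- grep("^distinct:", unique(membership(mem)$class),
                          value = TRUE)
    genes <- if (length(distinctClass))
        classGenes(mem, distinctClass[1L]) else membership(mem)$gene_id
    if (length(genes) < 1L) return(NULL)

    ann <- sampleAnnotation(cohort)
    Y <- SummarizedExperiment::assay(cohort, "log2")
    out <- list()
    for (g in unique(ann$group)) {
        subs <- intersect(
            ann$subject[ann$group == g & ann$timepoint == tps[2L]],
            ann$subject[ann$group == g & ann$timepoint == tps[3L]])
        subs <- intersect(subs, names(clinical))
        if (length(subs) < 3L) next
        dExpr <- vapply(subs, function(s) {
            s2 <- ann$sample_id[ann$subject == s &
                                ann$timepoint == tps[2L]]
            s3 <- ann$sample_id[ann$subject == s &
                                ann$timepoint == tps[3L]]
            mean(Y[genes, s3]) - mean(Y[genes, s2])
        }, numeric(1))
        dObst <- vapply(subs, function(s) {
            cs <- clinical[[s]]
            min(cs@illness$pef) / max(cs@baseline$pef) - 1
        }, numeric(1))
        out[[g]] <- tryCatch(spearmanRank(dExpr, dObst),
                             error = function(e) e$message)
    }
    out
}

.finishManifest <- function(config, stages, files, res, notes, outDir) {
    if (!is.null(outDir)) {
        p <- file.path(outDir, "manifest.tsv")
        df <- data.frame(stage = names(stages), complete = unname(stages))
        utils::write.table(df, p, sep = "\t", quote = FALSE,
                           row.names = FALSE)
        files <- c(files, p)
        missing <- files[!file.exists(files)]
        if (length(missing))
            warning("registered output missing: ",
                    paste(missing, collapse = ", "))
    }
    new("RunManifest", config = config, stages = stages, files = files,
        results = res, notes = notes)
}

#' Reference cohort group sizes
#'
#' Participant counts per clinical group of the 50-subject reference
#' cohort this pipeline models (9 healthy, 7 allergic rhinitis, 23 asthma
#' without exacerbation, 11 asthma with exacerbation), used for
#' descriptive percentage checks.
#'
#' @return named integer vector of per-group counts.
#' @export
referenceCohortCounts <- function() {
    c(Healthy = 9L, AllrgRhin = 7L, AsmNoEx = 23L, AsmEx = 11L)
}

#' Percentage composition of a count vector
#'
#' @param counts named nonnegative counts.
#' @param total denominator (defaults to \code{sum(counts)}).
#' @return percentages on the 0-100 scale, plus a \code{Total} entry.
#' @examples
#' groupPercentages(referenceCohortCounts())
#' @export
groupPercentages <- function(counts, total = sum(counts)) {
    stopifnot(total > 0, all(counts >= 0))
    c(100 * counts / total, Total = 100 * sum(counts) / total)
}
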