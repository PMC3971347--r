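#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @import SummarizedExperiment
NULL

## Canonical labels used throughout: four clinical groups and three visits.
.ARI_GROUPS <- c("Healthy", "AllrgRhin", "AsmNoEx", "AsmEx")
.ARI_TIMEPOINTS <- c("BL", "D2", "D6")

#' Configuration of a synthetic longitudinal ARI cohort
#'
#' Holds the study conditions under which a cohort is simulated: the 4 x 3
#' (group x visit) design, the three planted signature sets (core-D2 in all
#' groups, shared-D6 in three designated groups, distinct-D6 in the
#' exacerbation group only), the log2 noise level, the within-subject
#' equicorrelation and the whole-sample missingness probability.
#'
#' @slot nGenes number of gene probes simulated.
#' @slot nSubjectsPerGroup subjects per clinical group.
#' @slot groupNames four ordered group labels; the last is the
#'   exacerbation group carrying the distinct-D6 signature.
#' @slot timepoints three ordered visit labels (baseline, day 2, day 6).
#' @slot coreD2N,coreD2Effect size and log2 effect of the core-D2 set,
#'   applied at the second visit in every group.
#' @slot sharedD6N,sharedD6Effect size and log2 effect of the shared-D6 set,
#'   applied at the third visit in \code{sharedD6Groups}.
#' @slot sharedD6Groups the (three) groups carrying the shared-D6 signature.
#' @slot distinctD6N,distinctD6Effect size and log2 effect of the
#'   exacerbation-only distinct-D6 set, applied at the third visit.
#' @slot noiseSd residual log2 standard deviation per observation.
#' @slot withinSubjectRho within-subject equicorrelation in [0, 1).
#' @slot missingVisitProb probability that a subject-visit sample is dropped.
#' @slot seed integer seed keying all randomness of the generator.
#' @export
setClass("CohortConfig", representation(
    nGenes = "integer",
    nSubjectsPerGroup = "integer",
    groupNames = "character",
    timepoints = "character",
    coreD2N = "integer", coreD2Effect = "numeric",
    sharedD6N = "integer", sharedD6Effect = "numeric",
    sharedD6Groups = "character",
    distinctD6N = "integer", distinctD6Effect = "numeric",
    noiseSd = "numeric",
    withinSubjectRho = "numeric",
    missingVisitProb = "numeric",
    seed = "integer"
))

setValidity("CohortConfig", function(object) {
    msg <- character()
    if (object@nGenes < 1L)
        msg <- c(msg, "nGenes must be >= 1")
    if (length(object@groupNames) != 4L ||
        anyDuplicated(object@groupNames))
        msg <- c(msg, "groupNames must be 4 distinct labels")
    if (length(object@timepoints) != 3L ||
        anyDuplicated(object@timepoints))
        msg <- c(msg, "timepoints must be 3 distinct labels")
    if (!all(object@sharedD6Groups %in% object@groupNames))
        msg <- c(msg, "sharedD6Groups must be a subset of groupNames")
    nPlanted <- object@coreD2N + object@sharedD6N + object@distinctD6N
    if (nPlanted > object@nGenes)
        msg <- c(msg, "sum of planted set sizes exceeds nGenes")
    if (object@noiseSd <= 0)
        msg <- c(msg, "noiseSd must be > 0")
    if (object@withinSubjectRho < 0 || object@withinSubjectRho >= 1)
        msg <- c(msg, "withinSubjectRho must be in [0, 1)")
    if (object@missingVisitProb < 0 || object@missingVisitProb >= 1)
        msg <- c(msg, "missingVisitProb must be in [0, 1)")
    if (length(msg)) msg else TRUE
})

#' Longitudinal ARI expression cohort
#'
#' A \linkS4class{SummarizedExperiment} with one assay (\code{"log2"}) of
#' log2-normalized probe intensities, colData columns \code{sample_id},
#' \code{subject}, \code{group}, \code{timepoint} (plus optional
#' \code{meds}, \code{virus}), and, for synthetic cohorts, rowData columns
#' \code{gene_id} and \code{class} giving the planted truth
#' (\code{core_d2}, \code{shared_d6}, \code{distinct_d6} or \code{null})
#' and a per-cell offset matrix stored in \code{metadata(x)$offsets}.
#'
#' @export
setClass("AriCohort", contains = "SummarizedExperiment")

setValidity("AriCohort", function(object) {
    msg <- character()
    cd <- SummarizedExperiment::colData(object)
    need <- c("sample_id", "subject", "group", "timepoint")
    missing <- setdiff(need, colnames(cd))
    if (length(missing))
        msg <- c(msg, paste("colData lacks:", paste(missing, collapse = ", ")))
    if (!("log2" %in% SummarizedExperiment::assayNames(object)))
        msg <- c(msg, "assay 'log2' is required")
    if (!length(msg)) {
        ## each subject must sit in exactly one group
        tab <- unique(data.frame(subject = cd$subject, group = cd$group))
        if (anyDuplicated(tab$subject))
            msg <- c(msg, "a subject is annotated with more than one group")
        if (anyDuplicated(paste(cd$subject, cd$timepoint)))
            msg <- c(msg, "duplicate subject-timepoint sample")
    }
    if (length(msg)) msg else TRUE
})

#' Consensus within-subject correlation
#'
#' Per-gene method-of-moments estimates of the correlation among repeated
#' samples of one subject, and their robust consensus: a trimmed mean on
#' the inverse-hyperbolic-tangent scale, back-transformed.
#'
#' @slot consensus the single consensus correlation, strictly inside (-1, 1).
#' @slot perGene per-gene estimates (clamped to (-0.95, 0.99)).
#' @slot trim two-sided trim fraction used for the robust average.
#' @export
setClass("ConsensusCorrelation", representation(
    consensus = "numeric", perGene = "numeric", trim = "numeric"))

setValidity("ConsensusCorrelation", function(object) {
    if (length(object@consensus) != 1L ||
        abs(object@consensus) >= 1) "consensus must be a scalar in (-1, 1)"
    else TRUE
})

#' Per-gene generalized least-squares fits of the 4 x 3 cell-means model
#'
#' @slot coefficients genes x contrasts matrix of log2 fold changes.
#' @slot stdevUnscaled per-contrast unscaled coefficient standard deviations
#'   (shared by all genes under the common design).
#' @slot sigma2 per-gene residual variance (log2^2 units) on the whitened
#'   scale.
#' @slot df per-gene residual degrees of freedom.
#' @slot rho within-subject correlation used for whitening.
#' @slot cellMeans genes x (group.timepoint) matrix of fitted cell means.
#' @slot contrasts names of the time-point contrasts.
#' @export
setClass("GeneFits", representation(
    coefficients = "matrix", stdevUnscaled = "numeric",
    sigma2 = "numeric", df = "numeric", rho = "numeric",
    cellMeans = "matrix", contrasts = "character"))

#' Moderated differential-expression results
#'
#' Long-format table of per-gene, per-contrast moderated statistics with the
#' estimated variance prior.
#'
#' @slot table data.frame with columns gene_id, contrast, logFC,
#'   t, p_raw, p_holm, p_bh, B.
#' @slot d0 prior degrees of freedom (capped at 1e6 when the log-variance
#'   dispersion is at or below its theoretical minimum).
#' @slot s02 prior variance (log2^2 units).
#' @slot rho consensus correlation used by the fits.
#' @export
setClass("ContrastResults", representation(
    table = "data.frame", d0 = "numeric", s02 = "numeric", rho = "numeric"))

setValidity("ContrastResults", function(object) {
    need <- c("gene_id", "contrast", "logFC", "t", "p_raw", "p_holm", "p_bh")
    if (!all(need %in% colnames(object@table)))
        return("table lacks required columns")
    with(object@table, {
        if (any(p_holm < p_raw - 1e-12, na.rm = TRUE))
            return("adjusted p below raw p")
        TRUE
    })
})

#' Covariance-matrix principal component analysis of an expression block
#'
#' Genes are variables, samples observations; each gene is centered across
#' samples and no variance scaling is applied. Computed by singular value
#' decomposition of the centered matrix so that gene count may far exceed
#' sample count.
#'
#' @slot scores samples x components matrix of PC scores.
#' @slot loadings genes x components matrix of unit-norm loadings.
#' @slot varExplained proportion of variance per retained component.
#' @slot oriented whether PC1 has been oriented against a reference set.
#' @export
setClass("AriPCA", representation(
    scores = "matrix", loadings = "matrix",
    varExplained = "numeric", oriented = "logical"))

setValidity("AriPCA", function(object) {
    msg <- character()
    if (ncol(object@scores) != ncol(object@loadings))
        msg <- c(msg, "scores/loadings component mismatch")
    nrm <- sqrt(colSums(object@loadings^2))
    if (any(abs(nrm - 1) > 1e-6))
        msg <- c(msg, "loadings are not unit norm")
    if (is.unsorted(rev(object@varExplained), strictly = FALSE) &&
        any(diff(object@varExplained) > 1e-8))
        msg <- c(msg, "varExplained must be nonincreasing")
    if (sum(object@varExplained) > 1 + 1e-8)
        msg <- c(msg, "varExplained sums above 1")
    if (length(msg)) msg else TRUE
})

#' Ranked PC1-loading signature profile of one group at one focal time point
#'
#' @slot group group label.
#' @slot timepoint focal time point of the transition.
#' @slot direction "positive" (top most-positive loadings) or "negative".
#' @slot genes ranked gene identifiers (ties broken lexicographically).
#' @slot loadings PC1 loadings in rank order.
#' @export
setClass("SignatureProfile", representation(
    group = "character", timepoint = "character",
    direction = "character", genes = "character", loadings = "numeric"))

setValidity("SignatureProfile", function(object) {
    msg <- character()
    if (!object@direction %in% c("positive", "negative"))
        msg <- c(msg, "direction must be 'positive' or 'negative'")
    if (length(object@genes) != length(object@loadings))
        msg <- c(msg, "genes/loadings length mismatch")
    if (length(msg)) msg else TRUE
})

#' Core/shared/distinct membership of signature genes across groups
#'
#' @slot table data.frame with columns gene_id, groups (comma-joined
#'   member groups) and class (\code{core}, \code{shared:<groups>},
#'   \code{distinct:<group>}).
#' @slot regions data.frame of full Venn regions (region, count).
#' @slot groups the group labels compared.
#' @export
setClass("MembershipTable", representation(
    table = "data.frame", regions = "data.frame", groups = "character"))

#' Average-linkage dendrogram as a portable merge table
#'
#' @slot merges data.frame with columns step, left, right, height, size
#'   (negative left/right index a leaf, positive a previous merge step,
#'   following \code{\link[stats]{hclust}} conventions).
#' @slot order leaf order from recursive left-before-right traversal.
#' @slot labels leaf labels.
#' @export
setClass("DendrogramTable", representation(
    merges = "data.frame", order = "integer", labels = "character"))

#' One subject's clinical diary and spirometry series
#'
#' @slot subject,group identifiers.
#' @slot baseline data.frame (day, symptom, puffs, pef) for the baseline
#'   week; twice-daily diary entries are pre-averaged to daily values.
#' @slot illness data.frame (day, symptom, puffs, pef) for the illness
#'   window covering the D2 and D6 visits.
#' @slot visits data.frame (visit, fev1, eno) with one row per clinic visit.
#' @slot careSeeking whether the subject sought care or escalated
#'   corticosteroids during the illness (adjudicator criterion 1).
#' @slot planted generator truth (TRUE/FALSE) or NA for real data.
#' @export
setClass("ClinicalSeries", representation(
    subject = "character", group = "character",
    baseline = "data.frame", illness = "data.frame",
    visits = "data.frame", careSeeking = "logical", planted = "logical"))

setValidity("ClinicalSeries", function(object) {
    msg <- character()
    for (nm in c("baseline", "illness")) {
        df <- slot(object, nm)
        if (!all(c("day", "symptom", "puffs", "pef") %in% colnames(df)))
            msg <- c(msg, sprintf("%s lacks day/symptom/puffs/pef", nm))
    }
    if (nrow(object@baseline) < 2L)
        msg <- c(msg, "baseline week needs >= 2 days")
    if (nrow(object@illness) < 2L)
        msg <- c(msg, "illness window needs >= 2 days")
    pefs <- c(object@baseline$pef, object@illness$pef)
    if (any(pefs <= 0, na.rm = TRUE))
        msg <- c(msg, "PEF must be > 0")
    if (length(msg)) msg else TRUE
})

#' Result of the a priori exacerbation adjudication
#'
#' @slot verdict overall call: criterion 1 OR criterion 2.
#' @slot criterion1 care-seeking / corticosteroid-escalation criterion.
#' @slot criterion2 symptom-increase-plus-objective-change criterion.
#' @slot objectiveChanges subset of c("albuterol", "fev1", "pef") met.
#' @slot evidence named list tracing the per-day and per-visit comparisons.
#' @export
setClass("ExacerbationCall", representation(
    verdict = "logical", criterion1 = "logical", criterion2 = "logical",
    objectiveChanges = "character", evidence = "list"))

setValidity("ExacerbationCall", function(object) {
    if (!identical(object@verdict, object@criterion1 || object@criterion2))
        "verdict must equal criterion1 OR criterion2" else TRUE
})

#' Manifest of a pipeline run
#'
#' @slot config the pipeline configuration used.
#' @slot stages named logical vector of stage completion flags.
#' @slot files registry of files written (empty for in-memory runs).
#' @slot results named list of in-memory stage results.
#' @slot notes character vector of run notes (e.g. skipped stages).
#' @export
setClass("RunManifest", representation(
    config = "list", stages = "logical", files = "character",
    results = "list", notes = "character"))
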