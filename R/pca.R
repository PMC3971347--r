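## Covariance PCA over selected genes/samples, PC1 orientation, cluster
## separation testing, sign-directed loading profiles and core/shared/
## distinct membership classification.

#' Covariance-matrix PCA of an expression block
#'
#' Genes are the variables and samples the observations; each gene is
#' centered across samples and no variance scaling is applied (covariance,
#' not correlation, PCA). Computed by singular value decomposition of the
#' centered matrix, so gene count may far exceed sample count. Output is
#' deterministic up to component sign (resolved by
#' \code{\link{orientPC1}}).
#'
#' @param x an \linkS4class{AriCohort} or a genes x samples matrix.
#' @param genes optional gene identifiers to restrict to.
#' @param samples optional sample identifiers to restrict to.
#' @return an \linkS4class{AriPCA}.
#' @examples
#' m <- rbind(g1 = c(0, 0, 1, 1), g2 = c(0, 0, 2, 2))
#' colnames(m) <- paste0("s", 1:4)
#' p <- covariancePCA(m)
#' varExplained(p)[1]          # 1: a single direction of variation
#' pcaLoadings(p)[, 1]         # proportional to (1, 2)/sqrt(5)
#' @export
covariancePCA <- function(x, genes = NULL, samples = NULL) {
    m <- if (is(x, "AriCohort")) SummarizedExperiment::assay(x, "log2")
         else as.matrix(x)
    if (!is.null(genes)) m <- m[genes, , drop = FALSE]
    if (!is.null(samples)) m <- m[, samples, drop = FALSE]
    if (ncol(m) < 2L)
        stop("need >= 2 samples for a covariance decomposition")
    if (nrow(m) < 2L)
        stop("need >= 2 genes")
    ## observations (samples) in rows, variables (genes) in columns
    obs <- t(m)
    centered <- scale(obs, center = TRUE, scale = FALSE)
    if (all(abs(centered) < 1e-12))
        stop("zero variance: all genes constant across the selected samples")
    pr <- stats::prcomp(obs, center = TRUE, scale. = FALSE)
    keep <- which(pr$sdev > max(pr$sdev) * 1e-10)
    scores <- pr$x[, keep, drop = FALSE]
    loadings <- pr$rotation[, keep, drop = FALSE]
    ve <- pr$sdev[keep]^2 / sum(pr$sdev^2)
    new("AriPCA", scores = scores, loadings = loadings,
        varExplained = ve, oriented = FALSE)
}

#' Orient PC1 against a reference (symptomatic) sample set
#'
#' PC sign is arbitrary in any decomposition; here PC1 is flipped, scores
#' and loadings together, so that the mean PC1 score of the reference
#' samples is >= 0 — the convention that the symptomatic time point of a
#' transition scores positive.
#'
#' @param pca an \linkS4class{AriPCA}.
#' @param referenceSamples sample identifiers (rownames of the scores).
#' @return the oriented \linkS4class{AriPCA}.
#' @export
orientPC1 <- function(pca, referenceSamples) {
    if (length(referenceSamples) == 0L)
        stop("reference sample set is empty")
    missing <- setdiff(referenceSamples, rownames(pca@scores))
    if (length(missing))
        stop("reference samples not in the PCA: ",
             paste(missing, collapse = ", "))
    m <- mean(pca@scores[referenceSamples, 1L])
    if (m == 0) {
        warning("reference mean PC1 score is exactly 0; orientation kept")
    } else if (m < 0) {
        pca@scores[, 1L] <- -pca@scores[, 1L]
        pca@loadings[, 1L] <- -pca@loadings[, 1L]
    }
    pca@oriented <- TRUE
    pca
}

#' Test separation of two sample clusters along PC1
#'
#' Paired t-test when a subject pairing is supplied (matched samples),
#' otherwise a two-sided Mann-Whitney U test (exact by enumeration for
#' small samples, tie-corrected normal approximation otherwise).
#'
#' @param scoresA,scoresB named PC1 score vectors of the two clusters.
#' @param pairing optional two-column matrix/data.frame of sample-id pairs
#'   (A sample, B sample) defining the matching.
#' @return an object of class \code{htest}.
#' @export
testPC1Separation <- function(scoresA, scoresB, pairing = NULL) {
    if (length(scoresA) < 2L || length(scoresB) < 2L)
        stop("each cluster needs >= 2 observations")
    if (!is.null(pairing)) {
        pairing <- as.matrix(pairing)
        a <- scoresA[pairing[, 1L]]
        b <- scoresB[pairing[, 2L]]
        ok <- !is.na(a) & !is.na(b)
        if (sum(ok) < 2L)
            stop("paired mode requires >= 2 complete pairs")
        d <- a[ok] - b[ok]
        if (all(d == 0)) {
            out <- list(statistic = c(t = 0), p.value = 1,
                        parameter = c(df = sum(ok) - 1),
                        method = "Paired t-test",
                        data.name = "identical paired scores")
            class(out) <- "htest"
            return(out)
        }
        if (stats::sd(d) == 0)
            stop("degenerate paired test: differences have zero variance")
        stats::t.test(a[ok], b[ok], paired = TRUE)
    } else {
        mannWhitneyU(scoresA, scoresB)
    }
}

#' Extract the sign-directed top-N loading profile
#'
#' Direction is positive when the mean PC1 score of the focal samples is
#' positive (the profile is then the N most positive loadings), negative
#' otherwise (the N most negative). Loading ties are broken by gene
#' identifier in lexicographic order. When the focal mean is within 1e-9
#' of zero the direction defaults to positive with a warning.
#'
#' @param pca an oriented \linkS4class{AriPCA}.
#' @param focalSamples sample identifiers of the focal time point.
#' @param n profile size (default 100).
#' @param group,timepoint labels stored on the profile.
#' @return a \linkS4class{SignatureProfile}.
#' @export
selectLoadingProfile <- function(pca, focalSamples, n = 100L,
                                 group = "all", timepoint = "") {
    if (n <= 0) stop("profile size n must be >= 1")
    if (length(focalSamples) == 0L) stop("focal sample set is empty")
    if (!pca@oriented)
        warning("PCA has not been oriented; PC1 sign is arbitrary")
    m <- mean(pca@scores[focalSamples, 1L])
    if (abs(m) < 1e-9) {
        warning("focal mean PC1 score is near zero; defaulting to the ",
                "positive direction")
        direction <- "positive"
    } else direction <- if (m > 0) "positive" else "negative"
    lo <- pca@loadings[, 1L]
    ids <- rownames(pca@loadings)
    ord <- if (direction == "positive") order(-lo, ids) else order(lo, ids)
    take <- ord[seq_len(min(n, length(lo)))]
    new("SignatureProfile", group = group, timepoint = timepoint,
        direction = direction, genes = ids[take],
        loadings = unname(lo[take]))
}

#' Classify genes into core/shared/distinct membership across groups
#'
#' For each gene in the union of the supplied per-group profiles, records
#' the subset of groups whose profile contains it and derives the class:
#' \code{core} when present in all groups, \code{distinct:<group>} when in
#' exactly one, \code{shared:<groups>} for any strict subset of two or
#' more. All Venn region cardinalities are reported.
#'
#' @param profiles named list of \linkS4class{SignatureProfile}, one per
#'   group (names default to each profile's group label).
#' @return a \linkS4class{MembershipTable}.
#' @export
classifyMembership <- function(profiles) {
    if (is.null(names(profiles)) || any(!nzchar(names(profiles))))
        names(profiles) <- vapply(profiles, function(p) p@group,
                                  character(1))
    if (anyDuplicated(names(profiles)))
        stop("duplicate group labels in profiles")
    if (length(profiles) < 2L)
        stop("need >= 2 group profiles")
    groups <- names(profiles)
    sets <- lapply(profiles, profileGenes)
    universe <- sort(unique(unlist(sets)))
    inSet <- vapply(sets, function(s) universe %in% s,
                    logical(length(universe)))
    if (length(universe) == 1L) inSet <- matrix(inSet, nrow = 1L)
    memberStr <- apply(inSet, 1L, function(z)
        paste(groups[z], collapse = ","))
    k <- rowSums(inSet)
    class <- ifelse(k == length(groups), "core",
             ifelse(k == 1L, paste0("distinct:", memberStr),
                    paste0("shared:", gsub(",", "+", memberStr))))
    tab <- data.frame(gene_id = universe, groups = memberStr,
                      class = class, stringsAsFactors = FALSE)

    ## full Venn: one region per non-empty subset of groups
    subsets <- unlist(lapply(seq_along(groups), function(sz)
        utils::combn(groups, sz, simplify = FALSE)), recursive = FALSE)
    regions <- data.frame(
        region = vapply(subsets, paste, character(1), collapse = "+"),
        count = vapply(subsets, function(ss)
            sum(memberStr == paste(ss, collapse = ",")), numeric(1)),
        stringsAsFactors = FALSE)
    new("MembershipTable", table = tab, regions = regions, groups = groups)
}

#' Rank-correlate expression changes with PC1 loadings
#'
#' Spearman correlation between per-gene expression change over a
#' transition and the PC1 loadings that defined the transition's profile —
#' a check of how expression level defines each illness stage.
#'
#' @param deltaExpr named per-gene expression changes.
#' @param loadings named per-gene PC1 loadings (matched by name when both
#'   are named).
#' @return an \code{htest} with Spearman's rho and its p-value.
#' @export
correlateExpressionWithLoadings <- function(deltaExpr, loadings) {
    if (!is.null(names(deltaExpr)) && !is.null(names(loadings))) {
        common <- intersect(names(deltaExpr), names(loadings))
        if (length(common) < 3L)
            stop("need >= 3 genes with both quantities")
        deltaExpr <- deltaExpr[common]
        loadings <- loadings[common]
    }
    spearmanRank(deltaExpr, loadings)
}
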