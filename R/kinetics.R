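## Expression-kinetics scaling, transition fold changes and average-linkage
## clustering of fold-change profiles.

#' Mean log2 trajectory per (group, timepoint) cell
#'
#' @param cohort an \linkS4class{AriCohort}.
#' @param genes optional gene identifiers to restrict to.
#' @return genes x cells matrix with columns named
#'   \code{<group>.<timepoint>} ordered group-major.
#' @export
trajectoryMeans <- function(cohort, genes = NULL) {
    ann <- sampleAnnotation(cohort)
    Y <- SummarizedExperiment::assay(cohort, "log2")
    if (!is.null(genes)) Y <- Y[genes, , drop = FALSE]
    groups <- unique(ann$group)
    tps <- unique(ann$timepoint)
    cells <- as.vector(outer(tps, groups,
                             function(t, g) paste(g, t, sep = ".")))
    cells <- as.vector(t(outer(groups, tps, paste, sep = ".")))
    out <- matrix(NA_real_, nrow(Y), length(cells),
                  dimnames = list(rownames(Y), cells))
    cellOf <- paste(ann$group, ann$timepoint, sep = ".")
    for (cl in cells) {
        ix <- which(cellOf == cl)
        if (length(ix))
            out[, cl] <- rowMeans(Y[, ix, drop = FALSE])
    }
    out
}

#' Min-max scale each gene's trajectory to [0, 1]
#'
#' Per gene, (x - min)/(max - min) jointly over all group x timepoint
#' cells, so the maximum intensity of each gene across time points and
#' groups is exactly 1 and the minimum exactly 0. Constant genes map to
#' 0.5 everywhere and are flagged in the \code{"constant"} attribute.
#'
#' @param traj a genes x cells trajectory matrix
#'   (see \code{\link{trajectoryMeans}}).
#' @return the scaled matrix, with a logical \code{"constant"} attribute.
#' @examples
#' minmaxScaleTrajectories(rbind(g1 = c(2, 4, 6)))  # 0, 0.5, 1
#' @export
minmaxScaleTrajectories <- function(traj) {
    traj <- as.matrix(traj)
    if (ncol(traj) < 2L || nrow(traj) == 0L)
        stop("trajectory needs >= 1 gene and >= 2 cells")
    lo <- apply(traj, 1L, min, na.rm = TRUE)
    hi <- apply(traj, 1L, max, na.rm = TRUE)
    rng <- hi - lo
    constant <- rng == 0
    rng[constant] <- 1
    out <- (traj - lo) / rng
    out[constant, ] <- 0.5
    attr(out, "constant") <- stats::setNames(constant, rownames(traj))
    out
}

#' Per-gene log2 fold change over a time-point transition
#'
#' Mean log2 intensity at the later time point minus the earlier one,
#' within one group (or over all samples). Uses subject-matched means
#' when every subject present at either time point has both visits,
#' cell means over available samples otherwise.
#'
#' @param cohort an \linkS4class{AriCohort}.
#' @param transition length-2 character vector \code{c(from, to)}.
#' @param group optional group label; default uses all samples.
#' @param genes optional gene restriction.
#' @return named numeric vector of log2 fold changes.
#' @export
computeFoldChange <- function(cohort, transition, group = NULL,
                              genes = NULL) {
    stopifnot(length(transition) == 2L)
    ann <- sampleAnnotation(cohort)
    if (!is.null(group)) ann <- ann[ann$group == group, , drop = FALSE]
    Y <- SummarizedExperiment::assay(cohort, "log2")
    if (!is.null(genes)) Y <- Y[genes, , drop = FALSE]
    aFrom <- ann[ann$timepoint == transition[1L], , drop = FALSE]
    aTo <- ann[ann$timepoint == transition[2L], , drop = FALSE]
    if (nrow(aFrom) == 0L || nrow(aTo) == 0L)
        stop("a transition time point has zero samples")
    paired <- setequal(aFrom$subject, aTo$subject) &&
        !anyDuplicated(aFrom$subject) && !anyDuplicated(aTo$subject)
    if (paired) {
        ord <- match(aFrom$subject, aTo$subject)
        d <- Y[, aTo$sample_id[ord], drop = FALSE] -
            Y[, aFrom$sample_id, drop = FALSE]
        fc <- rowMeans(d)
    } else {
        fc <- rowMeans(Y[, aTo$sample_id, drop = FALSE]) -
            rowMeans(Y[, aFrom$sample_id, drop = FALSE])
    }
    fc
}

#' Agglomerative average-linkage (UPGMA) clustering
#'
#' Euclidean distances between rows, unweighted average linkage. Returned
#' as a portable merge table; merge heights are nondecreasing on finite
#' data, and the leaf order follows a recursive left-before-right
#' traversal.
#'
#' @param m numeric matrix of per-gene fold-change vectors (>= 2 rows,
#'   no missing values).
#' @return a \linkS4class{DendrogramTable}.
#' @examples
#' d <- averageLinkageCluster(cbind(c(0, 1, 5)))
#' dendroMerges(d)$height   # 1 then 4.5
#' @export
averageLinkageCluster <- function(m) {
    m <- as.matrix(m)
    if (nrow(m) < 2L) stop("need >= 2 rows to cluster")
    if (anyNA(m)) stop("missing values are not allowed in clustering input")
    hc <- stats::hclust(stats::dist(m, method = "euclidean"),
                        method = "average")
    sizes <- integer(nrow(hc$merge))
    leafCount <- function(ix) if (ix < 0) 1L else sizes[ix]
    for (s in seq_len(nrow(hc$merge)))
        sizes[s] <- leafCount(hc$merge[s, 1L]) + leafCount(hc$merge[s, 2L])
    labels <- if (is.null(hc$labels)) as.character(seq_len(nrow(m)))
              else hc$labels
    new("DendrogramTable",
        merges = data.frame(step = seq_len(nrow(hc$merge)),
                            left = hc$merge[, 1L], right = hc$merge[, 2L],
                            height = hc$height, size = sizes),
        order = as.integer(hc$order), labels = labels)
}
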