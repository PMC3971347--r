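## Generics, accessors and show() methods for the package's S4 containers.
## Slot access from user code should go through these.

#' Planted ground truth of a synthetic cohort
#'
#' @param x an \linkS4class{AriCohort}.
#' @return a \link[S4Vectors]{DataFrame} with columns \code{gene_id} and
#'   \code{class} (one of \code{core_d2}, \code{shared_d6},
#'   \code{distinct_d6}, \code{null}), or NULL for non-synthetic cohorts.
#' @export
setGeneric("plantedTruth", function(x) standardGeneric("plantedTruth"))

#' @rdname plantedTruth
#' @export
setMethod("plantedTruth", "AriCohort", function(x) {
    rd <- SummarizedExperiment::rowData(x)
    if (!"class" %in% colnames(rd)) return(NULL)
    rd[, c("gene_id", "class")]
})

#' Per-gene group x timepoint effect offsets of a synthetic cohort
#'
#' @param x an \linkS4class{AriCohort}.
#' @return genes x (group.timepoint) matrix of planted log2 offsets.
#' @export
setGeneric("plantedOffsets", function(x) standardGeneric("plantedOffsets"))

#' @rdname plantedOffsets
#' @export
setMethod("plantedOffsets", "AriCohort", function(x)
    S4Vectors::metadata(x)$offsets)

#' Sample annotation of a cohort as a data.frame
#' @param x an \linkS4class{AriCohort}.
#' @export
setGeneric("sampleAnnotation", function(x)
    standardGeneric("sampleAnnotation"))

#' @rdname sampleAnnotation
#' @export
setMethod("sampleAnnotation", "AriCohort", function(x)
    as.data.frame(SummarizedExperiment::colData(x)))

#' Consensus value of a ConsensusCorrelation
#' @param x a \linkS4class{ConsensusCorrelation}.
#' @export
setGeneric("consensus", function(x) standardGeneric("consensus"))

#' @rdname consensus
#' @export
setMethod("consensus", "ConsensusCorrelation", function(x) x@consensus)

#' Per-gene correlation estimates
#' @param x a \linkS4class{ConsensusCorrelation}.
#' @export
setGeneric("perGeneCorrelations", function(x)
    standardGeneric("perGeneCorrelations"))

#' @rdname perGeneCorrelations
#' @export
setMethod("perGeneCorrelations", "ConsensusCorrelation",
          function(x) x@perGene)

#' Long-format moderated statistics table
#' @param x a \linkS4class{ContrastResults}.
#' @export
setGeneric("deTable", function(x) standardGeneric("deTable"))

#' @rdname deTable
#' @export
setMethod("deTable", "ContrastResults", function(x) x@table)

#' Variance prior of the moderation step
#' @param x a \linkS4class{ContrastResults}.
#' @return list with elements \code{d0} and \code{s02}.
#' @export
setGeneric("moderationPrior", function(x)
    standardGeneric("moderationPrior"))

#' @rdname moderationPrior
#' @export
setMethod("moderationPrior", "ContrastResults", function(x)
    list(d0 = x@d0, s02 = x@s02))

#' PC scores, loadings and variance explained
#' @param x an \linkS4class{AriPCA}.
#' @export
setGeneric("pcaScores", function(x) standardGeneric("pcaScores"))
#' @rdname pcaScores
#' @export
setMethod("pcaScores", "AriPCA", function(x) x@scores)

#' @rdname pcaScores
#' @export
setGeneric("pcaLoadings", function(x) standardGeneric("pcaLoadings"))
#' @rdname pcaScores
#' @export
setMethod("pcaLoadings", "AriPCA", function(x) x@loadings)

#' @rdname pcaScores
#' @export
setGeneric("varExplained", function(x) standardGeneric("varExplained"))
#' @rdname pcaScores
#' @export
setMethod("varExplained", "AriPCA", function(x) x@varExplained)

#' Ranked genes of a signature profile
#' @param x a \linkS4class{SignatureProfile}.
#' @export
setGeneric("profileGenes", function(x) standardGeneric("profileGenes"))
#' @rdname profileGenes
#' @export
setMethod("profileGenes", "SignatureProfile", function(x) x@genes)

#' Direction of a signature profile
#' @param x a \linkS4class{SignatureProfile}.
#' @export
setGeneric("profileDirection", function(x)
    standardGeneric("profileDirection"))
#' @rdname profileDirection
#' @export
setMethod("profileDirection", "SignatureProfile", function(x) x@direction)

#' Gene-level membership table
#' @param x a \linkS4class{MembershipTable}.
#' @export
setGeneric("membership", function(x) standardGeneric("membership"))
#' @rdname membership
#' @export
setMethod("membership", "MembershipTable", function(x) x@table)

#' Full Venn-region counts
#' @param x a \linkS4class{MembershipTable}.
#' @export
setGeneric("vennRegions", function(x) standardGeneric("vennRegions"))
#' @rdname vennRegions
#' @export
setMethod("vennRegions", "MembershipTable", function(x) x@regions)

#' Genes falling in a membership class
#'
#' @param x a \linkS4class{MembershipTable}.
#' @param class a class label, e.g. \code{"core"} or
#'   \code{"distinct:AsmEx"}.
#' @export
setGeneric("classGenes", function(x, class) standardGeneric("classGenes"))
#' @rdname classGenes
#' @export
setMethod("classGenes", "MembershipTable", function(x, class)
    x@table$gene_id[x@table$class == class])

#' Merge table of a dendrogram
#' @param x a \linkS4class{DendrogramTable}.
#' @export
setGeneric("dendroMerges", function(x) standardGeneric("dendroMerges"))
#' @rdname dendroMerges
#' @export
setMethod("dendroMerges", "DendrogramTable", function(x) x@merges)

#' Verdict of an exacerbation call
#' @param x an \linkS4class{ExacerbationCall}.
#' @export
setGeneric("verdict", function(x) standardGeneric("verdict"))
#' @rdname verdict
#' @export
setMethod("verdict", "ExacerbationCall", function(x) x@verdict)

#' Evidence trace of an exacerbation call
#' @param x an \linkS4class{ExacerbationCall}.
#' @export
setGeneric("callEvidence", function(x) standardGeneric("callEvidence"))
#' @rdname callEvidence
#' @export
setMethod("callEvidence", "ExacerbationCall", function(x) x@evidence)

#' In-memory results registered in a run manifest
#' @param x a \linkS4class{RunManifest}.
#' @export
setGeneric("stageResults", function(x) standardGeneric("stageResults"))
#' @rdname stageResults
#' @export
setMethod("stageResults", "RunManifest", function(x) x@results)

#' Stage completion flags of a run manifest
#' @param x a \linkS4class{RunManifest}.
#' @export
setGeneric("stageFlags", function(x) standardGeneric("stageFlags"))
#' @rdname stageFlags
#' @export
setMethod("stageFlags", "RunManifest", function(x) x@stages)

setMethod("show", "CohortConfig", function(object) {
    cat("CohortConfig:", object@nGenes, "genes,",
        object@nSubjectsPerGroup, "subjects x",
        length(object@groupNames), "groups x",
        length(object@timepoints), "timepoints\n")
    cat("  planted: core-D2", object@coreD2N,
        sprintf("(%+.2f)", object@coreD2Effect),
        "| shared-D6", object@sharedD6N,
        sprintf("(%+.2f in %s)", object@sharedD6Effect,
                paste(object@sharedD6Groups, collapse = ",")),
        "| distinct-D6", object@distinctD6N,
        sprintf("(%+.2f in %s)", object@distinctD6Effect,
                object@groupNames[4L]), "\n")
    cat(sprintf("  noiseSd %.3g, rho %.3g, missing %.3g, seed %d\n",
                object@noiseSd, object@withinSubjectRho,
                object@missingVisitProb, object@seed))
})

setMethod("show", "ConsensusCorrelation", function(object) {
    cat(sprintf(
        "ConsensusCorrelation: %.4f (trim %.2f, %d genes)\n",
        object@consensus, object@trim, length(object@perGene)))
})

setMethod("show", "GeneFits", function(object) {
    cat(sprintf(
        "GeneFits: %d genes, contrasts %s, rho %.3f, df %g\n",
        nrow(object@coefficients),
        paste(object@contrasts, collapse = ", "),
        object@rho, object@df[1L]))
})

setMethod("show", "ContrastResults", function(object) {
    cat(sprintf(
        "ContrastResults: %d rows (%d genes x %d contrasts), d0 = %.4g, s02 = %.4g\n",
        nrow(object@table), length(unique(object@table$gene_id)),
        length(unique(object@table$contrast)), object@d0, object@s02))
})

setMethod("show", "AriPCA", function(object) {
    cat(sprintf(
        "AriPCA: %d samples x %d genes, %d components, PC1 %.1f%%%s\n",
        nrow(object@scores), nrow(object@loadings),
        ncol(object@scores), 100 * object@varExplained[1L],
        if (object@oriented) " (oriented)" else ""))
})

setMethod("show", "SignatureProfile", function(object) {
    cat(sprintf("SignatureProfile: %s @ %s, %s, %d genes\n",
                object@group, object@timepoint, object@direction,
                length(object@genes)))
})

setMethod("show", "MembershipTable", function(object) {
    cat(sprintf("MembershipTable over %s: %d genes, %d core, %d distinct\n",
                paste(object@groups, collapse = "/"),
                nrow(object@table),
                sum(object@table$class == "core"),
                sum(startsWith(object@table$class, "distinct"))))
})

setMethod("show", "DendrogramTable", function(object) {
    cat(sprintf("DendrogramTable: %d leaves, %d merges, max height %.4g\n",
                length(object@labels), nrow(object@merges),
                max(object@merges$height)))
})

setMethod("show", "ClinicalSeries", function(object) {
    cat(sprintf(
        "ClinicalSeries %s (%s): %d baseline days, %d illness days%s\n",
        object@subject, object@group, nrow(object@baseline),
        nrow(object@illness),
        if (isTRUE(object@careSeeking)) ", care-seeking" else ""))
})

setMethod("show", "ExacerbationCall", function(object) {
    cat(sprintf(
        "ExacerbationCall: %s (criterion1 %s, criterion2 %s%s)\n",
        if (object@verdict) "EXACERBATION" else "no exacerbation",
        object@criterion1, object@criterion2,
        if (length(object@objectiveChanges))
            paste0("; objective: ",
                   paste(object@objectiveChanges, collapse = ","))
        else ""))
})

setMethod("show", "RunManifest", function(object) {
    done <- names(object@stages)[object@stages]
    cat("RunManifest:", length(done), "of", length(object@stages),
        "stages complete\n")
    cat(" ", paste(names(object@stages),
                   ifelse(object@stages, "done", "SKIPPED/FAILED"),
                   collapse = "; "), "\n")
    if (length(object@files))
        cat("  files:", length(object@files), "registered\n")
})
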