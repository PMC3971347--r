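## Blocked differential expression over the 4 x 3 design: per-gene GLS under
## block-equicorrelated within-subject covariance, empirical-Bayes variance
## moderation, Holm step-down selection of the ARI gene set.

## cell-means design pieces shared by the correlation and fitting stages
.designPieces <- function(cohort) {
    ann <- sampleAnnotation(cohort)
    groups <- unique(ann$group)
    tps <- unique(ann$timepoint)
    if (length(tps) < 2L)
        stop("need >= 2 time points")
    cells <- as.vector(outer(groups, tps, paste, sep = "."))
    cell <- factor(paste(ann$group, ann$timepoint, sep = "."),
                   levels = cells)
    empty <- cells[tabulate(cell, length(cells)) == 0L]
    if (length(empty))
        stop("rank-deficient design; empty cells: ",
             paste(empty, collapse = ", "))
    X <- stats::model.matrix(~ 0 + cell)
    colnames(X) <- cells
    list(ann = ann, groups = groups, tps = tps, cells = cells, X = X)
}

#' Estimate the consensus within-subject correlation
#'
#' Fits, per gene, a method-of-moments estimate of the correlation among a
#' subject's repeated samples from the two-way (subject x time, within
#' group) ANOVA decomposition of the cell-means residuals:
#' E[MS_subject] = k0 * sigma_b^2 + sigma_e^2 and E[MS_error] = sigma_e^2,
#' giving rho = sigma_b^2 / (sigma_b^2 + sigma_e^2). Per-gene estimates are
#' clamped to (-0.95, 0.99); the consensus is a two-sided trimmed mean on
#' the inverse-hyperbolic-tangent scale, back-transformed.
#'
#' @param cohort an \linkS4class{AriCohort}.
#' @param trim two-sided trim fraction (default 0.15).
#' @return a \linkS4class{ConsensusCorrelation}.
#' @export
consensusCorrelation <- function(cohort, trim = 0.15) {
    dp <- .designPieces(cohort)
    ann <- dp$ann
    nVisits <- table(ann$subject)
    if (sum(nVisits >= 2L) < 2L)
        stop("need >= 2 subjects with repeated measures to estimate ",
             "the within-subject correlation")
    Y <- SummarizedExperiment::assay(cohort, "log2")

    ## OLS residuals of the cell-means model (same projection all genes)
    X <- dp$X
    H <- X %*% solve(crossprod(X), t(X))
    R <- Y - Y %*% t(H)

    subj <- factor(ann$subject)
    keep <- names(nVisits)[nVisits >= 2L]
    use <- subj %in% keep
    R <- R[, use, drop = FALSE]
    subj <- droplevels(subj[use])
    subjGroup <- ann$group[use][match(levels(subj), ann$subject[use])]
    ni <- as.vector(table(subj))
    N <- sum(ni)
    I <- nlevels(subj)
    G <- length(unique(subjGroup))
    ## subjects are nested in groups and the residuals are cell-centered,
    ## so the between-subject stratum has I - G df; the cluster-size
    ## coefficient uses the group-stratified n0 correction (equal to the
    ## common visit count k for balanced complete data)
    dfB <- I - G
    term <- vapply(split(ni, subjGroup), function(n) sum(n^2) / sum(n),
                   numeric(1))
    k0 <- (N - sum(term)) / dfB

    Zs <- stats::model.matrix(~ 0 + subj)           # samples x subjects
    subjSums <- R %*% Zs                            # genes x subjects
    subjMeans <- sweep(subjSums, 2L, ni, "/")
    SSB <- rowSums(sweep(subjMeans^2, 2L, ni, "*"))
    SST <- rowSums(R^2)
    SSW <- pmax(SST - SSB, 0)

    dfW <- N - ncol(X) - dfB
    if (dfW < 1L)
        stop("insufficient residual degrees of freedom for the ",
             "correlation estimate")
    MSB <- SSB / dfB
    MSW <- SSW / dfW
    sb2 <- (MSB - MSW) / k0
    rhoG <- sb2 / (sb2 + MSW)
    rhoG[!is.finite(rhoG)] <- 0
    rhoG <- pmin(pmax(rhoG, -0.95), 0.99)

    z <- atanh(rhoG)
    cons <- tanh(mean(z, trim = trim))
    cons <- min(max(cons, -1 + 1e-8), 1 - 1e-8)
    new("ConsensusCorrelation", consensus = cons, perGene = rhoG,
        trim = trim)
}

## inverse square root of the equicorrelation matrix of size k:
## a on the J/k projection, b on its complement
.whitenBlock <- function(k, rho) {
    a <- 1 / sqrt(1 + (k - 1) * rho)
    b <- 1 / sqrt(1 - rho)
    P1 <- matrix(1 / k, k, k)
    a * P1 + b * (diag(k) - P1)
}

#' Fit per-gene GLS models over the group x timepoint cells
#'
#' Generalized least squares under a block covariance: correlation
#' \code{rho} between samples of the same subject, independence across
#' subjects. With \code{rho = 0} this reduces exactly to ordinary least
#' squares. The three time-point contrasts (t2-t1, t3-t2, t3-t1) are time
#' main effects averaged with equal weight over the groups.
#'
#' @param cohort an \linkS4class{AriCohort}.
#' @param rho a \linkS4class{ConsensusCorrelation} or a scalar correlation.
#' @return a \linkS4class{GeneFits}.
#' @export
fitGeneModels <- function(cohort, rho = 0) {
    if (is(rho, "ConsensusCorrelation")) rho <- consensus(rho)
    stopifnot(is.numeric(rho), length(rho) == 1L, abs(rho) < 1)
    dp <- .designPieces(cohort)
    ann <- dp$ann
    Y <- SummarizedExperiment::assay(cohort, "log2")
    X <- dp$X
    N <- nrow(X)

    ## block-diagonal whitening by subject
    W <- diag(N)
    if (rho != 0) {
        for (s in unique(ann$subject)) {
            ix <- which(ann$subject == s)
            if (length(ix) > 1L)
                W[ix, ix] <- .whitenBlock(length(ix), rho)
            else W[ix, ix] <- 1
        }
    }
    M <- W %*% X
    XtXi <- solve(crossprod(M))
    A <- XtXi %*% t(M) %*% W                 # p x N projector onto betas
    Beta <- Y %*% t(A)                        # genes x cells
    colnames(Beta) <- dp$cells
    Yw <- Y %*% t(W)
    fitted <- Beta %*% t(M)
    res <- Yw - fitted
    dfRes <- N - ncol(X)
    if (dfRes < 1L)
        stop("no residual degrees of freedom")
    sigma2 <- rowSums(res^2) / dfRes

    tps <- dp$tps
    groups <- dp$groups
    ## the three time contrasts of the full design; a two-visit design
    ## degenerates to its single contrast
    pairIdx <- if (length(tps) >= 3L)
        list(c(2L, 1L), c(3L, 2L), c(3L, 1L)) else list(c(2L, 1L))
    contrastNames <- vapply(pairIdx, function(ix)
        paste0(tps[ix[1L]], "-", tps[ix[2L]]), character(1))
    C <- matrix(0, length(dp$cells), length(pairIdx),
                dimnames = list(dp$cells, contrastNames))
    for (j in seq_along(pairIdx)) {
        hi <- paste(groups, tps[pairIdx[[j]][1L]], sep = ".")
        lo <- paste(groups, tps[pairIdx[[j]][2L]], sep = ".")
        C[hi, j] <- C[hi, j] + 1 / length(groups)
        C[lo, j] <- C[lo, j] - 1 / length(groups)
    }
    coefs <- Beta %*% C
    stdevUnscaled <- sqrt(diag(t(C) %*% XtXi %*% C))

    new("GeneFits", coefficients = coefs,
        stdevUnscaled = stats::setNames(stdevUnscaled, contrastNames),
        sigma2 = stats::setNames(sigma2, rownames(Y)),
        df = rep(dfRes, nrow(Y)), rho = rho, cellMeans = Beta,
        contrasts = contrastNames)
}

## Newton inversion of the trigamma function (monotone decreasing on (0,Inf))
.trigammaInverse <- function(x) {
    vapply(x, function(xi) {
        if (!is.finite(xi) || xi <= 0) return(Inf)
        if (xi > 1e7) return(1 / sqrt(xi))
        if (xi < 1e-6) return(1 / xi)
        y <- 0.5 + 1 / xi
        for (iter in 1:50) {
            tri <- trigamma(y)
            dif <- tri * (1 - tri / xi) / psigamma(y, 2L)
            y <- y + dif
            if (abs(dif) / y < 1e-10) break
        }
        y
    }, numeric(1))
}

## moment-match d0 and s02 from the distribution of log sample variances:
## log s^2 - digamma(d/2) + log(d/2) has mean log s0^2 + digamma(d0/2)
## - log(d0/2) and excess variance trigamma(d0/2).
.estimatePrior <- function(sigma2, df, cap = 1e6) {
    ok <- df > 0 & is.finite(sigma2) & sigma2 > 0
    if (sum(ok) < 10L)
        stop("need >= 10 genes with positive residual variance and df ",
             "to estimate the variance prior")
    s2 <- sigma2[ok]
    d <- df[ok]
    e <- log(s2) - digamma(d / 2) + log(d / 2)
    emean <- mean(e)
    evar <- stats::var(e) - mean(trigamma(d / 2))
    if (is.finite(evar) && evar > 0) {
        d0 <- 2 * .trigammaInverse(evar)
        if (d0 > cap) d0 <- cap
        s02 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
    } else {
        d0 <- cap
        s02 <- exp(emean)
    }
    list(d0 = d0, s02 = s02)
}

## limma-style estimate of the prior variance v0 of nonzero coefficients,
## used only by the (reported, never selective) B statistic
.tmixtureV0 <- function(tstat, stdevUnscaled, df, proportion) {
    ngenes <- length(tstat)
    ntarget <- ceiling(proportion / 2 * ngenes)
    if (ntarget < 1L) return(NA_real_)
    p <- max(ntarget / ngenes, proportion)
    tstat <- abs(tstat)
    o <- order(tstat, decreasing = TRUE)[seq_len(ntarget)]
    tt <- tstat[o]
    v1 <- stdevUnscaled[o]^2
    r <- seq_len(ntarget) - 0.5
    dfm <- max(df)
    p0 <- 2 * stats::pt(-tt, df = dfm)
    ptarget <- ((r / ngenes) - (1 - p) * p0) / p
    v0 <- rep(0, ntarget)
    pos <- ptarget > p0
    if (any(pos)) {
        qtarget <- stats::qt(ptarget[pos] / 2, df = dfm,
                             lower.tail = FALSE)
        v0[pos] <- v1[pos] * ((tt[pos] / qtarget)^2 - 1)
    }
    mean(v0)
}

#' Empirical-Bayes moderation of the per-gene statistics
#'
#' Estimates the variance prior (d0, s02) by moment-matching the
#' distribution of log residual variances against its theoretical scaled-F
#' form (digamma/trigamma relations), squeezes each gene's variance to the
#' posterior \code{(d0 s02 + d s^2) / (d0 + d)}, and refers the moderated t
#' to a t distribution on d0 + d degrees of freedom. d0 is capped at 1e6
#' when the log-variance dispersion is at or below its theoretical minimum.
#' Raw p-values are Holm-adjusted within each contrast family (and
#' Benjamini-Hochberg adjusted for reference); a log-posterior-odds B
#' statistic with prior DE proportion \code{bProportion} is reported but
#' never used for selection. Genes with zero residual variance are excluded
#' from prior estimation and their statistics set to NA.
#'
#' @param fits a \linkS4class{GeneFits}.
#' @param d0 optional forced prior degrees of freedom (e.g. 0 for ordinary
#'   t-statistics); default NULL estimates it from the data.
#' @param s02 optional forced prior variance; default NULL estimates it.
#' @param bProportion assumed proportion of differentially expressed genes
#'   for the B statistic.
#' @return a \linkS4class{ContrastResults}.
#' @export
moderateStatistics <- function(fits, d0 = NULL, s02 = NULL,
                               bProportion = 0.01) {
    sigma2 <- fits@sigma2
    df <- fits@df
    if (all(sigma2 <= 0))
        stop("degenerate variances: all residual variances are zero")
    if (is.null(d0)) {
        prior <- .estimatePrior(sigma2, df)
        d0 <- prior$d0
        if (is.null(s02)) s02 <- prior$s02
    } else {
        stopifnot(d0 >= 0)
        if (is.null(s02))
            s02 <- if (d0 > 0) .estimatePrior(sigma2, df)$s02 else NA_real_
    }
    postVar <- if (d0 > 0) (d0 * s02 + df * sigma2) / (d0 + df)
               else sigma2
    dfTotal <- df + d0

    genes <- rownames(fits@coefficients)
    flagged <- sigma2 <= 0 | !is.finite(sigma2)
    tabs <- lapply(fits@contrasts, function(cn) {
        b <- fits@coefficients[, cn]
        se <- sqrt(postVar) * fits@stdevUnscaled[[cn]]
        tmod <- b / se
        tmod[flagged & b == 0] <- 0
        tmod[flagged & b != 0] <- NA_real_
        pRaw <- 2 * stats::pt(-abs(tmod), df = dfTotal)
        ok <- !is.na(tmod)
        B <- rep(NA_real_, length(tmod))
        if (sum(ok) >= 10L) {
            su <- rep(fits@stdevUnscaled[[cn]], sum(ok))
            v0 <- .tmixtureV0(tmod[ok], su, dfTotal[ok], bProportion)
            if (is.finite(v0) && v0 > 0) {
                v1 <- fits@stdevUnscaled[[cn]]^2
                rr <- (v1 + v0) / v1
                t2 <- tmod[ok]^2
                kernel <- ifelse(is.infinite(dfTotal[ok]),
                                 t2 * (1 - 1 / rr) / 2,
                                 (1 + dfTotal[ok]) / 2 *
                                     log((t2 + dfTotal[ok]) /
                                         (t2 / rr + dfTotal[ok])))
                B[ok] <- log(bProportion / (1 - bProportion)) -
                    log(rr) / 2 + kernel
            }
        }
        data.frame(gene_id = genes, contrast = cn, logFC = b, t = tmod,
                   p_raw = pRaw, p_holm = holmAdjust(pRaw),
                   p_bh = stats::p.adjust(pRaw, method = "BH"), B = B,
                   row.names = NULL, stringsAsFactors = FALSE)
    })
    new("ContrastResults", table = do.call(rbind, tabs),
        d0 = d0, s02 = if (is.na(s02)) NA_real_ else s02, rho = fits@rho)
}

#' Holm step-down adjustment
#'
#' Family-wise error-rate control: with p-values sorted ascending,
#' adj_(i) = max_{j <= i} min(1, (m - j + 1) p_(j)), returned in the
#' original order. NA values are left NA and do not count toward the
#' family size.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return adjusted p-values, elementwise >= the input.
#' @examples
#' holmAdjust(c(0.01, 0.04, 0.03))  # 0.03 0.06 0.06
#' @export
holmAdjust <- function(p) {
    ok <- !is.na(p)
    if (any(p[ok] < 0 | p[ok] > 1))
        stop("p-values must lie in [0, 1]")
    out <- p
    out[ok] <- stats::p.adjust(p[ok], method = "holm")
    out
}

#' Select the ARI gene set
#'
#' Union over the three time-point contrasts of the genes with
#' Holm-adjusted p below \code{alpha}; per the study's design no
#' fold-change filter is applied.
#'
#' @param results a \linkS4class{ContrastResults} (or a list of per-contrast
#'   data.frames sharing one gene universe).
#' @param alpha family-wise significance level (default 0.05).
#' @return character vector of selected gene identifiers (in gene order).
#' @export
selectAriGenes <- function(results, alpha = 0.05) {
    tab <- if (is(results, "ContrastResults")) deTable(results)
           else do.call(rbind, results)
    universes <- split(tab$gene_id, tab$contrast)
    u1 <- sort(universes[[1L]])
    for (u in universes[-1L])
        if (!identical(sort(u), u1))
            stop("contrast tables do not share one gene universe")
    hit <- tab$gene_id[!is.na(tab$p_holm) & tab$p_holm < alpha]
    unique(tab$gene_id)[unique(tab$gene_id) %in% hit]
}
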