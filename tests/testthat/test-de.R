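test_that("consensus correlation averages on the atanh scale", {
    # constants average to themselves; the {0.1, 0.3, 0.5} hand value
    expect_equal(tanh(mean(atanh(rep(0.3, 5)))), 0.3)
    z <- tanh(mean(atanh(c(0.1, 0.3, 0.5))))
    expect_equal(z, 0.309, tolerance = 1e-3)
    # the estimator reproduces both through the same transform
    co <- nullCohort(nGenes = 400L, nSubjectsPerGroup = 6L, seed = 2)
    cc <- consensusCorrelation(co, trim = 0)
    expect_equal(consensus(cc),
                 tanh(mean(atanh(perGeneCorrelations(cc)))))
    expect_true(abs(consensus(cc)) < 1)
})

test_that("consensus correlation needs repeated measures", {
    co <- smallCohort()
    ann <- sampleAnnotation(co)
    # one visit per subject, cycling the time points so the design keeps
    # all its cells
    subjects <- unique(ann$subject)
    tps <- unique(ann$timepoint)
    pick <- vapply(seq_along(subjects), function(i)
        ann$sample_id[ann$subject == subjects[i] &
                      ann$timepoint ==
                          tps[(i - 1L) %% length(tps) + 1L]],
        character(1))
    solo <- co[, pick]
    expect_error(consensusCorrelation(solo), "repeated measures")
})

test_that("per-gene correlation estimates agree with limma's consensus", {
    skip_if_not_installed("limma")
    co <- nullCohort(nGenes = 500L, nSubjectsPerGroup = 6L, seed = 8)
    ann <- sampleAnnotation(co)
    design <- stats::model.matrix(
        ~ 0 + factor(paste(ann$group, ann$timepoint)))
    dc <- limma::duplicateCorrelation(
        SummarizedExperiment::assay(co, "log2"), design,
        block = ann$subject)
    ours <- consensus(consensusCorrelation(co))
    expect_lt(abs(ours - dc$consensus.correlation), 0.05)
})

test_that("GLS with rho = 0 reduces exactly to OLS", {
    co <- smallCohort()
    fits <- fitGeneModels(co, rho = 0)
    ann <- sampleAnnotation(co)
    Y <- SummarizedExperiment::assay(co, "log2")
    cell <- paste(ann$group, ann$timepoint, sep = ".")
    for (g in c(1L, 50L, 300L)) {
        ols <- tapply(Y[g, ], cell, mean)
        expect_equal(unname(fits@cellMeans[g, names(ols)]),
                     as.vector(ols), tolerance = 1e-12)
    }
})

test_that("a constant gene yields zero contrasts and zero variance", {
    co <- nullCohort(nGenes = 20L, seed = 3)
    Y <- SummarizedExperiment::assay(co, "log2")
    Y[1L, ] <- 7.25
    SummarizedExperiment::assay(co, "log2") <- Y
    fits <- fitGeneModels(co, rho = 0.3)
    expect_equal(unname(fits@coefficients[1L, ]), rep(0, 3),
                 tolerance = 1e-12)
    expect_equal(unname(fits@sigma2[1L]), 0, tolerance = 1e-12)
})

test_that("paired two-subject toy recovers the mean paired difference", {
    # two subjects in one group with BL and D2 only; the D2-BL cell-mean
    # contrast must equal the average within-subject change whatever rho
    m <- matrix(c(5.0, 6.0, 4.0, 6.5), nrow = 1,
                dimnames = list("g1",
                                c("s1.BL", "s1.D2", "s2.BL", "s2.D2")))
    ann <- data.frame(sample_id = colnames(m),
                      subject = c("s1", "s1", "s2", "s2"),
                      group = "A", timepoint = c("BL", "D2", "BL", "D2"))
    rownames(ann) <- ann$sample_id
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(log2 = rbind(m, g2 = c(1, 2, 3, 4))),
        colData = S4Vectors::DataFrame(ann))
    co <- new("AriCohort", se)
    for (rho in c(0, 0.4)) {
        fits <- suppressWarnings(fitGeneModels(co, rho = rho))
        expect_equal(unname(fits@cellMeans["g1", "A.D2"] -
                            fits@cellMeans["g1", "A.BL"]),
                     mean(c(6.0 - 5.0, 6.5 - 4.0)), tolerance = 1e-10)
    }
})

test_that("GLS coefficients match limma's gls.series", {
    skip_if_not_installed("limma")
    co <- smallCohort(seed = 17L)
    ann <- sampleAnnotation(co)
    cell <- factor(paste(ann$group, ann$timepoint, sep = "."))
    design <- stats::model.matrix(~ 0 + cell)
    colnames(design) <- levels(cell)
    fit <- limma::lmFit(SummarizedExperiment::assay(co, "log2"), design,
                        block = ann$subject, correlation = 0.3)
    ours <- fitGeneModels(co, rho = 0.3)
    expect_equal(unname(ours@cellMeans[, colnames(fit$coefficients)]),
                 unname(fit$coefficients), tolerance = 1e-8)
    expect_equal(unname(ours@sigma2), unname(fit$sigma^2),
                 tolerance = 1e-8)
})

test_that("moderation reproduces the hand-computed posterior", {
    fits <- new("GeneFits",
                coefficients = matrix(1.0, 1, 1,
                                      dimnames = list("g1", "C1")),
                stdevUnscaled = c(C1 = sqrt(0.25)),
                sigma2 = c(g1 = 1.0), df = 4, rho = 0,
                cellMeans = matrix(0, 1, 1), contrasts = "C1")
    res <- moderateStatistics(fits, d0 = 4, s02 = 1.0)
    tab <- deTable(res)
    # posterior variance (4*1 + 4*1)/8 = 1; t = 1/sqrt(1 * 0.25) = 2 on
    # 8 df
    expect_equal(tab$t, 2.0, tolerance = 1e-12)
    expect_equal(tab$p_raw, 2 * pt(-2, df = 8), tolerance = 1e-12)
})

test_that("d0 = 0 gives the ordinary t-statistic", {
    co <- smallCohort(seed = 30L)
    fits <- fitGeneModels(co, rho = 0.3)
    res <- moderateStatistics(fits, d0 = 0)
    tab <- deTable(res)
    cn <- fits@contrasts[1L]
    sub <- tab[tab$contrast == cn, ]
    ordinary <- fits@coefficients[, cn] /
        (sqrt(fits@sigma2) * fits@stdevUnscaled[[cn]])
    expect_equal(sub$t, unname(ordinary), tolerance = 1e-10)
})

test_that("identical variances push d0 to the cap", {
    co <- nullCohort(nGenes = 50L, seed = 12)
    fits <- fitGeneModels(co, rho = 0)
    fits@sigma2[] <- 0.4
    res <- moderateStatistics(fits)
    expect_equal(moderationPrior(res)$d0, 1e6)
    # the posterior variance then returns (essentially) each gene's own
    tab <- deTable(res)
    tt <- tab$t[tab$contrast == fits@contrasts[1L]]
    ordinary <- fits@coefficients[, 1L] /
        (sqrt(0.4) * fits@stdevUnscaled[[1L]])
    expect_equal(tt, unname(ordinary), tolerance = 0.02)
})

test_that("moderation matches limma's squeezeVar prior", {
    skip_if_not_installed("limma")
    co <- nullCohort(nGenes = 800L, seed = 14,
                     nSubjectsPerGroup = 4L)
    # heterogeneous true variances so the prior is informative
    Y <- SummarizedExperiment::assay(co, "log2")
    scalef <- sqrt(stats::rchisq(nrow(Y), df = 5) / 5)
    Y <- Y * scalef
    SummarizedExperiment::assay(co, "log2") <- Y
    fits <- fitGeneModels(co, rho = 0.3)
    sq <- limma::squeezeVar(fits@sigma2, df = fits@df)
    res <- moderateStatistics(fits)
    prior <- moderationPrior(res)
    expect_equal(prior$d0, sq$df.prior, tolerance = 1e-6)
    expect_equal(prior$s02, sq$var.prior, tolerance = 1e-6)
})

test_that("moderated t converges to the ordinary t at large residual df", {
    # with d0 finite, the posterior variance weight of the prior decays
    # as d0/(d0 + d): at d = 200 the moderated and ordinary t differ by
    # under 1% across the bulk of the sampling distribution of s^2
    n <- 400L
    d <- 200
    sigma2 <- stats::qchisq(seq(0.01, 0.99, length.out = n), df = d) / d
    b <- rep(1, n)
    fits <- new("GeneFits",
                coefficients = matrix(b, n, 1,
                    dimnames = list(sprintf("g%03d", 1:n), "C1")),
                stdevUnscaled = c(C1 = 0.3), sigma2 = sigma2,
                df = rep(d, n), rho = 0,
                cellMeans = matrix(0, n, 1), contrasts = "C1")
    res <- moderateStatistics(fits, d0 = 8, s02 = 1)
    tab <- deTable(res)
    ordinary <- b / (sqrt(sigma2) * 0.3)
    expect_lt(max(abs(tab$t - ordinary) / abs(ordinary)), 0.01)
})

test_that("Holm adjustment follows the step-down definition", {
    expect_equal(holmAdjust(c(0.01, 0.04, 0.03)), c(0.03, 0.06, 0.06))
    expect_equal(holmAdjust(c(1, 1)), c(1, 1))
    set.seed(101)
    for (i in 1:50) {
        p <- stats::runif(sample(1:20, 1))
        adj <- holmAdjust(p)
        expect_equal(adj, bruteHolm(p))
        expect_true(all(adj >= p))
        expect_true(all(adj <= 1))
    }
    expect_error(holmAdjust(c(0.1, 1.2)), "\\[0, 1\\]")
})

test_that("ARI selection is the union over contrasts with no FC filter", {
    mk <- function(cn, sig) data.frame(
        gene_id = c("a", "b", "c"), contrast = cn,
        logFC = c(0.01, 5, -3), t = 1,
        p_raw = ifelse(c("a", "b", "c") %in% sig, 1e-5, 0.9),
        p_holm = ifelse(c("a", "b", "c") %in% sig, 1e-4, 1),
        p_bh = 1, B = 0)
    res <- list(mk("c1", c("a", "b")), mk("c2", c("b", "c")),
                mk("c3", character(0)))
    expect_setequal(selectAriGenes(res), c("a", "b", "c"))
    resNull <- list(mk("c1", character(0)), mk("c2", character(0)))
    expect_length(selectAriGenes(resNull), 0L)
    bad <- list(mk("c1", "a"),
                transform(mk("c2", "b"), gene_id = c("a", "b", "zzz")))
    expect_error(selectAriGenes(bad), "universe")
})

test_that("planted effects are selected with high power", {
    co <- simulateCohort(cohortConfig(nGenes = 1200L,
                                      nSubjectsPerGroup = 8L,
                                      coreD2N = 30L, sharedD6N = 30L,
                                      distinctD6N = 0L, seed = 19))
    rho <- consensusCorrelation(co)
    de <- moderateStatistics(fitGeneModels(co, rho))
    ari <- selectAriGenes(de)
    truth <- plantedTruth(co)
    broad <- truth$gene_id[truth$class %in% c("core_d2", "shared_d6")]
    expect_gte(mean(broad %in% ari), 0.95)
})
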