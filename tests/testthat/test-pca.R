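twoGene <- function() {
    m <- rbind(g1 = c(0, 0, 1, 1), g2 = c(0, 0, 2, 2))
    colnames(m) <- paste0("s", 1:4)
    m
}

test_that("covariance PCA matches the hand eigendecomposition", {
    p <- covariancePCA(twoGene())
    expect_equal(varExplained(p)[1L], 1, tolerance = 1e-12)
    lo <- pcaLoadings(p)[, 1L]
    expect_equal(abs(unname(lo)), c(1, 2) / sqrt(5), tolerance = 1e-10)
    sc <- pcaScores(p)[, 1L]
    expect_equal(sort(abs(unname(sc))), rep(sqrt(5) / 2, 4),
                 tolerance = 1e-10)
    # scores are the centered data projected on the loadings
    centered <- t(twoGene()) - rep(colMeans(t(twoGene())),
                                   each = 4)
    expect_equal(unname(centered %*% lo)[, 1L], unname(sc),
                 tolerance = 1e-10)
})

test_that("degenerate and duplicated inputs behave as specified", {
    const <- matrix(5, 3, 4,
                    dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
    expect_error(covariancePCA(const), "zero variance")
    expect_error(covariancePCA(twoGene()[, 1, drop = FALSE]),
                 ">= 2 samples")
    m <- twoGene()
    dup <- cbind(m, m)
    colnames(dup) <- paste0("s", 1:8)
    p1 <- covariancePCA(m)
    p2 <- covariancePCA(dup)
    l1 <- pcaLoadings(p1)[, 1L]
    l2 <- pcaLoadings(p2)[, 1L]
    expect_equal(abs(unname(l1)), abs(unname(l2)), tolerance = 1e-10)
})

test_that("PC1 orientation is a sign convention and an involution", {
    p <- covariancePCA(twoGene())
    # reference = the last two (high) samples: their mean must end up >= 0
    o1 <- orientPC1(p, c("s3", "s4"))
    expect_gte(mean(pcaScores(o1)[c("s3", "s4"), 1L]), 0)
    # orienting to the opposite reference flips scores and loadings
    o2 <- orientPC1(p, c("s1", "s2"))
    expect_gte(mean(pcaScores(o2)[c("s1", "s2"), 1L]), 0)
    expect_equal(pcaScores(o1)[, 1L], -pcaScores(o2)[, 1L])
    expect_equal(pcaLoadings(o1)[, 1L], -pcaLoadings(o2)[, 1L])
    # twice = once
    o11 <- orientPC1(o1, c("s3", "s4"))
    expect_identical(pcaScores(o11), pcaScores(o1))
    expect_error(orientPC1(p, character(0)), "empty")
})

test_that("zero reference mean keeps orientation with a warning", {
    p <- covariancePCA(twoGene())
    expect_warning(o <- orientPC1(p, c("s1", "s3")), "exactly 0")
    expect_equal(abs(pcaScores(o)[, 1L]), abs(pcaScores(p)[, 1L]))
})

test_that("PC1 separation tests dispatch paired and unpaired modes", {
    sA <- c(a1 = 1, a2 = 2, a3 = 3)
    sB <- c(b1 = 4, b2 = 5, b3 = 6)
    un <- testPC1Separation(sA, sB)
    expect_equal(unname(un$statistic), 0)
    expect_equal(un$p.value, 0.1)
    sB2 <- c(b1 = 4, b2 = 6, b3 = 5)
    pairing <- cbind(names(sA), names(sB2))
    pa <- testPC1Separation(sA, sB2, pairing)
    expect_s3_class(pa, "htest")
    expect_equal(unname(pa$statistic),
                 unname(t.test(sA - sB2)$statistic))
    # identical paired vectors: t = 0, p = 1
    same <- testPC1Separation(sA, sA + 0, cbind(names(sA), names(sA)))
    expect_equal(unname(same$statistic), 0)
    expect_equal(same$p.value, 1)
    # constant nonzero differences are degenerate
    expect_error(
        testPC1Separation(sA, sA + 1, cbind(names(sA), names(sA))),
        "degenerate")
    expect_error(testPC1Separation(sA[1], sB), ">= 2")
})

test_that("loading profiles rank by signed loading with lexicographic ties", {
    lo <- matrix(c(0.9, -0.8, 0.5) / sqrt(0.9^2 + 0.8^2 + 0.5^2), 3, 1,
                 dimnames = list(c("g1", "g2", "g3"), NULL))
    sc <- matrix(c(1, 1, -1, -1), 4, 1,
                 dimnames = list(paste0("s", 1:4), NULL))
    pca <- new("AriPCA", scores = sc, loadings = lo,
               varExplained = 1, oriented = TRUE)
    pos <- selectLoadingProfile(pca, c("s1", "s2"), n = 2)
    expect_identical(profileGenes(pos), c("g1", "g3"))
    expect_identical(profileDirection(pos), "positive")
    neg <- selectLoadingProfile(pca, c("s3", "s4"), n = 2)
    expect_identical(profileGenes(neg), c("g2", "g3"))
    expect_identical(profileDirection(neg), "negative")
    all3 <- selectLoadingProfile(pca, c("s1", "s2"), n = 10)
    expect_length(profileGenes(all3), 3L)
    expect_error(selectLoadingProfile(pca, "s1", n = 0), ">= 1")
    # exact ties fall back to lexicographic gene order
    loTie <- matrix(rep(0.5, 4), 4, 1,
                    dimnames = list(c("gb", "ga", "gd", "gc"), NULL))
    pcaTie <- new("AriPCA", scores = sc, loadings = loTie,
                  varExplained = 1, oriented = TRUE)
    tie <- selectLoadingProfile(pcaTie, c("s1", "s2"), n = 2)
    expect_identical(profileGenes(tie), c("ga", "gb"))
})

test_that("membership classification covers core/shared/distinct", {
    mk <- function(g, genes) new("SignatureProfile", group = g,
                                 timepoint = "D2",
                                 direction = "positive", genes = genes,
                                 loadings = rep(0.1, length(genes)))
    profs <- list(H = mk("H", c("a", "b", "c")),
                  AR = mk("AR", c("a", "b", "d")),
                  AN = mk("AN", c("a", "b", "e")),
                  AE = mk("AE", c("a", "f")))
    mem <- classifyMembership(profs)
    tab <- membership(mem)
    expect_equal(tab$class[tab$gene_id == "a"], "core")
    expect_equal(tab$class[tab$gene_id == "b"], "shared:H+AR+AN")
    expect_equal(tab$class[tab$gene_id == "f"], "distinct:AE")
    # region counts add up to the union
    expect_equal(sum(vennRegions(mem)$count), nrow(tab))
    expect_equal(classGenes(mem, "core"), "a")

    ident <- classifyMembership(list(A = mk("A", c("x", "y")),
                                     B = mk("B", c("x", "y"))))
    expect_true(all(membership(ident)$class == "core"))
    disj <- classifyMembership(list(A = mk("A", "x"), B = mk("B", "y")))
    expect_true(all(startsWith(membership(disj)$class, "distinct")))
    expect_error(classifyMembership(list(A = mk("A", "x"),
                                         A = mk("A", "y"))),
                 "duplicate")
})

test_that("rank-1 planted structure is captured by PC1", {
    set.seed(5)
    nG <- 120L; nS <- 12L
    effect <- stats::rnorm(nG)
    state <- rep(c(0, 1), each = nS / 2)
    Y <- outer(effect, state) + matrix(stats::rnorm(nG * nS, 0, 0.01),
                                       nG, nS)
    dimnames(Y) <- list(sprintf("g%03d", 1:nG), sprintf("s%02d", 1:nS))
    p <- covariancePCA(Y)
    expect_gte(varExplained(p)[1L], 0.99)
    rs <- spearmanRank(pcaLoadings(p)[, 1L], effect)
    expect_gte(abs(unname(rs$estimate)), 0.99)
})

test_that("expression-change vs loading correlation is Spearman's", {
    lo <- c(g1 = 0.5, g2 = 0.3, g3 = -0.2, g4 = 0.1)
    expect_equal(unname(
        correlateExpressionWithLoadings(lo, lo)$estimate), 1)
    expect_equal(unname(
        correlateExpressionWithLoadings(-lo, lo)$estimate), -1)
    r <- correlateExpressionWithLoadings(c(g1 = 1, g2 = 2, g3 = 3),
                                         c(g1 = 1, g2 = 1, g3 = 2))
    expect_equal(unname(r$estimate), 0.866, tolerance = 1e-3)
    expect_error(correlateExpressionWithLoadings(c(a = 1, b = 2),
                                                 c(a = 1, b = 2)),
                 ">= 3")
})
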