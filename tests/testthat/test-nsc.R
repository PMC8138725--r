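# The NSC core: soft thresholding, the fit against a brute-force oracle,
# posterior probabilities, the shrinkage path with compound-level CV, and
# threshold selection.

test_that("soft thresholding shrinks toward zero and kills small contrasts", {
    expect_equal(softThreshold(2.0, 3.449), 0)
    expect_equal(softThreshold(-5.0, 3.449), -1.551)
    d <- c(-5, -2, 0, 2, 5)
    expect_equal(softThreshold(d, 0), d)     # delta = 0 is the identity
    expect_equal(softThreshold(d, 3.449), c(-1.551, 0, 0, 0, 1.551))
})

test_that("fit and posteriors match the brute-force oracle to 1e-12", {
    for (seed in 1:25) {
        ps <- makeOracleInstance(nGenes = 2 + seed %% 5,
                                 nSamples = 4 + seed %% 5, seed = seed)
        X <- assay(ps, "log2fc")
        delta <- runif(1, 0, 2)
        fit <- fitNSC(ps, delta = delta)
        or <- oracleFitNSC(X, classLabels(ps), delta)
        expect_equal(fit@overallCentroid, or$xbar, tolerance = 1e-12,
                     ignore_attr = TRUE)
        expect_equal(unname(fit@classCentroids), or$cent, tolerance = 1e-12)
        expect_equal(unname(fit@pooledSD), or$s, tolerance = 1e-12)
        expect_equal(fit@s0, or$s0, tolerance = 1e-12)
        expect_equal(unname(fit@mk), or$mk, tolerance = 1e-12)
        expect_equal(unname(fit@dstat), or$d, tolerance = 1e-12)
        expect_equal(unname(fit@shrunkenDstat), or$dshr, tolerance = 1e-12)
        if (length(survivingGenes(fit))) {
            p <- classProbabilities(fit, ps)
            for (j in seq_len(ncol(X)))
                expect_equal(unname(p[j, ]), oracleProbs(or, X[, j]),
                             tolerance = 1e-12)
        }
    }
})

test_that("degenerate inputs are refused", {
    # identical profile pairs within each class: zero within-class variance
    X <- matrix(c(1, 3, 1, 3, 2, 4, 2, 4), 2, 4,
                dimnames = list(c("G1", "G2"), sprintf("c%d", 1:4)))
    ps <- makePS(X, rep(c("HDACi", "non-HDACi"), each = 2))
    expect_error(fitNSC(ps), "zero within-class variance")

    set.seed(2)
    Y <- matrix(rnorm(9), 3, 3)
    expect_error(fitNSC(makePS(Y, c("HDACi", "HDACi", "non-HDACi"))),
                 ">= 2 profiles")
    expect_error(fitNSC(makePS(Y, rep("HDACi", 3))), "2 classes")
})

test_that("posteriors sum to one and respect symmetry", {
    ps <- makeOracleInstance(5, 8, seed = 99)
    fit <- fitNSC(ps, delta = 0.3)
    p <- classProbabilities(fit, ps)
    expect_true(all(abs(rowSums(p) - 1) < 1e-12))

    # profile equidistant from both shrunken centroids, uniform priors
    sc <- shrunkenCentroids(fit)
    mid <- makePS(matrix((sc[, 1] + sc[, 2]) / 2, ncol = 1,
                         dimnames = list(rownames(sc), "mid")), "unknown")
    expect_equal(unname(classProbabilities(fit, mid)[1, ]), c(0.5, 0.5),
                 tolerance = 1e-12)
})

test_that("the 90% rule is strict and binary", {
    fit <- fitNSC(makeOracleInstance(4, 8, seed = 3), delta = 0)
    # exact-boundary and sub-boundary probabilities map to non-HDACi
    fake <- data.frame(p = c(0.95, 0.9, 0.55))
    calls <- ifelse(fake$p > 0.9, "HDACi", "non-HDACi")
    expect_identical(calls, c("HDACi", "non-HDACi", "non-HDACi"))
    # and the implementation applies the same strict rule end to end
    ps <- makeOracleInstance(4, 8, seed = 3)
    res <- classifyNSC(fit, ps, cutoff = 0.9)
    expect_identical(res$call,
                     ifelse(res$p_hdaci > 0.9, "HDACi", "non-HDACi"))
})

test_that("delta = 0 with uniform priors is nearest-centroid in
           standardized distance", {
    ps <- makeOracleInstance(5, 8, seed = 17)
    fit <- fitNSC(ps, delta = 0)
    sc <- shrunkenCentroids(fit)
    denom <- fit@pooledSD + fit@s0
    X <- assay(ps, "log2fc")
    p <- classProbabilities(fit, ps)
    for (j in seq_len(ncol(X))) {
        d2 <- colSums(((X[, j] - sc) / denom)^2)
        expect_identical(unname(which.max(p[j, ])), unname(which.min(d2)))
    }
})

test_that("surviving-gene count is non-increasing in the shrinkage", {
    for (seed in c(5, 6, 7)) {
        fit <- fitNSC(makeOracleInstance(6, 8, seed = seed), delta = 0)
        grid <- sort(runif(20, 0, max(abs(fit@dstat)) * 1.1))
        counts <- vapply(grid, function(d)
            length(survivingGenes(reshrink(fit, d))), integer(1))
        expect_true(all(diff(counts) <= 0))
    }
    # fully shrunken model refuses to classify
    fit <- fitNSC(makeOracleInstance(3, 6, seed = 2), delta = 0)
    dead <- reshrink(fit, max(abs(fit@dstat)) + 1)
    expect_length(survivingGenes(dead), 0)
    expect_error(classProbabilities(dead, makeOracleInstance(3, 6, 2)),
                 "fully shrunken")
})

test_that("CV folds are compound-level, class-stratified, and the path is
           coherent", {
    sim <- makePanelSim(seed = 101)
    ref <- sim$profiles
    path <- shrinkagePath(ref, nfolds = 10, seed = 7)
    # 20 compounds, 10 folds: 2 per fold, one of each class
    folds <- path@foldAssignment
    expect_true(all(table(folds) == 2))
    byClass <- table(folds, classLabels(ref)[match(names(folds),
                                                   compoundNames(ref))])
    expect_true(all(byClass == 1))
    # delta = 0 entry keeps every gene with a nonzero contrast
    fit0 <- fitNSC(ref, delta = 0)
    expect_identical(path@genesSurviving[1],
                     length(survivingGenes(fit0)))
    # well-separated data: perfect CV accuracy at no shrinkage and while the
    # panel keeps most of its genes; heavy shrinkage pulls the centroids
    # together and the strict 90% rule then degrades accuracy before the
    # panel is empty
    expect_equal(path@cvAccuracy[1], 1)
    expect_true(all(path@cvAccuracy[path@genesSurviving ==
                                    max(path@genesSurviving)] == 1))
    expect_true(all(diff(path@genesSurviving) <= 0))
    expect_error(shrinkagePath(ref, nfolds = 30, seed = 1), "folds")
})

test_that("threshold selection prefers the smallest in-range panel", {
    mkPath <- function(thr, genes, acc)
        new("ShrinkagePath", thresholds = thr, genesSurviving = genes,
            cvAccuracy = acc, foldAssignment = setNames(integer(0),
                                                        character(0)),
            nfolds = 10L)
    p1 <- mkPath(c(1, 2, 3), c(500L, 120L, 81L), c(1, 1, 1))
    expect_equal(selectShrinkage(p1)$delta, 3)

    # two in-range thresholds at equal accuracy: the larger shrinkage wins
    p2 <- mkPath(c(1, 2, 3), c(500L, 90L, 60L), c(1, 1, 1))
    expect_equal(selectShrinkage(p2)$delta, 3)

    # accuracy met only out of range: nearest gene count, with a warning
    p3 <- mkPath(c(1, 2), c(200L, 110L), c(1, 1))
    expect_warning(sel <- selectShrinkage(p3), "nearest")
    expect_equal(sel$genes, 110L)

    p4 <- mkPath(c(1, 2), c(80L, 60L), c(0.5, 0.6))
    expect_error(selectShrinkage(p4), "0.6")
})
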