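# PCA and clustering prongs, and the combined three-pronged call.

refSim <- function(seed = 201, ...) {
    sim <- makePanelSim(seed = seed, ...)
    sim$profiles
}

test_that("PCA projection is an identity on reference profiles", {
    ref <- refSim()
    res <- pcaClassify(ref, ref)
    expect_equal(res$pc1_score,
                 unname(attr(res, "reference_scores")[res$compound]),
                 tolerance = 1e-10)
    truth <- classLabels(ref)
    expect_identical(res$call, truth)
})

test_that("PCA calls are invariant to centering shifts and reference order", {
    ref <- refSim(seed = 202)
    q <- refSim(seed = 203, nRef = c(0, 0), nVal = c(4, 7))
    base <- pcaClassify(ref, q)

    shifted <- ProfileSet(assay(ref, "log2fc") + 1.7,
                          compound = compoundNames(ref),
                          class_label = classLabels(ref))
    qShift <- ProfileSet(assay(q, "log2fc") + 1.7,
                         compound = compoundNames(q),
                         class_label = classLabels(q))
    sh <- pcaClassify(shifted, qShift)
    expect_equal(sh$pc1_score, base$pc1_score, tolerance = 1e-8)
    expect_identical(sh$call, base$call)

    perm <- sample(ncol(ref))
    reord <- pcaClassify(ref[, perm], q)
    expect_equal(reord$pc1_score, base$pc1_score, tolerance = 1e-8)
    expect_identical(reord$call, base$call)
})

test_that("synthetic validation compounds all land on the correct PC1 side", {
    sim <- makePanelSim(seed = 204, nRef = c(10, 10), nVal = c(4, 7))
    ref <- sim$profiles[, sim$truth$role == "reference"]
    val <- sim$profiles[, sim$truth$role == "validation"]
    res <- pcaClassify(ref, val)
    expect_identical(res$call,
                     sim$truth$class_label[sim$truth$role == "validation"])
})

test_that("PCA has no systematic class bias under the null", {
    # both classes drawn from the same distribution: long-run call frequency
    # for either class is 0.5 +/- 0.1
    ref <- refSim(seed = 205, effectScale = 0)
    q <- refSim(seed = 206, nRef = c(100, 100), nVal = c(0, 0),
                effectScale = 0)
    res <- suppressWarnings(pcaClassify(ref, q))
    expect_gt(mean(res$call == "HDACi"), 0.4)
    expect_lt(mean(res$call == "HDACi"), 0.6)
})

test_that("clustering prong recovers classes on separated data", {
    # half the panel's between-compound noise: cleanly separated classes
    ref <- refSim(seed = 207, geneSD = builtinBiomarker()@sd * 0.5)
    # every reference, queried against the full reference set, gets its class
    res <- hclustClassify(ref, ref)
    expect_identical(res$call, classLabels(ref))

    # query at the HDACi class centroid
    asset <- builtinBiomarker()
    cent <- makePS(matrix(asset@centroids[, "HDACi"], ncol = 1,
                          dimnames = list(asset@genes, "query")), "unknown")
    expect_identical(hclustClassify(ref, cent)$call, "HDACi")

    # reference-only tree: the 2-cut reproduces the class partition
    pt <- profileTree(ref)
    split <- table(pt$cluster, classLabels(ref))
    expect_true(all(rowSums(split > 0) == 1))
})

test_that("three-pronged classification composes and flags concordance", {
    sim <- makePanelSim(seed = 208, nRef = c(10, 10), nVal = c(4, 7))
    ref <- sim$profiles[, sim$truth$role == "reference"]
    model <- assetToModel(builtinBiomarker())

    asset <- builtinBiomarker()
    cent <- makePS(matrix(asset@centroids[, "HDACi"], ncol = 1,
                          dimnames = list(asset@genes, "centroid")),
                   "unknown")
    res <- classifyCompounds(model, ref, cent)
    expect_identical(res$nsc_call, "HDACi")
    expect_identical(res$pca_call, "HDACi")
    expect_identical(res$hclust_call, "HDACi")
    expect_identical(res$ensemble_call, "HDACi")
    expect_true(res$concordant)

    # a null (all-zero) profile is never called HDACi by the 90% rule
    zero <- makePS(matrix(0, 19, 1, dimnames = list(asset@genes, "null")),
                   "unknown")
    res0 <- classifyCompounds(model, ref, zero)
    expect_identical(res0$nsc_call, "non-HDACi")
    expect_identical(res0$ensemble_call, "non-HDACi")
})

test_that("heatmap export has the plot-ready layout and round-trips", {
    sim <- makePanelSim(seed = 209, nRef = c(10, 10), nVal = c(4, 7))
    ps <- sim$profiles
    calls <- sim$truth$class_label
    tab <- exportHeatmapMatrix(ps, geneSymbols(ps), calls,
                               truth = sim$truth$class_label)
    expect_equal(dim(tab), c(19 + 2, 31 + 1))
    expect_identical(tab$row[1:2], c("call", "truth"))

    f <- tempfile()
    write.table(tab, f, sep = "\t", quote = FALSE, row.names = FALSE)
    back <- read.delim(f, check.names = FALSE, colClasses = "character")
    expect_identical(dim(back), dim(tab))
    num <- as.numeric(as.matrix(back[-(1:2), -1]))
    expect_equal(num, as.vector(assay(ps, "log2fc")), tolerance = 1e-12)

    empty <- ps[, 0]
    tab0 <- exportHeatmapMatrix(empty, geneSymbols(ps), character(0))
    expect_equal(ncol(tab0), 1L)

    expect_error(exportHeatmapMatrix(ps, c("BMF", "NOPE"), calls), "NOPE")
})
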