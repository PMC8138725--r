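# Preprocessing chain: CPM conservation, control ratios, replicate
# averaging, and the QC rules (negative-control share, reference
# correlations, dissimilarity-based outlier removal).

.rawCM <- function(counts, meta = NULL) CountMatrix(counts, meta, unit = "raw")

test_that("CPM normalization scales every column to one million", {
    m <- matrix(c(500, 999500), 2, 1, dimnames = list(c("A", "B"), "s1"))
    expect_equal(assay(cpmNormalize(.rawCM(m)), "counts")["A", "s1"], 500)

    m2 <- matrix(c(1, 1, 2), 3, 1, dimnames = list(c("A", "B", "C"), "s1"))
    expect_equal(unname(assay(cpmNormalize(.rawCM(m2)), "counts")[, 1]),
                 c(250000, 250000, 500000))

    set.seed(1)
    big <- matrix(rpois(600, 40), 30, 20,
                  dimnames = list(sprintf("G%d", 1:30), sprintf("s%d", 1:20)))
    cs <- colSums(assay(cpmNormalize(.rawCM(big)), "counts"))
    expect_true(all(abs(cs - 1e6) < 1e-6 * 1e6))

    zero <- matrix(c(1, 0), 1, 2, dimnames = list("A", c("ok", "empty")))
    expect_error(cpmNormalize(.rawCM(zero)), "empty")
    expect_error(cpmNormalize(cpmNormalize(.rawCM(m))), "raw")
})

.metaFor <- function(treated, ctrl = "ctl") {
    DataFrame(sample_id = c(treated, ctrl),
              compound = c(sub("_r[0-9]+$", "", treated), "DMSO"),
              class_label = c(rep("HDACi", length(treated)), "control"),
              replicate = c(seq_along(treated), 1L),
              vehicle_control_id = c(rep(ctrl, length(treated)), ""),
              batch = "b1", row.names = c(treated, ctrl))
}

test_that("control normalization computes pseudocounted log2 ratios", {
    cpm <- matrix(c(8, 2), 1, 2, dimnames = list("A", c("t1", "ctl")))
    cm <- CountMatrix(cpm, .metaFor("t1"), unit = "cpm")
    expect_equal(unname(assay(normalizeToControl(cm, pseudocount = 0),
                              "log2fc")[1, 1]), 2)

    # treated identical to control -> identically zero
    same <- matrix(c(5, 9, 5, 9), 2, 2,
                   dimnames = list(c("A", "B"), c("t1", "ctl")))
    cmSame <- CountMatrix(same, .metaFor("t1"), unit = "cpm")
    expect_true(all(assay(normalizeToControl(cmSame), "log2fc") == 0))

    # pseudocount symmetry: 0 vs 0 -> 0
    zz <- matrix(c(0, 1, 0, 1), 2, 2,
                 dimnames = list(c("A", "B"), c("t1", "ctl")))
    cmZ <- CountMatrix(zz, .metaFor("t1"), unit = "cpm")
    expect_equal(unname(assay(normalizeToControl(cmZ, 0.5), "log2fc")["A", 1]),
                 0)

    # missing control is a hard error
    bad <- CountMatrix(cpm, DataFrame(
        sample_id = c("t1", "ctl"), compound = c("TSA", "DMSO"),
        class_label = c("HDACi", "control"), replicate = c(1L, 1L),
        vehicle_control_id = c("", ""), batch = "b1",
        row.names = c("t1", "ctl")), unit = "cpm")
    expect_error(normalizeToControl(bad), "vehicle control")
    expect_error(normalizeToControl(.rawCM(cpm, .metaFor("t1"))), "CPM")
})

test_that("replicate averaging is a permutation-invariant arithmetic mean", {
    X <- matrix(c(1, 2, 3), 1, 3,
                dimnames = list("A", c("c_r1", "c_r2", "c_r3")))
    ps <- ProfileSet(X, compound = rep("c", 3), class_label = "HDACi",
                     replicate = 1:3)
    expect_equal(unname(assay(averageReplicates(ps), "log2fc")[1, 1]), 2)

    perm <- ps[, c(3, 1, 2)]
    expect_equal(assay(averageReplicates(perm), "log2fc"),
                 assay(averageReplicates(ps), "log2fc"))

    single <- ps[, 1]
    expect_warning(avg <- averageReplicates(single), "single surviving")
    expect_equal(unname(assay(avg, "log2fc")[1, 1]), 1)
})

test_that("negative-control share uses the strict 0.3% rule", {
    m <- matrix(c(100, 100, 0, 0), 2, 2,
                dimnames = list(c("A", "B"), c("t1", "w1")))
    res <- qcNegativeControl(.rawCM(m), "w1")
    expect_equal(res$fraction, 0)
    expect_true(res$pass)

    # share exactly 0.3% is flagged (< is strict)
    m2 <- matrix(c(997, 3), 1, 2, dimnames = list("A", c("t1", "w1")))
    expect_false(qcNegativeControl(.rawCM(m2), "w1")$pass)

    m3 <- matrix(c(999, 1), 1, 2, dimnames = list("A", c("t1", "w1")))
    res3 <- qcNegativeControl(.rawCM(m3), "w1")
    expect_equal(res3$fraction, 0.001, tolerance = 1e-12)
    expect_true(res3$pass)

    expect_warning(res4 <- qcNegativeControl(.rawCM(m), "absent"), "skipped")
    expect_true(is.na(res4$fraction))
})

test_that("reference correlations are scale-invariant on log2 CPM", {
    set.seed(11)
    base <- rpois(5000, 60)
    m <- cbind(a = base, b = 2L * base, n1 = rpois(5000, 60),
               n2 = rpois(5000, 60))
    rownames(m) <- sprintf("G%d", 1:5000)
    cm <- .rawCM(m)
    r <- qcReferenceCorrelation(cm, rbind(c("a", "a"), c("a", "b"),
                                          c("n1", "n2")))
    expect_equal(unname(r[1]), 1)
    expect_equal(unname(r[2]), 1, tolerance = 1e-12)  # 2x library: same CPM
    expect_lt(abs(r[3]), 0.05)                        # independent noise

    const <- matrix(c(1, 1, 1, 2), 2, 2, dimnames = list(c("A", "B"),
                                                         c("c1", "t")))
    expect_warning(rc <- qcReferenceCorrelation(.rawCM(const),
                                                rbind(c("c1", "t"))),
                   "constant")
    expect_true(is.na(rc[1]))
})

test_that("dissimilarity screen removes exactly the planted outliers", {
    set.seed(21)
    pattern <- rnorm(50, 0, 2)
    # three identical replicates: nothing removed
    X <- matrix(pattern, 50, 3,
                dimnames = list(sprintf("G%d", 1:50),
                                c("c_r1", "c_r2", "c_r3")))
    ps <- ProfileSet(X, compound = rep("c", 3), class_label = "HDACi",
                     replicate = 1:3)
    res <- removeOutliers(ps)
    expect_identical(outliersRemoved(res$report), character(0))
    expect_true(all(res$report@dissimilarity < 1e-12))

    # a replicate anticorrelated with its group: dissimilarity ~ 2, removed
    Xa <- cbind(X[, 1:2], c_r3 = -pattern)
    psa <- ProfileSet(Xa, compound = rep("c", 3), class_label = "HDACi",
                      replicate = 1:3)
    resa <- removeOutliers(psa)
    expect_identical(outliersRemoved(resa$report), "c_r3")
    expect_gt(resa$report@dissimilarity[["c_r3"]], 0.2)

    # planted noisy outlier (5x noise SD) among clean replicate groups
    set.seed(22)
    G <- 100
    mu1 <- rnorm(G, 0, 2); mu2 <- rnorm(G, 0, 2)
    mk <- function(mu, sdev) mu + rnorm(G, 0, sdev)
    Xp <- cbind(a_r1 = mk(mu1, .2), a_r2 = mk(mu1, .2), a_r3 = mk(mu1, 2.5),
                b_r1 = mk(mu2, .2), b_r2 = mk(mu2, .2), b_r3 = mk(mu2, .2))
    rownames(Xp) <- sprintf("G%d", 1:G)
    psp <- ProfileSet(Xp, compound = rep(c("a", "b"), each = 3),
                      class_label = "HDACi", replicate = rep(1:3, 2))
    resp <- removeOutliers(psp)
    expect_identical(outliersRemoved(resp$report), "a_r3")
})

test_that("the preprocessing pipeline is deterministic", {
    cfg <- simConfig(seed = 33, countLayer = TRUE, nReference = c(2, 2),
                     nValidation = c(0, 0))
    cm <- simulateCounts(cfg)$counts
    r1 <- preprocessCounts(cm, waterSamples = c("water_1", "water_2"))
    r2 <- preprocessCounts(cm, waterSamples = c("water_1", "water_2"))
    expect_identical(assay(r1$profiles, "log2fc"),
                     assay(r2$profiles, "log2fc"))
    expect_identical(r1$report@dissimilarity, r2$report@dissimilarity)
})

test_that("a removed replicate leaves the mean of the surviving two", {
    # three replicates, one garbage: the screen drops it and averaging uses
    # the remaining pair
    set.seed(44)
    G <- 80
    mu <- rnorm(G, 0, 1.5)
    clean1 <- mu + rnorm(G, 0, 0.2); clean2 <- mu + rnorm(G, 0, 0.2)
    garbage <- rnorm(G, 0, 3)
    mu2 <- rnorm(G, 0, 1.5)
    X <- cbind(pra_r1 = clean1, pra_r2 = clean2, pra_r3 = garbage,
               oth_r1 = mu2 + rnorm(G, .0, .2), oth_r2 = mu2 + rnorm(G, 0, .2),
               oth_r3 = mu2 + rnorm(G, 0, .2))
    rownames(X) <- sprintf("G%d", 1:G)
    ps <- ProfileSet(X, compound = rep(c("pra", "oth"), each = 3),
                     class_label = c(rep("HDACi", 3), rep("non-HDACi", 3)),
                     replicate = rep(1:3, 2))
    res <- removeOutliers(ps)
    expect_identical(outliersRemoved(res$report), "pra_r3")
    avg <- averageReplicates(res$profiles)
    expect_equal(assay(avg, "log2fc")[, "pra"], (clean1 + clean2) / 2,
                 tolerance = 1e-12, ignore_attr = TRUE)
})
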