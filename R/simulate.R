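# Synthetic compound-exposure data with the statistical structure the
# classifier assumes: per-gene Gaussian class means on the log2 fold-change
# scale, compound-level per-gene noise, within-compound replicate noise, and
# an optional Poisson count layer (control CPM -> treated CPM = control *
# 2^log2fc -> counts) that exercises the whole preprocessing chain including
# vehicle controls, water-only negative controls and duplicated
# reference-RNA QC samples.

#' Build a simulation configuration
#'
#' Defaults mirror the reference study design: class means and per-gene SDs
#' from the packaged 19-gene panel, 10+10 reference and 4+7 validation
#' compounds, 3 replicates each. The baseline (\code{overallMean}) is zero —
#' no transcriptional response — so \code{effectScale = 0} generates null
#' compounds and \code{effectScale = 1} places class means exactly at the
#' panel centroids.
#'
#' @param classCentroids genes x 2 matrix (\code{HDACi}, \code{non-HDACi});
#'   default: the packaged panel centroids.
#' @param geneSD per-gene between-compound SD; default: the panel SD column.
#' @param overallMean per-gene baseline, default 0.
#' @param nBackground number of extra genes with zero class contrast,
#'   default 0.
#' @param backgroundSD SD of background genes, default 1.
#' @param nReference,nValidation integer length-2 cohort sizes
#'   (HDACi, non-HDACi); defaults \code{c(10, 10)} and \code{c(4, 7)}.
#' @param nReplicates replicates per compound, default 3.
#' @param replicateSD within-compound SD, default 0.3.
#' @param effectScale multiplier on the class contrast, default 1.
#' @param seed integer seed (mandatory).
#' @param countLayer also emit Poisson counts, default \code{FALSE}.
#' @param librarySize expected reads per sample in the count layer,
#'   default 1e6.
#' @param phi negative-binomial overdispersion for the count layer
#'   (0 = Poisson, the default).
#' @return A \linkS4class{SimConfig}.
#' @export
simConfig <- function(classCentroids = NULL, geneSD = NULL, overallMean = 0,
                      nBackground = 0, backgroundSD = 1,
                      nReference = c(10, 10), nValidation = c(4, 7),
                      nReplicates = 3, replicateSD = 0.3, effectScale = 1,
                      seed, countLayer = FALSE, librarySize = 1e6, phi = 0) {
    if (missing(seed)) stop("a seed is mandatory", call. = FALSE)
    if (is.null(classCentroids) || is.null(geneSD)) {
        asset <- builtinBiomarker()
        if (is.null(classCentroids)) classCentroids <- asset@centroids
        if (is.null(geneSD)) geneSD <- setNames(asset@sd, asset@genes)
    }
    G <- nrow(classCentroids)
    new("SimConfig", classCentroids = classCentroids,
        geneSD = rep_len(geneSD, G), overallMean = rep_len(overallMean, G),
        nBackground = as.integer(nBackground), backgroundSD = backgroundSD,
        nReference = as.integer(rep_len(nReference, 2L)),
        nValidation = as.integer(rep_len(nValidation, 2L)),
        nReplicates = as.integer(nReplicates), replicateSD = replicateSD,
        effectScale = effectScale, seed = as.integer(seed),
        countLayer = countLayer, librarySize = librarySize, phi = phi)
}

.simGeneNames <- function(cfg) {
    c(rownames(cfg@classCentroids),
      if (cfg@nBackground > 0)
          sprintf("BG%04d", seq_len(cfg@nBackground)))
}

# Truth table + replicate-level log2fc draws shared by the profile and count
# layers so both emit the same underlying compounds.
.simDraw <- function(cfg) {
    set.seed(cfg@seed)
    genes <- .simGeneNames(cfg)
    G <- length(genes)
    panel <- nrow(cfg@classCentroids)
    counts <- c(HDACi_ref = cfg@nReference[1], nonHDACi_ref = cfg@nReference[2],
                HDACi_val = cfg@nValidation[1], nonHDACi_val = cfg@nValidation[2])
    truth <- data.frame(
        compound = unlist(mapply(function(pre, n) sprintf("%s_%02d", pre,
                                 seq_len(n)), names(counts), counts,
                                 SIMPLIFY = FALSE), use.names = FALSE),
        class_label = rep(c("HDACi", "non-HDACi", "HDACi", "non-HDACi"),
                          counts),
        role = rep(c("reference", "reference", "validation", "validation"),
                   counts),
        stringsAsFactors = FALSE)
    nC <- nrow(truth)
    geneSD <- c(cfg@geneSD, rep(cfg@backgroundSD, cfg@nBackground))
    overall <- c(cfg@overallMean, rep(0, cfg@nBackground))
    compoundMeans <- matrix(NA_real_, G, nC, dimnames = list(genes,
                                                             truth$compound))
    for (j in seq_len(nC)) {
        contrast <- c(cfg@classCentroids[, truth$class_label[j]] -
                      cfg@overallMean, rep(0, cfg@nBackground))
        compoundMeans[, j] <- overall + cfg@effectScale * contrast +
            rnorm(G, 0, geneSD)
    }
    reps <- matrix(NA_real_, G, nC * cfg@nReplicates)
    repCompound <- rep(truth$compound, each = cfg@nReplicates)
    repIndex <- rep(seq_len(cfg@nReplicates), times = nC)
    colnames(reps) <- sprintf("%s_r%d", repCompound, repIndex)
    for (j in seq_len(ncol(reps)))
        reps[, j] <- compoundMeans[, match(repCompound[j], truth$compound)] +
            rnorm(G, 0, cfg@replicateSD)
    list(truth = truth, genes = genes, compoundMeans = compoundMeans,
         reps = reps, repCompound = repCompound, repIndex = repIndex)
}

#' Simulate replicate-averaged compound profiles
#'
#' Each compound's per-gene mean is drawn around
#' \code{overallMean + effectScale * (class centroid - overallMean)} with SD
#' \code{geneSD}; replicates add \code{replicateSD} noise and are averaged.
#' Background genes carry zero class contrast. Deterministic given the seed.
#'
#' @param cfg A \linkS4class{SimConfig}.
#' @return list with \code{profiles} (a per-compound
#'   \linkS4class{ProfileSet} over reference + validation compounds) and
#'   \code{truth} (data.frame: compound, class_label, role).
#' @examples
#' sim <- simulateProfiles(simConfig(seed = 1))
#' sim$profiles
#' @export
simulateProfiles <- function(cfg) {
    stopifnot(is(cfg, "SimConfig"))
    draw <- .simDraw(cfg)
    prof <- matrix(NA_real_, length(draw$genes), nrow(draw$truth),
                   dimnames = list(draw$genes, draw$truth$compound))
    for (j in seq_len(ncol(prof)))
        prof[, j] <- rowMeans(draw$reps[, draw$repCompound ==
                              draw$truth$compound[j], drop = FALSE])
    list(profiles = ProfileSet(prof, compound = draw$truth$compound,
                               class_label = draw$truth$class_label),
         truth = draw$truth)
}

#' Simulate a raw count matrix with controls and QC samples
#'
#' Control expected CPM is drawn log-normally per gene and scaled to sum to
#' 1e6; a treated replicate's expected CPM is the control CPM times
#' \code{2^log2fc} for that replicate's drawn value, renormalized to sum to
#' 1e6 (CPM is compositional, so the recoverable fold changes carry a
#' per-sample renormalization; the recorded truth is on this CPM scale).
#' Counts are Poisson with mean \code{expected CPM * librarySize / 1e6}
#' (negative-binomial when \code{phi > 0}). The design includes one matched vehicle-control sample
#' per replicate slot, two water-only negative controls with near-zero
#' expected signal, and duplicated reference-RNA QC samples, all in one
#' batch.
#'
#' @param cfg A \linkS4class{SimConfig} with \code{countLayer = TRUE}.
#' @return list with \code{counts} (a raw \linkS4class{CountMatrix} whose
#'   \code{colData} holds the full sample metadata) and \code{truth}
#'   (data.frame with the generating replicate-averaged log2fc in attribute
#'   \code{"log2fc"}).
#' @export
simulateCounts <- function(cfg) {
    stopifnot(is(cfg, "SimConfig"))
    if (!cfg@countLayer)
        stop("simulateCounts needs countLayer = TRUE", call. = FALSE)
    draw <- .simDraw(cfg)
    G <- length(draw$genes)
    baseCPM <- rlnorm(G, meanlog = log(50), sdlog = 1.5)
    baseCPM <- baseCPM / sum(baseCPM) * 1e6
    L <- cfg@librarySize
    rcount <- function(mu) {
        if (cfg@phi > 0)
            rpois(length(mu), mu * stats::rgamma(length(mu),
                  shape = 1 / cfg@phi, scale = cfg@phi))
        else rpois(length(mu), mu)
    }
    ctrlNames <- sprintf("control_r%d", seq_len(cfg@nReplicates))
    ctrl <- vapply(ctrlNames, function(nm) rcount(baseCPM * L / 1e6),
                   numeric(G))
    # Expected treated CPM is compositional: scaling by 2^log2fc changes the
    # library total, and CPM by definition sums to 1e6, so the fold changes
    # recoverable from CPM ratios carry a per-sample renormalization. The
    # recorded truth is on this (recoverable) CPM scale.
    treatedMu <- apply(baseCPM * 2^draw$reps, 2L,
                       function(mu) mu / sum(mu) * 1e6)
    treated <- apply(treatedMu, 2L, function(mu) rcount(mu * L / 1e6))
    colnames(treated) <- colnames(draw$reps)
    waterNames <- c("water_1", "water_2")
    water <- vapply(waterNames, function(nm)
        rcount(rep(0.002 * L / 1e6 * 1e6 / G, G)), numeric(G))
    qcMu <- baseCPM[sample.int(G)]
    qcNames <- c("refRNA_1", "refRNA_2")
    qc <- vapply(qcNames, function(nm) rcount(qcMu * L / 1e6), numeric(G))
    counts <- cbind(treated, ctrl, water, qc)
    rownames(counts) <- draw$genes
    meta <- DataFrame(
        sample_id = colnames(counts),
        compound = c(draw$repCompound, rep("vehicle", cfg@nReplicates),
                     rep("water", 2L), rep("refRNA", 2L)),
        class_label = c(rep(draw$truth$class_label,
                            each = cfg@nReplicates),
                        rep("control", cfg@nReplicates), rep("qc", 4L)),
        replicate = c(draw$repIndex, seq_len(cfg@nReplicates), 1:2, 1:2),
        vehicle_control_id = c(ctrlNames[draw$repIndex],
                               rep("", cfg@nReplicates + 4L)),
        batch = "b1",
        row.names = colnames(counts))
    cpmScale <- log2(treatedMu / baseCPM)
    avg <- vapply(draw$truth$compound, function(cp)
        rowMeans(cpmScale[, draw$repCompound == cp, drop = FALSE]),
        numeric(G))
    truth <- draw$truth
    attr(truth, "log2fc") <- avg
    list(counts = CountMatrix(counts, sampleData = meta, unit = "raw"),
         truth = truth)
}

#' Tiny labeled instance for brute-force oracles
#'
#' Emits a small two-class profile set (at most 6 genes by 8 profiles)
#' suitable for checking an NSC implementation against a literal
#' transcription of the formulas. Deterministic given the seed.
#'
#' @param nGenes number of genes, <= 6.
#' @param nSamples number of profiles, 4..8 (at least 2 per class).
#' @param seed integer seed.
#' @return A labeled \linkS4class{ProfileSet}.
#' @export
makeOracleInstance <- function(nGenes, nSamples, seed) {
    stopifnot(nGenes >= 1, nGenes <= 6, nSamples >= 4, nSamples <= 8)
    set.seed(seed)
    sizes <- 2:(nSamples - 2L)
    nH <- sizes[sample.int(length(sizes), 1L)]
    labels <- c(rep("HDACi", nH), rep("non-HDACi", nSamples - nH))
    shift <- rnorm(nGenes, 0, 1.5)
    X <- matrix(rnorm(nGenes * nSamples), nGenes, nSamples,
                dimnames = list(sprintf("G%d", seq_len(nGenes)),
                                sprintf("cpd%02d", seq_len(nSamples))))
    X[, labels == "HDACi"] <- X[, labels == "HDACi"] + shift
    ProfileSet(X, compound = colnames(X), class_label = labels)
}
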