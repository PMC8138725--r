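#' @import methods
#' @importFrom stats cor dist hclust cutree prcomp median rnorm rpois rlnorm
#'   runif sd setNames predict
#' @importFrom utils read.delim write.table packageVersion
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#'   colData colData<-
#' @importFrom S4Vectors DataFrame metadata metadata<-
NULL

## Class-label vocabulary used throughout: treated samples carry the compound
## class, everything else is bookkeeping.
.CLASS_LEVELS <- c("HDACi", "non-HDACi", "control", "qc", "unknown")
.TREATED_LEVELS <- c("HDACi", "non-HDACi")
.META_COLUMNS <- c("sample_id", "compound", "class_label", "replicate",
                   "vehicle_control_id", "batch")

# ---------------------------------------------------------------------------
# CountMatrix
# ---------------------------------------------------------------------------

#' Gene-by-sample count container
#'
#' A \code{CountMatrix} is a \linkS4class{SummarizedExperiment} holding one
#' assay named \code{"counts"}: a non-negative gene-by-sample matrix of raw
#' read counts or counts-per-million (CPM), with the unit recorded in
#' \code{metadata(x)$unit}. Sample metadata (compound, class label, replicate,
#' matched vehicle control, batch) lives in \code{colData}.
#'
#' @slot .  Inherits all slots from \code{SummarizedExperiment}.
#' @seealso \code{\link{readCountMatrix}}, \code{\link{cpmNormalize}}
#' @export
setClass("CountMatrix", contains = "SummarizedExperiment")

.validCountMatrix <- function(object) {
    msg <- character()
    if (!identical(assayNames(object), "counts"))
        msg <- c(msg, "assay must be a single matrix named 'counts'")
    v <- assay(object, "counts")
    if (is.null(rownames(v)) || is.null(colnames(v)))
        msg <- c(msg, "counts must carry gene rownames and sample colnames")
    if (anyDuplicated(rownames(v)))
        msg <- c(msg, sprintf("duplicate gene symbol: %s",
                 paste(unique(rownames(v)[duplicated(rownames(v))]),
                       collapse = ", ")))
    if (anyDuplicated(colnames(v)))
        msg <- c(msg, "duplicate sample IDs")
    if (!is.numeric(v) || any(!is.finite(v)) || any(v < 0))
        msg <- c(msg, "counts must be finite and non-negative")
    unit <- metadata(object)$unit
    if (is.null(unit) || !unit %in% c("raw", "cpm"))
        msg <- c(msg, "metadata(x)$unit must be 'raw' or 'cpm'")
    if (length(msg)) msg else TRUE
}
setValidity("CountMatrix", .validCountMatrix)

#' Construct a CountMatrix
#'
#' @param counts numeric gene-by-sample matrix with dimnames.
#' @param sampleData optional \code{DataFrame}/\code{data.frame} of sample
#'   metadata (one row per sample, in column order of \code{counts}); when it
#'   carries the standard columns it is validated with
#'   \code{\link{validateSampleMetadata}}.
#' @param unit \code{"raw"} read counts or \code{"cpm"}.
#' @return A \linkS4class{CountMatrix}.
#' @examples
#' m <- matrix(1:6, 3, 2, dimnames = list(c("A", "B", "C"), c("s1", "s2")))
#' CountMatrix(m, unit = "raw")
#' @export
CountMatrix <- function(counts, sampleData = NULL, unit = c("raw", "cpm")) {
    unit <- match.arg(unit)
    counts <- as.matrix(counts)
    if (is.null(sampleData)) {
        sampleData <- DataFrame(row.names = colnames(counts))
    } else {
        sampleData <- DataFrame(sampleData)
        if (is.null(rownames(sampleData)) && "sample_id" %in% colnames(sampleData))
            rownames(sampleData) <- sampleData$sample_id
        if (all(.META_COLUMNS %in% c("sample_id", colnames(sampleData))))
            validateSampleMetadata(as.data.frame(sampleData))
        sampleData <- sampleData[colnames(counts), , drop = FALSE]
    }
    se <- SummarizedExperiment(assays = list(counts = counts),
                               colData = sampleData)
    metadata(se)$unit <- unit
    new("CountMatrix", se)
}

#' Unit of a CountMatrix
#' @param x A \linkS4class{CountMatrix}.
#' @return \code{"raw"} or \code{"cpm"}.
#' @export
unitType <- function(x) metadata(x)$unit

setMethod("show", "CountMatrix", function(object) {
    cat(sprintf("CountMatrix: %d genes x %d samples [%s]\n",
                nrow(object), ncol(object), unitType(object)))
    callNextMethod()
})

# ---------------------------------------------------------------------------
# ProfileSet
# ---------------------------------------------------------------------------

#' Control-normalized expression profiles
#'
#' A \code{ProfileSet} is a \linkS4class{SummarizedExperiment} with one assay
#' named \code{"log2fc"}: finite log2 control-relative expression, genes in
#' rows. Columns are either individual treated samples (with a
#' \code{replicate} column in \code{colData}) or replicate-averaged compound
#' profiles. \code{colData} always carries \code{compound} and
#' \code{class_label}.
#'
#' @seealso \code{\link{normalizeToControl}}, \code{\link{averageReplicates}}
#' @export
setClass("ProfileSet", contains = "SummarizedExperiment")

.validProfileSet <- function(object) {
    msg <- character()
    if (!identical(assayNames(object), "log2fc"))
        msg <- c(msg, "assay must be a single matrix named 'log2fc'")
    v <- assay(object, "log2fc")
    if (!is.numeric(v) || any(!is.finite(v)))
        msg <- c(msg, "log2fc values must be finite")
    if (anyDuplicated(rownames(v)))
        msg <- c(msg, "duplicate gene symbols")
    cd <- colData(object)
    if (!all(c("compound", "class_label") %in% colnames(cd)))
        msg <- c(msg, "colData must contain 'compound' and 'class_label'")
    else if (!all(cd$class_label %in% .CLASS_LEVELS))
        msg <- c(msg, sprintf("class_label must be one of: %s",
                              paste(.CLASS_LEVELS, collapse = ", ")))
    if (length(msg)) msg else TRUE
}
setValidity("ProfileSet", .validProfileSet)

#' Construct a ProfileSet
#'
#' @param log2fc numeric gene-by-profile matrix of log2 control-relative
#'   values, with gene rownames and profile colnames.
#' @param compound character vector, one entry per column.
#' @param class_label character vector of class labels
#'   (\code{"HDACi"}, \code{"non-HDACi"}, ...), recycled if length 1.
#' @param replicate optional integer replicate index per column.
#' @return A \linkS4class{ProfileSet}.
#' @export
ProfileSet <- function(log2fc, compound = colnames(log2fc),
                       class_label = "unknown", replicate = NULL) {
    log2fc <- as.matrix(log2fc)
    cd <- DataFrame(compound = as.character(compound),
                    class_label = rep_len(as.character(class_label),
                                          ncol(log2fc)),
                    row.names = colnames(log2fc))
    if (!is.null(replicate)) cd$replicate <- as.integer(replicate)
    new("ProfileSet",
        SummarizedExperiment(assays = list(log2fc = log2fc), colData = cd))
}

#' Gene symbols of an object
#' @param x An object with genes in rows.
#' @return Character vector of gene symbols.
#' @export
setGeneric("geneSymbols", function(x) standardGeneric("geneSymbols"))

#' @rdname geneSymbols
#' @export
setMethod("geneSymbols", "SummarizedExperiment", function(x) rownames(x))

#' Class labels of profiles
#' @param x A \linkS4class{ProfileSet}.
#' @return Character vector of per-column class labels.
#' @export
classLabels <- function(x) as.character(colData(x)$class_label)

#' Compound identifiers of profiles
#' @param x A \linkS4class{ProfileSet}.
#' @return Character vector of per-column compound names.
#' @export
compoundNames <- function(x) as.character(colData(x)$compound)

setMethod("show", "ProfileSet", function(object) {
    lab <- table(factor(classLabels(object), levels = .CLASS_LEVELS))
    lab <- lab[lab > 0]
    cat(sprintf("ProfileSet: %d genes x %d profiles (%s)\n",
                nrow(object), ncol(object),
                paste(sprintf("%s: %d", names(lab), lab), collapse = ", ")))
})

# ---------------------------------------------------------------------------
# QCReport
# ---------------------------------------------------------------------------

#' Quality-control report for a preprocessing run
#'
#' Collects the negative-control signal share, reference-sample correlations,
#' per-sample replicate dissimilarities and the outlier decisions made at the
#' dissimilarity cutoff (default 0.2, strict \code{>}).
#'
#' @slot negativeControlFraction share of total reads in water-only samples
#'   (\code{NA_real_} when no water samples were supplied).
#' @slot negativeControlPass logical; \code{TRUE} when the share is < 0.003.
#' @slot withinBatchCorrelations named numeric, QC-sample pair correlations.
#' @slot betweenBatchCorrelations named numeric.
#' @slot dissimilarity named numeric, per-sample 1 - r to the most similar
#'   replicate of the same compound.
#' @slot outliersRemoved character, sample IDs removed.
#' @slot dissimilarityCutoff numeric scalar.
#' @slot dendrogram list; the full-cohort \code{hclust} tree, for inspection.
#' @export
setClass("QCReport", representation(
    negativeControlFraction = "numeric",
    negativeControlPass = "logical",
    withinBatchCorrelations = "numeric",
    betweenBatchCorrelations = "numeric",
    dissimilarity = "numeric",
    outliersRemoved = "character",
    dissimilarityCutoff = "numeric",
    dendrogram = "list"))

setValidity("QCReport", function(object) {
    msg <- character()
    corrs <- c(object@withinBatchCorrelations, object@betweenBatchCorrelations)
    corrs <- corrs[!is.na(corrs)]
    if (length(corrs) && any(abs(corrs) > 1 + 1e-12))
        msg <- c(msg, "correlations must lie in [-1, 1]")
    d <- object@dissimilarity
    if (length(d) && any(d[!is.na(d)] < -1e-12))
        msg <- c(msg, "dissimilarities must be >= 0")
    out <- object@outliersRemoved
    if (length(out) &&
        any(d[out] <= object@dissimilarityCutoff))
        msg <- c(msg, "every removed sample must exceed the cutoff")
    if (length(msg)) msg else TRUE
})

setMethod("show", "QCReport", function(object) {
    cat("QCReport\n")
    if (!is.na(object@negativeControlFraction))
        cat(sprintf("  negative-control signal share: %.4g%% (%s)\n",
                    100 * object@negativeControlFraction,
                    if (object@negativeControlPass) "pass" else "FLAGGED"))
    cat(sprintf("  dissimilarity cutoff: > %g; %d sample(s) removed",
                object@dissimilarityCutoff, length(object@outliersRemoved)))
    if (length(object@outliersRemoved))
        cat(": ", paste(object@outliersRemoved, collapse = ", "), sep = "")
    cat("\n")
})

#' @rdname QCReport-class
#' @param object A \linkS4class{QCReport}.
#' @return \code{outliersRemoved}: character vector of removed sample IDs.
#' @export
outliersRemoved <- function(object) object@outliersRemoved

# ---------------------------------------------------------------------------
# NSCModel
# ---------------------------------------------------------------------------

#' Fitted nearest-shrunken-centroid classifier
#'
#' Stores everything the NSC discriminant needs: the overall centroid
#' \eqn{\bar x_i}, class centroids \eqn{\bar x_{ik}}, pooled within-class
#' standard deviations \eqn{s_i}, the fudge factor \eqn{s_0} (median of the
#' \eqn{s_i}), class priors \eqn{\pi_k}, the class-size factors
#' \eqn{m_k = \sqrt{1/n_k - 1/n}}, the shrinkage \eqn{\Delta}, and the
#' standardized contrasts \eqn{d_{ik}} before and after soft thresholding.
#' Genes with any nonzero shrunken contrast survive and enter the
#' discriminant.
#'
#' @slot genes character, all genes present at fit time.
#' @slot classes character, ordered class labels.
#' @slot overallCentroid numeric per gene.
#' @slot classCentroids genes x classes matrix.
#' @slot pooledSD numeric per gene (within-class pooled).
#' @slot s0 numeric scalar fudge factor.
#' @slot priors numeric per class, summing to 1.
#' @slot mk numeric per class.
#' @slot delta numeric scalar shrinkage.
#' @slot dstat genes x classes matrix of unshrunken contrasts.
#' @slot shrunkenDstat genes x classes matrix after soft thresholding.
#' @seealso \code{\link{fitNSC}}, \code{\link{classProbabilities}}
#' @export
setClass("NSCModel", representation(
    genes = "character",
    classes = "character",
    overallCentroid = "numeric",
    classCentroids = "matrix",
    pooledSD = "numeric",
    s0 = "numeric",
    priors = "numeric",
    mk = "numeric",
    delta = "numeric",
    dstat = "matrix",
    shrunkenDstat = "matrix"))

setValidity("NSCModel", function(object) {
    msg <- character()
    G <- length(object@genes); K <- length(object@classes)
    if (length(object@overallCentroid) != G)
        msg <- c(msg, "overallCentroid length must match genes")
    for (nm in c("classCentroids", "dstat", "shrunkenDstat")) {
        m <- slot(object, nm)
        if (!all(dim(m) == c(G, K)))
            msg <- c(msg, sprintf("%s must be genes x classes", nm))
    }
    if (length(object@pooledSD) != G || any(object@pooledSD < 0))
        msg <- c(msg, "pooledSD must be non-negative, one per gene")
    if (length(object@s0) != 1 || object@s0 < 0)
        msg <- c(msg, "s0 must be a non-negative scalar")
    if (length(object@priors) != K || abs(sum(object@priors) - 1) > 1e-8)
        msg <- c(msg, "priors must sum to 1")
    if (length(object@delta) != 1 || object@delta < 0)
        msg <- c(msg, "delta must be a scalar >= 0")
    if (length(msg)) msg else TRUE
})

#' Genes surviving shrinkage
#'
#' Genes whose shrunken contrast is nonzero for at least one class; only
#' these enter the discriminant.
#'
#' @param model A \linkS4class{NSCModel}.
#' @return Character vector of surviving gene symbols.
#' @export
survivingGenes <- function(model) {
    model@genes[rowSums(model@shrunkenDstat != 0) > 0]
}

#' Shrunken class centroids on the expression scale
#'
#' \eqn{\bar x'_{ik} = \bar x_i + m_k (s_i + s_0) d'_{ik}}.
#'
#' @param model A \linkS4class{NSCModel}.
#' @return Genes x classes matrix.
#' @export
shrunkenCentroids <- function(model) {
    sc <- model@overallCentroid +
        sweep(model@shrunkenDstat, 2, model@mk, `*`) *
        (model@pooledSD + model@s0)
    dimnames(sc) <- list(model@genes, model@classes)
    sc
}

setMethod("show", "NSCModel", function(object) {
    cat(sprintf(
        "NSCModel: %d genes, classes %s, delta = %.4g, %d surviving genes\n",
        length(object@genes), paste(object@classes, collapse = "/"),
        object@delta, length(survivingGenes(object))))
    cat(sprintf("  priors: %s; s0 = %.4g\n",
                paste(sprintf("%s = %.3g", object@classes, object@priors),
                      collapse = ", "), object@s0))
})

# ---------------------------------------------------------------------------
# ShrinkagePath
# ---------------------------------------------------------------------------

#' Shrinkage path with cross-validated accuracy
#'
#' One row per shrinkage threshold: the number of surviving genes and the
#' compound-level k-fold cross-validation accuracy of the 90%-probability
#' classification rule at that threshold.
#'
#' @slot thresholds increasing numeric grid of shrinkage values.
#' @slot genesSurviving integer per threshold (non-increasing).
#' @slot cvAccuracy numeric in [0, 1] per threshold.
#' @slot foldAssignment named integer, compound -> fold.
#' @slot nfolds integer.
#' @seealso \code{\link{shrinkagePath}}, \code{\link{selectShrinkage}}
#' @export
setClass("ShrinkagePath", representation(
    thresholds = "numeric",
    genesSurviving = "integer",
    cvAccuracy = "numeric",
    foldAssignment = "integer",
    nfolds = "integer"))

setValidity("ShrinkagePath", function(object) {
    msg <- character()
    n <- length(object@thresholds)
    if (is.unsorted(object@thresholds, strictly = TRUE))
        msg <- c(msg, "thresholds must be strictly increasing")
    if (length(object@genesSurviving) != n || length(object@cvAccuracy) != n)
        msg <- c(msg, "per-threshold vectors must match thresholds")
    if (any(diff(object@genesSurviving) > 0))
        msg <- c(msg, "genesSurviving must be non-increasing in the threshold")
    if (any(object@cvAccuracy < 0 | object@cvAccuracy > 1))
        msg <- c(msg, "cvAccuracy must lie in [0, 1]")
    if (length(msg)) msg else TRUE
})

#' Shrinkage path as a data.frame
#' @param x A \linkS4class{ShrinkagePath}.
#' @param row.names,optional,... ignored, present for the generic.
#' @return data.frame with columns threshold, genes_surviving, cv_accuracy.
#' @export
as.data.frame.ShrinkagePath <- function(x, row.names = NULL,
                                        optional = FALSE, ...) {
    data.frame(threshold = x@thresholds,
               genes_surviving = x@genesSurviving,
               cv_accuracy = x@cvAccuracy)
}

setMethod("show", "ShrinkagePath", function(object) {
    cat(sprintf("ShrinkagePath: %d thresholds in [%.3g, %.3g], %d-fold CV\n",
                length(object@thresholds), min(object@thresholds),
                max(object@thresholds), object@nfolds))
    print(utils::head(as.data.frame(object)))
    if (length(object@thresholds) > 6) cat("  ...\n")
})

# ---------------------------------------------------------------------------
# BiomarkerAsset
# ---------------------------------------------------------------------------

#' Frozen biomarker panel
#'
#' A self-contained classifier: gene symbols, per-class shrunken centroids on
#' the standardized scale of the panel, the per-gene standardization
#' denominator (pooled SD plus fudge), class priors and the probability
#' cutoff. The packaged 19-gene HDACi panel is loaded with
#' \code{\link{builtinBiomarker}}.
#'
#' @slot name character scalar.
#' @slot genes character.
#' @slot centroids genes x classes matrix (columns \code{HDACi},
#'   \code{non-HDACi}).
#' @slot sd numeric per gene, strictly positive.
#' @slot priors numeric per class.
#' @slot cutoff numeric scalar posterior-probability cutoff.
#' @slot provenance character scalar describing where the values come from.
#' @export
setClass("BiomarkerAsset", representation(
    name = "character",
    genes = "character",
    centroids = "matrix",
    sd = "numeric",
    priors = "numeric",
    cutoff = "numeric",
    provenance = "character"))

setValidity("BiomarkerAsset", function(object) {
    msg <- character()
    G <- length(object@genes)
    if (anyDuplicated(object@genes))
        msg <- c(msg, "gene symbols must be unique")
    if (!all(dim(object@centroids) == c(G, 2)) ||
        !identical(colnames(object@centroids), .TREATED_LEVELS))
        msg <- c(msg, "centroids must be genes x (HDACi, non-HDACi)")
    if (length(object@sd) != G || any(object@sd <= 0))
        msg <- c(msg, "sd must be strictly positive, one per gene")
    if (length(object@priors) != 2 || abs(sum(object@priors) - 1) > 1e-8)
        msg <- c(msg, "priors must be two values summing to 1")
    if (length(object@cutoff) != 1 || object@cutoff <= 0 || object@cutoff >= 1)
        msg <- c(msg, "cutoff must lie in (0, 1)")
    if (length(msg)) msg else TRUE
})

setMethod("show", "BiomarkerAsset", function(object) {
    cat(sprintf("BiomarkerAsset '%s': %d genes, cutoff %.2g\n",
                object@name, length(object@genes), object@cutoff))
    cat(sprintf("  %s\n", object@provenance))
})

#' @rdname geneSymbols
#' @export
setMethod("geneSymbols", "BiomarkerAsset", function(x) x@genes)

# ---------------------------------------------------------------------------
# SimConfig
# ---------------------------------------------------------------------------

#' Configuration of the synthetic-data generator
#'
#' Describes a two-class compound-exposure study: per-gene class means
#' (defaults: the packaged 19-gene panel centroids), per-gene
#' between-compound noise SD (defaults: the panel SD column), optional
#' uninformative background genes, reference and validation cohort sizes
#' (defaults 10+10 and 4+7), replicates per compound (default 3) and
#' within-compound replicate noise. \code{effectScale} multiplies the class
#' contrast around the no-response baseline; 0 gives the null model.
#'
#' @slot classCentroids genes x 2 matrix (HDACi, non-HDACi) of class mean
#'   log2 fold changes.
#' @slot geneSD per-gene between-compound SD on the log2 scale.
#' @slot overallMean per-gene baseline log2 fold change (default 0,
#'   no response).
#' @slot nBackground integer, extra genes with zero class contrast.
#' @slot backgroundSD numeric scalar SD for background genes.
#' @slot nReference integer length-2 (HDACi, non-HDACi) reference compounds.
#' @slot nValidation integer length-2 validation compounds.
#' @slot nReplicates integer replicates per compound.
#' @slot replicateSD numeric within-compound SD on the log2 scale.
#' @slot effectScale numeric >= 0 multiplier on the class contrast.
#' @slot seed integer, mandatory for any stochastic run.
#' @slot countLayer logical; also emit Poisson counts.
#' @slot librarySize numeric expected reads per sample for the count layer.
#' @slot phi numeric >= 0 negative-binomial overdispersion (0 = Poisson).
#' @seealso \code{\link{simConfig}}, \code{\link{simulateProfiles}}
#' @export
setClass("SimConfig", representation(
    classCentroids = "matrix",
    geneSD = "numeric",
    overallMean = "numeric",
    nBackground = "integer",
    backgroundSD = "numeric",
    nReference = "integer",
    nValidation = "integer",
    nReplicates = "integer",
    replicateSD = "numeric",
    effectScale = "numeric",
    seed = "integer",
    countLayer = "logical",
    librarySize = "numeric",
    phi = "numeric"))

setValidity("SimConfig", function(object) {
    msg <- character()
    G <- nrow(object@classCentroids)
    if (!identical(colnames(object@classCentroids), .TREATED_LEVELS))
        msg <- c(msg, "classCentroids columns must be HDACi, non-HDACi")
    if (length(object@geneSD) != G || any(object@geneSD < 0))
        msg <- c(msg, "geneSD must be non-negative, one per panel gene")
    if (length(object@overallMean) != G)
        msg <- c(msg, "overallMean must have one value per panel gene")
    if (object@effectScale < 0) msg <- c(msg, "effectScale must be >= 0")
    if (object@replicateSD < 0 || object@backgroundSD < 0)
        msg <- c(msg, "SDs must be >= 0")
    if (length(object@seed) != 1 || is.na(object@seed))
        msg <- c(msg, "a seed is mandatory")
    if (any(object@nReference < 0) || any(object@nValidation < 0) ||
        object@nReplicates < 1)
        msg <- c(msg, "cohort sizes must be non-negative, replicates >= 1")
    if (object@phi < 0) msg <- c(msg, "phi must be >= 0")
    if (length(msg)) msg else TRUE
})

setMethod("show", "SimConfig", function(object) {
    cat(sprintf(paste0(
        "SimConfig: %d panel + %d background genes; reference %d+%d, ",
        "validation %d+%d compounds x %d replicates\n",
        "  effectScale = %g, replicateSD = %g, seed = %d%s\n"),
        nrow(object@classCentroids), object@nBackground,
        object@nReference[1], object@nReference[2],
        object@nValidation[1], object@nValidation[2], object@nReplicates,
        object@effectScale, object@replicateSD, object@seed,
        if (object@countLayer)
            sprintf(", count layer L = %.3g", object@librarySize) else ""))
})
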