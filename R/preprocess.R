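# Preprocessing: raw counts -> CPM -> vehicle-control log2 ratios ->
# outlier screen -> replicate-averaged compound profiles, with the QC checks
# that belong to a targeted RNA-seq exposure study (negative-control signal
# share, reference-RNA correlations, dissimilarity-based outlier removal).

#' Counts-per-million normalization
#'
#' Scales every sample column to sum to 1e6.
#'
#' @param x A \linkS4class{CountMatrix} with \code{unit == "raw"}.
#' @return A \linkS4class{CountMatrix} with \code{unit == "cpm"}.
#' @examples
#' m <- matrix(c(1, 1, 2), 3, 1, dimnames = list(c("A", "B", "C"), "s1"))
#' assay(cpmNormalize(CountMatrix(m, unit = "raw")))
#' @export
cpmNormalize <- function(x) {
    stopifnot(is(x, "CountMatrix"))
    if (unitType(x) != "raw")
        stop("cpmNormalize expects raw counts (unit 'raw'), got '",
             unitType(x), "'", call. = FALSE)
    counts <- assay(x, "counts")
    totals <- colSums(counts)
    if (any(totals == 0))
        stop("zero-total sample column(s): ",
             paste(colnames(counts)[totals == 0], collapse = ", "),
             call. = FALSE)
    CountMatrix(sweep(counts, 2, totals / 1e6, `/`),
                sampleData = colData(x), unit = "cpm")
}

#' Normalize treated samples to their matched vehicle controls
#'
#' For every treated sample s with matched control c(s), computes per gene
#' \deqn{log2((CPM_{g,s} + p) / (CPM_{g,c(s)} + p))} with pseudocount p
#' (default 0.5) added to both numerator and denominator. Control and QC
#' samples are dropped from the output.
#'
#' @param x A \linkS4class{CountMatrix} with \code{unit == "cpm"} and full
#'   sample metadata in \code{colData}.
#' @param pseudocount non-negative CPM offset, default 0.5.
#' @return A per-sample \linkS4class{ProfileSet} (columns = treated samples,
#'   with \code{replicate} in \code{colData}).
#' @export
normalizeToControl <- function(x, pseudocount = 0.5) {
    stopifnot(is(x, "CountMatrix"), pseudocount >= 0)
    if (unitType(x) != "cpm")
        stop("normalizeToControl expects CPM values; run cpmNormalize() first",
             call. = FALSE)
    meta <- as.data.frame(colData(x))
    missingCols <- setdiff(.META_COLUMNS[-1L], colnames(meta))
    if (length(missingCols))
        stop("colData is missing metadata column(s): ",
             paste(missingCols, collapse = ", "), call. = FALSE)
    treated <- which(meta$class_label %in% .TREATED_LEVELS)
    if (!length(treated)) stop("no treated samples", call. = FALSE)
    ctrl <- as.character(meta$vehicle_control_id[treated])
    bad <- !nzchar(ctrl) | is.na(ctrl) | !(ctrl %in% colnames(x))
    if (any(bad))
        stop("treated sample(s) without resolvable vehicle control: ",
             paste(colnames(x)[treated[bad]], collapse = ", "), call. = FALSE)
    cpm <- assay(x, "counts")
    lfc <- log2((cpm[, treated, drop = FALSE] + pseudocount) /
                (cpm[, ctrl, drop = FALSE] + pseudocount))
    colnames(lfc) <- colnames(x)[treated]
    ProfileSet(lfc, compound = meta$compound[treated],
               class_label = meta$class_label[treated],
               replicate = meta$replicate[treated])
}

#' Average replicate profiles per compound
#'
#' Arithmetic mean per gene over the surviving replicates of each compound,
#' yielding one profile per compound. A compound left with a single replicate
#' (e.g. after outlier removal) is passed through unchanged with a warning.
#' Compound order follows first appearance in the input.
#'
#' @param x A per-sample \linkS4class{ProfileSet}.
#' @return A per-compound \linkS4class{ProfileSet}.
#' @export
averageReplicates <- function(x) {
    stopifnot(is(x, "ProfileSet"))
    compounds <- unique(compoundNames(x))
    lfc <- assay(x, "log2fc")
    out <- matrix(NA_real_, nrow(lfc), length(compounds),
                  dimnames = list(rownames(lfc), compounds))
    labels <- character(length(compounds))
    for (j in seq_along(compounds)) {
        idx <- which(compoundNames(x) == compounds[j])
        if (length(idx) == 1L)
            warning("compound '", compounds[j],
                    "' has a single surviving replicate", call. = FALSE)
        out[, j] <- rowMeans(lfc[, idx, drop = FALSE])
        labels[j] <- classLabels(x)[idx[1L]]
    }
    ProfileSet(out, compound = compounds, class_label = labels)
}

#' Negative-control (water-only) signal share
#'
#' Total counts in the water-only library wells divided by the grand total.
#' The run passes when the share is strictly below 0.3%.
#'
#' @param x A \linkS4class{CountMatrix} (raw counts).
#' @param waterSamples character, sample IDs of the water-only wells.
#' @return list with \code{fraction} and logical \code{pass}.
#' @export
qcNegativeControl <- function(x, waterSamples) {
    stopifnot(is(x, "CountMatrix"))
    waterSamples <- intersect(waterSamples, colnames(x))
    if (!length(waterSamples)) {
        warning("no water-only samples present; negative-control check skipped",
                call. = FALSE)
        return(list(fraction = NA_real_, pass = NA))
    }
    counts <- assay(x, "counts")
    frac <- sum(counts[, waterSamples, drop = FALSE]) / sum(counts)
    list(fraction = frac, pass = frac < 0.003)
}

#' Reference-sample correlations
#'
#' Pearson (or Spearman) correlation of log2(CPM + pseudocount) between pairs
#' of reference-RNA QC samples, used to confirm within- and between-batch
#' comparability. Raw input is CPM-normalized first, so the correlation is
#' invariant to library size.
#'
#' @param x A \linkS4class{CountMatrix}.
#' @param pairs two-column matrix or data.frame of sample-ID pairs.
#' @param method \code{"pearson"} (default) or \code{"spearman"}.
#' @param pseudocount CPM offset before log2, default 0.5.
#' @return Named numeric vector, one correlation per pair
#'   (\code{NA} with a warning for constant vectors).
#' @export
qcReferenceCorrelation <- function(x, pairs, method = c("pearson", "spearman"),
                                   pseudocount = 0.5) {
    stopifnot(is(x, "CountMatrix"))
    method <- match.arg(method)
    pairs <- as.matrix(pairs)
    stopifnot(ncol(pairs) == 2L)
    if (!all(pairs %in% colnames(x)))
        stop("unknown sample(s) in pairs: ",
             paste(setdiff(pairs, colnames(x)), collapse = ", "),
             call. = FALSE)
    if (unitType(x) == "raw") x <- cpmNormalize(x)
    lg <- log2(assay(x, "counts") + pseudocount)
    out <- numeric(nrow(pairs))
    names(out) <- paste(pairs[, 1L], pairs[, 2L], sep = " vs ")
    for (i in seq_len(nrow(pairs))) {
        a <- lg[, pairs[i, 1L]]; b <- lg[, pairs[i, 2L]]
        if (sd(a) == 0 || sd(b) == 0) {
            warning("constant expression vector in pair ", names(out)[i],
                    "; correlation undefined", call. = FALSE)
            out[i] <- NA_real_
        } else out[i] <- cor(a, b, method = method)
    }
    out
}

#' Remove outlier replicates by dissimilarity
#'
#' Per-sample dissimilarity is 1 minus the largest Pearson correlation
#' between the sample's log2 profile and any other replicate of the same
#' compound (0 for singleton groups). Samples with dissimilarity strictly
#' above the cutoff (default 0.2) are removed. An aberrant replicate is far
#' from every sibling and flags itself without dragging clean replicates
#' over the cutoff, which a group-mean reference does when one replicate of
#' a triplicate is badly off. A full-cohort average-linkage tree over
#' correlation distance is kept in the report for inspection; the removal
#' rule itself does not depend on tree topology.
#'
#' @param x A per-sample \linkS4class{ProfileSet}.
#' @param cutoff dissimilarity cutoff, default 0.2 (strict \code{>}).
#' @return list with \code{profiles} (the kept samples) and \code{report}
#'   (a \linkS4class{QCReport}).
#' @export
removeOutliers <- function(x, cutoff = 0.2) {
    stopifnot(is(x, "ProfileSet"), ncol(x) >= 3L)
    lfc <- assay(x, "log2fc")
    comp <- compoundNames(x)
    diss <- setNames(numeric(ncol(x)), colnames(x))
    for (j in seq_len(ncol(x))) {
        sibs <- setdiff(which(comp == comp[j]), j)
        if (!length(sibs) || sd(lfc[, j]) == 0) { diss[j] <- 0; next }
        rs <- vapply(sibs, function(k)
            if (sd(lfc[, k]) == 0) 0 else cor(lfc[, j], lfc[, k]),
            numeric(1))
        diss[j] <- 1 - max(rs)
    }
    removed <- names(diss)[diss > cutoff]
    dend <- if (ncol(x) >= 3L) {
        cc <- suppressWarnings(cor(lfc))
        cc[!is.finite(cc)] <- 0
        list(tree = hclust(stats::as.dist(1 - cc), method = "average"))
    } else list()
    keep <- setdiff(colnames(x), removed)
    report <- new("QCReport",
                  negativeControlFraction = NA_real_,
                  negativeControlPass = NA,
                  withinBatchCorrelations = numeric(),
                  betweenBatchCorrelations = numeric(),
                  dissimilarity = diss,
                  outliersRemoved = removed,
                  dissimilarityCutoff = cutoff,
                  dendrogram = dend)
    list(profiles = x[, keep], report = report)
}

#' One-shot preprocessing of a raw count matrix
#'
#' Runs the full chain: CPM normalization, vehicle-control log2 ratios with a
#' pseudocount, dissimilarity-based outlier removal, and replicate averaging.
#' Optional QC inputs populate the report.
#'
#' @param x A \linkS4class{CountMatrix} (raw counts or CPM) with full sample
#'   metadata in \code{colData}.
#' @param pseudocount CPM offset for the log2 ratio, default 0.5.
#' @param cutoff dissimilarity cutoff for outlier removal, default 0.2.
#' @param waterSamples optional water-only sample IDs for the
#'   negative-control check.
#' @param withinBatchPairs,betweenBatchPairs optional two-column sample-ID
#'   pair tables for reference-RNA correlations.
#' @return list with \code{profiles} (per-compound
#'   \linkS4class{ProfileSet}) and \code{report} (\linkS4class{QCReport}).
#' @export
preprocessCounts <- function(x, pseudocount = 0.5, cutoff = 0.2,
                             waterSamples = NULL, withinBatchPairs = NULL,
                             betweenBatchPairs = NULL) {
    stopifnot(is(x, "CountMatrix"))
    neg <- list(fraction = NA_real_, pass = NA)
    if (!is.null(waterSamples) && unitType(x) == "raw")
        neg <- qcNegativeControl(x, waterSamples)
    wb <- if (is.null(withinBatchPairs)) numeric()
          else qcReferenceCorrelation(x, withinBatchPairs,
                                      pseudocount = pseudocount)
    bb <- if (is.null(betweenBatchPairs)) numeric()
          else qcReferenceCorrelation(x, betweenBatchPairs,
                                      pseudocount = pseudocount)
    if (unitType(x) == "raw") x <- cpmNormalize(x)
    perSample <- normalizeToControl(x, pseudocount = pseudocount)
    screened <- removeOutliers(perSample, cutoff = cutoff)
    report <- screened$report
    report@negativeControlFraction <- neg$fraction
    report@negativeControlPass <- neg$pass
    report@withinBatchCorrelations <- wb
    report@betweenBatchCorrelations <- bb
    list(profiles = averageReplicates(screened$profiles), report = report)
}
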