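# Corroborating classification prongs: PCA projection onto the reference
# geometry with a midpoint threshold on PC1, and one-query-at-a-time
# hierarchical clustering (Euclidean distance, average linkage) cut into two
# clusters. The NSC probability call remains the formal classifier; the
# ensemble call equals it, with a concordance flag across all three prongs.

#' PCA-based classification against a labeled reference set
#'
#' Fits a PCA on the centered (not rescaled) reference profiles (compounds as
#' observations, genes as variables), orients PC1 so the HDACi class mean is
#' positive of the threshold, and projects queries with the reference
#' loadings — the reference geometry is never refit with queries included.
#' The decision threshold is the midpoint of the two class means on PC1.
#'
#' @param reference labeled \linkS4class{ProfileSet} (>= 3 compounds per
#'   class), restricted to the panel genes.
#' @param queries \linkS4class{ProfileSet} over the same genes.
#' @return data.frame with columns \code{compound}, \code{pc1_score},
#'   \code{call}; attribute \code{"threshold"} holds the PC1 threshold and
#'   attribute \code{"reference_scores"} the oriented reference scores.
#' @export
pcaClassify <- function(reference, queries) {
    stopifnot(is(reference, "ProfileSet"), is(queries, "ProfileSet"))
    if (!identical(geneSymbols(reference), geneSymbols(queries)))
        stop("reference and queries must share one ordered gene list",
             call. = FALSE)
    labels <- classLabels(reference)
    if (any(table(factor(labels, levels = .TREATED_LEVELS)) < 3L))
        stop("need >= 3 reference compounds per class", call. = FALSE)
    X <- t(assay(reference, "log2fc"))
    pc <- prcomp(X, center = TRUE, scale. = FALSE)
    refScores <- pc$x[, 1L]
    mH <- mean(refScores[labels == "HDACi"])
    mN <- mean(refScores[labels == "non-HDACi"])
    flip <- if (mH < mN) -1 else 1
    refScores <- flip * refScores
    threshold <- flip * (mH + mN) / 2
    pooled <- sd(refScores)
    if (abs(flip * mH - flip * mN) < 0.1 * pooled)
        warning("reference classes are not separated on PC1; ",
                "calls are unreliable", call. = FALSE)
    Q <- t(assay(queries, "log2fc"))
    qScores <- flip *
        as.numeric(scale(Q, center = pc$center, scale = FALSE) %*%
                   pc$rotation[, 1L])
    out <- data.frame(compound = compoundNames(queries),
                      pc1_score = qScores,
                      call = ifelse(qScores > threshold, "HDACi",
                                    "non-HDACi"),
                      stringsAsFactors = FALSE)
    attr(out, "threshold") <- threshold
    attr(out, "reference_scores") <- setNames(refScores,
                                              compoundNames(reference))
    out
}

#' Hierarchical-clustering classification, one query at a time
#'
#' For each query, builds a tree over the reference profiles plus that single
#' query (Euclidean distance, average linkage), cuts it into two clusters,
#' and calls the majority class of the reference compounds sharing the
#' query's cluster. A query landing in a singleton cluster, or a majority
#' tie, is unclassifiable for this prong (call \code{NA}).
#'
#' @param reference labeled \linkS4class{ProfileSet} (>= 2 compounds per
#'   class).
#' @param queries \linkS4class{ProfileSet} over the same genes.
#' @return data.frame with columns \code{compound}, \code{call}
#'   (\code{NA_character_} when unclassifiable).
#' @export
hclustClassify <- function(reference, queries) {
    stopifnot(is(reference, "ProfileSet"), is(queries, "ProfileSet"))
    if (!identical(geneSymbols(reference), geneSymbols(queries)))
        stop("reference and queries must share one ordered gene list",
             call. = FALSE)
    labels <- classLabels(reference)
    if (any(table(factor(labels, levels = .TREATED_LEVELS)) < 2L))
        stop("need >= 2 reference compounds per class", call. = FALSE)
    R <- t(assay(reference, "log2fc"))
    calls <- character(ncol(queries))
    for (j in seq_len(ncol(queries))) {
        q <- assay(queries, "log2fc")[, j]
        M <- rbind(R, query = q)
        ct <- cutree(hclust(dist(M), method = "average"), k = 2L)
        mates <- labels[ct[seq_len(nrow(R))] == ct[["query"]]]
        if (!length(mates)) { calls[j] <- NA_character_; next }
        tab <- table(factor(mates, levels = .TREATED_LEVELS))
        calls[j] <- if (tab["HDACi"] == tab["non-HDACi"]) NA_character_
                    else names(tab)[which.max(tab)]
    }
    data.frame(compound = compoundNames(queries), call = calls,
               stringsAsFactors = FALSE)
}

#' Reference-only tree and its two-cluster partition
#'
#' The joint dendrogram over a profile set (Euclidean distance, average
#' linkage), for display and for checking that the two-cluster cut
#' reproduces the class partition.
#'
#' @param x A \linkS4class{ProfileSet}.
#' @return list with \code{tree} (\code{hclust}) and \code{cluster} (named
#'   integer, the 2-cut membership).
#' @export
profileTree <- function(x) {
    stopifnot(is(x, "ProfileSet"), ncol(x) >= 2L)
    M <- t(assay(x, "log2fc"))
    rownames(M) <- compoundNames(x)
    tree <- hclust(dist(M), method = "average")
    list(tree = tree, cluster = cutree(tree, k = 2L))
}

#' Three-pronged classification of query compounds
#'
#' Runs the NSC probability rule (the formal classifier), the PCA prong and
#' the clustering prong, and combines them: the ensemble call equals the NSC
#' call, with a concordance flag that is \code{TRUE} only when all three
#' prongs agree. An unclassifiable clustering prong falls back to the NSC
#' call for the ensemble (which it already equals) and is reported as
#' \code{NA} with a warning.
#'
#' @param model A two-class \linkS4class{NSCModel} (e.g. from
#'   \code{\link{assetToModel}}).
#' @param reference labeled \linkS4class{ProfileSet} restricted to the
#'   model's surviving genes (used by the PCA and clustering prongs).
#' @param queries \linkS4class{ProfileSet} over the same genes.
#' @param cutoff posterior cutoff for the NSC call, default 0.9.
#' @return data.frame, one row per query: \code{compound},
#'   \code{nsc_probability_hdaci}, \code{nsc_call}, \code{pca_call},
#'   \code{pc1_score}, \code{hclust_call}, \code{ensemble_call},
#'   \code{concordant}.
#' @export
classifyCompounds <- function(model, reference, queries, cutoff = 0.9) {
    nsc <- classifyNSC(model, queries, cutoff = cutoff)
    pca <- pcaClassify(reference, queries)
    hcl <- hclustClassify(reference, queries)
    if (anyNA(hcl$call))
        warning("clustering prong unclassifiable for: ",
                paste(hcl$compound[is.na(hcl$call)], collapse = ", "),
                "; ensemble falls back to the NSC call", call. = FALSE)
    data.frame(compound = nsc$compound,
               nsc_probability_hdaci = nsc$p_hdaci,
               nsc_call = nsc$call,
               pca_call = pca$call,
               pc1_score = pca$pc1_score,
               hclust_call = hcl$call,
               ensemble_call = nsc$call,
               concordant = !is.na(hcl$call) & nsc$call == pca$call &
                   nsc$call == hcl$call,
               stringsAsFactors = FALSE)
}

#' Plot-ready heatmap table
#'
#' Panel-gene log2 values as a genes x compounds table with annotation rows
#' for the classification call and (optionally) the true class, matching the
#' usual up/down heatmap layout. Rendering is left to the caller.
#'
#' @param x A \linkS4class{ProfileSet}.
#' @param genes character, panel genes (rows, in this order); must all be
#'   present in \code{x}.
#' @param calls character, classification call per compound.
#' @param truth optional character, true class per compound.
#' @return data.frame whose first column \code{row} names the annotation
#'   rows (\code{call}, \code{truth}) and genes, one further column per
#'   compound.
#' @export
exportHeatmapMatrix <- function(x, genes = geneSymbols(x), calls, truth = NULL) {
    stopifnot(is(x, "ProfileSet"), length(calls) == ncol(x))
    missing <- setdiff(genes, geneSymbols(x))
    if (length(missing))
        stop("genes absent from profiles: ",
             paste(missing, collapse = ", "), call. = FALSE)
    vals <- assay(x, "log2fc")[genes, , drop = FALSE]
    ann <- rbind(call = as.character(calls))
    if (!is.null(truth)) ann <- rbind(ann, truth = as.character(truth))
    body <- rbind(ann, format(vals, digits = 15, trim = TRUE,
                              scientific = FALSE))
    df <- data.frame(row = rownames(body), body, check.names = FALSE,
                     row.names = NULL, stringsAsFactors = FALSE)
    colnames(df) <- c("row", compoundNames(x))
    df
}
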