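# Nearest shrunken centroid classification, implemented from first
# principles. Per-gene class contrasts are standardized by the pooled
# within-class SD plus a fudge factor, shrunk toward zero by soft
# thresholding, and classification uses the standardized squared distance to
# each shrunken centroid with a prior term; posteriors are a softmax of the
# discriminant scores.

#' Soft-threshold operator
#'
#' \code{sign(d) * max(|d| - delta, 0)}, applied elementwise. The workhorse
#' of centroid shrinkage: contrasts smaller than the shrinkage vanish, larger
#' ones move toward zero by \code{delta}.
#'
#' @param d numeric vector or matrix of standardized contrasts.
#' @param delta scalar shrinkage, >= 0.
#' @return Same shape as \code{d}.
#' @examples
#' softThreshold(c(-5, -2, 0, 2, 5), 3.449)
#' @export
softThreshold <- function(d, delta) {
    stopifnot(length(delta) == 1L, delta >= 0)
    sign(d) * pmax(abs(d) - delta, 0)
}

.orderClasses <- function(labels) {
    present <- unique(labels)
    c(intersect(.TREATED_LEVELS, present),
      sort(setdiff(present, .TREATED_LEVELS)))
}

#' Fit a nearest shrunken centroid classifier
#'
#' Computes per gene i and class k: the overall centroid \eqn{\bar x_i},
#' class centroids \eqn{\bar x_{ik}}, pooled within-class SD \eqn{s_i} with
#' denominator n - K, fudge \eqn{s_0 = \mathrm{median}(s_i)}, standardized
#' contrasts \eqn{d_{ik} = (\bar x_{ik} - \bar x_i) / (m_k (s_i + s_0))}
#' with \eqn{m_k = \sqrt{1/n_k - 1/n}}, and their soft-thresholded versions
#' \eqn{d'_{ik}} at shrinkage \code{delta}.
#'
#' @param x A \linkS4class{ProfileSet} of labeled per-compound profiles
#'   (class labels \code{HDACi} / \code{non-HDACi}; any two or more treated
#'   labels work).
#' @param delta scalar shrinkage, >= 0 (default 0, no shrinkage).
#' @param priors \code{"uniform"} (default, matching a balanced reference
#'   design) or \code{"empirical"} (class frequencies).
#' @return A \linkS4class{NSCModel}.
#' @seealso \code{\link{classProbabilities}}, \code{\link{shrinkagePath}}
#' @export
fitNSC <- function(x, delta = 0, priors = c("uniform", "empirical")) {
    stopifnot(is(x, "ProfileSet"), delta >= 0)
    priors <- match.arg(priors)
    X <- assay(x, "log2fc")
    labels <- classLabels(x)
    classes <- .orderClasses(labels)
    if (length(classes) < 2L)
        stop("need at least 2 classes to fit", call. = FALSE)
    nk <- table(factor(labels, levels = classes))
    if (any(nk < 2L))
        stop("every class needs >= 2 profiles; short: ",
             paste(classes[nk < 2L], collapse = ", "), call. = FALSE)
    n <- ncol(X); K <- length(classes); G <- nrow(X)
    overall <- rowMeans(X)
    centroids <- matrix(NA_real_, G, K, dimnames = list(rownames(X), classes))
    ssWithin <- numeric(G)
    for (k in seq_len(K)) {
        idx <- which(labels == classes[k])
        centroids[, k] <- rowMeans(X[, idx, drop = FALSE])
        ssWithin <- ssWithin +
            rowSums((X[, idx, drop = FALSE] - centroids[, k])^2)
    }
    s <- sqrt(ssWithin / (n - K))
    if (all(s == 0))
        stop("degenerate input: zero within-class variance for every gene",
             call. = FALSE)
    s0 <- median(s)
    if (s0 == 0)
        stop("degenerate variance structure: median pooled SD is zero",
             call. = FALSE)
    mk <- sqrt(1 / as.numeric(nk) - 1 / n)
    d <- (centroids - overall) / outer(s + s0, mk)
    pri <- if (priors == "uniform") rep(1 / K, K) else as.numeric(nk) / n
    new("NSCModel", genes = rownames(X), classes = classes,
        overallCentroid = overall, classCentroids = centroids,
        pooledSD = s, s0 = s0, priors = setNames(pri, classes),
        mk = setNames(mk, classes), delta = delta, dstat = d,
        shrunkenDstat = softThreshold(d, delta))
}

#' Re-shrink a fitted model at a new threshold
#'
#' The fit statistics do not depend on the shrinkage, so moving along the
#' shrinkage path only re-applies the soft threshold.
#'
#' @param model A \linkS4class{NSCModel}.
#' @param delta new scalar shrinkage, >= 0.
#' @return A \linkS4class{NSCModel}.
#' @export
reshrink <- function(model, delta) {
    stopifnot(is(model, "NSCModel"), delta >= 0)
    model@delta <- delta
    model@shrunkenDstat <- softThreshold(model@dstat, delta)
    model
}

#' Posterior class probabilities under an NSC model
#'
#' For profile x, the discriminant per class is
#' \deqn{\delta_k(x) = \sum_{i \in S} (x_i - \bar x'_{ik})^2 / (s_i + s_0)^2
#'   - 2 \log \pi_k}
#' over the surviving gene set S, with \eqn{\bar x'_{ik}} the shrunken
#' centroid; probabilities are \eqn{\exp(-\delta_k/2)} normalized over
#' classes.
#'
#' @param model A \linkS4class{NSCModel}.
#' @param x A \linkS4class{ProfileSet} covering all surviving genes of the
#'   model, in the model's gene order (align with
#'   \code{\link{subsetProfiles}} if needed).
#' @return Profiles x classes matrix of probabilities; rows sum to 1.
#' @export
classProbabilities <- function(model, x) {
    stopifnot(is(model, "NSCModel"), is(x, "ProfileSet"))
    surv <- survivingGenes(model)
    if (!length(surv))
        stop("fully shrunken model: no surviving genes", call. = FALSE)
    missing <- setdiff(surv, geneSymbols(x))
    if (length(missing))
        stop("profiles are missing surviving gene(s): ",
             paste(missing, collapse = ", "), call. = FALSE)
    X <- assay(x, "log2fc")[surv, , drop = FALSE]
    sc <- shrunkenCentroids(model)[surv, , drop = FALSE]
    denom <- (model@pooledSD + model@s0)[match(surv, model@genes)]
    delta <- matrix(NA_real_, ncol(X), length(model@classes),
                    dimnames = list(colnames(X), model@classes))
    for (k in seq_along(model@classes))
        delta[, k] <- colSums(((X - sc[, k]) / denom)^2) -
            2 * log(model@priors[k])
    ll <- -delta / 2
    ll <- ll - apply(ll, 1L, max)   # guard against underflow
    p <- exp(ll)
    p / rowSums(p)
}

#' Classify profiles with the 90% probability rule
#'
#' A profile is called \code{HDACi} if and only if its posterior probability
#' of HDACi class membership strictly exceeds the cutoff; otherwise it is
#' called \code{non-HDACi}. The probability is always reported.
#'
#' @param model A two-class \linkS4class{NSCModel} with classes
#'   \code{HDACi}, \code{non-HDACi}.
#' @param x A \linkS4class{ProfileSet}.
#' @param cutoff posterior cutoff, default 0.9 (strict \code{>}).
#' @return data.frame with columns \code{compound},
#'   \code{p_hdaci}, \code{call}.
#' @export
classifyNSC <- function(model, x, cutoff = 0.9) {
    if (!identical(model@classes, .TREATED_LEVELS))
        stop("classifyNSC needs a two-class HDACi / non-HDACi model",
             call. = FALSE)
    p <- classProbabilities(model, x)[, "HDACi"]
    data.frame(compound = compoundNames(x),
               p_hdaci = unname(p),
               call = ifelse(p > cutoff, "HDACi", "non-HDACi"),
               stringsAsFactors = FALSE)
}

# Compound-level, class-stratified fold assignment: within each class the
# compounds are shuffled and dealt round-robin, so a 10+10 design at k = 10
# yields one compound of each class per fold.
.assignFolds <- function(labels, compounds, k, seed) {
    set.seed(seed)
    fold <- setNames(integer(length(compounds)), compounds)
    for (cl in unique(labels)) {
        idx <- which(labels == cl)
        fold[idx[sample.int(length(idx))]] <-
            rep_len(seq_len(k), length(idx))
    }
    fold
}

#' Shrinkage path with k-fold cross-validation
#'
#' For every threshold on the grid, fits on k-1 folds and classifies the
#' held-out fold with the probability rule (an HDACi compound failing the
#' cutoff counts as an error), recording the surviving-gene count and the CV
#' accuracy. Folds are assigned at the compound level, stratified by class,
#' from the supplied seed.
#'
#' @param x A labeled per-compound \linkS4class{ProfileSet}.
#' @param thresholds optional increasing grid; default 30 evenly spaced
#'   values from 0 to the smallest shrinkage that removes every gene.
#' @param nfolds number of folds, default 10.
#' @param cutoff posterior cutoff for the held-out calls, default 0.9.
#' @param seed integer seed for the fold assignment (mandatory).
#' @param priors passed to \code{\link{fitNSC}}.
#' @return A \linkS4class{ShrinkagePath}.
#' @export
shrinkagePath <- function(x, thresholds = NULL, nfolds = 10, cutoff = 0.9,
                          seed, priors = "uniform") {
    stopifnot(is(x, "ProfileSet"))
    if (missing(seed)) stop("a seed is mandatory for fold assignment",
                            call. = FALSE)
    n <- ncol(x)
    if (nfolds > n)
        stop(sprintf("cannot make %d folds from %d compounds", nfolds, n),
             call. = FALSE)
    full <- fitNSC(x, delta = 0, priors = priors)
    if (is.null(thresholds))
        thresholds <- seq(0, max(abs(full@dstat)), length.out = 30L)
    stopifnot(!is.unsorted(thresholds, strictly = TRUE))
    fold <- .assignFolds(classLabels(x), compoundNames(x), nfolds, seed)
    survived <- vapply(thresholds, function(d)
        length(survivingGenes(reshrink(full, d))), integer(1))
    correct <- matrix(0L, length(thresholds), n)
    for (f in seq_len(nfolds)) {
        held <- which(fold == f)
        if (!length(held)) next
        trainFit <- fitNSC(x[, -held], delta = 0, priors = priors)
        for (t in seq_along(thresholds)) {
            m <- reshrink(trainFit, thresholds[t])
            if (!length(survivingGenes(m))) next  # no call possible: error
            calls <- classifyNSC(m, x[, held, drop = FALSE], cutoff = cutoff)
            correct[t, held] <- as.integer(calls$call ==
                                           classLabels(x)[held])
        }
    }
    new("ShrinkagePath", thresholds = as.numeric(thresholds),
        genesSurviving = survived, cvAccuracy = rowMeans(correct),
        foldAssignment = fold, nfolds = as.integer(nfolds))
}

#' Select the shrinkage threshold
#'
#' Among thresholds whose CV accuracy meets \code{minAccuracy} and whose
#' surviving-gene count falls in \code{geneRange}, returns the largest
#' threshold (most shrinkage, smallest panel). If accuracy is met but no
#' panel lands in the range, the accuracy-meeting threshold with gene count
#' nearest the range is returned with a warning. No threshold meeting the
#' accuracy floor is an error.
#'
#' @param path A \linkS4class{ShrinkagePath}.
#' @param geneRange integer length-2 target panel-size range,
#'   default \code{c(50, 100)}.
#' @param minAccuracy minimum CV accuracy, default 0.95.
#' @return list with \code{delta}, \code{genes}, \code{accuracy}.
#' @export
selectShrinkage <- function(path, geneRange = c(50, 100), minAccuracy = 0.95) {
    stopifnot(is(path, "ShrinkagePath"), length(path@thresholds) > 0)
    acc <- path@cvAccuracy >= minAccuracy
    if (!any(acc))
        stop(sprintf(
            "no threshold reaches CV accuracy %.3g (best achieved: %.3g)",
            minAccuracy, max(path@cvAccuracy)), call. = FALSE)
    g <- path@genesSurviving
    inRange <- acc & g >= geneRange[1] & g <= geneRange[2]
    idx <- if (any(inRange)) {
        max(which(inRange))
    } else {
        distTo <- pmax(geneRange[1] - g, g - geneRange[2], 0)
        distTo[!acc] <- Inf
        i <- which(distTo == min(distTo))
        i <- i[length(i)]
        warning(sprintf(
            "no accuracy-meeting panel within [%d, %d] genes; nearest is %d",
            geneRange[1], geneRange[2], g[i]), call. = FALSE)
        i
    }
    list(delta = path@thresholds[idx], genes = g[idx],
         accuracy = path@cvAccuracy[idx])
}
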