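# The frozen 19-gene HDACi biomarker panel: loading, integrity checking,
# conversion to a classifier, and alignment of incoming profiles to a panel.

# MD5 of the shipped asset file; verified at load so silent corruption of the
# frozen panel is impossible.
.BUILTIN_ASSET_FILE <- "tgx_hdaci_19.json"
.BUILTIN_ASSET_MD5 <- "53e3c604e8a04c36da64cbadcb68f534"

#' Read a biomarker asset from JSON
#'
#' The on-disk schema has fields \code{name}, \code{genes},
#' \code{centroids} (one array per class, \code{HDACi} and
#' \code{non-HDACi}), \code{sd}, \code{priors}, \code{cutoff},
#' \code{provenance}. The same schema is written by
#' \code{\link{writeBiomarkerAsset}} and by the derivation pipeline, so a
#' derived model is immediately loadable as a frozen panel.
#'
#' @param path JSON file path.
#' @return A \linkS4class{BiomarkerAsset}.
#' @export
readBiomarkerAsset <- function(path) {
    j <- jsonlite::read_json(path, simplifyVector = TRUE)
    centroids <- cbind("HDACi" = j$centroids[["HDACi"]],
                       "non-HDACi" = j$centroids[["non-HDACi"]])
    rownames(centroids) <- j$genes
    new("BiomarkerAsset", name = j$name, genes = j$genes,
        centroids = centroids, sd = as.numeric(j$sd),
        priors = setNames(as.numeric(j$priors), colnames(centroids)),
        cutoff = as.numeric(j$cutoff), provenance = j$provenance)
}

#' Write a biomarker asset to JSON
#'
#' @param asset A \linkS4class{BiomarkerAsset}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeBiomarkerAsset <- function(asset, path) {
    stopifnot(is(asset, "BiomarkerAsset"))
    jsonlite::write_json(list(
        name = asset@name,
        genes = asset@genes,
        centroids = list("HDACi" = asset@centroids[, "HDACi"],
                         "non-HDACi" = asset@centroids[, "non-HDACi"]),
        sd = asset@sd,
        priors = as.numeric(asset@priors),
        cutoff = asset@cutoff,
        provenance = asset@provenance),
        path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    invisible(path)
}

#' Load the packaged 19-gene HDACi biomarker
#'
#' The TGx-HDACi 19-gene panel (the subset of the 81-gene HDACi biomarker
#' lying on the S1500+ sentinel gene set), shipped with per-class shrunken
#' centroids, per-gene standardization SDs, uniform priors and the 0.9
#' probability cutoff. The shipped file is checksum-verified on every load.
#'
#' @return A \linkS4class{BiomarkerAsset} named \code{"TGx-HDACi-19"}.
#' @examples
#' builtinBiomarker()
#' @export
builtinBiomarker <- function() {
    path <- system.file("extdata", .BUILTIN_ASSET_FILE,
                        package = "hdacscreen", mustWork = TRUE)
    .verifiedReadAsset(path, .BUILTIN_ASSET_MD5)
}

.verifiedReadAsset <- function(path, expectedMd5) {
    md5 <- unname(tools::md5sum(path))
    if (!identical(md5, expectedMd5))
        stop("biomarker asset failed its integrity check (md5 ", md5,
             "); the file is corrupt", call. = FALSE)
    readBiomarkerAsset(path)
}

#' Turn a frozen panel into an NSC classifier
#'
#' The asset's centroids are used directly as the shrunken class centroids
#' and its SD column as the per-gene standardization denominator, so the
#' discriminant is
#' \deqn{\delta_k(x) = \sum_i (x_i - c_{ik})^2 / sd_i^2 - 2 \log \pi_k.}
#' No further shrinkage is applied; all panel genes survive.
#'
#' @param asset A \linkS4class{BiomarkerAsset}.
#' @return A \linkS4class{NSCModel} with every panel gene surviving.
#' @export
assetToModel <- function(asset) {
    stopifnot(is(asset, "BiomarkerAsset"))
    classes <- colnames(asset@centroids)
    d <- asset@centroids / asset@sd
    new("NSCModel", genes = asset@genes, classes = classes,
        overallCentroid = setNames(rep(0, length(asset@genes)), asset@genes),
        classCentroids = asset@centroids,
        pooledSD = setNames(asset@sd, asset@genes), s0 = 0,
        priors = asset@priors, mk = setNames(c(1, 1), classes),
        delta = 0, dstat = d, shrunkenDstat = d)
}

#' Export a fitted model as a frozen panel
#'
#' Restricts a fitted \linkS4class{NSCModel} to its surviving genes and
#' freezes the shrunken centroids together with the per-gene denominator
#' \eqn{s_i + s_0}, in the same schema as the packaged panel. Applying the
#' exported asset via \code{\link{assetToModel}} reproduces the fitted
#' model's discriminant exactly.
#'
#' @param model A two-class \linkS4class{NSCModel}.
#' @param name asset name.
#' @param cutoff probability cutoff to freeze, default 0.9.
#' @param provenance free-text provenance string.
#' @return A \linkS4class{BiomarkerAsset}.
#' @export
modelToAsset <- function(model, name, cutoff = 0.9,
                         provenance = "derived in-session") {
    stopifnot(is(model, "NSCModel"))
    surv <- survivingGenes(model)
    if (!length(surv)) stop("fully shrunken model", call. = FALSE)
    idx <- match(surv, model@genes)
    new("BiomarkerAsset", name = name, genes = surv,
        centroids = shrunkenCentroids(model)[idx, , drop = FALSE],
        sd = unname(model@pooledSD[idx] + model@s0),
        priors = model@priors, cutoff = cutoff, provenance = provenance)
}

#' Align profiles to a biomarker panel
#'
#' Reorders (and subsets) a profile set to a panel's gene order — the only
#' sanctioned reordering path in the package. By default every panel gene
#' must be present; with \code{maxMissing > 0}, up to that many absent genes
#' are imputed as 0 (null response) with a prominent warning.
#'
#' @param x A \linkS4class{ProfileSet}.
#' @param panel A \linkS4class{BiomarkerAsset}, \linkS4class{NSCModel}
#'   (surviving genes), or character vector of gene symbols.
#' @param maxMissing maximum number of absent panel genes tolerated,
#'   default 0 (fail closed).
#' @return A \linkS4class{ProfileSet} in panel gene order.
#' @export
subsetProfiles <- function(x, panel, maxMissing = 0) {
    stopifnot(is(x, "ProfileSet"))
    genes <- if (is.character(panel)) panel
             else if (is(panel, "BiomarkerAsset")) panel@genes
             else if (is(panel, "NSCModel")) survivingGenes(panel)
             else stop("unsupported panel type", call. = FALSE)
    missing <- setdiff(genes, geneSymbols(x))
    if (length(missing) > maxMissing)
        stop("profiles are missing panel gene(s): ",
             paste(missing, collapse = ", "), call. = FALSE)
    lfc <- assay(x, "log2fc")
    out <- matrix(0, length(genes), ncol(x),
                  dimnames = list(genes, colnames(lfc)))
    present <- intersect(genes, rownames(lfc))
    out[present, ] <- lfc[present, , drop = FALSE]
    if (length(missing))
        warning("panel gene(s) absent and imputed as 0 (null response): ",
                paste(missing, collapse = ", "), call. = FALSE)
    ProfileSet(out, compound = compoundNames(x),
               class_label = classLabels(x),
               replicate = colData(x)$replicate)
}
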