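# Readers and writers for the delimited tables the pipeline touches.
# Delimiter is auto-detected from the header line (tab preferred, comma
# fallback); all output is tab-delimited at full double precision. Readers
# never reorder rows or columns; writers refuse mismatched gene lists rather
# than silently reordering them.

.detectSep <- function(path) {
    header <- readLines(path, n = 1L)
    if (length(header) == 0L || !nzchar(header))
        stop("empty file: ", path, call. = FALSE)
    if (grepl("\t", header)) "\t" else if (grepl(",", header)) ","
    else stop("cannot detect delimiter (no tab or comma in header): ", path,
              call. = FALSE)
}

.readNumericTable <- function(path, what) {
    sep <- .detectSep(path)
    df <- read.delim(path, sep = sep, header = TRUE, check.names = FALSE,
                     colClasses = "character", stringsAsFactors = FALSE)
    if (nrow(df) == 0L) stop("empty table (no data rows): ", path,
                             call. = FALSE)
    ids <- df[[1L]]
    if (anyDuplicated(ids))
        stop(sprintf("duplicate %s symbol(s): %s", what,
                     paste(unique(ids[duplicated(ids)]), collapse = ", ")),
             call. = FALSE)
    vals <- as.matrix(df[, -1L, drop = FALSE])
    num <- suppressWarnings(array(as.numeric(vals), dim = dim(vals)))
    if (any(bad <- is.na(num) & !is.na(vals))) {
        idx <- which(bad, arr.ind = TRUE)[1L, ]
        stop(sprintf("non-numeric value '%s' at row %d (%s), column %d (%s)",
                     vals[idx[1L], idx[2L]], idx[1L], ids[idx[1L]], idx[2L],
                     colnames(vals)[idx[2L]]), call. = FALSE)
    }
    dimnames(num) <- list(ids, colnames(vals))
    num
}

.writeTable <- function(m, path, idColumn) {
    df <- data.frame(m, check.names = FALSE)
    df <- cbind(setNames(data.frame(rownames(m)), idColumn), df)
    write.table(format(df, digits = 15, trim = TRUE, scientific = FALSE),
                path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Read a gene-by-sample count table
#'
#' Reads the genes-in-rows dialect used for deposited normalized count
#' matrices: first column gene symbols, header row of sample IDs, tab- or
#' comma-delimited. Row and column order are preserved exactly as on disk.
#'
#' @param path file path.
#' @param unit whether the file holds \code{"raw"} read counts or
#'   \code{"cpm"}-normalized values; recorded, never inferred.
#' @param sampleData optional sample metadata, see \code{\link{CountMatrix}}.
#' @return A \linkS4class{CountMatrix}.
#' @examples
#' tf <- tempfile(fileext = ".txt")
#' writeLines("Gene\ts1\ts2\nBMF\t10\t0\nID1\t0\t5", tf)
#' readCountMatrix(tf, unit = "raw")
#' @export
readCountMatrix <- function(path, unit = c("raw", "cpm"), sampleData = NULL) {
    unit <- match.arg(unit)
    CountMatrix(.readNumericTable(path, "gene"), sampleData = sampleData,
                unit = unit)
}

#' Write a CountMatrix
#'
#' Tab-delimited, genes in rows, full double precision. Round-trips through
#' \code{\link{readCountMatrix}} exactly on names and to at least 12
#' significant digits on values.
#'
#' @param x A \linkS4class{CountMatrix}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeCountMatrix <- function(x, path) {
    stopifnot(is(x, "CountMatrix"))
    .writeTable(assay(x, "counts"), path, "Gene")
}

#' Validate a sample-metadata table
#'
#' Checks the six required columns, that every non-empty
#' \code{vehicle_control_id} resolves to a sample with
#' \code{class_label == "control"}, and that (compound, replicate, batch) is
#' unique.
#'
#' @param meta data.frame of sample metadata.
#' @return \code{meta}, invisibly, with \code{replicate} coerced to integer.
#' @export
validateSampleMetadata <- function(meta) {
    missing <- setdiff(.META_COLUMNS, colnames(meta))
    if (length(missing))
        stop("metadata is missing required column(s): ",
             paste(missing, collapse = ", "), call. = FALSE)
    if (anyDuplicated(meta$sample_id))
        stop("duplicate sample_id in metadata", call. = FALSE)
    if (!all(meta$class_label %in% .CLASS_LEVELS))
        stop("invalid class_label value(s): ",
             paste(setdiff(meta$class_label, .CLASS_LEVELS), collapse = ", "),
             call. = FALSE)
    meta$replicate <- as.integer(meta$replicate)
    ref <- meta$vehicle_control_id
    nonEmpty <- !is.na(ref) & nzchar(ref)
    controls <- meta$sample_id[meta$class_label == "control"]
    dangling <- setdiff(unique(ref[nonEmpty]), controls)
    if (length(dangling))
        stop("vehicle_control_id does not resolve to a control sample: ",
             paste(dangling, collapse = ", "), call. = FALSE)
    treated <- meta$class_label %in% .TREATED_LEVELS
    key <- paste(meta$compound, meta$replicate, meta$batch)[treated]
    if (anyDuplicated(key))
        stop("duplicate (compound, replicate, batch): ",
             paste(unique(key[duplicated(key)]), collapse = "; "),
             call. = FALSE)
    invisible(meta)
}

#' Read a sample-metadata table
#'
#' Delimited text with columns \code{sample_id}, \code{compound},
#' \code{class_label}, \code{replicate}, \code{vehicle_control_id},
#' \code{batch}. Control references are resolved at read time; a dangling
#' reference is an error.
#'
#' @param path file path.
#' @return data.frame of validated records, one per sample.
#' @export
readSampleMetadata <- function(path) {
    sep <- .detectSep(path)
    meta <- read.delim(path, sep = sep, header = TRUE,
                       colClasses = "character", stringsAsFactors = FALSE)
    meta <- validateSampleMetadata(meta)
    meta$replicate <- as.integer(meta$replicate)
    meta
}

#' Write compound profiles
#'
#' Genes in rows, compounds in columns, tab-delimited, full precision. All
#' profiles must share one identical, identically ordered gene list; a
#' mismatch is an error — \code{\link{subsetProfiles}} is the only reordering
#' path.
#'
#' @param x A \linkS4class{ProfileSet}.
#' @param path output file path.
#' @param labelsPath optional path for a companion table of compound,
#'   class_label (needed to round-trip labels).
#' @return \code{path}, invisibly.
#' @export
writeProfiles <- function(x, path, labelsPath = NULL) {
    stopifnot(is(x, "ProfileSet"))
    .writeTable(assay(x, "log2fc"), path, "Gene")
    if (!is.null(labelsPath)) {
        write.table(data.frame(compound = compoundNames(x),
                               class_label = classLabels(x)),
                    labelsPath, sep = "\t", quote = FALSE, row.names = FALSE)
    }
    invisible(path)
}

#' Read compound profiles
#'
#' Inverse of \code{\link{writeProfiles}}: genes in rows, compounds in
#' columns. Row/column order is preserved as on disk.
#'
#' @param path profiles file path.
#' @param labelsPath optional companion labels table (columns compound,
#'   class_label); when absent, labels default to \code{"unknown"}.
#' @return A \linkS4class{ProfileSet}.
#' @export
readProfiles <- function(path, labelsPath = NULL) {
    m <- .readNumericTable(path, "gene")
    labels <- rep("unknown", ncol(m))
    if (!is.null(labelsPath)) {
        lab <- read.delim(labelsPath, sep = .detectSep(labelsPath),
                          colClasses = "character")
        if (!all(c("compound", "class_label") %in% colnames(lab)))
            stop("labels table needs columns compound, class_label",
                 call. = FALSE)
        idx <- match(colnames(m), lab$compound)
        if (anyNA(idx))
            stop("labels missing for compound(s): ",
                 paste(colnames(m)[is.na(idx)], collapse = ", "),
                 call. = FALSE)
        labels <- lab$class_label[idx]
    }
    ProfileSet(m, compound = colnames(m), class_label = labels)
}

#' Column-bind profile sets
#'
#' Combines several \linkS4class{ProfileSet}s over an identical, identically
#' ordered gene list. A mismatched or reordered gene list is an error; use
#' \code{\link{subsetProfiles}} to align explicitly.
#'
#' @param ... \linkS4class{ProfileSet} objects.
#' @return A \linkS4class{ProfileSet}.
#' @export
combineProfiles <- function(...) {
    sets <- list(...)
    genes <- geneSymbols(sets[[1L]])
    for (s in sets[-1L])
        if (!identical(geneSymbols(s), genes))
            stop("profiles have mismatched gene lists; align explicitly with ",
                 "subsetProfiles()", call. = FALSE)
    ProfileSet(do.call(cbind, lapply(sets, assay, "log2fc")),
               compound = unlist(lapply(sets, compoundNames)),
               class_label = unlist(lapply(sets, classLabels)))
}
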