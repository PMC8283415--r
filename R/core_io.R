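#' Read an OTU count table from a tab-separated file
#'
#' Reads a TSV whose first column holds row identifiers and whose header
#' holds column identifiers; a leading \code{"#OTU ID"} header cell
#' (BIOM-style) is accepted. Cells must be non-negative integers.
#'
#' @param path path to the TSV file
#' @param orientation whether rows of the file are OTUs
#'   (\code{"otus-as-rows"}, the common export convention and the default)
#'   or samples (\code{"samples-as-rows"})
#' @param sampleData optional metadata data.frame or a path readable by
#'   \code{\link{readSampleMetadata}}
#' @return an \linkS4class{OtuExperiment}
#' @seealso \code{\link{writeOtuTable}}
#' @export
readOtuTable <- function(path,
                         orientation = c("otus-as-rows", "samples-as-rows"),
                         sampleData = NULL) {
    orientation <- match.arg(orientation)
    first <- readLines(path, n = 1L)
    df <- utils::read.table(path, header = TRUE, sep = "\t",
                            comment.char = "", check.names = FALSE,
                            stringsAsFactors = FALSE, quote = "")
    colnames(df)[1] <- "id"
    if (anyDuplicated(df$id))
        stop("duplicated row id(s): ",
             paste(unique(df$id[duplicated(df$id)]), collapse = ", "))
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- df$id
    bad <- which(!is.finite(m) | m < 0 | m != round(m), arr.ind = TRUE)
    if (nrow(bad))
        stop(sprintf("non-count value at row '%s', column '%s'",
                     rownames(m)[bad[1, 1]], colnames(m)[bad[1, 2]]))
    if (is.character(sampleData))
        sampleData <- readSampleMetadata(sampleData)
    OtuExperiment(m, sampleData = sampleData, orientation = orientation)
}

#' Write an OTU count table as TSV
#'
#' Writes OTUs as rows with a \code{"#OTU ID"} header cell, the inverse of
#' \code{\link{readOtuTable}}; the round trip is exact.
#'
#' @param x an \linkS4class{OtuExperiment}
#' @param path output path
#' @return \code{path}, invisibly
#' @export
writeOtuTable <- function(x, path) {
    m <- otuCounts(x)
    df <- data.frame("#OTU ID" = rownames(m), m, check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Read per-sample metadata
#'
#' Expects a TSV with columns \code{sample_id}, \code{treatment},
#' \code{dose} and optionally \code{replicate}.
#'
#' @param path path to the TSV file
#' @return data.frame keyed by \code{sample_id}
#' @export
readSampleMetadata <- function(path) {
    df <- utils::read.table(path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
    need <- c("sample_id", "treatment", "dose")
    if (!all(need %in% colnames(df)))
        stop("metadata needs columns: ", paste(need, collapse = ", "))
    if (anyDuplicated(df$sample_id))
        stop("duplicated sample_id in metadata")
    if (any(df$dose < 0)) stop("dose must be >= 0")
    df
}

#' Rarefy every sample to a common depth
#'
#' Subsamples each sample's reads without replacement (multivariate
#' hypergeometric) down to \code{depth}, the standard normalisation for
#' unequal sequencing effort. OTUs whose total count drops to zero are
#' retained so identifier spaces stay aligned across treatments; downstream
#' operations ignore all-zero rows.
#'
#' @param x an \linkS4class{OtuExperiment}
#' @param depth target reads per sample; every sample must have at least
#'   this many
#' @param seed integer seed controlling the subsampling (never global state)
#' @return a rarefied \linkS4class{OtuExperiment} with identical ids
#' @export
rarefyTable <- function(x, depth, seed) {
    m <- otuCounts(x)
    tot <- colSums(m)
    low <- tot < depth
    if (any(low))
        stop("sample(s) below depth ", depth, ": ",
             paste(colnames(m)[low], collapse = ", "))
    out <- m
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    for (j in seq_len(ncol(m))) {
        if (depth == 0) { out[, j] <- 0; next }
        if (tot[j] == depth) next
        idx <- rep.int(seq_len(nrow(m)), m[, j])
        keep <- sample(idx, depth, replace = FALSE)
        out[, j] <- tabulate(keep, nbins = nrow(m))
    }
    y <- x
    SummarizedExperiment::assay(y, "counts") <- out
    validObject(y)
    y
}

#' Relative abundance matrix
#'
#' Converts counts to per-sample proportions; each sample (column) sums to 1.
#'
#' @param x an \linkS4class{OtuExperiment} or a count matrix with OTUs as
#'   rows
#' @return numeric matrix of proportions, OTUs as rows
#' @export
relAbundance <- function(x) {
    m <- if (is(x, "OtuExperiment")) otuCounts(x) else as.matrix(x)
    tot <- colSums(m)
    if (any(tot <= 0))
        stop("all-zero sample(s): ",
             paste(colnames(m)[tot <= 0], collapse = ", "))
    sweep(m, 2, tot, "/")
}

#' Subset an OtuExperiment to the samples of one or more treatments
#'
#' @param x an \linkS4class{OtuExperiment} with a \code{treatment} column
#' @param treatment character vector of treatment labels
#' @return an \linkS4class{OtuExperiment}
#' @export
treatmentSamples <- function(x, treatment) {
    tr <- treatments(x)
    unknown <- setdiff(treatment, unique(tr))
    if (length(unknown))
        stop("unknown treatment(s): ", paste(unknown, collapse = ", "))
    x[, tr %in% treatment]
}
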