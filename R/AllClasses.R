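#' @import methods
#' @importFrom S4Vectors DataFrame SimpleList metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assay<- assays
#'   colData colData<- rowData rowData<-
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom Rcpp sourceCpp
#' @useDynLib microassembly, .registration = TRUE
NULL

#' OtuExperiment: a validated OTU count table with sample metadata
#'
#' An \code{OtuExperiment} holds a single integer count assay named
#' \code{"counts"} with OTUs as rows and samples as columns, following the
#' Bioconductor features-by-samples orientation. Sample metadata (treatment
#' label, stressor dose, replicate) live in \code{colData}; optional taxonomy
#' strings live in \code{rowData$taxonomy}.
#'
#' Validity requires unique, non-empty OTU and sample identifiers,
#' non-negative integral counts, and — when present — a numeric
#' \code{colData$dose} with no negative entries and exactly one metadata row
#' per sample (guaranteed by construction from \code{colData}).
#'
#' @slot .	inherits all slots from \linkS4class{SummarizedExperiment}
#' @seealso \code{\link{OtuExperiment}} (constructor),
#'   \code{\link{readOtuTable}}, \code{\link{rarefyTable}}
#' @exportClass OtuExperiment
setClass("OtuExperiment", contains = "SummarizedExperiment")

.validOtuExperiment <- function(object) {
    msg <- NULL
    if (!"counts" %in% names(assays(object)))
        msg <- c(msg, "assay 'counts' is required")
    else {
        m <- assay(object, "counts")
        if (is.null(rownames(m)) || is.null(colnames(m)))
            msg <- c(msg, "counts must carry OTU (row) and sample (column) names")
        else {
            if (anyDuplicated(rownames(m)))
                msg <- c(msg, sprintf("duplicated OTU ids: %s",
                    paste(unique(rownames(m)[duplicated(rownames(m))]),
                          collapse = ", ")))
            if (anyDuplicated(colnames(m)))
                msg <- c(msg, sprintf("duplicated sample ids: %s",
                    paste(unique(colnames(m)[duplicated(colnames(m))]),
                          collapse = ", ")))
        }
        if (any(!is.finite(m)) || any(m < 0))
            msg <- c(msg, "counts must be finite and non-negative")
        else if (any(m != round(m)))
            msg <- c(msg, "counts must be integral")
    }
    if ("dose" %in% colnames(colData(object))) {
        dose <- colData(object)$dose
        if (!is.numeric(dose) || any(is.na(dose)) || any(dose < 0))
            msg <- c(msg, "dose must be numeric and >= 0")
    }
    if (is.null(msg)) TRUE else msg
}
setValidity("OtuExperiment", .validOtuExperiment)

#' Construct an OtuExperiment
#'
#' @param counts integer matrix of read counts. Orientation is given by
#'   \code{orientation}; internally OTUs are stored as rows.
#' @param sampleData optional \code{data.frame}/\code{DataFrame} of per-sample
#'   metadata with columns such as \code{treatment}, \code{dose},
#'   \code{replicate}. Row order must match the samples of \code{counts} or
#'   carry a \code{sample_id} column to match on.
#' @param taxonomy optional named character vector of lineage strings,
#'   names = OTU ids.
#' @param orientation \code{"otus-as-rows"} (default) or
#'   \code{"samples-as-rows"}.
#' @return a validated \linkS4class{OtuExperiment}
#' @examples
#' m <- matrix(rpois(12, 5), nrow = 4,
#'             dimnames = list(paste0("OTU", 1:4), paste0("S", 1:3)))
#' oe <- OtuExperiment(m)
#' otuCounts(oe)[1:2, ]
#' @export
OtuExperiment <- function(counts, sampleData = NULL, taxonomy = NULL,
                          orientation = c("otus-as-rows", "samples-as-rows")) {
    orientation <- match.arg(orientation)
    counts <- as.matrix(counts)
    if (orientation == "samples-as-rows") counts <- t(counts)
    storage.mode(counts) <- "double"
    cd <- DataFrame(row.names = colnames(counts))
    if (!is.null(sampleData)) {
        sampleData <- as.data.frame(sampleData)
        if ("sample_id" %in% colnames(sampleData)) {
            rownames(sampleData) <- sampleData$sample_id
            sampleData$sample_id <- NULL
        }
        missing <- setdiff(colnames(counts), rownames(sampleData))
        if (length(missing))
            stop("metadata missing for sample(s): ",
                 paste(missing, collapse = ", "))
        cd <- DataFrame(sampleData[colnames(counts), , drop = FALSE])
    }
    rd <- DataFrame(row.names = rownames(counts))
    if (!is.null(taxonomy))
        rd$taxonomy <- unname(taxonomy[rownames(counts)])
    se <- SummarizedExperiment(assays = SimpleList(counts = counts),
                               colData = cd, rowData = rd)
    new("OtuExperiment", se)
}

#' @rdname OtuExperiment-accessors
#' @export
setGeneric("otuCounts", function(x) standardGeneric("otuCounts"))

#' Accessors for OtuExperiment
#'
#' \code{otuCounts} returns the OTU-by-sample count matrix; \code{otuIds} and
#' \code{sampleIds} the identifier vectors; \code{treatments} the per-sample
#' treatment labels (errors if absent).
#'
#' @param x an \linkS4class{OtuExperiment}
#' @return matrix or character vector
#' @name OtuExperiment-accessors
#' @aliases otuCounts otuIds sampleIds treatments
#' @export
setMethod("otuCounts", "OtuExperiment", function(x) assay(x, "counts"))

#' @rdname OtuExperiment-accessors
#' @export
setGeneric("otuIds", function(x) standardGeneric("otuIds"))
#' @rdname OtuExperiment-accessors
setMethod("otuIds", "OtuExperiment", function(x) rownames(x))

#' @rdname OtuExperiment-accessors
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))
#' @rdname OtuExperiment-accessors
setMethod("sampleIds", "OtuExperiment", function(x) colnames(x))

#' @rdname OtuExperiment-accessors
#' @export
setGeneric("treatments", function(x) standardGeneric("treatments"))
#' @rdname OtuExperiment-accessors
setMethod("treatments", "OtuExperiment", function(x) {
    cd <- colData(x)
    if (!"treatment" %in% colnames(cd))
        stop("no 'treatment' column in sample metadata")
    setNames(as.character(cd$treatment), rownames(cd))
})

setMethod("show", "OtuExperiment", function(object) {
    cat(sprintf("OtuExperiment: %d OTUs x %d samples\n",
                nrow(object), ncol(object)))
    tot <- colSums(otuCounts(object))
    cat(sprintf("  per-sample depth: %s\n",
                if (length(unique(tot)) == 1L) format(tot[1])
                else sprintf("%s-%s", format(min(tot)), format(max(tot)))))
    if ("treatment" %in% colnames(colData(object))) {
        tab <- table(colData(object)$treatment)
        cat("  treatments:",
            paste(sprintf("%s(%d)", names(tab), tab), collapse = " "), "\n")
    }
})

#' AbundanceClassification: per-treatment abundance classes
#'
#' Per (treatment, OTU) class labels in
#' \{abundant, moderate, rare, absent\}, with the relative-abundance
#' statistics and cutoffs that produced them. Created by
#' \code{\link{classifyAbundance}}.
#'
#' @slot table data.frame with columns \code{treatment}, \code{otu_id},
#'   \code{class} (factor), \code{mean_rel_abund}, \code{max_rel_abund}
#' @slot abundantCut relative-abundance cutoff for the abundant class
#' @slot rareCut relative-abundance cutoff for the rare class
#' @exportClass AbundanceClassification
setClass("AbundanceClassification",
    representation(table = "data.frame", abundantCut = "numeric",
                   rareCut = "numeric"))

setValidity("AbundanceClassification", function(object) {
    msg <- NULL
    need <- c("treatment", "otu_id", "class", "mean_rel_abund",
              "max_rel_abund")
    if (!all(need %in% colnames(object@table)))
        msg <- c(msg, paste("table needs columns:",
                            paste(need, collapse = ", ")))
    else if (!all(levels(object@table$class) ==
                  c("abundant", "moderate", "rare", "absent")))
        msg <- c(msg, "class levels must be abundant/moderate/rare/absent")
    if (!(object@rareCut < object@abundantCut))
        msg <- c(msg, "rareCut must be < abundantCut")
    if (is.null(msg)) TRUE else msg
})

setMethod("show", "AbundanceClassification", function(object) {
    cat(sprintf(
        "AbundanceClassification (abundant >= %g in a sample, rare < %g treatment mean)\n",
        object@abundantCut, object@rareCut))
    print(with(object@table, table(treatment, class)))
})

#' @rdname classTable
#' @export
setGeneric("classTable", function(x, ...) standardGeneric("classTable"))

#' Long-format class table of an AbundanceClassification
#'
#' @param x an \linkS4class{AbundanceClassification}
#' @param ... unused
#' @return data.frame: treatment, otu_id, class, mean_rel_abund, max_rel_abund
#' @name classTable
#' @export
setMethod("classTable", "AbundanceClassification", function(x, ...) x@table)

#' NcmFit: a fitted Sloan neutral community model
#'
#' @slot m estimated immigration probability
#' @slot N community size (reads per sample, fixed at fit time)
#' @slot d detection limit on the relative-abundance scale
#' @slot Nm product N * m
#' @slot r.squared goodness of fit about the mean observed frequency
#' @slot nSamples number of samples the occurrence frequency is taken over
#' @slot otuStats data.frame: otu_id, p (mean relative abundance), freq_obs,
#'   freq_pred, ci_lo, ci_hi, partition in \{above, neutral, below\}
#' @exportClass NcmFit
setClass("NcmFit",
    representation(m = "numeric", N = "numeric", d = "numeric",
                   Nm = "numeric", r.squared = "numeric",
                   nSamples = "integer", otuStats = "data.frame"))

setMethod("show", "NcmFit", function(object) {
    cat(sprintf("Sloan neutral community model fit (%d OTUs, %d samples)\n",
                nrow(object@otuStats), object@nSamples))
    cat(sprintf("  m = %.4g   N = %.5g   Nm = %.5g   R2 = %.3f\n",
                object@m, object@N, object@Nm, object@r.squared))
    fr <- prop.table(table(object@otuStats$partition))
    cat("  partition:",
        paste(sprintf("%s %.1f%%", names(fr), 100 * fr), collapse = ", "),
        "\n")
})

#' @rdname ncmAccessors
#' @export
setGeneric("ncmSummary", function(x) standardGeneric("ncmSummary"))

#' Accessors for NcmFit
#'
#' \code{ncmSummary} returns the scalar fit summary as a list;
#' \code{ncmOtuStats} the per-OTU table.
#'
#' @param x an \linkS4class{NcmFit}
#' @return list or data.frame
#' @name ncmAccessors
#' @aliases ncmSummary ncmOtuStats
#' @export
setMethod("ncmSummary", "NcmFit", function(x)
    list(m = x@m, N = x@N, Nm = x@Nm, d = x@d, r.squared = x@r.squared,
         n_samples = x@nSamples))

#' @rdname ncmAccessors
#' @export
setGeneric("ncmOtuStats", function(x) standardGeneric("ncmOtuStats"))
#' @rdname ncmAccessors
setMethod("ncmOtuStats", "NcmFit", function(x) x@otuStats)

#' AssemblyResult: pairwise assembly-process classification
#'
#' Holds per-sample-pair beta-MNTD, beta-NTI, Raup-Crick (Bray-Curtis) and
#' the process label derived from the fixed decision rules. Created by
#' \code{\link{assemblyProcesses}}.
#'
#' @slot pairs data.frame: sample_a, sample_b, beta_mntd, bnti, rc_bray,
#'   process (factor over the five process labels)
#' @slot nNull number of null-model randomisations
#' @slot seed RNG seed used for the nulls
#' @exportClass AssemblyResult
setClass("AssemblyResult",
    representation(pairs = "data.frame", nNull = "integer",
                   seed = "integer"))

setValidity("AssemblyResult", function(object) {
    need <- c("sample_a", "sample_b", "bnti", "rc_bray", "process")
    if (!all(need %in% colnames(object@pairs)))
        return(paste("pairs needs columns:", paste(need, collapse = ", ")))
    ok <- is.na(object@pairs$rc_bray) |
        (object@pairs$rc_bray >= -1 & object@pairs$rc_bray <= 1)
    if (!all(ok)) return("rc_bray must lie in [-1, 1]")
    TRUE
})

setMethod("show", "AssemblyResult", function(object) {
    cat(sprintf("AssemblyResult: %d sample pairs, %d nulls (seed %d)\n",
                nrow(object@pairs), object@nNull, object@seed))
    fr <- prop.table(table(object@pairs$process))
    for (nm in names(fr))
        cat(sprintf("  %-22s %5.1f%%\n", nm, 100 * fr[[nm]]))
})

#' @rdname assemblyPairs
#' @export
setGeneric("assemblyPairs", function(x) standardGeneric("assemblyPairs"))

#' Per-pair table of an AssemblyResult
#'
#' @param x an \linkS4class{AssemblyResult}
#' @return data.frame of pairwise null-model statistics and process labels
#' @name assemblyPairs
#' @export
setMethod("assemblyPairs", "AssemblyResult", function(x) x@pairs)

#' CoocNetwork: a thresholded Spearman co-occurrence network
#'
#' @slot graph an \code{igraph} object; edge attribute \code{rho} carries the
#'   signed Spearman correlation
#' @slot threshold absolute-correlation cutoff used to admit edges
#' @slot nodes data.frame of per-node annotation and topology (filled by
#'   \code{\link{nodeTopology}}): otu_id, class, degree, betweenness,
#'   betweenness_norm, clustering
#' @exportClass CoocNetwork
setClass("CoocNetwork",
    representation(graph = "ANY", threshold = "numeric",
                   nodes = "data.frame"))

setMethod("show", "CoocNetwork", function(object) {
    g <- object@graph
    cat(sprintf("CoocNetwork: %d nodes, %d edges (|rho| >= %.2f)\n",
                igraph::vcount(g), igraph::ecount(g), object@threshold))
    if (nrow(object@nodes) && "class" %in% colnames(object@nodes)) {
        tab <- table(object@nodes$class)
        tab <- tab[tab > 0]
        cat("  node classes:",
            paste(sprintf("%s(%d)", names(tab), tab), collapse = " "), "\n")
    }
})

#' @rdname network-accessors
#' @export
setGeneric("networkGraph", function(x) standardGeneric("networkGraph"))

#' Accessors for CoocNetwork
#'
#' \code{networkGraph} returns the underlying igraph object;
#' \code{networkNodes} the per-node annotation table.
#'
#' @param x a \linkS4class{CoocNetwork}
#' @return igraph or data.frame
#' @name network-accessors
#' @aliases networkGraph networkNodes
#' @export
setMethod("networkGraph", "CoocNetwork", function(x) x@graph)

#' @rdname network-accessors
#' @export
setGeneric("networkNodes", function(x) standardGeneric("networkNodes"))
#' @rdname network-accessors
setMethod("networkNodes", "CoocNetwork", function(x) x@nodes)
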