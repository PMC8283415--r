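#' Classify OTUs as abundant, moderate or rare within each treatment
#'
#' Applies the fixed relative-abundance cutoffs used to delimit
#' subcommunities in stress-gradient microbiome studies: an OTU is
#' \emph{abundant} in a treatment if its relative abundance reaches
#' \code{abundantCut} in at least one sample of that treatment, \emph{rare}
#' if its mean relative abundance across the treatment's samples is below
#' \code{rareCut} (and it is not abundant), \emph{absent} if it has zero
#' counts in every sample of the treatment, and \emph{moderate} otherwise.
#' Abundant takes precedence when a spiky OTU satisfies both rules.
#'
#' With \code{global = TRUE} the samples are pooled into a single scope,
#' for sensitivity analysis.
#'
#' @param x an \linkS4class{OtuExperiment} with treatment metadata
#' @param abundantCut relative abundance defining the abundant class
#'   (default 0.01, i.e. 1\% in a sample)
#' @param rareCut treatment-mean relative abundance below which an OTU is
#'   rare (default 1e-4, i.e. 0.01\%)
#' @param global classify over all samples pooled instead of per treatment
#' @return an \linkS4class{AbundanceClassification}
#' @examples
#' sim <- simulateGradient(simulationConfig(nOtus = 60, seed = 1))
#' classifyAbundance(sim$table)
#' @export
classifyAbundance <- function(x, abundantCut = 0.01, rareCut = 1e-4,
                              global = FALSE) {
    if (!(abundantCut > 0 && abundantCut < 1 && rareCut > 0 &&
          rareCut < abundantCut))
        stop("cutoffs must satisfy 0 < rareCut < abundantCut < 1")
    rel <- relAbundance(x)
    tr <- if (global) setNames(rep("all", ncol(x)), sampleIds(x))
          else treatments(x)
    lv <- c("abundant", "moderate", "rare", "absent")
    res <- lapply(unique(tr), function(t) {
        sub <- rel[, tr == t, drop = FALSE]
        if (ncol(sub) == 0L) stop("treatment with no samples: ", t)
        mx <- apply(sub, 1, max)
        mn <- rowMeans(sub)
        cls <- ifelse(mx == 0, "absent",
               ifelse(mx >= abundantCut, "abundant",
               ifelse(mn < rareCut, "rare", "moderate")))
        data.frame(treatment = t, otu_id = rownames(sub),
                   class = factor(cls, levels = lv),
                   mean_rel_abund = mn, max_rel_abund = mx,
                   row.names = NULL)
    })
    new("AbundanceClassification", table = do.call(rbind, res),
        abundantCut = abundantCut, rareCut = rareCut)
}

#' Extract the subcommunity table of one abundance class
#'
#' Restricts the table to the samples of \code{treatment} and the OTUs of
#' the requested class there; counts are unchanged.
#'
#' @param x the \linkS4class{OtuExperiment} the classification was computed
#'   from
#' @param cls an \linkS4class{AbundanceClassification}
#' @param which one of \code{"abundant"}, \code{"moderate"}, \code{"rare"}
#' @param treatment a treatment label present in the classification
#' @return an \linkS4class{OtuExperiment}; empty (0 OTUs) with a warning if
#'   the class is unpopulated
#' @export
subcommunity <- function(x, cls, which = c("abundant", "moderate", "rare"),
                         treatment) {
    which <- match.arg(which)
    tab <- classTable(cls)
    if (!treatment %in% tab$treatment)
        stop("unknown treatment: ", treatment)
    ids <- tab$otu_id[tab$treatment == treatment & tab$class == which]
    if (!length(ids))
        warning("empty ", which, " subcommunity in ", treatment)
    y <- treatmentSamples(x, treatment)
    y[match(ids, otuIds(y)), ]
}

#' Track abundance-class transitions between two treatments
#'
#' One record per OTU present in either treatment, pairing its class in the
#' reference treatment with its class in the target — used e.g. to ask which
#' taxa that are rare in unpolluted soil turn abundant under stress.
#'
#' @param cls an \linkS4class{AbundanceClassification}
#' @param ref,target treatment labels
#' @return data.frame: otu_id, class_ref, class_target
#' @export
classTransitions <- function(cls, ref, target) {
    tab <- classTable(cls)
    for (t in c(ref, target))
        if (!t %in% tab$treatment) stop("unknown treatment: ", t)
    a <- tab[tab$treatment == ref, c("otu_id", "class")]
    b <- tab[tab$treatment == target, c("otu_id", "class")]
    m <- merge(a, b, by = "otu_id", suffixes = c("_ref", "_target"))
    present <- m$class_ref != "absent" | m$class_target != "absent"
    m[present, , drop = FALSE]
}
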