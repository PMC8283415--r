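#' Levins' niche breadth of one OTU
#'
#' \eqn{B = 1 / \sum_j P_j^2} where \eqn{P_j} is the proportion of the OTU's
#' abundance found in resource state \eqn{j}. B ranges from 1 (perfect
#' specialist, all abundance in one state) to \eqn{r} (perfect generalist,
#' uniform across the \eqn{r} states) and is invariant to rescaling.
#'
#' @param abundances non-negative abundance of the OTU across the resource
#'   states; must have a positive sum
#' @return niche breadth B in [1, r]
#' @export
levinsBreadth <- function(abundances) {
    if (any(abundances < 0) || sum(abundances) <= 0)
        stop("abundances must be non-negative with positive sum")
    p <- abundances / sum(abundances)
    1 / sum(p^2)
}

#' Community-level niche width
#'
#' Mean Levins breadth over the OTUs of a class (or all OTUs), with resource
#' states defined either as individual samples or as treatments (treatment
#' states use summed counts). OTUs absent from every state of the scope are
#' excluded — breadth is undefined for them — rather than contributing B = 0.
#'
#' @param x an \linkS4class{OtuExperiment}
#' @param cls optional \linkS4class{AbundanceClassification}; required when
#'   \code{which != "all"}
#' @param which abundance class to restrict to, or \code{"all"}
#' @param treatment optional treatment label: breadth is then computed over
#'   that treatment's samples only, and class membership is taken in that
#'   treatment
#' @param states resource-state definition, \code{"samples"} (default) or
#'   \code{"treatments"}
#' @return list with \code{width} (mean B), \code{breadths} (named per-OTU
#'   vector) and \code{r} (number of states); width is \code{NA} with a
#'   warning for an empty class
#' @export
communityNicheWidth <- function(x, cls = NULL,
                                which = c("all", "abundant", "moderate",
                                          "rare"),
                                treatment = NULL,
                                states = c("samples", "treatments")) {
    which <- match.arg(which)
    states <- match.arg(states)
    scope <- if (is.null(treatment)) x else treatmentSamples(x, treatment)
    m <- otuCounts(scope)
    if (states == "treatments") {
        tr <- treatments(scope)
        m <- vapply(unique(tr),
                    function(t) rowSums(m[, tr == t, drop = FALSE]),
                    numeric(nrow(m)))
    }
    if (ncol(m) < 2) stop("need at least 2 resource states")
    if (which != "all") {
        if (is.null(cls))
            stop("a classification is required for which = '", which, "'")
        tab <- classTable(cls)
        scopeTr <- if (is.null(treatment)) unique(tab$treatment) else treatment
        ids <- unique(tab$otu_id[tab$treatment %in% scopeTr &
                                 tab$class == which])
        m <- m[rownames(m) %in% ids, , drop = FALSE]
    }
    m <- m[rowSums(m) > 0, , drop = FALSE]
    if (!nrow(m)) {
        warning("no OTUs in scope; width is NA")
        return(list(width = NA_real_, breadths = numeric(0), r = ncol(m)))
    }
    B <- apply(m, 1, levinsBreadth)
    list(width = mean(B), breadths = B, r = ncol(m))
}
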