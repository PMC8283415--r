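#' Pairwise Spearman correlation among OTUs
#'
#' Applies a prevalence filter (OTU present in at least
#' \code{prevalenceMin} of the samples — the "majority rule" convention at
#' the default 1/3), then computes the rank correlation of every OTU pair
#' across samples with mid-ranked ties. OTUs with a constant abundance
#' vector have undefined correlations, reported as \code{NA}.
#'
#' @param x an \linkS4class{OtuExperiment} with >= 5 samples
#' @param prevalenceMin minimum fraction of samples an OTU must occur in
#' @return list: \code{rho} (symmetric, unit diagonal), \code{p} (two-sided
#'   t-approximation p-values), \code{otu_ids} (OTUs retained by the filter)
#' @export
spearmanMatrix <- function(x, prevalenceMin = 1/3) {
    m <- otuCounts(x)
    if (ncol(m) < 5) stop("need at least 5 samples")
    m <- m[rowMeans(m > 0) >= prevalenceMin, , drop = FALSE]
    if (nrow(m) < 2) stop("fewer than 2 OTUs pass the prevalence filter")
    n <- ncol(m)
    const <- apply(m, 1, function(v) length(unique(v)) == 1L)
    rho <- suppressWarnings(stats::cor(t(m), method = "spearman"))
    rho[const, ] <- NA_real_
    rho[, const] <- NA_real_
    diag(rho) <- 1
    tstat <- rho * sqrt((n - 2) / pmax(1 - rho^2, .Machine$double.eps))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
    diag(p) <- 0
    list(rho = rho, p = p, otu_ids = rownames(m))
}

# Unfold a sorted eigenvalue spectrum with a smooth (degree-5 polynomial)
# fit to the cumulative spectral function, and return nearest-neighbour
# spacings normalised to unit mean.
.nnsd <- function(ev) {
    ev <- sort(unique(round(ev, 10)))
    if (length(ev) < 21) return(NULL)
    n <- length(ev)
    cdf <- seq_len(n) / n
    fit <- stats::lm(cdf ~ stats::poly(ev, 5))
    unfolded <- n * stats::fitted(fit)
    s <- diff(sort(unfolded))
    s <- s[s >= 0]
    if (!length(s) || mean(s) == 0) return(NULL)
    s / mean(s)
}

# Chi-square goodness-of-fit p-value of spacings against the Poisson
# (exponential) spacing law, binned on [0, 3].
.poissonGofP <- function(s, nBins = 20) {
    brk <- seq(0, 3, length.out = nBins + 1)
    obs <- table(cut(pmin(s, 3 - 1e-9), brk, include.lowest = TRUE))
    expProb <- exp(-brk[-length(brk)]) - exp(-brk[-1])
    expProb[nBins] <- expProb[nBins] + exp(-3)  # fold the tail in
    E <- length(s) * expProb
    keep <- E > 0
    X2 <- sum((as.numeric(obs)[keep] - E[keep])^2 / E[keep])
    stats::pchisq(X2, df = sum(keep) - 1, lower.tail = FALSE)
}

#' Random-matrix-theory correlation threshold
#'
#' Scans candidate cutoffs from \code{tMin} to \code{tMax}; at each, entries
#' with \eqn{|\rho|} below the cutoff are zeroed and the nearest-neighbour
#' spacing distribution (NNSD) of the unfolded eigenvalue spectrum is
#' tested against the Poisson law. Dense correlated noise follows
#' Wigner-Dyson (level repulsion); once the retained structure is sparse and
#' modular the NNSD becomes Poisson. The smallest cutoff whose NNSD is
#' consistent with Poisson (chi-square p > 0.05) is returned.
#'
#' If no cutoff qualifies the fallback \code{fallback} is returned with a
#' warning (attribute \code{rmt = FALSE} flags it).
#'
#' @param rho symmetric Spearman correlation matrix (e.g. from
#'   \code{\link{spearmanMatrix}})
#' @param tMin,tMax,step scan range and increment
#' @param fallback cutoff used when the scan fails
#' @return the chosen threshold, with attributes \code{rmt} (logical: did
#'   the NNSD test pick it) and \code{p} (the accepting p-value, if any)
#' @export
rmtThreshold <- function(rho, tMin = 0.30, tMax = 0.99, step = 0.01,
                         fallback = 0.8) {
    rho[is.na(rho)] <- 0
    for (t in seq(tMin, tMax, by = step)) {
        A <- rho
        A[abs(A) < t] <- 0
        diag(A) <- 1
        s <- .nnsd(eigen(A, symmetric = TRUE, only.values = TRUE)$values)
        if (is.null(s)) next
        p <- .poissonGofP(s)
        if (!is.na(p) && p > 0.05)
            return(structure(t, rmt = TRUE, p = p))
    }
    warning("no cutoff passed the NNSD test; falling back to |rho| >= ",
            fallback)
    structure(fallback, rmt = FALSE, p = NA_real_)
}

#' Build a co-occurrence network from a correlation matrix
#'
#' Admits an edge for every OTU pair with \eqn{|\rho| \ge} threshold
#' (signed correlations kept as the edge attribute \code{rho});
#' \code{mode = "abundant-rare"} restricts edges to pairs linking one
#' abundant and one rare OTU. Nodes without edges are dropped. Per-node
#' topology is computed immediately (see \code{\link{nodeTopology}}).
#'
#' @param rho symmetric correlation matrix with OTU dimnames (or the list
#'   returned by \code{\link{spearmanMatrix}})
#' @param threshold absolute-correlation cutoff in (0, 1); e.g. the value
#'   from \code{\link{rmtThreshold}}
#' @param classes optional named character vector otu_id -> abundance class
#'   (from \code{\link{classTable}}); required for
#'   \code{mode = "abundant-rare"}
#' @param mode edge admission rule
#' @return a \linkS4class{CoocNetwork}; empty (0 nodes) with a warning if no
#'   edge passes
#' @export
buildNetwork <- function(rho, threshold, classes = NULL,
                         mode = c("all", "abundant-rare")) {
    mode <- match.arg(mode)
    if (is.list(rho)) rho <- rho$rho
    if (!(threshold > 0 && threshold <= 1))
        stop("threshold must lie in (0, 1]")
    A <- rho
    A[is.na(A)] <- 0
    diag(A) <- 0
    keep <- abs(A) >= threshold
    if (mode == "abundant-rare") {
        if (is.null(classes))
            stop("abundant-rare mode needs per-OTU classes")
        cl <- classes[rownames(A)]
        ar <- outer(cl == "abundant", cl == "rare", "&")
        keep <- keep & (ar | t(ar))
    }
    idx <- which(keep & upper.tri(keep), arr.ind = TRUE)
    if (!nrow(idx)) {
        warning("no edges at |rho| >= ", threshold)
        g <- igraph::make_empty_graph(0, directed = FALSE)
        return(new("CoocNetwork", graph = g, threshold = threshold,
                   nodes = data.frame()))
    }
    edges <- data.frame(from = rownames(A)[idx[, 1]],
                        to = colnames(A)[idx[, 2]],
                        rho = A[idx])
    g <- igraph::graph_from_data_frame(edges, directed = FALSE)
    if (!is.null(classes))
        igraph::V(g)$class <-
            unname(classes[igraph::V(g)$name])
    net <- new("CoocNetwork", graph = g, threshold = threshold,
               nodes = data.frame())
    net@nodes <- nodeTopology(net)
    net
}

#' Per-node topology of a co-occurrence network
#'
#' Degree, betweenness centrality (shortest-path counting on the unweighted
#' graph; reported raw, so the closed form \eqn{(n-1)(n-2)/2} holds for a
#' star centre, plus a normalised column) and the local clustering
#' coefficient (0 for nodes with fewer than two neighbours).
#'
#' @param net a \linkS4class{CoocNetwork}
#' @return data.frame: otu_id, class (if annotated), degree, betweenness,
#'   betweenness_norm, clustering
#' @export
nodeTopology <- function(net) {
    g <- networkGraph(net)
    if (igraph::vcount(g) == 0) return(data.frame())
    cc <- igraph::transitivity(g, type = "local", isolates = "zero")
    cc[is.na(cc)] <- 0
    out <- data.frame(
        otu_id = igraph::V(g)$name,
        degree = as.numeric(igraph::degree(g)),
        betweenness = as.numeric(igraph::betweenness(g, weights = NA,
                                                     normalized = FALSE)),
        betweenness_norm = as.numeric(igraph::betweenness(g, weights = NA,
                                                          normalized = TRUE)),
        clustering = cc, row.names = NULL)
    if ("class" %in% igraph::vertex_attr_names(g))
        out <- cbind(out[1], class = igraph::V(g)$class, out[-1])
    out
}

#' Goodness of a power-law fit to a degree distribution
#'
#' Least-squares fit of \eqn{\log(\mathrm{frequency})} against
#' \eqn{\log(\mathrm{degree})} over the distinct positive degrees; the
#' returned \eqn{R^2} is the conventional scale-free-character statistic of
#' co-occurrence network studies.
#'
#' @param degrees integer degree sequence (e.g. \code{networkNodes(net)$degree})
#' @return \eqn{R^2} in [0, 1]; \code{NA} with a warning when fewer than 4
#'   distinct positive degrees exist
#' @export
powerLawFit <- function(degrees) {
    degrees <- degrees[degrees > 0]
    tab <- table(degrees)
    if (length(tab) < 4) {
        warning("need >= 4 distinct positive degrees for a power-law fit")
        return(NA_real_)
    }
    k <- as.numeric(names(tab))
    y <- log(as.numeric(tab))
    fit <- stats::lm(y ~ log(k))
    1 - sum(stats::residuals(fit)^2) / sum((y - mean(y))^2)
}

#' Export a co-occurrence network
#'
#' Writes the edge list and node table as TSV and, optionally, the graph as
#' GraphML for external visualisation.
#'
#' @param net a \linkS4class{CoocNetwork}
#' @param edgePath,nodePath TSV output paths (either may be \code{NULL})
#' @param graphmlPath optional GraphML output path
#' @return invisibly, \code{NULL}
#' @export
exportNetwork <- function(net, edgePath = NULL, nodePath = NULL,
                          graphmlPath = NULL) {
    g <- networkGraph(net)
    if (!is.null(edgePath)) {
        e <- igraph::as_data_frame(g, what = "edges")
        colnames(e)[1:2] <- c("source", "target")
        utils::write.table(e, edgePath, sep = "\t", quote = FALSE,
                           row.names = FALSE)
    }
    if (!is.null(nodePath))
        utils::write.table(networkNodes(net), nodePath, sep = "\t",
                           quote = FALSE, row.names = FALSE)
    if (!is.null(graphmlPath))
        igraph::write_graph(g, graphmlPath, format = "graphml")
    invisible(NULL)
}
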