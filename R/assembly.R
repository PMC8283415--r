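#' Abundance-weighted beta mean nearest taxon distance
#'
#' For communities \eqn{k, l} with relative abundances \eqn{f} and patristic
#' distance \eqn{D},
#' \deqn{\beta MNTD = \frac{1}{2}\Big[\sum_{i \in k} f_{ik} \min_{j \in l}
#'   D_{ij} + \sum_{j \in l} f_{jl} \min_{i \in k} D_{ij}\Big],}
#' the mean phylogenetic distance from each taxon to its nearest relative in
#' the other community, abundance-weighted. A taxon present in both
#' communities is its own nearest neighbour (distance 0); identical
#' communities score 0.
#'
#' @param x an \linkS4class{OtuExperiment}; all-zero OTUs are ignored
#' @param tree a rooted \code{phylo} whose tip labels cover the OTUs of
#'   \code{x}
#' @return symmetric samples-by-samples matrix in tree-distance units
#' @export
betaMNTD <- function(x, tree) {
    prep <- .assemblyPrep(x, tree)
    out <- cpp_bmntd(prep$D, prep$F)
    dimnames(out) <- list(prep$samples, prep$samples)
    out
}

.assemblyPrep <- function(x, tree) {
    m <- otuCounts(x)
    m <- m[rowSums(m) > 0, , drop = FALSE]
    missing <- setdiff(rownames(m), tree$tip.label)
    if (length(missing))
        stop("OTU(s) missing from tree: ",
             paste(utils::head(missing, 5), collapse = ", "),
             if (length(missing) > 5) sprintf(" (+%d more)",
                                              length(missing) - 5))
    tree <- ape::keep.tip(tree, rownames(m))
    D <- ape::cophenetic.phylo(tree)[rownames(m), rownames(m)]
    list(D = D, F = relAbundance(m), samples = colnames(m))
}

#' Beta nearest taxon index
#'
#' Standardises observed \code{\link{betaMNTD}} against a null distribution
#' obtained by shuffling tip labels across the whole tree (regional pool =
#' all OTUs in the scope) \code{nNull} times:
#' \eqn{\beta NTI = (obs - \bar{null}) / sd(null)}. Pairs whose null
#' standard deviation is zero (no phylogenetic variation to permute) are
#' reported \code{NA} with a warning.
#'
#' \eqn{|\beta NTI| > 2} flags deterministic turnover: \eqn{< -2}
#' homogeneous selection, \eqn{> 2} variable selection.
#'
#' @inheritParams betaMNTD
#' @param nNull number of tip-shuffling randomisations (>= 99)
#' @param seed integer seed for the permutations
#' @return list with symmetric matrices \code{bnti}, \code{bmntd_obs},
#'   \code{null_mean}, \code{null_sd}
#' @export
betaNTI <- function(x, tree, nNull = 999, seed = 1) {
    if (nNull < 99) stop("nNull must be >= 99")
    if (ncol(x) < 2) stop("need at least 2 samples")
    prep <- .assemblyPrep(x, tree)
    res <- .withSeed(seed, cpp_bmntd_null(prep$D, prep$F, as.integer(nNull)))
    # a degenerate null (all shuffles identical) leaves sd at sqrt-epsilon
    # roundoff of the mean, so the zero test is relative at that scale
    sd0 <- res$null_sd <= 1e-6 * (abs(res$null_mean) + 1e-12)
    diag(sd0) <- FALSE
    bnti <- (res$obs - res$null_mean) / res$null_sd
    if (any(sd0)) {
        warning("null sd is zero for ", sum(sd0) / 2,
                " pair(s); betaNTI undefined there")
        bnti[sd0] <- NA_real_
    }
    diag(bnti) <- 0
    for (nm in c("obs", "null_mean", "null_sd"))
        dimnames(res[[nm]]) <- list(prep$samples, prep$samples)
    dimnames(bnti) <- list(prep$samples, prep$samples)
    list(bnti = bnti, bmntd_obs = res$obs, null_mean = res$null_mean,
         null_sd = res$null_sd)
}

#' Probabilistic Raup-Crick metric on Bray-Curtis
#'
#' For each sample pair, builds \code{nNull} null community pairs that
#' preserve each sample's observed richness and total abundance: species are
#' drawn without replacement with probability proportional to their
#' occurrence frequency across the scope, each drawn species receives one
#' individual, and the remaining individuals are assigned multinomially with
#' probability proportional to the regional mean relative abundance. The
#' observed Bray-Curtis dissimilarity is then ranked within the null
#' distribution:
#' \deqn{RC = 2 \cdot \frac{\#\{null < obs\} + 0.5 \cdot \#\{null = obs\}}
#'   {n_{null}} - 1 \in [-1, 1].}
#'
#' @param x an \linkS4class{OtuExperiment} (>= 2 samples)
#' @param nNull number of null pairs per observed pair (>= 99)
#' @param seed integer seed
#' @param pool optional regional species pool: a list with numeric vectors
#'   \code{occ} (occurrence frequencies) and \code{pbar} (mean relative
#'   abundances), named by OTU id. Defaults to estimates from \code{x};
#'   supply the whole experiment's pool when computing RC within a subset
#'   (e.g. one treatment or subcommunity), so the null draws from the
#'   regional rather than the local pool.
#' @return symmetric samples-by-samples matrix in [-1, 1]
#' @export
raupCrickBray <- function(x, nNull = 999, seed = 1, pool = NULL) {
    if (nNull < 99) stop("nNull must be >= 99")
    m <- otuCounts(x)
    if (ncol(m) < 2) stop("need at least 2 samples")
    m <- m[rowSums(m) > 0, , drop = FALSE]
    S <- ncol(m)
    if (is.null(pool)) {
        occ <- rowMeans(m > 0)              # occurrence frequency
        pbar <- rowMeans(relAbundance(m))   # regional mean rel. abundance
    } else {
        if (!all(rownames(m) %in% names(pool$occ)) ||
            !all(rownames(m) %in% names(pool$pbar)))
            stop("pool must cover every OTU present in x")
        # the null draws over the full regional pool, including species
        # absent from this subset of samples
        universe <- names(pool$occ)
        full <- matrix(0, length(universe), S,
                       dimnames = list(universe, colnames(m)))
        full[rownames(m), ] <- m
        m <- full
        occ <- pool$occ
        pbar <- pool$pbar
    }
    rich <- colSums(m > 0)
    tot <- colSums(m)
    nOtu <- nrow(m)

    nullSample <- function(nk, Nk) .rcNullSample(occ, pbar, nk, Nk)
    bc <- function(a, b) sum(abs(a - b)) / sum(a + b)

    out <- matrix(0, S, S, dimnames = list(colnames(m), colnames(m)))
    .withSeed(seed, {
        for (k in seq_len(S - 1)) for (l in (k + 1):S) {
            obs <- bc(m[, k], m[, l])
            nullBC <- vapply(seq_len(nNull), function(r)
                bc(nullSample(rich[k], tot[k]),
                   nullSample(rich[l], tot[l])), numeric(1))
            rc <- 2 * (sum(nullBC < obs) + 0.5 * sum(nullBC == obs)) /
                nNull - 1
            out[k, l] <- out[l, k] <- rc
        }
    })
    out
}

# One draw from the Raup-Crick null ensemble: richness nk species chosen
# with probability proportional to occurrence frequency, one individual
# each, remaining Nk - nk individuals multinomial on the regional mean
# relative abundances of the chosen species. Species selection uses
# exponential race keys, distributionally identical to successive weighted
# sampling without replacement but O(n log n) per draw.
.rcNullSample <- function(occ, pbar, nk, Nk) {
    sp <- which(rank(stats::rexp(length(occ)) / occ,
                     ties.method = "first") <= nk)
    v <- numeric(length(occ))
    v[sp] <- 1
    if (Nk > nk)
        v[sp] <- v[sp] + stats::rmultinom(1, Nk - nk, prob = pbar[sp])[, 1]
    v
}

#' Classify a sample pair's assembly process
#'
#' Applies the fixed two-stage decision rules: \eqn{\beta NTI < -2} is
#' homogeneous selection and \eqn{\beta NTI > 2} variable selection; among
#' phylogenetically stochastic pairs (\eqn{|\beta NTI| < 2}),
#' \eqn{RC < -0.95} is homogenizing dispersal, \eqn{RC > 0.95} dispersal
#' limitation, and \eqn{|RC| < 0.95} undominated assembly. Exact boundary
#' values (probability zero in floating point, but made deterministic) fall
#' to the selection / dispersal side respectively.
#'
#' @param bnti beta nearest taxon index value(s)
#' @param rc Raup-Crick (Bray-Curtis) value(s) in [-1, 1]
#' @return factor over the five process labels; vectorised
#' @export
classifyProcess <- function(bnti, rc) {
    lv <- c("homogeneous_selection", "variable_selection",
            "homogenizing_dispersal", "dispersal_limitation", "undominated")
    out <- ifelse(bnti <= -2, "homogeneous_selection",
           ifelse(bnti >= 2, "variable_selection",
           ifelse(rc <= -0.95, "homogenizing_dispersal",
           ifelse(rc >= 0.95, "dispersal_limitation", "undominated"))))
    out[is.na(bnti) | is.na(rc)] <- NA
    factor(out, levels = lv)
}

#' Full pairwise assembly-process analysis
#'
#' Runs \code{\link{betaNTI}} and \code{\link{raupCrickBray}} over all
#' sample pairs of \code{x} and classifies each pair with
#' \code{\link{classifyProcess}}. Subset \code{x} first (e.g. with
#' \code{\link{subcommunity}}) to analyse one subcommunity or treatment
#' scope.
#'
#' @inheritParams betaNTI
#' @return an \linkS4class{AssemblyResult}
#' @export
assemblyProcesses <- function(x, tree, nNull = 999, seed = 1) {
    bnFull <- betaNTI(x, tree, nNull = nNull, seed = seed)
    bn <- bnFull$bnti
    rc <- raupCrickBray(x, nNull = nNull, seed = seed + 1L)
    ids <- colnames(bn)
    idx <- which(upper.tri(bn), arr.ind = TRUE)
    pairs <- data.frame(sample_a = ids[idx[, 1]], sample_b = ids[idx[, 2]],
                        beta_mntd = bnFull$bmntd_obs[idx], bnti = bn[idx],
                        rc_bray = rc[idx])
    tr <- tryCatch(treatments(x), error = function(e) NULL)
    if (!is.null(tr)) {
        pairs$treatment_a <- unname(tr[pairs$sample_a])
        pairs$treatment_b <- unname(tr[pairs$sample_b])
    }
    pairs$process <- classifyProcess(pairs$bnti, pairs$rc_bray)
    new("AssemblyResult", pairs = pairs, nNull = as.integer(nNull),
        seed = as.integer(seed))
}

#' Fractions of assembly processes per group of pairs
#'
#' Summarises an \linkS4class{AssemblyResult} into per-group fractions over
#' the five process labels. With \code{scope = "within"} only
#' within-treatment pairs count, grouped by treatment; with
#' \code{"within-plus-control"} (the default when treatment labels exist)
#' control-vs-treatment pairs are added to the perturbed treatment's group;
#' \code{"all"} pools every pair into one group.
#'
#' @param x an \linkS4class{AssemblyResult}
#' @param scope pair-selection rule, see Details
#' @param control control treatment label (used by
#'   \code{"within-plus-control"})
#' @return data.frame: group, one column per process, n_pairs; fractions in
#'   each row sum to 1 (pairs with undefined statistics are dropped)
#' @export
processFractions <- function(x, scope = c("within-plus-control", "within",
                                          "all"),
                             control = "Control") {
    scope <- match.arg(scope)
    p <- assemblyPairs(x)
    p <- p[!is.na(p$process), , drop = FALSE]
    if (!nrow(p)) stop("no classified pairs")
    if (scope == "all" || !"treatment_a" %in% colnames(p)) {
        grp <- rep("all", nrow(p))
    } else if (scope == "within") {
        keep <- p$treatment_a == p$treatment_b
        p <- p[keep, , drop = FALSE]
        grp <- p$treatment_a
    } else {
        within <- p$treatment_a == p$treatment_b
        ctrlA <- p$treatment_a == control & !within
        ctrlB <- p$treatment_b == control & !within
        keep <- within | ctrlA | ctrlB
        grp <- ifelse(p$treatment_a == control & !within, p$treatment_b,
                      p$treatment_a)
        p <- p[keep, , drop = FALSE]
        grp <- grp[keep]
    }
    lv <- levels(p$process)
    out <- lapply(unique(grp), function(g) {
        tab <- table(p$process[grp == g])
        fr <- as.numeric(tab[lv]) / sum(tab)
        df <- as.data.frame(as.list(setNames(fr, lv)))
        cbind(data.frame(group = g), df,
              data.frame(n_pairs = sum(grp == g)))
    })
    do.call(rbind, out)
}
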