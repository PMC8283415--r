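#' Shannon-Wiener diversity (natural log)
#'
#' @param counts non-negative abundance vector with at least one positive
#'   entry
#' @return Shannon entropy in nats, \eqn{-\sum p_i \ln p_i} over positive
#'   entries
#' @export
shannonIndex <- function(counts) {
    .checkCounts(counts)
    vegan::diversity(counts, index = "shannon", base = exp(1))
}

#' Gini-Simpson diversity
#'
#' @inheritParams shannonIndex
#' @return \eqn{1 - \sum p_i^2}
#' @export
simpsonIndex <- function(counts) {
    .checkCounts(counts)
    vegan::diversity(counts, index = "simpson")
}

.checkCounts <- function(counts) {
    if (any(counts < 0) || !any(counts > 0))
        stop("counts must be non-negative with at least one positive entry")
}

#' Per-sample alpha diversity table
#'
#' @param x an \linkS4class{OtuExperiment}
#' @return data.frame: sample_id, shannon (nats), simpson, richness
#' @export
alphaDiversity <- function(x) {
    m <- t(otuCounts(x))  # vegan wants samples as rows
    data.frame(sample_id = rownames(m),
               shannon = vegan::diversity(m, "shannon"),
               simpson = vegan::diversity(m, "simpson"),
               richness = rowSums(m > 0), row.names = NULL)
}

#' Bray-Curtis dissimilarity matrix
#'
#' \eqn{BC(x, y) = \sum |x_i - y_i| / \sum (x_i + y_i)}; a pair of all-zero
#' samples is undefined and reported as \code{NA}.
#'
#' @param x an \linkS4class{OtuExperiment} or a count matrix with OTUs as
#'   rows
#' @return symmetric matrix in [0, 1] with zero diagonal
#' @export
brayCurtis <- function(x) {
    m <- if (is(x, "OtuExperiment")) otuCounts(x) else as.matrix(x)
    if (ncol(m) < 2) stop("need at least 2 samples")
    d <- as.matrix(vegan::vegdist(t(m), method = "bray"))
    zero <- colSums(m) == 0
    if (any(zero)) {
        d[zero, zero] <- NA_real_
        diag(d) <- 0
    }
    d
}

#' Shannon-based resistance index
#'
#' Quantifies how little a perturbed community departs from the unperturbed
#' control: with \eqn{C_0} the control-mean Shannon, \eqn{P_0} the perturbed
#' Shannon and \eqn{D_0 = C_0 - P_0},
#' \deqn{RS = 1 - \frac{2 |D_0|}{C_0 + |D_0|}.}
#' RS equals 1 iff the perturbed value matches the control, decreases
#' strictly with \eqn{|D_0|}, and equals 0 at total loss
#' (\eqn{P_0 = 0}). Bounded in (-1, 1].
#'
#' @param controlShannons Shannon values of the control replicates (nats)
#' @param perturbedShannon a single perturbed-sample Shannon value
#' @return list with C0, P0, D0 and RS
#' @export
resistanceIndex <- function(controlShannons, perturbedShannon) {
    if (!length(controlShannons)) stop("control vector is empty")
    C0 <- mean(controlShannons)
    if (C0 <= 0) stop("control-mean Shannon must be positive")
    D0 <- C0 - perturbedShannon
    list(C0 = C0, P0 = perturbedShannon, D0 = D0,
         RS = 1 - 2 * abs(D0) / (C0 + abs(D0)))
}

#' Treatment-level resistance of a (sub)community
#'
#' Computes per-replicate resistance of every non-control treatment against
#' the control-mean Shannon and averages within treatment.
#'
#' @param x an \linkS4class{OtuExperiment} with treatment metadata
#' @param control label of the unperturbed treatment
#' @return data.frame: treatment, RS (mean over replicates), RS_sd
#' @export
treatmentResistance <- function(x, control = "Control") {
    tr <- treatments(x)
    if (!control %in% tr) stop("unknown control treatment: ", control)
    sh <- alphaDiversity(x)$shannon
    C <- sh[tr == control]
    out <- lapply(setdiff(unique(tr), control), function(t) {
        rs <- vapply(sh[tr == t],
                     function(p) resistanceIndex(C, p)$RS, numeric(1))
        data.frame(treatment = t, RS = mean(rs), RS_sd = stats::sd(rs))
    })
    do.call(rbind, out)
}
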