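# Shared fixtures and independent oracles, all built in code.

# small labelled count matrix -> OtuExperiment
oeFrom <- function(m, treatment = NULL, dose = NULL) {
    if (is.null(rownames(m))) rownames(m) <- sprintf("OTU%02d", seq_len(nrow(m)))
    if (is.null(colnames(m))) colnames(m) <- sprintf("S%02d", seq_len(ncol(m)))
    sd <- NULL
    if (!is.null(treatment))
        sd <- data.frame(sample_id = colnames(m), treatment = treatment,
                         dose = if (is.null(dose)) 0 else dose,
                         replicate = seq_along(treatment))
    OtuExperiment(m, sampleData = sd)
}

# four-tip tree with printed branch lengths, used by the beta-MNTD oracle
handTree <- function() ape::read.tree(text = "((A:1,B:2):0.5,(C:0.7,D:0.9):0.3);")

# exhaustive abundance-weighted beta-MNTD over all tip pairs
bruteBmntd <- function(x1, x2, D) {
    f1 <- x1 / sum(x1); f2 <- x2 / sum(x2)
    p1 <- which(x1 > 0); p2 <- which(x2 > 0)
    0.5 * (sum(vapply(p1, function(i) f1[i] * min(D[i, p2]), 0)) +
           sum(vapply(p2, function(j) f2[j] * min(D[j, p1]), 0)))
}

# exhaustive shortest-path topology oracle for small graphs (adjacency 0/1)
bruteTopology <- function(adj) {
    n <- nrow(adj)
    dist <- matrix(Inf, n, n)
    sigma <- matrix(0, n, n)
    for (s in seq_len(n)) {
        dist[s, s] <- 0; sigma[s, s] <- 1
        frontier <- s; d <- 0
        while (length(frontier)) {
            d <- d + 1
            nxt <- integer(0)
            for (v in frontier) for (w in which(adj[v, ] > 0)) {
                if (is.infinite(dist[s, w])) {
                    dist[s, w] <- d
                    nxt <- c(nxt, w)
                }
                if (dist[s, w] == d)
                    sigma[s, w] <- sigma[s, w] + sigma[s, v]
            }
            frontier <- unique(nxt)
        }
    }
    btw <- vapply(seq_len(n), function(v) {
        acc <- 0
        for (s in seq_len(n)) for (t in seq_len(n))
            if (s < t && s != v && t != v && is.finite(dist[s, t]) &&
                dist[s, v] + dist[v, t] == dist[s, t])
                acc <- acc + sigma[s, v] * sigma[v, t] / sigma[s, t]
        acc
    }, 0)
    cc <- vapply(seq_len(n), function(v) {
        nb <- which(adj[v, ] > 0)
        k <- length(nb)
        if (k < 2) return(0)
        sum(adj[nb, nb]) / (k * (k - 1))
    }, 0)
    list(degree = rowSums(adj), betweenness = btw, clustering = cc)
}

# multinomial community table drawn from a lognormal metacommunity
multinomTable <- function(nOtu, nSamp, depth, seed, sdlog = 2) {
    set.seed(seed)
    meta <- rlnorm(nOtu, 0, sdlog)
    meta <- meta / sum(meta)
    m <- vapply(seq_len(nSamp), function(s) rmultinom(1, depth, meta)[, 1],
                integer(nOtu))
    rownames(m) <- sprintf("OTU%04d", seq_len(nOtu))
    colnames(m) <- sprintf("S%02d", seq_len(nSamp))
    list(counts = m, meta = meta)
}
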