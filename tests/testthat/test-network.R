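test_that("Spearman matrix matches the rank formula and handles constants", {
    m <- rbind(a = c(1, 2, 3, 4, 5), b = c(1, 3, 2, 5, 4),
               c = c(5, 4, 3, 2, 1), k = c(2, 2, 2, 2, 2))
    storage.mode(m) <- "integer"
    sp <- spearmanMatrix(oeFrom(m), prevalenceMin = 0)
    expect_equal(sp$rho["a", "b"], 0.8, tolerance = 1e-12)  # 1 - 6*4/120
    expect_equal(sp$rho["a", "c"], -1, tolerance = 1e-12)
    expect_true(all(diag(sp$rho) == 1))
    expect_true(is.na(sp$rho["k", "a"]))
    expect_error(spearmanMatrix(oeFrom(matrix(1:8, 2))), "5 samples")
})

test_that("prevalence filter drops sporadic OTUs before correlation", {
    set.seed(18)
    m <- matrix(rpois(120, 5), nrow = 12)
    m[1, 1:8] <- 0L     # present in 2/10 samples only
    sp <- spearmanMatrix(oeFrom(m), prevalenceMin = 1/3)
    expect_false("OTU01" %in% sp$otu_ids)
})

test_that("network construction thresholds edges monotonically", {
    set.seed(19)
    tab <- multinomTable(40, 20, 800, seed = 19)
    sp <- spearmanMatrix(OtuExperiment(tab$counts), prevalenceMin = 1/3)
    n1 <- buildNetwork(sp, 0.4)
    n2 <- buildNetwork(sp, 0.55)
    e <- function(net) {
        d <- igraph::as_data_frame(networkGraph(net))
        paste(pmin(d$from, d$to), pmax(d$from, d$to))
    }
    expect_true(all(e(n2) %in% e(n1)))
    nodes <- networkNodes(n1)
    expect_equal(sum(nodes$degree), 2 * igraph::ecount(networkGraph(n1)))
    expect_true(all(nodes$clustering >= 0 & nodes$clustering <= 1))
    expect_warning(buildNetwork(sp, 1), "no edges")
})

test_that("abundant-rare mode admits only cross-class edges", {
    rho <- matrix(0.9, 4, 4,
                  dimnames = list(c("A1", "A2", "R1", "R2"),
                                  c("A1", "A2", "R1", "R2")))
    diag(rho) <- 1
    cl <- c(A1 = "abundant", A2 = "abundant", R1 = "rare", R2 = "rare")
    net <- buildNetwork(rho, 0.8, classes = cl, mode = "abundant-rare")
    ed <- igraph::as_data_frame(networkGraph(net))
    cls <- function(v) unname(cl[v])
    expect_true(all((cls(ed$from) == "abundant" & cls(ed$to) == "rare") |
                    (cls(ed$from) == "rare" & cls(ed$to) == "abundant")))
    expect_equal(nrow(ed), 4)
})

test_that("star and triangle topologies match their closed forms", {
    rho <- matrix(0, 5, 5, dimnames = list(paste0("n", 1:5), paste0("n", 1:5)))
    rho["n1", 2:5] <- rho[2:5, "n1"] <- 0.9
    diag(rho) <- 1
    star <- networkNodes(buildNetwork(rho, 0.8))
    hub <- star[star$otu_id == "n1", ]
    expect_equal(hub$degree, 4)
    expect_equal(hub$betweenness, (5 - 1) * (5 - 2) / 2)  # = 6
    expect_equal(hub$clustering, 0)
    expect_true(all(star$betweenness[star$otu_id != "n1"] == 0))

    tri <- matrix(0.95, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
    net <- networkNodes(buildNetwork(tri, 0.9))
    expect_true(all(net$degree == 2))
    expect_true(all(net$betweenness == 0))
    expect_true(all(net$clustering == 1))
})

test_that("topology metrics equal the exhaustive oracle on random graphs", {
    for (s in 1:4) {
        set.seed(400 + s)
        n <- 12
        adj <- matrix(0, n, n)
        adj[upper.tri(adj)] <- rbinom(n * (n - 1) / 2, 1, 0.3)
        adj <- adj + t(adj)
        keep <- rowSums(adj) > 0
        adj <- adj[keep, keep, drop = FALSE]
        ids <- paste0("v", seq_len(nrow(adj)))
        dimnames(adj) <- list(ids, ids)
        rho <- adj * 0.9
        diag(rho) <- 1
        nodes <- networkNodes(buildNetwork(rho, 0.8))
        oracle <- bruteTopology(adj)
        ord <- match(nodes$otu_id, ids)
        expect_equal(nodes$degree, unname(oracle$degree[ord]))
        expect_equal(nodes$betweenness, oracle$betweenness[ord],
                     tolerance = 1e-9)
        expect_equal(nodes$clustering, oracle$clustering[ord],
                     tolerance = 1e-9)
    }
})

test_that("power-law fit is exact on exact power laws and degrades on noise", {
    # frequencies 64,16,4,1 at degrees 1,2,4,8: log-log is exactly linear
    degs <- rep(c(1, 2, 4, 8), c(64, 16, 4, 1))
    expect_equal(powerLawFit(degs), 1, tolerance = 1e-12)
    expect_warning(r <- powerLawFit(rep(3, 30)), "4 distinct")
    expect_true(is.na(r))
    # discrete power law (exponent 2.5, n = 300): high R2 in the median run
    r2 <- vapply(1:7, function(s) {
        set.seed(22 + s)
        k <- floor((1 - runif(300))^(-1 / 1.5))
        powerLawFit(k[k <= 50])
    }, 0)
    expect_gt(median(r2), 0.8)
})

test_that("RMT scan accepts a low cutoff for independent data and isolates planted blocks", {
    set.seed(61)
    n <- 300
    mu <- rlnorm(n, 3, 1)
    ind <- sapply(1:30, function(s) rpois(n, mu))
    rownames(ind) <- sprintf("OTU%03d", 1:n)
    colnames(ind) <- paste0("S", 1:30)
    t1 <- rmtThreshold(spearmanMatrix(OtuExperiment(ind),
                                      prevalenceMin = 0)$rho)
    expect_true(attr(t1, "rmt"))
    expect_true(t1 >= 0.30 && t1 <= 0.99)
    expect_lte(as.numeric(t1), 0.6)

    blk <- sapply(1:30, function(s) {
        f <- rep(rlnorm(n / 10, 0, 1), each = 10)
        rpois(n, mu * f)
    })
    rownames(blk) <- sprintf("OTU%03d", 1:n)
    colnames(blk) <- paste0("S", 1:30)
    sp <- spearmanMatrix(OtuExperiment(blk), prevalenceMin = 0)
    t2 <- rmtThreshold(sp$rho)
    expect_true(t2 >= 0.30 && t2 <= 0.99)
    # the cutoff clears the typical background correlation ...
    noise <- abs(sp$rho[outer(rep(1:30, each = 10), rep(1:30, each = 10),
                              "!=") & upper.tri(sp$rho)])
    expect_gt(as.numeric(t2), median(noise))
    # ... so within-block pairs (3% of all pairs) dominate the edges
    ed <- igraph::as_data_frame(networkGraph(buildNetwork(sp, t2)))
    blkOf <- function(id) (as.integer(substr(id, 4, 6)) - 1) %/% 10
    expect_gt(mean(blkOf(ed$from) == blkOf(ed$to)), 0.3)
})

test_that("network export writes edge, node and GraphML files", {
    tri <- matrix(0.95, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
    net <- buildNetwork(tri, 0.9)
    ep <- withr::local_tempfile(fileext = ".tsv")
    np <- withr::local_tempfile(fileext = ".tsv")
    gp <- withr::local_tempfile(fileext = ".graphml")
    exportNetwork(net, ep, np, gp)
    expect_identical(colnames(read.delim(ep))[1:3],
                     c("source", "target", "rho"))
    expect_equal(nrow(read.delim(np)), 3)
    expect_true(any(grepl("graphml", readLines(gp, n = 5))))
})
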