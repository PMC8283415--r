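test_that("beta-MNTD equals exhaustive tip-pair computation on a hand tree", {
    tree <- handTree()
    D <- ape::cophenetic.phylo(tree)
    m <- cbind(S1 = c(A = 2L, B = 2L, C = 0L, D = 0L),
               S2 = c(A = 0L, B = 0L, C = 1L, D = 3L))
    got <- betaMNTD(OtuExperiment(m), tree)["S1", "S2"]
    expect_equal(got, bruteBmntd(m[, 1], m[, 2], D), tolerance = 1e-12)
    # the hand value: every nearest neighbour crosses the root (depth 0.5+0.3)
    hand <- 0.5 * ((0.5 * (1 + 0.8 + 0.7) + 0.5 * (2 + 0.8 + 0.7)) +
                   (0.25 * (0.7 + 0.8 + 1) + 0.75 * (0.9 + 0.8 + 1)))
    expect_equal(got, hand, tolerance = 1e-12)
    # identical communities have zero distance; singletons give the
    # patristic distance between their tips
    m2 <- cbind(S1 = c(A = 3L, B = 1L, C = 0L, D = 0L),
                S2 = c(A = 3L, B = 1L, C = 0L, D = 0L))
    expect_equal(unname(betaMNTD(OtuExperiment(m2), tree)[1, 2]), 0)
    m3 <- cbind(S1 = c(A = 5L, B = 0L, C = 0L, D = 0L),
                S2 = c(A = 0L, B = 0L, C = 2L, D = 0L))
    expect_equal(unname(betaMNTD(OtuExperiment(m3), tree)[1, 2]),
                 D["A", "C"])
    expect_error(betaMNTD(oeFrom(matrix(1:4, 2,
        dimnames = list(c("A", "nope"), c("S1", "S2")))), tree), "nope")
})

test_that("beta-MNTD agrees with an independent reference implementation", {
    library(picante)
    phy <- simulatePhylogeny(25, seed = 91)
    tab <- multinomTable(25, 8, 400, seed = 92)
    rownames(tab$counts) <- phy$tree$tip.label
    oe <- OtuExperiment(tab$counts)
    ours <- betaMNTD(oe, phy$tree)
    ref <- as.matrix(comdistnt(t(tab$counts),
                               cophenetic(phy$tree),
                               abundance.weighted = TRUE))
    expect_equal(ours, ref[rownames(ours), colnames(ours)],
                 tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("beta-NTI is symmetric, reproducible, and NA on permutation-invariant trees", {
    phy <- simulatePhylogeny(20, seed = 101)
    tab <- multinomTable(20, 6, 300, seed = 102)
    rownames(tab$counts) <- phy$tree$tip.label
    oe <- OtuExperiment(tab$counts)
    a <- betaNTI(oe, phy$tree, nNull = 199, seed = 7)
    b <- betaNTI(oe, phy$tree, nNull = 199, seed = 7)
    expect_identical(a$bnti, b$bnti)
    expect_equal(a$bnti, t(a$bnti))
    expect_true(all(diag(a$bnti) == 0))
    # star tree with equal branch lengths: every tip shuffle is identical,
    # the null has zero variance
    star <- ape::stree(20, type = "star")
    star$edge.length <- rep(1, nrow(star$edge))
    star$tip.label <- rownames(tab$counts)
    expect_warning(s <- betaNTI(oe, star, nNull = 99, seed = 1), "null sd")
    expect_true(all(is.na(s$bnti[upper.tri(s$bnti)])))
})

test_that("Raup-Crick hits the extreme ranks for forced pairs and stays in range", {
    set.seed(14)
    base <- multinomTable(40, 10, 500, seed = 14)$counts
    # duplicated sample: observed BC = 0 beats every null draw
    dup <- cbind(base, X = base[, 1])
    colnames(dup) <- c(colnames(base), "X")
    rc <- raupCrickBray(OtuExperiment(dup), nNull = 199, seed = 2)
    expect_lt(rc["S01", "X"], -0.99)
    expect_true(all(rc >= -1 & rc <= 1))
    expect_equal(rc, t(rc))
    # identical seed reproduces the matrix bit for bit
    rc2 <- raupCrickBray(OtuExperiment(dup), nNull = 199, seed = 2)
    expect_identical(rc, rc2)
    # disjoint support: observed BC = 1 is at or above every null
    disj <- oeFrom(rbind(matrix(c(20L, 0L), 10, 2, byrow = TRUE,
                                dimnames = list(paste0("u", 1:10), NULL)),
                         matrix(c(0L, 20L), 10, 2, byrow = TRUE,
                                dimnames = list(paste0("v", 1:10), NULL))))
    rcd <- raupCrickBray(disj, nNull = 199, seed = 3)
    expect_gt(rcd[1, 2], 0.9)
})

test_that("process classification covers the decision regions and their boundaries", {
    expect_identical(as.character(classifyProcess(-3, 0.1)),
                     "homogeneous_selection")
    expect_identical(as.character(classifyProcess(2.4, -0.3)),
                     "variable_selection")
    expect_identical(as.character(classifyProcess(1, 0.97)),
                     "dispersal_limitation")
    expect_identical(as.character(classifyProcess(-1.2, -0.99)),
                     "homogenizing_dispersal")
    expect_identical(as.character(classifyProcess(0.5, 0.2)),
                     "undominated")
    # closed boundaries: |bNTI| = 2 is selection, |RC| = 0.95 is dispersal
    expect_identical(as.character(classifyProcess(c(-2, 2), c(0, 0))),
                     c("homogeneous_selection", "variable_selection"))
    expect_identical(as.character(classifyProcess(c(0, 0), c(0.95, -0.95))),
                     c("dispersal_limitation", "homogenizing_dispersal"))
    # total and disjoint over a grid of finite values
    g <- expand.grid(b = seq(-4, 4, by = 0.5), r = seq(-1, 1, by = 0.25))
    lab <- classifyProcess(g$b, g$r)
    expect_false(any(is.na(lab)))
})

test_that("process fractions aggregate pair labels and sum to one", {
    lv <- c("homogeneous_selection", "variable_selection",
            "homogenizing_dispersal", "dispersal_limitation", "undominated")
    pairs <- data.frame(
        sample_a = paste0("a", 1:15), sample_b = paste0("b", 1:15),
        beta_mntd = 1, bnti = 0,
        rc_bray = c(rep(0.99, 9), rep(0, 6)),
        treatment_a = rep(c("PYR10", "Control", "PYR10"), each = 5),
        treatment_b = rep(c("PYR10", "PYR10", "PYR500"), each = 5))
    pairs$process <- classifyProcess(pairs$bnti, pairs$rc_bray)
    res <- new("AssemblyResult", pairs = pairs, nNull = 99L, seed = 1L)
    all <- processFractions(res, scope = "all")
    expect_equal(all$dispersal_limitation, 9 / 15)
    expect_equal(sum(all[, lv]), 1, tolerance = 1e-12)
    # within-plus-control folds Control-vs-PYR10 pairs into PYR10
    wpc <- processFractions(res, scope = "within-plus-control")
    expect_setequal(wpc$group, "PYR10")
    expect_equal(wpc$n_pairs, 10L)
    expect_equal(rowSums(wpc[, lv]), 1, tolerance = 1e-12,
                 ignore_attr = TRUE)
    onlyWithin <- processFractions(res, scope = "within")
    expect_equal(onlyWithin$n_pairs, 5L)
})

test_that("assemblyProcesses ties the null models together deterministically", {
    phy <- simulatePhylogeny(30, seed = 121)
    cfg <- simulationConfig(nOtus = 30, nPerTreatment = 3,
        treatments = data.frame(label = c("Control", "PYR500"),
                                dose = c(0, 500)),
        depth = 500, seed = 122)
    sim <- simulateNeutral(cfg, tree = phy$tree)
    r1 <- assemblyProcesses(sim$table, phy$tree, nNull = 99, seed = 5)
    r2 <- assemblyProcesses(sim$table, phy$tree, nNull = 99, seed = 5)
    expect_identical(assemblyPairs(r1), assemblyPairs(r2))
    p <- assemblyPairs(r1)
    expect_equal(nrow(p), choose(6, 2))
    expect_true(all(p$rc_bray >= -1 & p$rc_bray <= 1))
    expect_false(any(is.na(p$process)))
})
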