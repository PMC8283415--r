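makePlanted <- function() {
    # depth 10000 per sample; abundances straddle the 1% / 0.01% cutoffs
    m <- rbind(
        spiky    = c(200L, 0L,   150L, 100L),  # 2% in one Control sample
        faint    = c(1L,   0L,   0L,   0L),    # Control mean 0.005% -> rare
        middling = c(50L,  50L,  50L,  50L),   # 0.5% everywhere -> moderate
        gone     = c(0L,   0L,   80L,  90L),   # absent from Control
        filler   = c(9749L, 9950L, 9720L, 9760L))
    oeFrom(m, treatment = c("Control", "Control", "PYR500", "PYR500"),
           dose = c(0, 0, 500, 500))
}

test_that("hand-planted abundances classify exactly at the cutoffs", {
    cls <- classifyAbundance(makePlanted())
    tab <- classTable(cls)
    ctl <- setNames(as.character(tab$class[tab$treatment == "Control"]),
                    tab$otu_id[tab$treatment == "Control"])
    expect_identical(ctl[["spiky"]], "abundant")     # >= 1% in a sample
    expect_identical(ctl[["faint"]], "rare")         # treatment mean < 0.01%
    expect_identical(ctl[["middling"]], "moderate")
    expect_identical(ctl[["gone"]], "absent")
    expect_identical(ctl[["filler"]], "abundant")
})

test_that("abundant takes precedence and classes partition the present OTUs", {
    # one spike of 2% in a single sample, zero elsewhere: mean is far below
    # the rare cutoff, yet the per-sample rule wins
    m <- rbind(spike = c(200L, 0L, 0L, 0L, 0L, 0L),
               base = c(9800L, 10000L, 10000L, 10000L, 10000L, 10000L))
    cls <- classifyAbundance(oeFrom(m, treatment = rep("T1", 6)))
    expect_identical(as.character(classTable(cls)$class[1]), "abundant")

    set.seed(8)
    big <- oeFrom(matrix(rpois(600, 8), nrow = 60),
                  treatment = rep(c("A", "B"), each = 5))
    cls <- classifyAbundance(big, abundantCut = 0.05, rareCut = 0.01)
    tab <- classTable(cls)
    for (t in c("A", "B")) {
        sub <- tab[tab$treatment == t, ]
        present <- rowSums(otuCounts(treatmentSamples(big, t))) > 0
        expect_setequal(sub$otu_id[sub$class != "absent"],
                        otuIds(big)[present])
        expect_false(any(duplicated(sub$otu_id)))
    }
})

test_that("lowering the abundant cutoff never shrinks the abundant set", {
    set.seed(9)
    oe <- oeFrom(matrix(rpois(400, 15), nrow = 40),
                 treatment = rep("A", 10))
    cuts <- c(0.08, 0.05, 0.03, 0.02)
    sets <- lapply(cuts, function(ct) {
        tab <- classTable(classifyAbundance(oe, abundantCut = ct,
                                            rareCut = 1e-4))
        tab$otu_id[tab$class == "abundant"]
    })
    for (i in seq_along(sets)[-1])
        expect_true(all(sets[[i - 1]] %in% sets[[i]]))
})

test_that("subcommunity extraction restricts samples and OTUs, counts unchanged", {
    oe <- makePlanted()
    cls <- classifyAbundance(oe)
    ab <- subcommunity(oe, cls, "abundant", "Control")
    expect_setequal(otuIds(ab), c("spiky", "filler"))
    expect_identical(unname(treatments(ab)), rep("Control", 2))
    expect_identical(otuCounts(ab),
                     otuCounts(oe)[c("spiky", "filler"), 1:2])
    # abundant + moderate + rare covers everything present
    got <- unlist(lapply(c("abundant", "moderate", "rare"), function(w)
        otuIds(suppressWarnings(subcommunity(oe, cls, w, "PYR500")))))
    present <- rowSums(otuCounts(oe)[, 3:4]) > 0
    expect_setequal(got, otuIds(oe)[present])
    expect_warning(subcommunity(oe, cls, "rare", "PYR500"), "empty")
})

test_that("class transitions pair reference and target labels per OTU", {
    cls <- classifyAbundance(makePlanted())
    tr <- classTransitions(cls, "Control", "PYR500")
    expect_setequal(tr$otu_id, c("spiky", "faint", "middling", "gone",
                                 "filler"))
    faint <- tr[tr$otu_id == "faint", ]
    expect_identical(as.character(faint$class_ref), "rare")
    gone <- tr[tr$otu_id == "gone", ]
    expect_identical(as.character(gone$class_ref), "absent")
    expect_false(gone$class_target == "absent")
    # identical treatments compared: class-preserving, union-sized
    same <- classTransitions(cls, "Control", "Control")
    expect_true(all(same$class_ref == same$class_target))
    expect_error(classTransitions(cls, "Control", "nope"), "nope")
})

test_that("abundant share of the community rises with dose on the gradient generator", {
    shares <- vapply(1:3, function(r) {
        cfg <- simulationConfig(nOtus = 150, nPerTreatment = 3,
            treatments = data.frame(label = c("Control", "PYR500"),
                                    dose = c(0, 500)),
            depth = 2000, selectionStrength = 3, seed = 70 + r)
        sim <- simulateGradient(cfg)
        cls <- classifyAbundance(sim$table)
        rel <- relAbundance(sim$table)
        tr <- treatments(sim$table)
        tab <- classTable(cls)
        share <- function(t) {
            ids <- tab$otu_id[tab$treatment == t & tab$class == "abundant"]
            mean(colSums(rel[ids, tr == t, drop = FALSE]))
        }
        share("PYR500") - share("Control")
    }, 0)
    expect_gt(median(shares), 0)
})
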