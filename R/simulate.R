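#' Configuration for the community simulators
#'
#' Bundles the knobs shared by \code{\link{simulateNeutral}} and
#' \code{\link{simulateGradient}}. The defaults emulate the post-OTU-picking
#' state of a soil stress-gradient microcosm: 5 treatments (an unpolluted
#' control plus doses of 1, 10, 100 and 500 mg per kg dry soil) with 6
#' replicates each, a rarefied depth of 39,134 reads per sample, and a
#' lognormal metacommunity (meanlog 0, sdlog 2) giving a few dominant and
#' very many rare OTUs.
#'
#' @param nOtus number of OTUs in the metacommunity
#' @param nPerTreatment replicate samples per treatment
#' @param treatments data.frame with columns \code{label} and \code{dose}
#' @param depth reads per sample
#' @param metaMu,metaSigma lognormal parameters of the metacommunity
#'   relative-abundance distribution
#' @param m immigration probability of the neutral simulator, in (0, 1]
#' @param selectionStrength dose coefficient of the gradient simulator
#'   (0 = no selection)
#' @param degraderFraction top fraction of the trait distribution labelled
#'   as the dose-responsive "degrader" guild in the ground truth
#' @param traitSigma Brownian-motion rate of trait evolution on the
#'   unit-depth phylogeny
#' @param seed integer seed; every simulator call derives its randomness
#'   from it
#' @return a \code{SimulationConfig} list
#' @export
simulationConfig <- function(nOtus = 2000, nPerTreatment = 6,
                             treatments = data.frame(
                                 label = c("Control", "PYR1", "PYR10",
                                           "PYR100", "PYR500"),
                                 dose = c(0, 1, 10, 100, 500)),
                             depth = 39134, metaMu = 0, metaSigma = 2,
                             m = 0.5, selectionStrength = 3,
                             degraderFraction = 0.1, traitSigma = 1,
                             seed = 1) {
    stopifnot(nOtus >= 2, nPerTreatment >= 1, depth >= 1,
              m > 0, m <= 1, selectionStrength >= 0,
              all(treatments$dose >= 0), !anyDuplicated(treatments$label))
    structure(list(nOtus = nOtus, nPerTreatment = nPerTreatment,
                   treatments = treatments, depth = depth, metaMu = metaMu,
                   metaSigma = metaSigma, m = m,
                   selectionStrength = selectionStrength,
                   degraderFraction = degraderFraction,
                   traitSigma = traitSigma, seed = as.integer(seed)),
              class = "SimulationConfig")
}

.otuLabels <- function(n) sprintf("OTU%04d", seq_len(n))

.metacommunity <- function(config) {
    ab <- stats::rlnorm(config$nOtus, config$metaMu, config$metaSigma)
    setNames(ab / sum(ab), .otuLabels(config$nOtus))
}

#' Simulate a phylogeny with a heritable environmental optimum
#'
#' Grows a Yule (pure-birth) tree, rescales it to unit depth, and evolves a
#' continuous trait along it by Brownian motion, so that closely related
#' tips carry similar environmental optima — the phylogenetic signal that
#' makes selection detectable by tip-shuffling null models.
#'
#' @param nOtus number of tips (>= 2)
#' @param seed integer seed
#' @param traitSigma Brownian-motion rate
#' @return list: \code{tree} (ultrametric \code{phylo}, tip labels
#'   \code{OTU0001...}), \code{traits} (named numeric vector)
#' @export
simulatePhylogeny <- function(nOtus, seed = 1, traitSigma = 1) {
    if (nOtus < 2) stop("need at least 2 OTUs")
    .withSeed(seed, {
        tree <- ape::rphylo(nOtus, birth = 1, death = 0)
        depth <- max(ape::node.depth.edgelength(tree))
        tree$edge.length <- tree$edge.length / depth
        tree$tip.label <- .otuLabels(nOtus)
        traits <- ape::rTraitCont(tree, model = "BM", sigma = traitSigma)
        list(tree = tree, traits = setNames(traits, tree$tip.label))
    })
}

#' Simulate samples under neutral drift with immigration
#'
#' Each sample is an independent local community of \code{depth}
#' individuals evolved by death-replacement: per event one random
#' individual dies and is replaced from the metacommunity with probability
#' \code{m} (immigration) or by local reproduction otherwise. Communities
#' are initialised from the metacommunity and run for a burn-in of
#' \code{max(10, 5/m) * depth} events: the compositional variance of this
#' process relaxes towards stationarity at a rate of roughly \code{2m} per
#' generation (one generation = \code{depth} events), so the burn-in must
#' grow as immigration weakens for drift to equilibrate. With \code{m = 1}
#' samples reduce to multinomial draws from the metacommunity.
#'
#' @param config a \code{\link{simulationConfig}}; treatment labels and
#'   doses are carried into the metadata but have no effect on the counts
#' @param tree optional phylogeny whose tip labels name the OTUs (from
#'   \code{\link{simulatePhylogeny}} with the same \code{nOtus})
#' @return list: \code{table} (\linkS4class{OtuExperiment}),
#'   \code{meta} (metacommunity relative abundances)
#' @export
simulateNeutral <- function(config, tree = NULL) {
    nSamp <- nrow(config$treatments) * config$nPerTreatment
    .withSeed(config$seed, {
        meta <- .metacommunity(config)
        burnin <- as.integer(ceiling(max(10, 5 / config$m)) * config$depth)
        counts <- cpp_neutral_sim(unname(meta), nSamp, config$depth,
                                  config$m, burnin)
        rownames(counts) <- names(meta)
        colnames(counts) <- .sampleIdsFor(config)
        list(table = OtuExperiment(counts,
                                   sampleData = .sampleMetaFor(config)),
             meta = meta)
    })
}

.sampleIdsFor <- function(config)
    paste0(rep(config$treatments$label, each = config$nPerTreatment), "_R",
           rep(seq_len(config$nPerTreatment), nrow(config$treatments)))

.sampleMetaFor <- function(config) {
    data.frame(sample_id = .sampleIdsFor(config),
               treatment = rep(config$treatments$label,
                               each = config$nPerTreatment),
               dose = rep(config$treatments$dose,
                          each = config$nPerTreatment),
               replicate = rep(seq_len(config$nPerTreatment),
                               nrow(config$treatments)))
}

#' Simulate a dose-response gradient with phylogenetically structured
#' selection
#'
#' Per treatment, sampling weights are
#' \deqn{w_i \propto meta_i \cdot \exp(s \cdot dose' \cdot z_i)}
#' where \eqn{z_i} is the tip's standardised Brownian trait, \eqn{s} the
#' selection strength, and \eqn{dose'} the dose on a \eqn{\log(1+x)} scale
#' normalised to [0, 1] so the top dose does not numerically annihilate the
#' rare tail. Each sample is an independent multinomial draw of
#' \code{depth} reads. With \eqn{s = 0} this reduces to neutral
#' metacommunity sampling (the \code{m = 1} case of
#' \code{\link{simulateNeutral}}).
#'
#' @inheritParams simulateNeutral
#' @param traits optional named trait vector matching \code{tree}; both are
#'   simulated from \code{config} when missing
#' @return list: \code{table}, \code{tree}, \code{traits}, \code{meta},
#'   \code{degraders} (tip labels of the top \code{degraderFraction} of the
#'   trait distribution — the OTUs constructed to benefit from dose)
#' @export
simulateGradient <- function(config, tree = NULL, traits = NULL) {
    if (is.null(tree)) {
        sim <- simulatePhylogeny(config$nOtus, seed = config$seed + 7L,
                                 traitSigma = config$traitSigma)
        tree <- sim$tree
        traits <- sim$traits
    }
    if (is.null(traits)) stop("traits must accompany a supplied tree")
    if (!setequal(tree$tip.label, names(traits)) ||
        length(traits) != config$nOtus)
        stop("tree tips, traits and nOtus must agree")
    .withSeed(config$seed, {
        meta <- .metacommunity(config)
        z <- (traits - mean(traits)) / stats::sd(traits)
        z <- z[names(meta)]
        doseScaled <- log1p(config$treatments$dose) /
            max(log1p(config$treatments$dose), 1)
        counts <- matrix(0L, config$nOtus,
                         nrow(config$treatments) * config$nPerTreatment)
        j <- 0L
        for (t in seq_len(nrow(config$treatments))) {
            w <- meta * exp(config$selectionStrength * doseScaled[t] * z)
            w <- w / sum(w)
            for (r in seq_len(config$nPerTreatment)) {
                j <- j + 1L
                counts[, j] <- stats::rmultinom(1, config$depth, w)[, 1]
            }
        }
        rownames(counts) <- names(meta)
        colnames(counts) <- .sampleIdsFor(config)
        nDeg <- max(1L, round(config$degraderFraction * config$nOtus))
        list(table = OtuExperiment(counts,
                                   sampleData = .sampleMetaFor(config)),
             tree = tree, traits = traits, meta = meta,
             degraders = names(sort(z, decreasing = TRUE))[seq_len(nDeg)])
    })
}

#' Write paired neutral and gradient fixture files
#'
#' Materialises a matched pair of simulations (shared seed-derived
#' metacommunity and phylogeny) as plain-text files: count table TSV,
#' metadata TSV, newick tree and a ground-truth JSON recording the
#' generating parameters. Two scales are provided: \code{"tiny"} (50 OTUs,
#' 4 treatments x 3 replicates, depth 1,000 — seconds to analyse) and
#' \code{"paper"} (2,000 OTUs, 5 treatments x 6 replicates, depth 39,134).
#'
#' @param outDir writable output directory (created if needed)
#' @param seed integer seed; fixed seed gives byte-identical files
#' @param scale \code{"tiny"} or \code{"paper"}
#' @return named character vector of the files written, invisibly
#' @export
makeFixtures <- function(outDir, seed = 1, scale = c("tiny", "paper")) {
    scale <- match.arg(scale)
    config <- if (scale == "tiny")
        simulationConfig(nOtus = 50, nPerTreatment = 3,
                         treatments = data.frame(
                             label = c("Control", "PYR10", "PYR100",
                                       "PYR500"),
                             dose = c(0, 10, 100, 500)),
                         depth = 1000, seed = seed)
    else simulationConfig(seed = seed)
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    phy <- simulatePhylogeny(config$nOtus, seed = config$seed + 7L,
                             traitSigma = config$traitSigma)
    neut <- simulateNeutral(config, tree = phy$tree)
    grad <- simulateGradient(config, tree = phy$tree, traits = phy$traits)
    paths <- c(
        neutral_table = file.path(outDir, "neutral_table.tsv"),
        gradient_table = file.path(outDir, "gradient_table.tsv"),
        metadata = file.path(outDir, "metadata.tsv"),
        tree = file.path(outDir, "tree.nwk"),
        truth = file.path(outDir, "ground_truth.json"))
    writeOtuTable(neut$table, paths["neutral_table"])
    writeOtuTable(grad$table, paths["gradient_table"])
    utils::write.table(.sampleMetaFor(config), paths["metadata"],
                       sep = "\t", quote = FALSE, row.names = FALSE)
    ape::write.tree(phy$tree, paths["tree"])
    jsonlite::write_json(
        list(scale = scale, seed = config$seed, n_otus = config$nOtus,
             depth = config$depth, m = config$m,
             selection_strength = config$selectionStrength,
             meta_sigma = config$metaSigma,
             treatments = config$treatments,
             degraders = grad$degraders),
        paths["truth"], auto_unbox = TRUE, digits = NA)
    invisible(paths)
}
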