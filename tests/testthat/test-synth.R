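smallConfig <- function(seed = 1, ...) {
    simulationConfig(seed = seed, nChromosomes = 1, chromLength = 4e5,
                     nGenes = 40, nCres = 30, ...)
}

test_that("config validation rejects bad fractions, lengths and gene-free CREs", {
    expect_error(simulationConfig(fractionBidirectionalCre = 1.2), "fraction")
    expect_error(simulationConfig(fractionBidirectionalCre = 0.7,
                                  fractionInactiveCre = 0.5), "sum")
    expect_error(simulationConfig(chromLength = -5), "positive")
    expect_error(simulateGenome(simulationConfig(nGenes = 0, nCres = 10)),
                 "without genes")
})

test_that("gene placement respects spacing and chromosome bounds", {
    sim <- simulateGenome(smallConfig())
    g <- layoutGenes(sim$layout)
    expect_equal(length(g), 40)
    byChrom <- split(g, as.character(seqnames(g)))
    for (ci in seq_along(byChrom)) {
        gg <- sort(byChrom[[ci]], ignore.strand = TRUE)
        gapsBp <- start(gg)[-1] - end(gg)[-length(gg)] - 1L
        expect_true(all(gapsBp >= 4000 - 1))
        expect_true(all(start(gg) >= 1))
        expect_true(all(end(gg) <= chromSizes(sim$layout)[1]))
    }
    ## too many genes for the genome is an infeasible packing
    expect_error(simulateGenome(simulationConfig(nChromosomes = 1,
                                                 chromLength = 1e5,
                                                 nGenes = 200, nCres = 0)),
                 "infeasible")
})

test_that("simulation is byte-identical for a fixed seed", {
    cfg <- smallConfig(seed = 7)
    d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
    for (d in c(d1, d2)) {
        sim <- simulateGenome(cfg)
        nasc <- simulateNascent(sim, cfg)
        writeSimulation(sim, list(np = nasc$plus, nm = nasc$minus), d, cfg)
    }
    for (f in list.files(d1)) {
        expect_identical(unname(tools::md5sum(file.path(d1, f))),
                         unname(tools::md5sum(file.path(d2, f))),
                         label = paste("checksum of", f))
    }
})

test_that("decoy accessible sites never survive IAR extraction", {
    for (seed in 1:3) {
        sim <- simulateGenome(smallConfig(seed = seed))
        iars <- extractIars(sim$layout, sim$accessible)
        expect_gt(length(iars), 0)
        expect_false(any(grepl("^decoy", names(iars))))
        ## decoys exist in the accessible input
        expect_gt(sum(grepl("^decoy", names(sim$accessible))), 0)
        ## and every planted CRE survives with the right distance
        expect_true(all(iars$distance_to_gene >= 100 &
                        iars$distance_to_gene <= 2000))
    }
})

test_that("without bidirectional initiation, upstream antisense is background", {
    cfg <- smallConfig(seed = 3, fractionBidirectionalTss = 0,
                       fractionBidirectionalCre = 0,
                       fractionInactiveCre = 0.2)
    sim <- simulateGenome(cfg)
    nasc <- simulateNascent(sim, cfg)
    g <- layoutGenes(sim$layout)
    plusGenes <- g[strand(g) == "+"]
    ## antisense (minus-track) counts just upstream of plus-gene TSSs
    up <- GRanges(seqnames(plusGenes),
                  IRanges(pmax(start(plusGenes) - 500, 1),
                          start(plusGenes) - 1))
    anti <- aggregateOverRegions(nasc$minus, up)$mean_signal
    ## background reference: same track far from any gene is rate 0.005/bp;
    ## a one-sample rate comparison (Poisson total) should not reject
    nBinCounts <- sum(anti * width(up)) / cfg$binSize
    expected <- cfg$background * sum(width(up)) / cfg$binSize
    p <- poisson.test(round(nBinCounts), T = expected)$p.value
    expect_gt(p, 0.01)
})

test_that("divergent strength 1 gives symmetric flank means in expectation", {
    cfg <- smallConfig(seed = 5, fractionBidirectionalCre = 1,
                       fractionInactiveCre = 0, divergentStrength = 1,
                       noise = "none")
    sim <- simulateGenome(cfg)
    nasc <- simulateNascent(sim, cfg)
    cres <- sim$truth[sim$truth$element_type == "cre", ]
    iars <- extractIars(sim$layout, sim$accessible)
    sk <- computeLocusSkews(nasc$plus, nasc$minus,
                            iars[grepl("^cre", names(iars))], flank = 700)
    ## noiseless symmetric construction: flank means agree in expectation,
    ## up to the one-bin snapping of block edges onto the 10 bp grid
    expect_lt(mean(abs(sk$skew)), 0.05)
    expect_lt(abs(mean(sk$skew)), 0.02)
})

test_that("doubling the initiation rate doubles expected nascent coverage", {
    tot <- function(amp, seed) {
        cfg <- simulationConfig(seed = seed, nChromosomes = 1,
                                chromLength = 4e5, nGenes = 40,
                                nascentAmplitude = amp,
                                background = 0, nCres = 0,
                                decoyFraction = 0)
        sim <- simulateGenome(cfg)
        nasc <- simulateNascent(sim, cfg)
        sum(sum(trackCoverage(nasc$plus))) + sum(sum(trackCoverage(nasc$minus)))
    }
    ## same genome (same seed) at amplitude 2 vs 4, averaged over replicates
    r1 <- mean(vapply(1:20, function(s) tot(2, s), numeric(1)))
    r2 <- mean(vapply(1:20, function(s) tot(4, s), numeric(1)))
    expect_equal(r2 / r1, 2, tolerance = 0.05)
})

test_that("PTM bumps sit only on transcribed sides; inactive get K27me3", {
    cfg <- smallConfig(seed = 9, noise = "none")
    sim <- simulateGenome(cfg)
    ptm <- simulatePtmTracks(sim, cfg)
    cres <- sim$truth[sim$truth$element_type == "cre", ]
    sideMean <- function(track, mid, dir) {
        reg <- if (dir > 0) GRanges(cres$chrom[1], IRanges(mid + 2, mid + 1200))
               else GRanges(cres$chrom[1], IRanges(mid - 1199, mid - 1))
        aggregateOverRegions(track, reg)$mean_signal
    }
    for (i in seq_len(nrow(cres))) {
        mid <- cres$anchor[i]
        k4r <- sideMean(ptm$k4me3, mid, +1)
        k4l <- sideMean(ptm$k4me3, mid, -1)
        cl <- cres$class[i]
        if (cl == "unidirectional-plus")
            expect_gt(k4r / max(k4l, 1e-6), 4)
        if (cl == "unidirectional-minus")
            expect_gt(k4l / max(k4r, 1e-6), 4)
        if (cl == "inactive") {
            k27 <- aggregateOverRegions(ptm$k27me3,
                     GRanges(cres$chrom[1], IRanges(mid - 400, mid + 400)))
            expect_gt(k27$mean_signal, 1)
            expect_lt(k4r + k4l, 0.2)
        }
    }
    ## accessibility peaks at every element midpoint
    acc <- aggregateOverRegions(ptm$accessibility,
             GRanges(cres$chrom, IRanges(cres$anchor - 50, cres$anchor + 50)))
    expect_true(all(acc$mean_signal > 1))
})
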