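## Synthetic epigenome generator: gene models, accessible regions with
## ground-truth directionality labels, strand-specific nascent coverage and
## transcription-coupled histone-PTM tracks, with Poisson count noise.

#' Simulation configuration
#'
#' Builds and validates the parameter set of the synthetic epigenome.
#' Defaults describe a compact flowering-plant-like genome: densely packed
#' short genes, a nucleosome-depleted region (NDR) just upstream of every
#' TSS, gene-proximal intergenic cis-regulatory elements (CREs) 100--2000 bp
#' from a gene (the IAR window), plus decoy accessible sites placed more than
#' 2 kb from any gene, which must never survive IAR extraction.  Signal
#' geometry: H3K4me3 proximal (~300 bp from the element), H3K4me1 distal
#' (~1000 bp), H3K27ac near the element on active sides, H3K27me3 on
#' inactive elements, an accessibility peak over the NDR and an H3 dip under
#' it.  Noise is Poisson on binned counts (`noise = "nb"` adds
#' negative-binomial overdispersion for robustness checks; `"none"` gives
#' the exact mixture-of-bumps expectation).
#'
#' @param seed integer RNG seed (all outputs are reproducible from it).
#' @param nChromosomes,chromLength genome shape (default 2 x 1 Mb).
#' @param nGenes total gene count (default 200).
#' @param geneLengthMeanlog,geneLengthSdlog log-normal gene-length model
#'   (default median 1500 bp, sdlog 0.25).
#' @param minGeneSpacing minimum gap between gene bodies (default 7000 bp,
#'   wide enough that two CREs flanking into the same gap can never reach
#'   each other's 1.2 kb signal neighborhoods).
#' @param nCres intergenic CRE count placed 100--2000 bp from genes
#'   (default 150).
#' @param decoyFraction decoys as a fraction of `nCres`, placed > 2000 bp
#'   from every gene (default 0.2).
#' @param creWidth accessible-site width of CREs/decoys (default 200 bp).
#' @param fractionBidirectionalTss fraction of genes with divergent
#'   (bidirectional) promoter initiation (default 0, plant-like).
#' @param fractionBidirectionalCre,fractionInactiveCre CRE class mix; the
#'   remainder splits evenly between plus- and minus-oriented
#'   unidirectional elements (defaults 0.2 and 0.2).
#' @param divergentStrength ratio of antisense to sense initiation at
#'   bidirectional elements (default 1).
#' @param binSize simulation bin width in bp (default 10).
#' @param background background Poisson mean per bin on every track
#'   (default 0.05).
#' @param nascentAmplitude gene-body sense initiation level, counts per bin
#'   at the TSS, decaying 5'->3' (default 2).
#' @param eRNAAmplitude,eRNALength CRE transcript level (counts per bin) and
#'   length of the short non-elongating eRNA window (defaults 1 and 500 bp).
#' @param antisenseLength length of the divergent upstream antisense window
#'   at bidirectional TSSs (default 500 bp).
#' @param ndrWidth accessibility NDR width (default 200 bp).
#' @param accessAmplitude accessibility peak height, counts per bin
#'   (default 5).
#' @param ptmAmplitude histone-PTM bump height, counts per bin (default 5).
#' @param h3Level H3 baseline, counts per bin (default 2).
#' @param k4me3Offset,k4me3Width,k4me1Offset,k4me1Width,k27acOffset,k27acWidth
#'   flank-bump geometry in bp (defaults 300/300, 800/400, 200/300).
#' @param k27me3Width width of the broad H3K27me3 bump on inactive elements
#'   (default 800 bp).
#' @param h2azOffset,h2azWidth H2A.Z (+1 nucleosome) bump geometry
#'   (defaults 150/200).
#' @param noise `"poisson"` (default), `"nb"` or `"none"`.
#' @param nbSize negative-binomial size parameter when `noise = "nb"`
#'   (default 5).
#' @return A validated list of class `SimulationConfig`.
#' @export
simulationConfig <- function(seed = 1L,
                             nChromosomes = 2, chromLength = 1e6,
                             nGenes = 200,
                             geneLengthMeanlog = log(1500),
                             geneLengthSdlog = 0.25,
                             minGeneSpacing = 7000,
                             nCres = 150, decoyFraction = 0.2,
                             creWidth = 200,
                             fractionBidirectionalTss = 0,
                             fractionBidirectionalCre = 0.2,
                             fractionInactiveCre = 0.2,
                             divergentStrength = 1,
                             binSize = 10, background = 0.05,
                             nascentAmplitude = 2,
                             eRNAAmplitude = 1, eRNALength = 500,
                             antisenseLength = 500,
                             ndrWidth = 200, accessAmplitude = 5,
                             ptmAmplitude = 5, h3Level = 2,
                             k4me3Offset = 300, k4me3Width = 300,
                             k4me1Offset = 800, k4me1Width = 400,
                             k27acOffset = 200, k27acWidth = 300,
                             k27me3Width = 800,
                             h2azOffset = 150, h2azWidth = 200,
                             noise = c("poisson", "nb", "none"),
                             nbSize = 5) {
    cfg <- as.list(environment())
    cfg$noise <- match.arg(noise)
    fr <- c(cfg$fractionBidirectionalTss, cfg$fractionBidirectionalCre,
            cfg$fractionInactiveCre, cfg$decoyFraction)
    if (any(fr < 0 | fr > 1)) stop("fractions must lie in [0, 1]")
    if (cfg$fractionBidirectionalCre + cfg$fractionInactiveCre > 1)
        stop("CRE class fractions must sum to at most 1")
    lens <- c(cfg$chromLength, cfg$creWidth, cfg$binSize, cfg$eRNALength,
              cfg$ndrWidth, cfg$minGeneSpacing)
    if (any(lens <= 0)) stop("all lengths must be positive")
    if (cfg$chromLength %% cfg$binSize != 0)
        stop("binSize must divide chromLength")
    class(cfg) <- "SimulationConfig"
    cfg
}

#' Simulate a genome layout, accessible regions and ground truth
#'
#' Places genes uniformly without overlap (gaps of at least
#' `minGeneSpacing`), gives every gene a TSS-upstream NDR, places intergenic
#' CREs 100--2000 bp from a gene boundary (so they survive
#' [extractIars()]) and decoy accessible sites more than 2000 bp from every
#' gene (which must not), and assigns each element a directionality class.
#'
#' @param config A `SimulationConfig` from [simulationConfig()].
#' @return list with `layout` ([GenomeLayout-class]), `accessible` (named
#'   `GRanges` of NDRs, CREs and decoys) and `truth` (`data.frame` with
#'   `element_id`, `element_type` in gene/cre/decoy, `chrom`, `anchor`
#'   (0-based TSS or midpoint), `class` in unidirectional-plus /
#'   unidirectional-minus / bidirectional / inactive).
#' @export
simulateGenome <- function(config) {
    stopifnot(inherits(config, "SimulationConfig"))
    if (config$nGenes <= 0 && config$nCres > 0)
        stop("IARs are undefined without genes; set nGenes > 0")
    set.seed(config$seed)
    chroms <- sprintf("chr%d", seq_len(config$nChromosomes))
    chromSizes <- structure(rep(config$chromLength, config$nChromosomes),
                            names = chroms)
    perChrom <- diff(round(seq(0, config$nGenes,
                               length.out = config$nChromosomes + 1)))
    geneList <- list()
    creList <- list()
    gid <- 0L
    for (ci in seq_along(chroms)) {
        n <- perChrom[ci]
        if (n == 0) next
        len <- pmax(200, round(rlnorm(n, config$geneLengthMeanlog,
                                      config$geneLengthSdlog)))
        slack <- config$chromLength - sum(len) -
            (n + 1) * config$minGeneSpacing
        if (slack < 0)
            stop("infeasible packing: too many genes for chromosome ",
                 chroms[ci])
        cuts <- sort(runif(n, 0, slack))
        extra <- diff(c(0, cuts, slack))
        gaps <- config$minGeneSpacing + floor(extra)
        starts0 <- cumsum(gaps)[seq_len(n)] + cumsum(c(0, len))[seq_len(n)]
        geneList[[ci]] <- data.frame(
            chrom = chroms[ci], start0 = starts0, end0 = starts0 + len,
            strand = sample(c("+", "-"), n, replace = TRUE),
            gene_id = sprintf("gene%04d", gid + seq_len(n)))
        gid <- gid + n
    }
    genesDf <- do.call(rbind, geneList)
    genes <- GRanges(genesDf$chrom,
                     IRanges(genesDf$start0 + 1L, genesDf$end0),
                     strand = genesDf$strand, gene_id = genesDf$gene_id)
    layout <- GenomeLayout(genes, chromSizes)

    ## element classes
    geneClass <- ifelse(runif(length(genes)) < config$fractionBidirectionalTss,
                        "bidirectional",
                        ifelse(as.character(strand(genes)) == "+",
                               "unidirectional-plus", "unidirectional-minus"))
    nB <- round(config$fractionBidirectionalCre * config$nCres)
    nI <- round(config$fractionInactiveCre * config$nCres)
    nU <- config$nCres - nB - nI
    creClass <- sample(c(rep("bidirectional", nB), rep("inactive", nI),
                         rep("unidirectional-plus", ceiling(nU / 2)),
                         rep("unidirectional-minus", floor(nU / 2))))

    ## NDR upstream of each TSS (50 bp gap between NDR edge and TSS)
    tssGr <- tssPositions(layout)
    tss0 <- start(tssGr) - 1L
    plus <- as.character(strand(genes)) == "+"
    ndrS0 <- ifelse(plus, tss0 - 50L - config$ndrWidth, tss0 + 51L)
    ndr <- GRanges(seqnames(genes),
                   IRanges(pmax(ndrS0, 0L) + 1L,
                           width = config$ndrWidth))
    names(ndr) <- paste0("ndr_", genes$gene_id)

    ## CREs: one per sampled (gene, side) slot so elements never crowd each
    ## other's windows, distance 1200..1800 from the gene boundary, so the
    ## +/-1 kb neighborhood of each CRE midpoint is gene-free while the CRE
    ## stays inside the 100-2000 bp IAR window (min gene gaps of 4 kb
    ## guarantee no overlap with neighbors)
    nCre <- config$nCres
    if (nCre > 2L * length(genes))
        stop("infeasible: more CREs requested than gene-flank slots")
    slots <- sample(2L * length(genes), nCre)
    host <- (slots + 1L) %/% 2L
    side <- ifelse(slots %% 2L == 0L, 1L, -1L)
    dist <- sample(1200:1800, nCre, replace = TRUE)
    hs0 <- start(genes)[host] - 1L
    he0 <- end(genes)[host]
    creS0 <- ifelse(side < 0, hs0 - dist - config$creWidth, he0 + dist)
    creS0 <- pmax(creS0, 0L)
    creS0 <- pmin(creS0, config$chromLength - config$creWidth)
    cre <- GRanges(seqnames(genes)[host],
                   IRanges(creS0 + 1L, width = config$creWidth))
    ## reject CREs overlapping a gene body or NDR placement artifacts at
    ## chromosome edges, and re-check the distance window
    ok <- !overlapsAny(cre, genes, ignore.strand = TRUE)
    d <- mcols(distanceToNearest(cre, genes, ignore.strand = TRUE))$distance
    ok <- ok & d >= 100 & d <= 2000
    cre <- cre[ok]
    creClass <- creClass[ok]
    names(cre) <- sprintf("cre%04d", seq_along(cre))

    ## decoys: centered in gaps wide enough to be > 2000 bp from both genes
    nDecoy <- round(config$decoyFraction * config$nCres)
    decoy <- GRanges()
    if (nDecoy > 0) {
        gapsGr <- gaps(reduce(genes, ignore.strand = TRUE))
        gapsGr <- gapsGr[strand(gapsGr) == "*"]
        need <- 2 * 2200 + config$creWidth
        gapsGr <- gapsGr[width(gapsGr) >= need &
                         start(gapsGr) > 1 &
                         end(gapsGr) < chromSizes[as.character(seqnames(gapsGr))]]
        if (!length(gapsGr))
            stop("no gap wide enough to place decoy accessible sites")
        pick <- sample(length(gapsGr), nDecoy, replace = TRUE)
        mid <- floor((start(gapsGr)[pick] + end(gapsGr)[pick]) / 2)
        jit <- sample(-100:100, nDecoy, replace = TRUE)
        decoy <- GRanges(seqnames(gapsGr)[pick],
                         IRanges(mid + jit, width = config$creWidth))
        names(decoy) <- sprintf("decoy%04d", seq_len(nDecoy))
    }

    accessible <- sort(c(ndr, cre, decoy), ignore.strand = TRUE)
    seqlevels(accessible) <- chroms
    seqlengths(accessible) <- unname(chromSizes)
    S4Vectors::metadata(accessible)$provenance <- "synthetic accessible sites"

    truth <- rbind(
        data.frame(element_id = genes$gene_id, element_type = "gene",
                   chrom = as.character(seqnames(genes)),
                   anchor = tss0, class = geneClass),
        if (length(cre))
            data.frame(element_id = names(cre), element_type = "cre",
                       chrom = as.character(seqnames(cre)),
                       anchor = as.integer(floor((start(cre) - 1L +
                                                  end(cre)) / 2)),
                       class = creClass),
        if (length(decoy))
            data.frame(element_id = names(decoy), element_type = "decoy",
                       chrom = as.character(seqnames(decoy)),
                       anchor = as.integer(floor((start(decoy) - 1L +
                                                  end(decoy)) / 2)),
                       class = "inactive")
    )
    rownames(truth) <- NULL
    list(layout = layout, accessible = accessible, truth = truth)
}

## ---------------------------------------------------------------------------
## signal synthesis helpers (all on per-bin mean matrices)
## ---------------------------------------------------------------------------

## add a flat block [s0, e0) (0-based bp) of `amp` to a per-bin mean vector
.addBlock <- function(mu, s0, e0, amp, binSize, taper = 0) {
    nb <- length(mu)
    b1 <- max(floor(s0 / binSize) + 1, 1)
    b2 <- min(ceiling(e0 / binSize), nb)
    if (b2 < b1) return(mu)
    idx <- b1:b2
    if (taper > 0) {
        t <- seq(0, 1, length.out = length(idx))
        mu[idx] <- mu[idx] + amp * exp(-taper * t)
    } else {
        mu[idx] <- mu[idx] + amp
    }
    mu
}

## add a gaussian bump centered at 0-based bp `center0` with sd `width`/2
.addBump <- function(mu, center0, width, amp, binSize) {
    nb <- length(mu)
    sdv <- width / 2
    span <- ceiling(2 * width / binSize)
    cb <- floor(center0 / binSize) + 1
    idx <- max(1, cb - span):min(nb, cb + span)
    if (!length(idx)) return(mu)
    x <- (idx - 0.5) * binSize
    mu[idx] <- mu[idx] + amp * exp(-((x - center0)^2) / (2 * sdv^2))
    mu
}

.noisify <- function(mu, config) {
    switch(config$noise,
           none = mu,
           poisson = rpois(length(mu), mu),
           nb = rnbinom(length(mu), size = config$nbSize, mu = mu))
}

.binsToTrack <- function(binsByChrom, config, strand, label) {
    cov <- as(lapply(binsByChrom, function(v)
        Rle(as.numeric(v), rep(config$binSize, length(v)))), "RleList")
    CoverageTrack(cov, strand = strand, label = label,
                  binSize = config$binSize)
}

.emptyBins <- function(config, base = 0) {
    nb <- config$chromLength / config$binSize
    chroms <- sprintf("chr%d", seq_len(config$nChromosomes))
    structure(lapply(chroms, function(x) rep(base, nb)), names = chroms)
}

#' Simulate strand-specific nascent-transcription coverage
#'
#' Sense-strand coverage decays 5'->3' over each active gene body; divergent
#' (bidirectional) elements additionally produce a short (~500 bp)
#' non-elongating antisense transcript upstream of the anchor at
#' `divergentStrength` times the sense initiation level.  CREs produce short
#' eRNA windows on their transcribed side(s).  A uniform background rate
#' applies everywhere and counts are drawn per bin under the configured
#' noise model.
#'
#' @param sim output of [simulateGenome()].
#' @param config the same `SimulationConfig`.
#' @return list with `plus` and `minus` [CoverageTrack-class] objects.
#' @export
simulateNascent <- function(sim, config) {
    set.seed(config$seed + 7919L)
    muP <- .emptyBins(config, config$background)
    muM <- .emptyBins(config, config$background)
    genes <- layoutGenes(sim$layout)
    truth <- sim$truth
    gcl <- truth$class[match(genes$gene_id, truth$element_id)]
    for (i in seq_along(genes)) {
        ch <- as.character(seqnames(genes))[i]
        s0 <- start(genes)[i] - 1L
        e0 <- end(genes)[i]
        plusGene <- as.character(strand(genes))[i] == "+"
        amp <- config$nascentAmplitude
        if (plusGene)
            muP[[ch]] <- .addBlock(muP[[ch]], s0, e0, amp, config$binSize,
                                   taper = 1)
        else {
            ## 5'->3' decay for a minus gene runs right to left; emulate by
            ## tapering the reversed block
            nb <- length(muM[[ch]])
            tmp <- rev(.addBlock(rep(0, nb),
                                 config$chromLength - e0,
                                 config$chromLength - s0,
                                 amp, config$binSize, taper = 1))
            muM[[ch]] <- muM[[ch]] + tmp
        }
        if (gcl[i] == "bidirectional") {
            aamp <- amp * config$divergentStrength
            if (plusGene)
                muM[[ch]] <- .addBlock(muM[[ch]],
                                       s0 - config$antisenseLength, s0,
                                       aamp, config$binSize)
            else
                muP[[ch]] <- .addBlock(muP[[ch]], e0,
                                       e0 + config$antisenseLength,
                                       aamp, config$binSize)
        }
    }
    cres <- truth[truth$element_type == "cre", ]
    for (i in seq_len(nrow(cres))) {
        ch <- cres$chrom[i]
        mid <- cres$anchor[i]
        amp <- config$eRNAAmplitude
        cl <- cres$class[i]
        if (cl %in% c("unidirectional-plus", "bidirectional"))
            muP[[ch]] <- .addBlock(muP[[ch]], mid, mid + config$eRNALength,
                                   amp, config$binSize)
        if (cl %in% c("unidirectional-minus"))
            muM[[ch]] <- .addBlock(muM[[ch]], mid - config$eRNALength, mid,
                                   amp, config$binSize)
        if (cl == "bidirectional")
            muM[[ch]] <- .addBlock(muM[[ch]], mid - config$eRNALength, mid,
                                   amp * config$divergentStrength,
                                   config$binSize)
    }
    plus <- lapply(muP, .noisify, config = config)
    minus <- lapply(muM, .noisify, config = config)
    list(plus = .binsToTrack(plus, config, "+", "nascent.plus"),
         minus = .binsToTrack(minus, config, "-", "nascent.minus"))
}

#' Simulate histone-PTM, histone and accessibility tracks
#'
#' Places transcription-coupled PTM bumps only on the transcribed side(s) of
#' each element (both sides iff bidirectional): H3K4me3 proximal, H3K4me1
#' distal, H3K27ac near the element on active sides, H2A.Z at the +1
#' nucleosome.  Accessibility peaks over every NDR/element midpoint, H3 is a
#' uniform nucleosome baseline depleted in the NDR, and H3K27me3 covers
#' inactive elements.  Counts are drawn per bin under the configured noise
#' model.
#'
#' @param sim output of [simulateGenome()].
#' @param config the same `SimulationConfig`.
#' @return Named list of unstranded [CoverageTrack-class] objects:
#'   `k4me3`, `k4me1`, `k27ac`, `k27me3`, `h3`, `h2az`, `accessibility`.
#' @export
simulatePtmTracks <- function(sim, config) {
    set.seed(config$seed + 104729L)
    marks <- c("k4me3", "k4me1", "k27ac", "k27me3", "h3", "h2az",
               "accessibility")
    mu <- structure(lapply(marks, function(m)
        .emptyBins(config, if (m == "h3") config$h3Level
                           else config$background)), names = marks)
    truth <- sim$truth
    genes <- layoutGenes(sim$layout)
    tss0 <- start(tssPositions(sim$layout)) - 1L
    names(tss0) <- genes$gene_id

    addSide <- function(mark, ch, anchor0, dir, offset, width, amp) {
        mu[[mark]][[ch]] <<- .addBump(mu[[mark]][[ch]],
                                      anchor0 + dir * offset, width, amp,
                                      config$binSize)
    }
    for (i in seq_len(nrow(truth))) {
        el <- truth[i, ]
        ch <- el$chrom
        anchor0 <- el$anchor
        ## transcribed directions in genomic coordinates
        dirs <- switch(el$class,
                       "unidirectional-plus" = 1L,
                       "unidirectional-minus" = -1L,
                       "bidirectional" = c(-1L, 1L),
                       "inactive" = integer(0))
        for (d in dirs) {
            addSide("k4me3", ch, anchor0, d, config$k4me3Offset,
                    config$k4me3Width, config$ptmAmplitude)
            addSide("k4me1", ch, anchor0, d, config$k4me1Offset,
                    config$k4me1Width, config$ptmAmplitude)
            addSide("k27ac", ch, anchor0, d, config$k27acOffset,
                    config$k27acWidth, config$ptmAmplitude)
            addSide("h2az", ch, anchor0, d, config$h2azOffset,
                    config$h2azWidth, config$ptmAmplitude)
        }
        if (!length(dirs) && el$element_type != "gene") {
            mu$k27me3[[ch]] <- .addBump(mu$k27me3[[ch]], anchor0,
                                        config$k27me3Width,
                                        config$ptmAmplitude, config$binSize)
        }
        ## accessibility peak and H3 dip at the element center / NDR
        ndr0 <- if (el$element_type == "gene") {
            d <- if (grepl("minus", el$class)) 1L else -1L
            ## for bidirectional genes keep the NDR on the sense-upstream side
            if (el$class == "bidirectional")
                d <- if (as.character(strand(genes))[match(el$element_id,
                     genes$gene_id)] == "-") 1L else -1L
            anchor0 + d * (50L + config$ndrWidth %/% 2L)
        } else anchor0
        mu$accessibility[[ch]] <- .addBump(mu$accessibility[[ch]], ndr0,
                                           config$ndrWidth,
                                           config$accessAmplitude,
                                           config$binSize)
        hd <- .addBump(rep(0, length(mu$h3[[ch]])), ndr0, config$ndrWidth,
                       config$h3Level, config$binSize)
        mu$h3[[ch]] <- pmax(mu$h3[[ch]] - hd, 0)
    }
    out <- lapply(marks, function(m) {
        bins <- lapply(mu[[m]], .noisify, config = config)
        .binsToTrack(bins, config, "*", m)
    })
    names(out) <- marks
    out
}

#' Simulate one skew group directly
#'
#' Draws per-locus upstream and downstream flank totals from Poisson
#' distributions and returns them in the [computeLocusSkews()] layout --
#' the direct route for calibration studies of the skew test (type-I error
#' under a symmetric null, power under a one-sided alternative).
#'
#' @param nLoci loci in the group.
#' @param upMean,downMean Poisson means of the per-flank signal totals.
#' @return `data.frame` compatible with [filterSilent()] /
#'   [testDirectionality()].
#' @export
simulateSkewGroup <- function(nLoci, upMean, downMean) {
    up <- rpois(nLoci, upMean)
    down <- rpois(nLoci, downMean)
    data.frame(iar = paste0("locus", seq_len(nLoci)),
               up_signal = up, down_signal = down,
               up_log = log2(up + 1), down_log = log2(down + 1),
               skew = log2(down + 1) - log2(up + 1))
}

#' Write a simulation to disk
#'
#' Writes the annotation (GFF3), chrom.sizes, accessible regions (BED6),
#' ground-truth labels (TSV), every track (bedGraph) and the configuration
#' (YAML) into a directory.
#'
#' @param sim output of [simulateGenome()].
#' @param tracks named list of [CoverageTrack-class] objects (e.g. the
#'   nascent pair plus PTM tracks).
#' @param dir output directory (created if needed).
#' @param config the `SimulationConfig` (optional, stored as YAML).
#' @return Named list of written paths.
#' @export
writeSimulation <- function(sim, tracks, dir, config = NULL) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(
        annotation = file.path(dir, "annotation.gff3"),
        chromSizes = file.path(dir, "chrom.sizes"),
        accessible = file.path(dir, "accessible.bed"),
        truth = file.path(dir, "truth.tsv"))
    writeAnnotationGff3(sim$layout, paths$annotation)
    writeChromSizes(chromSizes(sim$layout), paths$chromSizes)
    writeRegionsBed(sim$accessible, paths$accessible)
    write.table(sim$truth, paths$truth, sep = "\t", quote = FALSE,
                row.names = FALSE)
    for (nm in names(tracks)) {
        p <- file.path(dir, paste0(nm, ".bedgraph"))
        writeTrack(tracks[[nm]], p)
        paths[[paste0("track_", nm)]] <- p
    }
    if (!is.null(config)) {
        paths$config <- file.path(dir, "simulation.yaml")
        yaml::write_yaml(unclass(config), paths$config)
    }
    paths
}

#' Score directionality recovery against ground truth
#'
#' Maps each group of loci to the majority ground-truth class of its members
#' and checks the group's directionality call against the expectation:
#' unidirectional-plus elements must be called unidirectional favoring the
#' downstream (genomic right) side, unidirectional-minus the upstream side,
#' bidirectional elements must not be called unidirectional, and inactive
#' groups must not be called unidirectional either.
#'
#' @param results `data.frame` from [testDirectionality()].
#' @param groupOf named vector mapping locus id -> group label.
#' @param truthClass named vector mapping locus id -> ground-truth class.
#' @return list with `per_group` data.frame and `recovery` (fraction of
#'   groups recovered).
#' @export
scoreDirectionalityRecovery <- function(results, groupOf, truthClass) {
    ids <- names(groupOf)
    maj <- vapply(split(truthClass[ids], as.character(groupOf)), function(x)
        names(sort(table(x), decreasing = TRUE))[1], character(1))
    per <- results
    per$truth_class <- maj[as.character(per$group)]
    expectCall <- function(cl, call, side) {
        switch(cl,
               "unidirectional-plus" = call == "unidirectional" &&
                   side == "downstream",
               "unidirectional-minus" = call == "unidirectional" &&
                   side == "upstream",
               "bidirectional" = call != "unidirectional",
               "inactive" = call != "unidirectional",
               NA)
    }
    per$recovered <- mapply(expectCall, per$truth_class, per$call,
                            per$favored_side)
    list(per_group = per, recovery = mean(per$recovered))
}
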