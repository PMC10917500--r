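## Config-driven orchestration: each stage reads files, writes files (plus a
## machine-readable manifest), so there is no hidden state between stages.
## Outputs are written atomically (temp file + rename).  Manifests contain
## parameters and input/output checksums but no timestamps, so identical
## config + seed reproduce byte-identical artifacts; stage timings go to
## stderr.

.configError <- function(...) {
    stop(structure(class = c("txinit_config_error", "error", "condition"),
                   list(message = paste0(...), call = sys.call(-1))))
}

.dataError <- function(...) {
    stop(structure(class = c("txinit_data_error", "error", "condition"),
                   list(message = paste0(...), call = sys.call(-1))))
}

#' Read and validate a run configuration
#'
#' A YAML file with the fields `seed`, `outdir`, either a `simulate` block
#' (parameters for [simulationConfig()]) or input paths (`annotation`,
#' `chromSizes`, `accessible`, `tracks` with `label`/`path`/`strand` and an
#' optional `nascent` flag), and optional `iar`, `profile`, `cluster`,
#' `skew` parameter blocks (defaults are the package defaults for each
#' stage).
#'
#' @param path YAML file, or a list with the same structure.
#' @return A validated list of class `RunConfig`.
#' @export
readRunConfig <- function(path) {
    cfg <- if (is.character(path)) yaml::read_yaml(path) else path
    if (is.null(cfg$seed))
        .configError("config field 'seed' is required")
    if (is.null(cfg$outdir))
        .configError("config field 'outdir' is required")
    cfg$seed <- as.integer(cfg$seed)
    defaults <- list(
        iar = list(minDist = 100, maxDist = 2000, minWidth = 50,
                   anchor = "gene"),
        profile = list(upstream = 2000, downstream = 2000, binSize = 50,
                       zscore = TRUE, trim = c(0.1, 0.1)),
        cluster = list(k = 5, nInit = 10, orient = "none",
                       standardizeTracks = FALSE, window = 1000,
                       maskGenes = FALSE, maskPad = 400),
        skew = list(flank = 2000, alpha = 0.05, minN = 10,
                    strandMode = "combined", groupBy = "cluster"))
    for (blk in names(defaults)) {
        given <- if (is.null(cfg[[blk]])) list() else cfg[[blk]]
        unknown <- setdiff(names(given), names(defaults[[blk]]))
        if (length(unknown))
            .configError("unknown key(s) in '", blk, "' block: ",
                         paste(unknown, collapse = ", "))
        cfg[[blk]] <- modifyList(defaults[[blk]], given)
    }
    if (is.null(cfg$simulate)) {
        for (f in c("annotation", "chromSizes", "accessible")) {
            if (is.null(cfg[[f]]))
                .configError("config field '", f,
                             "' is required when no 'simulate' block is given")
            if (!file.exists(cfg[[f]]))
                .configError("config field '", f, "': file not found: ",
                             cfg[[f]])
        }
        if (!length(cfg$tracks))
            .configError("config field 'tracks' must list at least one track")
        for (tr in cfg$tracks) {
            if (is.null(tr$label) || is.null(tr$path))
                .configError("every track needs 'label' and 'path'")
            if (!file.exists(tr$path))
                .configError("track '", tr$label, "': file not found: ",
                             tr$path)
        }
    }
    if (cfg$skew$strandMode == "oriented" && !is.null(cfg$tracks)) {
        strands <- vapply(cfg$tracks, function(tr)
            if (is.null(tr$strand)) "*" else tr$strand, character(1))
        nasc <- vapply(cfg$tracks, function(tr) isTRUE(tr$nascent), logical(1))
        if (!any(nasc & strands == "-"))
            .configError("strandMode 'oriented' requires a minus-strand ",
                         "nascent track; none is configured")
    }
    class(cfg) <- c("RunConfig", "list")
    cfg
}

.asRunConfig <- function(config) {
    if (inherits(config, "RunConfig")) config else readRunConfig(config)
}

.stageLog <- function(stage, t0) {
    message(sprintf("[txinit] %-14s %.2fs", stage,
                    as.numeric(proc.time()[3] - t0)))
}

## atomic writer: fn writes to a temp path (plus optional sidecar suffixes),
## then every produced file is renamed into place
.atomically <- function(path, fn, sidecars = character()) {
    tmp <- paste0(path, ".tmp")
    fn(tmp)
    stopifnot(file.rename(tmp, path))
    for (sc in sidecars) {
        stopifnot(file.rename(paste0(tmp, sc), paste0(path, sc)))
    }
    path
}

## checksums keyed by file name (not path), so manifests are identical
## across reruns in different directories
.md5List <- function(paths) {
    p <- as.character(unlist(paths))
    if (!length(p)) return(stats::setNames(list(), character()))
    md5 <- tools::md5sum(p)
    stats::setNames(as.list(unname(md5)), basename(p))
}

.writeManifest <- function(cfg, stage, params, inputs, outputs) {
    mf <- list(stage = stage,
               package = as.character(utils::packageVersion("txinit")),
               seed = cfg$seed,
               parameters = params,
               inputs = .md5List(inputs),
               outputs = .md5List(outputs))
    p <- file.path(cfg$outdir, paste0("manifest_", stage, ".json"))
    .atomically(p, function(tmp)
        jsonlite::write_json(mf, tmp, auto_unbox = TRUE, pretty = TRUE))
    p
}

#' Pipeline stage commands
#'
#' Config-driven stages of the directionality pipeline.  Each command reads
#' its inputs from the paths in the config, writes its documented TSV/BED/
#' bedGraph artifacts plus a manifest (parameters and input/output
#' checksums) into `outdir`, and returns the updated config invisibly so the
#' stages can be chained.  `cmdAll()` runs simulate (when configured),
#' extract-iars, profile, cluster and skew in order and is equivalent to
#' running the stage commands in sequence.
#'
#' @param config a `RunConfig` from [readRunConfig()], a path to one, or a
#'   list with the same structure.
#' @return The (possibly augmented) `RunConfig`, invisibly.
#' @name pipeline
NULL

#' @rdname pipeline
#' @export
cmdSimulate <- function(config) {
    cfg <- .asRunConfig(config)
    if (is.null(cfg$simulate))
        .configError("no 'simulate' block in config")
    t0 <- proc.time()[3]
    simdir <- file.path(cfg$outdir, "sim")
    args <- cfg$simulate
    args$seed <- cfg$seed
    scfg <- do.call(simulationConfig, args)
    sim <- simulateGenome(scfg)
    nasc <- simulateNascent(sim, scfg)
    ptm <- simulatePtmTracks(sim, scfg)
    tracks <- c(list(nascent.plus = nasc$plus, nascent.minus = nasc$minus),
                ptm)
    paths <- writeSimulation(sim, tracks, simdir, scfg)
    cfg$annotation <- paths$annotation
    cfg$chromSizes <- paths$chromSizes
    cfg$accessible <- paths$accessible
    cfg$truth <- paths$truth
    cfg$tracks <- lapply(names(tracks), function(nm) {
        list(label = nm, path = file.path(simdir, paste0(nm, ".bedgraph")),
             strand = trackStrand(tracks[[nm]]),
             binSize = trackBinSize(tracks[[nm]]),
             nascent = grepl("^nascent", nm))
    })
    .writeManifest(cfg, "simulate", args, list(), paths)
    .stageLog("simulate", t0)
    invisible(cfg)
}

.loadLayout <- function(cfg) {
    readAnnotation(cfg$annotation, format = "gff3",
                   chromSizes = cfg$chromSizes)
}

.loadConfiguredTrack <- function(tr, chromSizes) {
    loadTrack(tr$path, format = "bedgraph",
              strand = if (is.null(tr$strand)) "*" else tr$strand,
              label = tr$label, chromSizes = chromSizes,
              binSize = if (is.null(tr$binSize)) 1 else tr$binSize)
}

.readIarTable <- function(cfg) {
    p <- file.path(cfg$outdir, "iars.tsv")
    if (!file.exists(p))
        .dataError("iars.tsv not found in outdir; run cmdExtractIars first")
    read.table(p, sep = "\t", header = TRUE,
               colClasses = c(chrom = "character"))
}

.iarTableToGRanges <- function(tab) {
    gr <- GRanges(tab$chrom, IRanges(tab$start + 1L, tab$end))
    names(gr) <- tab$iar
    mcols(gr) <- S4Vectors::DataFrame(
        midpoint = tab$midpoint, nearest_gene_id = tab$nearest_gene_id,
        nearest_gene_strand = tab$nearest_gene_strand,
        relative_position = tab$relative_position,
        distance_to_gene = tab$distance_to_gene)
    gr
}

#' @rdname pipeline
#' @export
cmdExtractIars <- function(config) {
    cfg <- .asRunConfig(config)
    t0 <- proc.time()[3]
    dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
    layout <- .loadLayout(cfg)
    chromSizes <- chromSizes(layout)
    accessible <- readRegionsBed(cfg$accessible, chromSizes = chromSizes)
    if (!length(layoutGenes(layout)))
        .dataError("annotation contains no genes; IARs are undefined")
    iars <- extractIars(layout, accessible,
                        minDist = cfg$iar$minDist, maxDist = cfg$iar$maxDist,
                        minWidth = cfg$iar$minWidth, anchor = cfg$iar$anchor)
    src <- names(iars)
    names(iars) <- sprintf("iar%05d", seq_along(iars))
    bed <- file.path(cfg$outdir, "iars.bed")
    tsv <- file.path(cfg$outdir, "iars.tsv")
    .atomically(bed, function(tmp) writeRegionsBed(iars, tmp))
    tab <- data.frame(iar = names(iars),
                      chrom = as.character(seqnames(iars)),
                      start = start(iars) - 1L, end = end(iars),
                      source_region = if (length(iars)) src else character(0),
                      as.data.frame(mcols(iars)))
    .atomically(tsv, function(tmp)
        write.table(tab, tmp, sep = "\t", quote = FALSE, row.names = FALSE))
    .writeManifest(cfg, "extract_iars", cfg$iar,
                   list(annotation = cfg$annotation,
                        accessible = cfg$accessible),
                   list(bed = bed, tsv = tsv))
    .stageLog("extract_iars", t0)
    invisible(cfg)
}

#' @rdname pipeline
#' @export
cmdProfile <- function(config) {
    cfg <- .asRunConfig(config)
    t0 <- proc.time()[3]
    layout <- .loadLayout(cfg)
    chromSizes <- chromSizes(layout)
    tab <- .readIarTable(cfg)
    anchors <- GRanges(tab$chrom, IRanges(tab$midpoint + 1L, width = 1L))
    names(anchors) <- tab$iar
    seqlevels(anchors) <- names(chromSizes)
    seqlengths(anchors) <- unname(chromSizes)
    pdir <- file.path(cfg$outdir, "profiles")
    dir.create(pdir, recursive = TRUE, showWarnings = FALSE)
    outs <- list()
    for (tr in cfg$tracks) {
        track <- .loadConfiguredTrack(tr, chromSizes)
        pm <- pointAnchoredMatrix(track, anchors,
                                  upstreamBp = cfg$profile$upstream,
                                  downstreamBp = cfg$profile$downstream,
                                  binSize = cfg$profile$binSize)
        trim <- if (isTRUE(tr$nascent)) cfg$profile$trim else c(0, 0)
        sm <- summarizeProfile(pm, zscore = isTRUE(cfg$profile$zscore),
                               trim = trim)
        mp <- file.path(pdir, paste0(tr$label, ".matrix.tsv"))
        sp <- file.path(pdir, paste0(tr$label, ".summary.tsv"))
        .atomically(mp, function(tmp) writeProfileMatrix(pm, tmp),
                    sidecars = ".json")
        .atomically(sp, function(tmp)
            write.table(sm, tmp, sep = "\t", quote = FALSE,
                        row.names = FALSE))
        outs[[paste0(tr$label, "_matrix")]] <- mp
        outs[[paste0(tr$label, "_summary")]] <- sp
    }
    .writeManifest(cfg, "profile", cfg$profile,
                   c(list(iars = file.path(cfg$outdir, "iars.tsv")),
                     lapply(cfg$tracks, `[[`, "path")),
                   outs)
    .stageLog("profile", t0)
    invisible(cfg)
}

#' @rdname pipeline
#' @export
cmdCluster <- function(config) {
    cfg <- .asRunConfig(config)
    t0 <- proc.time()[3]
    pdir <- file.path(cfg$outdir, "profiles")
    labels <- vapply(cfg$tracks, `[[`, character(1), "label")
    paths <- file.path(pdir, paste0(labels, ".matrix.tsv"))
    if (!all(file.exists(paths)))
        .dataError("profile matrices missing; run cmdProfile first")
    mats <- lapply(paths, readProfileMatrix)
    if (!is.null(cfg$cluster$window) &&
        cfg$cluster$window < mats[[1]]@upstreamBp)
        mats <- lapply(mats, trimProfileWindow,
                       upstreamBp = cfg$cluster$window)
    if (isTRUE(cfg$cluster$maskGenes)) {
        layout <- .loadLayout(cfg)
        itab <- .readIarTable(cfg)
        anchors <- GRanges(itab$chrom, IRanges(itab$midpoint + 1L, width = 1L))
        names(anchors) <- itab$iar
        mats <- lapply(mats, maskAnnotatedBins, anchors = anchors,
                       layout = layout, promoterPad = cfg$cluster$maskPad)
    }
    ## strand-specific track pairs (label stem + strand flags) must swap
    ## blocks when rows are mirrored
    strands <- vapply(cfg$tracks, function(tr)
        if (is.null(tr$strand)) "*" else tr$strand, character(1))
    stems <- sub("\\.(plus|minus)$", "", labels)
    strandPairs <- list()
    for (st in unique(stems[strands == "+"])) {
        ip <- which(stems == st & strands == "+")
        im <- which(stems == st & strands == "-")
        if (length(ip) == 1 && length(im) == 1)
            strandPairs <- c(strandPairs, list(c(ip, im)))
    }
    refMat <- NULL
    if (identical(cfg$cluster$orient, "dominant") && length(strandPairs)) {
        pr <- strandPairs[[1]]
        refMat <- profileMatrix(mats[[pr[1]]])
        mm <- profileMatrix(mats[[pr[2]]])
        refMat[is.na(refMat)] <- 0
        mm[is.na(mm)] <- 0
        refMat <- refMat + mm
    }
    feats <- buildFeatureMatrix(mats,
                                standardizeTracks =
                                    isTRUE(cfg$cluster$standardizeTracks),
                                orient = cfg$cluster$orient,
                                referenceMatrix = refMat,
                                strandPairs = strandPairs)
    ca <- kmeansCluster(feats, k = cfg$cluster$k, seed = cfg$seed,
                        nInit = cfg$cluster$nInit)
    tab <- data.frame(iar = names(clusterLabels(ca)),
                      cluster = unname(clusterLabels(ca)))
    ctsv <- file.path(cfg$outdir, "clusters.tsv")
    cbed <- file.path(cfg$outdir, "clusters.bed")
    csum <- file.path(cfg$outdir, "cluster_summary.tsv")
    .atomically(ctsv, function(tmp)
        write.table(tab, tmp, sep = "\t", quote = FALSE, row.names = FALSE))
    itab <- .readIarTable(cfg)
    m <- match(itab$iar, tab$iar)
    bedTab <- data.frame(chrom = itab$chrom, start = itab$start,
                         end = itab$end,
                         name = paste0("cluster", tab$cluster[m]),
                         score = 0L, strand = ".")
    .atomically(cbed, function(tmp)
        write.table(bedTab, tmp, sep = "\t", quote = FALSE,
                    row.names = FALSE, col.names = FALSE))
    .atomically(csum, function(tmp)
        write.table(clusterSummary(ca, feats), tmp, sep = "\t",
                    quote = FALSE, row.names = FALSE))
    .writeManifest(cfg, "cluster", cfg$cluster,
                   as.list(structure(paths, names = labels)),
                   list(clusters = ctsv, bed = cbed, summary = csum))
    .stageLog("cluster", t0)
    invisible(cfg)
}

#' @rdname pipeline
#' @export
cmdSkew <- function(config) {
    cfg <- .asRunConfig(config)
    t0 <- proc.time()[3]
    layout <- .loadLayout(cfg)
    chromSizes <- chromSizes(layout)
    tab <- .readIarTable(cfg)
    iars <- .iarTableToGRanges(tab)
    nasc <- Filter(function(tr) isTRUE(tr$nascent), cfg$tracks)
    if (!length(nasc))
        .configError("no track flagged 'nascent' for the skew stage")
    strands <- vapply(nasc, function(tr)
        if (is.null(tr$strand)) "*" else tr$strand, character(1))
    plusTr <- nasc[strands %in% c("+", "*")]
    minusTr <- nasc[strands == "-"]
    if (cfg$skew$strandMode == "oriented" &&
        (!length(plusTr) || !length(minusTr)))
        .configError("strandMode 'oriented' requires plus- and minus-strand ",
                     "nascent tracks")
    plusTrack <- .loadConfiguredTrack(plusTr[[1]], chromSizes)
    minusTrack <- if (length(minusTr))
        .loadConfiguredTrack(minusTr[[1]], chromSizes) else NULL
    loci <- computeLocusSkews(plusTrack, minusTrack, iars,
                              flank = cfg$skew$flank,
                              strandMode = cfg$skew$strandMode,
                              chromSizes = chromSizes)
    groups <- NULL
    if (identical(cfg$skew$groupBy, "cluster")) {
        cpath <- file.path(cfg$outdir, "clusters.tsv")
        if (!file.exists(cpath))
            .dataError("clusters.tsv not found; run cmdCluster first or set ",
                       "skew$groupBy to 'none'")
        ctab <- read.table(cpath, sep = "\t", header = TRUE)
        groups <- structure(paste0("cluster", ctab$cluster), names = ctab$iar)
    }
    res <- testDirectionality(loci, groups, alpha = cfg$skew$alpha,
                              minN = cfg$skew$minN)
    viol <- exportSkewViolinData(filterSilent(loci), groups)
    lpath <- file.path(cfg$outdir, "locus_skews.tsv")
    tpath <- file.path(cfg$outdir, "skew_tests.tsv")
    vpath <- file.path(cfg$outdir, "violin_data.tsv")
    .atomically(lpath, function(tmp)
        write.table(loci, tmp, sep = "\t", quote = FALSE, row.names = FALSE))
    .atomically(tpath, function(tmp)
        write.table(res, tmp, sep = "\t", quote = FALSE, row.names = FALSE))
    .atomically(vpath, function(tmp)
        write.table(viol, tmp, sep = "\t", quote = FALSE, row.names = FALSE))
    .writeManifest(cfg, "skew", cfg$skew,
                   list(iars = file.path(cfg$outdir, "iars.tsv"),
                        plus = plusTr[[1]]$path),
                   list(loci = lpath, tests = tpath, violins = vpath))
    .stageLog("skew", t0)
    invisible(cfg)
}

#' @rdname pipeline
#' @export
cmdAll <- function(config) {
    cfg <- .asRunConfig(config)
    stages <- character()
    if (!is.null(cfg$simulate)) {
        cfg <- cmdSimulate(cfg)
        stages <- c(stages, "simulate")
    }
    cfg <- cmdExtractIars(cfg)
    cfg <- cmdProfile(cfg)
    cfg <- cmdCluster(cfg)
    cfg <- cmdSkew(cfg)
    stages <- c(stages, "extract_iars", "profile", "cluster", "skew")
    mf <- list(stage = "all", stages = stages,
               package = as.character(utils::packageVersion("txinit")),
               seed = cfg$seed)
    p <- file.path(cfg$outdir, "manifest_all.json")
    .atomically(p, function(tmp)
        jsonlite::write_json(mf, tmp, auto_unbox = TRUE, pretty = TRUE))
    invisible(cfg)
}
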