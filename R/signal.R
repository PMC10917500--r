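## Coverage-track access, normalization, and per-interval aggregation.

#' Load a coverage track
#'
#' Reads a bedGraph (or bigWig, where the rtracklayer build supports it) file
#' into a [CoverageTrack-class].  Bases not covered by any interval read as
#' zero; queries on chromosomes absent from the file return zero (with a
#' warning) or raise an error depending on downstream options.
#'
#' @param path signal file.
#' @param format `"bedgraph"` or `"bigwig"`; guessed from the extension when
#'   missing.
#' @param strand `"+"`, `"-"` or `"*"`.
#' @param label track name (defaults to the file name).
#' @param chromSizes optional named chromosome lengths; when absent the
#'   lengths are inferred as the maximum covered end per chromosome.
#' @param binSize counting-bin width behind the values (bp, default 1).
#' @return A [CoverageTrack-class].
#' @export
loadTrack <- function(path, format = c("bedgraph", "bigwig"), strand = "*",
                      label = basename(path), chromSizes = NULL,
                      binSize = 1) {
    if (missing(format)) {
        format <- if (grepl("\\.(bw|bigwig)$", path, ignore.case = TRUE))
            "bigwig" else "bedgraph"
    }
    format <- match.arg(format)
    gr <- rtracklayer::import(path, format = if (format == "bigwig") "BigWig"
                                             else "bedGraph")
    if (format == "bedgraph") {
        red <- reduce(gr, ignore.strand = TRUE)
        if (sum(width(red)) != sum(width(gr)))
            stop("overlapping bedGraph intervals in ", path)
    }
    if (is.null(chromSizes)) {
        chromSizes <- vapply(split(end(gr), as.character(seqnames(gr))),
                             max, numeric(1))
    }
    cov <- .grangesToRleList(gr, chromSizes)
    CoverageTrack(cov, strand = strand, label = label, binSize = binSize)
}

.grangesToRleList <- function(gr, chromSizes) {
    seqlevels(gr) <- names(chromSizes)
    seqlengths(gr) <- unname(chromSizes)
    coverage(gr, weight = gr$score)
}

#' Write a coverage track as bedGraph
#'
#' Zero-valued runs are omitted, the usual bedGraph convention.
#'
#' @param track A [CoverageTrack-class].
#' @param path output path.
#' @export
writeTrack <- function(track, path) {
    gr <- as(trackCoverage(track), "GRanges")
    gr <- gr[gr$score != 0]
    tab <- data.frame(chrom = as.character(seqnames(gr)),
                      start = start(gr) - 1L, end = end(gr),
                      score = format(gr$score, scientific = FALSE, trim = TRUE,
                                     digits = 12))
    write.table(tab, path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    invisible(path)
}

#' Add two coverage tracks
#'
#' Base-wise sum, used to combine plus- and minus-strand nascent tracks.
#'
#' @param a,b [CoverageTrack-class] objects on the same chromosomes.
#' @param label label of the combined track.
#' @return An unstranded [CoverageTrack-class].
#' @export
combineTracks <- function(a, b, label = paste(trackLabel(a), trackLabel(b),
                                              sep = "+")) {
    if (!identical(names(trackCoverage(a)), names(trackCoverage(b))))
        stop("tracks cover different chromosome sets")
    CoverageTrack(trackCoverage(a) + trackCoverage(b), strand = "*",
                  label = label, normalization = trackNormalization(a),
                  binSize = trackBinSize(a))
}

#' RPKM-normalize a raw track
#'
#' Scales binned counts to reads per kilobase per million mapped reads using
#' the bamCoverage convention
#' `value_rpkm = raw_bin_count * 1e9 / (bin_length_bp * total_reads)`.
#' Normalizing an already-normalized track is an error.
#'
#' @param track a raw [CoverageTrack-class].
#' @param totalReads total mapped reads in the library (> 0).
#' @return The normalized [CoverageTrack-class].
#' @export
rpkmNormalize <- function(track, totalReads) {
    if (trackNormalization(track) != "raw")
        stop("track '", trackLabel(track), "' is already normalized")
    if (totalReads <= 0) stop("totalReads must be > 0")
    fac <- 1e9 / (trackBinSize(track) * totalReads)
    CoverageTrack(trackCoverage(track) * fac, strand = trackStrand(track),
                  label = trackLabel(track), normalization = "rpkm",
                  binSize = trackBinSize(track))
}

#' Mean signal over regions (mean0 convention)
#'
#' One summary per region: the mean over all bases of the region, counting
#' uncovered bases as zero (the `bigWigAverageOverBed` "mean0" convention),
#' plus the number of bases with nonzero signal.
#'
#' @param track A [CoverageTrack-class].
#' @param regions `GRanges` within the genome; zero-width regions are an
#'   error.
#' @param unknownChrom `"zero"` (default; regions on chromosomes absent from
#'   the track score 0 with a warning) or `"error"`.
#' @return `data.frame` with columns `region`, `mean_signal`,
#'   `n_covered_bases`.
#' @export
aggregateOverRegions <- function(track, regions,
                                 unknownChrom = c("zero", "error")) {
    unknownChrom <- match.arg(unknownChrom)
    if (any(width(regions) == 0))
        stop("zero-width region(s)")
    cov <- trackCoverage(track)
    chrom <- as.character(seqnames(regions))
    known <- chrom %in% names(cov)
    if (!all(known)) {
        if (unknownChrom == "error")
            stop("unknown chromosome(s): ",
                 paste(unique(chrom[!known]), collapse = ", "))
        warning("chromosome(s) absent from track '", trackLabel(track),
                "' read as zero: ", paste(unique(chrom[!known]), collapse = ", "))
    }
    lens <- trackChromLengths(track)
    mean_signal <- numeric(length(regions))
    n_cov <- integer(length(regions))
    for (i in which(known)) {
        rle <- cov[[chrom[i]]]
        s <- max(start(regions)[i], 1L)
        e <- min(end(regions)[i], lens[[chrom[i]]])
        if (e < s) next
        v <- S4Vectors::window(rle, s, e)
        mean_signal[i] <- sum(v) / width(regions)[i]
        n_cov[i] <- sum(v != 0)
    }
    nm <- if (!is.null(names(regions))) names(regions)
          else paste0("region", seq_along(regions))
    data.frame(region = nm, mean_signal = mean_signal,
               n_covered_bases = n_cov, row.names = NULL)
}

#' Two-sided percentile trimming
#'
#' Removes the `floor(n * lowerFrac)` smallest and `floor(n * upperFrac)`
#' largest elements of a numeric vector, preserving the original order of the
#' survivors.  Used to keep high-signal artifacts in nascent-transcription
#' data from dominating metaprofile bins.
#'
#' @param values numeric vector.
#' @param lowerFrac,upperFrac trim fractions, `lowerFrac + upperFrac < 1`
#'   (defaults 0.10 each).
#' @return The surviving values in input order.
#' @export
trimExtremes <- function(values, lowerFrac = 0.10, upperFrac = 0.10) {
    if (lowerFrac < 0 || upperFrac < 0 || lowerFrac + upperFrac >= 1)
        stop("trim fractions must be >= 0 with lowerFrac + upperFrac < 1")
    n <- length(values)
    if (!n) return(values)
    nl <- floor(n * lowerFrac)
    nu <- floor(n * upperFrac)
    if (nl + nu == 0) return(values)
    o <- order(values)
    drop <- c(head(o, nl), tail(o, nu))
    values[-drop]
}
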