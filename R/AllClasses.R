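#' @import methods
#' @import BiocGenerics
#' @import S4Vectors
#' @import IRanges
#' @import GenomicRanges
#' @importFrom GenomeInfoDb seqlevels seqlevels<- seqlengths seqlengths<- seqinfo Seqinfo
#' @importFrom stats rpois rlnorm runif wilcox.test p.adjust rnbinom
#' @importFrom utils read.table write.table
NULL

## ---------------------------------------------------------------------------
## GenomeLayout
## ---------------------------------------------------------------------------

#' Gene annotation plus chromosome sizes
#'
#' A `GenomeLayout` bundles a collapsed gene annotation (one interval per
#' `gene_id`, as a [GenomicRanges::GRanges] with a `gene_id` metadata column)
#' with the chromosome lengths of the genome it lives on.  It is the reference
#' frame for intergenic accessible region (IAR) extraction and for all
#' anchored metaprofiles.
#'
#' @slot genes `GRanges` of gene bodies; `mcols(genes)$gene_id` holds unique
#'   identifiers and `strand()` is `+` or `-`.
#' @slot chromSizes named numeric vector of chromosome lengths in bp.
#'
#' @aliases GenomeLayout-class
#' @export
setClass("GenomeLayout",
         representation(genes = "GRanges", chromSizes = "numeric"))

setValidity("GenomeLayout", function(object) {
    msg <- character()
    cs <- object@chromSizes
    g <- object@genes
    if (length(cs) && anyDuplicated(names(cs)))
        msg <- c(msg, "chromosome names must be unique")
    if (length(g)) {
        if (is.null(g$gene_id))
            msg <- c(msg, "genes must carry a gene_id metadata column")
        else if (anyDuplicated(g$gene_id))
            msg <- c(msg, "gene_id values must be unique")
        if (!all(as.character(strand(g)) %in% c("+", "-")))
            msg <- c(msg, "gene strand must be '+' or '-'")
        bad <- !(as.character(seqnames(g)) %in% names(cs))
        if (any(bad))
            msg <- c(msg, "every gene must lie on a known chromosome")
        else {
            lens <- cs[as.character(seqnames(g))]
            if (any(start(g) < 1L) || any(end(g) > lens))
                msg <- c(msg, "every gene must lie within its chromosome bounds")
        }
    }
    if (length(msg)) msg else TRUE
})

#' Construct a GenomeLayout
#'
#' @param genes `GRanges` with a `gene_id` metadata column and `+`/`-` strand.
#' @param chromSizes named numeric vector of chromosome lengths; when `NULL`
#'   the lengths are inferred as the maximum gene end per chromosome.
#' @return A [GenomeLayout-class] object.
#' @examples
#' g <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1001, 2000),
#'                             strand = "+", gene_id = "g1")
#' GenomeLayout(g)
#' @export
GenomeLayout <- function(genes, chromSizes = NULL) {
    if (is.null(chromSizes)) {
        if (!length(genes))
            stop("chromSizes must be given when there are no genes")
        chromSizes <- vapply(split(end(genes), as.character(seqnames(genes))),
                             max, numeric(1))
    }
    chromSizes <- chromSizes[order(names(chromSizes))]
    genes <- sort(genes, ignore.strand = TRUE)
    new("GenomeLayout", genes = genes, chromSizes = chromSizes)
}

#' @describeIn GenomeLayout Gene bodies as a `GRanges`.
#' @param layout,object A `GenomeLayout`.
#' @export
layoutGenes <- function(layout) layout@genes

#' @describeIn GenomeLayout Named vector of chromosome lengths (bp).
#' @export
chromSizes <- function(layout) layout@chromSizes

setMethod("show", "GenomeLayout", function(object) {
    cat("GenomeLayout:", length(object@genes), "genes on",
        length(object@chromSizes), "chromosome(s),",
        sum(object@chromSizes), "bp total\n")
})

#' Transcription start sites of a layout
#'
#' Returns width-1 anchors at each gene's TSS (gene start for `+` genes,
#' gene end for `-` genes), carrying the gene strand and `gene_id`.
#'
#' @param layout A [GenomeLayout-class].
#' @return `GRanges` of width-1 TSS positions.
#' @export
tssPositions <- function(layout) {
    g <- layoutGenes(layout)
    pos <- ifelse(as.character(strand(g)) == "+", start(g), end(g))
    GRanges(seqnames(g), IRanges(pos, width = 1L), strand = strand(g),
            gene_id = g$gene_id)
}

#' Transcript end sites of a layout
#'
#' @param layout A [GenomeLayout-class].
#' @return `GRanges` of width-1 TES positions (terminus opposite the TSS).
#' @export
tesPositions <- function(layout) {
    g <- layoutGenes(layout)
    pos <- ifelse(as.character(strand(g)) == "+", end(g), start(g))
    GRanges(seqnames(g), IRanges(pos, width = 1L), strand = strand(g),
            gene_id = g$gene_id)
}

## ---------------------------------------------------------------------------
## CoverageTrack
## ---------------------------------------------------------------------------

#' Genome-wide numeric coverage signal
#'
#' A `CoverageTrack` holds per-base signal as an [IRanges::RleList] (one run-
#' length-encoded vector per chromosome, spanning the full chromosome), with
#' strand information, a label, the normalization state, and the bin size the
#' values were counted in (values are piecewise constant over bins when
#' `binSize > 1`, the convention of binned read-count tracks).
#'
#' @slot cov `RleList`, one full-length numeric Rle per chromosome.
#' @slot strand one of `"+"`, `"-"`, `"*"` (unstranded).
#' @slot label free-text track name.
#' @slot normalization `"raw"` or `"rpkm"`.
#' @slot binSize width in bp of the counting bins behind the per-base values.
#'
#' @aliases CoverageTrack-class
#' @export
setClass("CoverageTrack",
         representation(cov = "RleList", strand = "character",
                        label = "character", normalization = "character",
                        binSize = "numeric"))

setValidity("CoverageTrack", function(object) {
    msg <- character()
    if (!object@strand %in% c("+", "-", "*"))
        msg <- c(msg, "strand must be '+', '-' or '*'")
    if (!object@normalization %in% c("raw", "rpkm"))
        msg <- c(msg, "normalization must be 'raw' or 'rpkm'")
    if (object@binSize < 1)
        msg <- c(msg, "binSize must be >= 1")
    mins <- suppressWarnings(vapply(object@cov, function(x) min(min(x), Inf),
                                    numeric(1)))
    if (length(mins) && any(mins < 0))
        msg <- c(msg, "coverage values must be >= 0")
    if (length(msg)) msg else TRUE
})

#' Construct a CoverageTrack
#'
#' @param cov `RleList` of per-base values, or a named list coercible to one.
#' @param strand `"+"`, `"-"` or `"*"`.
#' @param label track name.
#' @param normalization `"raw"` (default) or `"rpkm"`.
#' @param binSize bp width of the counting bins the values come from.
#' @return A [CoverageTrack-class] object.
#' @export
CoverageTrack <- function(cov, strand = "*", label = "",
                          normalization = "raw", binSize = 1) {
    if (!is(cov, "RleList")) cov <- as(cov, "RleList")
    new("CoverageTrack", cov = cov, strand = strand, label = label,
        normalization = normalization, binSize = binSize)
}

#' @describeIn CoverageTrack The underlying `RleList` of per-base values.
#' @param track,object A `CoverageTrack`.
#' @export
trackCoverage <- function(track) track@cov

#' @describeIn CoverageTrack Track label.
#' @export
trackLabel <- function(track) track@label

#' @describeIn CoverageTrack Track strand flag.
#' @export
trackStrand <- function(track) track@strand

#' @describeIn CoverageTrack Normalization state (`"raw"` or `"rpkm"`).
#' @export
trackNormalization <- function(track) track@normalization

#' @describeIn CoverageTrack Counting bin size in bp.
#' @export
trackBinSize <- function(track) track@binSize

#' @describeIn CoverageTrack Named chromosome lengths covered by the track.
#' @export
trackChromLengths <- function(track) {
    len <- vapply(track@cov, length, numeric(1))
    names(len) <- names(track@cov)
    len
}

setMethod("show", "CoverageTrack", function(object) {
    cat(sprintf("CoverageTrack '%s' (strand %s, %s, bin %g bp): %d chromosome(s)\n",
                object@label, object@strand, object@normalization,
                object@binSize, length(object@cov)))
})

## ---------------------------------------------------------------------------
## ProfileMatrix
## ---------------------------------------------------------------------------

#' Regions-by-bins signal matrix
#'
#' A `ProfileMatrix` is the numeric backbone of a metaprofile or heatmap:
#' one row per region and one column per bin, together with the anchoring
#' geometry needed to interpret the columns.  Bins falling outside chromosome
#' bounds are `NA` and are excluded from summaries.  When `strandOriented` is
#' `TRUE`, rows of minus-strand regions have been mirrored so that column 1 is
#' biologically upstream.
#'
#' @slot mat numeric matrix (regions x bins), rownames are region identifiers.
#' @slot anchoring `"point"` (fixed-width window around an anchor base) or
#'   `"scaled"` (flank bins at fixed bp plus a gene body resampled to a fixed
#'   bin count).
#' @slot binSize bp per bin (point-anchored) or bp per flank bin (scaled).
#' @slot bodyBins number of body bins (0 for point-anchored matrices).
#' @slot upstreamBp,downstreamBp flank extents in bp.
#' @slot trackLabel label of the source track.
#' @slot strandOriented whether minus-strand rows were mirrored.
#'
#' @aliases ProfileMatrix-class
#' @export
setClass("ProfileMatrix",
         representation(mat = "matrix", anchoring = "character",
                        binSize = "numeric", bodyBins = "numeric",
                        upstreamBp = "numeric", downstreamBp = "numeric",
                        trackLabel = "character", strandOriented = "logical"))

setValidity("ProfileMatrix", function(object) {
    msg <- character()
    if (!object@anchoring %in% c("point", "scaled"))
        msg <- c(msg, "anchoring must be 'point' or 'scaled'")
    if (!is.numeric(object@mat))
        msg <- c(msg, "matrix must be numeric")
    if (length(msg)) msg else TRUE
})

ProfileMatrix <- function(mat, anchoring, binSize, upstreamBp, downstreamBp,
                          bodyBins = 0, trackLabel = "",
                          strandOriented = TRUE) {
    new("ProfileMatrix", mat = mat, anchoring = anchoring, binSize = binSize,
        bodyBins = bodyBins, upstreamBp = upstreamBp,
        downstreamBp = downstreamBp, trackLabel = trackLabel,
        strandOriented = strandOriented)
}

#' @describeIn ProfileMatrix The raw regions-by-bins matrix.
#' @param x,object A `ProfileMatrix`.
#' @export
profileMatrix <- function(x) x@mat

#' @describeIn ProfileMatrix Anchoring mode (`"point"` or `"scaled"`).
#' @export
profileAnchoring <- function(x) x@anchoring

#' @describeIn ProfileMatrix Label of the source track.
#' @export
profileTrackLabel <- function(x) x@trackLabel

setMethod("show", "ProfileMatrix", function(object) {
    cat(sprintf("ProfileMatrix '%s' (%s-anchored): %d regions x %d bins\n",
                object@trackLabel, object@anchoring,
                nrow(object@mat), ncol(object@mat)))
})

setMethod("dim", "ProfileMatrix", function(x) dim(x@mat))

## ---------------------------------------------------------------------------
## ClusterAssignment
## ---------------------------------------------------------------------------

#' k-means cluster membership
#'
#' Cluster labels for a set of regions, relabeled deterministically (clusters
#' ordered by descending size, ties broken by descending mean signal of a
#' designated feature block) so that labels are comparable across restarts.
#'
#' @slot labels named integer vector, one label in `1..k` per region.
#' @slot k number of clusters.
#' @slot seed RNG seed the assignment was produced under.
#' @slot totWithinSS total within-cluster sum of squares of the best restart.
#'
#' @aliases ClusterAssignment-class
#' @export
setClass("ClusterAssignment",
         representation(labels = "integer", k = "integer", seed = "integer",
                        totWithinSS = "numeric"))

setValidity("ClusterAssignment", function(object) {
    msg <- character()
    if (length(object@labels) &&
        (min(object@labels) < 1L || max(object@labels) > object@k))
        msg <- c(msg, "labels must lie in 1..k")
    if (length(msg)) msg else TRUE
})

#' @describeIn ClusterAssignment Named integer vector of cluster labels.
#' @param x,object A `ClusterAssignment`.
#' @export
clusterLabels <- function(x) x@labels

#' @describeIn ClusterAssignment Number of clusters.
#' @export
clusterK <- function(x) x@k

#' @describeIn ClusterAssignment Total within-cluster sum of squares.
#' @export
clusterWithinSS <- function(x) x@totWithinSS

setMethod("show", "ClusterAssignment", function(object) {
    cat(sprintf("ClusterAssignment: %d regions in %d clusters (WCSS %.4g, seed %d)\n",
                length(object@labels), object@k, object@totWithinSS,
                object@seed))
    print(table(object@labels))
})
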