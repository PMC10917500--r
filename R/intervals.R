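## Interval arithmetic and IAR extraction.

#' bedtools-style per-region subtraction
#'
#' Returns, for each region of `a`, the parts not covered by any region of
#' `b` (the semantics of `bedtools subtract`).  Names and metadata columns of
#' `a` are propagated to the surviving fragments.  Strand is ignored.
#'
#' @param a,b `GRanges`.
#' @return Sorted `GRanges` of fragments of `a`.
#' @export
intervalSubtract <- function(a, b) {
    if (!length(a)) return(a)
    if (!length(b)) return(sort(a, ignore.strand = TRUE))
    frags <- GenomicRanges::subtract(a, b, ignore.strand = TRUE)
    n <- S4Vectors::elementNROWS(frags)
    out <- unlist(frags, use.names = FALSE)
    mcols(out) <- mcols(a)[rep(seq_along(a), n), , drop = FALSE]
    if (!is.null(names(a))) names(out) <- rep(names(a), n)
    sort(out, ignore.strand = TRUE)
}

#' bedtools-style per-region intersection
#'
#' Returns the overlapping parts of each region of `a` with each region of
#' `b` (the semantics of `bedtools intersect`).  Strand is ignored.
#'
#' @param a,b `GRanges`.
#' @return Sorted `GRanges` of overlap pieces, carrying `a`'s metadata.
#' @export
intervalIntersect <- function(a, b) {
    if (!length(a) || !length(b)) return(a[0])
    b <- reduce(b, ignore.strand = TRUE)
    hits <- findOverlaps(a, b, ignore.strand = TRUE)
    if (!length(hits)) return(a[0])
    pieces <- pintersect(a[queryHits(hits)], b[subjectHits(hits)],
                         ignore.strand = TRUE)
    mcols(pieces) <- mcols(a)[queryHits(hits), , drop = FALSE]
    if (!is.null(names(a))) names(pieces) <- names(a)[queryHits(hits)]
    sort(pieces, ignore.strand = TRUE)
}

#' Extract gene-proximal intergenic accessible regions (IARs)
#'
#' Starting from accessible-chromatin intervals and a gene annotation,
#' removes any overlap with gene bodies (per-region subtraction), drops
#' fragments narrower than `minWidth`, and keeps fragments whose distance
#' from their closest edge to the nearest gene boundary (or TSS when
#' `anchor = "tss"`) lies within `[minDist, maxDist]`.  Each surviving IAR is
#' annotated with its midpoint, nearest gene, that gene's strand, the side it
#' lies on relative to the gene's orientation, and the distance.  Ties
#' (equidistant genes) resolve to the leftmost gene by coordinate, so the
#' result is independent of input ordering and each IAR is counted once.
#'
#' @param layout A [GenomeLayout-class]; must contain at least one gene.
#' @param accessible `GRanges` of accessible regions.
#' @param minDist,maxDist distance window in bp (defaults 100 and 2000).
#' @param minWidth minimum surviving fragment width in bp (default 50).
#' @param anchor measure distance to the nearest gene `"gene"` boundary
#'   (either end, default) or to the `"tss"` only.
#' @return Sorted `GRanges` with metadata columns `midpoint` (0-based
#'   coordinate, `floor((start0 + end0) / 2)`), `nearest_gene_id`,
#'   `nearest_gene_strand`, `relative_position`
#'   (`"upstream-of-gene"`/`"downstream-of-gene"`), and `distance_to_gene`.
#' @export
extractIars <- function(layout, accessible, minDist = 100, maxDist = 2000,
                        minWidth = 50, anchor = c("gene", "tss")) {
    anchor <- match.arg(anchor)
    genes <- layoutGenes(layout)
    if (!length(genes))
        stop("IARs are undefined without genes in the layout")
    frags <- intervalSubtract(accessible, genes)
    frags <- frags[width(frags) >= minWidth]
    if (!length(frags)) return(.emptyIars())
    targets <- if (anchor == "gene") genes else tssPositions(layout)
    ## nearest target on each side; an exact distance tie resolves to the
    ## left neighbor, i.e. the leftmost gene by coordinate
    idxL <- follow(frags, unstrand(targets), ignore.strand = TRUE)
    idxR <- precede(frags, unstrand(targets), ignore.strand = TRUE)
    distTo <- function(idx) {
        d <- rep(Inf, length(frags))
        ok <- !is.na(idx)
        d[ok] <- distance(frags[ok], targets[idx[ok]], ignore.strand = TRUE)
        d
    }
    dL <- distTo(idxL)
    dR <- distTo(idxR)
    useL <- dL <= dR
    dist <- pmin(dL, dR)
    sh <- ifelse(useL, idxL, idxR)
    sel <- is.finite(dist) & dist >= minDist & dist <= maxDist
    if (!any(sel)) return(.emptyIars())
    iars <- frags[sel]
    gsel <- targets[sh[sel]]
    dist <- dist[sel]
    start0 <- start(iars) - 1L
    end0 <- end(iars)
    isLeft <- end(iars) <= start(gsel)
    gplus <- as.character(strand(gsel)) == "+"
    relpos <- ifelse(isLeft == gplus, "upstream-of-gene", "downstream-of-gene")
    mcols(iars) <- S4Vectors::DataFrame(
        midpoint = as.integer(floor((start0 + end0) / 2)),
        nearest_gene_id = gsel$gene_id,
        nearest_gene_strand = as.character(strand(gsel)),
        relative_position = relpos,
        distance_to_gene = as.integer(dist))
    sort(iars, ignore.strand = TRUE)
}

.emptyIars <- function() {
    gr <- GRanges()
    mcols(gr) <- S4Vectors::DataFrame(midpoint = integer(),
                                      nearest_gene_id = character(),
                                      nearest_gene_strand = character(),
                                      relative_position = character(),
                                      distance_to_gene = integer())
    gr
}

#' Upstream/downstream flanks around IAR midpoints
#'
#' Builds the two fixed-width flank windows used by the skew statistic: in
#' 0-based coordinates, upstream `[midpoint - flank, midpoint)` and
#' downstream `[midpoint, midpoint + flank)`, both clipped at chromosome
#' bounds with the clipping recorded.
#'
#' @param iars `GRanges` from [extractIars()] (must carry a `midpoint`
#'   metadata column; it is recomputed when absent).
#' @param flank flank width in bp (> 0, default 2000).
#' @param chromSizes named chromosome lengths used for clipping; taken from
#'   `seqlengths(iars)` when `NULL`, and left unclipped at the right end if
#'   unavailable.
#' @return A list with `upstream` and `downstream` `GRanges` (parallel to
#'   `iars`, with logical metadata column `clipped`).
#' @export
flanksFromMidpoint <- function(iars, flank = 2000, chromSizes = NULL) {
    if (flank <= 0) stop("flank must be > 0")
    mid0 <- iars$midpoint
    if (is.null(mid0))
        mid0 <- as.integer(floor((start(iars) - 1L + end(iars)) / 2))
    chrom <- as.character(seqnames(iars))
    if (is.null(chromSizes)) {
        sl <- seqlengths(iars)
        chromSizes <- if (all(is.na(sl))) NULL else sl
    }
    lens <- if (is.null(chromSizes)) rep(Inf, length(iars))
            else unname(chromSizes[chrom])
    mk <- function(s0, e0) {
        cs <- pmax(s0, 0)
        ce <- pmin(e0, lens)
        if (any(ce <= cs))
            stop("flank window collapsed to zero width; midpoint at chromosome edge")
        gr <- GRanges(chrom, IRanges(cs + 1L, ce))
        gr$clipped <- (cs != s0) | (ce != e0)
        names(gr) <- names(iars)
        gr
    }
    list(upstream = mk(mid0 - flank, mid0),
         downstream = mk(mid0, mid0 + flank))
}
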