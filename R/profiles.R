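## Anchored and scaled-gene-body metaprofiles.

## Per-base values over a genomic window [gstart0, gstart0 + len) in 0-based
## coordinates: 0 where uncovered, NA outside chromosome bounds or on
## chromosomes absent from the track.
.windowValues <- function(track, chrom, gstart0, len) {
    v <- rep(NA_real_, len)
    cov <- trackCoverage(track)
    if (!chrom %in% names(cov)) return(v)
    clen <- length(cov[[chrom]])
    s0 <- max(gstart0, 0)
    e0 <- min(gstart0 + len, clen)
    if (e0 > s0)
        v[(s0 - gstart0 + 1):(e0 - gstart0)] <-
            as.numeric(window(cov[[chrom]], s0 + 1, e0))
    v
}

## Means of consecutive fixed-width bins; a bin with any NA base (outside the
## chromosome) becomes NA.
.fixedBinMeans <- function(v, binSize) {
    colMeans(matrix(v, nrow = binSize))
}

## Means of nbins equal-length sub-intervals of v with fractional-base
## weighting at bin edges (treating base i as the unit interval [i-1, i)).
.fracBinMeans <- function(v, nbins) {
    L <- length(v)
    S <- c(0, cumsum(v))
    edges <- seq(0, L, length.out = nbins + 1)
    integ <- function(t) {
        i <- floor(t)
        if (i >= L) return(S[L + 1])
        S[i + 1] + (t - i) * v[i + 1]
    }
    vals <- numeric(nbins)
    for (j in seq_len(nbins))
        vals[j] <- (integ(edges[j + 1]) - integ(edges[j])) /
            (edges[j + 1] - edges[j])
    vals
}

#' Point-anchored signal matrix
#'
#' Builds a regions-by-bins matrix of mean signal in fixed-width bins across
#' `[pos - upstreamBp, pos + downstreamBp)` around each anchor base.  Rows of
#' minus-strand anchors are mirrored (when `strandOriented`) so that column 1
#' is biologically upstream; bins reaching outside the chromosome are `NA`.
#'
#' @param track A [CoverageTrack-class].
#' @param anchors width-1 `GRanges` of anchor positions (e.g. TSSs or IAR
#'   midpoints); strand `*` is treated as `+`.
#' @param upstreamBp,downstreamBp flank extents in bp (defaults 2000).
#' @param binSize bin width in bp (default 50); must divide both extents.
#' @param strandOriented mirror minus-strand rows (default `TRUE`).
#' @return A [ProfileMatrix-class]; rownames are anchor names (or the
#'   `gene_id` column, or `region<i>`).
#' @export
pointAnchoredMatrix <- function(track, anchors, upstreamBp = 2000,
                                downstreamBp = 2000, binSize = 50,
                                strandOriented = TRUE) {
    if (upstreamBp %% binSize != 0 || downstreamBp %% binSize != 0)
        stop("binSize must divide both flank extents")
    nbins <- (upstreamBp + downstreamBp) / binSize
    len <- upstreamBp + downstreamBp
    pos0 <- start(anchors) - 1L
    chrom <- as.character(seqnames(anchors))
    minus <- strandOriented & as.character(strand(anchors)) == "-"
    mat <- matrix(NA_real_, nrow = length(anchors), ncol = nbins)
    for (r in seq_along(anchors)) {
        ## minus-strand rows read the reversed window [pos - down, pos + up)
        gstart0 <- if (minus[r]) pos0[r] - downstreamBp
                   else pos0[r] - upstreamBp
        v <- .windowValues(track, chrom[r], gstart0, len)
        if (minus[r]) v <- rev(v)
        mat[r, ] <- .fixedBinMeans(v, binSize)
    }
    rownames(mat) <- .anchorNames(anchors)
    ProfileMatrix(mat, anchoring = "point", binSize = binSize,
                  upstreamBp = upstreamBp, downstreamBp = downstreamBp,
                  trackLabel = trackLabel(track),
                  strandOriented = strandOriented)
}

.anchorNames <- function(gr) {
    if (!is.null(names(gr)) && length(gr)) names(gr)
    else if (!is.null(gr$gene_id)) as.character(gr$gene_id)
    else paste0("region", seq_along(gr))
}

#' Scaled-gene-body signal matrix
#'
#' Builds a matrix over TSS - `flankBp` ... TES + `flankBp` in which the two
#' flanks are binned at `flankBin` bp and the gene body is resampled to
#' exactly `bodyBins` bins by averaging over equal-length sub-intervals with
#' fractional-base weighting at bin edges (so genes shorter than `bodyBins`
#' bases still work).  Minus-strand genes are orientation-flipped.
#'
#' @param track A [CoverageTrack-class].
#' @param layout A [GenomeLayout-class] (or a `GRanges` of genes with
#'   `gene_id` and `+`/`-` strand).
#' @param flankBp flank extent in bp (default 2000).
#' @param bodyBins number of body bins (default 100).
#' @param flankBin flank bin width in bp (default 50); must divide `flankBp`.
#' @return A [ProfileMatrix-class] with `bodyBins` body bins between two
#'   `flankBp/flankBin` flank blocks.
#' @export
scaledBodyMatrix <- function(track, layout, flankBp = 2000, bodyBins = 100,
                             flankBin = 50) {
    genes <- if (is(layout, "GenomeLayout")) layoutGenes(layout) else layout
    if (any(width(genes) < 1)) stop("gene length must be >= 1")
    if (flankBp %% flankBin != 0) stop("flankBin must divide flankBp")
    nf <- flankBp / flankBin
    nbins <- 2 * nf + bodyBins
    chrom <- as.character(seqnames(genes))
    minus <- as.character(strand(genes)) == "-"
    mat <- matrix(NA_real_, nrow = length(genes), ncol = nbins)
    for (r in seq_along(genes)) {
        s0 <- start(genes)[r] - 1L
        e0 <- end(genes)[r]
        up <- .windowValues(track, chrom[r],
                            if (minus[r]) e0 else s0 - flankBp, flankBp)
        body <- .windowValues(track, chrom[r], s0, e0 - s0)
        down <- .windowValues(track, chrom[r],
                              if (minus[r]) s0 - flankBp else e0, flankBp)
        if (minus[r]) { up <- rev(up); body <- rev(body); down <- rev(down) }
        mat[r, ] <- c(.fixedBinMeans(up, flankBin),
                      .fracBinMeans(body, bodyBins),
                      .fixedBinMeans(down, flankBin))
    }
    rownames(mat) <- .anchorNames(genes)
    ProfileMatrix(mat, anchoring = "scaled", binSize = flankBin,
                  upstreamBp = flankBp, downstreamBp = flankBp,
                  bodyBins = bodyBins, trackLabel = trackLabel(track),
                  strandOriented = TRUE)
}

#' Summarize a profile matrix into a metaprofile curve
#'
#' Per-bin mean with standard error and normal-approximation 95% confidence
#' band (`mean +/- 1.96 * SE`; region counts in real uses are far above 30).
#' `NA` bins are excluded per column.  An optional two-sided percentile trim
#' (see [trimExtremes()]) is applied per bin before averaging, the treatment
#' given to nascent-transcription tracks so single high-signal loci do not
#' dominate a bin.  With `zscore = TRUE` the final mean/CI curves are jointly
#' shifted and scaled by the mean and standard deviation of the per-bin means
#' (SE is scaled only), so the reported mean curve has mean 0 and sd 1 across
#' bins.
#'
#' @param pm A [ProfileMatrix-class].
#' @param zscore z-score-normalize the summary curves (default `TRUE`).
#' @param trim length-2 numeric `(lower, upper)` per-bin trim fractions
#'   (default `c(0, 0)`, no trimming).
#' @return `data.frame` with columns `bin`, `position` (bp offset of the bin
#'   center from the anchor; body-bin index for scaled matrices), `mean`,
#'   `se`, `ci95_low`, `ci95_high`, `n_regions`.  With a single region SE and
#'   the CI are `NA`.
#' @export
summarizeProfile <- function(pm, zscore = TRUE, trim = c(0, 0)) {
    mat <- profileMatrix(pm)
    if (!nrow(mat)) stop("empty profile matrix")
    nbins <- ncol(mat)
    mean_ <- se <- rep(NA_real_, nbins)
    n <- integer(nbins)
    for (j in seq_len(nbins)) {
        v <- mat[, j]
        v <- v[!is.na(v)]
        if (any(trim > 0)) v <- trimExtremes(v, trim[1], trim[2])
        n[j] <- length(v)
        if (!length(v)) next
        mean_[j] <- mean(v)
        if (length(v) > 1) se[j] <- sd(v) / sqrt(length(v))
    }
    lo <- mean_ - 1.96 * se
    hi <- mean_ + 1.96 * se
    if (zscore) {
        mu <- mean(mean_, na.rm = TRUE)
        s <- sd(mean_, na.rm = TRUE)
        if (!is.na(s) && s > 0) {
            mean_ <- (mean_ - mu) / s
            lo <- (lo - mu) / s
            hi <- (hi - mu) / s
            se <- se / s
        }
    }
    data.frame(bin = seq_len(nbins), position = .binPositions(pm),
               mean = mean_, se = se, ci95_low = lo, ci95_high = hi,
               n_regions = n)
}

.binPositions <- function(pm) {
    if (pm@anchoring == "point") {
        nbins <- ncol(pm@mat)
        -pm@upstreamBp + (seq_len(nbins) - 0.5) * pm@binSize
    } else {
        nf <- pm@upstreamBp / pm@binSize
        c(-pm@upstreamBp + (seq_len(nf) - 0.5) * pm@binSize,
          seq_len(pm@bodyBins) - 0.5,
          (seq_len(nf) - 0.5) * pm@binSize)
    }
}

#' Write / read a ProfileMatrix as TSV plus JSON sidecar
#'
#' The matrix is stored as a TSV (rownames in the first column) and the
#' anchoring metadata in `<path>.json`.
#'
#' @param pm A [ProfileMatrix-class].
#' @param path TSV path.
#' @return `writeProfileMatrix`: `path`, invisibly.  `readProfileMatrix`:
#'   the reconstructed [ProfileMatrix-class].
#' @export
writeProfileMatrix <- function(pm, path) {
    mat <- profileMatrix(pm)
    tab <- data.frame(region = rownames(mat), mat, check.names = FALSE)
    colnames(tab) <- c("region", paste0("bin", seq_len(ncol(mat))))
    write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
    meta <- list(anchoring = pm@anchoring, binSize = pm@binSize,
                 bodyBins = pm@bodyBins, upstreamBp = pm@upstreamBp,
                 downstreamBp = pm@downstreamBp, trackLabel = pm@trackLabel,
                 strandOriented = pm@strandOriented)
    jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
    invisible(path)
}

#' @rdname writeProfileMatrix
#' @export
readProfileMatrix <- function(path) {
    tab <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE)
    mat <- as.matrix(tab[, -1, drop = FALSE])
    rownames(mat) <- tab[[1]]
    colnames(mat) <- NULL
    meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
    ProfileMatrix(mat, anchoring = meta$anchoring, binSize = meta$binSize,
                  upstreamBp = meta$upstreamBp,
                  downstreamBp = meta$downstreamBp, bodyBins = meta$bodyBins,
                  trackLabel = meta$trackLabel,
                  strandOriented = meta$strandOriented)
}
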