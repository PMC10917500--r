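## k-means partitioning of multi-track IAR signal matrices.

#' Concatenate profile matrices into a clustering feature matrix
#'
#' Each matrix is transformed by `log2(x + 1)` (the display transform of the
#' heatmaps; the `+1` offset keeps zeros finite) and the matrices are
#' concatenated horizontally.  Missing bins (outside chromosome bounds) are
#' imputed as 0.  With `orient = "dominant"` every row is flipped, in every
#' matrix consistently, so that the stronger half of the reference track lies
#' on the downstream side -- the standard way to pool the two mirror-image
#' orientations of unidirectionally transcribed elements before clustering.
#'
#' @param matrices list of [ProfileMatrix-class] objects sharing region order.
#' @param standardizeTracks scale each matrix block to unit overall standard
#'   deviation before concatenation (default `FALSE`, mirroring clustering of
#'   displayed log-transformed heatmap signal).
#' @param orient `"none"` (default) or `"dominant"`.
#' @param referenceTrack index of the matrix used to decide row orientation.
#' @param referenceMatrix optional numeric matrix overriding
#'   `referenceTrack` as the orientation reference (e.g. the sum of the two
#'   strand-specific nascent matrices).
#' @param strandPairs list of length-2 index vectors naming (plus, minus)
#'   strand-specific matrix pairs; when a row is mirrored its values are also
#'   swapped between the paired matrices, since the mirror image of a genomic
#'   window reads the opposite strand.
#' @return Numeric feature matrix (regions x total bins) with an attribute
#'   `flipped` (logical per row) when `orient = "dominant"`.
#' @export
buildFeatureMatrix <- function(matrices, standardizeTracks = FALSE,
                               orient = c("none", "dominant"),
                               referenceTrack = 1, referenceMatrix = NULL,
                               strandPairs = list()) {
    orient <- match.arg(orient)
    if (!length(matrices)) stop("no matrices given")
    mats <- lapply(matrices, profileMatrix)
    rn <- rownames(mats[[1]])
    for (m in mats) {
        if (nrow(m) != nrow(mats[[1]]) || !identical(rownames(m), rn))
            stop("matrices do not share region order")
    }
    flipped <- rep(FALSE, nrow(mats[[1]]))
    if (orient == "dominant") {
        ref <- if (is.null(referenceMatrix)) mats[[referenceTrack]]
               else referenceMatrix
        ref[is.na(ref)] <- 0
        half <- floor(ncol(ref) / 2)
        left <- rowSums(ref[, seq_len(half), drop = FALSE])
        right <- rowSums(ref[, (ncol(ref) - half + 1):ncol(ref), drop = FALSE])
        flipped <- left > right
        mirror <- function(m) {
            m[flipped, ] <- m[flipped, ncol(m):1, drop = FALSE]
            m
        }
        paired <- unlist(strandPairs)
        for (pr in strandPairs) {
            p <- mirror(mats[[pr[1]]])
            m <- mirror(mats[[pr[2]]])
            mats[[pr[1]]][] <- p
            mats[[pr[2]]][] <- m
            mats[[pr[1]]][flipped, ] <- m[flipped, , drop = FALSE]
            mats[[pr[2]]][flipped, ] <- p[flipped, , drop = FALSE]
        }
        for (i in setdiff(seq_along(mats), paired))
            mats[[i]] <- mirror(mats[[i]])
    }
    blocks <- lapply(mats, function(m) {
        m[is.na(m)] <- 0
        m <- log2(m + 1)
        if (standardizeTracks) {
            s <- sd(as.vector(m))
            if (s > 0) m <- m / s
        }
        m
    })
    feats <- do.call(cbind, blocks)
    rownames(feats) <- rn
    colnames(feats) <- NULL
    attr(feats, "flipped") <- flipped
    feats
}

## k-means++ seeding: first center uniform, then each next center sampled
## with probability proportional to squared distance to the nearest chosen
## center.
.kmeansPlusPlusInit <- function(x, k) {
    n <- nrow(x)
    centers <- matrix(0, k, ncol(x))
    idx <- sample.int(n, 1)
    centers[1, ] <- x[idx, ]
    if (k > 1) {
        d2 <- rowSums(sweep(x, 2, centers[1, ])^2)
        for (j in 2:k) {
            if (all(d2 == 0)) idx <- sample.int(n, 1)
            else idx <- sample.int(n, 1, prob = d2)
            centers[j, ] <- x[idx, ]
            d2 <- pmin(d2, rowSums(sweep(x, 2, centers[j, ])^2))
        }
    }
    centers
}

.assignToCenters <- function(x, centers) {
    ## squared distances to each center; ties -> lowest center index
    d <- outer(rowSums(x^2), rep(1, nrow(centers))) -
        2 * x %*% t(centers) +
        outer(rep(1, nrow(x)), rowSums(centers^2))
    max.col(-d, ties.method = "first")
}

.lloyd <- function(x, centers, maxIter) {
    prevWcss <- Inf
    assign <- .assignToCenters(x, centers)
    for (it in seq_len(maxIter)) {
        for (j in seq_len(nrow(centers))) {
            rows <- which(assign == j)
            if (!length(rows)) {
                ## empty cluster: seize the point farthest from its center
                d2 <- rowSums((x - centers[assign, , drop = FALSE])^2)
                rows <- which.max(d2)
                assign[rows] <- j
            }
            centers[j, ] <- colMeans(x[rows, , drop = FALSE])
        }
        newAssign <- .assignToCenters(x, centers)
        wcss <- sum((x - centers[newAssign, , drop = FALSE])^2)
        stopifnot(wcss <= prevWcss + 1e-8)  # Lloyd monotonicity
        if (identical(newAssign, assign) && it > 1) break
        assign <- newAssign
        prevWcss <- wcss
    }
    wcss <- sum((x - centers[assign, , drop = FALSE])^2)
    list(assign = assign, centers = centers, wcss = wcss)
}

#' k-means clustering with deterministic relabeling
#'
#' Lloyd's algorithm with k-means++ initialization, keeping the best of
#' `nInit` restarts by total within-cluster sum of squares.  Fully
#' deterministic for a fixed `seed`.  Clusters are relabeled `1..k` by
#' descending size, ties broken by descending mean feature signal over
#' `orderColumns`, so labels are comparable across seeds and row orders
#' (the display order of published heatmap clusters is not itself
#' reproducible).
#'
#' @param features numeric matrix (regions x features), e.g. from
#'   [buildFeatureMatrix()]; `nrow >= k` required.
#' @param k number of clusters (default 5).
#' @param seed mandatory integer RNG seed.
#' @param nInit number of restarts (default 10).
#' @param maxIter Lloyd iteration cap per restart (default 100).
#' @param orderColumns feature columns used for the relabeling tie-break
#'   (default: all columns).
#' @return A [ClusterAssignment-class].
#' @export
kmeansCluster <- function(features, k = 5, seed, nInit = 10, maxIter = 100,
                          orderColumns = seq_len(ncol(features))) {
    if (missing(seed)) stop("seed is mandatory")
    features <- as.matrix(features)
    n <- nrow(features)
    if (n < k) stop("fewer rows (", n, ") than clusters (", k, ")")
    set.seed(as.integer(seed))
    best <- NULL
    for (i in seq_len(nInit)) {
        fit <- .lloyd(features, .kmeansPlusPlusInit(features, k), maxIter)
        if (is.null(best) || fit$wcss < best$wcss) best <- fit
    }
    ## deterministic relabeling: descending size, then descending mean signal
    sizes <- tabulate(best$assign, nbins = k)
    meansig <- vapply(seq_len(k), function(j) {
        rows <- which(best$assign == j)
        if (!length(rows)) return(-Inf)
        mean(features[rows, orderColumns, drop = FALSE])
    }, numeric(1))
    ord <- order(-sizes, -meansig)
    relabel <- integer(k)
    relabel[ord] <- seq_len(k)
    labels <- as.integer(relabel[best$assign])
    names(labels) <- rownames(features)
    new("ClusterAssignment", labels = labels, k = as.integer(k),
        seed = as.integer(seed), totWithinSS = best$wcss)
}

#' Trim a point-anchored matrix to a narrower window
#'
#' Drops outer bins so the matrix covers `[-upstreamBp, +downstreamBp)`
#' around the anchor.  Used to cluster on element-proximal signal while
#' displaying wider windows.
#'
#' @param pm a point-anchored [ProfileMatrix-class].
#' @param upstreamBp,downstreamBp the narrower extents (multiples of the bin
#'   size, at most the original extents).
#' @return The trimmed [ProfileMatrix-class].
#' @export
trimProfileWindow <- function(pm, upstreamBp, downstreamBp = upstreamBp) {
    if (pm@anchoring != "point") stop("only point-anchored matrices can be trimmed")
    if (upstreamBp > pm@upstreamBp || downstreamBp > pm@downstreamBp)
        stop("trim window exceeds the matrix extents")
    if (upstreamBp %% pm@binSize != 0 || downstreamBp %% pm@binSize != 0)
        stop("trim extents must be multiples of the bin size")
    nUp <- pm@upstreamBp / pm@binSize
    keep <- seq.int(nUp - upstreamBp / pm@binSize + 1,
                    nUp + downstreamBp / pm@binSize)
    ProfileMatrix(pm@mat[, keep, drop = FALSE], anchoring = "point",
                  binSize = pm@binSize, upstreamBp = upstreamBp,
                  downstreamBp = downstreamBp, trackLabel = pm@trackLabel,
                  strandOriented = pm@strandOriented)
}

#' Mask annotated-gene bins in a point-anchored matrix
#'
#' Sets to `NA` every bin that overlaps an annotated gene body (optionally
#' extended upstream by `promoterPad` bp to cover the promoter NDR), so that
#' clustering of intergenic accessible regions reflects the elements' own
#' intergenic signal rather than proximity to neighboring genes.
#'
#' @param pm a point-anchored, unoriented [ProfileMatrix-class].
#' @param anchors the width-1 `GRanges` of anchor positions the matrix was
#'   built from (same order).
#' @param layout a [GenomeLayout-class] (or `GRanges` of genes).
#' @param promoterPad bp added upstream of each TSS (default 400).
#' @return The masked [ProfileMatrix-class].
#' @export
maskAnnotatedBins <- function(pm, anchors, layout, promoterPad = 400) {
    genes <- if (is(layout, "GenomeLayout")) layoutGenes(layout) else layout
    ext <- punion(genes, promoters(genes, upstream = promoterPad,
                                   downstream = 0), fill.gap = TRUE)
    mat <- profileMatrix(pm)
    nbins <- ncol(mat)
    pos0 <- start(anchors) - 1L
    chrom <- as.character(seqnames(anchors))
    for (r in seq_len(nrow(mat))) {
        binStarts <- pos0[r] - pm@upstreamBp + (seq_len(nbins) - 1L) * pm@binSize
        bingr <- GRanges(chrom[r], IRanges(binStarts + 1L, width = pm@binSize))
        mat[r, overlapsAny(bingr, ext, ignore.strand = TRUE)] <- NA
    }
    ProfileMatrix(mat, anchoring = pm@anchoring, binSize = pm@binSize,
                  upstreamBp = pm@upstreamBp, downstreamBp = pm@downstreamBp,
                  bodyBins = pm@bodyBins, trackLabel = pm@trackLabel,
                  strandOriented = pm@strandOriented)
}

#' Per-cluster summary table
#'
#' @param assignment A [ClusterAssignment-class].
#' @param features the feature matrix that was clustered.
#' @return `data.frame` with cluster, size and mean feature signal.
#' @export
clusterSummary <- function(assignment, features) {
    labels <- clusterLabels(assignment)
    do.call(rbind, lapply(seq_len(clusterK(assignment)), function(j) {
        rows <- which(labels == j)
        data.frame(cluster = j, n_regions = length(rows),
                   mean_signal = if (length(rows))
                       mean(features[rows, , drop = FALSE]) else NA_real_)
    }))
}
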