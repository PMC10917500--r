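## Independent brute-force oracles and small fixture builders shared across
## the suite.  Oracles use only base R (plain vectors), never the code paths
## they check.

suppressPackageStartupMessages({
    library(GenomicRanges)
    library(IRanges)
})

## --- fixture builders ------------------------------------------------------

## CoverageTrack from plain numeric per-base vectors (one per chromosome)
makeTrack <- function(..., strand = "*", label = "test", binSize = 1) {
    vecs <- list(...)
    cov <- as(lapply(vecs, S4Vectors::Rle), "RleList")
    CoverageTrack(cov, strand = strand, label = label, binSize = binSize)
}

## GRanges from 0-based half-open coordinate pairs on one chromosome
gr0 <- function(starts0, ends0, chrom = "chr1", strand = "*", names = NULL) {
    gr <- GRanges(chrom, IRanges(starts0 + 1L, ends0), strand = strand)
    if (!is.null(names)) names(gr) <- names
    gr
}

## random non-degenerate region set on a small genome
randomRegions <- function(n, genomeLen, maxWidth = 400) {
    s <- sample.int(genomeLen - 1L, n, replace = TRUE) - 1L
    w <- sample.int(maxWidth, n, replace = TRUE)
    gr0(s, pmin(s + w, genomeLen))
}

## the three-gene toy layout used for IAR filter checks
toyLayout <- function() {
    genes <- c(gr0(5000, 8000, strand = "+"),
               gr0(12000, 14000, strand = "-"),
               gr0(17000, 18500, strand = "+"))
    genes$gene_id <- c("gA", "gB", "gC")
    GenomeLayout(genes, c(chr1 = 20000))
}

toyAccessible <- function() {
    gr0(starts0 = c(6000, 4920, 3500, 100, 4950, 8500, 10500, 15450),
        ends0   = c(6200, 4970, 3700, 300, 5050, 8800, 10700, 15550),
        names = c("r_inside", "r_close", "r_up", "r_far", "r_edge",
                  "r_down", "r_between", "r_tie"))
}

## --- per-base bitmap oracles for interval arithmetic -----------------------

bitmapOf <- function(gr, genomeLen) {
    bm <- logical(genomeLen)
    for (i in seq_along(gr)) {
        s <- start(gr)[i]; e <- end(gr)[i]
        if (e >= s) bm[s:e] <- TRUE
    }
    bm
}

## base positions (1-based) covered by a per-region bedtools-style subtract
subtractBitmapOracle <- function(a, b, genomeLen) {
    bmB <- bitmapOf(b, genomeLen)
    out <- logical(genomeLen)
    for (i in seq_along(a)) {
        idx <- start(a)[i]:end(a)[i]
        out[idx] <- out[idx] | !bmB[idx]
    }
    which(out)
}

intersectBitmapOracle <- function(a, b, genomeLen) {
    which(bitmapOf(a, genomeLen) & bitmapOf(b, genomeLen))
}

coveredBases <- function(gr) {
    if (!length(gr)) return(integer(0))
    sort(unique(unlist(lapply(seq_along(gr), function(i)
        start(gr)[i]:end(gr)[i]))))
}

## --- per-base profile oracle -----------------------------------------------

## mean per fixed bin over [pos0 - up, pos0 + down) from a raw numeric
## per-base vector (NA outside), mirrored for minus-strand anchors
profileRowOracle <- function(values, pos0, up, down, binSize,
                             minus = FALSE) {
    len <- up + down
    gstart0 <- if (minus) pos0 - down else pos0 - up
    idx0 <- gstart0 + seq_len(len) - 1L
    v <- rep(NA_real_, len)
    ok <- idx0 >= 0 & idx0 < length(values)
    v[ok] <- values[idx0[ok] + 1L]
    if (minus) v <- rev(v)
    vapply(seq_len(len / binSize), function(j)
        mean(v[((j - 1) * binSize + 1):(j * binSize)]), numeric(1))
}

## fractional-weight body-bin oracle at fine resolution
scaledBodyOracle <- function(values, nbins, res = 1000L) {
    ## upsample each base into `res` equal slices and average slices per bin
    fine <- rep(values, each = res)
    edges <- round(seq(0, length(fine), length.out = nbins + 1))
    vapply(seq_len(nbins), function(j)
        mean(fine[(edges[j] + 1):edges[j + 1]]), numeric(1))
}

## --- Wilcoxon enumeration oracle -------------------------------------------

## two-sided rank-sum p by enumerating all C(n1+n2, n1) rank splits
wilcoxEnumOracle <- function(x, y) {
    n1 <- length(x); n2 <- length(y)
    pooled <- c(x, y)
    r <- rank(pooled)
    uOf <- function(id1) sum(r[id1]) - n1 * (n1 + 1) / 2
    uObs <- uOf(seq_len(n1))
    splits <- utils::combn(n1 + n2, n1)
    uDist <- apply(splits, 2, uOf)
    pl <- mean(uDist <= uObs + 1e-9)
    pu <- mean(uDist >= uObs - 1e-9)
    min(1, 2 * min(pl, pu))
}

## --- misc oracles -----------------------------------------------------------

trimOracle <- function(values, l, u) {
    n <- length(values)
    srt <- sort(values)
    keepSet <- srt[seq.int(floor(n * l) + 1, n - floor(n * u))]
    keepSet
}

## exhaustive best-WCSS 2-partition of a small matrix
bestTwoPartitionWcss <- function(x) {
    n <- nrow(x)
    best <- Inf
    for (code in 1:(2^(n - 1) - 1)) {
        g <- as.integer(intToBits(code))[1:n]
        w <- 0
        for (lab in 0:1) {
            rows <- which(g == lab)
            if (!length(rows)) { w <- Inf; break }
            c0 <- colMeans(x[rows, , drop = FALSE])
            w <- w + sum(sweep(x[rows, , drop = FALSE], 2, c0)^2)
        }
        if (w < best) best <- w
    }
    best
}

## simple adjusted Rand index (used where mclust is not loaded)
ariOracle <- function(a, b) {
    tab <- table(a, b)
    n <- sum(tab)
    sumij <- sum(choose(tab, 2))
    sumi <- sum(choose(rowSums(tab), 2))
    sumj <- sum(choose(colSums(tab), 2))
    expected <- sumi * sumj / choose(n, 2)
    maxidx <- (sumi + sumj) / 2
    (sumij - expected) / (maxidx - expected)
}
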