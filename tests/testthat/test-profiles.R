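test_that("a delta signal lands in the first downstream bin, mirrored on minus", {
    v <- rep(0, 4000); v[2001] <- 50  # delta at 0-based position 2000
    tr <- makeTrack(chr1 = v)
    anchors <- GRanges("chr1", IRanges(2001, width = 1), strand = c("+", "-"))
    pm <- pointAnchoredMatrix(tr, anchors, upstreamBp = 1000,
                              downstreamBp = 1000, binSize = 50)
    mat <- profileMatrix(pm)
    nUp <- 1000 / 50
    expect_equal(which(mat[1, ] != 0), nUp + 1)          # + anchor
    expect_equal(which(mat[2, ] != 0), ncol(mat) - nUp)  # - anchor, mirrored
})

test_that("point-anchored rows equal the per-base oracle, NA out of bounds", {
    set.seed(31)
    v <- rpois(5000, 2)
    tr <- makeTrack(chr1 = v)
    pos0 <- c(40, 2500, 4990)   # near start, interior, near end
    strandv <- c("+", "-", "+")
    anchors <- GRanges("chr1", IRanges(pos0 + 1L, width = 1), strand = strandv)
    pm <- pointAnchoredMatrix(tr, anchors, upstreamBp = 400,
                              downstreamBp = 600, binSize = 20)
    for (r in seq_along(pos0)) {
        expect_equal(profileMatrix(pm)[r, ],
                     profileRowOracle(v, pos0[r], 400, 600, 20,
                                      minus = strandv[r] == "-"),
                     tolerance = 1e-9)
    }
    expect_true(anyNA(profileMatrix(pm)[1, ]))
})

test_that("scaled-body bins are exact on constants and on exact divisions", {
    v <- rep(0, 10000); v[3001:5000] <- 2   # gene [3000, 5000), constant 2
    tr <- makeTrack(chr1 = v)
    g <- gr0(3000, 5000, strand = "+"); g$gene_id <- "g1"
    lay <- GenomeLayout(g, c(chr1 = 10000))
    pm <- scaledBodyMatrix(tr, lay, flankBp = 1000, bodyBins = 40,
                           flankBin = 50)
    nf <- 1000 / 50
    body <- profileMatrix(pm)[1, (nf + 1):(nf + 40)]
    expect_equal(body, rep(2, 40), tolerance = 1e-12)

    ## gene length an exact multiple of the bin count: equals naive binning
    set.seed(5)
    w <- rpois(2000, 3)
    v2 <- rep(0, 6000); v2[1001:3000] <- w
    tr2 <- makeTrack(chr1 = v2)
    g2 <- gr0(1000, 3000, strand = "+"); g2$gene_id <- "g2"
    pm2 <- scaledBodyMatrix(tr2, GenomeLayout(g2, c(chr1 = 6000)),
                            flankBp = 1000, bodyBins = 100, flankBin = 50)
    naive <- colMeans(matrix(w, nrow = 20))
    expect_equal(profileMatrix(pm2)[1, 21:120], naive, tolerance = 1e-9)
})

test_that("fractional body binning matches a high-resolution oracle", {
    set.seed(77)
    for (len in c(37, 101, 250)) {   # incl. genes shorter than the bin count
        w <- rpois(len, 4)
        v <- rep(0, 3000); v[501:(500 + len)] <- w
        tr <- makeTrack(chr1 = v)
        g <- gr0(500, 500 + len, strand = "+"); g$gene_id <- "g"
        pm <- scaledBodyMatrix(tr, GenomeLayout(g, c(chr1 = 3000)),
                               flankBp = 500, bodyBins = 100, flankBin = 50)
        body <- profileMatrix(pm)[1, 11:110]
        expect_equal(body, scaledBodyOracle(w, 100), tolerance = 1e-6)
    }
})

test_that("minus-strand genes are orientation-flipped in scaled profiles", {
    v <- rep(0, 8000)
    v[2001:4000] <- seq(1, 3, length.out = 2000)  # rising left to right
    tr <- makeTrack(chr1 = v)
    gPlus <- gr0(2000, 4000, strand = "+"); gPlus$gene_id <- "p"
    gMinus <- gr0(2000, 4000, strand = "-"); gMinus$gene_id <- "m"
    lay <- GenomeLayout(c(gPlus, gMinus), c(chr1 = 8000))
    pm <- scaledBodyMatrix(tr, lay, flankBp = 500, bodyBins = 50,
                           flankBin = 50)
    bodyP <- profileMatrix(pm)[1, 11:60]
    bodyM <- profileMatrix(pm)[2, 11:60]
    expect_equal(bodyM, rev(bodyP), tolerance = 1e-9)
})

test_that("profile summaries give SE, CI bands and z-scored curves", {
    ## identical rows: SE = 0, CI collapses onto the mean
    mat <- matrix(rep(c(1, 5, 3, 2), each = 10), nrow = 10)
    pm <- txinit:::ProfileMatrix(mat, "point", 50, 100, 100)
    sm <- summarizeProfile(pm, zscore = FALSE)
    expect_equal(sm$se, rep(0, 4))
    expect_equal(sm$ci95_low, sm$mean)
    expect_equal(sm$ci95_high, sm$mean)
    ## z-scored mean curve has mean 0, sd 1 across bins
    smz <- summarizeProfile(pm, zscore = TRUE)
    expect_equal(mean(smz$mean), 0, tolerance = 1e-12)
    expect_equal(sd(smz$mean), 1, tolerance = 1e-12)
    expect_true(all(smz$ci95_low <= smz$mean & smz$mean <= smz$ci95_high))
    ## single-region matrix: SE undefined, CI suppressed
    pm1 <- txinit:::ProfileMatrix(mat[1, , drop = FALSE], "point", 50, 100, 100)
    sm1 <- summarizeProfile(pm1, zscore = FALSE)
    expect_true(all(is.na(sm1$se)))
    expect_true(all(is.na(sm1$ci95_low)))
})

test_that("per-bin trimming tames a single huge outlier", {
    set.seed(13)
    col <- c(rnorm(19, 5, 0.1), 500)
    mat <- matrix(col, ncol = 1)
    pm <- txinit:::ProfileMatrix(mat, "point", 50, 50, 0)
    plain <- summarizeProfile(pm, zscore = FALSE)$mean
    trimmed <- summarizeProfile(pm, zscore = FALSE, trim = c(0.1, 0.1))$mean
    expect_gt(plain, 25)
    expect_equal(trimmed, mean(trimOracle(col, 0.1, 0.1)), tolerance = 1e-12)
})

test_that("strand-mirror symmetry holds on strand-symmetric signal", {
    set.seed(19)
    v <- rpois(6000, 1)
    tr <- makeTrack(chr1 = v)
    pos <- sample(2200:3800, 40)
    plusA <- GRanges("chr1", IRanges(pos, width = 1), strand = "+")
    minusA <- GRanges("chr1", IRanges(pos, width = 1), strand = "-")
    pmP <- pointAnchoredMatrix(tr, plusA, 2000, 2000, 100)
    pmM <- pointAnchoredMatrix(tr, minusA, 2000, 2000, 100)
    meanP <- colMeans(profileMatrix(pmP))
    meanM <- colMeans(profileMatrix(pmM))
    expect_equal(meanM, rev(meanP), tolerance = 1e-9)
})

test_that("profile matrices round-trip through TSV + JSON sidecar", {
    set.seed(2)
    v <- rpois(3000, 2)
    tr <- makeTrack(chr1 = v, label = "rt")
    anchors <- GRanges("chr1", IRanges(c(1200, 1500, 2000), width = 1))
    names(anchors) <- paste0("a", 1:3)
    pm <- pointAnchoredMatrix(tr, anchors, 1000, 1000, 50)
    tmp <- withr::local_tempfile(fileext = ".tsv")
    writeProfileMatrix(pm, tmp)
    pm2 <- readProfileMatrix(tmp)
    expect_equal(profileMatrix(pm), profileMatrix(pm2), tolerance = 1e-9)
    expect_equal(profileTrackLabel(pm2), "rt")
    expect_equal(pm2@binSize, 50)
})

test_that("CI width shrinks roughly like 1/sqrt(n) on i.i.d. rows", {
    set.seed(4)
    widthAt <- function(n) {
        mat <- matrix(rnorm(n * 10), nrow = n)
        sm <- summarizeProfile(txinit:::ProfileMatrix(mat, "point", 50, 250, 250),
                               zscore = FALSE)
        mean(sm$ci95_high - sm$ci95_low)
    }
    w <- vapply(c(20, 80, 320, 1280), widthAt, numeric(1))
    slope <- coef(lm(log(w) ~ log(c(20, 80, 320, 1280))))[2]
    expect_lt(abs(slope + 0.5), 0.15)
})
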