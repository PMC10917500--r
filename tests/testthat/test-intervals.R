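test_that("annotation readers apply the coordinate-dialect conventions", {
    tmp <- withr::local_tempdir()
    ## GFF3 is 1-based closed: start=1001,end=2000 is the half-open [1000,2000)
    gff <- file.path(tmp, "g.gff3")
    writeLines(c("##gff-version 3",
                 "chr1\tsrc\tgene\t1001\t2000\t.\t+\t.\tID=g1"), gff)
    lay <- readAnnotation(gff, format = "gff3")
    g <- layoutGenes(lay)
    expect_equal(start(g) - 1L, 1000L)
    expect_equal(end(g), 2000L)
    expect_equal(as.character(strand(g)), "+")

    ## BED is already 0-based half-open; minus-strand TSS is end - 1
    bed <- file.path(tmp, "g.bed")
    writeLines("chr1\t999\t2000\tg1\t0\t-", bed)
    lay2 <- readAnnotation(bed, format = "bed")
    g2 <- layoutGenes(lay2)
    expect_equal(start(g2) - 1L, 999L)
    expect_equal(end(g2), 2000L)
    expect_equal(start(tssPositions(lay2)) - 1L, 1999L)
    expect_equal(start(tesPositions(lay2)) - 1L, 999L)

    ## unknown strand is a rejected record
    bad <- file.path(tmp, "bad.bed")
    writeLines("chr1\t10\t20\tg2\t0\t.", bad)
    expect_error(readAnnotation(bad, format = "bed"), "strand")
})

test_that("a synthetic annotation round-trips through GFF3 write + read", {
    lay <- toyLayout()
    tmp <- withr::local_tempfile(fileext = ".gff3")
    writeAnnotationGff3(lay, tmp)
    lay2 <- readAnnotation(tmp, format = "gff3",
                           chromSizes = chromSizes(lay))
    g1 <- layoutGenes(lay); g2 <- layoutGenes(lay2)
    expect_equal(start(g1), start(g2))
    expect_equal(end(g1), end(g2))
    expect_equal(as.character(strand(g1)), as.character(strand(g2)))
    expect_equal(g1$gene_id, g2$gene_id)
    expect_equal(chromSizes(lay), chromSizes(lay2))
})

test_that("interval subtraction handles split, identity and empty cases", {
    a <- gr0(10, 100)
    expect_equal(as.data.frame(ranges(intervalSubtract(a, gr0(40, 60))))[, 1:2],
                 data.frame(start = c(11, 61), end = c(40, 100)))
    expect_equal(start(intervalSubtract(a, GRanges())), start(a))
    expect_length(intervalSubtract(GRanges(), a), 0)
})

test_that("interval intersection handles overlap and disjoint cases", {
    a <- gr0(10, 100)
    out <- intervalIntersect(a, gr0(40, 60))
    expect_equal(start(out) - 1L, 40L)
    expect_equal(end(out), 60L)
    expect_length(intervalIntersect(a, gr0(200, 300)), 0)
})

test_that("subtract/intersect agree with a per-base bitmap oracle", {
    set.seed(42)
    for (rep in 1:50) {
        L <- sample(2000:10000, 1)
        a <- randomRegions(sample(5:50, 1), L)
        b <- randomRegions(sample(5:50, 1), L)
        sub <- intervalSubtract(a, b)
        int <- intervalIntersect(a, b)
        expect_identical(coveredBases(sub), subtractBitmapOracle(a, b, L))
        expect_identical(coveredBases(int), intersectBitmapOracle(a, b, L))
        ## conservation of bases: subtract(a, int) together with int covers a
        expect_identical(sort(unique(c(coveredBases(sub), coveredBases(int)))),
                         coveredBases(a))
    }
})

test_that("the toy layout yields exactly the expected IAR set", {
    lay <- toyLayout()
    iars <- extractIars(lay, toyAccessible())
    expect_equal(names(iars), c("r_up", "r_down", "r_between", "r_tie"))
    expect_equal(start(iars) - 1L, c(3500L, 8500L, 10500L, 15450L))
    expect_equal(end(iars), c(3700L, 8800L, 10700L, 15550L))
    expect_equal(iars$distance_to_gene, c(1300L, 500L, 1300L, 1450L))
    expect_equal(iars$nearest_gene_id, c("gA", "gA", "gB", "gB"))
    expect_equal(iars$midpoint, c(3600L, 8650L, 10600L, 15500L))
    ## side relative to gene orientation: left of + gene is upstream, left
    ## and right of the - gene gB are downstream and upstream respectively
    expect_equal(iars$relative_position,
                 c("upstream-of-gene", "downstream-of-gene",
                   "downstream-of-gene", "upstream-of-gene"))
    ## every IAR respects the window and never touches a gene body
    expect_true(all(iars$distance_to_gene >= 100 &
                    iars$distance_to_gene <= 2000))
    expect_false(any(overlapsAny(iars, layoutGenes(lay),
                                 ignore.strand = TRUE)))
})

test_that("IAR extraction is invariant to input ordering and errors without genes", {
    lay <- toyLayout()
    acc <- toyAccessible()
    set.seed(7)
    shuffled <- acc[sample(length(acc))]
    i1 <- extractIars(lay, acc)
    i2 <- extractIars(lay, shuffled)
    expect_equal(names(i1), names(i2))
    expect_equal(start(i1), start(i2))
    expect_error(extractIars(GenomeLayout(GRanges(), c(chr1 = 100)), acc),
                 "without genes")
})

test_that("midpoint flanks follow the +/- flank arithmetic and clip at bounds", {
    iar <- gr0(9950, 10050)
    iar$midpoint <- 10000L
    fl <- flanksFromMidpoint(iar, flank = 2000, chromSizes = c(chr1 = 50000))
    expect_equal(start(fl$upstream) - 1L, 8000L)
    expect_equal(end(fl$upstream), 10000L)
    expect_equal(start(fl$downstream) - 1L, 10000L)
    expect_equal(end(fl$downstream), 12000L)
    expect_false(fl$upstream$clipped || fl$downstream$clipped)

    near <- gr0(480, 520)
    near$midpoint <- 500L
    fl2 <- flanksFromMidpoint(near, flank = 2000, chromSizes = c(chr1 = 50000))
    expect_equal(start(fl2$upstream) - 1L, 0L)
    expect_equal(end(fl2$upstream), 500L)
    expect_true(fl2$upstream$clipped)
    expect_error(flanksFromMidpoint(iar, flank = 0), "flank")
})
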