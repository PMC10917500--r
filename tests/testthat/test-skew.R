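mkIars <- function(mids0, chrom = "chr1") {
    gr <- GRanges(chrom, IRanges(mids0 - 49L, mids0 + 50L))
    gr$midpoint <- mids0
    names(gr) <- paste0("iar", seq_along(gr))
    gr
}

test_that("locus skews follow the log2(x+1) difference formula", {
    ## uniform signal both sides -> skew 0
    tr <- makeTrack(chr1 = rep(4, 10000))
    sk <- computeLocusSkews(tr, NULL, mkIars(5000L), flank = 2000)
    expect_equal(sk$skew, 0)
    expect_equal(sk$up_signal, 4)
    ## downstream mean 7 vs upstream 0 -> skew log2(8) - log2(1) = 3
    v <- rep(0, 10000); v[5001:7000] <- 7
    sk2 <- computeLocusSkews(makeTrack(chr1 = v), NULL, mkIars(5000L),
                             flank = 2000)
    expect_equal(sk2$skew, 3)
    expect_equal(sk2$up_log, 0)
})

test_that("skews compose from independent flank aggregations", {
    set.seed(23)
    vp <- rpois(20000, 0.7); vm <- rpois(20000, 0.4)
    plus <- makeTrack(chr1 = vp, strand = "+")
    minus <- makeTrack(chr1 = vm, strand = "-")
    iars <- mkIars(c(4000L, 9000L, 15000L))
    sk <- computeLocusSkews(plus, minus, iars, flank = 2000)
    fl <- flanksFromMidpoint(iars, 2000, c(chr1 = 20000))
    comb <- combineTracks(plus, minus)
    expect_equal(sk$up_signal,
                 aggregateOverRegions(comb, fl$upstream)$mean_signal)
    expect_equal(sk$down_signal,
                 aggregateOverRegions(comb, fl$downstream)$mean_signal)
    ## oriented mode reads minus upstream, plus downstream
    sko <- computeLocusSkews(plus, minus, iars, flank = 2000,
                             strandMode = "oriented")
    expect_equal(sko$up_signal,
                 aggregateOverRegions(minus, fl$upstream)$mean_signal)
    expect_equal(sko$down_signal,
                 aggregateOverRegions(plus, fl$downstream)$mean_signal)
    expect_error(computeLocusSkews(plus, NULL, iars,
                                   strandMode = "oriented"), "both strand")
})

test_that("silent-locus filtering drops only doubly-zero loci", {
    loci <- data.frame(iar = c("a", "b", "c"),
                       up_signal = c(0, 0, 2), down_signal = c(0, 5, 0),
                       up_log = 0, down_log = 0, skew = 0)
    kept <- filterSilent(loci)
    expect_equal(kept$iar, c("b", "c"))
    set.seed(10)
    up <- rpois(500, 0.2); down <- rpois(500, 0.2)
    loci2 <- data.frame(iar = seq_along(up), up_signal = up,
                        down_signal = down, up_log = log2(up + 1),
                        down_log = log2(down + 1), skew = 0)
    expect_equal(nrow(filterSilent(loci2)), sum(pmax(up, down) > 0))
})

test_that("the rank-sum test matches its closed cases", {
    ## identical samples -> p = 1
    expect_equal(wilcoxonRankSum(c(2, 2, 2), c(2, 2, 2))$p_value, 1)
    expect_equal(wilcoxonRankSum(1:5, 1:5)$p_value, 1, tolerance = 1e-9)
    ## fully separated triples: exact two-sided p = 2/20 = 0.1
    out <- wilcoxonRankSum(c(1, 2, 3), c(4, 5, 6))
    expect_equal(out$p_value, 0.1)
    expect_equal(out$statistic, 0)
})

test_that("exact p-values agree with rank-split enumeration", {
    set.seed(15)
    for (rep in 1:40) {
        n1 <- sample(1:7, 1); n2 <- sample(1:7, 1)
        x <- runif(n1); y <- runif(n2)
        expect_equal(wilcoxonRankSum(x, y)$p_value, wilcoxEnumOracle(x, y),
                     tolerance = 1e-12)
    }
})

test_that("p-values are invariant under monotone transforms of the data", {
    set.seed(44)
    x <- rpois(40, 6); y <- rpois(35, 9)
    p1 <- wilcoxonRankSum(x, y)$p_value
    p2 <- wilcoxonRankSum(2 * x + 1, 2 * y + 1)$p_value
    expect_equal(p1, p2, tolerance = 1e-12)
})

test_that("group testing calls extremes, applies Bonferroni, reports m", {
    set.seed(3)
    strong <- simulateSkewGroup(200, 1, 30)
    weak <- simulateSkewGroup(200, 8, 8)
    tiny <- simulateSkewGroup(5, 4, 4)
    loci <- rbind(strong, weak, tiny)
    loci$iar <- paste0("L", seq_len(nrow(loci)))
    groups <- rep(c("g_strong", "g_weak", "g_tiny"), c(200, 200, 5))
    res <- testDirectionality(loci, groups, alpha = 0.05)
    res <- res[order(res$group), ]
    expect_equal(res$m_tests, rep(2L, 3))           # tiny group not tested
    expect_equal(res$bonferroni_threshold, rep(0.025, 3))
    expect_equal(res$call[res$group == "g_strong"], "unidirectional")
    expect_equal(res$favored_side[res$group == "g_strong"], "downstream")
    expect_equal(res$call[res$group == "g_tiny"], "insufficient data")
    ## significance flag is exactly p < threshold
    tested <- !is.na(res$p_value)
    expect_equal(res$significant[tested],
                 res$p_value[tested] < res$bonferroni_threshold[tested])
})

test_that("swapping the flanks flips the favored side, not the p-value", {
    set.seed(12)
    loci <- simulateSkewGroup(80, 2, 12)
    swapped <- data.frame(iar = loci$iar,
                          up_signal = loci$down_signal,
                          down_signal = loci$up_signal,
                          up_log = loci$down_log, down_log = loci$up_log,
                          skew = -loci$skew)
    r1 <- testDirectionality(loci, alpha = 0.05)
    r2 <- testDirectionality(swapped, alpha = 0.05)
    expect_equal(r1$p_value, r2$p_value, tolerance = 1e-12)
    expect_equal(r1$favored_side, "downstream")
    expect_equal(r2$favored_side, "upstream")
})

test_that("a symmetric group is rarely called unidirectional", {
    set.seed(99)
    calls <- replicate(60, {
        g <- simulateSkewGroup(200, 8, 8)
        testDirectionality(g, alpha = 0.05)$call
    })
    expect_gte(mean(calls == "bidirectional"), 0.9)
})

test_that("violin export is long-format with two rows per locus", {
    loci <- simulateSkewGroup(2, 3, 3)
    tab <- exportSkewViolinData(loci)
    expect_equal(nrow(tab), 4)
    expect_equal(sort(unique(tab$side)), c("down", "up"))
    empty <- exportSkewViolinData(loci[0, ])
    expect_equal(nrow(empty), 0)
    expect_named(empty, c("group", "side", "log_value"))
    set.seed(2)
    sizes <- c(a = 7, b = 13)
    loci2 <- rbind(simulateSkewGroup(7, 2, 2), simulateSkewGroup(13, 2, 2))
    loci2$iar <- paste0("L", seq_len(20))
    tab2 <- exportSkewViolinData(loci2, rep(c("a", "b"), c(7, 13)))
    expect_equal(nrow(tab2), 2 * sum(sizes))
    expect_equal(as.vector(table(tab2$group)), unname(as.integer(2 * sizes)))
})
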