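## The upstream/downstream skew statistic: per-IAR flank signal,
## zero-signal filtering, log2(x+1) transform, Wilcoxon rank-sum testing
## with Bonferroni correction, and uni/bidirectional calls.

#' Per-IAR upstream/downstream flank signal
#'
#' Aggregates mean signal (mean0 convention) over the two 2 kb windows on
#' either side of each IAR midpoint.  `strandMode = "combined"` sums the
#' plus- and minus-strand tracks before aggregation (the default, matching a
#' single aggregation pass over an unstranded signal file);
#' `strandMode = "oriented"` aggregates the minus-strand track over the
#' upstream flank and the plus-strand track over the downstream flank, since
#' transcription pointing away from the element reads upstream on the minus
#' strand.
#'
#' @param plusTrack [CoverageTrack-class]; for `"combined"` with a single
#'   unstranded track, pass it here and leave `minusTrack` `NULL`.
#' @param minusTrack [CoverageTrack-class] or `NULL`; required for
#'   `"oriented"`.
#' @param iars `GRanges` from [extractIars()].
#' @param flank flank width in bp (default 2000).
#' @param strandMode `"combined"` (default) or `"oriented"`.
#' @param chromSizes optional named chromosome lengths for flank clipping;
#'   defaults to the track's own chromosome lengths.
#' @return `data.frame` with columns `iar`, `up_signal`, `down_signal`,
#'   `up_log`, `down_log` (`log2(x + 1)` transforms) and
#'   `skew = down_log - up_log`.
#' @export
computeLocusSkews <- function(plusTrack, minusTrack = NULL, iars,
                              flank = 2000,
                              strandMode = c("combined", "oriented"),
                              chromSizes = NULL) {
    strandMode <- match.arg(strandMode)
    if (strandMode == "oriented" && is.null(minusTrack))
        stop("strandMode 'oriented' requires both strand tracks")
    if (is.null(chromSizes)) chromSizes <- trackChromLengths(plusTrack)
    if (is.null(names(iars)) && length(iars))
        names(iars) <- paste0("iar", seq_along(iars))
    fl <- flanksFromMidpoint(iars, flank = flank, chromSizes = chromSizes)
    if (strandMode == "combined") {
        track <- if (is.null(minusTrack)) plusTrack
                 else combineTracks(plusTrack, minusTrack)
        up <- aggregateOverRegions(track, fl$upstream)$mean_signal
        down <- aggregateOverRegions(track, fl$downstream)$mean_signal
    } else {
        up <- aggregateOverRegions(minusTrack, fl$upstream)$mean_signal
        down <- aggregateOverRegions(plusTrack, fl$downstream)$mean_signal
    }
    data.frame(iar = names(iars), up_signal = up, down_signal = down,
               up_log = log2(up + 1), down_log = log2(down + 1),
               skew = log2(down + 1) - log2(up + 1), row.names = NULL)
}

#' Drop loci with no signal on either side
#'
#' Removes loci whose upstream AND downstream flank signals are both zero
#' (a locus with one-sided signal is informative and kept).
#'
#' @param loci `data.frame` from [computeLocusSkews()].
#' @return The filtered `data.frame`.
#' @export
filterSilent <- function(loci) {
    loci[!(loci$up_signal == 0 & loci$down_signal == 0), , drop = FALSE]
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Exact null distribution when the combined sample size is at most
#' `exactThreshold` and the pooled values are tie-free; otherwise the normal
#' approximation with tie and continuity corrections.  Two samples whose
#' pooled values are all identical give p = 1.
#'
#' @param x,y numeric samples (each nonempty).
#' @param exactThreshold combined-size switch point (default 25).
#' @return list with `statistic` (the Mann-Whitney rank-sum U of `x`) and
#'   `p_value`.
#' @export
wilcoxonRankSum <- function(x, y, exactThreshold = 25) {
    if (!length(x) || !length(y)) stop("both samples must be nonempty")
    pooled <- c(x, y)
    if (all(pooled == pooled[1]))
        return(list(statistic = length(x) * length(y) / 2, p_value = 1))
    exact <- (length(x) + length(y) <= exactThreshold) &&
        !anyDuplicated(pooled)
    ht <- suppressWarnings(wilcox.test(x, y, alternative = "two.sided",
                                       exact = exact, correct = TRUE))
    list(statistic = unname(ht$statistic), p_value = ht$p.value)
}

#' Per-group directionality test
#'
#' For each group of loci, tests the `log2(x + 1)`-transformed upstream
#' signals against the downstream signals as two samples with the Wilcoxon
#' rank-sum test (two-sided), applying a Bonferroni family-wise threshold of
#' `alpha / m` where `m` is the number of groups actually tested in this
#' invocation.  Silent loci (zero on both sides) are removed per group first;
#' groups left with fewer than `minN` loci are reported as
#' `"insufficient data"`.  Significant groups are called `"unidirectional"`
#' with the favored side taken from the larger median; non-significant
#' groups with signal are called `"bidirectional"`.
#'
#' @param loci `data.frame` from [computeLocusSkews()].
#' @param groups group label per locus: a vector parallel to `loci`, a named
#'   vector / [ClusterAssignment-class] indexed by `loci$iar`, or `NULL` for
#'   a single group.
#' @param alpha family-wise significance level (default 0.05).
#' @param minN minimum group size after filtering (default 10).
#' @param exactThreshold passed to [wilcoxonRankSum()].
#' @return `data.frame` with one row per group: `group`, `n_loci`,
#'   `statistic`, `p_value`, `alpha`, `m_tests`, `bonferroni_threshold`,
#'   `significant`, `call`, `favored_side`.
#' @export
testDirectionality <- function(loci, groups = NULL, alpha = 0.05, minN = 10,
                               exactThreshold = 25) {
    if (is.null(groups)) {
        grp <- rep("all", nrow(loci))
    } else if (is(groups, "ClusterAssignment")) {
        grp <- as.character(clusterLabels(groups)[loci$iar])
    } else if (!is.null(names(groups))) {
        grp <- as.character(groups[loci$iar])
    } else {
        stopifnot(length(groups) == nrow(loci))
        grp <- as.character(groups)
    }
    if (anyNA(grp)) stop("every locus must be mapped to a group")
    split_ <- split(loci, grp)
    kept <- lapply(split_, filterSilent)
    tested <- vapply(kept, nrow, integer(1)) >= minN
    m <- sum(tested)
    res <- lapply(names(split_), function(g) {
        li <- kept[[g]]
        if (!tested[g]) {
            return(data.frame(group = g, n_loci = nrow(li),
                              statistic = NA_real_, p_value = NA_real_,
                              alpha = alpha, m_tests = m,
                              bonferroni_threshold = if (m) alpha / m else NA_real_,
                              significant = NA, call = "insufficient data",
                              favored_side = "none"))
        }
        wt <- wilcoxonRankSum(li$up_log, li$down_log,
                              exactThreshold = exactThreshold)
        thr <- alpha / m
        sig <- wt$p_value < thr
        if (sig) {
            mu <- median(li$up_log); md <- median(li$down_log)
            if (mu == md) { mu <- mean(li$up_log); md <- mean(li$down_log) }
            side <- if (md >= mu) "downstream" else "upstream"
            call <- "unidirectional"
        } else {
            side <- "none"
            call <- "bidirectional"
        }
        data.frame(group = g, n_loci = nrow(li), statistic = wt$statistic,
                   p_value = wt$p_value, alpha = alpha, m_tests = m,
                   bonferroni_threshold = thr, significant = sig,
                   call = call, favored_side = side)
    })
    out <- do.call(rbind, res)
    rownames(out) <- NULL
    out
}

#' Long-format table for violin plots of flank signal
#'
#' @param loci `data.frame` from [computeLocusSkews()].
#' @param groups group label per locus (same conventions as
#'   [testDirectionality()]).
#' @return `data.frame` with columns `group`, `side` (`"up"`/`"down"`),
#'   `log_value` -- two rows per locus.
#' @export
exportSkewViolinData <- function(loci, groups = NULL) {
    if (!nrow(loci))
        return(data.frame(group = character(), side = character(),
                          log_value = numeric()))
    if (is.null(groups)) {
        grp <- rep("all", nrow(loci))
    } else if (is(groups, "ClusterAssignment")) {
        grp <- as.character(clusterLabels(groups)[loci$iar])
    } else if (!is.null(names(groups))) {
        grp <- as.character(groups[loci$iar])
    } else {
        grp <- as.character(groups)
    }
    data.frame(group = rep(grp, 2),
               side = rep(c("up", "down"), each = nrow(loci)),
               log_value = c(loci$up_log, loci$down_log))
}

#' Violin plot of upstream/downstream flank signal
#'
#' Thin ggplot2 wrapper over [exportSkewViolinData()]; requires ggplot2.
#'
#' @param loci,groups as in [exportSkewViolinData()].
#' @return A ggplot object.
#' @export
plotSkewViolins <- function(loci, groups = NULL) {
    if (!requireNamespace("ggplot2", quietly = TRUE))
        stop("ggplot2 is required for plotting")
    tab <- exportSkewViolinData(loci, groups)
    ggplot2::ggplot(tab, ggplot2::aes(x = .data$side, y = .data$log_value)) +
        ggplot2::geom_violin() +
        ggplot2::facet_wrap(~group) +
        ggplot2::labs(x = NULL, y = "log2(signal + 1)")
}
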