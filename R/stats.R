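#' Wilcoxon signed-rank test for paired samples
#'
#' The statistic `W` is the smaller of the positive- and negative-rank sums
#' of the paired differences (zero differences dropped, midranks for tied
#' absolute differences). Two modes:
#' \describe{
#'   \item{exact}{the two-sided p-value is computed by full enumeration of
#'     all `2^n` sign assignments of the observed absolute ranks (feasible
#'     for `n <= 15`, the default mode there); correct under ties because
#'     the enumeration uses the observed midranks.}
#'   \item{normal}{the large-sample approximation
#'     `z = (W+ - n(n+1)/4) / sqrt(Var)` with the tie-corrected variance
#'     `n(n+1)(2n+1)/24 - sum(t^3 - t)/48`, two-sided p from the standard
#'     normal.}
#' }
#'
#' @param a,b paired numeric vectors of equal length.
#' @param mode `"exact"`, `"normal"`, or `"auto"` (exact for `n <= 15`).
#' @return list: `test`, `W`, `z` (`NA` in exact mode), `p`, `n` (non-zero
#'   differences), `mode`.
#' @export
#' @examples
#' wilcoxonSignedRank(c(5, 6, 7, 8, 9, 10, 11, 12, 13),
#'                    c(4, 5, 6, 7, 8, 9, 10, 11, 12))
wilcoxonSignedRank <- function(a, b, mode = c("auto", "exact", "normal")) {
    mode <- match.arg(mode)
    if (length(a) != length(b)) stop("paired samples must have equal length")
    d <- a - b
    d <- d[d != 0]
    n <- length(d)
    if (!n) stop("all differences are zero")
    if (mode == "auto") mode <- if (n <= 15) "exact" else "normal"
    r <- rank(abs(d))                     # midranks for ties
    w_pos <- sum(r[d > 0])
    w_neg <- sum(r[d < 0])
    W <- min(w_pos, w_neg)
    total <- n * (n + 1) / 2
    if (mode == "exact") {
        if (n > 20) stop("exact mode is limited to n <= 20")
        # distribution of W+ over all sign assignments of the observed ranks
        sums <- 0
        for (ri in r) sums <- as.vector(outer(sums, c(0, ri), "+"))
        p <- (sum(sums <= W) + sum(sums >= total - W)) / length(sums)
        p <- min(1, p)
        return(list(test = "wilcoxon_signed_rank", W = W, z = NA_real_,
                    p = p, n = n, mode = "exact"))
    }
    mu <- total / 2
    tie_tab <- table(r)
    t_sizes <- as.numeric(tie_tab)
    v <- n * (n + 1) * (2 * n + 1) / 24 - sum(t_sizes^3 - t_sizes) / 48
    if (v <= 0) stop("zero variance (all ranks tied); exact mode required")
    z <- (w_pos - mu) / sqrt(v)
    p <- 2 * stats::pnorm(-abs(z))
    list(test = "wilcoxon_signed_rank", W = W, z = z, p = p, n = n,
         mode = "normal")
}

#' Two-sided p-value of a standard-normal z statistic
#'
#' `2 * pnorm(-|z|)`; the reporting convention used with the normal-mode
#' signed-rank test.
#'
#' @param z z statistic.
#' @return two-sided p-value.
#' @export
zToP <- function(z) 2 * stats::pnorm(-abs(z))

#' Two-sample Kolmogorov-Smirnov test
#'
#' `D = sup |ECDF1 - ECDF2|` with the asymptotic two-sided p-value, as used
#' for comparing cumulative frequency distributions of run lengths across
#' conditions.
#'
#' @param sample1,sample2 non-empty numeric samples.
#' @return list: `test`, `D`, `p`, `n` (c(n1, n2)).
#' @export
ksTwoSample <- function(sample1, sample2) {
    if (!length(sample1) || !length(sample2))
        stop("both samples must be non-empty")
    kt <- suppressWarnings(stats::ks.test(sample1, sample2, exact = FALSE))
    list(test = "ks_two_sample", D = unname(kt$statistic),
         p = unname(kt$p.value), n = c(length(sample1), length(sample2)))
}

#' Pairwise Student's t-tests with Bonferroni-corrected significance
#'
#' Two-sided two-sample Student's t-tests (equal variances) for each listed
#' pair of groups; the significance threshold is `alpha / n_comparisons`.
#' Both the raw p-value and the corrected decision are reported.
#'
#' @param groups named list of numeric samples (each `n >= 2`).
#' @param comparisons list of character pairs `c(name1, name2)`; default all
#'   pairwise comparisons.
#' @param alpha family-wise significance level (default 0.05).
#' @return data.frame: `group1`, `group2`, `statistic`, `p`, `n1`, `n2`,
#'   `corrected_alpha`, `significant`.
#' @export
tTestBonferroni <- function(groups, comparisons = NULL, alpha = 0.05) {
    if (is.null(comparisons)) {
        nm <- names(groups)
        comparisons <- utils::combn(nm, 2, simplify = FALSE)
    }
    m <- length(comparisons)
    thr <- alpha / m
    rows <- lapply(comparisons, function(cmp) {
        x <- groups[[cmp[1]]]; y <- groups[[cmp[2]]]
        if (length(x) < 2L || length(y) < 2L)
            stop("each group needs n >= 2")
        if (stats::var(x) == 0 && stats::var(y) == 0)
            stop("zero pooled variance in comparison ", cmp[1], " vs ",
                 cmp[2])
        tt <- stats::t.test(x, y, var.equal = TRUE)
        data.frame(group1 = cmp[1], group2 = cmp[2],
                   statistic = unname(tt$statistic), p = tt$p.value,
                   n1 = length(x), n2 = length(y), corrected_alpha = thr,
                   significant = tt$p.value < thr,
                   stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}
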