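# Group-level statistics: mean +/- SEM summaries, two-tailed unpaired
# t-tests, and punctum-size frequency distributions.

#' Summarize a group of measurements
#'
#' @param values numeric vector, length >= 2.
#' @return a \linkS4class{GroupStats}: n, mean, sample SD (n - 1
#'   denominator), and SEM = SD / sqrt(n).
#' @export
summarizeGroup <- function(values) {
    values <- as.numeric(values)
    n <- length(values)
    if (n < 2L) stop("need at least 2 values to summarize a group")
    s <- stats::sd(values)
    new("GroupStats", n = n, mean = mean(values), sd = s, sem = s / sqrt(n))
}

#' Two-tailed unpaired t-test
#'
#' Student's pooled-variance two-sample t-test by default (df = n1 + n2 - 2),
#' matching the conventional "unpaired t-test" of the commercial statistics
#' packages used for this kind of data; Welch's unequal-variance form is
#' available via \code{welch = TRUE}.
#'
#' @param a,b numeric vectors, each of length >= 2.
#' @param welch use the Welch form instead of the pooled form.
#' @return a \linkS4class{TTestResult}.
#' @export
unpairedTTest <- function(a, b, welch = FALSE) {
    a <- as.numeric(a); b <- as.numeric(b)
    if (length(a) < 2L || length(b) < 2L)
        stop("each group needs at least 2 values")
    if (stats::var(a) == 0 && stats::var(b) == 0 && mean(a) == mean(b))
        stop("degenerate: both groups constant and equal")
    ht <- stats::t.test(a, b, var.equal = !welch, paired = FALSE,
                        alternative = "two.sided")
    new("TTestResult", t_statistic = unname(ht$statistic),
        degrees_of_freedom = unname(ht$parameter),
        p_value = unname(ht$p.value),
        method = if (welch) "welch" else "pooled")
}

#' Frequency distribution of punctum sizes
#'
#' Histogram with bin edges anchored at 0 and fixed width; counts conserve
#' the number of input values.
#'
#' @param values_nm FWHM values in nm.
#' @param bin_width_nm bin width in nm (> 0).
#' @return a \linkS4class{FrequencyDistribution}.
#' @export
fwhmFrequencyDistribution <- function(values_nm, bin_width_nm = 10) {
    if (bin_width_nm <= 0) stop("bin_width_nm must be > 0")
    values_nm <- as.numeric(values_nm)
    if (!length(values_nm)) stop("no values to bin")
    if (any(values_nm < 0)) stop("FWHM values must be nonnegative")
    edges <- seq(0, (floor(max(values_nm) / bin_width_nm) + 1) * bin_width_nm,
                 by = bin_width_nm)
    idx <- findInterval(values_nm, edges, rightmost.closed = FALSE)
    counts <- tabulate(idx, nbins = length(edges) - 1L)
    new("FrequencyDistribution", bin_edges_nm = edges,
        counts = as.integer(counts))
}
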