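#' Build and validate a contingency table
#'
#' Thin validating constructor around a matrix of counts. All downstream tests
#' ([fisher_exact_two_tailed()], [g_test()]) accept either a plain matrix or an
#' object built here.
#'
#' @param counts Matrix (or object coercible to one) of non-negative integer
#'   counts, at least 2x2.
#' @param row_labels,col_labels Optional dimnames; taken from `counts` if absent.
#' @return A `contingency_table`: the integer matrix with labels attached.
#' @export
contingency_table <- function(counts, row_labels = NULL, col_labels = NULL) {
  m <- as.matrix(counts)
  if (nrow(m) < 2L || ncol(m) < 2L)
    stop("contingency table must have at least 2 rows and 2 columns")
  if (any(is.na(m)) || any(m < 0) || any(m != round(m)))
    stop("counts must be non-negative integers")
  if (sum(m) <= 0) stop("grand total must be positive")
  storage.mode(m) <- "double"
  if (!is.null(row_labels)) rownames(m) <- row_labels
  if (!is.null(col_labels)) colnames(m) <- col_labels
  class(m) <- c("contingency_table", class(m))
  m
}

new_assay_test <- function(method, statistic, df, p_value, note = NULL) {
  structure(
    list(method = method, statistic = statistic, df = df,
         p_value = p_value, note = note),
    class = "assay_test")
}

#' @export
print.assay_test <- function(x, ...) {
  cat(x$method, "\n")
  if (!is.na(x$statistic))
    cat(sprintf("  statistic = %.6g", x$statistic),
        if (!is.null(x$df) && !is.na(x$df)) sprintf(", df = %d", x$df) else "",
        "\n", sep = "")
  cat(sprintf("  p-value   = %.4g\n", x$p_value))
  if (!is.null(x$note)) cat("  note: ", x$note, "\n", sep = "")
  invisible(x)
}

#' Two-tailed Fisher's exact test for a 2x2 table
#'
#' Conditions on both margins and sums the hypergeometric probabilities of all
#' tables whose probability does not exceed that of the observed table (the
#' probability-mass two-sided rule used by standard implementations).
#'
#' @param table 2x2 matrix of counts (or [contingency_table()]).
#' @return An `assay_test` with `p_value`; `statistic` is `NA` (exact test).
#' @examples
#' fisher_exact_two_tailed(matrix(c(5, 5, 5, 5), 2))$p_value  # 1
#' @export
fisher_exact_two_tailed <- function(table) {
  m <- unclass(as.matrix(table))
  if (!all(dim(m) == c(2L, 2L))) stop("Fisher's exact test requires a 2x2 table")
  if (any(m < 0) || any(m != round(m))) stop("counts must be non-negative integers")
  n <- sum(m)
  r1 <- sum(m[1L, ]); c1 <- sum(m[, 1L])
  if (r1 == 0 || r1 == n || c1 == 0 || c1 == n)
    stop("a margin of the table is zero; the test is undefined")
  lo <- max(0L, r1 + c1 - n)
  hi <- min(r1, c1)
  support <- lo:hi
  dens <- stats::dhyper(support, c1, n - c1, r1)
  obs <- stats::dhyper(m[1L, 1L], c1, n - c1, r1)
  # relative tolerance guards against ties broken by floating-point noise
  p <- sum(dens[dens <= obs * (1 + 1e-7)])
  new_assay_test("Fisher's exact test (two-tailed)",
                 statistic = NA_real_, df = NULL, p_value = min(1, p))
}

#' Likelihood-ratio (G) test of independence
#'
#' G = 2 * sum O * ln(O/E) over cells with O > 0, expected counts from the
#' product of margins; df = (r-1)(c-1); p-value from the chi-square upper tail.
#' No Williams or continuity correction is applied.
#'
#' @param table r x c matrix of counts.
#' @return An `assay_test` with `statistic` (G), `df` and `p_value`.
#' @export
g_test <- function(table) {
  m <- unclass(as.matrix(table))
  if (nrow(m) < 2L || ncol(m) < 2L) stop("G test requires at least a 2x2 table")
  if (any(m < 0)) stop("counts must be non-negative")
  rs <- rowSums(m); cs <- colSums(m)
  if (any(rs == 0) || any(cs == 0))
    stop("a row or column sums to zero; the test is undefined")
  n <- sum(m)
  e <- outer(rs, cs) / n
  keep <- m > 0
  g <- 2 * sum(m[keep] * log(m[keep] / e[keep]))
  g <- max(g, 0)  # clip tiny negative rounding on proportional tables
  df <- (nrow(m) - 1L) * (ncol(m) - 1L)
  new_assay_test("G test of independence", statistic = g, df = df,
                 p_value = stats::pchisq(g, df, lower.tail = FALSE))
}

#' Confidence interval for a proportion
#'
#' Symmetric Wald interval by default, matching the "mean +/- 95% CI"
#' presentation of proportion data; a Wilson score interval is available via
#' `method = "wilson"` (asymmetric; `ci_half_width` is then half its span and
#' the bounds are returned explicitly).
#'
#' @param k Number of successes.
#' @param n Number of trials (> 0).
#' @param level Confidence level, default 0.95.
#' @param method `"wald"` (default) or `"wilson"`.
#' @return A `proportion_estimate` list: `k`, `n`, `p_hat`, `ci_half_width`,
#'   `lower`, `upper`, `level`, `method`.
#' @export
proportion_ci <- function(k, n, level = 0.95, method = c("wald", "wilson")) {
  method <- match.arg(method)
  if (length(k) != 1L || length(n) != 1L || n <= 0) stop("need scalar k and n > 0")
  if (k < 0 || k > n) stop("k must lie in [0, n]")
  p <- k / n
  z <- stats::qnorm(1 - (1 - level) / 2)
  if (method == "wald") {
    hw <- z * sqrt(p * (1 - p) / n)
    lower <- p - hw; upper <- p + hw
  } else {
    den <- 1 + z^2 / n
    centre <- (p + z^2 / (2 * n)) / den
    hw <- (z / den) * sqrt(p * (1 - p) / n + z^2 / (4 * n^2))
    lower <- centre - hw; upper <- centre + hw
  }
  structure(list(k = k, n = n, p_hat = p, ci_half_width = hw,
                 lower = max(0, lower), upper = min(1, upper),
                 level = level, method = method),
            class = "proportion_estimate")
}

#' @export
print.proportion_estimate <- function(x, ...) {
  cat(sprintf("proportion %d/%d = %.4g +/- %.4g (%s %g%% CI)\n",
              x$k, x$n, x$p_hat, x$ci_half_width, x$method, 100 * x$level))
  invisible(x)
}

#' Reversion frequency from fluctuation cultures
#'
#' Per-culture frequency is revertants per colony-forming unit; the aggregate
#' is the mean across cultures by default (frequencies are presented as
#' mean +/- SD over independent cultures), with a jackpot-robust median behind
#' `aggregate_rule = "median"`. An optional reference aggregate normalizes the
#' result (e.g. to a deletion strain).
#'
#' @param revertants,cfu Equal-length vectors of per-culture counts; `cfu > 0`.
#' @param aggregate_rule `"mean"` (default) or `"median"`.
#' @param reference Optional reference aggregate frequency to normalize to.
#' @return A `reversion_frequency` list: `replicate_frequencies`, `aggregate`,
#'   `sd`, and `relative` when a reference is supplied.
#' @export
reversion_frequency <- function(revertants, cfu,
                                aggregate_rule = c("mean", "median"),
                                reference = NULL) {
  aggregate_rule <- match.arg(aggregate_rule)
  if (length(revertants) == 0L) stop("at least one culture is required")
  if (length(cfu) != length(revertants)) stop("revertants and cfu lengths differ")
  if (any(cfu <= 0)) stop("cfu must be positive")
  if (any(revertants < 0)) stop("revertant counts must be non-negative")
  f <- revertants / cfu
  agg <- if (aggregate_rule == "mean") mean(f) else stats::median(f)
  out <- list(replicate_frequencies = f, aggregate = agg,
              sd = if (length(f) > 1L) stats::sd(f) else NA_real_,
              rule = aggregate_rule)
  if (!is.null(reference)) {
    if (reference <= 0) stop("reference frequency must be positive")
    out$relative <- agg / reference
  }
  structure(out, class = "reversion_frequency")
}

#' @export
print.reversion_frequency <- function(x, ...) {
  cat(sprintf("reversion frequency (%s of %d cultures): %.3g",
              x$rule, length(x$replicate_frequencies), x$aggregate))
  if (!is.na(x$sd)) cat(sprintf(" (SD %.3g)", x$sd))
  if (!is.null(x$relative)) cat(sprintf("; %.3g relative to reference", x$relative))
  cat("\n")
  invisible(x)
}

#' Read a labelled count table from TSV
#'
#' First column holds row labels, header holds column labels.
#' @param path TSV file path.
#' @return A [contingency_table()].
#' @export
read_counts_tsv <- function(path) {
  d <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(d[, -1L, drop = FALSE])
  rownames(m) <- d[[1L]]
  contingency_table(m)
}

#' Serialize a test result to a JSON record
#' @param x An `assay_test`.
#' @param path Optional file; if `NULL` the JSON string is returned.
#' @export
write_test_json <- function(x, path = NULL) {
  rec <- list(method = x$method,
              statistic = if (is.na(x$statistic)) NULL else x$statistic,
              df = x$df, p_value = x$p_value)
  js <- jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA, null = "null")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
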