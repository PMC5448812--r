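# Tetrad classification and map-distance estimation for the three-color
# spore-autonomous fluorescence assay: red at CEN8 and green at ARG4 on one
# chromosome VIII homolog, blue at THR1 on the other. Interval 1 is CEN8-ARG4,
# interval 2 is ARG4-THR1.

TETRAD_TYPES <- c("PD", "TT", "NPD")

parse_spores <- function(spores) {
  if (is.matrix(spores) && is.logical(spores)) {
    if (!all(dim(spores) == c(4L, 3L))) stop("expected a 4 x 3 logical pattern")
    return(spores)
  }
  if (length(spores) != 4L) stop("a tetrad has exactly 4 spores")
  s <- toupper(as.character(spores))
  if (any(nchar(s) != 3L)) stop("spore patterns are 3-character strings like 'RG-'")
  m <- matrix(FALSE, 4L, 3L, dimnames = list(NULL, c("R", "G", "B")))
  for (i in 1:4) {
    ch <- strsplit(s[i], "")[[1L]]
    m[i, ] <- ch != "-"
    if (m[i, 1L] && ch[1L] != "R" || m[i, 2L] && ch[2L] != "G" ||
        m[i, 3L] && ch[3L] != "B")
      stop("spore flags must be R/G/B or '-' in fixed positions: ", s[i])
  }
  m
}

#' Classify one tetrad from its spore fluorescence pattern
#'
#' Each spore is a chromatid's marker triple (red at *CEN8*, green at *ARG4*,
#' blue at *THR1*). Chromatids recombinant for interval 1 carry red XOR green;
#' chromatids recombinant for interval 2 carry green and blue together or
#' neither. 0/2/4 recombinant chromatids give PD/TT/NPD per interval. The
#' pattern with two triple-labelled and two dark spores is scored as MI
#' nondisjunction and flagged ambiguous (it is also the signature of a
#' four-chromatid double crossover in the second interval, but nondisjunction
#' is overwhelmingly the more frequent cause in crossover-deficient strains).
#' Any other deviation from 2:2 marker segregation is flagged aberrant and
#' excluded from tallies.
#'
#' @param spores Character vector of 4 three-character patterns (`"RG-"`,
#'   `"--B"`, ...) or a 4x3 logical matrix with columns R, G, B.
#' @return A `tetrad_class` list: `interval1`, `interval2` (`"PD"/"TT"/"NPD"`
#'   or `NA`), `nd`, `ambiguous`, `aberrant`.
#' @examples
#' classify_tetrad(c("RG-", "RG-", "--B", "--B"))  # PD / PD
#' classify_tetrad(c("RGB", "RGB", "---", "---"))  # MI nondisjunction
#' @export
classify_tetrad <- function(spores) {
  m <- parse_spores(spores)
  cls <- classify_pattern_matrix(m[, 1L, drop = FALSE] |> t(),
                                 m[, 2L, drop = FALSE] |> t(),
                                 m[, 3L, drop = FALSE] |> t())
  structure(list(interval1 = cls$interval1, interval2 = cls$interval2,
                 nd = cls$nd, ambiguous = cls$ambiguous,
                 aberrant = cls$aberrant),
            class = "tetrad_class")
}

#' @export
print.tetrad_class <- function(x, ...) {
  if (x$nd) cat("MI nondisjunction", if (x$ambiguous) "(ambiguous pattern)", "\n")
  else if (x$aberrant) cat("aberrant (non-2:2) pattern, excluded\n")
  else cat(sprintf("interval 1: %s, interval 2: %s\n", x$interval1, x$interval2))
  invisible(x)
}

# Vectorized core: R, G, B are n x 4 logical matrices (tetrads x spores).
classify_pattern_matrix <- function(R, G, B) {
  rgb <- R & G & B
  dark <- !R & !G & !B
  nd <- rowSums(rgb) == 2L & rowSums(dark) == 2L
  two2 <- rowSums(R) == 2L & rowSums(G) == 2L & rowSums(B) == 2L
  aberrant <- !two2 & !nd
  n1 <- rowSums(xor(R, G))
  n2 <- rowSums(G == B)
  type_of <- function(k) {
    out <- rep(NA_character_, length(k))
    out[k == 0L] <- "PD"; out[k == 2L] <- "TT"; out[k == 4L] <- "NPD"
    out
  }
  i1 <- type_of(n1); i2 <- type_of(n2)
  i1[nd | aberrant] <- NA_character_
  i2[nd | aberrant] <- NA_character_
  # odd recombinant counts can only arise from non-2:2 patterns
  aberrant <- aberrant | (!nd & (is.na(i1) | is.na(i2)))
  if (length(nd) == 1L)
    list(interval1 = i1, interval2 = i2, nd = nd,
         ambiguous = nd, aberrant = aberrant)
  else
    data.frame(interval1 = i1, interval2 = i2, nd = nd,
               ambiguous = nd, aberrant = aberrant)
}

#' Classify many tetrads at once
#'
#' @param patterns Data frame or matrix with 4 columns of spore pattern
#'   strings (one row per tetrad), e.g. as read by [read_tetrads_tsv()].
#' @return Data frame with columns `interval1`, `interval2`, `nd`,
#'   `ambiguous`, `aberrant`, one row per tetrad.
#' @export
classify_tetrads <- function(patterns) {
  p <- as.matrix(patterns)
  if (ncol(p) != 4L) stop("expected 4 spore columns")
  chars <- function(j, k) substr(p[, j], k, k) != "-"
  R <- cbind(chars(1, 1), chars(2, 1), chars(3, 1), chars(4, 1))
  G <- cbind(chars(1, 2), chars(2, 2), chars(3, 2), chars(4, 2))
  B <- cbind(chars(1, 3), chars(2, 3), chars(3, 3), chars(4, 3))
  classify_pattern_matrix(R, G, B)
}

#' Tally classified tetrads into per-interval counts
#'
#' Aberrant tetrads are excluded from every denominator; nondisjunction
#' tetrads are counted once and contribute to neither interval's PD/NPD/TT.
#'
#' @param classes Data frame from [classify_tetrads()].
#' @return A `tetrad_counts` object: matrix `counts` (2 intervals x PD/TT/NPD),
#'   `nd`, `aberrant`, `n` (non-aberrant tetrads scored).
#' @export
tally_tetrads <- function(classes) {
  ab <- sum(classes$aberrant)
  nd <- sum(classes$nd & !classes$aberrant)
  ok <- !classes$aberrant & !classes$nd
  cnt <- rbind(
    interval1 = table(factor(classes$interval1[ok], levels = TETRAD_TYPES)),
    interval2 = table(factor(classes$interval2[ok], levels = TETRAD_TYPES)))
  tetrad_counts(cnt, nd = nd, aberrant = ab)
}

#' Construct tetrad counts directly
#'
#' @param counts Matrix with columns PD, TT, NPD and one row per interval.
#' @param nd Number of MI-nondisjunction tetrads.
#' @param aberrant Number of excluded non-2:2 tetrads.
#' @export
tetrad_counts <- function(counts, nd = 0, aberrant = 0) {
  m <- as.matrix(counts)
  if (!all(TETRAD_TYPES %in% colnames(m)))
    stop("counts needs columns PD, TT, NPD")
  m <- m[, TETRAD_TYPES, drop = FALSE]
  if (any(m < 0) || nd < 0 || aberrant < 0) stop("counts must be non-negative")
  structure(list(counts = m, nd = nd, aberrant = aberrant,
                 n = sum(m[1L, ]) + nd),
            class = "tetrad_counts")
}

#' @export
print.tetrad_counts <- function(x, ...) {
  cat("tetrad counts (", x$n, " scored, ", x$aberrant, " aberrant excluded)\n",
      sep = "")
  print(x$counts)
  cat("MI nondisjunction:", x$nd, "\n")
  invisible(x)
}

#' Perkins map distance with delta-method standard error
#'
#' cM = 100 (6 NPD + TT) / (2 (PD + NPD + TT)). The standard error treats
#' (TT, NPD) as multinomial fractions t and p of the n informative tetrads:
#' se = 50 sqrt((t(1-t) + 36 p(1-p) - 12 t p) / n).
#'
#' @param counts A `tetrad_counts` object (or a named vector with PD, TT, NPD).
#' @param interval 1 or 2.
#' @return A `genetic_distance`: `cM`, `se`, `n`.
#' @examples
#' perkins_distance(tetrad_counts(rbind(interval1 = c(PD = 80, TT = 20, NPD = 0))))
#' @export
perkins_distance <- function(counts, interval = 1L) {
  v <- if (inherits(counts, "tetrad_counts")) counts$counts[interval, ]
       else counts[TETRAD_TYPES]
  pd <- v[["PD"]]; tt <- v[["TT"]]; npd <- v[["NPD"]]
  n <- pd + tt + npd
  if (n <= 0) stop("no informative tetrads for this interval")
  cm <- 100 * (6 * npd + tt) / (2 * n)
  t <- tt / n; p <- npd / n
  se <- 50 * sqrt((t * (1 - t) + 36 * p * (1 - p) - 12 * t * p) / n)
  structure(list(cM = cm, se = se, n = n), class = "genetic_distance")
}

#' @export
print.genetic_distance <- function(x, ...) {
  cat(sprintf("map distance: %.3f +/- %.3f cM (n = %d tetrads)\n",
              x$cM, x$se, as.integer(x$n)))
  invisible(x)
}

#' MI nondisjunction frequency with Wald confidence interval
#'
#' @param counts A `tetrad_counts` object.
#' @param level Confidence level.
#' @return A `proportion_estimate` with an added `percent` field
#'   (`p_hat` and `ci_half_width` are on the proportion scale).
#' @export
nondisjunction_rate <- function(counts, level = 0.95) {
  if (counts$n <= 0) stop("no tetrads scored")
  est <- proportion_ci(counts$nd, counts$n, level = level)
  est$percent <- 100 * est$p_hat
  est$percent_half_width <- 100 * est$ci_half_width
  est
}

#' Compare two strains' crossover and nondisjunction data
#'
#' Crossovers: G test on the 2x3 strain-by-(PD/TT/NPD) table per interval
#' (the default; `crossover_table = "spores"` instead compares recombinant vs
#' parental chromatid counts in a 2x2 table). Nondisjunction: two-tailed
#' Fisher's exact test on the 2x2 (nd, n - nd) table. Also reports the map
#' distance ratio a/b and a's distance as percent of b's (the percent-of-wild
#' type normalization when b is the wild-type strain).
#'
#' @param a,b `tetrad_counts` for the two strains.
#' @param crossover_table `"tetrads"` (2x3, default) or `"spores"` (2x2).
#' @return A `strain_comparison` list with per-interval crossover tests,
#'   the nondisjunction test, distance ratios and percent normalizations.
#' @export
compare_strains <- function(a, b, crossover_table = c("tetrads", "spores")) {
  crossover_table <- match.arg(crossover_table)
  ivs <- seq_len(nrow(a$counts))
  xo <- lapply(ivs, function(i) {
    if (crossover_table == "tetrads") {
      tab <- rbind(a = a$counts[i, ], b = b$counts[i, ])
      tab <- tab[, colSums(tab) > 0, drop = FALSE]  # unobserved classes carry
      if (ncol(tab) < 2L)                           # no information
        new_assay_test("G test of independence", NA_real_, NULL, NA_real_,
                       note = "only one tetrad class observed; no test")
      else g_test(tab)
    } else {
      rec <- function(x) {
        v <- x$counts[i, ]
        # recombinant chromatids per tetrad: TT 2, NPD 4 (of 4)
        r <- 2 * v[["TT"]] + 4 * v[["NPD"]]
        c(recombinant = r, parental = 4 * sum(v) - r)
      }
      g_test(rbind(a = rec(a), b = rec(b)))
    }
  })
  dist_ratio <- vapply(ivs, function(i) {
    perkins_distance(a, i)$cM / perkins_distance(b, i)$cM
  }, numeric(1))
  nd <- if (a$nd + b$nd == 0)
    new_assay_test("Fisher's exact test (two-tailed)", NA_real_, NULL, 1,
                   note = "no nondisjunction observed in either strain")
  else fisher_exact_two_tailed(rbind(a = c(a$nd, a$n - a$nd),
                                     b = c(b$nd, b$n - b$nd)))
  structure(list(crossover_tests = xo,
                 distance_ratio = dist_ratio,
                 percent_of_reference = 100 * dist_ratio,
                 nd_test = nd,
                 nd_ratio = (a$nd / a$n) / (b$nd / b$n)),
            class = "strain_comparison")
}

#' @export
print.strain_comparison <- function(x, ...) {
  for (i in seq_along(x$crossover_tests)) {
    cat(sprintf("interval %d crossovers: %.1f%% of reference, G test p = %.4g\n",
                i, x$percent_of_reference[i], x$crossover_tests[[i]]$p_value))
  }
  cat(sprintf("MI nondisjunction: %.3g-fold, Fisher p = %.4g\n",
              x$nd_ratio, x$nd_test$p_value))
  invisible(x)
}

#' Read per-tetrad spore patterns from TSV
#'
#' Expects columns `tetrad_id`, `spore1`..`spore4` holding 3-character RGB
#' flag strings (`"RG-"`, `"--B"`, ...).
#' @param path TSV file.
#' @return Data frame of spore pattern columns, tetrad ids as row names.
#' @export
read_tetrads_tsv <- function(path) {
  d <- utils::read.delim(path, colClasses = "character")
  need <- c("spore1", "spore2", "spore3", "spore4")
  if (!all(need %in% names(d))) stop("TSV needs columns spore1..spore4")
  out <- d[, need]
  if ("tetrad_id" %in% names(d)) rownames(out) <- d$tetrad_id
  out
}

#' Write per-tetrad spore patterns to TSV
#' @param patterns Data frame with columns spore1..spore4.
#' @param path Output TSV file.
#' @export
write_tetrads_tsv <- function(patterns, path) {
  d <- data.frame(tetrad_id = seq_len(nrow(patterns)), patterns)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
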