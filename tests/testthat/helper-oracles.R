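# Independent oracles and fixture builders used across the suite.

# Two-tailed Fisher p by raw hypergeometric enumeration from log-binomials
# (no dhyper, no fisher.test): sums probabilities of all margin-preserving
# tables at most as probable as the observed one.
fisher_enum_oracle <- function(m) {
  n <- sum(m); r1 <- sum(m[1, ]); c1 <- sum(m[, 1])
  a <- max(0, r1 + c1 - n):min(r1, c1)
  logp <- lchoose(r1, a) + lchoose(n - r1, c1 - a) - lchoose(n, c1)
  p <- exp(logp)
  obs <- p[a == m[1, 1]]
  sum(p[p <= obs * (1 + 1e-7)])
}

# Tetrad type probabilities for one interval under Poisson(m) crossovers with
# random chromatid choice: Markov chain PD -> TT -> {PD 1/4, TT 1/2, NPD 1/4},
# NPD -> TT, weighted by the Poisson mass.
tetrad_type_probs <- function(m, kmax = 40) {
  M <- rbind(PD  = c(0, 1, 0),
             TT  = c(1 / 4, 1 / 2, 1 / 4),
             NPD = c(0, 1, 0))
  p <- c(PD = 1, TT = 0, NPD = 0)
  out <- p * stats::dpois(0, m)
  for (k in seq_len(kmax)) {
    p <- as.numeric(p %*% M)
    out <- out + p * stats::dpois(k, m)
  }
  names(out) <- c("PD", "TT", "NPD")
  out
}

# Expected Perkins estimates for the two intervals under the classifier's
# rule that the {2xRGB, 2xdark} pattern (true PD1 & NPD2) is scored as MI
# nondisjunction and removed from both tallies.
expected_perkins <- function(d1, d2) {
  p1 <- tetrad_type_probs(2 * d1 / 100)
  p2 <- tetrad_type_probs(2 * d2 / 100)
  f <- p1[["PD"]] * p2[["NPD"]]  # ambiguous-pattern probability
  c(interval1 = 50 * (p1[["TT"]] + 6 * p1[["NPD"]]) / (1 - f),
    interval2 = 50 * (p2[["TT"]] + 6 * (p2[["NPD"]] - f)) / (1 - f))
}

# Walk-based tetrad pattern for given crossover strand choices; independent
# of the package's simulator internals. ch1/ch2: 2-column matrices of
# (homolog-1 chromatid in 1:2, homolog-2 chromatid in 3:4) per crossover.
walk_pattern <- function(ch1, ch2 = NULL) {
  cur <- 1:4
  apply_cos <- function(cur, ch) {
    if (!is.null(ch)) for (r in seq_len(nrow(ch))) {
      i <- ch[r, 1]; j <- ch[r, 2]
      cur[cur == i | cur == j] <- (i + j) - cur[cur == i | cur == j]
    }
    cur
  }
  at_arg4 <- apply_cos(cur, ch1)
  at_thr1 <- apply_cos(at_arg4, ch2)
  r <- c(TRUE, TRUE, FALSE, FALSE)
  g <- at_arg4 <= 2
  b <- at_thr1 >= 3
  paste0(ifelse(r, "R", "-"), ifelse(g, "G", "-"), ifelse(b, "B", "-"))
}

# Random protein with chosen residues pinned at given positions.
make_protein <- function(length = 769, pin = NULL, tag_mass = 5000,
                         domains = list(nterm = c(1, 340),
                                        linker = c(341, 480),
                                        cterm = c(481, length)),
                         seed = 101) {
  set.seed(seed)
  aa <- c("A","D","E","F","G","H","I","L","N","P","Q","S","T","V","Y")
  s <- sample(aa, length, replace = TRUE)  # no K/R unless pinned
  if (!is.null(pin)) s[as.integer(names(pin))] <- pin
  protein_record("synthetic-protein", paste(s, collapse = ""),
                 tag_mass = tag_mass, domains = domains)
}

# A strictly decreasing quartic migration law over [20, 120] kDa.
quartic_law <- function(mw) 90 - 0.9 * mw + 0.004 * mw^2 - 1e-5 * mw^3 + 1e-8 * mw^4

# Nearest-match residue errors between estimated and true site sets.
site_errors <- function(estimated, truth) {
  vapply(truth, function(s) min(abs(estimated - s)), numeric(1))
}
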