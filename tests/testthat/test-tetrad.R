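test_that("spore patterns classify to the correct tetrad types", {
  pd <- classify_tetrad(c("RG-", "RG-", "--B", "--B"))
  expect_equal(pd$interval1, "PD"); expect_equal(pd$interval2, "PD")
  expect_false(pd$nd); expect_false(pd$aberrant)

  # single interval-1 crossover: two recombinant chromatids
  tt <- classify_tetrad(c("RG-", "R-B", "-G-", "--B"))
  expect_equal(tt$interval1, "TT"); expect_equal(tt$interval2, "PD")

  # single interval-2 crossover
  tt2 <- classify_tetrad(c("RG-", "RGB", "---", "--B"))
  expect_equal(tt2$interval1, "PD"); expect_equal(tt2$interval2, "TT")

  nd <- classify_tetrad(c("RGB", "RGB", "---", "---"))
  expect_true(nd$nd); expect_true(nd$ambiguous)
  expect_true(is.na(nd$interval1))

  ab <- classify_tetrad(c("RG-", "RG-", "R-B", "--B"))  # 3 reds: non-2:2
  expect_true(ab$aberrant); expect_false(ab$nd)

  expect_error(classify_tetrad(c("RG-", "--B")), "4 spores")
  expect_error(classify_tetrad(c("GR-", "RG-", "--B", "--B")), "fixed positions")

  # classification cannot depend on spore order
  sp <- c("RG-", "R-B", "-G-", "--B")
  for (i in 1:10) {
    p <- classify_tetrad(sample(sp))
    expect_equal(p$interval1, "TT"); expect_equal(p$interval2, "PD")
  }
})

test_that("two crossovers give PD:TT:NPD = 1/4:1/2:1/4 over the 16 strand choices", {
  types <- character(0)
  for (i1 in 1:2) for (j1 in 3:4) for (i2 in 1:2) for (j2 in 3:4) {
    pat <- walk_pattern(rbind(c(i1, j1), c(i2, j2)))
    types <- c(types, classify_tetrad(pat)$interval1)
  }
  expect_equal(as.vector(table(factor(types, c("PD", "TT", "NPD")))),
               c(4, 8, 4))
})

test_that("Perkins distances follow the printed formula with delta-method SE", {
  expect_equal(perkins_distance(c(PD = 100, TT = 0, NPD = 0))$cM, 0)
  expect_equal(perkins_distance(c(PD = 80, TT = 20, NPD = 0))$cM, 10)
  expect_equal(perkins_distance(c(PD = 70, TT = 25, NPD = 5))$cM, 27.5)

  d1 <- perkins_distance(c(PD = 700, TT = 250, NPD = 50))
  d10 <- perkins_distance(c(PD = 7000, TT = 2500, NPD = 500))
  expect_equal(d1$cM, d10$cM)                      # scale invariance
  expect_equal(d1$se / d10$se, sqrt(10))           # se ~ 1/sqrt(n)

  tse <- 250 / 1000; pse <- 50 / 1000
  expect_equal(d1$se, 50 * sqrt((tse * (1 - tse) + 36 * pse * (1 - pse) -
                                   12 * tse * pse) / 1000))
  expect_error(perkins_distance(c(PD = 0, TT = 0, NPD = 0)), "informative")
})

test_that("nondisjunction rates reproduce the printed worked example", {
  counts <- tetrad_counts(rbind(interval1 = c(PD = 1267, TT = 0, NPD = 0),
                                interval2 = c(PD = 1267, TT = 0, NPD = 0)),
                          nd = 1)
  nd <- nondisjunction_rate(counts)
  expect_equal(nd$percent, 100 / 1268, tolerance = 1e-12)
  expect_equal(round(nd$percent, 1), 0.1)  # the ~0.1% of 1 in 1268 tetrads

  z <- tetrad_counts(rbind(interval1 = c(PD = 1000, TT = 0, NPD = 0)), nd = 0)
  expect_equal(nondisjunction_rate(z)$percent, 0)
  expect_equal(nondisjunction_rate(z)$percent_half_width, 0)

  c15 <- tetrad_counts(rbind(interval1 = c(PD = 1285, TT = 0, NPD = 0)), nd = 15)
  r <- nondisjunction_rate(c15)
  p <- 15 / 1300
  expect_equal(r$percent, 100 * p)
  expect_equal(r$percent_half_width,
               100 * qnorm(0.975) * sqrt(p * (1 - p) / 1300))
})

test_that("strain comparisons pair G tests with exact nondisjunction tests", {
  a <- tetrad_counts(rbind(interval1 = c(PD = 500, TT = 120, NPD = 6),
                           interval2 = c(PD = 580, TT = 44, NPD = 2)), nd = 12)
  same <- compare_strains(a, a)
  expect_equal(same$crossover_tests[[1]]$statistic, 0)
  expect_equal(same$nd_test$p_value, 1)
  expect_equal(same$distance_ratio, c(1, 1))

  # exact test on nd tallies matches the enumeration oracle
  b29 <- tetrad_counts(rbind(interval1 = c(PD = 2000, TT = 480, NPD = 11)),
                       nd = 29)  # n = 2520
  b12 <- tetrad_counts(rbind(interval1 = c(PD = 2020, TT = 470, NPD = 8)),
                       nd = 12)  # n = 2510
  cmp <- compare_strains(b29, b12)
  oracle <- fisher_enum_oracle(matrix(c(29, 12, 2520 - 29, 2510 - 12), 2))
  expect_equal(cmp$nd_test$p_value, oracle)

  # percent-of-wild-type normalization: 7.0 cM mutant vs 11.63 cM reference
  mut <- tetrad_counts(rbind(interval1 = c(PD = 860, TT = 140, NPD = 0)))
  wt <- tetrad_counts(rbind(interval1 = c(PD = 76740, TT = 23260, NPD = 0)))
  expect_equal(perkins_distance(mut)$cM, 7)
  expect_equal(perkins_distance(wt)$cM, 11.63)
  expect_equal(compare_strains(mut, wt)$percent_of_reference[1],
               60.2, tolerance = 5e-3)

  # 2x2 recombinant/parental chromatid variant stays available
  alt <- compare_strains(b29, b12, crossover_table = "spores")
  expect_equal(alt$crossover_tests[[1]]$df, 1L)
})

test_that("per-tetrad TSV round-trips and tallies stay consistent", {
  sim <- simulate_tetrads(500, 12, 4, nd_prob = 0.02, seed = 77)
  tmp <- tempfile(fileext = ".tsv")
  write_tetrads_tsv(sim$patterns, tmp)
  back <- read_tetrads_tsv(tmp)
  expect_equal(unname(as.matrix(back)), unname(as.matrix(sim$patterns)))
  cls <- classify_tetrads(back)
  tc <- tally_tetrads(cls)
  expect_equal(sum(tc$counts[1, ]) + tc$nd + tc$aberrant, 500)
  expect_equal(sum(tc$counts[1, ]), sum(tc$counts[2, ]))
})
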