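test_that("lane peak detection finds band centers at subsample precision", {
  pos <- seq(0, 100, length.out = 1000)
  flat <- data.frame(position = pos, intensity = rep(1, 1000))
  expect_equal(nrow(detect_lane_peaks(flat)), 0)

  # two Gaussian bands, sigma 1% of lane, 10 sigma apart
  centers <- c(45, 55); sig <- 1
  y <- exp(-(pos - centers[1])^2 / (2 * sig^2)) +
       0.8 * exp(-(pos - centers[2])^2 / (2 * sig^2))
  pk <- detect_lane_peaks(data.frame(position = pos, intensity = y),
                          baseline_frac = 0)
  expect_equal(nrow(pk), 2)
  step <- diff(pos)[1]
  expect_lt(max(abs(sort(pk$position) - centers)), step / 2)

  # bands closer than ~2x FWHM merge into one reported peak
  close <- exp(-(pos - 49)^2 / (2 * sig^2)) + exp(-(pos - 51)^2 / (2 * sig^2))
  pk2 <- detect_lane_peaks(data.frame(position = pos, intensity = close),
                           baseline_frac = 0)
  expect_equal(nrow(pk2), 1)
  expect_error(detect_lane_peaks(flat[1:10, ]), "short")
})

test_that("quartic calibration is interpolation-exact and guards monotonicity", {
  mw <- c(20, 35, 50, 70, 95, 120)
  cal <- fit_migration_calibration(mw, quartic_law(mw))
  expect_equal(cal$rms, 0, tolerance = 1e-8)
  expect_equal(coef(cal), c(90, -0.9, 0.004, -1e-5, 1e-8), tolerance = 1e-6)
  # forward prediction reproduces the generating law everywhere in range
  grid <- seq(20, 120, by = 1)
  expect_equal(predict(cal, grid), quartic_law(grid), tolerance = 1e-6)

  expect_error(fit_migration_calibration(mw[1:4], quartic_law(mw[1:4])),
               "at least 5")
  bad_mig <- c(80, 70, 72, 60, 50, 40)  # not strictly decreasing
  expect_error(fit_migration_calibration(mw, bad_mig), "decrease")
})

test_that("calibration inverts to molecular weight within residual error", {
  sim <- simulate_lane_set(make_protein(), sites = c(200, 400),
                           noise_sd = 0.01, seed = 21)
  pk <- detect_lane_peaks(sim$ladder_lane)
  expect_equal(nrow(pk), nrow(sim$ladder))
  cal <- fit_migration_calibration(sort(sim$ladder$mw_kda, decreasing = TRUE),
                                   sort(pk$position))
  # residual RMS below 2% of lane length for a log migration law with noise
  expect_lt(cal$rms, 2)

  # inversion composed with the forward model is the identity
  grid <- seq(min(cal$mw_range), max(cal$mw_range), length.out = 25)
  expect_equal(invert_migration(cal, predict(cal, grid)), grid,
               tolerance = 1e-6)
  # outside the calibrated range -> NA, not extrapolation
  expect_true(is.na(invert_migration(cal, predict(cal, max(grid)) - 50)))

  # leave-one-out on the 60 kDa marker recovers it within 5%
  keep <- sim$ladder$mw_kda != 60
  cal_loo <- fit_migration_calibration(
    sort(sim$ladder$mw_kda[keep], decreasing = TRUE),
    sort(pk$position[rev(keep)]))
  mw60 <- invert_migration(cal_loo, pk$position[rev(sim$ladder$mw_kda == 60)])
  expect_lt(abs(mw60 - 60) / 60, 0.05)
})

test_that("fragment masses map to residues and back consistently", {
  prot <- make_protein()
  fm <- fragment_masses(prot)
  expect_equal(length(fm), 769)
  expect_true(all(diff(fm) > 0))
  expect_equal(fm[1], prot$tag_mass + 18.0153 + fm[2] - fm[1],
               tolerance = 200)  # tag + water dominate the first residue

  mw <- c(20, 35, 50, 70, 95, 120)
  cal <- fit_migration_calibration(mw, quartic_law(mw))

  # a peak exactly at tag + mass(1..150) maps to residue 150
  target <- fm[150] / 1000
  pk <- data.frame(position = predict(cal, target), intensity = 1)
  est <- estimate_cleavage_sites(pk, cal, prot)
  expect_equal(est$residue, 150L)
  expect_gte(est$uncertainty, 5)

  # the full-length band maps to the protein length
  pk_full <- data.frame(position = predict(cal, fm[769] / 1000), intensity = 1)
  expect_equal(estimate_cleavage_sites(pk_full, cal, prot)$residue, 769L)

  # monotone: larger fragment mass never gives a smaller residue
  mws <- seq(25, 95, length.out = 40)
  res <- estimate_cleavage_sites(
    data.frame(position = predict(cal, mws), intensity = 1), cal, prot)$residue
  expect_true(all(diff(res) >= 0))  # heavier fragment, never a smaller residue

  # a peak migrating past the calibrated range is flagged, not mapped
  far <- data.frame(position = predict(cal, 19) + 30, intensity = 1)
  est_far <- estimate_cleavage_sites(far, cal, prot)
  expect_true(est_far$out_of_range)
  expect_true(is.na(est_far$residue))
})

test_that("noiseless lanes round-trip to the true sites", {
  prot <- make_protein()
  sites <- c(180, 260, 430, 600)  # fragments inside the 20-150 kDa ladder
  sim <- simulate_lane_set(prot, sites, noise_sd = 0, seed = 33)
  pk_l <- detect_lane_peaks(sim$ladder_lane, baseline_frac = 0)
  cal <- fit_migration_calibration(sort(sim$ladder$mw_kda, decreasing = TRUE),
                                   sort(pk_l$position))
  pk <- detect_lane_peaks(sim$lane, baseline_frac = 0)
  est <- estimate_cleavage_sites(pk, cal, prot)
  got <- est$residue[!est$out_of_range]
  # quartic approximation of the log law limits accuracy, not noise
  expect_lt(max(site_errors(got, c(sites, 769))), 4)
})

test_that("domain intensity ratios contrast N-terminal and linker contacts", {
  prot <- make_protein()
  linker_only <- data.frame(residue = c(360, 420), intensity = c(2, 1))
  expect_equal(domain_intensity_ratio(linker_only, prot), 0)

  mix <- data.frame(residue = c(200, 300, 400, 450),
                    intensity = c(1, 2, 2, 1))
  expect_equal(domain_intensity_ratio(mix, prot), 1)
  # invariant to uniform rescaling
  mix10 <- transform(mix, intensity = intensity * 10)
  expect_equal(domain_intensity_ratio(mix10, prot), 1)

  nterm_only <- data.frame(residue = c(200, 300), intensity = c(1, 1))
  r <- domain_intensity_ratio(nterm_only, prot)
  expect_true(is.infinite(r) && attr(r, "zero_linker"))

  # ssDNA-like (N-term + linker) vs HJ-like (linker-dominated) profile
  ss <- data.frame(residue = c(214, 282, 362, 400), intensity = c(1, 1, 1, 1))
  hj <- data.frame(residue = c(214, 282, 362, 400), intensity = c(.2, .2, 2, 2))
  expect_gt(domain_intensity_ratio(ss, prot), domain_intensity_ratio(hj, prot))
})

test_that("candidate basic residues are scanned near the cleavage site", {
  bare <- make_protein()  # built without K/R anywhere
  expect_length(select_candidate_residues(bare, 400, 12), 0)

  prot <- make_protein(pin = c(`50` = "K", `55` = "R", `214` = "R",
                               `373` = "R", `419` = "R"))
  expect_equal(unname(select_candidate_residues(prot, 52, 12)), c(50, 55))
  # Mlh1-like: predicted site 214 pairs with the basic residue at 214
  expect_true(214 %in% select_candidate_residues(prot, 214, 12))
  # the widest printed pairings (362 -> R373, 431 -> R419) fit window 12
  expect_true(373 %in% select_candidate_residues(prot, 362, 12))
  expect_true(419 %in% select_candidate_residues(prot, 431, 12))
  expect_error(select_candidate_residues(prot, 1000, 12), "outside")

  # conservation filter drops columns where K/R is not maintained
  ref <- "AAKAARAA"
  aln <- c(`synthetic-protein` = "AAKAARAA",
           sp2 = "AAKAAQAA", sp3 = "AAKAA-AA")
  p2 <- protein_record("synthetic-protein", ref)
  hits <- select_candidate_residues(p2, 4, 4, alignment = aln,
                                    min_conservation = 0.9)
  expect_equal(unname(hits), 3)
})
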