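# Seeded generators emulating every data type the pipeline consumes, each
# returning a machine-readable ground-truth record so the paired estimator can
# be scored with no further inputs. All generators are bit-reproducible under
# a fixed seed.

maybe_seed <- function(seed) if (!is.null(seed)) set.seed(seed)

#' Simulate spore-autonomous fluorescence tetrads
#'
#' Per meiosis: with probability `nd_prob` the tetrad is an MI nondisjunction
#' (two triple-labelled, two dark spores). Otherwise crossover counts per
#' interval are Poisson with mean `2 d / 100` per bivalent (d the map distance
#' in cM; a map distance of d cM per chromatid is d/100 Morgans, and the
#' bivalent as a whole sees twice that), each crossover picks one chromatid
#' from each homolog uniformly and independently (no chromatid or
#' inter-interval interference), and the three markers (red at CEN8, green at
#' ARG4 on homolog 1; blue at THR1 on homolog 2) are propagated through the
#' exchanged chromatids.
#'
#' @param n Number of tetrads.
#' @param d1,d2 True map distances of the CEN8-ARG4 and ARG4-THR1 intervals,
#'   cM.
#' @param nd_prob MI nondisjunction probability.
#' @param seed Optional RNG seed.
#' @return List with `patterns` (data frame spore1..spore4 of RGB flag
#'   strings), `truth` (per-tetrad generative interval types from crossover
#'   parity bookkeeping, plus `nd`), and `params`.
#' @export
simulate_tetrads <- function(n, d1, d2, nd_prob = 0, seed = NULL) {
  if (n < 1 || d1 < 0 || d2 < 0 || nd_prob < 0 || nd_prob > 1)
    stop("invalid simulation parameters")
  maybe_seed(seed)
  nd <- stats::runif(n) < nd_prob
  c1 <- stats::rpois(n, 2 * d1 / 100); c1[nd] <- 0L
  c2 <- stats::rpois(n, 2 * d2 / 100); c2[nd] <- 0L
  # Each spore is a walk along the bivalent starting at one of the four
  # centromeres; every crossover is a transposition of the two original
  # chromatids it joins (one per homolog, chosen uniformly: no chromatid
  # interference), applied in positional order. cur[s] = original chromatid
  # the walk for spore s is on at the current position.
  cur1 <- matrix(rep(1:4, each = n), n, 4L)  # strand at ARG4 (after interval 1)
  cur2 <- cur1                               # strand at THR1 (after interval 2)
  work <- which(!nd & (c1 + c2) > 0L)
  for (t in work) {
    cur <- 1:4
    if (c1[t] > 0L) for (k in seq_len(c1[t])) {
      i <- sample.int(2L, 1L); j <- sample.int(2L, 1L) + 2L
      cur[cur == i | cur == j] <- (i + j) - cur[cur == i | cur == j]
    }
    cur1[t, ] <- cur
    if (c2[t] > 0L) for (k in seq_len(c2[t])) {
      i <- sample.int(2L, 1L); j <- sample.int(2L, 1L) + 2L
      cur[cur == i | cur == j] <- (i + j) - cur[cur == i | cur == j]
    }
    cur2[t, ] <- cur
  }
  hom <- function(chromatid) chromatid > 2L  # FALSE = homolog 1, TRUE = homolog 2
  R <- matrix(rep(c(TRUE, TRUE, FALSE, FALSE), n), n, 4L, byrow = TRUE)
  G <- !hom(cur1)          # green travels with homolog 1's ARG4 segment
  B <- hom(cur2)           # blue with homolog 2's THR1 segment
  type_of_k <- function(k) c("PD", NA, "TT", NA, "NPD")[k + 1L]
  truth <- data.frame(
    interval1 = type_of_k(rowSums(hom(cur1) != hom(col(cur1)))),
    interval2 = type_of_k(rowSums(hom(cur2) != hom(cur1))),
    nd = nd)
  truth$interval1[nd] <- NA; truth$interval2[nd] <- NA
  # nondisjunction: both homologs to one pole, sisters split at MII
  R[nd, ] <- matrix(rep(c(TRUE, TRUE, FALSE, FALSE), sum(nd)),
                    ncol = 4L, byrow = TRUE)
  G[nd, ] <- R[nd, ]; B[nd, ] <- R[nd, ]
  flag <- function(m, ch) ifelse(m, ch, "-")
  pat <- lapply(1:4, function(j)
    paste0(flag(R[, j], "R"), flag(G[, j], "G"), flag(B[, j], "B")))
  names(pat) <- paste0("spore", 1:4)
  list(patterns = as.data.frame(pat), truth = truth,
       params = list(n = n, d1 = d1, d2 = d2, nd_prob = nd_prob))
}

#' Simulate a cleavage lane set with marker ladder
#'
#' Forward model: fragment mass = tag + cumulative residue mass (+ water);
#' band centers follow a smooth monotone migration law, by default
#' migration = a - b ln(MW) -- deliberately not a quartic, so the quartic
#' calibration is exercised as an approximation, as with real gels. Bands are
#' Gaussian; i.i.d. Gaussian noise is added on top.
#'
#' @param protein A [protein_record()].
#' @param sites True cleavage residue positions (within the sequence).
#' @param intensities Band intensities, recycled to `length(sites)`.
#' @param ladder_mw Marker molecular weights, kDa (>= 5).
#' @param lane_length Lane length (arbitrary units, e.g. mm).
#' @param n_samples Samples per trace.
#' @param band_sigma Gaussian band SD as a fraction of lane length.
#' @param noise_sd Additive noise SD as a fraction of the tallest band.
#' @param include_full_length Add the uncleaved full-length band.
#' @param seed Optional RNG seed.
#' @return List: `lane` and `ladder_lane` (two-column traces), `ladder`
#'   (marker mw and true migration), `truth` (site, fragment mw, migration,
#'   intensity), and the migration-law constants.
#' @export
simulate_lane_set <- function(protein, sites, intensities = 1,
                              ladder_mw = c(20, 30, 40, 50, 60, 80, 100, 120, 150),
                              lane_length = 100, n_samples = 1500,
                              band_sigma = 0.004, noise_sd = 0.01,
                              include_full_length = TRUE, seed = NULL) {
  if (length(ladder_mw) < 5L) stop("need at least 5 ladder markers")
  if (length(sites) && (any(sites < 1) || any(sites > protein$length)))
    stop("cleavage sites outside the protein sequence")
  if (noise_sd < 0) stop("noise SD must be non-negative")
  maybe_seed(seed)
  b <- 0.84 * lane_length / log(max(ladder_mw) / min(ladder_mw))
  a <- 0.08 * lane_length + b * log(max(ladder_mw))
  migrate <- function(mw_kda) a - b * log(mw_kda)
  fmass <- fragment_masses(protein) / 1000  # kDa
  mw <- fmass[sites]
  intens <- rep_len(intensities, length(sites))
  if (include_full_length) {
    mw <- c(mw, fmass[protein$length])
    intens <- c(intens, max(intens, 1))
    sites_out <- c(sites, protein$length)
  } else sites_out <- sites
  pos <- seq(0, lane_length, length.out = n_samples)
  sig <- band_sigma * lane_length
  trace_of <- function(centers, heights) {
    y <- numeric(n_samples)
    for (i in seq_along(centers))
      y <- y + heights[i] * exp(-(pos - centers[i])^2 / (2 * sig^2))
    y + stats::rnorm(n_samples, 0, noise_sd * max(heights))
  }
  cent <- migrate(mw)
  lane <- data.frame(position = pos, intensity = trace_of(cent, intens))
  lad_cent <- migrate(ladder_mw)
  ladder_lane <- data.frame(position = pos,
                            intensity = trace_of(lad_cent,
                                                 rep(1, length(ladder_mw))))
  list(lane = lane, ladder_lane = ladder_lane,
       ladder = data.frame(mw_kda = ladder_mw, migration = lad_cent),
       truth = data.frame(site = sites_out, mw_kda = mw,
                          migration = cent, intensity = intens),
       law = c(a = a, b = b))
}

#' Simulate an AFM field of monomer- and dimer-sized particles
#'
#' Particles are Gaussian caps scaled so the analytic cap volume
#' (2 pi H sigma^2) equals the drawn true volume, placed by rejection so no
#' two caps overlap, on a flat surface plus an optional tilted plane and
#' Gaussian roughness.
#'
#' @param n_particles Number of particles to place.
#' @param dimer_fraction Probability a particle is dimer-sized.
#' @param monomer_volume,dimer_volume Class mean true volumes, nm^3.
#' @param volume_cv Coefficient of variation of true volumes within a class.
#' @param grid Image size in pixels (square).
#' @param pixel_size_nm Lateral pixel size, nm.
#' @param cap_sigma_nm Lateral SD of the Gaussian caps, nm.
#' @param noise_sd_nm Surface roughness SD, nm.
#' @param tilt Plane tilt added across the field, nm per pixel, to exercise
#'   background subtraction.
#' @param seed Optional RNG seed.
#' @return List with `map` (a [height_map()]) and `truth` (row, col, volume,
#'   class per particle).
#' @export
simulate_afm_field <- function(n_particles, dimer_fraction = 1 / 3,
                               monomer_volume = 100, dimer_volume = 250,
                               volume_cv = 0.12, grid = 512L,
                               pixel_size_nm = 2, cap_sigma_nm = 7,
                               noise_sd_nm = 0.05, tilt = 0, seed = NULL) {
  maybe_seed(seed)
  s_px <- cap_sigma_nm / pixel_size_nm
  margin <- ceiling(4 * s_px) + 2L
  if (2L * margin >= grid) stop("grid too small for the cap size")
  min_sep <- 8 * s_px
  centers <- matrix(numeric(0), 0L, 2L)
  tries <- 0L
  while (nrow(centers) < n_particles) {
    tries <- tries + 1L
    if (tries > 200L * max(n_particles, 1L))
      stop("cannot place particles without overlap; density infeasible")
    p <- stats::runif(2, margin + 1, grid - margin)
    if (nrow(centers) == 0L ||
        min(sqrt(rowSums((centers - matrix(p, nrow(centers), 2L,
                                           byrow = TRUE))^2))) > min_sep)
      centers <- rbind(centers, p)
  }
  is_dimer <- stats::runif(n_particles) < dimer_fraction
  mu <- ifelse(is_dimer, dimer_volume, monomer_volume)
  vol <- stats::rnorm(n_particles, mu, volume_cv * mu)
  vol <- pmax(vol, 1)
  h <- matrix(stats::rnorm(grid * grid, 0, noise_sd_nm), grid, grid)
  if (tilt != 0) h <- h + tilt * row(h)
  for (i in seq_len(n_particles)) {
    H <- vol[i] / (2 * pi * cap_sigma_nm^2)  # analytic Gaussian cap volume
    r0 <- centers[i, 1L]; c0 <- centers[i, 2L]
    rr <- max(1L, floor(r0 - 4 * s_px)):min(grid, ceiling(r0 + 4 * s_px))
    cc <- max(1L, floor(c0 - 4 * s_px)):min(grid, ceiling(c0 + 4 * s_px))
    d2 <- outer((rr - r0)^2, (cc - c0)^2, "+")
    h[rr, cc] <- h[rr, cc] + H * exp(-d2 / (2 * s_px^2))
  }
  list(map = height_map(h, pixel_size_nm),
       truth = data.frame(row = centers[, 1L], col = centers[, 2L],
                          volume = vol,
                          class = ifelse(is_dimer, "dimer", "monomer")))
}

#' Simulate a titration series from a Hill or Michaelis-Menten model
#'
#' Exact model curve plus i.i.d. Gaussian noise; fraction responses are
#' truncated to `[0, 1]`.
#'
#' @param x Concentration grid (>= 4 points).
#' @param model `"hill"` or `"mm"`.
#' @param params For `"hill"`: `list(K=, n=)`; for `"mm"`:
#'   `list(vmax=, km=)`.
#' @param noise_sd Gaussian noise SD (on the response scale).
#' @param response For `"hill"`, return the `"unbound"` (default) or
#'   `"bound"` fraction.
#' @param seed Optional RNG seed.
#' @return Data frame `x`, `y` with the noiseless curve in attribute
#'   `"truth"` and the generative parameters in attribute `"params"`.
#' @export
simulate_titration <- function(x, model = c("hill", "mm"), params,
                               noise_sd = 0, response = c("unbound", "bound"),
                               seed = NULL) {
  model <- match.arg(model); response <- match.arg(response)
  if (length(x) < 4L) stop("need at least 4 concentrations")
  if (noise_sd < 0) stop("noise SD must be non-negative")
  maybe_seed(seed)
  mu <- if (model == "hill") {
    f <- hill_bound(x, params$K, params$n)
    if (response == "unbound") 1 - f else f
  } else params$vmax * x / (params$km + x)
  y <- mu + stats::rnorm(length(x), 0, noise_sd)
  if (model == "hill") y <- pmin(1, pmax(0, y))
  else y <- pmax(0, y)
  structure(data.frame(x = x, y = y), truth = mu, params = params)
}

#' Simulate a fluctuation-style reversion assay
#'
#' Revertant counts per culture are Poisson with mean `frequency * cfu`
#' (no Luria-Delbruck jackpot modelling; the assay reports frequencies, not
#' mutation rates).
#'
#' @param frequency True per-cell reversion frequency in `[0, 1]`.
#' @param cfu Colony-forming units plated per culture (scalar or vector).
#' @param cultures Number of cultures (ignored when `cfu` is a vector).
#' @param seed Optional RNG seed.
#' @return Data frame `revertants`, `cfu` with attribute `"frequency"`.
#' @export
simulate_reversion_assay <- function(frequency, cfu, cultures = length(cfu),
                                     seed = NULL) {
  if (frequency < 0 || frequency > 1) stop("frequency must be in [0, 1]")
  if (any(cfu <= 0)) stop("cfu must be positive")
  maybe_seed(seed)
  cfu <- rep_len(cfu, cultures)
  structure(data.frame(revertants = stats::rpois(cultures, frequency * cfu),
                       cfu = cfu),
            frequency = frequency)
}
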