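# Mapping hydroxyl-radical cleavage fragments from western-blot lane traces to
# protein residue coordinates. Fragment sizes are read off a quartic calibration
# of migration distance against molecular weight fitted to a marker ladder;
# because the tag sits at the N terminus, detected fragments are N-terminal
# prefixes and a fragment mass converts to a residue index through the
# cumulative average residue mass of the actual sequence.

# Average (not monoisotopic) residue masses, Da; water added once per chain.
RESIDUE_MASS <- c(
  A = 71.0788, R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0519, H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782, T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326)
WATER_MASS <- 18.0153

#' Protein record with domain annotations
#'
#' @param id Identifier.
#' @param sequence Amino-acid sequence (single string, standard one-letter code).
#' @param tag_mass Mass of the N-terminal tag, Da.
#' @param domains Named list of `c(start, end)` residue intervals (e.g.
#'   `nterm`, `linker`, `cterm`) tiling `[1, nchar(sequence)]` without overlap.
#' @return A `protein_record`.
#' @export
protein_record <- function(id, sequence, tag_mass = 0,
                           domains = NULL) {
  sequence <- toupper(gsub("\\s", "", sequence))
  if (nchar(sequence) == 0L) stop("empty sequence")
  aa <- strsplit(sequence, "")[[1L]]
  if (!all(aa %in% names(RESIDUE_MASS)))
    stop("sequence contains non-standard residues: ",
         paste(unique(aa[!aa %in% names(RESIDUE_MASS)]), collapse = ","))
  L <- length(aa)
  if (!is.null(domains)) {
    iv <- do.call(rbind, domains)
    iv <- iv[order(iv[, 1L]), , drop = FALSE]
    if (iv[1L, 1L] != 1L || iv[nrow(iv), 2L] != L ||
        (nrow(iv) > 1L && any(iv[-1L, 1L] != iv[-nrow(iv), 2L] + 1L)))
      stop("domains must tile [1, protein length] without gaps or overlap")
  }
  structure(list(id = id, sequence = sequence, residues = aa,
                 tag_mass = tag_mass, domains = domains, length = L),
            class = "protein_record")
}

#' @export
print.protein_record <- function(x, ...) {
  cat(sprintf("protein %s: %d aa, tag %.0f Da, full-length %.1f kDa\n",
              x$id, x$length, x$tag_mass,
              fragment_masses(x)[x$length] / 1000))
  if (!is.null(x$domains))
    for (d in names(x$domains))
      cat(sprintf("  %s: %d-%d\n", d, x$domains[[d]][1L], x$domains[[d]][2L]))
  invisible(x)
}

#' Cumulative N-terminal fragment masses (Da)
#'
#' `fragment_masses(p)[k]` is the mass of tag + residues 1..k + water.
#' @param protein A [protein_record()].
#' @return Numeric vector of length `protein$length`.
#' @export
fragment_masses <- function(protein) {
  protein$tag_mass + WATER_MASS + cumsum(RESIDUE_MASS[protein$residues])
}

domain_of <- function(protein, residue) {
  if (is.null(protein$domains)) return(rep(NA_character_, length(residue)))
  out <- rep(NA_character_, length(residue))
  for (d in names(protein$domains)) {
    iv <- protein$domains[[d]]
    out[residue >= iv[1L] & residue <= iv[2L]] <- d
  }
  out
}

#' Read a protein record from FASTA plus a JSON domain annotation
#'
#' @param fasta Path to a FASTA file (first record is used).
#' @param domains_json Path to JSON like
#'   `{"tag_mass": 5000, "domains": {"nterm": [1,340], ...}}`; optional.
#' @export
read_protein_record <- function(fasta, domains_json = NULL) {
  seqs <- Biostrings::readAAStringSet(fasta)
  if (length(seqs) == 0L) stop("no sequences in ", fasta)
  tag <- 0; dom <- NULL
  if (!is.null(domains_json)) {
    meta <- jsonlite::read_json(domains_json, simplifyVector = TRUE)
    if (!is.null(meta$tag_mass)) tag <- meta$tag_mass
    if (!is.null(meta$domains)) dom <- lapply(meta$domains, as.numeric)
  }
  protein_record(names(seqs)[1L], as.character(seqs[[1L]]),
                 tag_mass = tag, domains = dom)
}

#' Detect bands in a lane intensity trace
#'
#' Baseline (running-median) subtraction, Savitzky-Golay smoothing, local
#' maxima above a prominence threshold relative to the tallest peak, and
#' subsample peak centers by local quadratic interpolation.
#'
#' @param profile Data frame with columns `position` (strictly increasing)
#'   and `intensity`.
#' @param smooth_frac Smoothing window as a fraction of the trace length.
#' @param prominence Minimum peak height relative to the tallest peak.
#' @param baseline_frac Running-median window (fraction of trace length) for
#'   baseline estimation; 0 disables baseline subtraction.
#' @return Data frame with columns `position`, `intensity` (one row per peak,
#'   ordered by position); zero rows for flat or empty traces.
#' @export
detect_lane_peaks <- function(profile, smooth_frac = 0.005, prominence = 0.05,
                              baseline_frac = 0.25) {
  if (smooth_frac <= 0 || prominence <= 0) stop("settings must be positive")
  x <- profile$position; y <- profile$intensity
  n <- length(y)
  if (n < 50L) stop("trace too short (< 50 samples)")
  if (any(diff(x) <= 0)) stop("positions must be strictly increasing")
  if (baseline_frac > 0) {
    k <- max(3L, 2L * floor(baseline_frac * n / 2) + 1L)
    y <- y - stats::runmed(y, k)
  }
  w <- max(5L, 2L * floor(smooth_frac * n / 2) + 1L)
  ys <- signal::sgolayfilt(y, p = 2, n = w)
  if (max(ys) <= 0 || stats::sd(ys) < 1e-12 * max(abs(ys), 1))
    return(data.frame(position = numeric(0), intensity = numeric(0)))
  i <- 2:(n - 1L)
  is_max <- ys[i] > ys[i - 1L] & ys[i] >= ys[i + 1L]
  cand <- i[is_max & ys[i] >= prominence * max(ys)]
  if (length(cand) == 0L)
    return(data.frame(position = numeric(0), intensity = numeric(0)))
  pos <- vapply(cand, function(j) {
    # quadratic through the three points around the discrete maximum
    denom <- ys[j - 1L] - 2 * ys[j] + ys[j + 1L]
    if (denom >= 0) return(x[j])
    delta <- 0.5 * (ys[j - 1L] - ys[j + 1L]) / denom
    x[j] + delta * (x[j + 1L] - x[j - 1L]) / 2
  }, numeric(1))
  data.frame(position = pos, intensity = ys[cand])
}

#' Fit the quartic migration-versus-molecular-weight calibration
#'
#' Least-squares fourth-order polynomial of migration distance as a function
#' of molecular weight, fitted to a marker ladder. The fit is rejected unless
#' it is strictly monotone (decreasing migration with increasing mass) over
#' the marker range, since an unconstrained quartic can oscillate.
#'
#' @param mw Marker molecular weights, kDa (>= 5 markers).
#' @param migration Detected marker migration positions (same units as lane
#'   traces).
#' @return A `migration_calibration`: coefficients (degree 0..4), `mw_range`,
#'   `rms` residual, with [predict()][predict.migration_calibration] and
#'   [invert_migration()] support.
#' @export
fit_migration_calibration <- function(mw, migration) {
  if (length(mw) < 5L) stop("need at least 5 markers for a quartic fit")
  if (length(mw) != length(migration)) stop("mw and migration lengths differ")
  o <- order(mw)
  mw <- mw[o]; migration <- migration[o]
  if (any(diff(migration) >= 0))
    stop("marker migration must strictly decrease with molecular weight")
  fit <- stats::lm(migration ~ stats::poly(mw, 4, raw = TRUE))
  cf <- unname(stats::coef(fit))
  rng <- range(mw)
  grid <- seq(rng[1L], rng[2L], length.out = 512L)
  dmig <- cf[2L] + 2 * cf[3L] * grid + 3 * cf[4L] * grid^2 + 4 * cf[5L] * grid^3
  if (any(dmig >= 0))
    stop("calibration is non-monotone over the marker range (derivative ",
         "changes sign near MW ~", signif(grid[which(dmig >= 0)[1L]], 3),
         " kDa); check the ladder assignment")
  structure(list(coefficients = cf, mw_range = rng,
                 rms = sqrt(mean(stats::residuals(fit)^2)),
                 markers = data.frame(mw = mw, migration = migration)),
            class = "migration_calibration")
}

#' @export
print.migration_calibration <- function(x, ...) {
  cat(sprintf(
    "quartic migration calibration: %d markers, %.3g-%.3g kDa, residual RMS %.3g\n",
    nrow(x$markers), x$mw_range[1L], x$mw_range[2L], x$rms))
  invisible(x)
}

#' @export
coef.migration_calibration <- function(object, ...) object$coefficients

#' Predict migration from molecular weight
#' @param object A `migration_calibration`.
#' @param mw Molecular weights, kDa.
#' @param ... Ignored.
#' @export
predict.migration_calibration <- function(object, mw, ...) {
  cf <- object$coefficients
  cf[1L] + cf[2L] * mw + cf[3L] * mw^2 + cf[4L] * mw^3 + cf[5L] * mw^4
}

#' Invert the calibration: migration position to molecular weight
#'
#' Numerical (bisection) inversion of the monotone quartic over the marker
#' range.
#'
#' @param calibration A `migration_calibration`.
#' @param migration Migration positions.
#' @return Molecular weights in kDa; `NA` outside the calibrated range.
#' @export
invert_migration <- function(calibration, migration) {
  rng <- calibration$mw_range
  lim <- sort(predict(calibration, rng))  # migration decreasing in MW
  vapply(migration, function(m) {
    if (m < lim[1L] || m > lim[2L]) return(NA_real_)
    stats::uniroot(function(w) predict(calibration, w) - m,
                   interval = rng, tol = 1e-9)$root
  }, numeric(1))
}

#' Map detected peaks to protein cleavage sites
#'
#' Each peak's migration is inverted to a fragment molecular weight, then to
#' the residue index whose cumulative N-terminal prefix mass (tag + residues
#' 1..k + water) is nearest. Uncertainty propagates the calibration residual
#' RMS through the local calibration slope into residues and is floored at 5
#' residues, the assay's stated precision class.
#'
#' @param peaks Data frame from [detect_lane_peaks()].
#' @param calibration A [fit_migration_calibration()] result.
#' @param protein A [protein_record()].
#' @return Data frame of cleavage sites: `mw_kda`, `residue`, `uncertainty`,
#'   `intensity`, `domain`, `out_of_range`.
#' @export
estimate_cleavage_sites <- function(peaks, calibration, protein) {
  fmass <- fragment_masses(protein)  # Da
  mw <- invert_migration(calibration, peaks$position)
  res <- rep(NA_integer_, length(mw))
  unc <- rep(NA_real_, length(mw))
  cf <- calibration$coefficients
  for (i in seq_along(mw)) {
    if (is.na(mw[i])) next
    k <- which.min(abs(fmass - mw[i] * 1000))
    res[i] <- k
    slope <- abs(cf[2L] + 2 * cf[3L] * mw[i] + 3 * cf[4L] * mw[i]^2 +
                   4 * cf[5L] * mw[i]^3)  # migration units per kDa
    dmw_da <- 1000 * calibration$rms / max(slope, .Machine$double.eps)
    local_mass <- mean(RESIDUE_MASS[protein$residues[
      max(1L, k - 10L):min(protein$length, k + 10L)]])
    unc[i] <- max(5, dmw_da / local_mass)
  }
  data.frame(mw_kda = mw, residue = res, uncertainty = unc,
             intensity = peaks$intensity,
             domain = domain_of(protein, res),
             out_of_range = is.na(mw))
}

#' Ratio of N-terminal-domain to linker cleavage intensity
#'
#' Summed intensity of sites mapping to the N-terminal domain divided by the
#' summed intensity of sites mapping to the linker; sites elsewhere are
#' ignored. A larger ratio means contacts concentrate in the ATPase domain, a
#' smaller one that they concentrate in the linker.
#'
#' @param sites Data frame from [estimate_cleavage_sites()].
#' @param protein A [protein_record()] with `nterm` and `linker` domains.
#' @param nterm,linker Domain names, defaults `"nterm"` and `"linker"`.
#' @return Scalar ratio; `Inf` with attribute `zero_linker = TRUE` when no
#'   linker intensity is present.
#' @export
domain_intensity_ratio <- function(sites, protein,
                                   nterm = "nterm", linker = "linker") {
  dm <- domain_of(protein, sites$residue)
  num <- sum(sites$intensity[dm %in% nterm], na.rm = TRUE)
  den <- sum(sites$intensity[dm %in% linker], na.rm = TRUE)
  if (num + den == 0) stop("no cleavage intensity in either domain")
  if (den == 0) return(structure(Inf, zero_linker = TRUE))
  num / den
}

#' Candidate basic residues near a cleavage site
#'
#' All lysine/arginine positions within `window` residues of the predicted
#' cleavage site. If a multiple alignment is supplied (named character vector
#' of equal-length aligned sequences including the reference), candidates are
#' kept only when the fraction of sequences with K or R in that column meets
#' `min_conservation`.
#'
#' @param protein A [protein_record()].
#' @param site Predicted cleavage residue index.
#' @param window Half-width of the scan window, residues.
#' @param alignment Optional named character vector of aligned sequences; the
#'   entry named `protein$id` (or the first entry) is the reference row.
#' @param min_conservation Minimum K/R column conservation fraction.
#' @return Integer vector of residue positions (possibly empty), named with
#'   the residue letters.
#' @export
select_candidate_residues <- function(protein, site, window = 12,
                                      alignment = NULL,
                                      min_conservation = 0.7) {
  if (site < 1L || site > protein$length) stop("site outside the sequence")
  if (window <= 0) stop("window must be positive")
  lo <- max(1L, site - window); hi <- min(protein$length, site + window)
  idx <- lo:hi
  hits <- idx[protein$residues[idx] %in% c("K", "R")]
  if (!is.null(alignment) && length(hits)) {
    ref_name <- if (protein$id %in% names(alignment)) protein$id
                else names(alignment)[1L]
    rows <- do.call(rbind, strsplit(toupper(alignment), ""))
    ref <- rows[match(ref_name, names(alignment)), ]
    col_of <- cumsum(ref != "-")  # alignment column -> ungapped ref position
    keep <- vapply(hits, function(h) {
      col <- which(col_of == h & ref != "-")[1L]
      mean(rows[, col] %in% c("K", "R")) >= min_conservation
    }, logical(1))
    hits <- hits[keep]
  }
  stats::setNames(hits, protein$residues[hits])
}

#' Write cleavage sites to TSV
#' @param sites Data frame from [estimate_cleavage_sites()].
#' @param path Output file.
#' @export
write_sites_tsv <- function(sites, path) {
  utils::write.table(sites, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a two-column lane trace CSV
#' @param path CSV with columns `position`, `intensity`.
#' @export
read_lane_csv <- function(path) {
  d <- utils::read.csv(path)
  if (!all(c("position", "intensity") %in% names(d)))
    stop("lane CSV needs columns position,intensity")
  d
}

#' Read a marker ladder definition (CSV or JSON)
#' @param path CSV with columns `mw_kda[,label]`, or JSON array of objects.
#' @return Data frame with columns `mw_kda` and `label`.
#' @export
read_ladder <- function(path) {
  d <- if (grepl("\\.json$", path, ignore.case = TRUE))
    as.data.frame(jsonlite::read_json(path, simplifyVector = TRUE))
  else utils::read.csv(path)
  if (!"mw_kda" %in% names(d)) stop("ladder needs an mw_kda column")
  if (!"label" %in% names(d)) d$label <- paste0(d$mw_kda, "kDa")
  d[order(-d$mw_kda), ]
}
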