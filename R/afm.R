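# AFM particle volumetrics: background-corrected particle segmentation on
# height maps, per-particle volume integration, oligomer classification by
# volume windows, and the hydration-corrected predicted volume of a protein of
# known mass.

#' Predicted hydrated protein volume from molecular weight
#'
#' V_c = (M0 / N0) (V1 + d V2), with M0 the molecular weight, N0 Avogadro's
#' number, V1 and V2 the specific volumes of protein and water and d the
#' hydration extent; the cm^3 result is returned in nm^3. Linear in M0.
#'
#' @param mw_da Molecular weight in Da (use `mw_kda * 1000` for kDa).
#' @param v1 Protein specific volume, cm^3/g (default 0.74).
#' @param v2 Water specific volume, cm^3/g (default 1).
#' @param hydration Hydration extent, g water per g protein (default 0.4).
#' @return Predicted volume in nm^3.
#' @examples
#' predicted_volume(175e3)  # the 175 kDa heterodimer
#' @export
predicted_volume <- function(mw_da, v1 = 0.74, v2 = 1, hydration = 0.4) {
  if (any(mw_da < 0)) stop("molecular weight must be non-negative")
  if (v1 <= 0 || v2 <= 0 || hydration < 0) stop("invalid volume constants")
  avogadro <- 6.02214076e23
  (mw_da / avogadro) * (v1 + hydration * v2) * 1e21  # cm^3 -> nm^3
}

#' Height map container
#'
#' @param heights Numeric matrix of heights in nm.
#' @param pixel_size_nm Lateral pixel size, nm per pixel.
#' @export
height_map <- function(heights, pixel_size_nm) {
  m <- as.matrix(heights)
  if (!is.numeric(m)) stop("heights must be numeric")
  if (is.null(pixel_size_nm) || pixel_size_nm <= 0)
    stop("pixel size must be positive")
  structure(list(heights = m, pixel_size_nm = pixel_size_nm),
            class = "height_map")
}

#' @export
print.height_map <- function(x, ...) {
  cat(sprintf("height map %d x %d px, %.3g nm/px (%.3g x %.3g nm)\n",
              nrow(x$heights), ncol(x$heights), x$pixel_size_nm,
              nrow(x$heights) * x$pixel_size_nm,
              ncol(x$heights) * x$pixel_size_nm))
  invisible(x)
}

#' Read a height map from TIFF or a plain numeric matrix file
#'
#' For plain-text matrices a JSON sidecar `<file>.json` holding
#' `{"pixel_size_nm": ...}` is read when `pixel_size_nm` is not given.
#'
#' @param path TIFF (nm-scaled values) or whitespace-delimited matrix file.
#' @param pixel_size_nm Pixel size; overrides any sidecar.
#' @export
read_heightmap <- function(path, pixel_size_nm = NULL) {
  if (is.null(pixel_size_nm)) {
    sidecar <- paste0(path, ".json")
    if (file.exists(sidecar))
      pixel_size_nm <- jsonlite::read_json(sidecar)$pixel_size_nm
  }
  m <- if (grepl("\\.tiff?$", path, ignore.case = TRUE))
    tiff::readTIFF(path, as.is = TRUE)
  else as.matrix(utils::read.table(path))
  dimnames(m) <- NULL
  height_map(m, pixel_size_nm)
}

# 8-connected component labelling: EBImage::bwlabel (4-connected) followed by
# a union-find merge of labels that touch diagonally.
label_components8 <- function(mask) {
  lab <- EBImage::bwlabel(mask)
  nlab <- max(lab)
  if (nlab < 2L) return(lab)
  parent <- seq_len(nlab)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  nr <- nrow(lab); nc <- ncol(lab)
  for (shift in list(c(1L, 1L), c(1L, -1L))) {
    a <- lab[seq_len(nr - 1L), if (shift[2L] > 0) seq_len(nc - 1L) else 2L:nc]
    b <- lab[2L:nr, if (shift[2L] > 0) 2L:nc else seq_len(nc - 1L)]
    touch <- a > 0 & b > 0 & a != b
    if (any(touch)) {
      pairs <- unique(cbind(pmin(a[touch], b[touch]),
                            pmax(a[touch], b[touch])))
      for (r in seq_len(nrow(pairs))) {
        ra <- find(pairs[r, 1L]); rb <- find(pairs[r, 2L])
        if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
      }
    }
  }
  root <- vapply(seq_len(nlab), find, integer(1))
  relab <- match(root, sort(unique(root)))
  out <- lab
  out[lab > 0] <- relab[lab[lab > 0]]
  out
}

# Least-squares plane fit over the grid, returned as fitted values.
fit_background_plane <- function(h) {
  nr <- nrow(h); nc <- ncol(h)
  r <- rep(seq_len(nr), times = nc); c <- rep(seq_len(nc), each = nr)
  cf <- stats::lm.fit(cbind(1, r, c), as.vector(h))$coefficients
  matrix(cf[1L] + cf[2L] * r + cf[3L] * c, nr, nc)
}

#' Segment particles from an AFM height map
#'
#' Background is removed as a least-squares plane plus the median of the
#' residual; pixels above `threshold_k` robust SDs (MAD) of the residual
#' background are grouped by 8-connectivity. Particles touching the image
#' edge are flagged and excluded from downstream summaries.
#'
#' @param map A [height_map()].
#' @param threshold_k Height threshold in background robust SDs (default 3).
#' @param min_pixels Discard components smaller than this (speckle guard).
#' @param grow_px Dilate each particle's integration region by this many
#'   pixels beyond the threshold mask so sub-threshold skirts are included in
#'   the volume integral (centroids and areas still use the core mask).
#' @return A `particle_set`: data frame `particles` with `id`, `row`, `col`
#'   (centroid, px), `area_nm2`, `volume_nm3`, `max_height_nm`, `edge`; plus
#'   the label matrix and corrected heights as attributes for reuse.
#' @export
segment_particles <- function(map, threshold_k = 3, min_pixels = 4L,
                              grow_px = 3L) {
  h <- map$heights
  if (nrow(h) < 64L || ncol(h) < 64L) stop("height map smaller than 64 x 64")
  corr <- h - fit_background_plane(h)
  corr <- corr - stats::median(corr)
  sdev <- stats::mad(corr)
  # relative floor keeps essentially noise-free images from thresholding at
  # numerical background ripple
  thr <- max(threshold_k * sdev, 0.01 * max(corr), .Machine$double.eps)
  mask <- corr > thr
  empty <- data.frame(id = integer(0), row = numeric(0), col = numeric(0),
                      area_nm2 = numeric(0), volume_nm3 = numeric(0),
                      max_height_nm = numeric(0), edge = logical(0))
  if (!any(mask))
    return(structure(list(particles = empty, pixel_size_nm = map$pixel_size_nm,
                          labels = matrix(0L, nrow(h), ncol(h)),
                          corrected = corr),
                     class = "particle_set"))
  lab <- label_components8(mask)
  px_area <- map$pixel_size_nm^2
  ids <- seq_len(max(lab))
  # grown region for volume integration (max filter keeps labels; core mask
  # takes precedence where regions meet)
  labg <- if (grow_px > 0L) {
    g <- EBImage::dilate(lab, EBImage::makeBrush(2L * grow_px + 1L, "disc"))
    g[lab > 0] <- lab[lab > 0]
    g
  } else lab
  idx <- which(lab > 0, arr.ind = TRUE)
  labv <- lab[lab > 0]
  rows <- tapply(idx[, 1L], labv, mean)
  cols <- tapply(idx[, 2L], labv, mean)
  npx <- tabulate(labv, nbins = length(ids))
  hmax <- tapply(corr[lab > 0], labv, max)
  idxg <- which(labg > 0, arr.ind = TRUE)
  labgv <- labg[labg > 0]
  vol <- tapply(corr[labg > 0], labgv, sum) * px_area
  touches <- tapply(seq_along(labgv), labgv, function(i) {
    any(idxg[i, 1L] %in% c(1L, nrow(h))) || any(idxg[i, 2L] %in% c(1L, ncol(h)))
  })
  d <- data.frame(id = ids, row = as.numeric(rows), col = as.numeric(cols),
                  area_nm2 = npx * px_area, volume_nm3 = as.numeric(vol),
                  max_height_nm = as.numeric(hmax), edge = as.logical(touches))
  d <- d[npx >= min_pixels, , drop = FALSE]
  rownames(d) <- NULL
  structure(list(particles = d, pixel_size_nm = map$pixel_size_nm,
                 labels = lab, corrected = corr),
            class = "particle_set")
}

#' @export
print.particle_set <- function(x, ...) {
  cat(sprintf("%d particles (%d at image edge)\n",
              nrow(x$particles), sum(x$particles$edge)))
  invisible(x)
}

#' Classify particle volumes into oligomer classes
#'
#' Dimers occupy the closed window `[dimer_window[1], dimer_window[2]]` nm^3
#' (both bounds inclusive); volumes between `monomer_floor` and the dimer
#' window are monomers; above the window, multimers; below the floor,
#' sub-threshold speckles. Summary fractions are computed over non-edge
#' particles at or above the monomer floor.
#'
#' @param particles A `particle_set` or its `particles` data frame.
#' @param dimer_window Inclusive dimer volume window, nm^3 (default
#'   `c(170, 350)`).
#' @param monomer_floor Minimum volume counted as a particle, nm^3.
#' @return A `particle_classification`: the particle table with a `class`
#'   column, plus `fractions` (named proportions among classified non-edge
#'   particles) and `n`.
#' @export
measure_and_classify <- function(particles, dimer_window = c(170, 350),
                                 monomer_floor = 40) {
  d <- if (inherits(particles, "particle_set")) particles$particles
       else particles
  if (is.null(d$volume_nm3)) stop("particles lack volumes; run segment_particles")
  v <- d$volume_nm3
  cl <- ifelse(v < monomer_floor, "sub-threshold",
        ifelse(v < dimer_window[1L], "monomer",
        ifelse(v <= dimer_window[2L], "dimer", "multimer")))
  d$class <- factor(cl, levels = c("sub-threshold", "monomer", "dimer",
                                   "multimer"))
  keep <- !d$edge & d$class != "sub-threshold"
  frac <- prop.table(table(droplevels(factor(
    d$class[keep], levels = c("monomer", "dimer", "multimer")))))
  structure(list(particles = d, fractions = c(frac), n = sum(keep),
                 dimer_window = dimer_window, monomer_floor = monomer_floor),
            class = "particle_classification")
}

#' @export
print.particle_classification <- function(x, ...) {
  cat(sprintf("%d classified particles (dimer window [%g, %g] nm^3)\n",
              x$n, x$dimer_window[1L], x$dimer_window[2L]))
  print(round(x$fractions, 3))
  invisible(x)
}

#' Compare dimer configuration distributions between conditions
#'
#' G test on the condition-by-configuration count table (e.g. extended,
#' one-arm folded, semi-condensed, condensed dimers with and without ATP).
#' Configurations unobserved in both conditions are dropped with a warning,
#' reducing the degrees of freedom.
#'
#' @param a,b Named count vectors over the same configurations.
#' @return An `assay_test` from [g_test()].
#' @export
compare_configurations <- function(a, b) {
  if (length(a) != length(b)) stop("conditions score different configurations")
  tab <- rbind(a = a, b = b)
  zero <- colSums(tab) == 0
  if (any(zero)) {
    warning("dropping configurations unobserved in both conditions: ",
            paste(colnames(tab)[zero], collapse = ", "))
    tab <- tab[, !zero, drop = FALSE]
  }
  g_test(tab)
}

#' Write per-particle measurements and class fractions
#'
#' @param classification A `particle_classification`.
#' @param tsv,json Output paths for the per-particle TSV and the
#'   class-fraction JSON (either may be `NULL`).
#' @export
write_particles <- function(classification, tsv = NULL, json = NULL) {
  if (!is.null(tsv))
    utils::write.table(classification$particles, tsv, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  if (!is.null(json))
    jsonlite::write_json(as.list(classification$fractions), json,
                         auto_unbox = TRUE, digits = NA)
  invisible(classification)
}
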