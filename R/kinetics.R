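# Cooperative-binding (Hill) and Michaelis-Menten fits for EMSA titrations and
# ATPase kinetics, plus gel band fraction arithmetic and competition
# normalization. Nonlinear fits use Levenberg-Marquardt least squares
# (minpack.lm) with data-driven starting values; standard errors come from the
# local curvature of the least-squares objective.

#' Band fractions from gel lane intensities
#'
#' Fraction per band = intensity / total lane intensity. When a band named
#' `"free"` (or `"unbound"`) is present, the bound fraction `1 - free` is also
#' reported, the usual EMSA convention.
#'
#' @param intensities Named non-negative numeric vector of band intensities.
#' @return List with `fractions` (sums to 1) and, when applicable, `bound`.
#' @examples
#' gel_fraction(c(free = 30, shifted = 70))$bound  # 0.7
#' @export
gel_fraction <- function(intensities) {
  if (any(intensities < 0)) stop("band intensities must be non-negative")
  tot <- sum(intensities)
  if (tot <= 0) stop("all-zero lane; fractions are undefined")
  f <- intensities / tot
  out <- list(fractions = f)
  free <- intersect(c("free", "unbound"), names(f))
  if (length(free)) out$bound <- unname(1 - f[free[1L]])
  out
}

hill_bound <- function(L, K, n) {
  f <- ifelse(L > 0, 1 / (1 + exp(n * (log(K) - log(L)))), 0)
  f
}

#' Fit the Hill equation to a binding titration
#'
#' Bound fraction f(L) = L^n / (K^n + L^n), with K the half-saturation
#' constant in concentration units and n the Hill slope; the saturating bound
#' fraction is fixed at 1 unless `free_amplitude = TRUE` (binding typically
#' runs past 90% completion in these titrations, so the amplitude is not
#' identifiable as a free parameter from most series). The fit minimizes
#' squared residuals on the scale the data arrive in: EMSA quantifications
#' are typically of the unbound substrate, so `response = "unbound"` fits
#' 1 - f(L) directly.
#'
#' @param x Ligand (protein) concentrations, same units as the returned K.
#' @param y Fractions in `[0, 1]` (>= 4 points spanning both sides of
#'   half-saturation).
#' @param response Whether `y` is the `"unbound"` (default) or `"bound"`
#'   fraction.
#' @param free_amplitude Also fit the saturating amplitude (default fixed 1).
#' @return A `hill_fit`: `kd`, `n_h`, `se` (named vector), `rss`, `data`, the
#'   underlying `nls` object, with `print`, `coef`, `predict` and `plot`
#'   methods.
#' @export
fit_hill <- function(x, y, response = c("unbound", "bound"),
                     free_amplitude = FALSE) {
  response <- match.arg(response)
  if (length(x) != length(y)) stop("x and y lengths differ")
  if (length(x) < 4L) stop("need at least 4 titration points")
  if (any(x < 0) || any(y < -1e-9) || any(y > 1 + 1e-9))
    stop("concentrations must be >= 0 and fractions within [0, 1]")
  b <- if (response == "unbound") 1 - y else y
  if (all(b < 0.5) || all(b > 0.5))
    stop("titration does not span half-saturation; K is not identifiable")
  # starting values: K from the half-max crossing, n from the logit slope
  o <- order(x)
  k0 <- stats::approx(b[o], x[o], xout = 0.5, ties = mean)$y
  if (is.na(k0) || k0 <= 0) k0 <- stats::median(x[x > 0])
  mid <- which(b > 0.05 & b < 0.95 & x > 0)
  n0 <- if (length(mid) >= 2L) {
    cf <- stats::coef(stats::lm(log(b[mid] / (1 - b[mid])) ~ log(x[mid])))[2L]
    min(max(cf, 0.2), 6)
  } else 1
  d <- data.frame(x = x, b = b)
  if (free_amplitude) {
    fit <- minpack.lm::nlsLM(
      b ~ A * hill_bound(x, K, n), data = d,
      start = list(A = max(b), K = k0, n = n0),
      lower = c(A = 1e-6, K = 1e-12, n = 1e-3), upper = c(A = 2, K = Inf, n = 6),
      control = minpack.lm::nls.lm.control(maxiter = 200))
  } else {
    fit <- minpack.lm::nlsLM(
      b ~ hill_bound(x, K, n), data = d,
      start = list(K = k0, n = n0),
      lower = c(K = 1e-12, n = 1e-3), upper = c(K = Inf, n = 6),
      control = minpack.lm::nls.lm.control(maxiter = 200))
  }
  cf <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) stats::setNames(rep(NA_real_, length(cf)),
                                                     names(cf)))
  structure(list(kd = unname(cf[["K"]]), n_h = unname(cf[["n"]]),
                 amplitude = if (free_amplitude) unname(cf[["A"]]) else 1,
                 se = se, rss = sum(stats::residuals(fit)^2),
                 response = response, data = d, fit = fit),
            class = "hill_fit")
}

#' @export
print.hill_fit <- function(x, ...) {
  cat(sprintf("Hill fit: K_D = %.4g +/- %.2g, n_H = %.3g +/- %.2g (RSS %.3g)\n",
              x$kd, x$se[["K"]], x$n_h, x$se[["n"]], x$rss))
  invisible(x)
}

#' @export
coef.hill_fit <- function(object, ...) c(K = object$kd, n = object$n_h)

#' Predicted bound fraction from a Hill fit
#' @param object A `hill_fit`.
#' @param x Concentrations.
#' @param ... Ignored.
#' @export
predict.hill_fit <- function(object, x, ...) {
  object$amplitude * hill_bound(x, object$kd, object$n_h)
}

#' @export
plot.hill_fit <- function(x, ...) {
  d <- x$data
  grid <- seq(0, max(d$x), length.out = 200)
  plot(d$x, d$b, xlab = "concentration", ylab = "fraction bound", ...)
  graphics::lines(grid, predict(x, grid))
  invisible(x)
}

#' @export
residuals.hill_fit <- function(object, ...) stats::residuals(object$fit)

#' Fit Michaelis-Menten kinetics
#'
#' v(S) = V_max S / (K_m + S) by Levenberg-Marquardt least squares. When
#' rates are already per enzyme (min^-1), k_cat = V_max; otherwise supply
#' `enzyme` (same units as v's numerator) to normalize.
#'
#' @param s Substrate concentrations.
#' @param v Rates (>= 4 points; at least one should approach saturation).
#' @param enzyme Optional enzyme concentration for k_cat = V_max / enzyme.
#' @return An `mm_fit`: `vmax`, `km`, `kcat`, `se`, `rss`, `data`, `fit`.
#' @export
fit_michaelis_menten <- function(s, v, enzyme = NULL) {
  if (length(s) != length(v)) stop("s and v lengths differ")
  if (length(s) < 2L) stop("need at least 2 substrate concentrations")
  if (any(s < 0)) stop("substrate concentrations must be >= 0")
  vmax0 <- max(v) * 1.2
  km0 <- stats::approx(v[order(s)], sort(s), xout = vmax0 / 2.4,
                       ties = mean)$y
  if (is.na(km0) || km0 <= 0) km0 <- stats::median(s[s > 0])
  d <- data.frame(s = s, v = v)
  fit <- minpack.lm::nlsLM(v ~ Vmax * s / (Km + s), data = d,
                           start = list(Vmax = vmax0, Km = km0),
                           lower = c(Vmax = 1e-12, Km = 1e-12),
                           control = minpack.lm::nls.lm.control(maxiter = 200))
  cf <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) stats::setNames(rep(NA_real_, 2L),
                                                     names(cf)))
  if (max(s) < cf[["Km"]])
    warning("no substrate concentration reaches K_m; the fit is ",
            "unsaturated and the parameter SEs will be wide")
  structure(list(vmax = unname(cf[["Vmax"]]), km = unname(cf[["Km"]]),
                 kcat = unname(cf[["Vmax"]]) / if (is.null(enzyme)) 1 else enzyme,
                 se = se, rss = sum(stats::residuals(fit)^2),
                 data = d, fit = fit),
            class = "mm_fit")
}

#' @export
print.mm_fit <- function(x, ...) {
  cat(sprintf(
    "Michaelis-Menten fit: V_max = %.4g +/- %.2g, K_m = %.4g +/- %.2g\n",
    x$vmax, x$se[["Vmax"]], x$km, x$se[["Km"]]))
  if (x$kcat != x$vmax) cat(sprintf("  k_cat = %.4g\n", x$kcat))
  invisible(x)
}

#' @export
coef.mm_fit <- function(object, ...) c(Vmax = object$vmax, Km = object$km)

#' Predicted rate from a Michaelis-Menten fit
#' @param object An `mm_fit`.
#' @param s Substrate concentrations.
#' @param ... Ignored.
#' @export
predict.mm_fit <- function(object, s, ...) {
  object$vmax * s / (object$km + s)
}

#' @export
residuals.mm_fit <- function(object, ...) stats::residuals(object$fit)

#' Percent competition relative to a no-competitor reference
#'
#' 100 (1 - bound / bound_reference), clipped to [0, 100]; values clipped
#' because of noise (bound exceeding the reference) are flagged.
#'
#' @param bound Bound fractions in the presence of competitor.
#' @param reference Bound fraction without competitor (> 0).
#' @return Numeric vector of percent competition with logical attribute
#'   `clipped`.
#' @export
competition_normalize <- function(bound, reference) {
  if (reference <= 0) stop("reference binding must be positive")
  pc <- 100 * (1 - bound / reference)
  clipped <- pc < 0 | pc > 100
  structure(pmin(100, pmax(0, pc)), clipped = clipped)
}

#' Read a titration series CSV
#' @param path CSV with columns `x`, `y` and optionally `replicate`.
#' @export
read_titration_csv <- function(path) {
  d <- utils::read.csv(path)
  if (!all(c("x", "y") %in% names(d))) stop("titration CSV needs columns x,y")
  d
}

#' Serialize a fit to a JSON record
#' @param fit A `hill_fit` or `mm_fit`.
#' @param path Optional output file.
#' @export
write_fit_json <- function(fit, path = NULL) {
  rec <- if (inherits(fit, "hill_fit"))
    list(model = "hill", kd = fit$kd, n_h = fit$n_h,
         se = as.list(fit$se), rss = fit$rss)
  else list(model = "michaelis-menten", vmax = fit$vmax, km = fit$km,
            kcat = fit$kcat, se = as.list(fit$se), rss = fit$rss)
  js <- jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
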