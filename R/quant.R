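# Quantitation: scan stream -> XIC -> peak area -> identity scores ->
# internal-standard-ratio calibration -> back-calculated concentration.

#' Extract an exact-mass ion chromatogram
#'
#' For every MS1 scan of the requested polarity inside `rt_window`, sums the
#' centroid intensities falling in `mz_window(mz, tol)`. Scans of the other
#' polarity or of MS2 level contribute no sample point (no zero-filling
#' across polarity gaps); a scan with no matching centroid contributes an
#' intensity of 0.
#'
#' @param stream a `scan_stream`.
#' @param mz extraction center m/z (Da).
#' @param tol extraction tolerance (ppm), > 0.
#' @param rt_window `c(lo, hi)` minutes, or NULL for the full stream.
#' @param polarity `"negative"` or `"positive"`.
#' @return an `xic`: data.frame with strictly increasing `rt` and
#'   non-negative `intensity`, plus extraction metadata attributes.
#' @export
extract_xic <- function(stream, mz, tol, rt_window = NULL,
                        polarity = "negative") {
  stopifnot(inherits(stream, "scan_stream"))
  if (tol <= 0) stop("ppm tolerance must be positive", call. = FALSE)
  w <- mz_window(mz, tol)
  rt <- numeric(0); inten <- numeric(0)
  for (s in stream$scans) {
    if (s$ms_level != 1L || s$polarity != polarity) next
    if (!is.null(rt_window) && (s$rt_min < rt_window[1] || s$rt_min > rt_window[2]))
      next
    rt <- c(rt, s$rt_min)
    inten <- c(inten, sum(s$intensity[s$mz >= w[1] & s$mz <= w[2]]))
  }
  if (length(rt) == 0L)
    stop("no MS1 scans of the requested polarity in the RT window", call. = FALSE)
  o <- order(rt)
  out <- data.frame(rt = rt[o], intensity = inten[o])
  attr(out, "mz") <- mz; attr(out, "tol_ppm") <- tol
  attr(out, "polarity") <- polarity
  class(out) <- c("xic", "data.frame")
  out
}

#' @export
plot.xic <- function(x, ...) {
  graphics::plot(x$rt, x$intensity, type = "l", xlab = "retention time (min)",
                 ylab = "intensity",
                 main = sprintf("XIC m/z %.4f +/- %g ppm",
                                attr(x, "mz"), attr(x, "tol_ppm")), ...)
  invisible(x)
}

#' Integrate a chromatographic peak
#'
#' Finds the apex as the maximum intensity within `expected_rt +/-
#' max_shift`, extends integration boundaries outward until the intensity
#' falls below `boundary_fraction x apex`, and integrates trapezoidally
#' between them. Because the stop rule is a fraction of the apex, a bimodal
#' breakthrough peak whose valley stays above the threshold is integrated
#' across both modes, while a valley collapsing below it truncates the peak.
#' A zero apex yields a flagged not-detected result with area 0 rather than
#' an error, so validation statistics always see a complete replicate grid.
#'
#' @param xic an `xic`.
#' @param expected_rt expected apex (min).
#' @param max_shift maximum allowed apex shift (min).
#' @param boundary_fraction boundary threshold as a fraction of apex height.
#' @return a `peak_area` list: `area` (intensity x min), `apex_rt`,
#'   `bounds`, `n_points` (points across the peak), `detected`.
#' @export
integrate_peak <- function(xic, expected_rt, max_shift = 0.5,
                           boundary_fraction = 0.02) {
  stopifnot(inherits(xic, "xic"), nrow(xic) > 0)
  in_win <- which(xic$rt >= expected_rt - max_shift &
                  xic$rt <= expected_rt + max_shift)
  if (length(in_win) == 0L)
    stop("no XIC points within max_shift of expected_rt", call. = FALSE)
  apex <- in_win[which.max(xic$intensity[in_win])]
  apex_int <- xic$intensity[apex]
  if (apex_int <= 0)
    return(structure(list(area = 0, apex_rt = xic$rt[apex],
                          bounds = c(NA_real_, NA_real_), n_points = 0L,
                          detected = FALSE), class = "peak_area"))
  thr <- boundary_fraction * apex_int
  lo <- apex
  while (lo > 1L && xic$intensity[lo - 1L] >= thr) lo <- lo - 1L
  hi <- apex
  n <- nrow(xic)
  while (hi < n && xic$intensity[hi + 1L] >= thr) hi <- hi + 1L
  idx <- lo:hi
  area <- if (length(idx) > 1L)
    sum(diff(xic$rt[idx]) * (utils::head(xic$intensity[idx], -1) +
                             utils::tail(xic$intensity[idx], -1)) / 2)
  else 0
  structure(list(area = area, apex_rt = xic$rt[apex],
                 bounds = c(xic$rt[lo], xic$rt[hi]),
                 n_points = length(idx), detected = TRUE),
            class = "peak_area")
}

#' @export
print.peak_area <- function(x, ...) {
  if (!x$detected) cat("<peak_area> not detected (area 0)\n")
  else cat(sprintf("<peak_area> area %.4g, apex %.3f min, %d points [%.3f, %.3f]\n",
                   x$area, x$apex_rt, x$n_points, x$bounds[1], x$bounds[2]))
  invisible(x)
}

#' Isotope-envelope match score (idotp)
#'
#' Normalized dot product (cosine) between observed intensities measured at
#' the predicted isotope m/z positions and the predicted relative
#' abundances. Scale-invariant; 1 for a perfect shape match, 0 for an
#' all-zero or orthogonal observation.
#'
#' @param observed numeric intensities, one per predicted pattern peak
#'   (aligned within the pattern's merge width).
#' @param predicted an [isotope_pattern()] (or data.frame with `abundance`).
#' @return idotp in [0, 1]; an all-zero observation returns 0 with
#'   attribute `flag = "no-signal"`.
#' @export
score_idotp <- function(observed, predicted) {
  p <- predicted$abundance
  if (length(observed) != length(p))
    stop("observed must align 1:1 with predicted pattern peaks", call. = FALSE)
  if (all(observed == 0)) {
    out <- 0
    attr(out, "flag") <- "no-signal"
    return(out)
  }
  .cosine(observed, p)
}

.cosine <- function(a, b) {
  d <- sqrt(sum(a^2)) * sqrt(sum(b^2))
  if (d == 0) return(0)
  min(1, max(0, sum(a * b) / d))
}

#' MS2 fragment-template match score (dotp)
#'
#' Matches observed centroids to template fragment m/z values within
#' `tol_ppm` (nearest centroid wins; unmatched template entries contribute
#' zeros) and returns the cosine similarity of the square-root-transformed
#' intensity vectors -- the convention of spectral-library dot products in
#' proteomics tooling. Set `transform = "none"` for a plain-intensity
#' cosine.
#'
#' @param observed data.frame with `mz` and `intensity` (e.g. an MS2 scan).
#' @param template data.frame with `mz` and `abundance` (relative).
#' @param tol_ppm matching tolerance.
#' @param transform `"sqrt"` (default) or `"none"`.
#' @return dotp in [0, 1].
#' @export
score_dotp <- function(observed, template, tol_ppm = 10,
                       transform = c("sqrt", "none")) {
  transform <- match.arg(transform)
  if (nrow(template) == 0L) stop("template must be non-empty", call. = FALSE)
  obs <- vapply(template$mz, function(m) {
    if (length(observed$mz) == 0L) return(0)
    d <- abs(observed$mz - m)
    i <- which.min(d)
    if (d[i] / m * 1e6 <= tol_ppm) observed$intensity[i] else 0
  }, numeric(1))
  tf <- if (transform == "sqrt") sqrt else identity
  .cosine(tf(obs), tf(template$abundance))
}

#' Fit an internal-standard-ratio calibration curve
#'
#' Weighted least squares of the analyte/IS area ratio on the calibration
#' level. Weighting `"1/x"` (default) down-weights the top of a
#' several-decade calibration range; `"none"` and `"1/x^2"` are also
#' available. R-squared is computed on the weighted fit. Pairs with
#' non-finite ratios (e.g. zero IS area) are dropped with a warning.
#'
#' @param levels calibration levels (ng/L).
#' @param ratios analyte/IS area ratios, same length.
#' @param weighting `"1/x"`, `"none"`, or `"1/x^2"`.
#' @param analyte,is_id optional compound ids carried for reporting.
#' @return a `cal_curve` model object with `slope`, `intercept`,
#'   `r_squared`, the pairs used, and the weighting. Supports `print()`,
#'   `summary()`, `coef()`, `predict()`, `residuals()`, `plot()`, and
#'   [back_calculate()].
#' @examples
#' cc <- fit_calibration(c(2, 10, 100), 0.002 * c(2, 10, 100))
#' coef(cc); back_calculate(cc, 0.02)
#' @export
fit_calibration <- function(levels, ratios, weighting = c("1/x", "none", "1/x^2"),
                            analyte = NA_character_, is_id = NA_character_) {
  weighting <- match.arg(weighting)
  stopifnot(length(levels) == length(ratios))
  keep <- is.finite(ratios) & is.finite(levels)
  if (any(!keep)) {
    warning(sum(!keep), " calibration pair(s) with non-finite ratio dropped")
    levels <- levels[keep]; ratios <- ratios[keep]
  }
  if (length(unique(levels)) < 2L)
    stop("calibration requires >= 2 distinct levels", call. = FALSE)
  w <- switch(weighting, none = rep(1, length(levels)),
              "1/x" = 1 / levels, "1/x^2" = 1 / levels^2)
  fit <- stats::lm.wfit(cbind(`(Intercept)` = 1, level = levels), ratios, w)
  coefs <- fit$coefficients
  ybar <- sum(w * ratios) / sum(w)
  sse <- sum(w * fit$residuals^2)
  sst <- sum(w * (ratios - ybar)^2)
  r2 <- if (sst > 0) 1 - sse / sst else 1
  structure(list(slope = unname(coefs["level"]),
                 intercept = unname(coefs["(Intercept)"]),
                 r_squared = min(1, max(0, r2)), weighting = weighting,
                 pairs = data.frame(level = levels, ratio = ratios, weight = w),
                 analyte = analyte, is_id = is_id),
            class = "cal_curve")
}

#' @export
print.cal_curve <- function(x, ...) {
  cat(sprintf("<cal_curve>%s ratio = %.6g + %.6g x level  (R^2 = %.5f, weighting %s, n = %d)\n",
              if (!is.na(x$analyte)) sprintf(" %s / %s:", x$analyte, x$is_id) else "",
              x$intercept, x$slope, x$r_squared, x$weighting, nrow(x$pairs)))
  invisible(x)
}

#' @export
summary.cal_curve <- function(object, ...) {
  cat("Internal-standard-ratio calibration curve\n")
  print(object)
  cat(sprintf("levels: %s\n", paste(sort(unique(object$pairs$level)), collapse = ", ")))
  res <- stats::quantile(residuals(object), c(0, 0.5, 1))
  cat(sprintf("residuals (min/median/max): %.3g / %.3g / %.3g\n",
              res[1], res[2], res[3]))
  invisible(object)
}

#' @export
coef.cal_curve <- function(object, ...)
  c(intercept = object$intercept, slope = object$slope)

#' @export
predict.cal_curve <- function(object, newdata = NULL, ...) {
  lev <- if (is.null(newdata)) object$pairs$level
    else if (is.data.frame(newdata)) newdata$level else newdata
  object$intercept + object$slope * lev
}

#' @export
residuals.cal_curve <- function(object, ...)
  object$pairs$ratio - predict(object)

#' @export
plot.cal_curve <- function(x, ...) {
  graphics::plot(x$pairs$level, x$pairs$ratio, xlab = "level (ng/L)",
                 ylab = "area ratio",
                 main = if (!is.na(x$analyte))
                   sprintf("%s / %s (R^2 = %.4f)", x$analyte, x$is_id, x$r_squared)
                 else sprintf("calibration (R^2 = %.4f)", x$r_squared), ...)
  graphics::abline(x$intercept, x$slope, col = "grey40")
  invisible(x)
}

#' Back-calculate a concentration from a fitted curve
#'
#' `(ratio - intercept) / slope`. May legitimately be negative at
#' noise-dominated levels; the validation layer judges recovery.
#'
#' @param curve a `cal_curve`.
#' @param ratio observed area ratio(s).
#' @return concentration(s) in ng/L.
#' @export
back_calculate <- function(curve, ratio) {
  stopifnot(inherits(curve, "cal_curve"))
  if (curve$slope == 0) stop("calibration slope is zero", call. = FALSE)
  (ratio - curve$intercept) / curve$slope
}

#' Calibrate and back-calculate a whole study
#'
#' Turns an area table into back-calculated concentrations: computes the
#' analyte/assigned-IS area ratio for every (replicate, level), fits each
#' analyte's calibration curve on the `cal_replicate` rows, and
#' back-calculates all replicates against it. Rows from the calibration
#' replicate are flagged so validation can use QC replicates only.
#'
#' @param areas an area table (replicate_id, level_ngL, compound,
#'   is_internal_standard, area) -- from [simulate_replicate_study()],
#'   [quantify_scan_streams()] or [read_area_table()].
#' @param registry a `compound_registry`.
#' @param weighting calibration weighting, see [fit_calibration()].
#' @param cal_replicate which replicate serves as the calibration curve.
#' @return a list of class `quantified_study`: `conc` (replicate_id,
#'   level_ngL, compound, conc_ngL, is_cal_replicate), `curves` (named list
#'   of `cal_curve`), `ratios`.
#' @export
quantify_study <- function(areas, registry, weighting = "1/x",
                           cal_replicate = 1L) {
  stopifnot(inherits(registry, "compound_registry"))
  analytes <- registry$id[registry$role == "analyte"]
  analytes <- intersect(analytes, unique(areas$compound))
  key <- function(df) paste(df$replicate_id, df$level_ngL, sep = "\r")
  curves <- list(); ratio_rows <- list(); conc_rows <- list()
  for (a in analytes) {
    isid <- registry$surrogate_is[match(a, registry$id)]
    aa <- areas[areas$compound == a, ]
    ii <- areas[areas$compound == isid, ]
    m <- match(key(aa), key(ii))
    ratio <- aa$area / ii$area[m]
    rd <- data.frame(replicate_id = aa$replicate_id, level_ngL = aa$level_ngL,
                     compound = a, ratio = ratio, stringsAsFactors = FALSE)
    cal <- rd[rd$replicate_id == cal_replicate, ]
    curve <- fit_calibration(cal$level_ngL, cal$ratio, weighting = weighting,
                             analyte = a, is_id = isid)
    curves[[a]] <- curve
    conc_rows[[a]] <- data.frame(
      replicate_id = rd$replicate_id, level_ngL = rd$level_ngL, compound = a,
      conc_ngL = back_calculate(curve, rd$ratio),
      is_cal_replicate = rd$replicate_id == cal_replicate,
      stringsAsFactors = FALSE)
    ratio_rows[[a]] <- rd
  }
  structure(list(conc = do.call(rbind, c(conc_rows, make.row.names = FALSE)),
                 curves = curves,
                 ratios = do.call(rbind, c(ratio_rows, make.row.names = FALSE)),
                 cal_replicate = cal_replicate, weighting = weighting),
            class = "quantified_study")
}

#' @export
print.quantified_study <- function(x, ...) {
  r2 <- vapply(x$curves, `[[`, numeric(1), "r_squared")
  cat(sprintf("<quantified_study> %d analytes, cal replicate %d, weighting %s; median R^2 = %.5f\n",
              length(x$curves), x$cal_replicate, x$weighting, stats::median(r2)))
  invisible(x)
}

#' Quantify compounds from scan streams
#'
#' The scan-stream route to an area table: extract each compound's XIC at
#' its theoretical m/z and integrate the peak at its registered retention
#' time. Streams are supplied one per (replicate, level) sample.
#'
#' @param streams a list of `scan_stream` objects.
#' @param samples data.frame with one row per stream: `replicate_id`,
#'   `level_ngL`.
#' @param registry a `compound_registry`.
#' @param compounds compound ids to quantify (default: all non-interference
#'   registry rows).
#' @param tol_ppm XIC extraction tolerance.
#' @param rt_halfwidth half-width of the XIC RT window around the registered
#'   RT (min).
#' @param max_shift,boundary_fraction passed to [integrate_peak()].
#' @return an area table in the standard schema.
#' @export
quantify_scan_streams <- function(streams, samples, registry,
                                  compounds = NULL, tol_ppm = 5,
                                  rt_halfwidth = 1, max_shift = 0.5,
                                  boundary_fraction = 0.02) {
  stopifnot(length(streams) == nrow(samples))
  masses <- registry_masses(registry)
  if (is.null(compounds))
    compounds <- registry$id[registry$role != "interference"]
  out <- list()
  for (k in seq_along(streams)) {
    for (id in compounds) {
      i <- match(id, registry$id)
      mz <- masses$mz[match(id, masses$id)]
      xic <- tryCatch(
        extract_xic(streams[[k]], mz, tol_ppm,
                    rt_window = registry$rt_min[i] + c(-1, 1) * rt_halfwidth,
                    polarity = registry$polarity[i]),
        error = function(e) NULL)
      if (is.null(xic)) {  # compound not covered by this acquisition
        warning("no scans cover ", id, " in stream ", k, "; skipped")
        next
      }
      pk <- integrate_peak(xic, registry$rt_min[i], max_shift = max_shift,
                           boundary_fraction = boundary_fraction)
      out[[length(out) + 1L]] <- data.frame(
        replicate_id = samples$replicate_id[k], level_ngL = samples$level_ngL[k],
        compound = id,
        is_internal_standard = registry$role[i] == "internal_standard",
        area = pk$area, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, c(out, make.row.names = FALSE))
}
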