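# Surrogate internal-standard screening: quantify one analyte against every
# candidate IS and relate calibration fit quality to fluorine-count
# difference.

#' Scan candidate internal standards for one analyte
#'
#' Fits the analyte's calibration curve against every candidate internal
#' standard (pooling all replicates' level/ratio pairs) and attaches the
#' absolute fluorine-count difference between analyte and candidate. A
#' candidate missing at any analyte level is skipped with a warning.
#'
#' @param analyte analyte compound id.
#' @param candidates candidate internal-standard ids (default: every
#'   internal standard in the registry).
#' @param areas an area table in the standard schema.
#' @param registry a `compound_registry`.
#' @param weighting calibration weighting, see [fit_calibration()].
#' @return a `surrogate_scan`: data.frame (is_id, delta_f, r_squared,
#'   slope), one row per usable candidate, sorted by delta_f.
#' @export
surrogate_scan <- function(analyte, candidates = NULL, areas, registry,
                           weighting = "1/x") {
  stopifnot(inherits(registry, "compound_registry"))
  if (is.null(candidates))
    candidates <- registry$id[registry$role == "internal_standard"]
  f_of <- function(id) {
    f <- registry$parsed_formula[[match(id, registry$id)]]
    if (is.null(f)) NA_integer_ else fluorine_count(f)
  }
  fa <- f_of(analyte)
  aa <- areas[areas$compound == analyte, ]
  if (length(unique(aa$level_ngL)) < 2L)
    stop("analyte must be present at >= 2 levels", call. = FALSE)
  key <- function(df) paste(df$replicate_id, df$level_ngL, sep = "\r")
  rows <- list()
  for (cid in candidates) {
    ci <- areas[areas$compound == cid, ]
    m <- match(key(aa), key(ci))
    if (anyNA(m)) {
      warning("candidate ", cid, " missing at some levels; skipped")
      next
    }
    curve <- fit_calibration(aa$level_ngL, aa$area / ci$area[m],
                             weighting = weighting, analyte = analyte,
                             is_id = cid)
    rows[[length(rows) + 1L]] <- data.frame(
      is_id = cid, delta_f = abs(fa - f_of(cid)),
      r_squared = curve$r_squared, slope = curve$slope,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, c(rows, make.row.names = FALSE))
  out <- out[order(out$delta_f, out$is_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "analyte") <- analyte
  class(out) <- c("surrogate_scan", "data.frame")
  out
}

#' Rank surrogate candidates
#'
#' Orders candidates by calibration R-squared (descending), breaking ties by
#' smaller fluorine-count difference, then lexical id.
#'
#' @param scan a `surrogate_scan`.
#' @return the scan rows in recommendation order.
#' @export
rank_surrogates <- function(scan) {
  stopifnot(inherits(scan, "surrogate_scan"), nrow(scan) >= 1L)
  o <- order(-scan$r_squared, scan$delta_f, scan$is_id)
  out <- scan[o, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @export
print.surrogate_scan <- function(x, ...) {
  cat(sprintf("<surrogate_scan> analyte %s, %d candidates\n",
              attr(x, "analyte"), nrow(x)))
  print(as.data.frame(x), row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
plot.surrogate_scan <- function(x, ...) {
  graphics::plot(x$delta_f, x$r_squared, xlab = "|delta fluorine count|",
                 ylab = expression(R^2),
                 main = sprintf("surrogate IS scan: %s", attr(x, "analyte")),
                 ...)
  invisible(x)
}

#' Export a surrogate scan as a scatter CSV
#'
#' Columns `analyte, is_id, delta_f, r_squared` -- directly plottable as a
#' fluorine-mismatch vs fit-quality scatter.
#'
#' @param scan a `surrogate_scan`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_surrogate_scatter <- function(scan, path) {
  stopifnot(inherits(scan, "surrogate_scan"))
  out <- data.frame(analyte = attr(scan, "analyte"), is_id = scan$is_id,
                    delta_f = scan$delta_f, r_squared = scan$r_squared)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
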