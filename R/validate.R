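# EPA Method 537.1-style validation statistics from replicate calibration
# data: half-range prediction intervals, MRL, DL, IDP, IDA.

#' Half range of the prediction interval of results (HR_PIR)
#'
#' `s * t(df = N - 1, 1 - alpha/2) * sqrt(1 + 1/N)`, with `s` the sample
#' standard deviation (N - 1 denominator) of the back-calculated replicate
#' concentrations. This is the half-width against which the 50-150% PIR
#' recovery criteria are judged.
#'
#' @param x back-calculated replicate concentrations (ng/L), length >= 2.
#' @param alpha two-sided significance level (default 0.01, the 99%
#'   two-tailed Student t).
#' @return HR_PIR in the units of `x`.
#' @export
half_range_pir <- function(x, alpha = 0.01) {
  n <- length(x)
  if (n < 2L) stop("HR_PIR requires at least 2 replicates", call. = FALSE)
  stats::sd(x) * stats::qt(1 - alpha / 2, df = n - 1) * sqrt(1 + 1 / n)
}

#' PIR recovery criteria for one replicate set
#'
#' Upper PIR recovery = (mean + HR_PIR) / actual x 100, lower =
#' (mean - HR_PIR) / actual x 100. The set passes when upper <= 150 *and*
#' lower >= 50 (both bounds inclusive).
#'
#' @param x back-calculated replicate concentrations (ng/L).
#' @param actual the nominal ("Actual") concentration, > 0.
#' @param alpha passed to [half_range_pir()].
#' @return a `pir_result` list: `mean`, `hr_pir`, `upper`, `lower`, `pass`,
#'   `fail_reason` (`NA`, `"upper"`, `"lower"` or `"both"`).
#' @export
pir_recovery <- function(x, actual, alpha = 0.01) {
  if (actual <= 0) stop("actual concentration must be positive", call. = FALSE)
  hr <- half_range_pir(x, alpha = alpha)
  m <- mean(x)
  upper <- (m + hr) / actual * 100
  lower <- (m - hr) / actual * 100
  up_ok <- upper <= 150
  lo_ok <- lower >= 50
  structure(list(mean = m, hr_pir = hr, upper = upper, lower = lower,
                 n = length(x), pass = up_ok && lo_ok,
                 fail_reason = if (up_ok && lo_ok) NA_character_
                   else if (!up_ok && !lo_ok) "both"
                   else if (!up_ok) "upper" else "lower"),
            class = "pir_result")
}

#' @export
print.pir_result <- function(x, ...) {
  cat(sprintf("<pir_result> mean %.4g, HR_PIR %.4g, recovery %.1f-%.1f%% -> %s\n",
              x$mean, x$hr_pir, x$lower, x$upper,
              if (x$pass) "pass" else paste0("fail (", x$fail_reason, ")")))
  invisible(x)
}

#' Determine the minimum reporting limit (MRL)
#'
#' The MRL is the lowest calibration level whose QC-replicate set passes
#' both PIR recovery criteria. Levels with fewer than `min_replicates`
#' replicates are excluded with a warning; if no level passes, the MRL is
#' undefined and flagged.
#'
#' @param conc_by_level named list: level (ng/L, as names, ascending) ->
#'   numeric vector of back-calculated QC replicate concentrations.
#' @param alpha passed to [pir_recovery()].
#' @param min_replicates minimum replicates per level (default 7).
#' @return an `mrl_result`: `mrl` (ng/L or NA), `defined`, and `per_level`
#'   (level, n, mean, hr_pir, lower, upper, pass, fail_reason).
#' @export
determine_mrl <- function(conc_by_level, alpha = 0.01, min_replicates = 7L) {
  levels <- as.numeric(names(conc_by_level))
  if (any(is.na(levels))) stop("conc_by_level must be named by level", call. = FALSE)
  o <- order(levels)
  levels <- levels[o]; conc_by_level <- conc_by_level[o]
  rows <- list()
  for (i in seq_along(levels)) {
    x <- conc_by_level[[i]]
    if (length(x) < min_replicates) {
      warning(sprintf("level %g has %d < %d replicates; excluded",
                      levels[i], length(x), min_replicates))
      next
    }
    p <- pir_recovery(x, actual = levels[i], alpha = alpha)
    rows[[length(rows) + 1L]] <- data.frame(
      level_ngL = levels[i], n = p$n, mean = p$mean, hr_pir = p$hr_pir,
      lower = p$lower, upper = p$upper, pass = p$pass,
      fail_reason = if (is.na(p$fail_reason)) "" else p$fail_reason,
      stringsAsFactors = FALSE)
  }
  per_level <- do.call(rbind, c(rows, make.row.names = FALSE))
  if (is.null(per_level) || !any(per_level$pass))
    return(structure(list(mrl = NA_real_, defined = FALSE,
                          per_level = per_level), class = "mrl_result"))
  mrl <- min(per_level$level_ngL[per_level$pass])
  structure(list(mrl = mrl, defined = TRUE, per_level = per_level),
            class = "mrl_result")
}

#' @export
print.mrl_result <- function(x, ...) {
  if (x$defined) cat(sprintf("<mrl_result> MRL = %g ng/L\n", x$mrl))
  else cat("<mrl_result> MRL undefined (no level passed both PIR criteria)\n")
  if (!is.null(x$per_level)) print(x$per_level, row.names = FALSE)
  invisible(x)
}

#' Detection limit (DL) from the MRL level's replicates
#'
#' `s * t(df = N - 1, quantile)`. The default follows the two-tailed
#' rendering `t(df, 1 - alpha/2)` used alongside HR_PIR (so DL =
#' HR_PIR / sqrt(1 + 1/N) algebraically); `sided = "one"` gives the
#' one-sided EPA 537.1 convention `t(df, 1 - alpha)`. Both are provided
#' because printed renderings of the method differ; neither is asserted to
#' be the only correct reading.
#'
#' @param x back-calculated replicate concentrations at the MRL level.
#' @param alpha significance level (default 0.01).
#' @param sided `"two"` (default) or `"one"`.
#' @return DL in the units of `x`.
#' @export
detection_limit <- function(x, alpha = 0.01, sided = c("two", "one")) {
  sided <- match.arg(sided)
  n <- length(x)
  if (n < 2L) stop("DL requires at least 2 replicates", call. = FALSE)
  q <- if (sided == "two") 1 - alpha / 2 else 1 - alpha
  stats::sd(x) * stats::qt(q, df = n - 1)
}

#' Initial demonstration of precision (IDP)
#'
#' Relative standard deviation (%) of the mid-level replicate data:
#' `s / mean * 100`.
#'
#' @param x back-calculated replicate concentrations at the mid level.
#' @return IDP in percent.
#' @export
idp <- function(x) {
  m <- mean(x)
  if (m == 0) stop("IDP undefined for zero mean", call. = FALSE)
  stats::sd(x) / m * 100
}

#' Initial demonstration of accuracy (IDA)
#'
#' Mean recovery (%) of the mid-level replicate data against the prepared
#' concentration: `mean / actual * 100`.
#'
#' @param x back-calculated replicate concentrations at the mid level.
#' @param actual the prepared mid-level concentration, > 0.
#' @return IDA in percent.
#' @export
ida <- function(x, actual) {
  if (actual <= 0) stop("actual concentration must be positive", call. = FALSE)
  mean(x) / actual * 100
}

# optional replicate trimming: drop the largest |z| until n_target remain
trim_replicates <- function(x, n_target) {
  while (length(x) > n_target) {
    z <- abs(x - mean(x))
    x <- x[-which.max(z)]
  }
  x
}

#' Build a Table-1-style validation report
#'
#' Runs the full validation per analyte from back-calculated QC-replicate
#' concentrations: MRL from the per-level PIR criteria, DL from the MRL
#' level's replicates, IDP/IDA at the mid (QC) level, and both ng/L and
#' pg-on-column renderings of MRL and DL.
#'
#' @param quantified a `quantified_study` (or a data.frame in its `conc`
#'   schema). Calibration-replicate rows are excluded from the statistics.
#' @param registry a `compound_registry`.
#' @param design the [study_design()] (for the pg-on-column conversion and
#'   the mid level).
#' @param alpha significance level for HR_PIR / DL.
#' @param sided DL sidedness, see [detection_limit()].
#' @param min_replicates minimum replicates per level for the MRL search.
#' @param trim_to if not `NULL`, trim each replicate set to this size by
#'   repeatedly dropping the farthest-from-mean value before computing
#'   statistics (the method text requires only "at least seven" of the QC
#'   replicates without printing a selection rule, so no trimming is done
#'   by default).
#' @return a `validation_report`: data.frame with compound, mrl_ngL,
#'   mrl_pg_on_column, dl_ngL, dl_pg_on_column, idp_pct, ida_pct,
#'   mrl_defined; per-level PIR detail in `attr(, "per_level")`.
#' @export
build_validation_report <- function(quantified, registry,
                                    design = study_design(), alpha = 0.01,
                                    sided = "two", min_replicates = 7L,
                                    trim_to = NULL) {
  conc <- if (inherits(quantified, "quantified_study")) quantified$conc
    else quantified
  stopifnot(all(c("replicate_id", "level_ngL", "compound", "conc_ngL") %in%
                  names(conc)))
  if ("is_cal_replicate" %in% names(conc))
    conc <- conc[!conc$is_cal_replicate, , drop = FALSE]
  analytes <- registry$id[registry$role == "analyte"]
  analytes <- intersect(analytes, unique(conc$compound))
  rows <- list(); detail <- list()
  for (a in analytes) {
    ca <- conc[conc$compound == a, ]
    sets <- split(ca$conc_ngL, ca$level_ngL)
    if (!is.null(trim_to))
      sets <- lapply(sets, trim_replicates, n_target = trim_to)
    m <- determine_mrl(sets, alpha = alpha, min_replicates = min_replicates)
    detail[[a]] <- m$per_level
    dl <- NA_real_
    if (m$defined)
      dl <- detection_limit(sets[[as.character(m$mrl)]], alpha = alpha,
                            sided = sided)
    mid <- as.character(design$qc_level_ngL)
    has_mid <- mid %in% names(sets)
    if (!has_mid)
      warning("no mid-level (", mid, " ng/L) data for ", a,
              "; IDP/IDA left blank")
    rows[[a]] <- data.frame(
      compound = a,
      mrl_ngL = m$mrl,
      mrl_pg_on_column = if (m$defined) pg_on_column(m$mrl, design) else NA_real_,
      dl_ngL = dl,
      dl_pg_on_column = if (m$defined) pg_on_column(dl, design) else NA_real_,
      idp_pct = if (has_mid) idp(sets[[mid]]) else NA_real_,
      ida_pct = if (has_mid) ida(sets[[mid]], design$qc_level_ngL) else NA_real_,
      mrl_defined = m$defined,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, c(rows, make.row.names = FALSE))
  attr(out, "per_level") <- detail
  attr(out, "design") <- design
  class(out) <- c("validation_report", "data.frame")
  out
}

#' @export
print.validation_report <- function(x, digits_dl = 2, ...) {
  cat(sprintf("<validation_report> %d compounds (MRL undefined for %d)\n",
              nrow(x), sum(!x$mrl_defined)))
  fmt <- data.frame(
    compound = x$compound,
    `MRL (ng/L)` = ifelse(x$mrl_defined, format(x$mrl_ngL, trim = TRUE), "--"),
    `MRL (pg)` = ifelse(x$mrl_defined, sprintf("%.3g", x$mrl_pg_on_column), "--"),
    `DL (ng/L)` = ifelse(x$mrl_defined, sprintf("%.2f", x$dl_ngL), "--"),
    `DL (pg)` = ifelse(x$mrl_defined, sprintf("%.3f", x$dl_pg_on_column), "--"),
    `IDP (%)` = sprintf("%.2f", x$idp_pct),
    `IDA (%)` = sprintf("%.2f", x$ida_pct),
    check.names = FALSE)
  print(fmt, row.names = FALSE)
  invisible(x)
}

#' Write / read a validation report CSV
#'
#' Seven numeric columns mirroring the standard report layout; round-trips
#' losslessly for its own dialect.
#'
#' @param report a `validation_report`.
#' @param path output path.
#' @return `path` invisibly (writer); a data.frame (reader).
#' @export
write_validation_report <- function(report, path) {
  stopifnot(inherits(report, "validation_report"))
  cols <- c("compound", "mrl_ngL", "mrl_pg_on_column", "dl_ngL",
            "dl_pg_on_column", "idp_pct", "ida_pct")
  utils::write.csv(as.data.frame(report)[cols], path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_validation_report
#' @export
read_validation_report <- function(path)
  utils::read.csv(path, stringsAsFactors = FALSE)
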