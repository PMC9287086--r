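# Synthetic-data generation: replicate calibration studies (area tables with
# full ground truth) and centroided scan streams with inclusion-list
# acquisition structure. The generator stands in for the instrument in every
# end-to-end test.

#' Replicate calibration study design
#'
#' Captures the sample-preparation arithmetic of the assay: calibrators
#' spanning `levels` ng/L are mixed with internal-standard working solution
#' in the ratio `vol_cal:vol_is` (default 900:100, i.e. a 10:1 mix giving a
#' calibrator dilution factor of 0.9), and `injection_uL` of the mixture is
#' injected. `n_replicates` full curves are prepared; one serves as the
#' calibration curve and the rest as quality-control replicates.
#'
#' @param levels calibration levels in ng/L, strictly increasing, positive.
#'   The default spans the 2-2000 ng/L range typical of drinking-water PFAS
#'   panels and includes the 500 ng/L mid-level used for IDP/IDA.
#' @param n_replicates total replicate curves (>= 8: one calibration curve
#'   plus at least seven QC replicates).
#' @param is_conc_ngL internal-standard working concentration (ng/L).
#' @param vol_cal,vol_is mixed volumes (any common unit).
#' @param injection_uL injection volume in microliters.
#' @param qc_level_ngL mid-level concentration for IDP/IDA.
#' @return a `study_design` list with derived `dilution_factor`
#'   (vol_cal / (vol_cal + vol_is)) and `is_dilution_factor`.
#' @examples
#' d <- study_design()
#' d$dilution_factor  # 0.9
#' @export
study_design <- function(levels = c(2, 5, 10, 50, 100, 500, 1000, 2000),
                         n_replicates = 10, is_conc_ngL = 10000,
                         vol_cal = 900, vol_is = 100,
                         injection_uL = 100, qc_level_ngL = 500) {
  if (any(levels <= 0) || any(diff(levels) <= 0))
    stop("levels must be positive and strictly increasing", call. = FALSE)
  if (n_replicates < 8)
    stop("n_replicates must be >= 8 (one curve + >= 7 QC replicates)",
         call. = FALSE)
  dil <- vol_cal / (vol_cal + vol_is)
  if (dil <= 0 || dil >= 1) stop("invalid mix volumes", call. = FALSE)
  structure(list(levels = levels, n_replicates = n_replicates,
                 is_conc_ngL = is_conc_ngL, vol_cal = vol_cal, vol_is = vol_is,
                 injection_uL = injection_uL, qc_level_ngL = qc_level_ngL,
                 dilution_factor = dil, is_dilution_factor = 1 - dil),
            class = "study_design")
}

#' @export
print.study_design <- function(x, ...) {
  cat(sprintf(paste0("<study_design> %d levels (%g-%g ng/L), %d replicates, ",
                     "dilution x%.3g, %g uL injection\n"),
              length(x$levels), min(x$levels), max(x$levels),
              x$n_replicates, x$dilution_factor, x$injection_uL))
  invisible(x)
}

#' Per-compound detector response model
#'
#' Response factors map on-column amount (pg) to noiseless MS1 peak area.
#' Analyte-IS noise correlation `rho` (on the log scale) models shared
#' ionization/injection variation: the area ratio cancels noise completely
#' at `rho = 1` and not at all at `rho = 0`. A "driver" scenario (built by
#' [make_surrogate_scenario()]) instead correlates every internal standard
#' with one focal analyte, each with its own coefficient.
#'
#' @param registry a `compound_registry`.
#' @param rf response factor(s), area per pg on column; scalar or named by
#'   compound id.
#' @param rho correlation between each analyte's log-noise and its assigned
#'   internal standard's; scalar or named by analyte id, in [0, 1].
#' @param saturation optional per-compound area cap (detector saturation).
#' @param driver optional focal analyte id for the surrogate scenario.
#' @param rho_is named correlation per internal standard with the driver
#'   (required when `driver` is set).
#' @return a `response_model`.
#' @export
response_model <- function(registry, rf = 1000, rho = 1, saturation = Inf,
                           driver = NULL, rho_is = NULL) {
  stopifnot(inherits(registry, "compound_registry"))
  ids <- registry$id[registry$role != "interference"]
  expand <- function(x, who, what) {
    if (length(x) == 1L && is.null(names(x))) x <- stats::setNames(rep(x, length(who)), who)
    if (!all(who %in% names(x)))
      stop("missing ", what, " for: ",
           paste(setdiff(who, names(x)), collapse = ", "), call. = FALSE)
    x[who]
  }
  rf <- expand(rf, ids, "response factor")
  if (any(rf <= 0)) stop("response factors must be positive", call. = FALSE)
  analytes <- registry$id[registry$role == "analyte"]
  rho <- expand(rho, analytes, "rho")
  if (any(rho < 0 | rho > 1)) stop("rho must be in [0, 1]", call. = FALSE)
  saturation <- expand(saturation, ids, "saturation cap")
  if (!is.null(driver)) {
    iss <- registry$id[registry$role == "internal_standard"]
    rho_is <- expand(rho_is, iss, "driver correlation")
    if (any(rho_is < 0 | rho_is > 1)) stop("rho_is must be in [0, 1]", call. = FALSE)
    if (!(driver %in% analytes)) stop("driver must be an analyte id", call. = FALSE)
  }
  structure(list(rf = rf, rho = rho, saturation = saturation,
                 driver = driver, rho_is = rho_is),
            class = "response_model")
}

#' Area and m/z noise model
#'
#' @param cv proportional (lognormal) area coefficient of variation: a
#'   scalar, or a vector named by calibration level (ng/L) for
#'   level-dependent noise profiles.
#' @param area_floor additive baseline area (median of a lognormal additive
#'   term); inflates and biases low-level areas, the mechanism that pushes
#'   an MRL above the lowest level.
#' @param mz_jitter_ppm per-centroid mass jitter standard deviation (ppm).
#' @param baseline_peaks expected random baseline centroids per MS1 scan.
#' @param baseline_intensity mean intensity of baseline centroids
#'   (exponentially distributed).
#' @param rt_jitter_sd per-sample retention-time jitter sd (min).
#' @return a `noise_model`.
#' @export
noise_model <- function(cv = 0.05, area_floor = 0, mz_jitter_ppm = 2,
                        baseline_peaks = 0, baseline_intensity = 100,
                        rt_jitter_sd = 0.02) {
  vals <- c(cv, area_floor, mz_jitter_ppm, baseline_peaks,
            baseline_intensity, rt_jitter_sd)
  if (any(vals < 0)) stop("noise parameters must be non-negative", call. = FALSE)
  structure(list(cv = cv, area_floor = area_floor,
                 mz_jitter_ppm = mz_jitter_ppm, baseline_peaks = baseline_peaks,
                 baseline_intensity = baseline_intensity,
                 rt_jitter_sd = rt_jitter_sd),
            class = "noise_model")
}

# cv for a given level (supports level-named cv vectors)
.cv_at <- function(noise, level) {
  cv <- noise$cv
  if (length(cv) == 1L && is.null(names(cv))) return(unname(cv))
  key <- as.character(level)
  if (!(key %in% names(cv)))
    stop("noise cv has no entry for level ", level, call. = FALSE)
  unname(cv[[key]])
}

#' On-column amount for a pre-dilution concentration
#'
#' pg on column = concentration (ng/L) x dilution factor x injection volume
#' (L) x 1000. Under the default design this is `conc * 0.09`
#' (e.g. the 10 ng/L level puts 0.9 pg on column).
#'
#' @param conc_ngL concentration(s) in ng/L before IS mixing.
#' @param design a [study_design()].
#' @return pg on column.
#' @examples
#' pg_on_column(10, study_design())  # 0.9
#' @export
pg_on_column <- function(conc_ngL, design = study_design()) {
  if (any(conc_ngL < 0)) stop("concentration must be non-negative", call. = FALSE)
  conc_ngL * design$dilution_factor * (design$injection_uL * 1e-6) * 1000
}

# IS on-column pg: working conc diluted by the IS share of the mix
.is_pg_on_column <- function(design) {
  design$is_conc_ngL * design$is_dilution_factor *
    (design$injection_uL * 1e-6) * 1000
}

#' Simulate a replicate calibration study
#'
#' Generates the peak-area table of a full replicate calibration study: one
#' area per (replicate, level, compound), analytes at their level
#' concentration and internal standards at their constant working
#' concentration. Areas are `rf x pg-on-column` times a mean-one lognormal
#' multiplicative noise term (correlated between analyte and internal
#' standard per the response model), plus an optional additive baseline
#' term. Output is deterministic for a fixed seed.
#'
#' @param design a [study_design()].
#' @param registry a `compound_registry`; every analyte must have an
#'   assigned internal standard.
#' @param response a [response_model()].
#' @param noise a [noise_model()].
#' @param seed integer seed (mandatory; recorded in the result).
#' @return a list of class `replicate_study`: `areas` (data.frame
#'   replicate_id, level_ngL, compound, is_internal_standard, area), `truth`
#'   (per sample x compound: true concentration, pg on column, noiseless
#'   area), plus the design/models/seed used.
#' @examples
#' reg <- pfas_registry()
#' sim <- simulate_replicate_study(study_design(), reg,
#'                                 response_model(reg), noise_model(cv = 0),
#'                                 seed = 1)
#' head(sim$areas)
#' @export
simulate_replicate_study <- function(design, registry, response, noise, seed) {
  stopifnot(inherits(design, "study_design"), inherits(registry, "compound_registry"),
            inherits(response, "response_model"), inherits(noise, "noise_model"))
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  set.seed(as.integer(seed))

  analytes <- registry$id[registry$role == "analyte"]
  iss <- registry$id[registry$role == "internal_standard"]
  no_is <- analytes[!(registry$surrogate_is[match(analytes, registry$id)] %in% iss)]
  if (length(no_is))
    stop("compound(s) without assigned internal standard: ",
         paste(no_is, collapse = ", "), call. = FALSE)
  assigned <- registry$surrogate_is[match(analytes, registry$id)]

  grid <- expand.grid(replicate_id = seq_len(design$n_replicates),
                      level_ngL = design$levels, KEEP.OUT.ATTRS = FALSE)
  n_s <- nrow(grid)
  n_a <- length(analytes); n_i <- length(iss)

  # latent standard normals, fixed draw order for determinism
  z_is <- matrix(stats::rnorm(n_s * n_i), n_s, n_i, dimnames = list(NULL, iss))
  z_an <- matrix(stats::rnorm(n_s * n_a), n_s, n_a, dimnames = list(NULL, analytes))

  if (is.null(response$driver)) {
    eps_is <- z_is
    rho <- response$rho[analytes]
    eps_an <- sweep(z_is[, assigned, drop = FALSE], 2, rho, `*`) +
      sweep(z_an, 2, sqrt(1 - rho^2), `*`)
    colnames(eps_an) <- analytes
  } else {
    # focal-analyte-driven: each IS shares the driver's noise with its own rho
    eps_an <- z_an
    zd <- z_an[, response$driver]
    r <- response$rho_is[iss]
    eps_is <- outer(zd, r) + sweep(z_is, 2, sqrt(1 - r^2), `*`)
    colnames(eps_is) <- iss
  }

  sigma <- sqrt(log(1 + vapply(grid$level_ngL, function(L) .cv_at(noise, L),
                               numeric(1))^2))
  lognoise <- function(eps) exp(eps * sigma - sigma^2 / 2)

  floor_draw <- if (noise$area_floor > 0)
    matrix(noise$area_floor * exp(0.5 * stats::rnorm(n_s * (n_a + n_i))),
           n_s, n_a + n_i)
  else matrix(0, n_s, n_a + n_i)

  pg_an <- pg_on_column(grid$level_ngL, design)        # per sample
  pg_is <- .is_pg_on_column(design)

  rows <- vector("list", n_a + n_i)
  truth <- vector("list", n_a + n_i)
  k <- 0L
  for (a in analytes) {
    k <- k + 1L
    base <- pmin(response$rf[[a]] * pg_an, response$saturation[[a]])
    area <- base * lognoise(eps_an[, a]) + floor_draw[, k]
    rows[[k]] <- data.frame(grid, compound = a, is_internal_standard = FALSE,
                            area = area, stringsAsFactors = FALSE)
    truth[[k]] <- data.frame(grid, compound = a, conc_ngL = grid$level_ngL,
                             pg_on_column = pg_an, noiseless_area = base,
                             stringsAsFactors = FALSE)
  }
  for (i in iss) {
    k <- k + 1L
    base <- pmin(response$rf[[i]] * pg_is, response$saturation[[i]])
    area <- base * lognoise(eps_is[, i]) + floor_draw[, k]
    rows[[k]] <- data.frame(grid, compound = i, is_internal_standard = TRUE,
                            area = area, stringsAsFactors = FALSE)
    truth[[k]] <- data.frame(grid, compound = i, conc_ngL = design$is_conc_ngL,
                             pg_on_column = pg_is, noiseless_area = base,
                             stringsAsFactors = FALSE)
  }
  areas <- do.call(rbind, rows)
  truth <- do.call(rbind, truth)
  rownames(areas) <- rownames(truth) <- NULL
  structure(list(areas = areas, truth = truth, design = design,
                 response = response, noise = noise, seed = as.integer(seed)),
            class = "replicate_study")
}

#' @export
print.replicate_study <- function(x, ...) {
  cat(sprintf("<replicate_study> %d areas (%d replicates x %d levels x %d compounds), seed %d\n",
              nrow(x$areas), x$design$n_replicates, length(x$design$levels),
              length(unique(x$areas$compound)), x$seed))
  invisible(x)
}

#' Surrogate internal-standard scenario
#'
#' Builds a [response_model()] in which every internal standard's log-noise
#' shares the focal analyte's with correlation `exp(-rate * dF)`, where `dF`
#' is the absolute fluorine-count difference between the candidate and the
#' focal analyte. Calibration R-squared against a candidate then degrades
#' with fluorine mismatch, giving the surrogate-selection scan a recoverable
#' trend.
#'
#' @param registry a `compound_registry`.
#' @param base_response a [response_model()] supplying rf/saturation.
#' @param rate decay rate per fluorine of mismatch, >= 0.
#' @param focal focal analyte id (default the ether acid PFO4DA).
#' @param seed unused, accepted for interface symmetry.
#' @return a `response_model` with the driver fields set.
#' @export
make_surrogate_scenario <- function(registry, base_response = response_model(registry),
                                    rate = 0.2, focal = "PFO4DA", seed = NULL) {
  stopifnot(inherits(registry, "compound_registry"))
  if (rate < 0) stop("rate must be non-negative", call. = FALSE)
  f_of <- function(id) {
    f <- registry$parsed_formula[[match(id, registry$id)]]
    if (is.null(f)) stop("compound ", id, " has no formula", call. = FALSE)
    fluorine_count(f)
  }
  iss <- registry$id[registry$role == "internal_standard"]
  dF <- abs(vapply(iss, f_of, numeric(1)) - f_of(focal))
  response_model(registry, rf = base_response$rf, rho = base_response$rho,
                 saturation = base_response$saturation,
                 driver = focal, rho_is = stats::setNames(exp(-rate * dF), iss))
}
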