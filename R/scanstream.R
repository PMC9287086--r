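# Centroided scan-stream simulation with inclusion-list MS2 triggering,
# plus the JSON-lines serialization of scan streams.

#' Chromatographic peak model
#'
#' @param apex_rt apex retention time (min).
#' @param width_sd peak width standard deviation (min), > 0.
#' @param shape `"gaussian"`, `"emg"` (exponentially modified Gaussian with
#'   exponential tail constant `tau`), or `"bimodal"` (breakthrough of
#'   minimally retained material: two Gaussian modes, a `split` fraction of
#'   the area eluting `delta_rt` earlier).
#' @param tau EMG tail time constant (min).
#' @param split bimodal early-mode area fraction in (0, 1).
#' @param delta_rt bimodal mode separation (min).
#' @return a `peak_model`.
#' @export
peak_model <- function(apex_rt, width_sd = 0.05, shape = c("gaussian", "emg", "bimodal"),
                       tau = 0.08, split = 0.3, delta_rt = 0.15) {
  shape <- match.arg(shape)
  if (width_sd <= 0) stop("width_sd must be positive", call. = FALSE)
  if (shape == "bimodal" && (split <= 0 || split >= 1))
    stop("bimodal split fraction must be in (0, 1)", call. = FALSE)
  structure(list(apex_rt = apex_rt, width_sd = width_sd, shape = shape,
                 tau = tau, split = split, delta_rt = delta_rt),
            class = "peak_model")
}

# unit-area elution profile evaluated at times t
.profile_density <- function(pm, t) {
  g <- function(mu) stats::dnorm(t, mu, pm$width_sd)
  switch(pm$shape,
         gaussian = g(pm$apex_rt),
         emg = {
           # exponentially modified Gaussian, unit area
           l <- 1 / pm$tau
           mu <- pm$apex_rt; s <- pm$width_sd
           l / 2 * exp(l / 2 * (2 * mu + l * s^2 - 2 * t)) *
             stats::pnorm((t - mu - l * s^2) / s) * 2
         },
         bimodal = pm$split * g(pm$apex_rt - pm$delta_rt) +
           (1 - pm$split) * g(pm$apex_rt))
}

#' Acquisition configuration
#'
#' Describes the scan scheduler: MS1 scan period, inclusion-list MS2
#' triggering with optional dynamic exclusion, the timed positive-mode
#' window, and the active MS1 mass range(s) (compounds outside every active
#' range are invisible to triggering and to MS1 scans).
#'
#' @param ms1_period MS1 scan period (min).
#' @param inclusion_tol_ppm matching tolerance around inclusion m/z values.
#' @param trigger_threshold minimum summed MS1 intensity inside an inclusion
#'   window to schedule an MS2 scan.
#' @param dynamic_exclusion re-trigger suppression window (min); 0 disables.
#' @param positive_window `c(start, end)` minutes during which positive-mode
#'   scan events run.
#' @param ms1_ranges list of `c(lo, hi)` Da mass ranges.
#' @return an `acquisition_config`.
#' @export
acquisition_config <- function(ms1_period = 0.01, inclusion_tol_ppm = 5,
                               trigger_threshold = 1000, dynamic_exclusion = 0,
                               positive_window = c(9.5, 11.5),
                               ms1_ranges = list(c(50, 1500))) {
  stopifnot(ms1_period > 0, inclusion_tol_ppm >= 0, dynamic_exclusion >= 0)
  structure(list(ms1_period = ms1_period, inclusion_tol_ppm = inclusion_tol_ppm,
                 trigger_threshold = trigger_threshold,
                 dynamic_exclusion = dynamic_exclusion,
                 positive_window = positive_window, ms1_ranges = ms1_ranges),
            class = "acquisition_config")
}

.in_ranges <- function(mz, ranges)
  any(vapply(ranges, function(r) mz >= r[1] && mz <= r[2], logical(1)))

#' Simulate a centroided scan stream for one injection
#'
#' Produces a time-ordered stream of centroided MS1 and MS2 scans. Each MS1
#' scan carries, for every compound of that polarity whose ion falls in an
#' active MS1 mass range, its theoretical isotope pattern scaled by the
#' chromatographic profile (total XIC area = `rf x pg on column`), with
#' ppm-scale mass jitter and optional random baseline centroids. After any
#' MS1 scan in which an inclusion-list entry's window exceeds the trigger
#' threshold (and is not dynamically excluded), an MS2 scan is scheduled
#' whose content is the registry fragment template with
#' concentration-independent relative abundances (times noise). Positive
#' mode scan events run only inside the configured positive window.
#'
#' @param registry a `compound_registry`.
#' @param conc named concentrations (ng/L, pre-dilution) per compound id;
#'   compounds absent from `conc` get their internal-standard working
#'   concentration if they are internal standards, else 0.
#' @param design a [study_design()] (for on-column conversion).
#' @param response a [response_model()] (response factors).
#' @param noise a [noise_model()].
#' @param peaks optional named list of [peak_model()]s; defaults derive from
#'   registry RT, with bimodal shape for early-eluter rows.
#' @param gradient `c(start, end)` minutes.
#' @param acquisition an [acquisition_config()].
#' @param seed integer seed (mandatory).
#' @return a `scan_stream`: list with `scans` (each: rt_min, polarity,
#'   ms_level, mz, intensity, precursor_mz, trigger_id) and the configs used.
#' @export
simulate_scan_stream <- function(registry, conc, design = study_design(),
                                 response = response_model(registry),
                                 noise = noise_model(), peaks = NULL,
                                 gradient = c(0, 20),
                                 acquisition = acquisition_config(), seed) {
  stopifnot(inherits(registry, "compound_registry"),
            inherits(acquisition, "acquisition_config"))
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  set.seed(as.integer(seed))

  reg <- registry[registry$role != "interference", , drop = FALSE]
  masses <- registry_masses(registry)

  comp <- list()
  for (i in seq_len(nrow(reg))) {
    id <- reg$id[i]
    rt <- reg$rt_min[i]
    if (rt < gradient[1] || rt > gradient[2]) {
      warning("compound ", id, " RT outside gradient span; skipped")
      next
    }
    cc <- if (id %in% names(conc)) conc[[id]]
      else if (reg$role[i] == "internal_standard") design$is_conc_ngL else 0
    if (cc <= 0) next
    mz0 <- masses$mz[match(id, masses$id)]
    if (!.in_ranges(mz0, acquisition$ms1_ranges)) next
    pg <- if (reg$role[i] == "internal_standard")
      cc * design$is_dilution_factor * design$injection_uL * 1e-6 * 1000
    else pg_on_column(cc, design)
    pm <- if (!is.null(peaks) && id %in% names(peaks)) peaks[[id]]
      else peak_model(rt + stats::rnorm(1, 0, noise$rt_jitter_sd),
                      shape = if (isTRUE(reg$early_eluter[i])) "bimodal" else "gaussian")
    f <- reg$parsed_formula[[i]]
    pat <- if (!is.null(f)) isotope_pattern(f, threshold = 0.005)
      else data.frame(mz = mz0, abundance = 1)
    # position the pattern at the ion m/z (pattern is neutral-mass based)
    pat$mz <- pat$mz - pat$mz[1] + mz0
    comp[[id]] <- list(id = id, mz = mz0, polarity = reg$polarity[i],
                       area = response$rf[[id]] * pg, pm = pm, pat = pat,
                       frag = parse_frag_template(reg$frag_template[i]))
  }

  times <- seq(gradient[1], gradient[2], by = acquisition$ms1_period)
  pos_win <- acquisition$positive_window
  tol <- acquisition$inclusion_tol_ppm
  last_trigger <- stats::setNames(rep(-Inf, length(comp)), names(comp))
  scans <- vector("list", 0L)
  jit <- noise$mz_jitter_ppm * 1e-6

  emit_ms1 <- function(t, pol) {
    mzs <- numeric(0); ints <- numeric(0)
    for (cp in comp) {
      if (cp$polarity != pol) next
      h <- cp$area * .profile_density(cp$pm, t)
      if (h <= cp$area * 1e-12) next  # negligible tail: keep scans sparse
      keep <- cp$pat$abundance * h
      m <- cp$pat$mz * (1 + stats::rnorm(nrow(cp$pat), 0, jit))
      mzs <- c(mzs, m); ints <- c(ints, keep)
    }
    if (noise$baseline_peaks > 0) {
      nb <- stats::rpois(1, noise$baseline_peaks)
      if (nb > 0) {
        r <- acquisition$ms1_ranges[[1]]
        mzs <- c(mzs, stats::runif(nb, r[1], r[2]))
        ints <- c(ints, stats::rexp(nb, 1 / noise$baseline_intensity))
      }
    }
    o <- order(mzs)
    list(rt_min = t, polarity = pol, ms_level = 1L,
         mz = mzs[o], intensity = ints[o],
         precursor_mz = NULL, trigger_id = NULL)
  }

  for (t in times) {
    pols <- "negative"
    if (t >= pos_win[1] && t <= pos_win[2]) pols <- c("negative", "positive")
    for (pol in pols) {
      s1 <- emit_ms1(t, pol)
      scans[[length(scans) + 1L]] <- s1
      # inclusion-list triggering off this MS1 scan
      for (id in names(comp)) {
        cp <- comp[[id]]
        if (cp$polarity != pol || nrow(cp$frag) == 0L) next
        w <- mz_window(cp$mz, tol)
        inten <- sum(s1$intensity[s1$mz >= w[1] & s1$mz <= w[2]])
        if (inten < acquisition$trigger_threshold) next
        if (acquisition$dynamic_exclusion > 0 &&
            (t - last_trigger[[id]]) < acquisition$dynamic_exclusion) next
        last_trigger[[id]] <- t
        fr <- cp$frag[order(cp$frag$mz), , drop = FALSE]
        fi <- fr$abundance * 1e4 *
          exp(stats::rnorm(nrow(fr), 0, sqrt(log(1 + .cv_at_scalar(noise)^2))))
        scans[[length(scans) + 1L]] <- list(
          rt_min = t + acquisition$ms1_period / 4, polarity = pol,
          ms_level = 2L, mz = fr$mz, intensity = fi,
          precursor_mz = cp$mz, trigger_id = id)
      }
    }
  }
  structure(list(scans = scans, gradient = gradient, acquisition = acquisition,
                 seed = as.integer(seed)),
            class = "scan_stream")
}

# scalar cv for scan-level noise (level-keyed cv vectors fall back to mean)
.cv_at_scalar <- function(noise) {
  cv <- noise$cv
  if (length(cv) == 1L) unname(cv) else mean(cv)
}

#' @export
print.scan_stream <- function(x, ...) {
  lev <- vapply(x$scans, `[[`, integer(1), "ms_level")
  cat(sprintf("<scan_stream> %d scans (%d MS1, %d MS2), %.2f-%.2f min\n",
              length(x$scans), sum(lev == 1L), sum(lev == 2L),
              x$gradient[1], x$gradient[2]))
  invisible(x)
}

#' Write / read a scan stream as JSON lines
#'
#' The documented scan-stream dialect: one JSON object per line with keys
#' `rt_min`, `polarity`, `ms_level`, `mz` (array), `intensity` (array), and
#' for MS2 scans `precursor_mz` and `trigger_id`. Round-trips bit-identically
#' through [read_scan_stream()].
#'
#' @param stream a `scan_stream`.
#' @param path output file path.
#' @return `path` invisibly (writer); a `scan_stream` (reader).
#' @export
write_scan_stream <- function(stream, path) {
  stopifnot(inherits(stream, "scan_stream"))
  con <- file(path, "w")
  on.exit(close(con))
  header <- list(format = "pfasq-scanstream-jsonl", version = 1L,
                 gradient = stream$gradient, seed = stream$seed)
  writeLines(jsonlite::toJSON(header, auto_unbox = TRUE, digits = NA), con)
  for (s in stream$scans) {
    rec <- list(rt_min = s$rt_min, polarity = s$polarity, ms_level = s$ms_level,
                mz = as.numeric(s$mz), intensity = as.numeric(s$intensity))
    if (!is.null(s$precursor_mz)) {
      rec$precursor_mz <- s$precursor_mz
      rec$trigger_id <- s$trigger_id
    }
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA), con)
  }
  invisible(path)
}

#' @rdname write_scan_stream
#' @export
read_scan_stream <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0L) stop("empty scan stream file", call. = FALSE)
  header <- jsonlite::fromJSON(lines[1])
  if (!identical(header$format, "pfasq-scanstream-jsonl"))
    stop("not a pfasq JSON-lines scan stream: ", path, call. = FALSE)
  scans <- lapply(lines[-1], function(l) {
    s <- jsonlite::fromJSON(l)
    list(rt_min = s$rt_min, polarity = s$polarity, ms_level = as.integer(s$ms_level),
         mz = as.numeric(s$mz), intensity = as.numeric(s$intensity),
         precursor_mz = s$precursor_mz, trigger_id = s$trigger_id)
  })
  structure(list(scans = scans, gradient = as.numeric(header$gradient),
                 acquisition = NULL, seed = header$seed),
            class = "scan_stream")
}
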