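# End-to-end study runner: simulate -> calibrate -> validate.

#' Run a full synthetic validation study
#'
#' Convenience wrapper chaining [simulate_replicate_study()],
#' [quantify_study()], and [build_validation_report()]. With `noise =
#' noise_model(cv = 0)` the pipeline is an identity check: every
#' back-calculated concentration equals its level, IDA = 100%, IDP = 0%,
#' and the MRL is the lowest level.
#'
#' @param registry a `compound_registry`.
#' @param design a [study_design()].
#' @param response a [response_model()].
#' @param noise a [noise_model()].
#' @param seed integer seed.
#' @param weighting calibration weighting.
#' @param cal_replicate replicate used as the calibration curve.
#' @param alpha,sided,min_replicates validation parameters, see
#'   [build_validation_report()].
#' @return a `pfas_study` list: `sim` (`replicate_study`), `quant`
#'   (`quantified_study`), `report` (`validation_report`), `seed`.
#' @examples
#' \donttest{
#' reg <- pfas_registry()
#' st <- run_validation_study(reg, noise = noise_model(cv = 0), seed = 1)
#' st$report[1:3, ]
#' }
#' @export
run_validation_study <- function(registry = pfas_registry(),
                                 design = study_design(),
                                 response = response_model(registry),
                                 noise = noise_model(), seed,
                                 weighting = "1/x", cal_replicate = 1L,
                                 alpha = 0.01, sided = "two",
                                 min_replicates = 7L) {
  sim <- simulate_replicate_study(design, registry, response, noise, seed = seed)
  quant <- quantify_study(sim$areas, registry, weighting = weighting,
                          cal_replicate = cal_replicate)
  report <- build_validation_report(quant, registry, design = design,
                                    alpha = alpha, sided = sided,
                                    min_replicates = min_replicates)
  structure(list(sim = sim, quant = quant, report = report,
                 seed = as.integer(seed)),
            class = "pfas_study")
}

#' @export
print.pfas_study <- function(x, ...) {
  cat("End-to-end synthetic PFAS validation study (seed ", x$seed, ")\n",
      sep = "")
  print(x$sim); print(x$quant); print(x$report)
  invisible(x)
}
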