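#' Analysis configuration
#'
#' Bundles every tunable setting consumed by the pipeline, with JSON
#' round-trip support so runs are reproducible from a single file.
#'
#' @param alpha_normality significance level of the Shapiro-Wilk gate that
#'   chooses between t-test and Wilcoxon ([compare_groups()]).
#' @param dnt_normalization `"split"` (wrong turns per intersection +
#'   hesitations per km) or `"combined"` ([route_disorientation_score()]).
#' @param dnt_risk_tolerance tolerance around a composite score of 1 for the
#'   high/low risk split ([classify_risk()]).
#' @param shq_reference_distance,shq_reference_duration wayfinding
#'   normalization constants ([shq_wayfinding_scores()]).
#' @param imputation whether non-attempters receive worst observed
#'   wayfinding scores at the regression stage ([impute_worst()]).
#' @param seed integer seed for any stochastic step.
#' @param out_dir default output directory for [write_results()].
#' @return validated list of class `analysis_config`.
#' @export
analysis_config <- function(alpha_normality = 0.05,
                            dnt_normalization = "split",
                            dnt_risk_tolerance = 1e-9,
                            shq_reference_distance = 1,
                            shq_reference_duration = 1,
                            imputation = TRUE,
                            seed = 1,
                            out_dir = "results") {
  stopifnot(alpha_normality > 0, alpha_normality < 1,
            dnt_normalization %in% c("split", "combined"),
            dnt_risk_tolerance >= 0,
            shq_reference_distance > 0, shq_reference_duration > 0,
            is.logical(imputation), length(seed) == 1)
  out <- list(alpha_normality = alpha_normality,
              dnt_normalization = dnt_normalization,
              dnt_risk_tolerance = dnt_risk_tolerance,
              shq_reference_distance = shq_reference_distance,
              shq_reference_duration = shq_reference_duration,
              imputation = imputation,
              seed = as.integer(seed),
              out_dir = out_dir)
  class(out) <- "analysis_config"
  out
}

#' @rdname analysis_config
#' @param config an `analysis_config` object.
#' @param path JSON file path.
#' @export
write_analysis_config <- function(config, path) {
  stopifnot(inherits(config, "analysis_config"))
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname analysis_config
#' @export
read_analysis_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(analysis_config, raw)
}
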