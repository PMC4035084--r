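#' Default run configuration
#'
#' Returns the full set of pipeline parameters as a nested list. Every
#' threshold used by a pipeline stage lives here so that a single YAML file
#' controls a run. Defaults are the analysis conventions this package is
#' built around: consensus CNVs require a 50% reciprocal overlap between
#' callers, catalog matches require 40% reciprocal overlap, calls with a
#' Log Bayes Factor below 10 are dropped, CNV regions at carrier frequency
#' >= 1% are "common", the large-CNV score keeps events >= 100 kb, and
#' interaction terms enter association models at Bonferroni alpha 0.002.
#'
#' @param seed integer seed recorded in (and controlling) every stochastic
#'   stage of a run.
#' @return a named list with components `seed`, `cohort`, `thresholds`,
#'   `variance_fractions`, `paths`.
#' @export
default_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    genome_build = "unspecified",   # annotation only; coordinates pass through verbatim
    cohort = list(
      n_subjects = 2348L,
      n_group_a = 1850L,           # two-level ancestry split
      n_group_b = 498L,
      imputation_quality = 0.95,
      proxy_r2 = 0.8
    ),
    thresholds = list(
      reciprocal_overlap = 0.5,
      catalog_overlap = 0.4,
      lbf_min = 10,
      common_freq = 0.01,
      large_cnv_bp = 100000,
      interaction_alpha = 0.002
    ),
    variance_fractions = list(
      covariates = 0.083,
      grss = 0.031,
      cnv = 0.001
    ),
    paths = list(
      variant_catalog = NULL,
      genotypes = NULL,
      cnv_calls = NULL,
      cnv_catalog = NULL,
      exclusion_bed = NULL,
      phenotypes = NULL
    )
  )
}

#' Validate a run configuration
#'
#' Checks the invariants every stage relies on: variance fractions in
#' \[0, 1\] summing to at most 1, strictly positive thresholds, and an
#' integer seed.
#'
#' @param config a list as returned by [default_config()].
#' @return the config, invisibly, if valid; otherwise an error.
#' @export
validate_config <- function(config) {
  fr <- unlist(config$variance_fractions)
  if (any(fr < 0 | fr > 1)) {
    stop("variance fractions must lie in [0, 1]", call. = FALSE)
  }
  if (sum(fr) > 1) {
    stop("variance fractions sum to ", sum(fr), " (> 1)", call. = FALSE)
  }
  th <- unlist(config$thresholds)
  if (any(!is.finite(th)) || any(th <= 0)) {
    stop("all thresholds must be strictly positive", call. = FALSE)
  }
  if (is.null(config$seed) || is.na(suppressWarnings(as.integer(config$seed)))) {
    stop("config must carry an integer seed", call. = FALSE)
  }
  invisible(config)
}

#' Read a YAML run configuration
#'
#' Values absent from the file fall back to [default_config()]; the merged
#' configuration is validated before being returned.
#'
#' @param path YAML file.
#' @return validated config list.
#' @export
read_run_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- utils::modifyList(default_config(), user)
  validate_config(cfg)
  cfg
}

#' Write a run configuration as YAML
#'
#' Every pipeline run emits its fully resolved configuration (seed included)
#' alongside its outputs so that re-running the file reproduces the run.
#'
#' @param config config list.
#' @param path output YAML file.
#' @export
write_run_config <- function(config, path) {
  validate_config(config)
  yaml::write_yaml(config, path)
  invisible(path)
}

# Stage logging: every filtering stage reports counts in/out on one line.
stage_log <- function(stage, n_in, n_out, extra = NULL, verbose = TRUE) {
  msg <- sprintf("[%s] in=%d out=%d removed=%d%s", stage, n_in, n_out,
                 n_in - n_out, if (is.null(extra)) "" else paste0(" ", extra))
  if (verbose) message(msg)
  invisible(msg)
}
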