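#' Assemble a validated pipeline run configuration
#'
#' Collects per-stage parameters for a full smFRET analysis run:
#' simulation (or a path to trace TSVs), QC settings, histogram and
#' mixture-fit settings, and the Förster radius.  All randomness in the
#' run flows from the single `seed`.  When `R0` is omitted the working
#' value of 5.8 nm is used and a notice is logged.
#'
#' @param simulate list of arguments for [sim_params()], or `NULL` to
#'   read traces from `traces_path`
#' @param traces_path TSV of traces (see [read_traces()]) when not
#'   simulating
#' @param qc list: `min_segment`, `penalty`, `gamma_window`,
#'   `gamma_bounds`
#' @param histogram list: `min_points`
#' @param fit list: `n_components`, `init` (optional means)
#' @param R0 Förster radius in nm; `NULL` for the 5.8 nm default
#' @param seed master seed
#' @param out_dir output directory for the run report files, or `NULL`
#'   to skip writing
#' @return an object of class `run_config`
#' @export
run_config <- function(simulate = list(), traces_path = NULL,
                       qc = list(), histogram = list(), fit = list(),
                       R0 = NULL, seed = 1L, out_dir = NULL) {
  assert_that(!(is.null(simulate) && is.null(traces_path)),
              "either simulate parameters or traces_path must be given")
  cfg <- list(simulate = simulate, traces_path = traces_path,
              qc = qc, histogram = histogram, fit = fit,
              R0 = R0, seed = as.integer(seed), out_dir = out_dir)
  # validate eagerly so a bad config fails before any stage runs
  if (!is.null(simulate)) do.call(sim_params, c(simulate, list(seed = seed)))
  if (!is.null(R0)) forster_model(R0)
  nc <- cfg$fit$n_components
  if (!is.null(nc))
    assert_that(nc >= 1 && nc <= 4, "fit$n_components must be between 1 and 4")
  class(cfg) <- "run_config"
  cfg
}

#' Load / save a run configuration as YAML
#' @param path YAML file
#' @return a [run_config()] object
#' @export
read_run_config <- function(path) {
  do.call(run_config, yaml::read_yaml(path))
}

#' @rdname read_run_config
#' @param config a `run_config`
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

# Stable hash of a config for the provenance block.
config_hash <- function(config) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  jsonlite::write_json(unclass(config), f, auto_unbox = TRUE, digits = NA,
                       null = "null", force = TRUE)
  unname(tools::md5sum(f))
}

#' Run the full smFRET analysis pipeline
#'
#' Executes simulate (optional) -> QC/trace selection -> gamma-corrected
#' FRET computation -> summed trace-normalized histogram -> Gaussian
#' mixture fit -> Förster distance conversion of the fitted peaks.
#' Identical config + seed gives identical numeric outputs.  When
#' `config$out_dir` is set, writes `histogram.tsv`, `fit.json`,
#' `distances.tsv`, `qc_summary.tsv` and `provenance.json`.
#'
#' @param config a [run_config()]
#' @param quiet suppress log messages
#' @return a run report: list with `qc_summary`, `n_traces`, `histogram`,
#'   `fit`, `distances` (data.frame of fitted peaks with nm distances),
#'   `R0`, `provenance`
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  log_msg <- function(...) if (!quiet) message("[smfretr] ", ...)

  if (!is.null(config$simulate)) {
    params <- do.call(sim_params, c(config$simulate,
                                    list(seed = config$seed)))
    log_msg("simulating ", params$n_molecules, " traces")
    traces <- simulate_ensemble(params)
  } else {
    log_msg("reading traces from ", config$traces_path)
    traces <- read_traces(config$traces_path)
  }

  qc_args <- config$qc[names(config$qc) %in%
                         c("min_segment", "penalty", "gamma_window",
                           "gamma_bounds")]
  qc <- do.call(qc_ensemble, c(list(traces), qc_args))
  log_msg("QC: ", qc$summary[["accepted"]], "/", length(traces), " accepted")

  fret_traces <- list()
  n_fret_rejected <- 0L
  for (i in seq_along(traces)) {
    r <- qc$results[[i]]
    if (!r$accepted) next
    ft <- tryCatch(compute_fret(traces[[i]], r), error = function(e) NULL)
    if (is.null(ft)) n_fret_rejected <- n_fret_rejected + 1L
    else fret_traces[[length(fret_traces) + 1L]] <- ft
  }

  min_points <- config$histogram$min_points
  if (is.null(min_points)) min_points <- 20L
  hist <- build_histogram(fret_traces, min_points = min_points)

  nc <- config$fit$n_components
  if (is.null(nc)) nc <- 2L
  fit <- fit_mixture(hist, n_components = nc, init = config$fit$init)

  if (is.null(config$R0)) {
    log_msg("no R0 configured; using the 5.8 nm working value")
    model <- forster_model()
  } else model <- forster_model(config$R0)
  R <- fret_to_distance(fit$components$mean, model, clamp = TRUE)
  distances <- data.frame(
    component = seq_len(nc),
    mean_E = fit$components$mean,
    fractional_area = fit$components$fractional_area,
    distance_nm = as.numeric(R),
    distance_nm_reported = format_distance(as.numeric(R)),
    clamped = if (is.null(attr(R, "clamped"))) FALSE else attr(R, "clamped"))

  provenance <- list(config_hash = config_hash(config), seed = config$seed,
                     r_version = as.character(getRversion()),
                     package_version = as.character(
                       utils::packageVersion("smfretr")))

  report <- list(qc_summary = qc$summary, n_traces = length(traces),
                 n_fret_rejected = n_fret_rejected,
                 histogram = hist, fit = fit, distances = distances,
                 R0 = model$R0, provenance = provenance)

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_histogram(hist, file.path(config$out_dir, "histogram.tsv"))
    jsonlite::write_json(
      list(components = fit$components, residual_sse = fit$residual_sse,
           n_components = fit$n_components, bic = fit$bic),
      file.path(config$out_dir, "fit.json"),
      auto_unbox = TRUE, digits = NA, dataframe = "columns")
    utils::write.table(distances, file.path(config$out_dir, "distances.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    utils::write.table(
      data.frame(code = names(qc$summary), count = as.integer(qc$summary)),
      file.path(config$out_dir, "qc_summary.tsv"),
      sep = "\t", row.names = FALSE, quote = FALSE)
    jsonlite::write_json(provenance, file.path(config$out_dir, "provenance.json"),
                         auto_unbox = TRUE)
  }
  report
}
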