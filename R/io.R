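# Readers/writers and the pipeline runner.  Canonical interchange formats:
# comma-separated text with a header row for tables, JSON for model
# configurations, YAML for run specifications.

trial_table_columns <- c("cell_id", "cell_class", "condition_type",
                         "condition_value", "trial_index", "spike_count",
                         "spl_db")

#' Write a trial table
#'
#' @param table Trial-table data frame (see [read_trial_table()] for the
#'   schema).
#' @param path Output CSV path.
#' @export
write_trial_table <- function(table, path) {
  missing <- setdiff(trial_table_columns, names(table))
  if (length(missing))
    stop("trial table is missing columns: ", paste(missing, collapse = ", "))
  write.csv(table[trial_table_columns], path, row.names = FALSE)
  invisible(path)
}

#' Read and validate a trial table
#'
#' Canonical per-trial spike-count format: CSV with header columns
#' `cell_id`, `cell_class`, `condition_type` (ITD, IID or SPL),
#' `condition_value` (ms for ITD, dB otherwise), `trial_index`,
#' `spike_count`, `spl_db`.  Validation failures name the offending rows.
#'
#' @param path CSV file path.
#' @return Validated data frame; ragged repetition counts are flagged with a
#'   `ragged` attribute.
#' @export
read_trial_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(trial_table_columns, names(df))
  if (length(missing))
    stop("schema violation: missing columns ", paste(missing, collapse = ", "))
  bad <- which(!is.finite(df$spike_count) | df$spike_count < 0 |
                 df$spike_count != round(df$spike_count))
  if (length(bad))
    stop("schema violation: non-integer or negative spike_count in row(s) ",
         paste(head(bad, 5), collapse = ", "))
  if (!all(df$condition_type %in% c("ITD", "IID", "SPL")))
    stop("schema violation: condition_type must be ITD, IID or SPL")
  nt <- table(df$cell_id, df$condition_value)
  ragged <- length(unique(nt[nt > 0])) > 1
  attr(df, "ragged") <- ragged
  df
}

#' Serialize a model configuration to JSON
#'
#' Writes the coupling configuration (keys `kappa_fwd`, `kappa_bwd`,
#' `R1_Mohm`, `tau_m_ms`, `alpha`, `Cm_uF_cm2`, `E_rest_mV`), the synaptic
#' preset, and the derived passive/calibrated parameters under `"derived"`.
#'
#' @param model An [lso_model()] object.
#' @param path Output JSON path.
#' @export
write_model_config <- function(model, path) {
  cfg <- list(
    kappa_fwd = model$coupling$kappa_fwd,
    kappa_bwd = model$coupling$kappa_bwd,
    R1_Mohm = model$coupling$R1,
    tau_m_ms = model$coupling$tau_m,
    alpha = model$coupling$alpha,
    Cm_uF_cm2 = model$coupling$Cm,
    E_rest_mV = model$E_rest,
    preset = model$preset,
    spike_threshold_mV = model$spike_threshold,
    dt_ms = model$dt,
    derived = list(
      g1_uS = model$passive$g1, g2_uS = model$passive$g2,
      gax_uS = model$passive$gax, c1_nF = model$passive$c1,
      R2_Mohm = model$passive$R2, R12_Mohm = model$passive$R12,
      g_Na_uS = model$currents$g_Na, g_KHT_uS = model$currents$g_KHT,
      threshold_epsp_mV = model$calibration$threshold_epsp
    )
  )
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Rebuild a model from a JSON configuration
#'
#' @param path JSON path written by [write_model_config()].
#' @param recalibrate Re-run [calibrate_gna()] (default) or reuse the stored
#'   `g_Na`.
#' @return An [lso_model()] object.
#' @export
read_model_config <- function(path, recalibrate = TRUE) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  m <- lso_model(kappa_fwd = cfg$kappa_fwd, kappa_bwd = cfg$kappa_bwd,
                 R1 = cfg$R1_Mohm, tau_m = cfg$tau_m_ms, alpha = cfg$alpha,
                 Cm = cfg$Cm_uF_cm2, E_rest = cfg$E_rest_mV,
                 preset = cfg$preset,
                 spike_threshold = cfg$spike_threshold_mV, dt = cfg$dt_ms,
                 calibrate = recalibrate,
                 g_Na = if (recalibrate) 0.3 else cfg$derived$g_Na_uS)
  if (!recalibrate && !is.null(cfg$derived$g_Na_uS)) {
    m$currents$g_Na <- cfg$derived$g_Na_uS
    m$currents$g_KHT <- 0.1 * cfg$derived$g_Na_uS
    m$calibration <- list(threshold_epsp = cfg$derived$threshold_epsp_mV,
                          target = NA_real_)
    m$calibrated <- TRUE
  }
  m
}

#' Run a full pipeline from a configuration
#'
#' Executes a stage sequence and writes all outputs plus a provenance record
#' (configuration hash, seed, package version) to `out_dir`.  Supported
#' stages:
#' \describe{
#'   \item{`model`}{build and calibrate an [lso_model()] from
#'     `config$model` arguments; writes `model.json`.}
#'   \item{`tune`}{semi-analytic tuning curves for `config$arrangements`
#'     over `config$itd_grid`; writes `tuning.csv`.}
#'   \item{`synth`}{generate a synthetic trial table from
#'     `config$synth` ([synth_spec()] arguments); writes `trials.csv`.}
#'   \item{`metrics`}{tuning metrics + ITD-SNR on the generated (or
#'     `config$table`) trial table; writes `metrics.csv`.}
#' }
#'
#' @param config A named list, or path to a YAML file with the same
#'   structure.  `config$stages` selects and orders the stages;
#'   `config$seed` seeds all stochastic stages.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the stage results and the provenance
#'   record.
#' @export
run_pipeline <- function(config, out_dir = ".") {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed %||% 1
  stages <- config$stages %||% c("model", "tune")

  cfg_file <- tempfile(fileext = ".json")
  jsonlite::write_json(config, cfg_file, auto_unbox = TRUE, digits = NA)
  provenance <- list(config_hash = unname(tools::md5sum(cfg_file)),
                     seed = seed,
                     package_version = as.character(utils::packageVersion("lsoveto")))
  unlink(cfg_file)

  results <- list()
  model <- NULL
  trials <- NULL
  for (stage in stages) {
    res <- tryCatch(switch(stage,
      model = {
        model <- do.call(lso_model, config$model %||% list())
        write_model_config(model, file.path(out_dir, "model.json"))
        model
      },
      tune = {
        if (is.null(model)) model <- lso_model()
        grid <- config$itd_grid %||% seq(-2, 2, by = 0.05)
        arrs <- config$arrangements %||% c("8+0", "6+2", "0+2")
        curve <- predict(model, itd = grid, arrangement = arrs)
        write_tuning(curve, file.path(out_dir, "tuning.csv"))
        curve
      },
      synth = {
        spec <- do.call(synth_spec,
                        modifyList(config$synth %||% list(),
                                   list(seed = seed)))
        trials <- gen_trial_table(spec)
        write_trial_table(trials, file.path(out_dir, "trials.csv"))
        trials
      },
      metrics = {
        if (!is.null(config$table)) trials <- read_trial_table(config$table)
        if (is.null(trials)) stop("metrics stage requires a synth stage or config$table")
        agg <- aggregate(spike_count ~ condition_value, trials, mean)
        mode <- if (any(trials$cell_class == "MSO")) "peak" else "trough"
        tm <- tuning_metrics(agg$condition_value, agg$spike_count, mode)
        snr <- itd_snr(trials, min_reps = 1, allow_ragged = TRUE)
        mdf <- data.frame(metric = c("halfwidth_ms", "slope_left", "slope_right",
                                     "itd_snr"),
                          value = c(tm$halfwidth, tm$slopes["left"],
                                    tm$slopes["right"], snr))
        write.csv(mdf, file.path(out_dir, "metrics.csv"), row.names = FALSE)
        mdf
      },
      stop("unknown stage: ", stage)
    ), error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", stage,
                   conditionMessage(e)), call. = FALSE)
    })
    results[[stage]] <- res
  }
  jsonlite::write_json(provenance, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(c(results, list(provenance = provenance)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
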