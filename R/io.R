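# CSV I/O for measured datasets and YAML round-tripping for run
# configurations. All concentrations are nM, volumes uL, times hours.

#' Read a measured dataset from CSV
#'
#' Reads and validates a tidy replicate-level dataset (schema:
#' `condition_id, inhibitor_level_nM, chamber, analyte, replicate, conc_nM,
#' dilution, esterase_inhibitors`). Malformed rows — missing or negative
#' concentrations, unknown chambers — are reported with their line numbers.
#'
#' @param path Path to a CSV file.
#' @return A `measured_dataset` tibble.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' write_measured_dataset(generate_dataset(assay_design(seed = 1)), f)
#' d <- read_measured_dataset(f)
#' @export
read_measured_dataset <- function(path) {
  if (!file.exists(path)) {
    rlang::abort(paste0("file not found: ", path), class = "dialyzr_io_error")
  }
  d <- tryCatch(
    readr::read_csv(path, col_types = readr::cols(
      condition_id = readr::col_character(),
      inhibitor_level_nM = readr::col_double(),
      chamber = readr::col_character(),
      analyte = readr::col_character(),
      replicate = readr::col_integer(),
      conc_nM = readr::col_double(),
      dilution = readr::col_double(),
      esterase_inhibitors = readr::col_logical()
    ), na = c("", "NA")),
    error = function(e) {
      rlang::abort(paste0("could not parse ", path, ": ",
                          conditionMessage(e)),
                   class = "dialyzr_io_error")
    })
  if (nrow(d) == 0) {
    rlang::abort("dataset file is empty", class = "dialyzr_io_error")
  }
  .check_dataset(d)
  # data-file lines: header is line 1, so row i lives on line i + 1
  bad_na <- which(is.na(d$conc_nM))
  bad_neg <- which(!is.na(d$conc_nM) & d$conc_nM < 0)
  bad_cham <- which(!d$chamber %in% c("sample", "buffer"))
  problems <- c(
    if (length(bad_na)) paste0("missing conc_nM on line(s) ",
                               paste(bad_na + 1, collapse = ", ")),
    if (length(bad_neg)) paste0("negative conc_nM on line(s) ",
                                paste(bad_neg + 1, collapse = ", ")),
    if (length(bad_cham)) paste0("unknown chamber on line(s) ",
                                 paste(bad_cham + 1, collapse = ", "))
  )
  if (length(problems) > 0) {
    rlang::abort(paste(problems, collapse = "; "),
                 class = "dialyzr_validation_error")
  }
  class(d) <- c("measured_dataset", class(d))
  d
}

#' @rdname read_measured_dataset
#' @param data A `measured_dataset` tibble to write.
#' @return `write_measured_dataset()` returns `path` invisibly.
#' @export
write_measured_dataset <- function(data, path) {
  .check_dataset(data)
  readr::write_csv(
    data[, c("condition_id", "inhibitor_level_nM", "chamber", "analyte",
             "replicate", "conc_nM", "dilution", "esterase_inhibitors")],
    path)
  invisible(path)
}

#' Assemble a complete, validated run configuration
#'
#' A run configuration gathers every knob of the simulate-estimate-compare
#' workflow with its standard default: geometry, design parameters, noise,
#' seed, reporting scale, and the QC thresholds (b window 0.4-0.7, stability
#' gate 0.90, classification threshold 5 %). Configurations round-trip
#' losslessly through YAML via [read_run_config()] / [write_run_config()].
#'
#' @param site_conc,tracer_name,tracer_kd,tracer_conc,inhibitor_name,inhibitor_kd,inhibitor_amounts,dilution,esterase_inhibitors,replicates,noise_cv,incubation_h
#'   Passed to [assay_design()].
#' @param v_sample,v_buffer Chamber volumes (uL).
#' @param scale I50 reporting scale.
#' @param b_window,stability_threshold,classification_threshold QC gate
#'   settings.
#' @param elisa_ic50_true_uM,elisa_hill Parameters of the simulated plate
#'   comparison stage.
#' @param seed Integer seed driving all randomness in the workflow.
#' @return A named list of class `run_config`.
#' @examples
#' cfg <- run_config(seed = 11)
#' @export
run_config <- function(site_conc = 2.4,
                       tracer_name = "d3-morphine", tracer_kd = 2,
                       tracer_conc = 5,
                       inhibitor_name = "morphine", inhibitor_kd = 2,
                       inhibitor_amounts = NULL,
                       dilution = 400, esterase_inhibitors = FALSE,
                       replicates = 3, noise_cv = 0.02, incubation_h = 24,
                       v_sample = 100, v_buffer = 300,
                       scale = c("buffer-initial", "total-volume"),
                       b_window = c(0.4, 0.7),
                       stability_threshold = 0.90,
                       classification_threshold = 5,
                       elisa_ic50_true_uM = 1.1, elisa_hill = 1,
                       seed = 1L) {
  scale <- match.arg(scale)
  stopifnot(length(b_window) == 2, b_window[1] < b_window[2],
            stability_threshold > 0, stability_threshold <= 1,
            is.numeric(seed), length(seed) == 1)
  cfg <- list(
    site_conc = site_conc,
    tracer_name = tracer_name, tracer_kd = tracer_kd,
    tracer_conc = tracer_conc,
    inhibitor_name = inhibitor_name, inhibitor_kd = inhibitor_kd,
    inhibitor_amounts = inhibitor_amounts,
    dilution = dilution, esterase_inhibitors = esterase_inhibitors,
    replicates = as.integer(replicates), noise_cv = noise_cv,
    incubation_h = incubation_h,
    v_sample = v_sample, v_buffer = v_buffer,
    scale = scale,
    b_window = b_window,
    stability_threshold = stability_threshold,
    classification_threshold = classification_threshold,
    elisa_ic50_true_uM = elisa_ic50_true_uM, elisa_hill = elisa_hill,
    seed = as.integer(seed)
  )
  class(cfg) <- "run_config"
  cfg
}

#' Read / write a run configuration as YAML
#'
#' @param path Path to a YAML file.
#' @return `read_run_config()` returns a validated `run_config`;
#'   `write_run_config()` returns `path` invisibly.
#' @examples
#' f <- tempfile(fileext = ".yml")
#' write_run_config(run_config(seed = 5), f)
#' identical(read_run_config(f), run_config(seed = 5))
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) {
    rlang::abort(paste0("file not found: ", path), class = "dialyzr_io_error")
  }
  raw <- yaml::read_yaml(path)
  do.call(run_config, raw[!vapply(raw, is.null, logical(1))])
}

#' @rdname read_run_config
#' @param config A [run_config()].
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Run the full simulate-estimate-compare workflow
#'
#' Chains the three stages under one seed: (1) simulate a replicate-level
#' measured dataset from the configured cassette, (2) estimate b, Tt, I50 and
#' the Mueller Kd with QC gates and classification, (3) simulate and fit the
#' matching competition-ELISA curve and report the fitted-IC50-to-estimated-Kd
#' ratio. A provenance record (config hash, seed, package version) makes any
#' report re-runnable; identical configurations yield identical reports.
#'
#' @param config A [run_config()].
#' @param out_dir Optional directory; when given, the dataset (CSV), the
#'   estimate (JSON), the comparison (CSV) and the provenance (JSON) are
#'   written there.
#' @return A list of class `workflow_report`: `dataset`, `estimate`,
#'   `elisa_fit`, `comparison` (one-row tibble), `provenance`.
#' @examples
#' rep <- run_workflow(run_config(seed = 3))
#' rep$comparison
#' @export
run_workflow <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  geo <- dialysis_geometry(config$v_sample, config$v_buffer)
  design <- assay_design(
    site_conc = config$site_conc,
    tracer_name = config$tracer_name, tracer_kd = config$tracer_kd,
    tracer_conc = config$tracer_conc,
    inhibitor_name = config$inhibitor_name,
    inhibitor_kd = config$inhibitor_kd,
    inhibitor_amounts = config$inhibitor_amounts,
    dilution = config$dilution,
    esterase_inhibitors = config$esterase_inhibitors,
    replicates = config$replicates, noise_cv = config$noise_cv,
    incubation_h = config$incubation_h, geometry = geo,
    scale = config$scale, seed = config$seed
  )

  dataset <- .stage("simulate", generate_dataset(design))
  estimate <- .stage("estimate", estimate_kd(
    dataset,
    b_window = config$b_window,
    stability_threshold = config$stability_threshold,
    classification_threshold = config$classification_threshold
  ))

  elisa_data <- .stage("compare", simulate_elisa_curve(
    config$elisa_ic50_true_uM, hill = config$elisa_hill,
    noise_cv = config$noise_cv, n_replicates = config$replicates,
    seed = config$seed + 1L))
  elisa_fit <- .stage("compare", fit_4pl(elisa_data))

  comparison <- tibble::tibble(
    kd_nM = estimate$kd,
    ic50_uM = elisa_fit$ic50,
    ratio = dplyr::if_else(!is.na(estimate$kd) & !is.na(elisa_fit$ic50),
                           elisa_fit$ic50 * 1e3 / estimate$kd, NA_real_)
  )

  provenance <- list(
    config_hash = digest::digest(unclass(config)),
    seed = config$seed,
    package_version = as.character(utils::packageVersion("dialyzr"))
  )

  report <- structure(
    list(dataset = dataset, estimate = estimate, elisa_fit = elisa_fit,
         comparison = comparison, provenance = provenance),
    class = "workflow_report")

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_measured_dataset(dataset, file.path(out_dir, "dataset.csv"))
    jsonlite::write_json(as.list(tidy(estimate)),
                         file.path(out_dir, "estimate.json"),
                         auto_unbox = TRUE, digits = NA)
    readr::write_csv(comparison, file.path(out_dir, "comparison.csv"))
    jsonlite::write_json(provenance, file.path(out_dir, "provenance.json"),
                         auto_unbox = TRUE)
  }
  report
}

# label stage errors with the stage name for workflow diagnostics
.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    rlang::abort(paste0("stage '", name, "' failed: ", conditionMessage(e)),
                 class = "dialyzr_stage_error", parent = e)
  })
}

#' @export
print.workflow_report <- function(x, ...) {
  cat("<workflow_report>\n")
  cat(sprintf("  provenance: seed %d, config %s, dialyzr %s\n",
              x$provenance$seed, substr(x$provenance$config_hash, 1, 8),
              x$provenance$package_version))
  print(x$estimate)
  cat(sprintf("  ELISA IC50: %.4g uM | IC50/Kd ratio: %.4g\n",
              x$elisa_fit$ic50, x$comparison$ratio))
  invisible(x)
}
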