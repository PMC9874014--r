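#' Assemble a pipeline configuration
#'
#' Collects every knob of the end-to-end run. Paths may be `NULL` when the
#' corresponding object is passed directly to [run_pipeline()].
#'
#' @param model_path model file (JSON or SBML); ignored when `model` given.
#' @param proteome_path,annotation_path,medium_path,measured_flux_path input
#'   TSVs (see the `read_*_tsv` helpers).
#' @param objective_reaction_id objective override (default: the model's
#'   flagged objective).
#' @param k_grid,r_grid sweep axes; defaults are log-spaced and include the
#'   working point k = 0.016, r = 0.05.
#' @param b_max flux bound of the most abundant reaction.
#' @param turnover_rate assumed protein turnover, day^-1.
#' @param measured_atp,measured_glucose calibration measurements (pmol per
#'   ng protein per day); `NULL` skips calibration and reports the budget
#'   in arbitrary units at the default working point.
#' @param mode exchange-bound mode, `"dmem"` or `"measured"`.
#' @param seed integer seed recorded with the outputs.
#' @param output_dir directory for result tables; `NULL` disables writing.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(model_path = NULL, proteome_path = NULL,
                            annotation_path = NULL, medium_path = NULL,
                            measured_flux_path = NULL,
                            objective_reaction_id = NULL,
                            k_grid = signif(10^seq(log10(0.004), log10(4),
                                                   length.out = 7), 3),
                            r_grid = signif(10^seq(log10(0.0125), log10(0.8),
                                                   length.out = 7), 3),
                            b_max = 1000, turnover_rate = 0.5,
                            measured_atp = NULL, measured_glucose = NULL,
                            mode = c("dmem", "measured"), seed = 1L,
                            output_dir = NULL) {
  mode <- match.arg(mode)
  stopifnot(length(k_grid) > 0, length(r_grid) > 0, b_max > 0)
  k_grid <- sort(unique(c(k_grid, 0.016)))
  r_grid <- sort(unique(c(r_grid, 0.05)))
  structure(
    list(model_path = model_path, proteome_path = proteome_path,
         annotation_path = annotation_path, medium_path = medium_path,
         measured_flux_path = measured_flux_path,
         objective_reaction_id = objective_reaction_id,
         k_grid = k_grid, r_grid = r_grid, b_max = b_max,
         turnover_rate = turnover_rate, measured_atp = measured_atp,
         measured_glucose = measured_glucose, mode = mode,
         seed = as.integer(seed), output_dir = output_dir),
    class = "pipeline_config"
  )
}

#' Run the whole-cell energy pipeline
#'
#' Executes the full chain: impute missing proteome values
#' ([impute_completerot()]), aggregate abundances onto reactions
#' ([reaction_abundance()]), sweep compression x availability
#' ([sweep_atp()]), calibrate against measured ATP production
#' ([calibrate_sweep()]), distribute the capacity into the energy budget
#' ([energy_budget()]) and predict protein synthesis
#' ([protein_synthesis()]). Deterministic given the config.
#'
#' @param config a [pipeline_config()].
#' @param model,proteome,annotation,medium,measured_fluxes objects passed
#'   directly; when `NULL` the corresponding `*_path` is read.
#' @return list of class `pipeline_result` with elements `imputation`
#'   (report), `completed`, `sweep`, `calibration` (or `NULL`), `budget`,
#'   `synthesis`, `exchange`, and `config`.
#' @export
run_pipeline <- function(config, model = NULL, proteome = NULL,
                         annotation = NULL, medium = NULL,
                         measured_fluxes = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- function(what, expr) {
    tryCatch(expr, error = function(e) {
      stop("[", what, "] ", conditionMessage(e), call. = FALSE)
    })
  }
  model <- model %||% stage("model", read_model(config$model_path))
  proteome <- proteome %||% stage("proteome",
                                  read_proteome_tsv(config$proteome_path))
  annotation <- annotation %||% stage("annotation",
                                      load_annotation(config$annotation_path))
  annotation <- stage("annotation", validate_annotation(annotation))
  medium <- medium %||% stage("medium", read_medium_tsv(config$medium_path))
  if (is.null(measured_fluxes) && !is.null(config$measured_flux_path)) {
    measured_fluxes <- stage("measured fluxes",
                             read_measured_flux_tsv(config$measured_flux_path))
  }
  mode <- if (is.null(measured_fluxes)) "dmem" else config$mode

  imp <- stage("impute", impute_completerot(proteome, annotation))
  abundance <- stage("abundance", {
    scols <- sample_cols(imp$completed)
    stats::setNames(rowMeans(as.matrix(imp$completed[, scols])),
                    imp$completed$protein_id)
  })
  grid <- stage("sweep", sweep_atp(
    model, abundance, k_values = config$k_grid, r_values = config$r_grid,
    medium = medium, measured_fluxes = measured_fluxes, mode = mode,
    b_max = config$b_max
  ))

  calibration <- NULL
  k_star <- 0.016; r_star <- 0.05
  total_capacity <- NA_real_
  scale_factor <- 1
  if (!is.null(config$measured_atp) && !is.null(config$measured_glucose)) {
    calibration <- stage("calibrate", calibrate_sweep(
      grid, config$measured_atp, config$measured_glucose))
    k_star <- calibration$k_star; r_star <- calibration$r_star
    total_capacity <- calibration$predicted_atp
    scale_factor <- calibration$scale_factor
  } else {
    cell <- dplyr::filter(grid, .data$k == k_star, .data$r == r_star,
                          .data$status == "optimal")
    if (nrow(cell) == 1) total_capacity <- cell$objective
  }
  if (!is.finite(total_capacity)) {
    stop("[calibrate] no feasible solution at the working point")
  }

  consumers <- stage("budget", build_consumers(abundance, annotation,
                                               k = k_star))
  budget <- stage("budget", energy_budget(consumers, total_capacity))
  synthesis <- stage("synthesis", tryCatch(
    protein_synthesis(budget, turnover_rate = config$turnover_rate),
    error = function(e) NULL
  ))

  # solved model at the working point, for the exchange report
  eff <- reaction_abundance(model, abundance)
  m_star <- internal_bounds(model, eff, k = k_star, b_max = config$b_max)
  sp <- exchange_spec(mode = mode, medium = medium,
                      measured_fluxes = measured_fluxes, r = r_star)
  m_star <- exchange_bounds(m_star, sp, b_max = config$b_max)
  sol_star <- solve_fba(m_star, config$objective_reaction_id)
  exchange <- if (sol_star$status == "optimal") {
    exchange_report(sol_star, model, scale_factor = scale_factor)
  }

  result <- structure(
    list(imputation = imp$report, completed = imp$completed, sweep = grid,
         calibration = calibration, budget = budget, synthesis = synthesis,
         exchange = exchange, k_star = k_star, r_star = r_star,
         total_capacity = total_capacity, config = config),
    class = "pipeline_result"
  )
  if (!is.null(config$output_dir)) write_pipeline_outputs(result)
  result
}

write_pipeline_outputs <- function(result) {
  dir <- result$config$output_dir
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_tsv(result$sweep, file.path(dir, "sweep_grid.tsv"))
  readr::write_tsv(result$budget, file.path(dir, "energy_budget.tsv"))
  readr::write_tsv(result$imputation, file.path(dir, "imputation_report.tsv"))
  write_proteome_tsv(result$completed, file.path(dir, "proteome_completed.tsv"))
  if (!is.null(result$synthesis)) {
    readr::write_tsv(result$synthesis, file.path(dir, "protein_synthesis.tsv"))
  }
  if (!is.null(result$exchange)) {
    readr::write_tsv(result$exchange, file.path(dir, "exchange_report.tsv"))
  }
  cfg <- result$config
  cfg$output_dir <- NULL
  jsonlite::write_json(
    c(unclass(cfg),
      list(k_star = result$k_star, r_star = result$r_star,
           total_capacity = result$total_capacity,
           package_version = as.character(utils::packageVersion("enerflow")))),
    file.path(dir, "resolved_config.json"),
    auto_unbox = TRUE, digits = NA, null = "null", pretty = TRUE
  )
  invisible(dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  cat("  sweep: ", nrow(x$sweep), " cells (",
      sum(x$sweep$status == "optimal"), " feasible)\n", sep = "")
  cat("  working point: k = ", x$k_star, ", r = ", x$r_star,
      ", capacity = ", format(x$total_capacity), "\n", sep = "")
  if (!is.null(x$synthesis)) {
    cat("  protein synthesis: total ", format(x$synthesis$total_rate),
        " / net ", format(x$synthesis$net_rate), " day^-1\n", sep = "")
  }
  invisible(x)
}
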