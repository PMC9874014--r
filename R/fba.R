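#' Maximise an objective flux at steady state
#'
#' Solves the flux balance linear program: maximise the objective reaction's
#' flux subject to `S v = 0` and the model's bounds. Infeasibility is a
#' result, not an error — in the parameter sweeps of this package an
#' infeasible cell marks an implausible parameterisation.
#'
#' @param model a [metabolic_model()] with finite bounds.
#' @param objective reaction id to maximise; defaults to the model's flagged
#'   objective reaction.
#' @return object of class `fba_solution`: list with `status`
#'   (`"optimal"`, `"infeasible"` or `"maxiter"`), `objective`, and `flux`
#'   (tibble `reaction_id`, `flux`).
#' @export
solve_fba <- function(model, objective = NULL) {
  stopifnot(inherits(model, "metabolic_model"))
  objective <- objective %||% objective_reaction(model)
  if (!objective %in% model$reactions$id) {
    stop("objective reaction '", objective, "' absent from model")
  }
  S <- stoich_matrix(model)
  obj <- as.numeric(model$reactions$id == objective)
  res <- lp_solve_bounded(S, model$reactions$lb, model$reactions$ub, obj)
  structure(
    list(status = res$status,
         objective = res$objective,
         flux = tibble::tibble(reaction_id = model$reactions$id,
                               flux = unname(res$flux)),
         objective_reaction = objective),
    class = "fba_solution"
  )
}

#' @export
print.fba_solution <- function(x, ...) {
  cat("<fba_solution> status: ", x$status, sep = "")
  if (x$status == "optimal") cat(", objective (", x$objective_reaction, ") = ",
                                 format(x$objective), sep = "")
  cat("\n")
  invisible(x)
}

#' Flux of one reaction in a solution
#' @param sol an `fba_solution`.
#' @param reaction_id reaction to extract.
#' @return numeric scalar (`NA` if not optimal).
#' @export
flux_of <- function(sol, reaction_id) {
  stopifnot(inherits(sol, "fba_solution"))
  i <- match(reaction_id, sol$flux$reaction_id)
  if (is.na(i)) stop("unknown reaction id '", reaction_id, "'")
  sol$flux$flux[i]
}

#' ATP yield per glucose of a solution
#'
#' The dimensionless molar ratio of maximum ATP flux to realised glucose
#' uptake flux; 2 for pure glycolytic fermentation, ~30 for full oxidation
#' in genome-scale models (32 in the toy network).
#'
#' @param sol an optimal `fba_solution`.
#' @param glucose_exchange id of the glucose exchange reaction.
#' @return numeric scalar; `NA` (with a warning) when glucose uptake is zero
#'   or the solution is not optimal.
#' @export
atp_glucose_ratio <- function(sol, glucose_exchange = "EX_glc") {
  stopifnot(inherits(sol, "fba_solution"))
  if (sol$status != "optimal") return(NA_real_)
  glc <- flux_of(sol, glucose_exchange)
  if (!is.finite(glc) || glc >= -1e-12) {
    warning("glucose uptake is zero; ATP/glucose ratio undefined")
    return(NA_real_)
  }
  sol$objective / abs(glc)
}

#' Convert an ATP/glucose ratio to measured units
#'
#' Multiplying the dimensionless ATP/glucose molar ratio by a measured
#' glucose uptake rate yields a predicted ATP-production capacity in the
#' measurement's units (here typically pmol ATP per ng protein per day).
#'
#' @param ratio dimensionless ATP/glucose ratio (>= 0).
#' @param measured_glucose measured glucose uptake magnitude (>= 0), e.g.
#'   pmol glucose per ng protein per day.
#' @return predicted ATP capacity in the measured units.
#' @export
scale_to_measured <- function(ratio, measured_glucose) {
  if (is.na(ratio)) return(NA_real_)
  if (ratio < 0 || measured_glucose < 0) {
    stop("ratio and measured glucose uptake must be non-negative")
  }
  ratio * measured_glucose
}

#' Two-dimensional compression x availability sweep
#'
#' For every combination of compression `k` and availability ratio `r`,
#' rebuilds the internal bounds ([internal_bounds()]) and exchange bounds
#' ([exchange_bounds()]) and solves for maximum ATP. The result is the long
#' form of the sweep heatmaps: one row per grid cell with the objective,
#' realised glucose uptake, ATP/glucose ratio and solver status (infeasible
#' cells stay in the grid with `NA` objective).
#'
#' @param model a [metabolic_model()].
#' @param abundance named numeric vector, gene id -> abundance (the
#'   completed proteome for one condition).
#' @param k_values,r_values sweep axes (typically log-spaced).
#' @param medium,measured_fluxes,mode,efflux_policy,glucose_id passed to
#'   [exchange_spec()].
#' @param b_max bound of the most abundant internal reaction.
#' @return tibble of class `sweep_grid` with columns `k`, `r`, `status`,
#'   `objective`, `glucose_uptake`, `atp_per_glucose`.
#' @export
sweep_atp <- function(model, abundance, k_values, r_values,
                      medium, measured_fluxes = NULL,
                      mode = c("dmem", "measured"),
                      b_max = 1000, glucose_id = "glc_e",
                      efflux_policy = "floor") {
  mode <- match.arg(mode)
  stopifnot(length(k_values) > 0, length(r_values) > 0)
  eff <- reaction_abundance(model, abundance)
  glc_ex <- exchange_for_metabolite(model, glucose_id)
  cells <- tidyr::expand_grid(k = sort(k_values), r = sort(r_values))
  rows <- purrr::pmap_dfr(cells, function(k, r) {
    m <- internal_bounds(model, eff, k = k, b_max = b_max)
    sp <- exchange_spec(mode = mode, medium = medium,
                        measured_fluxes = measured_fluxes, r = r,
                        glucose_id = glucose_id,
                        efflux_policy = efflux_policy)
    m <- exchange_bounds(m, sp, b_max = b_max)
    sol <- solve_fba(m)
    glc <- if (sol$status == "optimal") flux_of(sol, glc_ex) else NA_real_
    ratio <- if (sol$status == "optimal" && is.finite(glc) && glc < -1e-12) {
      sol$objective / abs(glc)
    } else NA_real_
    tibble::tibble(k = k, r = r, status = sol$status,
                   objective = sol$objective,
                   glucose_uptake = glc, atp_per_glucose = ratio)
  })
  structure(rows, class = c("sweep_grid", class(rows)),
            b_max = b_max, mode = mode)
}

#' Calibrate a sweep against a measured ATP-production rate
#'
#' Scales every feasible grid cell's ATP/glucose ratio by the measured
#' glucose uptake (pmol per ng protein per day) and returns the cell whose
#' predicted ATP capacity is closest to the measured total ATP-production
#' rate (e.g. from an extracellular-flux assay). Ties go to the smaller
#' availability ratio `r`, then the smaller compression `k`.
#'
#' @param grid a `sweep_grid` from [sweep_atp()].
#' @param measured_atp measured ATP-production rate, pmol per ng protein per
#'   day.
#' @param measured_glucose measured glucose uptake magnitude, same units.
#' @return one-row tibble of class `calibration_point`: `k_star`, `r_star`,
#'   `predicted_atp`, `measured_atp`, `scale_factor` (measured over
#'   model-realised glucose uptake at the calibration cell).
#' @export
calibrate_sweep <- function(grid, measured_atp, measured_glucose) {
  stopifnot(inherits(grid, "sweep_grid"), measured_atp >= 0,
            measured_glucose >= 0)
  feas <- dplyr::filter(grid, .data$status == "optimal",
                        is.finite(.data$atp_per_glucose))
  if (nrow(feas) == 0) stop("no feasible cell in the sweep grid")
  feas <- dplyr::mutate(feas,
                        predicted_atp = .data$atp_per_glucose * measured_glucose,
                        miss = abs(.data$predicted_atp - measured_atp))
  feas <- dplyr::arrange(feas, .data$miss, .data$r, .data$k)
  best <- feas[1, ]
  out <- tibble::tibble(
    k_star = best$k, r_star = best$r,
    predicted_atp = best$predicted_atp,
    measured_atp = measured_atp,
    scale_factor = measured_glucose / abs(best$glucose_uptake)
  )
  structure(out, class = c("calibration_point", class(out)))
}

#' Exchange fluxes rescaled to measured units
#'
#' Multiplies every exchange flux of a solution by the calibration scale
#' factor (measured glucose uptake over model-predicted uptake), yielding
#' secretion/uptake rates in the measured units — e.g. the proton efflux to
#' compare with extracellular acidification.
#'
#' @param sol an optimal `fba_solution`.
#' @param model the model the solution came from.
#' @param scale_factor measured-over-predicted glucose uptake ratio (from
#'   [calibrate_sweep()]), or 1 for raw model units.
#' @return tibble `reaction_id`, `metabolite_id`, `flux` (rescaled; positive
#'   = secretion).
#' @export
exchange_report <- function(sol, model, scale_factor = 1) {
  stopifnot(inherits(sol, "fba_solution"), inherits(model, "metabolic_model"))
  if (!is.finite(scale_factor)) stop("scale factor must be finite")
  ex <- model$reactions$id[model$reactions$exchange]
  st <- model$stoichiometry
  mets <- vapply(ex, function(rid) {
    st$metabolite_id[st$reaction_id == rid][1]
  }, "")
  tibble::tibble(
    reaction_id = ex,
    metabolite_id = unname(mets),
    flux = vapply(ex, function(rid) flux_of(sol, rid), 0) * scale_factor
  )
}
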