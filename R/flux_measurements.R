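#' Normalize values across experimental repeats
#'
#' Removes between-experiment level shifts by dividing each experiment's
#' values by that experiment's mean and multiplying by the grand mean, so
#' every experiment ends up with the same mean while within-experiment
#' structure is preserved.
#'
#' @param data data frame of measurements.
#' @param value name of the value column (string).
#' @param experiment name of the experiment/repeat identifier column.
#' @return `data` with `value` rescaled.
#' @export
normalize_replicates <- function(data, value = "value",
                                 experiment = "experiment") {
  stopifnot(all(c(value, experiment) %in% names(data)))
  grand <- mean(data[[value]], na.rm = TRUE)
  exp_mean <- stats::ave(data[[value]], data[[experiment]],
                         FUN = function(x) mean(x, na.rm = TRUE))
  if (any(exp_mean == 0, na.rm = TRUE)) stop("experiment with zero mean")
  data[[value]] <- data[[value]] / exp_mean * grand
  data
}

#' Daily uptake/secretion rates from concentration time courses
#'
#' Converts metabolite (or biomass) concentration time courses into daily
#' fluxes: the rate at day `d` is the value at day `d` minus the replicate-
#' average value at day `d - 1`, per day. Dividing by the mean cell
#' concentration of the two days gives a per-cell rate, and further by the
#' mean protein content per cell a per-ng-protein rate. Consumption is
#' negative throughout (exchange-reaction sign convention). The summary
#' used for comparison with flux balance predictions is the mean of the
#' day-1-to-2 and day-2-to-3 rates (the 24 h - 72 h window).
#'
#' @param tc tibble with columns `condition`, `replicate`, `analyte`,
#'   `day`, `value` (concentration per mL).
#' @param cell_conc optional tibble `condition`, `day`, `cells_per_ml`
#'   (replicate-averaged); enables per-cell rates.
#' @param protein_per_cell optional tibble `condition`, `day`, `ng_per_cell`;
#'   enables per-ng-protein rates.
#' @param symmetric also average replicates at day `d` (not only `d - 1`).
#' @return list with `rates` (tibble: `condition`, `replicate`, `analyte`,
#'   `day`, `rate_per_ml`, and when inputs allow `rate_per_cell`,
#'   `rate_per_ng`) and `fba_comparison` (per condition x analyte mean of
#'   the day 2 and day 3 rates).
#' @export
daily_flux <- function(tc, cell_conc = NULL, protein_per_cell = NULL,
                       symmetric = FALSE) {
  stopifnot(all(c("condition", "replicate", "analyte", "day", "value")
                %in% names(tc)))
  day_mean <- dplyr::summarise(
    dplyr::group_by(tc, .data$condition, .data$analyte, .data$day),
    mean_value = mean(.data$value), .groups = "drop"
  )
  rates <- dplyr::inner_join(
    tc,
    dplyr::mutate(day_mean, day = .data$day + 1,
                  prev_mean = .data$mean_value, mean_value = NULL),
    by = c("condition", "analyte", "day")
  )
  rates <- dplyr::mutate(
    rates,
    rate_per_ml = ((if (symmetric) {
      day_mean$mean_value[match(paste(.data$condition, .data$analyte, .data$day),
                                paste(day_mean$condition, day_mean$analyte,
                                      day_mean$day))]
    } else .data$value) - .data$prev_mean) / 1
  )
  if (!is.null(cell_conc)) {
    cc <- function(cond, d) {
      cell_conc$cells_per_ml[match(paste(cond, d),
                                   paste(cell_conc$condition, cell_conc$day))]
    }
    rates <- dplyr::mutate(
      rates,
      mean_cells = (cc(.data$condition, .data$day) +
                      cc(.data$condition, .data$day - 1)) / 2,
      rate_per_cell = .data$rate_per_ml / .data$mean_cells
    )
    if (!is.null(protein_per_cell)) {
      pc <- function(cond, d) {
        protein_per_cell$ng_per_cell[match(paste(cond, d),
                                           paste(protein_per_cell$condition,
                                                 protein_per_cell$day))]
      }
      rates <- dplyr::mutate(
        rates,
        mean_protein = (pc(.data$condition, .data$day) +
                          pc(.data$condition, .data$day - 1)) / 2,
        rate_per_ng = .data$rate_per_cell / .data$mean_protein
      )
    }
  }
  rate_col <- if ("rate_per_ng" %in% names(rates)) "rate_per_ng"
              else if ("rate_per_cell" %in% names(rates)) "rate_per_cell"
              else "rate_per_ml"
  fba_cmp <- dplyr::summarise(
    dplyr::group_by(dplyr::filter(rates, .data$day %in% c(2, 3)),
                    .data$condition, .data$analyte),
    rate = mean(.data[[rate_col]]), .groups = "drop"
  )
  list(rates = tibble::as_tibble(rates), fba_comparison = fba_cmp)
}

#' Net protein synthesis rate from two protein measurements
#'
#' The net accumulation of protein between 24 h and 72 h, per day:
#' `(p72 - p24) / 2`. The normalized variant divides by the mean protein
#' amount, giving a rate per unit protein per day directly comparable with
#' the model's synthesis prediction.
#'
#' @param p24,p72 protein amounts (ng) at 24 h and 72 h (> 0).
#' @param normalized divide by the mean of the two amounts.
#' @return numeric rate (ng/day, or day^-1 when `normalized`).
#' @export
net_protein_synthesis <- function(p24, p72, normalized = FALSE) {
  if (any(c(p24, p72) <= 0)) stop("protein amounts must be positive")
  rate <- (p72 - p24) / 2
  if (normalized) rate / mean(c(p24, p72)) else rate
}
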