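#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a flux balance solution
#'
#' @param x an `fba_solution`.
#' @param ... unused.
#' @return tibble with `reaction_id` and `flux`.
#' @export
tidy.fba_solution <- function(x, ...) x$flux

#' @rdname tidy.fba_solution
#' @return for `glance()`: one-row tibble with `status`, `objective` and
#'   the objective reaction id.
#' @export
glance.fba_solution <- function(x, ...) {
  tibble::tibble(status = x$status, objective = x$objective,
                 objective_reaction = x$objective_reaction)
}

#' Tidy a calibrated sweep point
#'
#' @param x a `calibration_point`.
#' @param ... unused.
#' @return the underlying one-row tibble.
#' @export
tidy.calibration_point <- function(x, ...) tibble::as_tibble(unclass(x))

#' Summary of an energy budget
#'
#' @param x an `energy_budget`.
#' @param ... unused.
#' @return one-row tibble: `total_capacity`, `n_classes`,
#'   `n_classes_90pct` (classes jointly covering 90% of the demand),
#'   `top_class`.
#' @export
glance.energy_budget <- function(x, ...) {
  tibble::tibble(
    total_capacity = attr(x, "total_capacity"),
    n_classes = nrow(x),
    n_classes_90pct = sum(x$cum_fraction <= 0.9) + 1,
    top_class = x$class_level1[1]
  )
}
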