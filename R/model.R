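#' Construct a metabolic model
#'
#' A `metabolic_model` bundles the three tables a constraint-based model
#' needs: reactions (with bounds, gene-reaction rule strings, exchange and
#' objective flags), metabolites, and the stoichiometry in long form. The
#' layout mirrors the JSON dialect used by constraint-based toolkits: every
#' structural fact is a row in a tidy table.
#'
#' @param reactions tibble with columns `id`, `lb`, `ub`, `gpr` (rule string,
#'   `""` for gene-free reactions), `exchange` (logical), `objective`
#'   (logical; exactly one `TRUE`).
#' @param metabolites tibble with columns `id` and optionally `name`,
#'   `compartment`.
#' @param stoichiometry tibble with columns `metabolite_id`, `reaction_id`,
#'   `coefficient` (negative = consumed).
#'
#' @return object of class `metabolic_model`.
#' @export
metabolic_model <- function(reactions, metabolites, stoichiometry) {
  reactions <- tibble::as_tibble(reactions)
  metabolites <- tibble::as_tibble(metabolites)
  stoichiometry <- tibble::as_tibble(stoichiometry)
  for (col in c("lb", "ub")) {
    if (col %in% names(reactions)) reactions[[col]] <- as.double(reactions[[col]])
  }
  if ("coefficient" %in% names(stoichiometry)) {
    stoichiometry$coefficient <- as.double(stoichiometry$coefficient)
  }
  required <- c("id", "lb", "ub", "gpr", "exchange", "objective")
  missing_cols <- setdiff(required, names(reactions))
  if (length(missing_cols) > 0) {
    stop("reactions table lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(reactions$id)) stop("duplicate reaction ids")
  if (anyDuplicated(metabolites$id)) stop("duplicate metabolite ids")
  bad_met <- setdiff(stoichiometry$metabolite_id, metabolites$id)
  if (length(bad_met) > 0) {
    stop("stoichiometry cites unknown metabolite(s): ",
         paste(bad_met, collapse = ", "))
  }
  bad_rxn <- setdiff(stoichiometry$reaction_id, reactions$id)
  if (length(bad_rxn) > 0) {
    stop("stoichiometry cites unknown reaction(s): ",
         paste(bad_rxn, collapse = ", "))
  }
  if (sum(reactions$objective) != 1) {
    stop("exactly one reaction must be flagged as the objective")
  }
  structure(
    list(reactions = reactions, metabolites = metabolites,
         stoichiometry = stoichiometry),
    class = "metabolic_model"
  )
}

#' Dense stoichiometric matrix of a model
#'
#' @param model a `metabolic_model`.
#' @return numeric matrix, metabolites x reactions, with dimnames.
#' @export
stoich_matrix <- function(model) {
  stopifnot(inherits(model, "metabolic_model"))
  S <- matrix(0, nrow = nrow(model$metabolites), ncol = nrow(model$reactions),
              dimnames = list(model$metabolites$id, model$reactions$id))
  st <- model$stoichiometry
  S[cbind(match(st$metabolite_id, rownames(S)),
          match(st$reaction_id, colnames(S)))] <- st$coefficient
  S
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat("<metabolic_model> ", nrow(x$reactions), " reactions, ",
      nrow(x$metabolites), " metabolites (",
      sum(x$reactions$exchange), " exchanges)\n", sep = "")
  cat("objective: ", x$reactions$id[x$reactions$objective], "\n", sep = "")
  invisible(x)
}

#' Replace bounds of selected reactions
#'
#' @param model a `metabolic_model`.
#' @param ids reaction ids to modify.
#' @param lb,ub new bounds (recycled); `NULL` leaves that side untouched.
#' @return modified model.
#' @export
set_bounds <- function(model, ids, lb = NULL, ub = NULL) {
  stopifnot(inherits(model, "metabolic_model"))
  idx <- match(ids, model$reactions$id)
  if (anyNA(idx)) stop("unknown reaction id(s): ",
                       paste(ids[is.na(idx)], collapse = ", "))
  if (!is.null(lb)) model$reactions$lb[idx] <- rep_len(lb, length(idx))
  if (!is.null(ub)) model$reactions$ub[idx] <- rep_len(ub, length(idx))
  model
}

#' Objective reaction id of a model
#' @param model a `metabolic_model`.
#' @return character scalar.
#' @export
objective_reaction <- function(model) {
  model$reactions$id[model$reactions$objective]
}

#' Exchange reaction id carrying a given metabolite
#'
#' @param model a `metabolic_model`.
#' @param metabolite_id metabolite to look up.
#' @return reaction id, or `NA_character_` if the metabolite has no exchange.
#' @export
exchange_for_metabolite <- function(model, metabolite_id) {
  ex <- model$reactions$id[model$reactions$exchange]
  st <- model$stoichiometry
  hit <- st$reaction_id[st$metabolite_id == metabolite_id &
                          st$reaction_id %in% ex]
  if (length(hit) == 0) NA_character_ else hit[[1]]
}
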