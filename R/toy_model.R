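#' Specification for the toy energy network
#'
#' The toy model is a deliberately small metabolic network whose maximum ATP
#' output has a closed form, so the linear-programming supply machinery can
#' be tested against analytic truth. It lumps central carbon metabolism into
#' a handful of reactions: a glycolytic conversion of glucose to pyruvate
#' yielding `glycolytic_atp_yield` ATP per glucose, a mitochondria-like
#' oxidative branch burning pyruvate with oxygen at
#' `(oxidative_atp_yield - glycolytic_atp_yield) / 2` ATP per pyruvate, a
#' lactate overflow that exports excess pyruvate together with a proton, and
#' (optionally) glutamine oxidation and an ATP -> GTP branch.
#'
#' @param n_carbon_sources 1 (glucose only) or 2 (glucose + glutamine; the
#'   glutamine exchange ships closed and is opened by medium composition).
#' @param glycolytic_atp_yield mol ATP per mol glucose through glycolysis
#'   (default 2).
#' @param oxidative_atp_yield mol ATP per mol glucose fully oxidised
#'   (default 32).
#' @param include_gtp_branch add an NDPK-like ATP -> GTP reaction plus a GTP
#'   sink (does not change the ATP optimum).
#' @param gpr_templates named character vector of gene-reaction rule strings
#'   for the enzyme-associated reactions; names are reaction ids. Rules mix
#'   AND (complex subunits) and OR (isozymes) as in genome-scale models.
#' @param default_bound magnitude used for unconstrained reaction bounds.
#' @param glucose_lb default glucose exchange lower bound (uptake is
#'   negative; default -10).
#'
#' @return list of class `toy_model_spec`.
#' @export
toy_model_spec <- function(n_carbon_sources = 2,
                           glycolytic_atp_yield = 2,
                           oxidative_atp_yield = 32,
                           include_gtp_branch = TRUE,
                           gpr_templates = NULL,
                           default_bound = 1000,
                           glucose_lb = -10) {
  stopifnot(glycolytic_atp_yield > 0,
            oxidative_atp_yield > glycolytic_atp_yield,
            n_carbon_sources %in% c(1, 2),
            default_bound > 0)
  if (is.null(gpr_templates)) {
    gpr_templates <- c(
      GLCt   = "Slc2a1 or Slc2a3",
      GLYC   = "Hk1 and Pfkl and Pkm",
      LDH    = "Ldha or Ldhb",
      LACt   = "Slc16a1",
      OXPHOS = "(Ndufa1 and Cox4i1 and Atp5f1a) or (Ndufa2 and Cox4i1 and Atp5f1a)",
      GLNt   = "Slc1a5",
      GLNOX  = "Gls and Glud1",
      NDPK   = "Nme1 or Nme2"
    )
  }
  structure(list(n_carbon_sources = n_carbon_sources,
                 glycolytic_atp_yield = glycolytic_atp_yield,
                 oxidative_atp_yield = oxidative_atp_yield,
                 include_gtp_branch = include_gtp_branch,
                 gpr_templates = gpr_templates,
                 default_bound = default_bound,
                 glucose_lb = glucose_lb),
            class = "toy_model_spec")
}

# Glutamine oxidation stoichiometry for the toy network: ATP and O2 per
# glutamine. ATP/O2 efficiency (18/4 = 4.5) is kept strictly below the
# pyruvate branch (15/3 = 5) so the analytic optimum allocates scarce oxygen
# to glucose first.
.toy_gln_atp <- 18
.toy_gln_o2 <- 4

#' Build the toy metabolic model
#'
#' Constructs the network described in [toy_model_spec()]. The returned
#' model carries an attribute `analytic_max_atp`: a function
#' `f(glucose, oxygen, glutamine)` (uptake magnitudes) returning the
#' closed-form maximum ATP flux, used as the oracle for the LP solver.
#'
#' @param spec a [toy_model_spec()].
#' @return a [metabolic_model()] with attributes `analytic_max_atp` and
#'   `spec`.
#' @export
make_toy_model <- function(spec = toy_model_spec()) {
  stopifnot(inherits(spec, "toy_model_spec"))
  gy <- spec$glycolytic_atp_yield
  per_pyr <- (spec$oxidative_atp_yield - gy) / 2
  B <- spec$default_bound
  g <- function(id) if (id %in% names(spec$gpr_templates)) spec$gpr_templates[[id]] else ""

  mets <- c("glc_e", "o2_e", "lac_e", "h_e", "co2_e",
            "glc_c", "o2_c", "pyr_c", "lac_c", "h_c", "atp_c", "co2_c")
  rxn <- list(
    # id, lb, ub, gpr, exchange, objective, stoich (named: negative consumed)
    list("EX_glc", spec$glucose_lb, B, "", TRUE, FALSE, c(glc_e = -1)),
    list("EX_o2", -B, B, "", TRUE, FALSE, c(o2_e = -1)),
    list("EX_lac", 0, B, "", TRUE, FALSE, c(lac_e = -1)),
    list("EX_h", 0, B, "", TRUE, FALSE, c(h_e = -1)),
    list("EX_co2", 0, B, "", TRUE, FALSE, c(co2_e = -1)),
    list("GLCt", 0, B, g("GLCt"), FALSE, FALSE, c(glc_e = -1, glc_c = 1)),
    list("O2t", 0, B, "", FALSE, FALSE, c(o2_e = -1, o2_c = 1)),
    list("GLYC", 0, B, g("GLYC"), FALSE, FALSE,
         c(glc_c = -1, pyr_c = 2, atp_c = gy)),
    list("LDH", 0, B, g("LDH"), FALSE, FALSE,
         c(pyr_c = -1, lac_c = 1, h_c = 1)),
    list("LACt", 0, B, g("LACt"), FALSE, FALSE,
         c(lac_c = -1, h_c = -1, lac_e = 1, h_e = 1)),
    list("OXPHOS", 0, B, g("OXPHOS"), FALSE, FALSE,
         c(pyr_c = -1, o2_c = -3, atp_c = per_pyr, co2_c = 3)),
    list("CO2t", 0, B, "", FALSE, FALSE, c(co2_c = -1, co2_e = 1)),
    list("ATPM", 0, B, "", FALSE, TRUE, c(atp_c = -1))
  )
  if (spec$n_carbon_sources >= 2) {
    mets <- c(mets, "gln_e", "gln_c")
    rxn <- c(rxn, list(
      list("EX_gln", 0, B, "", TRUE, FALSE, c(gln_e = -1)),
      list("GLNt", 0, B, g("GLNt"), FALSE, FALSE, c(gln_e = -1, gln_c = 1)),
      list("GLNOX", 0, B, g("GLNOX"), FALSE, FALSE,
           c(gln_c = -1, o2_c = -.toy_gln_o2, atp_c = .toy_gln_atp, co2_c = 5))
    ))
  }
  if (spec$include_gtp_branch) {
    mets <- c(mets, "gtp_c")
    rxn <- c(rxn, list(
      list("NDPK", 0, B, g("NDPK"), FALSE, FALSE, c(atp_c = -1, gtp_c = 1)),
      list("GTPM", 0, B, "", FALSE, FALSE, c(gtp_c = -1))
    ))
  }

  reactions <- tibble::tibble(
    id = vapply(rxn, `[[`, "", 1),
    lb = vapply(rxn, `[[`, 0, 2),
    ub = vapply(rxn, `[[`, 0, 3),
    gpr = vapply(rxn, `[[`, "", 4),
    exchange = vapply(rxn, `[[`, TRUE, 5),
    objective = vapply(rxn, `[[`, TRUE, 6)
  )
  stoich <- purrr::map_dfr(rxn, function(r) {
    tibble::tibble(metabolite_id = names(r[[7]]), reaction_id = r[[1]],
                   coefficient = unname(r[[7]]))
  })
  compartment <- ifelse(grepl("_e$", mets), "extracellular", "cytosol")
  model <- metabolic_model(
    reactions = reactions,
    metabolites = tibble::tibble(id = mets, name = mets,
                                 compartment = compartment),
    stoichiometry = stoich
  )
  analytic <- function(glucose, oxygen = Inf, glutamine = 0) {
    toy_analytic_max_atp(glucose, oxygen, glutamine,
                         glycolytic_atp_yield = gy,
                         oxidative_atp_yield = spec$oxidative_atp_yield)
  }
  attr(model, "analytic_max_atp") <- analytic
  attr(model, "spec") <- spec
  model
}

#' Closed-form maximum ATP flux of the toy network
#'
#' Greedy allocation: every imported glucose yields the glycolytic ATP;
#' oxygen is then spent on pyruvate oxidation (the most ATP-per-O2 efficient
#' branch) and any remainder on glutamine; surplus pyruvate leaves as
#' lactate at no ATP cost.
#'
#' @param glucose,oxygen,glutamine uptake magnitudes (non-negative).
#' @param glycolytic_atp_yield,oxidative_atp_yield per-glucose ATP yields.
#' @return maximum ATP flux (numeric scalar).
#' @export
toy_analytic_max_atp <- function(glucose, oxygen = Inf, glutamine = 0,
                                 glycolytic_atp_yield = 2,
                                 oxidative_atp_yield = 32) {
  stopifnot(glucose >= 0, oxygen >= 0, glutamine >= 0)
  per_pyr <- (oxidative_atp_yield - glycolytic_atp_yield) / 2
  # allocate scarce oxygen to the more ATP-per-O2 efficient branch first
  branches <- list(
    pyr = c(cap = 2 * glucose, o2 = 3, atp = per_pyr),
    gln = c(cap = glutamine, o2 = .toy_gln_o2, atp = .toy_gln_atp)
  )
  branches <- branches[order(vapply(branches, function(b) b[["atp"]] / b[["o2"]],
                                    0), decreasing = TRUE)]
  o2_left <- oxygen
  atp <- glucose * glycolytic_atp_yield
  for (b in branches) {
    used <- min(b[["cap"]], o2_left / b[["o2"]])
    atp <- atp + b[["atp"]] * used
    o2_left <- o2_left - b[["o2"]] * used
  }
  atp
}
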