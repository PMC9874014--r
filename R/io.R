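#' Write a metabolic model as JSON
#'
#' Serialises reactions (with bounds, rule strings, exchange/objective
#' flags), metabolites and long-form stoichiometry to a JSON dialect that
#' round-trips losslessly through [read_model_json()].
#'
#' @param model a [metabolic_model()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_model_json <- function(model, path) {
  stopifnot(inherits(model, "metabolic_model"))
  jsonlite::write_json(
    list(reactions = model$reactions, metabolites = model$metabolites,
         stoichiometry = model$stoichiometry),
    path, dataframe = "columns", digits = NA, auto_unbox = TRUE, pretty = TRUE
  )
  invisible(path)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  metabolic_model(
    reactions = tibble::as_tibble(raw$reactions),
    metabolites = tibble::as_tibble(raw$metabolites),
    stoichiometry = tibble::as_tibble(raw$stoichiometry)
  )
}

sbml_ns <- c(
  sbml = "http://www.sbml.org/sbml/level3/version1/core",
  fbc = "http://www.sbml.org/sbml/level3/version1/fbc/version2"
)

#' Write a metabolic model as SBML level 3 with the fbc extension
#'
#' Emits species, reactions with flux bounds as fbc parameters, gene
#' products, and gene-product associations (`fbc:and` / `fbc:or` /
#' `fbc:geneProductRef`) translated from the rule strings. The objective
#' reaction becomes the active fbc objective.
#'
#' @param model a [metabolic_model()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_model_sbml <- function(model, path) {
  stopifnot(inherits(model, "metabolic_model"))
  genes <- sort(unique(unlist(lapply(model$reactions$gpr, function(g) {
    gpr_genes(parse_gpr(g))
  }))))
  gid <- function(g) paste0("G_", gsub("[^A-Za-z0-9_]", "_", g))

  doc <- xml2::xml_new_root(
    "sbml", xmlns = sbml_ns[["sbml"]], "xmlns:fbc" = sbml_ns[["fbc"]],
    level = "3", version = "1", "fbc:required" = "false"
  )
  mod <- xml2::xml_add_child(doc, "model", id = "model", "fbc:strict" = "false")

  comps <- unique(model$metabolites$compartment %||% "c")
  loc <- xml2::xml_add_child(mod, "listOfCompartments")
  for (cp in comps) {
    xml2::xml_add_child(loc, "compartment", id = gsub("[^A-Za-z0-9_]", "_", cp),
                        constant = "true")
  }
  los <- xml2::xml_add_child(mod, "listOfSpecies")
  for (i in seq_len(nrow(model$metabolites))) {
    m <- model$metabolites[i, ]
    xml2::xml_add_child(
      los, "species", id = paste0("M_", m$id), name = m$name %||% m$id,
      compartment = gsub("[^A-Za-z0-9_]", "_",
                         m$compartment %||% "c"),
      hasOnlySubstanceUnits = "false", boundaryCondition = "false",
      constant = "false"
    )
  }
  lop <- xml2::xml_add_child(mod, "listOfParameters")
  bound_param <- function(rid, side, value) {
    id <- paste0("B_", rid, "_", side)
    xml2::xml_add_child(lop, "parameter", id = id, value = format(value),
                        constant = "true")
    id
  }
  logp <- xml2::xml_add_child(mod, "fbc:listOfGeneProducts")
  for (g in genes) {
    xml2::xml_add_child(logp, "fbc:geneProduct", "fbc:id" = gid(g),
                        "fbc:label" = g)
  }
  add_assoc <- function(parent, node) {
    if (node$op == "leaf") {
      xml2::xml_add_child(parent, "fbc:geneProductRef",
                          "fbc:geneProduct" = gid(node$gene))
    } else {
      el <- xml2::xml_add_child(parent,
                                if (node$op == "and") "fbc:and" else "fbc:or")
      for (a in node$args) add_assoc(el, a)
    }
    invisible(NULL)
  }
  lor <- xml2::xml_add_child(mod, "listOfReactions")
  for (i in seq_len(nrow(model$reactions))) {
    r <- model$reactions[i, ]
    lbp <- bound_param(r$id, "lb", r$lb)
    ubp <- bound_param(r$id, "ub", r$ub)
    rx <- xml2::xml_add_child(
      lor, "reaction", id = paste0("R_", r$id),
      reversible = tolower(as.character(r$lb < 0)), fast = "false",
      "fbc:lowerFluxBound" = lbp, "fbc:upperFluxBound" = ubp
    )
    st <- model$stoichiometry[model$stoichiometry$reaction_id == r$id, ]
    reac <- st[st$coefficient < 0, ]
    prod <- st[st$coefficient > 0, ]
    if (nrow(reac) > 0) {
      lr <- xml2::xml_add_child(rx, "listOfReactants")
      for (j in seq_len(nrow(reac))) {
        xml2::xml_add_child(lr, "speciesReference",
                            species = paste0("M_", reac$metabolite_id[j]),
                            stoichiometry = format(abs(reac$coefficient[j])),
                            constant = "true")
      }
    }
    if (nrow(prod) > 0) {
      lp <- xml2::xml_add_child(rx, "listOfProducts")
      for (j in seq_len(nrow(prod))) {
        xml2::xml_add_child(lp, "speciesReference",
                            species = paste0("M_", prod$metabolite_id[j]),
                            stoichiometry = format(prod$coefficient[j]),
                            constant = "true")
      }
    }
    expr <- parse_gpr(r$gpr)
    if (!is.null(expr) && length(expr) > 0) {
      ga <- xml2::xml_add_child(rx, "fbc:geneProductAssociation")
      add_assoc(ga, unclass(expr))
    }
  }
  loo <- xml2::xml_add_child(mod, "fbc:listOfObjectives",
                             "fbc:activeObjective" = "obj")
  ob <- xml2::xml_add_child(loo, "fbc:objective", "fbc:id" = "obj",
                            "fbc:type" = "maximize")
  lfo <- xml2::xml_add_child(ob, "fbc:listOfFluxObjectives")
  xml2::xml_add_child(lfo, "fbc:fluxObjective",
                      "fbc:reaction" = paste0("R_", objective_reaction(model)),
                      "fbc:coefficient" = "1")
  xml2::write_xml(doc, path)
  invisible(path)
}

#' @rdname write_model_sbml
#' @export
read_model_sbml <- function(path) {
  doc <- xml2::read_xml(path)
  ns <- c(s = sbml_ns[["sbml"]], f = sbml_ns[["fbc"]])
  strip <- function(x, prefix) sub(paste0("^", prefix), "", x)
  # fbc attributes may or may not carry their namespace prefix depending on
  # the writer; try both spellings
  attr2 <- function(node, name) {
    v <- xml2::xml_attr(node, name)
    if (is.na(v)) v <- xml2::xml_attr(node, paste0("fbc:", name))
    v
  }

  sp <- xml2::xml_find_all(doc, ".//s:listOfSpecies/s:species", ns)
  metabolites <- tibble::tibble(
    id = strip(xml2::xml_attr(sp, "id"), "M_"),
    name = dplyr::coalesce(xml2::xml_attr(sp, "name"),
                           strip(xml2::xml_attr(sp, "id"), "M_")),
    compartment = xml2::xml_attr(sp, "compartment")
  )
  pars <- xml2::xml_find_all(doc, ".//s:listOfParameters/s:parameter", ns)
  pval <- stats::setNames(as.numeric(xml2::xml_attr(pars, "value")),
                          xml2::xml_attr(pars, "id"))
  gps <- xml2::xml_find_all(doc, ".//f:listOfGeneProducts/f:geneProduct", ns)
  glabel <- stats::setNames(vapply(gps, function(g) attr2(g, "label"), ""),
                            vapply(gps, function(g) attr2(g, "id"), ""))
  assoc_to_rule <- function(node) {
    nm <- xml2::xml_name(node)
    if (nm == "geneProductRef") {
      return(glabel[[attr2(node, "geneProduct")]])
    }
    kids <- xml2::xml_children(node)
    parts <- vapply(kids, assoc_to_rule, "")
    joined <- paste(parts, collapse = if (nm == "and") " and " else " or ")
    paste0("(", joined, ")")
  }

  obj_rxn <- attr2(xml2::xml_find_first(doc, ".//f:fluxObjective", ns),
                   "reaction")
  rxns <- xml2::xml_find_all(doc, ".//s:listOfReactions/s:reaction", ns)
  rows <- purrr::map(rxns, function(rx) {
    rid_raw <- xml2::xml_attr(rx, "id")
    rid <- strip(rid_raw, "R_")
    ga <- xml2::xml_find_first(rx, "./f:geneProductAssociation/*", ns)
    rule <- if (inherits(ga, "xml_missing")) "" else {
      gpr_render(parse_gpr(assoc_to_rule(ga)))
    }
    get_st <- function(xpath, sign) {
      refs <- xml2::xml_find_all(rx, xpath, ns)
      if (length(refs) == 0) return(NULL)
      tibble::tibble(
        metabolite_id = strip(xml2::xml_attr(refs, "species"), "M_"),
        reaction_id = rid,
        coefficient = sign * as.numeric(xml2::xml_attr(refs, "stoichiometry"))
      )
    }
    st <- dplyr::bind_rows(get_st("./s:listOfReactants/s:speciesReference", -1),
                           get_st("./s:listOfProducts/s:speciesReference", 1))
    list(
      reaction = tibble::tibble(
        id = rid,
        lb = pval[[attr2(rx, "lowerFluxBound")]],
        ub = pval[[attr2(rx, "upperFluxBound")]],
        gpr = rule,
        exchange = FALSE,
        objective = identical(rid_raw, obj_rxn)
      ),
      stoich = st
    )
  })
  reactions <- dplyr::bind_rows(purrr::map(rows, "reaction"))
  stoich <- dplyr::bind_rows(purrr::map(rows, "stoich"))
  # exchange = single-metabolite boundary reactions named by the EX_ convention
  n_mets <- table(stoich$reaction_id)
  reactions$exchange <- reactions$id %in% names(n_mets)[n_mets == 1] &
    grepl("^EX_", reactions$id)
  metabolic_model(reactions, metabolites, stoich)
}

#' Read a metabolic model from JSON or SBML
#'
#' @param path model file.
#' @param dialect `"json"`, `"sbml"`, or `"auto"` (by file extension).
#' @return a [metabolic_model()].
#' @export
read_model <- function(path, dialect = c("auto", "json", "sbml")) {
  dialect <- match.arg(dialect)
  if (dialect == "auto") {
    dialect <- if (grepl("\\.(xml|sbml)$", path, ignore.case = TRUE))
      "sbml" else "json"
  }
  switch(dialect, json = read_model_json(path), sbml = read_model_sbml(path))
}

#' Read / write a proteome table as TSV
#'
#' Missing values are encoded as empty fields.
#'
#' @param path TSV file.
#' @return tibble with `protein_id` and numeric sample columns.
#' @export
read_proteome_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                  na = c("", "NA"))
}

#' @rdname read_proteome_tsv
#' @param proteome table to write.
#' @export
write_proteome_tsv <- function(proteome, path) {
  readr::write_tsv(proteome, path, na = "")
  invisible(path)
}

#' Read a growth-medium composition table
#'
#' @param path TSV with columns `metabolite_id`, `mM`.
#' @return tibble.
#' @export
read_medium_tsv <- function(path) {
  med <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  stopifnot(all(c("metabolite_id", "mM") %in% names(med)))
  med
}

#' Read measured exchange fluxes
#'
#' @param path TSV with columns `condition`, `metabolite_id`, `flux`
#'   (uptake negative) and optionally `unit`.
#' @return tibble.
#' @export
read_measured_flux_tsv <- function(path) {
  mf <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  stopifnot(all(c("condition", "metabolite_id", "flux") %in% names(mf)))
  mf
}
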