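#' Build the table of ATP/GTP-consuming proteins
#'
#' The demand side of the energy framework: every protein annotated with
#' cofactor ATP or GTP is a consumer. Its abundance is corrected the same
#' way as on the supply side — complex members aggregated by minimum,
#' isozyme sets by sum (when a complex-definition rule is supplied),
#' then passed through the same saturating compression
#' ([compress_abundance()]) with the supply-side `k`. Where a turnover
#' number is known the weight is `compressed abundance x kcat`; missing
#' kcats are imputed with the arithmetic mean of the available kcats within
#' the same cofactor group. Each consumer's share is its weight over the
#' total consumer weight.
#'
#' @param abundance named numeric vector, protein/gene id -> completed
#'   abundance for one condition (e.g. mean of imputed replicates).
#' @param ann annotation table with `cofactor` and optional `kcat`.
#' @param k compression parameter (same value as the supply-side sweep
#'   point).
#' @param complex_rules optional tibble `consumer_id`, `rule` defining
#'   complexes/isoform sets over protein ids in gene-reaction-rule syntax;
#'   proteins not covered by any rule are treated as monomeric consumers.
#' @param a_max abundance normalising the compression; defaults to the
#'   maximum corrected abundance over all proteins (consumers and not), so
#'   supply and demand share one abundance-to-activity mapping.
#' @return tibble of class `consumer_table`: `consumer_id`, `class_level1`,
#'   `cofactor`, `corrected_abundance`, `compressed`, `kcat`,
#'   `kcat_imputed`, `weight`, `share`; attribute
#'   `total_corrected_expression` is the compressed, kcat-weighted total
#'   over all proteins (the denominator of the budget's expression
#'   percentages).
#' @export
build_consumers <- function(abundance, ann, k, complex_rules = NULL,
                            a_max = NULL) {
  stopifnot(is.numeric(abundance), !is.null(names(abundance)), k > 0)
  if (anyNA(abundance)) stop("abundance must be complete (run imputation first)")
  ann_idx <- match(names(abundance), ann$gene_id)
  cof <- ann$cofactor[ann_idx]
  cls <- ann$function_level1[ann_idx]
  kcat <- ann$kcat[ann_idx]

  # complex correction: covered proteins collapse into one consumer via minsum
  covered <- character()
  complexes <- NULL
  if (!is.null(complex_rules) && nrow(complex_rules) > 0) {
    complexes <- purrr::map_dfr(seq_len(nrow(complex_rules)), function(i) {
      expr <- parse_gpr(complex_rules$rule[i])
      members <- intersect(gpr_genes(expr), names(abundance))
      m1 <- members[1]
      tibble::tibble(
        consumer_id = complex_rules$consumer_id[i],
        class_level1 = cls[match(m1, names(abundance))],
        cofactor = cof[match(m1, names(abundance))],
        corrected_abundance = as.numeric(minsum(expr, abundance)),
        kcat = mean(kcat[match(members, names(abundance))], na.rm = TRUE),
        members = list(members)
      )
    })
    covered <- unique(unlist(complexes$members))
    complexes$members <- NULL
  }
  monomer <- !names(abundance) %in% covered
  all_tab <- tibble::tibble(
    consumer_id = names(abundance)[monomer],
    class_level1 = cls[monomer],
    cofactor = cof[monomer],
    corrected_abundance = unname(abundance[monomer]),
    kcat = kcat[monomer]
  )
  if (!is.null(complexes)) all_tab <- dplyr::bind_rows(all_tab, complexes)
  all_tab$cofactor[is.na(all_tab$cofactor)] <- "none"
  all_tab$kcat[is.nan(all_tab$kcat)] <- NA_real_

  # mean-impute kcat within cofactor group (fall back to overall mean)
  overall_kcat <- mean(all_tab$kcat, na.rm = TRUE)
  if (is.nan(overall_kcat)) overall_kcat <- 1
  all_tab <- dplyr::mutate(
    dplyr::group_by(all_tab, .data$cofactor),
    kcat_imputed = is.na(.data$kcat),
    kcat = dplyr::coalesce(.data$kcat,
                           mean(.data$kcat, na.rm = TRUE),
                           overall_kcat)
  )
  all_tab <- dplyr::ungroup(all_tab)

  if (is.null(a_max)) a_max <- max(all_tab$corrected_abundance)
  if (!is.finite(a_max) || a_max <= 0) stop("no positive abundances")
  all_tab <- dplyr::mutate(
    all_tab,
    compressed = compress_abundance(pmin(.data$corrected_abundance, a_max),
                                    a_max, k),
    weight = .data$compressed * .data$kcat
  )
  total_expression <- sum(all_tab$weight)

  consumers <- dplyr::filter(all_tab, .data$cofactor %in% c("ATP", "GTP"))
  if (nrow(consumers) == 0) stop("no ATP/GTP-consuming proteins found")
  consumers <- dplyr::mutate(consumers, share = .data$weight / sum(.data$weight))
  structure(consumers, class = c("consumer_table", class(consumers)),
            total_corrected_expression = total_expression)
}

#' Distribute ATP/GTP capacity into a whole-cell energy budget
#'
#' Allocates the calibrated total ATP(+GTP) capacity across functional
#' classes in proportion to the summed consumer shares, yielding a per-class
#' flux in the capacity's units. Expression percentages are relative to the
#' total corrected (compressed, kcat-weighted) expression of all proteins.
#' Classes are sorted by descending flux with a cumulative-coverage column,
#' so the classes making up 90% of the demand can be read off directly.
#'
#' @param consumers a `consumer_table` from [build_consumers()].
#' @param total_capacity total ATP capacity, pmol per ng protein per day
#'   (or arbitrary units for uncalibrated runs).
#' @param cofactor_filter which consumers draw on this capacity pool
#'   (default ATP and GTP share one pool).
#' @return tibble of class `energy_budget`: `class_level1`,
#'   `expression_pct`, `share`, `flux`, `cum_fraction`; attribute
#'   `total_capacity`.
#' @export
energy_budget <- function(consumers, total_capacity,
                          cofactor_filter = c("ATP", "GTP")) {
  stopifnot(inherits(consumers, "consumer_table"), total_capacity >= 0)
  pool <- dplyr::filter(consumers, .data$cofactor %in% cofactor_filter)
  if (nrow(pool) == 0) stop("no consumers match the cofactor filter")
  pool <- dplyr::mutate(pool, share = .data$weight / sum(.data$weight))
  total_expr <- attr(consumers, "total_corrected_expression")
  out <- dplyr::summarise(
    dplyr::group_by(pool, .data$class_level1),
    expression_pct = 100 * sum(.data$weight) / total_expr,
    share = sum(.data$share), .groups = "drop"
  )
  out <- dplyr::mutate(
    dplyr::arrange(out, dplyr::desc(.data$share)),
    flux = total_capacity * .data$share,
    cum_fraction = cumsum(.data$share)
  )
  structure(out, class = c("energy_budget", class(out)),
            total_capacity = total_capacity)
}

#' Predict protein synthesis from the tRNA-ligase energy share
#'
#' Charging an amino acid onto its tRNA costs 2 ATP, so the ATP flux routed
#' to the amino-acid-tRNA-ligase class caps the amino-acid incorporation
#' flux at half that value. With a mean amino-acid mass of 110 Da, an
#' amino-acid flux in pmol per ng protein per day converts to a total
#' synthesis rate in units of the existing protein pool per day
#' (`aa_flux * 110 pg/pmol / 1000 pg/ng`). Subtracting the assumed protein
#' turnover (default 0.5/day) gives the net accumulation rate comparable to
#' growth-curve measurements.
#'
#' @param budget an `energy_budget` whose fluxes are in pmol ATP per ng
#'   protein per day.
#' @param turnover_rate fraction of the protein pool replaced per day.
#' @param ligase_pattern regular expression identifying the
#'   amino-acid-tRNA-ligase class label.
#' @return one-row tibble: `ligase_class`, `atp_to_ligases`, `aa_flux`,
#'   `total_rate`, `turnover_rate`, `net_rate` (day^-1).
#' @export
protein_synthesis <- function(budget, turnover_rate = 0.5,
                              ligase_pattern = "tRNA ligase") {
  stopifnot(inherits(budget, "energy_budget"), turnover_rate >= 0)
  hit <- grepl(ligase_pattern, budget$class_level1, ignore.case = TRUE)
  if (!any(hit)) stop("no class matching '", ligase_pattern, "' in budget")
  atp <- sum(budget$flux[hit])
  aa_flux <- atp / 2                      # 2 ATP per amino acid charged
  total_rate <- aa_flux * 110 / 1000      # 110 Da; pg -> ng
  tibble::tibble(
    ligase_class = paste(budget$class_level1[hit], collapse = " + "),
    atp_to_ligases = atp,
    aa_flux = aa_flux,
    total_rate = total_rate,
    turnover_rate = turnover_rate,
    net_rate = total_rate - turnover_rate
  )
}

#' Coerce an external per-class flux table to an energy budget
#'
#' Builds an `energy_budget` object from an already-computed per-class
#' table (for example a published reference budget), so downstream
#' estimators like [protein_synthesis()] can run on it.
#'
#' @param data data frame with one row per class.
#' @param class_col,flux_col column names (strings) holding the class label
#'   and its ATP/GTP flux.
#' @param expression_pct_col optional column with the expression
#'   percentage.
#' @param total_capacity total capacity the fluxes were drawn from;
#'   defaults to the column sum (a lower bound when the table is truncated
#'   to the top classes).
#' @return an `energy_budget`.
#' @export
as_energy_budget <- function(data, class_col = "class", flux_col = "flux",
                             expression_pct_col = NULL,
                             total_capacity = NULL) {
  stopifnot(all(c(class_col, flux_col) %in% names(data)))
  flux <- data[[flux_col]]
  if (is.null(total_capacity)) total_capacity <- sum(flux)
  out <- tibble::tibble(
    class_level1 = data[[class_col]],
    expression_pct = if (!is.null(expression_pct_col))
      data[[expression_pct_col]] else NA_real_,
    share = flux / total_capacity,
    flux = flux
  )
  out <- dplyr::arrange(out, dplyr::desc(.data$flux))
  out$cum_fraction <- cumsum(out$share)
  structure(out, class = c("energy_budget", class(out)),
            total_capacity = total_capacity)
}
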