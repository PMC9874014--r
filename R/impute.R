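#' Rule-based imputation of missing label-free abundances
#'
#' Fills every missing value in a proteome table using the protein's
#' functional class and its tissue-expression category. The premise is that
#' proteins of one functional class are expressed at a similar order of
#' magnitude, and that a tissue-general protein that went undetected is
#' nevertheless present. Per category the rule is:
#'
#' * `"Detected in all"` -> class **average** of detected values
#' * `"Detected in many"`, `"Detected in some"`, `"Detected in single"`,
#'   `"#N/A"` -> class **minimum** of detected values
#' * `"Not detected"` -> **zero**, regardless of class
#'
#' Statistics are computed per sample column over the *detected* (observed,
#' non-missing) members of the protein's level-1 class; if that class has
#' no detected member in the sample, the level-2 class is used, then the
#' whole table (level 3). For the minimum rule, zeros are excluded from the
#' candidate values. A protein absent from the annotation is treated as
#' category `"#N/A"` with unknown class (level-3 fallback).
#'
#' @param proteome tibble with `protein_id` and one numeric column per
#'   sample; missing encoded as `NA`.
#' @param ann an annotation table ([validate_annotation()]).
#' @return list with `completed` (same shape, no `NA` left) and `report`
#'   (tibble: `protein_id`, `sample`, `rule_applied`, `source_class`,
#'   `source_level`, `value`, `fallback` flag for the global-fallback
#'   degenerate case). Observed entries are never altered.
#' @export
impute_completerot <- function(proteome, ann) {
  stopifnot(is.data.frame(proteome), "protein_id" %in% names(proteome))
  scols <- sample_cols(proteome)
  if (length(scols) == 0) stop("proteome has no sample columns")
  idx <- match(proteome$protein_id, ann$gene_id)
  category <- ifelse(is.na(idx), "#N/A", ann$hpa_category[idx])
  l1 <- ann$function_level1[idx]
  l2 <- ann$function_level2[idx]

  rule_of <- function(cat) {
    switch(cat,
           "Detected in all" = "average",
           "Not detected" = "zero",
           "minimum")  # many / some / single / #N/A
  }

  completed <- proteome
  report <- vector("list", length(scols))
  for (s in seq_along(scols)) {
    col <- scols[s]
    x <- proteome[[col]]
    miss <- which(is.na(x))
    if (length(miss) == 0) { report[[s]] <- NULL; next }
    detected <- !is.na(x)
    rows <- purrr::map_dfr(miss, function(i) {
      rule <- rule_of(category[i])
      if (rule == "zero") {
        return(tibble::tibble(protein_id = proteome$protein_id[i],
                              sample = col, rule_applied = "zero",
                              source_class = NA_character_,
                              source_level = NA_character_,
                              value = 0, fallback = FALSE))
      }
      # nearest-first fallback cascade: level1 -> level2 -> whole table
      pools <- list(
        level1 = if (!is.na(l1[i])) detected & l1 == l1[i] & !is.na(l1),
        level2 = if (!is.na(l2[i])) detected & l2 == l2[i] & !is.na(l2),
        level3 = detected
      )
      pools <- pools[!vapply(pools, is.null, TRUE)]
      value <- NA_real_; level_used <- NA_character_; fb <- FALSE
      for (lev in names(pools)) {
        vals <- x[pools[[lev]]]
        if (rule == "minimum") vals <- vals[vals > 0]
        if (length(vals) > 0) {
          value <- if (rule == "average") mean(vals) else min(vals)
          level_used <- lev
          break
        }
      }
      if (is.na(value)) { value <- 0; level_used <- "global"; fb <- TRUE }
      tibble::tibble(protein_id = proteome$protein_id[i], sample = col,
                     rule_applied = rule,
                     source_class = if (identical(level_used, "level1")) l1[i]
                                    else if (identical(level_used, "level2")) l2[i]
                                    else NA_character_,
                     source_level = level_used, value = value, fallback = fb)
    })
    completed[[col]][miss] <- rows$value
    report[[s]] <- rows
  }
  list(completed = completed, report = dplyr::bind_rows(report))
}

#' Compare group sums before and after imputation
#'
#' Sums abundances per functional group for the masked and the completed
#' table and reports the Pearson correlation of the paired sums — high
#' correlation indicates imputation preserved the group-level abundance
#' structure.
#'
#' @param proteome the masked table (missing as `NA`).
#' @param completed the imputed table from [impute_completerot()].
#' @param ann annotation table.
#' @param grouping passed to [class_sums()].
#' @return list with `sums` (tibble: `group_label`, `sample`, `before`,
#'   `after`) and `correlation` (Pearson r; `NA` with a message when fewer
#'   than two groups are present).
#' @export
compare_prepost <- function(proteome, completed, ann, grouping = "level2") {
  stopifnot(identical(proteome$protein_id, completed$protein_id))
  before <- dplyr::rename(class_sums(proteome, ann, grouping), before = "sum")
  after <- dplyr::rename(class_sums(completed, ann, grouping), after = "sum")
  sums <- dplyr::inner_join(before, after, by = c("group_label", "sample"))
  r <- if (dplyr::n_distinct(sums$group_label) < 2) {
    message("fewer than two groups; correlation undefined")
    NA_real_
  } else {
    stats::cor(sums$before, sums$after, method = "pearson")
  }
  list(sums = sums, correlation = r)
}
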