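#' Tissue-expression categories
#'
#' The closed vocabulary of Human-Protein-Atlas-style tissue-expression
#' categories that drives the imputation rules.
#'
#' @return character vector of the six category labels.
#' @export
hpa_categories <- function() {
  c("Detected in all", "Detected in many", "Detected in some",
    "Detected in single", "Not detected", "#N/A")
}

cofactor_vocabulary <- function() c("ATP", "GTP", "CTP", "NAD", "NADP", "none")

#' Load and validate an energy-centric annotation table
#'
#' Reads a TSV mapping each gene to its dominant subcellular localization,
#' level-1 and level-2 functional class, required energy cofactor, tissue-
#' expression category, and (optionally) a turnover number kcat. The
#' annotation is the backbone of both the imputation (class statistics per
#' category rule) and the demand budget (cofactor-consuming classes).
#'
#' @param path TSV file with header columns `gene_id`, `localization`,
#'   `function_level1`, `function_level2`, `cofactor`, `hpa_category` and
#'   optionally `kcat`.
#' @return validated tibble of class `annotation_table`.
#' @export
load_annotation <- function(path) {
  ann <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  validate_annotation(ann)
}

#' @rdname load_annotation
#' @param ann data frame to validate in place of a file.
#' @export
validate_annotation <- function(ann) {
  required <- c("gene_id", "localization", "function_level1",
                "function_level2", "cofactor", "hpa_category")
  missing_cols <- setdiff(required, names(ann))
  if (length(missing_cols) > 0) {
    stop("annotation lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  ann <- tibble::as_tibble(ann)
  if (!"kcat" %in% names(ann)) ann$kcat <- NA_real_
  dup <- ann$gene_id[duplicated(ann$gene_id)]
  if (length(dup) > 0) {
    stop("duplicate gene id(s) in annotation: ",
         paste(utils::head(unique(dup), 5), collapse = ", "))
  }
  bad_cat <- setdiff(unique(ann$hpa_category), hpa_categories())
  if (length(bad_cat) > 0) {
    stop("unknown tissue-expression category: ",
         paste(bad_cat, collapse = ", "))
  }
  cof <- ifelse(is.na(ann$cofactor), "none", ann$cofactor)
  bad_cof <- setdiff(unique(cof), cofactor_vocabulary())
  if (length(bad_cof) > 0) {
    stop("unknown cofactor value: ", paste(bad_cof, collapse = ", "))
  }
  ann$cofactor <- cof
  structure(ann, class = c("annotation_table", class(ann)))
}

#' Sample (abundance) columns of a proteome table
#'
#' Everything that is not a recognised metadata column is treated as a
#' sample column.
#'
#' @param proteome proteome tibble.
#' @return character vector of column names.
#' @export
sample_cols <- function(proteome) {
  meta <- c("protein_id", "class_level1", "class_level2", "localization",
            "hpa_category")
  setdiff(names(proteome), meta)
}

#' Per-group abundance sums
#'
#' Sums protein abundances per functional class, localization or cofactor,
#' for each sample column — the group-level summaries used to compare
#' conditions (and, after imputation, to build the energy budget's
#' expression shares). Proteins absent from the annotation fall into group
#' `"UNKNOWN"`. Groups are ordered by decreasing grand mean.
#'
#' @param proteome tibble with `protein_id` and one column per sample;
#'   missing values are ignored in sums.
#' @param ann an annotation table ([validate_annotation()]).
#' @param grouping one of `"localization"`, `"level1"`, `"level2"`,
#'   `"cofactor"`.
#' @return tibble with `group_label`, `sample`, `sum`, ordered by the
#'   grand mean of `sum` within `group_label` (descending).
#' @export
class_sums <- function(proteome, ann,
                       grouping = c("level1", "level2", "localization",
                                    "cofactor")) {
  grouping <- match.arg(grouping)
  if (nrow(proteome) == 0) stop("empty proteome")
  col <- switch(grouping, level1 = "function_level1",
                level2 = "function_level2", localization = "localization",
                cofactor = "cofactor")
  key <- ann[[col]][match(proteome$protein_id, ann$gene_id)]
  key[is.na(key)] <- "UNKNOWN"
  long <- tidyr::pivot_longer(
    dplyr::mutate(proteome[, c("protein_id", sample_cols(proteome))],
                  group_label = key),
    cols = dplyr::all_of(sample_cols(proteome)),
    names_to = "sample", values_to = "abundance"
  )
  sums <- dplyr::summarise(
    dplyr::group_by(long, .data$group_label, .data$sample),
    sum = sum(.data$abundance, na.rm = TRUE), .groups = "drop"
  )
  order_tbl <- dplyr::arrange(
    dplyr::summarise(dplyr::group_by(sums, .data$group_label),
                     grand = mean(.data$sum), .groups = "drop"),
    dplyr::desc(.data$grand)
  )
  sums$group_label <- factor(sums$group_label, levels = order_tbl$group_label)
  dplyr::mutate(dplyr::arrange(sums, .data$group_label, .data$sample),
                group_label = as.character(.data$group_label))
}

#' Rank conditions by group abundance sums
#'
#' Given per-condition group sums, assigns rank 1 to the condition with the
#' highest sum within each group. Conditions whose mean sums differ by less
#' than a relative threshold are treated as tied and share the average of
#' the ranks they span (two tied leaders both get 1.5). The threshold is a
#' pluggable stand-in for a formal significance call; alternatively a
#' logical "significantly different" matrix can be supplied and ties are
#' taken from it.
#'
#' @param sums tibble with `group_label`, `condition`, `sum` (one row per
#'   group x condition; replicate sums should be averaged beforehand).
#' @param tie_threshold relative difference below which two conditions tie
#'   (default 0.05); ignored when `signif_matrix` is given.
#' @param signif_matrix optional symmetric logical matrix (condition x
#'   condition), `TRUE` where two conditions differ significantly.
#' @return tibble `group_label`, `condition`, `mean_sum`, `rank`.
#' @export
rank_groups <- function(sums, tie_threshold = 0.05, signif_matrix = NULL) {
  stopifnot(all(c("group_label", "condition", "sum") %in% names(sums)))
  if (dplyr::n_distinct(sums$condition) < 2) {
    stop("ranking needs at least two conditions")
  }
  per_group <- dplyr::summarise(
    dplyr::group_by(sums, .data$group_label, .data$condition),
    mean_sum = mean(.data$sum), .groups = "drop"
  )
  purrr::map_dfr(split(per_group, per_group$group_label), function(g) {
    g <- dplyr::arrange(g, dplyr::desc(.data$mean_sum))
    n <- nrow(g)
    tied_with_prev <- vapply(seq_len(n), function(i) {
      if (i == 1) return(FALSE)
      a <- g$mean_sum[i - 1]; b <- g$mean_sum[i]
      if (!is.null(signif_matrix)) {
        !isTRUE(signif_matrix[g$condition[i - 1], g$condition[i]])
      } else {
        denom <- max(abs(a), abs(b))
        a == b || (denom > 0 && abs(a - b) / denom < tie_threshold)
      }
    }, TRUE)
    block <- cumsum(!tied_with_prev)
    rank <- stats::ave(seq_len(n), block, FUN = mean)
    dplyr::mutate(g, rank = rank)
  })
}
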