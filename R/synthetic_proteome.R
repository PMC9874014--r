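#' Specification for a synthetic label-free proteome
#'
#' Emulates the structure the imputation and demand modules rely on: protein
#' abundances are log-normal around a class-specific mean (proteins in the
#' same functional class sit at a similar expression level), each protein
#' carries a tissue-expression category, and values are masked (missing)
#' with a category-specific probability — mimicking the missingness of
#' label-free shotgun proteomics, where tissue-general proteins that go
#' undetected are presumed present.
#'
#' Defaults emulate a triplicate LFQ experiment: 20 functional classes of
#' 50 proteins (1000 proteins total), log-normal abundances with 0.5
#' log-scale dispersion, and a 20% masking probability for every category
#' of quantifiable protein. Proteins in the "Not detected" category have
#' true abundance 0 and are always masked — they are genuinely absent, and
#' the category rule recovers them as exact zeros.
#'
#' @param n_classes number of level-1 functional classes.
#' @param proteins_per_class proteins per class.
#' @param n_samples replicate columns.
#' @param class_log_means numeric vector (length `n_classes`) of natural-log
#'   abundance locations; default spans e^6 .. e^12.
#' @param noise_sd log-scale within-class dispersion.
#' @param missing_frac_by_category named masking probabilities for the six
#'   tissue-expression categories.
#' @param category_probs named sampling probabilities of the categories.
#' @param seed integer; fixes the output bit-for-bit.
#' @return list of class `synthetic_proteome_spec`.
#' @export
synthetic_proteome_spec <- function(n_classes = 20,
                                    proteins_per_class = 50,
                                    n_samples = 3,
                                    class_log_means = NULL,
                                    noise_sd = 0.5,
                                    missing_frac_by_category = NULL,
                                    category_probs = NULL,
                                    seed = 1L) {
  if (is.null(class_log_means)) {
    class_log_means <- seq(6, 12, length.out = n_classes)
  }
  stopifnot(length(class_log_means) == n_classes, noise_sd >= 0,
            n_classes >= 1, proteins_per_class >= 1, n_samples >= 1)
  if (is.null(missing_frac_by_category)) {
    missing_frac_by_category <- c(
      "Detected in all" = 0.2, "Detected in many" = 0.2,
      "Detected in some" = 0.2, "Detected in single" = 0.2,
      "Not detected" = 1.0, "#N/A" = 0.2
    )
  }
  if (is.null(category_probs)) {
    category_probs <- c(
      "Detected in all" = 0.50, "Detected in many" = 0.20,
      "Detected in some" = 0.12, "Detected in single" = 0.05,
      "Not detected" = 0.05, "#N/A" = 0.08
    )
  }
  stopifnot(setequal(names(missing_frac_by_category), hpa_categories()),
            all(missing_frac_by_category >= 0 & missing_frac_by_category <= 1),
            setequal(names(category_probs), hpa_categories()))
  structure(list(n_classes = n_classes,
                 proteins_per_class = proteins_per_class,
                 n_samples = n_samples,
                 class_log_means = class_log_means,
                 noise_sd = noise_sd,
                 missing_frac_by_category = missing_frac_by_category,
                 category_probs = category_probs,
                 seed = as.integer(seed)),
            class = "synthetic_proteome_spec")
}

# Level-1 class labels. The first few mirror energy-consuming classes of an
# energy-centric gene ontology (with their cofactor in the label) so the
# demand module can be exercised end-to-end on synthetic data.
synthetic_class_labels <- function(n) {
  named <- c("Amino acid tRNA ligase (ATP)", "Transporting ATPases (ATP)",
             "Chaperone (ATP)", "Protein kinases (ATP)",
             "Cytoskeleton (GTP)", "Ras GTPases (GTP)",
             "Glycolysis and Gluconeogenesis", "Citric acid and TCA cycle",
             "Oxidoreductase (NAD)", "Oxidoreductase (NADP)")
  extra <- sprintf("Class_%02d", seq_len(max(0, n - length(named))))
  c(named, extra)[seq_len(n)]
}

synthetic_class_cofactor <- function(labels) {
  dplyr::case_when(
    grepl("\\(ATP\\)", labels) ~ "ATP",
    grepl("\\(GTP\\)", labels) ~ "GTP",
    grepl("\\(NADP\\)", labels) ~ "NADP",
    grepl("\\(NAD\\)", labels) ~ "NAD",
    TRUE ~ "none"
  )
}

#' Generate a synthetic proteome with known truth
#'
#' Draws the complete (truth) abundance table, assigns tissue-expression
#' categories, masks entries per category, and builds the matching
#' annotation table (localization, level-1/level-2 class, cofactor, kcat
#' with ~30% missing). Deterministic given `spec$seed`.
#'
#' @param spec a [synthetic_proteome_spec()].
#' @return list with `proteome` (masked; `protein_id` + sample columns,
#'   missing as `NA`), `truth` (complete), and `annotation` (tibble as
#'   accepted by [load_annotation()]'s validator).
#' @export
make_synthetic_proteome <- function(spec = synthetic_proteome_spec()) {
  stopifnot(inherits(spec, "synthetic_proteome_spec"))
  withr::local_seed(spec$seed)
  n <- spec$n_classes * spec$proteins_per_class
  classes <- rep(synthetic_class_labels(spec$n_classes),
                 each = spec$proteins_per_class)
  level2 <- paste0("L2_", sprintf("%02d", (match(classes, unique(classes)) - 1) %/% 3 + 1))
  locs <- c("Cytosol", "Nucleus", "Mitochondria", "Plasma membrane",
            "Endoplasmic reticulum", "Golgi apparatus", "Lysosome",
            "Peroxisome", "Extracellular")
  localization <- sample(locs, n, replace = TRUE)
  category <- sample(hpa_categories(), n, replace = TRUE,
                     prob = spec$category_probs[hpa_categories()])
  protein_id <- sprintf("P%04d", seq_len(n))

  log_mean <- rep(spec$class_log_means, each = spec$proteins_per_class)
  truth_mat <- matrix(
    exp(stats::rnorm(n * spec$n_samples, mean = log_mean, sd = spec$noise_sd)),
    nrow = n
  )
  truth_mat[category == "Not detected", ] <- 0

  mask_p <- spec$missing_frac_by_category[category]
  mask <- matrix(stats::runif(n * spec$n_samples), nrow = n) < mask_p
  masked_mat <- truth_mat
  masked_mat[mask] <- NA_real_

  sample_names <- paste0("sample_", seq_len(spec$n_samples))
  as_proteome <- function(mat) {
    out <- tibble::as_tibble(stats::setNames(as.data.frame(mat), sample_names))
    dplyr::bind_cols(tibble::tibble(protein_id = protein_id), out)
  }
  kcat <- exp(stats::rnorm(n, mean = log(10), sd = 1))
  kcat[stats::runif(n) < 0.3] <- NA_real_
  annotation <- tibble::tibble(
    gene_id = protein_id,
    localization = localization,
    function_level1 = classes,
    function_level2 = level2,
    cofactor = synthetic_class_cofactor(classes),
    hpa_category = category,
    kcat = kcat
  )
  list(proteome = as_proteome(masked_mat),
       truth = as_proteome(truth_mat),
       annotation = annotation)
}

#' Abundance vector for the toy model's genes
#'
#' The toy metabolic model names its enzymes by gene symbol; this helper
#' draws a deterministic log-normal abundance for each gene appearing in
#' any rule of the model, so supply-side sweeps can run on synthetic data.
#'
#' @param model a [metabolic_model()].
#' @param seed integer seed.
#' @param log_mean,log_sd log-scale location and dispersion.
#' @return named numeric vector, gene -> abundance.
#' @export
synthetic_model_abundance <- function(model, seed = 1L,
                                      log_mean = 9, log_sd = 0.8) {
  genes <- sort(unique(unlist(lapply(model$reactions$gpr, function(g) {
    gpr_genes(parse_gpr(g))
  }))))
  withr::local_seed(as.integer(seed))
  stats::setNames(exp(stats::rnorm(length(genes), log_mean, log_sd)), genes)
}

#' Generate a complete synthetic input bundle for the pipeline
#'
#' Combines [make_toy_model()], [make_synthetic_proteome()] and
#' [synthetic_model_abundance()] into one coherent input set: the toy
#' model's enzymes are appended to the synthetic proteome (with mild
#' replicate jitter and their own annotation rows) so one table drives both
#' the supply and the demand side, together with a DMEM-like medium and
#' plausible measured rates for calibration.
#'
#' @param seed integer; fixes everything.
#' @param proteome_spec a [synthetic_proteome_spec()]; its seed is
#'   overridden by `seed`.
#' @param model_spec a [toy_model_spec()].
#' @return list with `model`, `proteome` (masked), `truth`, `annotation`,
#'   `medium`, `measured_fluxes`, `measured_atp`, `measured_glucose`.
#' @export
make_toy_bundle <- function(seed = 1L,
                            proteome_spec = synthetic_proteome_spec(),
                            model_spec = toy_model_spec()) {
  proteome_spec$seed <- as.integer(seed)
  syn <- make_synthetic_proteome(proteome_spec)
  model <- make_toy_model(model_spec)
  genes <- synthetic_model_abundance(model, seed = seed + 1000L)
  withr::local_seed(as.integer(seed) + 2000L)
  scols <- paste0("sample_", seq_len(proteome_spec$n_samples))
  jitter <- matrix(exp(stats::rnorm(length(genes) * length(scols), 0, 0.05)),
                   nrow = length(genes))
  extra <- tibble::as_tibble(stats::setNames(
    as.data.frame(unname(genes) * jitter), scols))
  extra <- dplyr::bind_cols(tibble::tibble(protein_id = names(genes)), extra)
  ann_extra <- tibble::tibble(
    gene_id = names(genes), localization = "Cytosol",
    function_level1 = "Metabolic enzymes and transporters",
    function_level2 = "L2_00", cofactor = "none",
    hpa_category = "Detected in all", kcat = NA_real_
  )
  list(
    model = model,
    proteome = dplyr::bind_rows(syn$proteome, extra),
    truth = dplyr::bind_rows(syn$truth, extra),
    annotation = dplyr::bind_rows(syn$annotation, ann_extra),
    medium = tibble::tibble(metabolite_id = c("glc_e", "gln_e"), mM = c(25, 4)),
    measured_fluxes = tibble::tibble(
      metabolite_id = c("glc_e", "gln_e", "lac_e"),
      flux = c(-5.8, -1.2, 9.5)
    ),
    measured_atp = 187,      # pmol ATP / ng protein / day
    measured_glucose = 5.8   # pmol glucose / ng protein / day
  )
}
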