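test_that("each tissue-expression category applies its rule", {
  ann <- tiny_annotation()
  # A1 "Detected in all" -> average; A2 "Detected in some" -> minimum;
  # A3 "Not detected" -> zero; B1 "Detected in many" -> minimum;
  # B2 "#N/A" -> minimum
  prot <- tibble::tibble(
    protein_id = c("A1", "A2", "A3", "A4", "A5", "B1", "B2", "B3"),
    s1 = c(NA, NA, NA, 10, 30, NA, NA, 12)
  )
  ann2 <- validate_annotation(dplyr::bind_rows(
    tiny_annotation(),
    tibble::tibble(gene_id = c("A4", "A5", "B3"), localization = "Cytosol",
                   function_level1 = c("ClassA", "ClassA", "ClassB"),
                   function_level2 = "L2_1", cofactor = "none",
                   hpa_category = "Detected in all", kcat = NA_real_)
  ))
  res <- impute_completerot(prot, ann2)
  cmpl <- res$completed
  expect_equal(cmpl$s1[cmpl$protein_id == "A1"], 20)  # mean(10, 30)
  expect_equal(cmpl$s1[cmpl$protein_id == "A2"], 10)  # min
  expect_equal(cmpl$s1[cmpl$protein_id == "A3"], 0)   # Not detected -> zero
  expect_equal(cmpl$s1[cmpl$protein_id == "B1"], 12)  # min of ClassB = {12}
  expect_equal(cmpl$s1[cmpl$protein_id == "B2"], 12)  # #N/A -> minimum
  rules <- res$report$rule_applied[match(c("A1", "A2", "A3", "B1", "B2"),
                                         res$report$protein_id)]
  expect_identical(rules, c("average", "minimum", "zero", "minimum", "minimum"))
})

test_that("fallback cascades level1 -> level2 -> whole table", {
  ann <- validate_annotation(tibble::tibble(
    gene_id = c("X1", "X2", "Y1", "Z1"),
    localization = "Cytosol",
    function_level1 = c("CX", "CX", "CY", "CZ"),
    function_level2 = c("L2_a", "L2_a", "L2_a", "L2_b"),
    cofactor = "none",
    hpa_category = "Detected in all", kcat = NA_real_
  ))
  # X1 missing; X2 (same level1) also missing -> fall to level2 (Y1 = 40);
  # Z1 in another level2 entirely -> would need whole-table fallback
  prot <- tibble::tibble(protein_id = c("X1", "X2", "Y1", "Z1"),
                         s1 = c(NA, NA, 40, 8))
  res <- impute_completerot(prot, ann)
  rep1 <- res$report[res$report$protein_id == "X1", ]
  expect_identical(rep1$source_level, "level2")
  expect_equal(rep1$value, 40)
  # whole-table fallback
  prot2 <- tibble::tibble(protein_id = c("X1", "X2", "Y1", "Z1"),
                          s1 = c(NA, NA, NA, 8))
  res2 <- impute_completerot(prot2, ann)
  expect_identical(res2$report$source_level[res2$report$protein_id == "X1"],
                   "level3")
  expect_equal(res2$completed$s1, c(8, 8, 8, 8))
})

test_that("a class with no detected member anywhere is flagged", {
  ann <- validate_annotation(tibble::tibble(
    gene_id = "L1", localization = "Cytosol", function_level1 = "C",
    function_level2 = "L2", cofactor = "none",
    hpa_category = "Detected in all", kcat = NA_real_
  ))
  prot <- tibble::tibble(protein_id = "L1", s1 = NA_real_)
  res <- impute_completerot(prot, ann)
  expect_true(res$report$fallback)
  expect_equal(res$completed$s1, 0)
})

test_that("imputation is idempotent and preserves observed values", {
  syn <- make_synthetic_proteome(synthetic_proteome_spec(
    n_classes = 5, proteins_per_class = 20, seed = 11))
  ann <- validate_annotation(syn$annotation)
  once <- impute_completerot(syn$proteome, ann)
  twice <- impute_completerot(once$completed, ann)
  expect_identical(once$completed, twice$completed)
  expect_equal(nrow(twice$report), 0)
  # observed entries bit-identical
  obs <- !is.na(as.matrix(syn$proteome[, -1]))
  expect_identical(as.matrix(syn$proteome[, -1])[obs],
                   as.matrix(once$completed[, -1])[obs])
  # every originally missing entry has exactly one report row
  expect_equal(nrow(once$report), sum(!obs))
  # group sums never shrink
  before <- class_sums(syn$proteome, ann, "level1")
  after <- class_sums(once$completed, ann, "level1")
  j <- dplyr::inner_join(before, after, by = c("group_label", "sample"),
                         suffix = c("_b", "_a"))
  expect_true(all(j$sum_a >= j$sum_b - 1e-9))
})

test_that("pre/post comparison is exact when nothing is missing", {
  syn <- make_synthetic_proteome(synthetic_proteome_spec(
    n_classes = 4, proteins_per_class = 10, seed = 3,
    missing_frac_by_category = stats::setNames(rep(0, 6), hpa_categories())))
  ann <- validate_annotation(syn$annotation)
  expect_identical(syn$proteome, syn$truth)
  res <- impute_completerot(syn$proteome, ann)
  cmp <- compare_prepost(syn$proteome, res$completed, ann)
  expect_equal(cmp$correlation, 1)
})

test_that("correlation is undefined for a single group", {
  ann <- validate_annotation(tibble::tibble(
    gene_id = c("P1", "P2"), localization = "Cytosol",
    function_level1 = "C", function_level2 = "L2", cofactor = "none",
    hpa_category = "Detected in all", kcat = NA_real_
  ))
  prot <- tibble::tibble(protein_id = c("P1", "P2"), s1 = c(1, 2))
  expect_message(
    cmp <- compare_prepost(prot, prot, ann, grouping = "level1"),
    "undefined"
  )
  expect_true(is.na(cmp$correlation))
})

test_that("recovery error of class-average imputation shrinks with class size", {
  # imputed "Detected in all" values estimate the class expectation
  # exp(mu + sd^2/2); the estimate tightens as the class grows
  mus <- seq(6, 12, length.out = 4)
  expected <- exp(mus + 0.5 * 0.5^2)
  errs <- vapply(c(5, 20, 80), function(ppc) {
    syn <- make_synthetic_proteome(synthetic_proteome_spec(
      n_classes = 4, proteins_per_class = ppc, seed = 99,
      category_probs = c("Detected in all" = 1, "Detected in many" = 0,
                         "Detected in some" = 0, "Detected in single" = 0,
                         "Not detected" = 0, "#N/A" = 0)))
    ann <- validate_annotation(syn$annotation)
    res <- impute_completerot(syn$proteome, ann)
    miss <- is.na(as.matrix(syn$proteome[, -1]))
    imp <- as.matrix(res$completed[, -1])
    cls <- unique(ann$function_level1)
    errors <- unlist(lapply(seq_along(cls), function(j) {
      sel <- ann$function_level1 == cls[j]
      abs(log(imp[sel, ][miss[sel, ]]) - log(expected[j]))
    }))
    mean(errors)
  }, 0)
  expect_true(all(diff(errs) < 0))
})
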