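demand_ann <- function() {
  validate_annotation(tibble::tibble(
    gene_id = c("E1", "E2", "E3", "G1", "N1"),
    localization = "Cytosol",
    function_level1 = c("Transporting ATPases (ATP)",
                        "Amino acid tRNA ligase (ATP)",
                        "Amino acid tRNA ligase (ATP)",
                        "Ras GTPases (GTP)", "Other"),
    function_level2 = "L2_1",
    cofactor = c("ATP", "ATP", "ATP", "GTP", "none"),
    hpa_category = "Detected in all",
    kcat = c(10, 10, NA, 5, 2)
  ))
}

test_that("consumer shares are proportional and sum to one", {
  ab <- c(E1 = 50, E2 = 50, E3 = 50, G1 = 50, N1 = 100)
  cons <- build_consumers(ab, demand_ann(), k = 1e6)  # ~linear regime
  expect_equal(sum(cons$share), 1, tolerance = 1e-12)
  expect_equal(nrow(cons), 4)                  # N1 is not a consumer
  # equal weights (E1, E2 share abundance and kcat) -> equal shares
  s <- stats::setNames(cons$share, cons$consumer_id)
  expect_equal(s[["E1"]], s[["E2"]])
  # kcat doubling doubles the share: E1 kcat 10 vs G1 kcat 5, equal abundance
  expect_equal(s[["E1"]], 2 * s[["G1"]], tolerance = 1e-9)
  # missing kcat imputed by cofactor-group mean: E3 gets mean(10, 10) = 10
  expect_equal(cons$kcat[cons$consumer_id == "E3"], 10)
  expect_true(cons$kcat_imputed[cons$consumer_id == "E3"])
})

test_that("a single consumer takes the whole share", {
  ab <- c(E1 = 10, N1 = 99)
  ann <- demand_ann()[c(1, 5), ]
  cons <- build_consumers(ab, validate_annotation(ann), k = 0.016)
  expect_equal(cons$share, 1)
})

test_that("complex rules aggregate members by minsum", {
  ab <- c(E1 = 30, E2 = 10, E3 = 50, G1 = 7, N1 = 1)
  rules <- tibble::tibble(consumer_id = "CPLX1", rule = "E1 and E2")
  cons <- build_consumers(ab, demand_ann(), k = 1e6, complex_rules = rules)
  expect_true("CPLX1" %in% cons$consumer_id)
  expect_false(any(c("E1", "E2") %in% cons$consumer_id))
  expect_equal(cons$corrected_abundance[cons$consumer_id == "CPLX1"], 10)
})

test_that("budget fluxes scale with capacity and respect class shares", {
  ab <- c(E1 = 60, E2 = 40, E3 = 40, G1 = 20, N1 = 10)
  cons <- build_consumers(ab, demand_ann(), k = 1e6)
  b1 <- energy_budget(cons, total_capacity = 100)
  expect_equal(sum(b1$flux), 100, tolerance = 1e-9)
  b2 <- energy_budget(cons, total_capacity = 250)
  expect_equal(b2$flux, 2.5 * b1$flux, tolerance = 1e-12)  # homogeneous
  # flux / capacity equals the class's summed consumer share
  expect_equal(b1$flux / 100, b1$share, tolerance = 1e-12)
  # zero capacity zeroes all fluxes
  b0 <- energy_budget(cons, total_capacity = 0)
  expect_true(all(b0$flux == 0))
  # cumulative coverage is sorted and ends at 1
  expect_true(all(diff(b1$cum_fraction) > 0))
  expect_equal(b1$cum_fraction[nrow(b1)], 1, tolerance = 1e-12)
})

test_that("budget ordering is invariant to consumer row order", {
  ab <- c(E1 = 60, E2 = 40, E3 = 40, G1 = 20, N1 = 10)
  cons <- build_consumers(ab, demand_ann(), k = 0.5)
  perm <- cons[sample(nrow(cons)), ]
  class(perm) <- class(cons)
  attr(perm, "total_corrected_expression") <-
    attr(cons, "total_corrected_expression")
  expect_equal(as.data.frame(energy_budget(cons, 10)),
               as.data.frame(energy_budget(perm, 10)))
})

test_that("removing a consumer increases every remaining share", {
  set.seed(31)
  for (i in 1:5) {
    ab <- stats::setNames(stats::runif(5, 10, 100),
                          c("E1", "E2", "E3", "G1", "N1"))
    cons <- build_consumers(ab, demand_ann(), k = 0.3)
    drop_id <- sample(cons$consumer_id, 1)
    kept <- cons[cons$consumer_id != drop_id, ]
    new_share <- kept$weight / sum(kept$weight)
    expect_true(all(new_share > kept$share))
  }
})

test_that("GTP consumers can be pooled separately", {
  ab <- c(E1 = 50, E2 = 50, E3 = 50, G1 = 50, N1 = 10)
  cons <- build_consumers(ab, demand_ann(), k = 1)
  atp_only <- energy_budget(cons, 100, cofactor_filter = "ATP")
  expect_false(any(grepl("GTP", atp_only$class_level1)))
  expect_equal(sum(atp_only$flux), 100, tolerance = 1e-9)
})

test_that("protein synthesis follows the 2-ATP / 110-Da stoichiometry", {
  bud <- as_energy_budget(
    tibble::tibble(class = c("084_Amino acid tRNA ligase (ATP)", "Other (ATP)"),
                   flux = c(10, 90)))
  ps <- protein_synthesis(bud, turnover_rate = 0.5)
  expect_equal(ps$aa_flux, 5)
  expect_equal(ps$total_rate, 5 * 110 / 1000)
  expect_equal(ps$net_rate, ps$total_rate - 0.5)
  # zero ligase flux -> net equals minus the turnover
  bud0 <- as_energy_budget(
    tibble::tibble(class = c("Amino acid tRNA ligase (ATP)", "Other"),
                   flux = c(0, 50)))
  expect_equal(protein_synthesis(bud0, 0.5)$net_rate, -0.5)
  # zero turnover -> net equals total
  ps0 <- protein_synthesis(bud, turnover_rate = 0)
  expect_equal(ps0$net_rate, ps0$total_rate)
  # ligase class absent -> error
  bud_no <- as_energy_budget(tibble::tibble(class = "Other", flux = 50))
  expect_error(protein_synthesis(bud_no), "tRNA ligase")
})
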