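test_that("rules parse to the expected trees", {
  t1 <- parse_gpr("A or B")
  expect_identical(t1$op, "or")
  expect_identical(vapply(t1$args, `[[`, "", "gene"), c("A", "B"))

  t2 <- parse_gpr("(A and B) or C")
  expect_identical(t2$op, "or")
  expect_identical(t2$args[[1]]$op, "and")
  expect_identical(t2$args[[2]]$gene, "C")

  expect_length(parse_gpr(""), 0)
  expect_length(parse_gpr(NA_character_), 0)
})

test_that("malformed rules are rejected", {
  expect_error(parse_gpr("A and (B or"), "unexpected end|unbalanced")
  expect_error(parse_gpr("A and and B"), "unexpected token")
  expect_error(parse_gpr("(A or B"), "unbalanced")
  expect_error(parse_gpr("A B"), "stray token")
})

test_that("parse and render are mutually inverse", {
  rules <- c("A", "A or B", "A and B and C", "(A and B) or (C and D)",
             "((A or B) and C) or D")
  for (r in rules) {
    expect_identical(gpr_render(parse_gpr(r)), gpr_render(parse_gpr(gpr_render(parse_gpr(r)))))
    expect_identical(parse_gpr(gpr_render(parse_gpr(r))), parse_gpr(r))
  }
})

test_that("minsum follows sum-over-OR, min-over-AND", {
  ab <- c(A = 2, B = 3, C = 10)
  expect_equal(as.numeric(minsum(parse_gpr("A or B"), ab)), 5)
  expect_equal(as.numeric(minsum(parse_gpr("A and B"), ab)), 2)
  expect_equal(as.numeric(minsum(parse_gpr("(A and B) or C"), ab)), 12)
  # missing gene counts as absent (0) and is logged
  res <- minsum(parse_gpr("A and Z"), ab)
  expect_equal(as.numeric(res), 0)
  expect_identical(attr(res, "missing_genes"), "Z")
  # empty rule: no enzyme information
  expect_true(is.na(minsum(parse_gpr(""), ab)))
})

test_that("minsum agrees with a brute-force evaluator on random trees", {
  set.seed(55)
  genes <- paste0("g", 1:8)
  for (i in 1:200) {
    tree <- random_gpr_tree(genes)
    ab <- stats::setNames(stats::runif(6, 0, 100), sample(genes, 6))
    got <- as.numeric(minsum(parse_gpr(tree$string), ab))
    expect_equal(got, unname(tree$eval(ab)), tolerance = 1e-12)
    # minsum never exceeds the summed abundance of the tree leaves
    leaf_total <- sum(vapply(tree$leaves,
                             function(g) if (g %in% names(ab)) ab[[g]] else 0,
                             0))
    expect_lte(got, leaf_total + 1e-9)
  }
})

test_that("AND-only trees give the min, OR-only trees the sum", {
  ab <- c(A = 4, B = 9, C = 1)
  expect_equal(as.numeric(minsum(parse_gpr("A and B and C"), ab)), 1)
  expect_equal(as.numeric(minsum(parse_gpr("A or B or C"), ab)), 14)
})

test_that("compression is normalised, monotone, and has the right limits", {
  expect_equal(compress_abundance(10, 10, k = 0.3), 1)       # a = a_max
  expect_equal(compress_abundance(0, 10, k = 0.3), 0)        # a = 0
  expect_equal(compress_abundance(5, 10, k = 1), 2 / 3)      # half saturation
  # strictly increasing in a
  a <- seq(0.1, 9.9, length.out = 50)
  expect_true(all(diff(compress_abundance(a, 10, k = 0.016)) > 0))
  # decreasing in k for fixed a < a_max
  ks <- c(0.001, 0.016, 0.1, 1, 10)
  vals <- vapply(ks, function(k) compress_abundance(3, 10, k), 0)
  expect_true(all(diff(vals) < 0))
  # k -> Inf approaches the linear mapping a / a_max
  expect_equal(compress_abundance(3, 10, k = 1e6), 0.3, tolerance = 1e-4)
  # k -> 0 approaches 1 for any expressed protein
  expect_equal(compress_abundance(0.01, 10, k = 1e-7), 1, tolerance = 1e-3)
  expect_error(compress_abundance(1, 0, k = 1), "positive")
})
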