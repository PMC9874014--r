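test_that("annotation files load and validate", {
  path <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tiny_annotation(), path)
  ann <- load_annotation(path)
  expect_s3_class(ann, "annotation_table")
  expect_equal(nrow(ann), 6)
})

test_that("duplicate gene ids and unknown vocabulary are rejected", {
  ann <- tiny_annotation()
  dup <- dplyr::bind_rows(ann, ann[1, ])
  expect_error(validate_annotation(dup), "duplicate")
  bad <- ann
  bad$hpa_category[2] <- "Detected sometimes"
  expect_error(validate_annotation(bad), "category")
  bad2 <- ann
  bad2$cofactor[1] <- "AMP"
  expect_error(validate_annotation(bad2), "cofactor")
})

test_that("class sums partition the table total", {
  ann <- tiny_annotation()
  prot <- tibble::tibble(
    protein_id = ann$gene_id,
    s1 = c(10, 30, 5, 2, 8, 100),
    s2 = c(20, 10, 5, 1, 4, 50)
  )
  sums <- class_sums(prot, ann, grouping = "level1")
  expect_equal(sums$sum[sums$group_label == "ClassA" & sums$sample == "s1"], 45)
  expect_equal(sum(sums$sum), sum(prot$s1, prot$s2))
  # invariant to row order
  sums2 <- class_sums(prot[sample(nrow(prot)), ], ann, grouping = "level1")
  expect_equal(dplyr::arrange(sums, group_label, sample),
               dplyr::arrange(sums2, group_label, sample))
  # unannotated proteins fall into UNKNOWN
  prot2 <- dplyr::bind_rows(prot, tibble::tibble(protein_id = "ZZ",
                                                 s1 = 7, s2 = 7))
  sums3 <- class_sums(prot2, ann, grouping = "level1")
  expect_true("UNKNOWN" %in% sums3$group_label)
  # cofactor grouping omits groups with no members
  prot_gtp <- prot[4, ]
  s_cof <- class_sums(prot_gtp, ann, grouping = "cofactor")
  expect_false("ATP" %in% s_cof$group_label)
  expect_error(class_sums(prot[0, ], ann), "empty")
})

test_that("rank assignment averages tied conditions", {
  mk <- function(sums) {
    tibble::tibble(group_label = "G",
                   condition = paste0("c", seq_along(sums)), sum = sums)
  }
  expect_equal(rank_groups(mk(c(100, 50, 10, 5)), tie_threshold = 0)$rank,
               c(1, 2, 3, 4))
  expect_equal(rank_groups(mk(c(100, 100, 10)), tie_threshold = 0)$rank,
               c(1.5, 1.5, 3))
  expect_equal(rank_groups(mk(c(7, 7, 7)), tie_threshold = 0)$rank,
               rep(2, 3))
  # close but unequal sums tie under a relative threshold
  expect_equal(rank_groups(mk(c(100, 98, 10)), tie_threshold = 0.05)$rank,
               c(1.5, 1.5, 3))
  expect_error(rank_groups(mk(100)), "two conditions")
})

test_that("ranks are permutation-equivariant across conditions", {
  sums <- tibble::tibble(group_label = "G",
                         condition = c("a", "b", "c", "d"),
                         sum = c(5, 100, 10, 50))
  r1 <- rank_groups(sums, tie_threshold = 0)
  perm <- sums[c(3, 1, 4, 2), ]
  r2 <- rank_groups(perm, tie_threshold = 0)
  expect_equal(r1$rank[match(r2$condition, r1$condition)], r2$rank)
})

test_that("an external significance matrix overrides the threshold", {
  sums <- tibble::tibble(group_label = "G", condition = c("a", "b", "c"),
                         sum = c(100, 60, 10))
  sig <- matrix(TRUE, 3, 3, dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  sig["a", "b"] <- sig["b", "a"] <- FALSE   # a and b not separable
  r <- rank_groups(sums, signif_matrix = sig)
  expect_equal(r$rank, c(1.5, 1.5, 3))
})
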