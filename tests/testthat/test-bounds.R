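test_that("internal bounds keep the most abundant reaction at b_max", {
  m <- make_toy_model()
  ab <- synthetic_model_abundance(m, seed = 4)
  eff <- reaction_abundance(m, ab)
  top <- eff$reaction_id[which.max(eff$effective)]
  for (k in c(0.001, 0.016, 1, 100)) {
    mk <- internal_bounds(m, eff, k = k, b_max = 500)
    expect_equal(mk$reactions$ub[mk$reactions$id == top], 500)
  }
})

test_that("zero abundance blocks a reaction; irreversible keeps lb = 0", {
  m <- make_toy_model()
  eff <- c(GLYC = 0, LDH = 50, OXPHOS = 100)
  mk <- internal_bounds(m, eff, k = 0.1, b_max = 1000)
  glyc <- mk$reactions[mk$reactions$id == "GLYC", ]
  expect_equal(glyc$ub, 0)
  expect_equal(glyc$lb, 0)
  ldh <- mk$reactions[mk$reactions$id == "LDH", ]
  expect_gt(ldh$ub, 0)
  expect_equal(ldh$lb, 0)   # irreversible in the toy network
  # gene-free reactions are untouched
  expect_equal(mk$reactions$ub[mk$reactions$id == "ATPM"], 1000)
})

test_that("reversible gene-associated reactions get symmetric bounds", {
  m <- make_toy_model()
  m$reactions$lb[m$reactions$id == "LDH"] <- -1000  # make LDH reversible
  mk <- internal_bounds(m, c(LDH = 50, OXPHOS = 100), k = 1, b_max = 100)
  ldh <- mk$reactions[mk$reactions$id == "LDH", ]
  expect_equal(ldh$lb, -ldh$ub)
})

test_that("medium-proportional exchange bounds follow concentration ratios", {
  m <- make_toy_model()
  sp <- exchange_spec(mode = "dmem", medium = toy_medium(), r = 0.05)
  mb <- exchange_bounds(m, sp, b_max = 1000)
  expect_equal(mb$reactions$lb[mb$reactions$id == "EX_glc"], -50)
  expect_equal(mb$reactions$lb[mb$reactions$id == "EX_gln"], -8)  # 4/25 of -50
  # metabolite absent from the medium: uptake closed, secretion open
  expect_equal(mb$reactions$lb[mb$reactions$id == "EX_lac"], 0)
  expect_equal(mb$reactions$ub[mb$reactions$id == "EX_lac"], 1000)
})

test_that("exchange lower bounds weakly decrease as r grows", {
  m <- make_toy_model()
  prev <- NULL
  for (r in c(0.01, 0.05, 0.2, 0.8)) {
    sp <- exchange_spec(mode = "dmem", medium = toy_medium(), r = r)
    lb <- exchange_bounds(m, sp, b_max = 1000)$reactions$lb
    if (!is.null(prev)) expect_true(all(lb <= prev + 1e-12))
    prev <- lb
  }
})

test_that("measured fluxes are rescaled to the glucose reference", {
  measured <- tibble::tibble(metabolite_id = c("glc_e", "gln_e", "lac_e"),
                             flux = c(-12.5, -2, 10))
  norm <- normalize_measured_fluxes(measured, reference = 25)
  expect_equal(attr(norm, "scale"), 2)           # -12.5 -> -25 doubles all
  expect_equal(norm$flux, c(-25, -4, 20))
  expect_error(normalize_measured_fluxes(
    tibble::tibble(metabolite_id = "gln_e", flux = -3)), "glucose")
})

test_that("measured mode sets uptakes and secretion floors", {
  m <- make_toy_model()
  measured <- tibble::tibble(metabolite_id = c("glc_e", "gln_e", "lac_e"),
                             flux = c(-5, -1, 8))
  sp <- exchange_spec(mode = "measured", medium = toy_medium(),
                      measured_fluxes = measured, r = 0.05)
  mb <- exchange_bounds(m, sp, b_max = 1000)
  # glucose normalised to the DMEM reference bound
  expect_equal(mb$reactions$lb[mb$reactions$id == "EX_glc"], -50)
  expect_equal(mb$reactions$lb[mb$reactions$id == "EX_gln"], -10) # 1/5 ratio
  expect_equal(mb$reactions$lb[mb$reactions$id == "EX_lac"], 80)  # efflux floor
  # free policy leaves secretions unconstrained
  sp2 <- exchange_spec(mode = "measured", medium = toy_medium(),
                       measured_fluxes = measured, r = 0.05,
                       efflux_policy = "free")
  mb2 <- exchange_bounds(m, sp2, b_max = 1000)
  expect_equal(mb2$reactions$lb[mb2$reactions$id == "EX_lac"], 0)
})
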