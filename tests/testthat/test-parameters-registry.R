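test_that("packaged defaults carry every region and litter group", {
  reg <- fc_default_registry()
  expect_equal(nrow(reg$regions), 8L)
  # 13 published species-group rows (see the litter coefficient table)
  expect_equal(nrow(reg$litter), 13L)
  expect_true(all(reg$regions$dfdw > 0 & reg$regions$dfdw < 0.10))
  expect_identical(reg$constants$co2_per_c, 44 / 12)
  expect_identical(reg$constants$litter_fallback, 0.04)
  expect_identical(reg$shrub$carbon_fraction, 0.47)
  expect_identical(reg$shrub$root_shoot, 0.40)
})

test_that("lookup_dfdw returns published fractions and rejects unknowns", {
  expect_identical(lookup_dfdw("south China"), 0.0225)
  expect_identical(lookup_dfdw("northeast"), 0.0351)
  expect_identical(lookup_dfdw("southwest"), 0.0188)
  expect_identical(lookup_dfdw("SOUTH  china"), 0.0225)  # normalized match
  err <- tryCatch(lookup_dfdw("atlantis"), error = identity)
  expect_s3_class(err, "error")
  # the error enumerates the valid regions
  for (r in c("northeast", "south China", "northwest"))
    expect_match(conditionMessage(err), r, fixed = TRUE)
})

test_that("lookup_litter_params hits table rows, aliases, and the fallback", {
  p <- lookup_litter_params("Spruce, fir")
  expect_equal(c(p$a, p$b), c(20.7385, -0.0102))
  expect_false(p$fallback)
  p <- lookup_litter_params("eucalyptus")
  expect_equal(c(p$a, p$b), c(24.6966, -0.0137))
  # untranslatable legacy key is retained verbatim
  expect_equal(lookup_litter_params("yearning between lovers")$a, 9.53883)
  # alias routing
  p <- lookup_litter_params("China fir")
  expect_equal(p$group, "Cedar trees and other Chinese fir species")
  expect_equal(lookup_litter_params("Soft broad class")$group,
               "Other soft broad")
  # no-match is a valid outcome, not an error
  p <- lookup_litter_params("unknown-mix")
  expect_true(p$fallback)
  expect_true(is.na(p$a))
})

test_that("registry validation names the offending row and field", {
  sp <- toy_species()
  sp$carbon_fraction[2] <- 1.5
  base <- fc_default_registry()
  err <- tryCatch(forest_registry(sp, base$regions, base$litter),
                  error = identity)
  expect_s3_class(err, "error")
  expect_match(conditionMessage(err), "row 2")
  expect_match(conditionMessage(err), "carbon_fraction")
  expect_match(conditionMessage(err), "broadB")

  sp <- toy_species(); sp$bef[1] <- 0.9
  expect_error(forest_registry(sp, base$regions, base$litter), "bef")
  bad_regions <- base$regions; bad_regions$dfdw[3] <- 0.5
  expect_error(forest_registry(toy_species(), bad_regions, base$litter),
               "dfdw")
})

test_that("an omitted optional litter_group column defaults to NA and loads", {
  sp <- toy_species(); sp$litter_group <- NULL
  reg <- forest_registry(sp, fc_default_registry()$regions,
                         fc_default_registry()$litter)
  expect_true(all(is.na(reg$species$litter_group)))
})

test_that("save/load round-trips a registry exactly", {
  dir <- withr::local_tempdir()
  reg <- toy_registry()
  save_registry(reg, dir)
  reg2 <- load_registry_dir(dir)
  expect_identical(reg2$species[names(toy_species())], reg$species)
  expect_identical(reg2$regions, reg$regions)
  expect_identical(reg2$litter, reg$litter)
  # packaged defaults round-trip too, bit-identically for printed decimals
  defs <- fc_default_registry()
  save_registry(defs, dir)
  defs2 <- load_registry_dir(dir)
  expect_identical(defs2$regions$dfdw, defs$regions$dfdw)
  expect_identical(defs2$litter$a, defs$litter$a)
  expect_identical(defs2$litter$b, defs$litter$b)
})
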