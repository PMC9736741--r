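test_that("tree_biomass applies the BEF chain under both volume bases", {
  expect_identical(tree_biomass(0, 0.5, 1.6, 0.25), 0)
  # hand product 100 * 0.5 * 1.6 * 1.25
  expect_equal(tree_biomass(100, 0.5, 1.6, 0.25), 100)
  # per-stem basis with N = 1 and area = 1 collapses to total-stock basis
  expect_equal(tree_biomass(7.3, 0.5, 1.6, 0.25, basis = "per_stem_per_ha",
                            stems = 1, area_ha = 1),
               tree_biomass(7.3, 0.5, 1.6, 0.25))
  expect_error(tree_biomass(10, 0.5, 1.6, 0.25, basis = "per_stem_per_ha"),
               "stems")
})

test_that("tree_carbon converts biomass to CO2-e and is additive", {
  reg <- toy_registry()
  # single species: biomass 100 t at CF 0.5 -> 100*0.5*44/12
  inv1 <- toy_inventory(volumes = 100)  # biomass = 100*0.5*1.6*1.25 = 100 t
  expect_equal(tree_carbon(inv1, reg), 100 * 0.5 * 44 / 12)
  # all-zero stand
  expect_identical(tree_carbon(toy_inventory(volumes = c(0, 0)), reg), 0)
  # doubling every volume doubles the pool (homogeneity of degree 1)
  inv2 <- toy_inventory(volumes = c(100, 200))
  inv2x <- toy_inventory(volumes = c(200, 400))
  expect_equal(tree_carbon(inv2x, reg), 2 * tree_carbon(inv2, reg))
  # unknown species errors with its name
  bad <- farm_inventory("x", data.frame(species = "ghost",
                                        stock_volume_m3 = 1), 1)
  expect_error(tree_carbon(bad, reg), "ghost")
})

test_that("shrub pool honours the 5% cover threshold", {
  sh <- shrub_defaults(bdrsf = 0.1, regional_agb_per_ha = 80)
  expect_identical(shrub_biomass(0.04, sh), 0)
  expect_identical(shrub_biomass(0, sh), 0)
  expect_equal(shrub_biomass(0.05, sh), 0.1 * 80 * 0.05)  # 0.4 t/ha
  # 1 ha, 1 t/ha with published defaults 0.47 / 0.40
  reg <- toy_registry(shrub = shrub_defaults(bdrsf = 1,
                                             regional_agb_per_ha = 1))
  inv <- toy_inventory(volumes = 0, area_ha = 1, shrub_cover = 1)
  expect_equal(shrub_carbon(inv, registry = reg), (44 / 12) * 0.47 * 1.40)
  # linear in area
  inv2 <- toy_inventory(volumes = 0, area_ha = 2, shrub_cover = 1)
  expect_equal(shrub_carbon(inv2, registry = reg),
               2 * shrub_carbon(inv, registry = reg))
})

test_that("dead-wood pool uses the regional default factor", {
  expect_equal(deadwood_carbon(100, "south China"), 2.25)
  expect_equal(deadwood_carbon(100, "southwest"), 1.88)
  expect_identical(deadwood_carbon(0, "south China"), 0)
  expect_error(deadwood_carbon(100, "atlantis"), "unknown region")
})

test_that("litter ratio follows the a/b curve with the 4% fallback", {
  expect_identical(litter_ratio(100, "unknown-mix"), 0.04)
  expect_identical(litter_ratio(100, NULL), 0.04)
  # closed form (a/100) * exp(b * agb), a read as a percentage
  expect_equal(litter_ratio(100, "Spruce, fir"),
               20.7385 * exp(-0.0102 * 100) / 100)
  # b < 0 makes the ratio strictly decreasing in biomass
  agb <- seq(0, 500, by = 25)
  r <- litter_ratio(agb, "eucalyptus")
  expect_true(all(diff(r) < 0))
  # litter carbon stays below tree carbon for any ratio < 1
  expect_equal(litter_carbon(100, 0.04), 4)
  expect_identical(litter_carbon(0, 0.04), 0)
  expect_lt(litter_carbon(123.4, 0.999), 123.4)
  expect_error(litter_carbon(1, 1.2), "ratio")
})

test_that("hwp_in_use_fraction is half-life decay with the right bounds", {
  expect_equal(hwp_in_use_fraction(30, 30), 0.5)
  expect_identical(hwp_in_use_fraction(30, 0), 1)
  expect_equal(hwp_in_use_fraction(15, 30), 0.25)
  expect_error(hwp_in_use_fraction(0, 30), "service_life")
  expect_error(hwp_in_use_fraction(-5, 30), "service_life")
  # strictly decreasing in WT, strictly increasing in LT, in (0, 1]
  wt <- seq(0, 120, by = 5)
  of <- hwp_in_use_fraction(25, wt)
  expect_true(all(diff(of) < 0))
  expect_true(all(of > 0 & of <= 1))
  lt <- seq(1, 80, by = 4)
  expect_true(all(diff(hwp_in_use_fraction(lt, 30)) > 0))
})

test_that("stem carbon and HWP change follow the product chain", {
  expect_identical(stem_carbon(0, 0.5, 0.5), 0)
  expect_equal(stem_carbon(100, 0.5, 0.5), 100 * 0.25 * 44 / 12)
  expect_equal(stem_carbon(c(1, 2, 4), 0.5, 0.5),
               c(1, 2, 4) * stem_carbon(1, 0.5, 0.5))  # linear in volume
  expect_identical(hwp_carbon_change(NULL), 0)
  reg <- toy_registry()
  # stem carbon 100 requires V = 100 / (WD*CF*44/12)
  v <- 100 / (0.5 * 0.5 * 44 / 12)
  spec <- hwp_specs("pineA", "sawnwood", v, yield_rate = 0.6,
                    waste_rate = 0.1, service_life_yr = 30)
  expect_equal(hwp_carbon_change(spec, reg, wt = 30), 100 * 0.6 * 0.9 * 0.5)
  # total waste kills the pool regardless of other fields
  spec$waste_rate <- 1
  expect_identical(hwp_carbon_change(spec, reg, wt = 30), 0)
  expect_error(hwp_specs("pineA", "x", 1, 1.2, 0.1, 30), "yield_rate")
  expect_error(hwp_specs("pineA", "x", 1, 0.5, 0.1, 0), "service_life")
})

test_that("farm_pool_breakdown conserves the pool sum and matches the oracle", {
  reg <- toy_registry()
  # all-zero inventory -> all-zero breakdown
  bd0 <- farm_pool_breakdown(toy_inventory(volumes = c(0, 0),
                                           shrub_cover = 0.01), reg)
  expect_identical(bd0$total, 0)
  expect_identical(bd0$tree + bd0$shrub + bd0$deadwood + bd0$litter, 0)

  # two-species toy farm vs the spreadsheet-style oracle, 12 significant digits
  hwp <- hwp_specs(c("pineA", "broadB"), "sawnwood", c(20, 35),
                   c(0.6, 0.55), c(0.4, 0.35), c(35, 28))
  bd <- farm_pool_breakdown(toy_inventory(c(100, 200), area_ha = 10,
                                          shrub_cover = 0.1), reg, hwp = hwp)
  or <- toy_oracle(c(100, 200), 10, 0.1, hwp = hwp)
  for (pool in c("tree", "shrub", "deadwood", "litter", "hwp_change", "total"))
    expect_rel_equal(bd[[pool]], or[[pool]], tol = 1e-12)
  expect_equal(bd$density, bd$total / 10)

  # conservation + degree-1 homogeneity in stock over randomized inventories
  set.seed(42)
  for (i in 1:25) {
    v <- runif(2, 0, 500)
    cov <- runif(1)
    bd <- farm_pool_breakdown(toy_inventory(v, area_ha = runif(1, 1, 100),
                                            shrub_cover = cov), reg)
    expect_equal(bd$total,
                 bd$tree + bd$shrub + bd$deadwood + bd$litter + bd$hwp_change)
    expect_true(all(c(bd$tree, bd$shrub, bd$deadwood, bd$litter) >= 0))
  }
  v <- c(40, 90)
  b1 <- farm_pool_breakdown(toy_inventory(v, shrub_cover = 0), reg)
  # litter is nonlinear in AGB, so scale only the strictly linear pools
  b2 <- farm_pool_breakdown(toy_inventory(2 * v, shrub_cover = 0), reg)
  expect_equal(b2$tree, 2 * b1$tree)
  expect_equal(b2$deadwood, 2 * b1$deadwood)
  expect_equal(b2$tree_agb, 2 * b1$tree_agb)
})

test_that("computing in t C then converting equals computing in t CO2-e", {
  reg <- toy_registry()
  inv <- toy_inventory(c(100, 200))
  tab <- toy_species()
  agb <- c(100, 200) * tab$wood_density * tab$bef
  carbon_tC <- sum(agb * (1 + tab$root_shoot_ratio) * tab$carbon_fraction)
  expect_equal(tree_carbon(inv, reg), carbon_tC * 44 / 12)
})

test_that("reserves_from_density is density times area", {
  expect_equal(reserves_from_density(75.64, 2074.5), 75.64 * 2074.5)
  expect_identical(reserves_from_density(0, 10), 0)
  expect_error(reserves_from_density(1, 0), "area")
})
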