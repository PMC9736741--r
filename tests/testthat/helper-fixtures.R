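# shared fixtures: a tiny fully-known registry and inventories built in code

toy_species <- function() {
  data.frame(
    species_id = c("pineA", "broadB"),
    wood_density = c(0.5, 0.45),
    bef = c(1.6, 1.8),
    root_shoot_ratio = c(0.25, 0.28),
    carbon_fraction = c(0.5, 0.48),
    product_wood_density = c(0.5, 0.45),
    product_carbon_fraction = c(0.5, 0.48),
    litter_group = c("Chinese red pine", "Other hard broad class"))
}

toy_registry <- function(shrub = shrub_defaults(bdrsf = 0.1,
                                                regional_agb_per_ha = 80)) {
  base <- fc_default_registry()
  forest_registry(toy_species(), base$regions, base$litter, shrub = shrub)
}

toy_inventory <- function(volumes = c(100, 200), area_ha = 10,
                          shrub_cover = 0.1, region = "south China") {
  farm_inventory("toy",
                 data.frame(species = c("pineA", "broadB")[seq_along(volumes)],
                            stock_volume_m3 = volumes),
                 area_ha = area_ha, shrub_cover = shrub_cover,
                 region = region)
}

# independent spreadsheet-style evaluation of the full pool chain for the
# toy registry (plain arithmetic, no package accounting functions)
toy_oracle <- function(volumes, area_ha, shrub_cover, region = "south China",
                       hwp = NULL, wt = 30) {
  sp <- toy_species()[seq_along(volumes), ]
  base <- fc_default_registry()
  k <- 44 / 12
  agb <- volumes * sp$wood_density * sp$bef
  bio <- agb * (1 + sp$root_shoot_ratio)
  treeC_j <- k * bio * sp$carbon_fraction
  tree <- sum(treeC_j)
  li_tab <- base$litter
  li <- 0
  for (j in seq_along(volumes)) {
    row <- li_tab[li_tab$group == sp$litter_group[j], ]
    li <- li + treeC_j[j] * (row$a / 100) * exp(row$b * agb[j])
  }
  shrubB <- if (shrub_cover < 0.05) 0 else 0.1 * 80 * shrub_cover
  shrub <- k * 0.47 * 1.40 * area_ha * shrubB
  dfdw <- base$regions$dfdw[base$regions$region == region]
  dw <- tree * dfdw
  hwpC <- 0
  if (!is.null(hwp)) {
    for (i in seq_len(nrow(hwp))) {
      spi <- toy_species()[toy_species()$species_id == hwp$species[i], ]
      hwpC <- hwpC + hwp$harvested_volume_m3[i] * spi$product_wood_density *
        spi$product_carbon_fraction * k * hwp$yield_rate[i] *
        (1 - hwp$waste_rate[i]) * exp(-log(2) * wt / hwp$service_life_yr[i])
    }
  }
  list(tree = tree, shrub = shrub, deadwood = dw, litter = li,
       hwp_change = hwpC, total = tree + shrub + dw + li + hwpC)
}

expect_rel_equal <- function(actual, expected, tol = 1e-12) {
  denom <- ifelse(abs(expected) > 0, abs(expected), 1)
  expect_lt(max(abs(actual - expected) / denom), tol)
}
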