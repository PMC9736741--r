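## Five-pool forest carbon accounting with the biomass expansion factor (BEF)
## method. Pools: live trees, shrubs, dead wood, litter, harvested wood
## products (HWP); all reported in t CO2-equivalent (carbon mass x 44/12).

#' Construct a farm inventory
#'
#' A farm-year inventory: one record per tree species (stock volume in m3,
#' optionally stem counts), plus total area, shrub cover and region.
#'
#' @param farm farm label.
#' @param records data.frame with columns `species`, `stock_volume_m3` and
#'   optionally `stems` and `basis` (`"total_stock"`, the default, or
#'   `"per_stem_per_ha"`).
#' @param area_ha total forest area in hectares (> 0).
#' @param shrub_cover shrub canopy cover as a fraction in \[0, 1\].
#' @param region region name used for the dead-wood default factor.
#' @param year integer year index.
#' @return An object of class `farm_inventory`.
#' @export
farm_inventory <- function(farm, records, area_ha, shrub_cover = 0,
                           region = "south China", year = 1L) {
  records <- as.data.frame(records)
  if (nrow(records)) {
    if (!all(c("species", "stock_volume_m3") %in% names(records)))
      stopf("records must have columns 'species' and 'stock_volume_m3'")
    if (!"stems" %in% names(records)) records$stems <- NA_real_
    if (!"basis" %in% names(records)) records$basis <- "total_stock"
    if (anyDuplicated(norm_key(records$species)))
      stopf("duplicate species in inventory records for farm '%s'", farm)
    if (any(records$stock_volume_m3 < 0))
      stopf("stock_volume_m3 must be >= 0")
    if (any(!is.na(records$stems) & records$stems < 0))
      stopf("stems must be >= 0 when given")
    bad <- !records$basis %in% c("total_stock", "per_stem_per_ha")
    if (any(bad)) stopf("unknown volume basis '%s'", records$basis[bad][1])
  } else {
    records <- data.frame(species = character(), stock_volume_m3 = numeric(),
                          stems = numeric(), basis = character())
  }
  assert_scalar(area_ha, "area_ha", 0, strict_lower = TRUE)
  assert_scalar(shrub_cover, "shrub_cover", 0, 1)
  structure(list(farm = as.character(farm), year = as.integer(year),
                 records = records, area_ha = area_ha,
                 shrub_cover = shrub_cover, region = as.character(region)),
            class = "farm_inventory")
}

#' @export
print.farm_inventory <- function(x, ...) {
  cat(sprintf("<farm_inventory> %s (year %d, %s)\n", x$farm, x$year, x$region))
  cat(sprintf("  %d species, %.1f ha, shrub cover %.0f%%\n",
              nrow(x$records), x$area_ha, 100 * x$shrub_cover))
  invisible(x)
}

#' Stand biomass from stock volume (BEF method)
#'
#' Converts stem-wood volume to whole-stand biomass in three factors: basic
#' wood density D (t/m3) takes volume to stem mass, the biomass expansion
#' factor BEF takes stem mass to aboveground biomass, and (1 + R) adds roots
#' via the root:shoot ratio. Under the `per_stem_per_ha` basis the volume is
#' per stem and per hectare, so stem count and area multiply in as well.
#'
#' @param volume stock volume, m3 (total, or per stem per ha).
#' @param wood_density basic wood density D, t/m3.
#' @param bef biomass expansion factor (>= 1).
#' @param root_shoot root:shoot ratio R (>= 0).
#' @param basis `"total_stock"` (default) or `"per_stem_per_ha"`.
#' @param stems,area_ha stem count and area, required for `per_stem_per_ha`.
#' @return Stand biomass in tonnes (vectorized over species).
#' @export
#' @examples
#' tree_biomass(100, 0.5, 1.6, 0.25)  # 100 t
tree_biomass <- function(volume, wood_density, bef, root_shoot,
                         basis = c("total_stock", "per_stem_per_ha"),
                         stems = NULL, area_ha = NULL) {
  basis <- match.arg(basis)
  if (any(volume < 0)) stopf("volume must be >= 0")
  b <- volume * wood_density * bef * (1 + root_shoot)
  if (basis == "per_stem_per_ha") {
    if (is.null(stems) || is.null(area_ha))
      stopf("basis 'per_stem_per_ha' requires 'stems' and 'area_ha'")
    b <- b * stems * area_ha
  }
  b
}

## per-species accounting table: agb (t), biomass (t), carbon (t CO2-e)
tree_pool_table <- function(inventory, registry) {
  rec <- inventory$records
  if (!nrow(rec))
    return(data.frame(species = character(), agb = numeric(),
                      biomass = numeric(), carbon_co2e = numeric()))
  out <- lapply(seq_len(nrow(rec)), function(i) {
    p <- registry_species_row(rec$species[i], registry)
    basis <- rec$basis[i]
    mult <- if (basis == "per_stem_per_ha") rec$stems[i] * inventory$area_ha else 1
    if (basis == "per_stem_per_ha" && is.na(rec$stems[i]))
      stopf("species '%s': basis 'per_stem_per_ha' requires stems", rec$species[i])
    agb <- rec$stock_volume_m3[i] * p$wood_density * p$bef * mult
    biomass <- agb * (1 + p$root_shoot_ratio)
    data.frame(species = rec$species[i], agb = agb, biomass = biomass,
               carbon_co2e = co2_per_c() * biomass * p$carbon_fraction,
               carbon_fraction = p$carbon_fraction,
               litter_group = if (!is.na(p$litter_group) && nzchar(p$litter_group))
                 p$litter_group else rec$species[i])
  })
  do.call(rbind, out)
}

#' Live-tree carbon pool of a farm
#'
#' Sum over species of biomass times carbon fraction, converted to CO2-e by
#' the exact molar ratio 44/12.
#'
#' @param inventory a [farm_inventory()].
#' @param registry a `forest_registry` supplying D, BEF, R, CF per species.
#' @return Tree carbon pool, t CO2-e.
#' @export
tree_carbon <- function(inventory, registry = fc_default_registry()) {
  sum(tree_pool_table(inventory, registry)$carbon_co2e)
}

#' Average shrub aboveground biomass per hectare
#'
#' Below 5% shrub cover the pool is counted as zero; at or above the
#' threshold the biomass is BDRSF x B_FOREST x cover.
#'
#' @param cover shrub cover fraction in \[0, 1\].
#' @param shrub shrub parameter list, see [shrub_defaults()].
#' @return Shrub aboveground biomass, t/ha.
#' @export
#' @examples
#' shrub_biomass(0.04)  # 0: below the 5% threshold
shrub_biomass <- function(cover, shrub = shrub_defaults()) {
  assert_scalar(cover, "cover", 0, 1)
  if (cover < 0.05) return(0)
  shrub$bdrsf * shrub$regional_agb_per_ha * cover
}

#' Shrub carbon pool of a farm
#'
#' (44/12) x CF_S x (1 + R_S) x area x per-ha shrub biomass, with the
#' published defaults CF_S = 0.47 and R_S = 0.40.
#'
#' @inheritParams tree_carbon
#' @param shrub shrub parameter list; defaults to the registry's.
#' @return Shrub carbon pool, t CO2-e.
#' @export
shrub_carbon <- function(inventory, shrub = NULL,
                         registry = fc_default_registry()) {
  shrub <- shrub %||% registry$shrub
  b <- shrub_biomass(inventory$shrub_cover, shrub)
  co2_per_c() * shrub$carbon_fraction * (1 + shrub$root_shoot) *
    inventory$area_ha * b
}

#' Dead-wood carbon pool (default-factor method)
#'
#' @param tree_carbon_co2e live-tree carbon pool, t CO2-e (>= 0).
#' @param region region name for the DF_DW lookup.
#' @param registry a `forest_registry`.
#' @return Dead-wood carbon, t CO2-e.
#' @export
#' @examples
#' deadwood_carbon(100, "south China")  # 2.25
deadwood_carbon <- function(tree_carbon_co2e, region,
                            registry = fc_default_registry()) {
  assert_scalar(tree_carbon_co2e, "tree_carbon_co2e", 0)
  tree_carbon_co2e * lookup_dfdw(region, registry)
}

#' Litter : live-tree carbon ratio
#'
#' With species-group coefficients the ratio is (a/100) x exp(b x AGB) — the
#' published `a` values are percentages, consistent with the 4% fallback.
#' Without coefficients the IPCC default of 4% applies.
#'
#' @param agb aboveground biomass of the stand, tonnes (>= 0).
#' @param species_group group label looked up via [lookup_litter_params()];
#'   `NULL` forces the fallback.
#' @param registry a `forest_registry`.
#' @return Litter ratio DF_LI as a fraction.
#' @export
#' @examples
#' litter_ratio(100, "Spruce, fir")  # 0.2073850 * exp(-1.02)
#' litter_ratio(100, "unknown-mix")  # 0.04
litter_ratio <- function(agb, species_group = NULL,
                         registry = fc_default_registry()) {
  if (any(agb < 0)) stopf("agb must be >= 0")
  if (is.null(species_group))
    return(rep_len(registry$constants$litter_fallback, length(agb)))
  p <- lookup_litter_params(species_group, registry)
  if (p$fallback) return(rep_len(registry$constants$litter_fallback, length(agb)))
  (p$a / 100) * exp(p$b * agb)
}

#' Litter carbon pool
#'
#' @param tree_carbon_co2e live-tree carbon, t CO2-e.
#' @param ratio litter ratio from [litter_ratio()], in (0, 1).
#' @return Litter carbon, t CO2-e.
#' @export
litter_carbon <- function(tree_carbon_co2e, ratio) {
  if (any(ratio < 0 | ratio >= 1)) stopf("ratio must be in [0, 1)")
  tree_carbon_co2e * ratio
}

#' Fraction of wood products still in use after WT years
#'
#' First-order (half-life) decay: OF = exp(-ln(2) x WT / LT), where LT is the
#' product-class service life. One half-life (WT = LT) leaves exactly 0.5.
#'
#' @param service_life product service life LT in years (> 0).
#' @param wt accounting horizon WT in years (>= 0, default 30).
#' @return Fraction in (0, 1].
#' @export
#' @examples
#' hwp_in_use_fraction(30, 30)  # 0.5
hwp_in_use_fraction <- function(service_life, wt = 30) {
  if (any(service_life <= 0)) stopf("service_life must be > 0")
  if (any(wt < 0)) stopf("wt must be >= 0")
  exp(-log(2) * wt / service_life)
}

#' Carbon in harvested stem wood
#'
#' Volume x product wood density x product carbon fraction, as t CO2-e.
#'
#' @param volume harvested stem volume, m3 (>= 0).
#' @param product_wood_density t/m3.
#' @param product_carbon_fraction fraction in (0, 1).
#' @return Stem carbon, t CO2-e.
#' @export
stem_carbon <- function(volume, product_wood_density, product_carbon_fraction) {
  if (any(volume < 0)) stopf("volume must be >= 0")
  volume * product_wood_density * product_carbon_fraction * co2_per_c()
}

#' Build a harvested-wood-product specification table
#'
#' @param species species id (resolved in the registry for wood density and
#'   carbon fraction).
#' @param product_class product class label (e.g. "sawnwood").
#' @param harvested_volume_m3 harvested stem volume, m3.
#' @param yield_rate product yield rate TOR in \[0, 1\].
#' @param waste_rate processing waste rate WW in \[0, 1\].
#' @param service_life_yr product service life LT, years (> 0).
#' @return data.frame of class `hwp_specs` (one row per species x product).
#' @export
hwp_specs <- function(species, product_class, harvested_volume_m3,
                      yield_rate, waste_rate, service_life_yr) {
  df <- data.frame(species = species, product_class = product_class,
                   harvested_volume_m3 = harvested_volume_m3,
                   yield_rate = yield_rate, waste_rate = waste_rate,
                   service_life_yr = service_life_yr)
  if (any(df$harvested_volume_m3 < 0)) stopf("harvested_volume_m3 must be >= 0")
  if (any(df$yield_rate < 0 | df$yield_rate > 1)) stopf("yield_rate must be in [0, 1]")
  if (any(df$waste_rate < 0 | df$waste_rate > 1)) stopf("waste_rate must be in [0, 1]")
  if (any(df$service_life_yr <= 0)) stopf("service_life_yr must be > 0")
  class(df) <- c("hwp_specs", class(df))
  df
}

#' Carbon stock change of harvested wood products
#'
#' Sums, over product classes and species, the stem carbon actually retained
#' in products: stem carbon x yield x (1 - waste) x fraction still in use
#' after WT years.
#'
#' @param specs an [hwp_specs()] table (possibly empty or `NULL`).
#' @param registry a `forest_registry`.
#' @param wt accounting horizon WT, years; defaults to the registry constant.
#' @return HWP carbon stock change, t CO2-e.
#' @export
hwp_carbon_change <- function(specs, registry = fc_default_registry(),
                              wt = registry$constants$wt_horizon) {
  if (is.null(specs) || nrow(specs) == 0) return(0)
  total <- 0
  for (i in seq_len(nrow(specs))) {
    p <- registry_species_row(specs$species[i], registry)
    cs <- stem_carbon(specs$harvested_volume_m3[i], p$product_wood_density,
                      p$product_carbon_fraction)
    total <- total + cs * specs$yield_rate[i] * (1 - specs$waste_rate[i]) *
      hwp_in_use_fraction(specs$service_life_yr[i], wt)
  }
  total
}

#' Full five-pool carbon breakdown of a farm
#'
#' Computes the tree, shrub, dead-wood, litter and harvested-wood-product
#' pools and their total (all t CO2-e), plus aboveground and whole-stand
#' biomass and the per-hectare carbon density. The litter pool is evaluated
#' per species: each species' litter ratio (from its group's a/b
#' coefficients, or the 4% fallback) is applied to that species' tree carbon.
#'
#' @param inventory a [farm_inventory()].
#' @param registry a `forest_registry`.
#' @param hwp optional [hwp_specs()] table for the farm.
#' @param wt HWP accounting horizon, years.
#' @param agb_basis `"total"` (default) feeds each species' total aboveground
#'   biomass (t) into the litter ratio; `"per_ha"` divides by farm area first.
#' @return An object of class `pool_breakdown`: list with `tree`, `shrub`,
#'   `deadwood`, `litter`, `hwp_change`, `total`, `tree_agb`, `tree_biomass`,
#'   `area_ha`, `density` (total / area) and the per-species table.
#' @export
farm_pool_breakdown <- function(inventory, registry = fc_default_registry(),
                                hwp = NULL,
                                wt = registry$constants$wt_horizon,
                                agb_basis = c("total", "per_ha")) {
  agb_basis <- match.arg(agb_basis)
  tab <- tree_pool_table(inventory, registry)
  tree <- sum(tab$carbon_co2e)
  shrub <- shrub_carbon(inventory, registry = registry)
  dw <- if (tree > 0) deadwood_carbon(tree, inventory$region, registry) else {
    lookup_dfdw(inventory$region, registry)  # still validate the region
    0
  }
  litter <- 0
  if (nrow(tab)) {
    for (i in seq_len(nrow(tab))) {
      agb_i <- if (agb_basis == "per_ha") tab$agb[i] / inventory$area_ha else tab$agb[i]
      r <- litter_ratio(agb_i, tab$litter_group[i], registry)
      litter <- litter + litter_carbon(tab$carbon_co2e[i], r)
    }
  }
  hwpc <- hwp_carbon_change(hwp, registry, wt)
  total <- tree + shrub + dw + litter + hwpc
  structure(list(farm = inventory$farm, year = inventory$year,
                 tree = tree, shrub = shrub, deadwood = dw, litter = litter,
                 hwp_change = hwpc, total = total,
                 tree_agb = sum(tab$agb), tree_biomass = sum(tab$biomass),
                 area_ha = inventory$area_ha,
                 density = total / inventory$area_ha,
                 per_species = tab[, c("species", "agb", "biomass",
                                       "carbon_co2e")]),
            class = "pool_breakdown")
}

#' @export
print.pool_breakdown <- function(x, ...) {
  cat(sprintf("<pool_breakdown> %s (year %d)\n", x$farm, x$year))
  pools <- c(tree = x$tree, shrub = x$shrub, deadwood = x$deadwood,
             litter = x$litter, hwp_change = x$hwp_change)
  for (nm in names(pools))
    cat(sprintf("  %-10s %14.3f t CO2-e\n", nm, pools[[nm]]))
  cat(sprintf("  %-10s %14.3f t CO2-e (%.2f t CO2-e/ha over %.1f ha)\n",
              "total", x$total, x$density, x$area_ha))
  invisible(x)
}

#' Carbon reserves from per-hectare density
#'
#' Convenience product density x area, used to reproduce published farm
#' reserves from their printed per-hectare carbon densities.
#'
#' @param density carbon density, t CO2-e per ha (>= 0).
#' @param area_ha area in hectares (> 0).
#' @return Reserves, t CO2-e.
#' @export
#' @examples
#' reserves_from_density(75.64, 2074.5)
reserves_from_density <- function(density, area_ha) {
  if (any(density < 0)) stopf("density must be >= 0")
  if (any(area_ha <= 0)) stopf("area_ha must be > 0")
  density * area_ha
}
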