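## Parameter registry: every per-species, per-region and global constant the
## accounting and valuation chains consume. Packaged defaults live under
## inst/extdata and mirror the published regional dead-wood ratios (8 regions)
## and the IPCC litter a/b coefficients (13 species groups).

fc_extdata <- function(file) {
  system.file("extdata", file, package = "forestcarbon", mustWork = TRUE)
}

#' Shrub-pool default parameters
#'
#' Defaults for the shrub carbon pool: carbon fraction 0.47 and root:shoot
#' ratio 0.40 are published defaults; `bdrsf` (ratio of average shrub biomass
#' per ha at full cover to average forest biomass per ha) and
#' `regional_agb_per_ha` (regional mean aboveground forest biomass, t/ha) are
#' site quantities with illustrative subtropical defaults — override them with
#' local survey values for real analyses.
#'
#' @param carbon_fraction carbon fraction of shrub biomass (0-1).
#' @param root_shoot belowground:aboveground biomass ratio of shrubs.
#' @param bdrsf dimensionless shrub:forest biomass ratio at full cover.
#' @param regional_agb_per_ha regional average aboveground biomass, t/ha.
#' @return A list with the four shrub parameters.
#' @export
shrub_defaults <- function(carbon_fraction = 0.47, root_shoot = 0.40,
                           bdrsf = 0.1, regional_agb_per_ha = 80) {
  assert_scalar(carbon_fraction, "carbon_fraction", 0, 1,
                strict_lower = TRUE, strict_upper = TRUE)
  assert_scalar(root_shoot, "root_shoot", 0)
  assert_scalar(bdrsf, "bdrsf", 0)
  assert_scalar(regional_agb_per_ha, "regional_agb_per_ha", 0)
  list(carbon_fraction = carbon_fraction, root_shoot = root_shoot,
       bdrsf = bdrsf, regional_agb_per_ha = regional_agb_per_ha)
}

#' Global accounting constants
#'
#' @param wt_horizon wood-product accounting horizon WT in years (default 30:
#'   products still in use or landfilled 30 years after production count).
#' @param litter_fallback litter:live-tree carbon ratio used when no species
#'   group coefficients are available (IPCC recommended 4%).
#' @return List with `co2_per_c` (exactly 44/12), `wt_horizon`,
#'   `litter_fallback`.
#' @export
global_constants <- function(wt_horizon = 30, litter_fallback = 0.04) {
  assert_scalar(wt_horizon, "wt_horizon", 0)
  assert_scalar(litter_fallback, "litter_fallback", 0, 1)
  list(co2_per_c = 44 / 12, wt_horizon = wt_horizon,
       litter_fallback = litter_fallback)
}

#' Default species-name to litter-group aliases
#'
#' The mapping from inventory species labels to the litter coefficient table's
#' group rows is not standardised; this editable alias table covers the common
#' south-China inventory labels. Keys are matched case- and
#' whitespace-insensitively.
#'
#' @return Named character vector: normalized species key -> litter group.
#' @export
default_litter_aliases <- function() {
  c("soft broad class"  = "Other soft broad",
    "hard broad class"  = "Other hard broad class",
    "china fir"         = "Cedar trees and other Chinese fir species",
    "chinese fir"       = "Cedar trees and other Chinese fir species",
    "castanopsis fissa" = "Other hard broad class",
    "wetland pine"      = "Other pine species",
    "masson pine"       = "Chinese red pine",
    "spruce"            = "Spruce, fir",
    "fir"               = "Spruce, fir",
    "larch"             = "Dahurian larch")
}

.registry_species_cols <- c("species_id", "wood_density", "bef",
                            "root_shoot_ratio", "carbon_fraction",
                            "product_wood_density", "product_carbon_fraction",
                            "litter_group")

validate_species_table <- function(species) {
  missing <- setdiff(setdiff(.registry_species_cols, "litter_group"),
                     names(species))
  if (length(missing))
    stopf("species table is missing column(s): %s",
          paste(missing, collapse = ", "))
  if (!"litter_group" %in% names(species)) species$litter_group <- NA_character_
  if (anyDuplicated(norm_key(species$species_id)))
    stopf("species table has duplicated species_id values")
  chk <- function(col, test, what) {
    bad <- which(!test(species[[col]]))
    if (length(bad))
      stopf("species table row %d (%s): '%s' %s", bad[1],
            species$species_id[bad[1]], col, what)
  }
  chk("wood_density", function(x) x > 0, "must be > 0")
  chk("bef", function(x) x >= 1, "must be >= 1")
  chk("root_shoot_ratio", function(x) x >= 0, "must be >= 0")
  chk("carbon_fraction", function(x) x > 0 & x < 1, "must be in (0, 1)")
  chk("product_wood_density", function(x) x > 0, "must be > 0")
  chk("product_carbon_fraction", function(x) x > 0 & x < 1,
      "must be in (0, 1)")
  species
}

#' Construct a parameter registry
#'
#' Bundles species coefficients (wood density D, biomass expansion factor BEF,
#' root:shoot ratio R, carbon fraction CF, product wood density/carbon
#' fraction, litter group), regional dead-wood default factors, litter a/b
#' coefficients, shrub defaults and global constants, and validates every
#' invariant.
#'
#' @param species data.frame with columns `species_id`, `wood_density`, `bef`,
#'   `root_shoot_ratio`, `carbon_fraction`, `product_wood_density`,
#'   `product_carbon_fraction` and optionally `litter_group`.
#' @param regions data.frame with columns `region`, `dfdw` (dead wood : live
#'   tree carbon ratio as a fraction).
#' @param litter data.frame with columns `group`, `a`, `b` (the litter ratio is
#'   (a/100)·exp(b·AGB)).
#' @param shrub list as returned by [shrub_defaults()].
#' @param constants list as returned by [global_constants()].
#' @param aliases named character vector mapping normalized species keys to
#'   litter groups; see [default_litter_aliases()].
#' @return An object of class `forest_registry`.
#' @seealso [load_registry()], [fc_default_registry()]
#' @export
forest_registry <- function(species, regions, litter,
                            shrub = shrub_defaults(),
                            constants = global_constants(),
                            aliases = default_litter_aliases()) {
  species <- validate_species_table(as.data.frame(species))
  regions <- as.data.frame(regions)
  litter <- as.data.frame(litter)
  if (!all(c("region", "dfdw") %in% names(regions)))
    stopf("regions table must have columns 'region' and 'dfdw'")
  bad <- which(!(regions$dfdw > 0 & regions$dfdw < 0.10))
  if (length(bad))
    stopf("regions table row %d (%s): 'dfdw' must be a fraction in (0, 0.10)",
          bad[1], regions$region[bad[1]])
  if (!all(c("group", "a", "b") %in% names(litter)))
    stopf("litter table must have columns 'group', 'a' and 'b'")
  structure(list(species = species, regions = regions, litter = litter,
                 shrub = shrub, constants = constants, aliases = aliases),
            class = "forest_registry")
}

#' Load a registry from delimited tables
#'
#' Any file argument left `NULL` falls back to the packaged default table.
#' The packaged species table is a clearly-labelled *synthetic illustrative*
#' set (the per-species D/BEF/R/CF behind the published farm densities are not
#' public); replace it with measured values for real accounting.
#'
#' @param species_file,regions_file,litter_file CSV paths (see
#'   [forest_registry()] for the column schemas).
#' @param shrub,constants,aliases see [forest_registry()].
#' @return A validated `forest_registry`.
#' @export
load_registry <- function(species_file = NULL, regions_file = NULL,
                          litter_file = NULL, shrub = shrub_defaults(),
                          constants = global_constants(),
                          aliases = default_litter_aliases()) {
  read1 <- function(path, default) {
    path <- path %||% fc_extdata(default)
    if (!file.exists(path)) stopf("registry file not found: %s", path)
    utils::read.csv(path, stringsAsFactors = FALSE, check.names = TRUE)
  }
  species <- read1(species_file, "species_params_synthetic.csv")
  if ("litter_group" %in% names(species) &&
      !is.character(species$litter_group))
    species$litter_group <- as.character(species$litter_group)
  forest_registry(species,
                  read1(regions_file, "region_deadwood.csv"),
                  read1(litter_file, "litter_params.csv"),
                  shrub = shrub, constants = constants, aliases = aliases)
}

#' Save a registry's tables to a directory
#'
#' Writes `species_params.csv`, `region_deadwood.csv` and `litter_params.csv`
#' so that [load_registry()] on the same directory round-trips all values.
#'
#' @param registry a `forest_registry`.
#' @param dir output directory (created if needed).
#' @return Invisibly, the three file paths.
#' @export
save_registry <- function(registry, dir) {
  stopifnot(inherits(registry, "forest_registry"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("species_params.csv", "region_deadwood.csv",
                            "litter_params.csv"))
  utils::write.csv(registry$species, paths[1], row.names = FALSE)
  utils::write.csv(registry$regions, paths[2], row.names = FALSE)
  utils::write.csv(registry$litter, paths[3], row.names = FALSE)
  invisible(paths)
}

#' Load a registry saved with [save_registry()]
#'
#' @param dir directory containing the three registry CSVs.
#' @param ... passed on to [load_registry()].
#' @return A `forest_registry`.
#' @export
load_registry_dir <- function(dir, ...) {
  load_registry(species_file = file.path(dir, "species_params.csv"),
                regions_file = file.path(dir, "region_deadwood.csv"),
                litter_file = file.path(dir, "litter_params.csv"), ...)
}

.registry_cache <- new.env(parent = emptyenv())

#' Packaged default registry
#'
#' The registry built from the packaged default tables (cached after the
#' first call).
#'
#' @return A `forest_registry`.
#' @export
fc_default_registry <- function() {
  if (is.null(.registry_cache$reg)) .registry_cache$reg <- load_registry()
  .registry_cache$reg
}

#' Dead-wood default factor for a region
#'
#' Ratio of dead-wood carbon to live-tree carbon (DF_DW) from the packaged
#' national-inventory reference table, as a fraction (e.g. 0.0225 for
#' south China).
#'
#' @param region region name; matched case- and whitespace-insensitively
#'   against the registry's eight regions.
#' @param registry a `forest_registry`.
#' @return The DF_DW fraction.
#' @export
#' @examples
#' lookup_dfdw("south China")  # 0.0225
lookup_dfdw <- function(region, registry = fc_default_registry()) {
  i <- match(norm_key(region), norm_key(registry$regions$region))
  if (is.na(i))
    stopf("unknown region '%s'; valid regions: %s", region,
          paste(registry$regions$region, collapse = ", "))
  registry$regions$dfdw[i]
}

#' Litter a/b coefficients for a species group
#'
#' Looks up the litter-ratio coefficients for a species group, first directly
#' and then through the alias table. A miss is not an error: the returned
#' marker tells the caller to apply the 4% IPCC fallback ratio instead.
#'
#' @param species_group group or species label.
#' @param registry a `forest_registry`.
#' @return List with `a`, `b`, `group` and logical `fallback`; when
#'   `fallback` is `TRUE`, `a` and `b` are `NA`.
#' @export
#' @examples
#' lookup_litter_params("Spruce, fir")   # a = 20.7385, b = -0.0102
#' lookup_litter_params("unknown-mix")$fallback  # TRUE
lookup_litter_params <- function(species_group,
                                 registry = fc_default_registry()) {
  key <- norm_key(species_group)
  groups <- norm_key(registry$litter$group)
  i <- match(key, groups)
  if (is.na(i) && key %in% names(registry$aliases))
    i <- match(norm_key(registry$aliases[[key]]), groups)
  if (is.na(i))
    return(list(a = NA_real_, b = NA_real_, group = NA_character_,
                fallback = TRUE))
  list(a = registry$litter$a[i], b = registry$litter$b[i],
       group = registry$litter$group[i], fallback = FALSE)
}

#' @export
print.forest_registry <- function(x, ...) {
  cat("<forest_registry>\n")
  cat("  species:", nrow(x$species), "| regions:", nrow(x$regions),
      "| litter groups:", nrow(x$litter), "\n")
  cat(sprintf("  shrub CF=%.2f R=%.2f BDRSF=%.2f B_FOREST=%.1f t/ha\n",
              x$shrub$carbon_fraction, x$shrub$root_shoot, x$shrub$bdrsf,
              x$shrub$regional_agb_per_ha))
  cat(sprintf("  WT=%g yr, litter fallback=%.0f%%, CO2/C=44/12\n",
              x$constants$wt_horizon, 100 * x$constants$litter_fallback))
  invisible(x)
}

## resolve a species row from the registry, erroring with the species name
registry_species_row <- function(species_id, registry) {
  i <- match(norm_key(species_id), norm_key(registry$species$species_id))
  if (is.na(i))
    stopf("no species parameters for '%s' in the registry", species_id)
  registry$species[i, , drop = FALSE]
}
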