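## Synthetic-data generators: age-volume growth series with known truth, and
## whole forest-farm inventories whose pool breakdown is also computed by an
## independent closed-form code path (the oracle the pipeline is tested
## against).

#' Simulate an age-volume growth series
#'
#' Draws ages in `age_range` (evenly spaced or seeded-uniform), evaluates the
#' true model and perturbs the volumes with Gaussian noise. Multiplicative
#' noise (the default) keeps young-age volumes positive; additive noise is
#' available for sensitivity checks.
#'
#' @param family growth-model family of the truth.
#' @param params named numeric `c(a=, b=, c=)` true parameters (c ignored
#'   for mitscherlich).
#' @param n_obs number of observations (>= 4; default 30).
#' @param age_range numeric length-2, years (default 1 to 100).
#' @param noise_sd noise standard deviation as a fraction of volume
#'   (multiplicative) or in m3 (additive); >= 0 (default 0.02).
#' @param noise `"multiplicative"` (default) or `"additive"`.
#' @param ages `"even"` (default) or `"random"` placement in `age_range`.
#' @param seed integer seed for reproducibility (`NULL`: current RNG state).
#' @return List with `obs` (data.frame age, volume), `truth` (the
#'   `growth_model`), and the configuration.
#' @export
#' @examples
#' sim <- simulate_growth_series(params = c(a = 1.54, b = 8.434, c = 0.034),
#'                               seed = 1)
#' head(sim$obs)
simulate_growth_series <- function(family = "gompertz",
                                   params = c(a = 1.54, b = 8.434, c = 0.034),
                                   n_obs = 30, age_range = c(1, 100),
                                   noise_sd = 0.02,
                                   noise = c("multiplicative", "additive"),
                                   ages = c("even", "random"), seed = NULL) {
  noise <- match.arg(noise)
  ages <- match.arg(ages)
  if (n_obs < 4) stopf("n_obs must be >= 4")
  if (noise_sd < 0) stopf("noise_sd must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  truth <- growth_model(family, a = params[["a"]], b = params[["b"]],
                        c = if ("c" %in% names(params)) params[["c"]]
                            else NA_real_)
  A <- if (ages == "even") seq(age_range[1], age_range[2], length.out = n_obs)
       else sort(stats::runif(n_obs, age_range[1], age_range[2]))
  mu <- predict(truth, A)
  y <- if (noise == "multiplicative") mu * (1 + stats::rnorm(n_obs, 0, noise_sd))
       else mu + stats::rnorm(n_obs, 0, noise_sd)
  list(obs = data.frame(age = A, volume = y), truth = truth,
       family = truth$family, noise_sd = noise_sd, noise = noise, seed = seed)
}

#' Simulate a forest farm with closed-form true pools
#'
#' Generates an internally consistent farm: species parameters inside
#' plausible inventory ranges, stock volumes, shrub cover, and a harvested
#' wood product spec per species, together with the five-pool breakdown
#' computed *independently* (straight vectorized arithmetic, not the
#' accounting functions) as ground truth.
#'
#' @param n_species number of species (0 gives an empty farm).
#' @param area_range,stock_range,shrub_cover_range sampling ranges for total
#'   area (ha), per-species stock (m3) and shrub cover (fraction). Defaults
#'   bracket the published farm inventories.
#' @param region region name (must exist in the registry's region table).
#' @param hwp_fraction fraction of each species' stock treated as harvested
#'   into products (default 0.1).
#' @param seed integer seed (`NULL`: current RNG state).
#' @return List with `inventory` (a `farm_inventory`), `registry` (a
#'   `forest_registry` carrying the generated species and litter tables),
#'   `hwp` (an `hwp_specs` table), `truth` (named list of the five pools,
#'   their total, tree_agb and tree_biomass — t CO2-e / t), and `seed`.
#' @export
simulate_farm <- function(n_species = 5, area_range = c(1500, 2700),
                          stock_range = c(500, 110000),
                          shrub_cover_range = c(0, 0.3),
                          region = "south China", hwp_fraction = 0.1,
                          seed = NULL) {
  if (n_species < 0) stopf("n_species must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  runif1 <- function(n, r) stats::runif(n, r[1], r[2])
  area <- runif1(1, area_range)
  cover <- runif1(1, shrub_cover_range)
  n <- as.integer(n_species)
  sp <- if (n > 0) sprintf("sim_species_%02d", seq_len(n)) else character()
  D <- runif1(n, c(0.30, 0.65)); BEF <- runif1(n, c(1.2, 1.8))
  R <- runif1(n, c(0.20, 0.30)); CF <- runif1(n, c(0.45, 0.55))
  la <- runif1(n, c(4, 25)); lb <- -runif1(n, c(0.001, 0.02))
  V <- runif1(n, stock_range)
  yield <- runif1(n, c(0.5, 0.7)); waste <- runif1(n, c(0.3, 0.5))
  lt <- runif1(n, c(20, 40))
  lgroups <- if (n > 0) sprintf("sim_group_%02d", seq_len(n)) else character()

  base <- fc_default_registry()
  species <- data.frame(species_id = sp, wood_density = D, bef = BEF,
                        root_shoot_ratio = R, carbon_fraction = CF,
                        product_wood_density = D, product_carbon_fraction = CF,
                        litter_group = lgroups)
  litter <- data.frame(group = lgroups, a = la, b = lb)
  registry <- forest_registry(species, base$regions, litter,
                              shrub = base$shrub, constants = base$constants,
                              aliases = base$aliases)
  inventory <- farm_inventory(sprintf("sim_farm_seed%s", seed %||% "NA"),
                              data.frame(species = sp, stock_volume_m3 = V),
                              area_ha = area, shrub_cover = cover,
                              region = region)
  hwp <- if (n > 0)
    hwp_specs(sp, "simulated_product", hwp_fraction * V, yield, waste, lt)
  else NULL

  ## ---- independent closed-form truth (no accounting functions) ----
  k <- 44 / 12
  agb <- V * D * BEF
  bio <- agb * (1 + R)
  treeC <- k * sum(bio * CF)
  dfdw <- base$regions$dfdw[match(norm_key(region),
                                  norm_key(base$regions$region))]
  sh <- base$shrub
  shrubB <- if (cover < 0.05) 0 else sh$bdrsf * sh$regional_agb_per_ha * cover
  shrubC <- k * sh$carbon_fraction * (1 + sh$root_shoot) * area * shrubB
  dwC <- treeC * dfdw
  liC <- sum((k * bio * CF) * (la / 100) * exp(lb * agb))
  hwpC <- sum(hwp_fraction * V * D * CF * k * yield * (1 - waste) *
                exp(-log(2) * base$constants$wt_horizon / lt))
  truth <- list(tree = treeC, shrub = shrubC, deadwood = dwC, litter = liC,
                hwp_change = hwpC,
                total = treeC + shrubC + dwC + liC + hwpC,
                tree_agb = sum(agb), tree_biomass = sum(bio))

  list(inventory = inventory, registry = registry, hwp = hwp, truth = truth,
       seed = seed)
}
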