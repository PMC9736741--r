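## End-to-end pipeline and command-line interface: chains accounting ->
## fitting -> projection -> valuation into CSV reports with a JSON run
## manifest (seed, versions, input digests) for reproducibility.

#' Read a farm inventory CSV
#'
#' Expected columns: `farm`, `year`, `species`, `stock_volume_m3`, `stems`
#' (optional), `area_ha`, `shrub_cover`, `region`. One [farm_inventory()] is
#' built per farm.
#'
#' @param path CSV file path.
#' @return Named list of `farm_inventory` objects.
#' @export
read_inventory_csv <- function(path) {
  if (!file.exists(path)) stopf("inventory file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("farm", "species", "stock_volume_m3", "area_ha")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stopf("inventory CSV is missing column(s): %s",
          paste(missing, collapse = ", "))
  out <- lapply(split(df, df$farm), function(d) {
    farm_inventory(d$farm[1],
                   data.frame(species = d$species,
                              stock_volume_m3 = d$stock_volume_m3,
                              stems = if ("stems" %in% names(d)) d$stems
                                      else NA_real_),
                   area_ha = d$area_ha[1],
                   shrub_cover = if ("shrub_cover" %in% names(d))
                     d$shrub_cover[1] else 0,
                   region = if ("region" %in% names(d)) d$region[1]
                            else "south China",
                   year = if ("year" %in% names(d)) d$year[1] else 1L)
  })
  out[unique(df$farm)]
}

breakdowns_to_df <- function(breakdowns) {
  do.call(rbind, lapply(breakdowns, function(b) {
    data.frame(farm = b$farm, year = b$year, tree = b$tree, shrub = b$shrub,
               deadwood = b$deadwood, litter = b$litter,
               hwp_change = b$hwp_change, total = b$total,
               area_ha = b$area_ha, density_tco2e_ha = b$density)
  }))
}

#' Run the full analysis pipeline
#'
#' Stages (each optional depending on the config): carbon accounting of every
#' farm in the inventory, growth-model fitting and selection per species,
#' stock projection, and TEV valuation. Writes `pools.csv`, `fits.csv`,
#' `projection.csv`, `tev.csv` and `manifest.json` into `out_dir`. Reruns
#' with the same seed and inputs are byte-identical.
#'
#' @param config named list (or path to a JSON file encoding it) with fields:
#' \describe{
#'   \item{seed}{integer; seeds every stochastic stage (required).}
#'   \item{out_dir}{output directory (required).}
#'   \item{inventory}{inventory CSV path; or `simulate = list(...)` args for
#'     [simulate_farm()].}
#'   \item{registry}{optional directory written by [save_registry()].}
#'   \item{growth}{optional CSV with columns species, age_years, volume_m3;
#'     or `growth_simulate = list(...)` args for [simulate_growth_series()].}
#'   \item{families}{families to fit (default all five).}
#'   \item{horizon}{projection horizon, years (default 100).}
#'   \item{wt}{HWP horizon, years (default registry constant).}
#'   \item{valuation}{optional list with `land`, `tree`, `carbon_fixation`,
#'     `habitat` argument lists for the four indicator functions.}
#' }
#' @return Invisibly, a list with the in-memory stage results and the output
#'   file paths.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  if (is.null(config$seed)) stopf("config$seed is required")
  if (is.null(config$out_dir)) stopf("config$out_dir is required")
  seed <- as.integer(config$seed)
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)
  registry <- if (!is.null(config$registry))
    load_registry_dir(config$registry) else fc_default_registry()
  paths <- character()
  results <- list(seed = seed)
  digests <- list()

  ## --- accounting ---
  sim <- NULL
  if (!is.null(config$inventory)) {
    invs <- read_inventory_csv(config$inventory)
    digests[["inventory"]] <- unname(tools::md5sum(config$inventory))
    hwp <- NULL
  } else {
    sim <- do.call(simulate_farm,
                   c(config$simulate %||% list(), list(seed = seed)))
    invs <- list(sim$inventory)
    names(invs) <- sim$inventory$farm
    registry <- sim$registry
    hwp <- sim$hwp
    results$truth <- sim$truth
  }
  wt <- config$wt %||% registry$constants$wt_horizon
  breakdowns <- lapply(invs, farm_pool_breakdown, registry = registry,
                       hwp = hwp, wt = wt)
  pools_df <- breakdowns_to_df(breakdowns)
  p <- file.path(out_dir, "pools.csv")
  utils::write.csv(pools_df, p, row.names = FALSE)
  paths <- c(paths, pools = p)
  results$breakdowns <- breakdowns

  ## --- growth fitting & projection ---
  families <- config$families %||% growth_families()
  horizon <- config$horizon %||% 100
  obs <- NULL
  if (!is.null(config[["growth"]])) {
    obs <- utils::read.csv(config[["growth"]], stringsAsFactors = FALSE)
    digests[["growth"]] <- unname(tools::md5sum(config[["growth"]]))
  } else if (!is.null(config$growth_simulate)) {
    gs <- do.call(simulate_growth_series,
                  c(config$growth_simulate, list(seed = seed + 1L)))
    obs <- data.frame(species = "simulated", age_years = gs$obs$age,
                      volume_m3 = gs$obs$volume)
    results$growth_truth <- gs$truth
  }
  if (!is.null(obs)) {
    fit_rows <- list(); proj_rows <- list()
    for (spn in unique(obs$species)) {
      d <- obs[obs$species == spn, ]
      ranking <- select_growth_model(d$age_years, d$volume_m3,
                                     families = families, seed = seed)
      s <- attr(ranking, "summary")
      s <- cbind(species = spn, s)
      fit_rows[[spn]] <- s
      best <- ranking[[1]]
      pr <- project_stock(best$model, horizon)
      proj_rows[[spn]] <- data.frame(
        species = spn, family = best$family, horizon = horizon,
        mean_annual_increase = pr$mean_annual_increase,
        volume_at_horizon = pr$series$volume[horizon])
      results$rankings[[spn]] <- ranking
    }
    p <- file.path(out_dir, "fits.csv")
    utils::write.csv(do.call(rbind, fit_rows), p, row.names = FALSE)
    paths <- c(paths, fits = p)
    p <- file.path(out_dir, "projection.csv")
    utils::write.csv(do.call(rbind, proj_rows), p, row.names = FALSE)
    paths <- c(paths, projection = p)
  }

  ## --- valuation ---
  if (!is.null(config$valuation)) {
    v <- config$valuation
    rep <- tev_report(do.call(land_value, v$land),
                      do.call(tree_value, v$tree),
                      do.call(carbon_fixation_value, v$carbon_fixation),
                      do.call(habitat_value, v$habitat),
                      farm = v$farm %||% NULL)
    tev_df <- data.frame(indicator = names(rep$values),
                         value_wan = unname(rep$values),
                         rounded = unname(rep$rounded))
    p <- file.path(out_dir, "tev.csv")
    utils::write.csv(tev_df, p, row.names = FALSE)
    paths <- c(paths, tev = p)
    results$tev <- rep
  }

  manifest <- list(package = "forestcarbon",
                   version = as.character(utils::packageVersion("forestcarbon")),
                   seed = seed, wt = wt, horizon = horizon,
                   input_md5 = digests,
                   outputs = as.list(paths))
  p <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, p, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  paths <- c(paths, manifest = p)
  results$paths <- paths
  invisible(results)
}

## ---- minimal subcommand CLI -------------------------------------------

cli_flags <- function(args) {
  out <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--")) stopf("unexpected argument '%s'", a)
    key <- gsub("-", "_", substring(a, 3))
    if (i == length(args) || startsWith(args[i + 1L], "--")) {
      out[[key]] <- TRUE; i <- i + 1L
    } else {
      out[[key]] <- args[i + 1L]; i <- i + 2L
    }
  }
  out
}

cli_usage <- function() {
  cat("usage: forestcarbon <simulate|account|fit|project|value|run> [--flag value ...]\n",
      "  simulate --seed S --out-dir DIR [--n-species N]\n",
      "  account  --inventory FILE --out FILE [--registry DIR] [--wt YEARS]\n",
      "  fit      --growth FILE --out FILE [--families f1,f2] [--seed S]\n",
      "  project  --models FILE --out FILE [--horizon YEARS]\n",
      "  value    --config FILE.json --out FILE\n",
      "  run      --config FILE.json\n", sep = "")
}

#' Command-line entry point
#'
#' Dispatches the `simulate`, `account`, `fit`, `project`, `value` and `run`
#' subcommands (see the package vignette for the file schemas). Exposed so
#' the thin installed script `inst/cli/forestcarbon` — and tests — can call
#' it directly.
#'
#' @param args character vector of command-line arguments (defaults to the
#'   process arguments).
#' @return Invisibly, the subcommand's result.
#' @export
fc_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args)) { cli_usage(); return(invisible(NULL)) }
  cmd <- args[1]
  fl <- cli_flags(args[-1])
  reg <- if (!is.null(fl$registry)) load_registry_dir(fl$registry)
         else fc_default_registry()
  res <- switch(cmd,
    simulate = {
      sim <- simulate_farm(n_species = as.integer(fl$n_species %||% 5),
                           seed = as.integer(fl$seed %||% 1))
      dir.create(fl$out_dir, showWarnings = FALSE, recursive = TRUE)
      rec <- sim$inventory$records
      inv_df <- data.frame(farm = sim$inventory$farm, year = sim$inventory$year,
                           species = rec$species,
                           stock_volume_m3 = rec$stock_volume_m3, stems = NA,
                           area_ha = sim$inventory$area_ha,
                           shrub_cover = sim$inventory$shrub_cover,
                           region = sim$inventory$region)
      utils::write.csv(inv_df, file.path(fl$out_dir, "inventory.csv"),
                       row.names = FALSE)
      save_registry(sim$registry, fl$out_dir)
      sim
    },
    account = {
      invs <- read_inventory_csv(fl$inventory)
      wt <- as.numeric(fl$wt %||% reg$constants$wt_horizon)
      df <- breakdowns_to_df(lapply(invs, farm_pool_breakdown,
                                    registry = reg, wt = wt))
      utils::write.csv(df, fl$out, row.names = FALSE)
      df
    },
    fit = {
      obs <- utils::read.csv(fl$growth, stringsAsFactors = FALSE)
      fams <- if (is.null(fl$families)) growth_families()
              else strsplit(fl$families, ",")[[1]]
      seed <- as.integer(fl$seed %||% 1)
      rows <- lapply(unique(obs$species), function(spn) {
        d <- obs[obs$species == spn, ]
        cbind(species = spn,
              attr(select_growth_model(d$age_years, d$volume_m3,
                                       families = fams, seed = seed),
                   "summary"))
      })
      df <- do.call(rbind, rows)
      utils::write.csv(df, fl$out, row.names = FALSE)
      df
    },
    project = {
      models <- utils::read.csv(fl$models, stringsAsFactors = FALSE)
      horizon <- as.numeric(fl$horizon %||% 100)
      df <- do.call(rbind, lapply(seq_len(nrow(models)), function(i) {
        m <- growth_model(models$family[i], models$a[i], models$b[i],
                          if ("c" %in% names(models)) models$c[i] else NA_real_)
        data.frame(species = models$species[i], family = m$family,
                   horizon = horizon,
                   mean_annual_increase =
                     project_stock(m, horizon)$mean_annual_increase)
      }))
      utils::write.csv(df, fl$out, row.names = FALSE)
      df
    },
    value = {
      v <- jsonlite::read_json(fl$config, simplifyVector = TRUE)
      rep <- tev_report(do.call(land_value, v$land),
                        do.call(tree_value, v$tree),
                        do.call(carbon_fixation_value, v$carbon_fixation),
                        do.call(habitat_value, v$habitat),
                        farm = v$farm %||% NULL)
      utils::write.csv(data.frame(indicator = names(rep$values),
                                  value_wan = unname(rep$values),
                                  rounded = unname(rep$rounded)),
                       fl$out, row.names = FALSE)
      rep
    },
    run = run_pipeline(fl$config),
    { cli_usage(); stopf("unknown subcommand '%s'", cmd) })
  invisible(res)
}
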