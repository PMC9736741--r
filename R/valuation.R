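## Total-economic-value (TEV) indicators for a forest farm: land resources
## (annuity capitalization), standing timber (market value), carbon fixation
## (NPP x carbon price) and biological habitat (willingness-to-pay per ha).

#' Economic value of forest land (annuity capitalization)
#'
#' A perpetual annuity of the annual land rent, capitalized at `cap_rate`:
#' value per ha = rent x rent_share / cap_rate. The `rent_share` argument
#' implements the convention that land rent is a share of pure income
#' (published convention: 20%); use `rent_share = 1` for the plain
#' perpetuity.
#'
#' @param area_ha forest land area, ha (> 0).
#' @param annual_rent average annual rent, currency per ha per year (>= 0).
#' @param cap_rate capitalization (benchmark interest) rate, fraction > 0.
#' @param rent_share share of pure income counted as land rent, (0, 1].
#' @return Land value in the rent's currency.
#' @export
#' @examples
#' land_value(1, 417, 0.026)              # full perpetuity per ha
#' land_value(1, 417, 0.026, rent_share = 0.2)
land_value <- function(area_ha, annual_rent, cap_rate, rent_share = 1) {
  assert_scalar(area_ha, "area_ha", 0, strict_lower = TRUE)
  assert_scalar(annual_rent, "annual_rent", 0)
  assert_scalar(cap_rate, "cap_rate", 0, strict_lower = TRUE)
  assert_scalar(rent_share, "rent_share", 0, 1, strict_lower = TRUE)
  area_ha * annual_rent * rent_share / cap_rate
}

#' Market value of standing timber
#'
#' Assumes all standing stock could be logged: sum over species of stock
#' volume x log output rate x log price.
#'
#' @param stock_m3 named numeric vector of stock volumes by species, m3.
#' @param price_per_m3 named numeric vector of log prices by species (or a
#'   single price applied to all).
#' @param output_rate log output rate(s) in \[0, 1\] (scalar or named).
#' @return Timber value in the price's currency.
#' @export
tree_value <- function(stock_m3, price_per_m3, output_rate = 1) {
  if (any(stock_m3 < 0)) stopf("stock_m3 must be >= 0")
  if (length(price_per_m3) > 1 || !is.null(names(price_per_m3))) {
    missing <- setdiff(names(stock_m3), names(price_per_m3))
    if (length(missing))
      stopf("no log price for species: %s", paste(missing, collapse = ", "))
    price_per_m3 <- price_per_m3[names(stock_m3)]
  }
  if (length(output_rate) > 1 || !is.null(names(output_rate))) {
    missing <- setdiff(names(stock_m3), names(output_rate))
    if (length(missing))
      stopf("no output rate for species: %s", paste(missing, collapse = ", "))
    output_rate <- output_rate[names(stock_m3)]
  }
  if (any(output_rate < 0 | output_rate > 1))
    stopf("output_rate must be in [0, 1]")
  sum(stock_m3 * output_rate * price_per_m3)
}

#' Value of forest carbon fixation
#'
#' NPP-based annual fixation value: coefficient x B x A x Pa, where B is net
#' primary productivity (t/ha/yr), A the area (ha) and Pa the carbon trading
#' price. The default coefficient 1.63 x 0.2727 converts NPP to CO2 then to
#' its carbon content.
#'
#' @param npp net primary productivity B, t/ha/yr (>= 0).
#' @param area_ha forest area, ha (>= 0).
#' @param carbon_price carbon trading price Pa, currency per tonne (>= 0).
#' @param coefficient combined conversion coefficient (default 1.63 x 0.2727
#'   = 0.444501).
#' @return Carbon fixation value in the price's currency.
#' @export
#' @examples
#' carbon_fixation_value(10, 100, 50)  # 22225.05
carbon_fixation_value <- function(npp, area_ha, carbon_price,
                                  coefficient = 1.63 * 0.2727) {
  assert_scalar(npp, "npp", 0)
  assert_scalar(area_ha, "area_ha", 0)
  assert_scalar(carbon_price, "carbon_price", 0)
  coefficient * npp * area_ha * carbon_price
}

#' Calibrate the per-hectare habitat constant
#'
#' Fixes the combined habitat willingness-to-pay constant (per ha, in report
#' currency) from one farm whose area and habitat value are known, so the
#' same constant can be applied to other areas. This is the supported
#' reproduction path for published habitat values, whose implied per-ha
#' constant is not recoverable from the stated USD rates.
#'
#' @param ref_area_ha reference farm area, ha (> 0).
#' @param ref_value reference farm habitat value (same unit the result
#'   should be in).
#' @return Habitat constant, currency per ha.
#' @export
#' @examples
#' calibrate_habitat_constant(2074.5, 15.93)
calibrate_habitat_constant <- function(ref_area_ha, ref_value) {
  assert_scalar(ref_area_ha, "ref_area_ha", 0, strict_lower = TRUE)
  assert_scalar(ref_value, "ref_value", 0)
  ref_value / ref_area_ha
}

#' Biological habitat value
#'
#' Area x per-hectare habitat constant. By default the constant is the
#' habitat-loss estimate plus willingness-to-pay, (400 + 112) USD/ha,
#' converted by `exchange_rate`; alternatively pass `constant_per_ha`
#' (e.g. from [calibrate_habitat_constant()]) directly.
#'
#' @param area_ha forest area, ha (>= 0).
#' @param exchange_rate report currency per USD (required unless
#'   `constant_per_ha` is given).
#' @param wtp_usd_per_ha combined USD per-ha constant (default 400 + 112).
#' @param constant_per_ha per-ha constant already in report currency;
#'   overrides the USD route.
#' @return Habitat value in report currency.
#' @export
habitat_value <- function(area_ha, exchange_rate = NULL,
                          wtp_usd_per_ha = 400 + 112,
                          constant_per_ha = NULL) {
  assert_scalar(area_ha, "area_ha", 0)
  if (!is.null(constant_per_ha)) {
    assert_scalar(constant_per_ha, "constant_per_ha", 0)
    return(area_ha * constant_per_ha)
  }
  if (is.null(exchange_rate))
    stopf("either 'exchange_rate' or 'constant_per_ha' must be supplied")
  assert_scalar(exchange_rate, "exchange_rate", 0, strict_lower = TRUE)
  area_ha * wtp_usd_per_ha * exchange_rate
}

#' Assemble a TEV report
#'
#' Collects the four indicator values (already in CNY 10,000) into a report
#' with their total. Values are rounded half-up to `digits` decimals at the
#' presentation layer only; the full-precision values are retained.
#'
#' @param land,tree,carbon_fixation,habitat indicator values, CNY 10,000
#'   (>= 0).
#' @param farm optional farm label.
#' @param digits decimals for the printed report (default 2).
#' @return Object of class `tev_report`: list with `values` (named, full
#'   precision), `total`, `rounded`, `farm`, `digits`.
#' @export
tev_report <- function(land, tree, carbon_fixation, habitat, farm = NULL,
                       digits = 2) {
  vals <- c(land = land, tree = tree, carbon_fixation = carbon_fixation,
            habitat = habitat)
  if (any(vals < 0)) stopf("all TEV indicators must be >= 0")
  vals <- c(vals, total = sum(vals))
  structure(list(values = vals, total = vals[["total"]],
                 rounded = round_half_up(vals, digits),
                 farm = farm, digits = digits),
            class = "tev_report")
}

#' @export
print.tev_report <- function(x, ...) {
  cat(sprintf("<tev_report>%s (CNY 10,000)\n",
              if (is.null(x$farm)) "" else paste0(" ", x$farm)))
  for (nm in names(x$rounded))
    cat(sprintf("  %-16s %12.*f\n", nm, x$digits, x$rounded[[nm]]))
  invisible(x)
}
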