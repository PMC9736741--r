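## Stand growth: five sigmoid age-volume families, nonlinear least-squares
## fitting with seeded multi-start, R^2/SSE scoring, model ranking and
## century-scale stock projection.

#' Growth model families
#' @return Character vector of the five supported family names.
#' @export
growth_families <- function() {
  c("logistic", "richards", "korf", "gompertz", "mitscherlich")
}

.needs_c <- c(logistic = TRUE, richards = TRUE, korf = TRUE, gompertz = TRUE,
              mitscherlich = FALSE)

#' Construct a growth model
#'
#' Parameterizations (y = volume, A = age in years; a is the asymptote):
#' \describe{
#'   \item{logistic}{a / (1 + b exp(-c A))}
#'   \item{richards}{a (1 - exp(-b A))^c}
#'   \item{korf}{a exp(-b A^(-c)) (upper limit a as A grows; 0 at A = 0)}
#'   \item{gompertz}{a exp(-b exp(-c A))}
#'   \item{mitscherlich}{a (1 - exp(-b A)); the two-parameter form, c unused}
#' }
#'
#' @param family one of [growth_families()].
#' @param a asymptote parameter (> 0).
#' @param b shape/rate parameter (>= 0; strictly positive for fitting).
#' @param c rate parameter (> 0) where the family uses it.
#' @return Object of class `growth_model`.
#' @export
#' @examples
#' m <- growth_model("gompertz", a = 1.54, b = 8.434, c = 0.034)
#' predict(m, age = c(20, 50, 100))
growth_model <- function(family, a, b, c = NA_real_) {
  family <- match.arg(family, growth_families())
  assert_scalar(a, "a", 0, strict_lower = TRUE)
  assert_scalar(b, "b", 0)
  if (.needs_c[[family]]) {
    assert_scalar(c, "c", 0, strict_lower = TRUE)
  } else {
    c <- NA_real_
  }
  structure(list(family = family, a = a, b = b, c = c),
            class = "growth_model")
}

#' @export
print.growth_model <- function(x, ...) {
  cat(sprintf("<growth_model> %s: a=%g b=%g%s\n", x$family, x$a, x$b,
              if (is.na(x$c)) "" else sprintf(" c=%g", x$c)))
  invisible(x)
}

eval_growth <- function(family, a, b, c, age) {
  switch(family,
    logistic = a / (1 + b * exp(-c * age)),
    richards = a * (1 - exp(-b * age))^c,
    korf = ifelse(age <= 0, 0, a * exp(-b * age^(-c))),
    gompertz = a * exp(-b * exp(-c * age)),
    mitscherlich = a * (1 - exp(-b * age)))
}

#' Evaluate a growth model at given ages
#'
#' @param object a `growth_model`.
#' @param age numeric vector of ages in years (>= 0).
#' @param ... unused.
#' @return Predicted volumes, same length as `age`.
#' @export
predict.growth_model <- function(object, age, ...) {
  if (any(age < 0)) stopf("age must be >= 0")
  eval_growth(object$family, object$a, object$b, object$c, age)
}

#' Goodness of fit of a growth model
#'
#' R^2 = 1 - SSE/SST with SST taken about the observation mean, and
#' SSE = sum((y - yhat)^2). Constant observations make SST zero and R^2
#' undefined (`NA`), unless SSE is also ~0, in which case R^2 = 1.
#'
#' @param age,volume observation vectors (same length, >= 1 point).
#' @param model a `growth_model`.
#' @return List with `r2`, `sse`, `sst`.
#' @export
goodness_of_fit <- function(age, volume, model) {
  if (length(age) != length(volume) || length(age) < 1)
    stopf("age and volume must be equal-length vectors with >= 1 point")
  yhat <- predict(model, age)
  sse <- sum((volume - yhat)^2)
  sst <- sum((volume - mean(volume))^2)
  r2 <- if (sst > 0) 1 - sse / sst else if (sse <= 1e-12) 1 else NA_real_
  list(r2 = r2, sse = sse, sst = sst)
}

## SSE objective over log-parameters (positivity by construction)
fit_objective <- function(family, age, volume) {
  np <- if (.needs_c[[family]]) 3L else 2L
  function(theta) {
    p <- exp(theta)
    yhat <- eval_growth(family, p[1], p[2], if (np == 3L) p[3] else NA_real_,
                        age)
    if (any(!is.finite(yhat))) return(1e300)
    sum((volume - yhat)^2)
  }
}

## data-driven starting values on the log scale
fit_start <- function(family, age, volume) {
  a0 <- 1.2 * max(volume)
  if (a0 <= 0) a0 <- 1
  y <- pmin(pmax(volume, 1e-8 * a0), a0 * (1 - 1e-6))
  slope_fit <- function(x, z) tryCatch(stats::coef(stats::lm(z ~ x)),
                                       error = function(e) c(0, -0.05))
  safe <- function(x, lo, hi) min(max(x, lo), hi)
  th <- switch(family,
    gompertz = {
      cf <- slope_fit(age, log(log(a0 / y)))
      c(log(a0), safe(cf[1], -5, 8), log(safe(-cf[2], 1e-4, 2)))
    },
    logistic = {
      cf <- slope_fit(age, log(a0 / y - 1))
      c(log(a0), safe(cf[1], -5, 12), log(safe(-cf[2], 1e-4, 2)))
    },
    korf = {
      cf <- slope_fit(log(pmax(age, 1e-6)), log(log(a0 / y)))
      c(log(a0), safe(cf[1], -5, 8), log(safe(cf[2], 1e-3, 3)))
    },
    richards = {
      cf <- slope_fit(age, log(pmax(1 - y / a0, 1e-8)))
      c(log(a0), log(safe(-cf[2], 1e-4, 1)), log(1))
    },
    mitscherlich = {
      cf <- slope_fit(age, log(pmax(1 - y / a0, 1e-8)))
      c(log(a0), log(safe(-cf[2], 1e-4, 1)))
    })
  as.numeric(th)
}

#' Fit one growth-model family by nonlinear least squares
#'
#' Minimizes the sum of squared residuals over log-parameters (which enforces
#' positivity) with `stats::nlminb`, restarted from `n_starts` seeded
#' perturbations of a data-driven initial guess; the best local optimum is
#' returned. Non-convergence is reported in the `converged` flag, never as an
#' error.
#'
#' @param age,volume observation vectors; >= 4 points, ages not all equal.
#' @param family one of [growth_families()].
#' @param n_starts number of multi-start initializations (default 20).
#' @param seed integer seed controlling the random restarts (`NULL` leaves
#'   the RNG state alone).
#' @return Object of class `growth_fit`: list with `model` (a
#'   `growth_model`), `r2`, `sse`, `n_obs`, `converged`, `seed`.
#' @export
fit_growth_model <- function(age, volume, family, n_starts = 20, seed = NULL) {
  family <- match.arg(family, growth_families())
  if (length(age) != length(volume)) stopf("age and volume lengths differ")
  if (length(age) < 4) stopf("need at least 4 observations to fit")
  if (length(unique(age)) < 2) stopf("ages must not all be equal")
  if (!is.null(seed)) set.seed(seed)
  obj <- fit_objective(family, age, volume)
  th0 <- fit_start(family, age, volume)
  np <- length(th0)
  best <- NULL; best_conv <- NULL
  for (s in seq_len(n_starts)) {
    th <- if (s == 1) th0 else th0 + stats::rnorm(np, sd = 0.6)
    res <- tryCatch(
      stats::nlminb(th, obj, control = list(eval.max = 2000, iter.max = 1000,
                                            rel.tol = 1e-14)),
      error = function(e) NULL)
    if (is.null(res) || !is.finite(res$objective)) next
    if (is.null(best) || res$objective < best$objective) best <- res
    if (res$convergence == 0 &&
        (is.null(best_conv) || res$objective < best_conv$objective))
      best_conv <- res
  }
  # prefer a cleanly converged optimum when it is essentially as good as the
  # overall best (restarts ending in "false convergence" can undercut it by
  # a numerically irrelevant margin)
  if (!is.null(best_conv) &&
      best_conv$objective <= best$objective * (1 + 1e-6) + 1e-12)
    best <- best_conv
  if (is.null(best)) {
    return(structure(list(model = NULL, r2 = NA_real_, sse = NA_real_,
                          n_obs = length(age), converged = FALSE,
                          family = family, seed = seed),
                     class = "growth_fit"))
  }
  p <- exp(best$par)
  model <- growth_model(family, a = p[1], b = p[2],
                        c = if (np == 3L) p[3] else NA_real_)
  gof <- goodness_of_fit(age, volume, model)
  structure(list(model = model, r2 = gof$r2, sse = gof$sse,
                 n_obs = length(age), converged = best$convergence == 0,
                 family = family, seed = seed),
            class = "growth_fit")
}

#' @export
print.growth_fit <- function(x, ...) {
  if (is.null(x$model)) {
    cat(sprintf("<growth_fit> %s: did not converge\n", x$family))
  } else {
    cat(sprintf("<growth_fit> %s: a=%.6g b=%.6g%s  R2=%.4f SSE=%.4g (n=%d%s)\n",
                x$family, x$model$a, x$model$b,
                if (is.na(x$model$c)) "" else sprintf(" c=%.6g", x$model$c),
                x$r2, x$sse, x$n_obs,
                if (x$converged) "" else ", not converged"))
  }
  invisible(x)
}

#' Fit and rank several growth-model families
#'
#' Fits each requested family with [fit_growth_model()] and ranks the results
#' by R^2 (descending); fits whose R^2 differ by less than 1e-6 are ordered
#' by lower SSE, and non-converged or failed fits rank last. Deterministic
#' for a given seed: family `i` is fitted with sub-seed `seed + i`.
#'
#' @param age,volume observation vectors.
#' @param families character vector of >= 1 family names (default all five).
#' @param seed integer seed (`NULL` for current RNG state).
#' @param n_starts multi-start count per family.
#' @return List of `growth_fit` objects in rank order, with a `summary`
#'   attribute data.frame (family, a, b, c, r2, sse, converged, rank).
#' @export
select_growth_model <- function(age, volume, families = growth_families(),
                                seed = NULL, n_starts = 20) {
  if (length(families) < 1) stopf("at least one family must be requested")
  fits <- lapply(seq_along(families), function(i) {
    fit_growth_model(age, volume, families[i], n_starts = n_starts,
                     seed = if (is.null(seed)) NULL else seed + i)
  })
  ok <- vapply(fits, function(f) f$converged && !is.null(f$model), logical(1))
  r2 <- vapply(fits, function(f) if (is.na(f$r2)) -Inf else f$r2, numeric(1))
  sse <- vapply(fits, function(f) if (is.na(f$sse)) Inf else f$sse, numeric(1))
  # quantize r2 so near-ties (< 1e-6) fall through to the SSE key
  ord <- order(!ok, -floor(r2 / 1e-6), sse)
  fits <- fits[ord]
  if (!any(ok)) stopf("no growth-model family could be fitted")
  summ <- do.call(rbind, lapply(seq_along(fits), function(i) {
    f <- fits[[i]]
    data.frame(rank = i, family = f$family,
               a = if (is.null(f$model)) NA_real_ else f$model$a,
               b = if (is.null(f$model)) NA_real_ else f$model$b,
               c = if (is.null(f$model)) NA_real_ else f$model$c,
               r2 = f$r2, sse = f$sse, converged = f$converged)
  }))
  attr(fits, "summary") <- summ
  class(fits) <- "growth_ranking"
  fits
}

#' @export
print.growth_ranking <- function(x, ...) {
  print(attr(x, "summary"), row.names = FALSE)
  invisible(x)
}

#' Project stock volume over a horizon
#'
#' Evaluates the model yearly over `1..horizon`, reports annual increments
#' and the mean annual increase (V(horizon) - V(0)) / horizon.
#'
#' @param model a `growth_model`.
#' @param horizon projection horizon in years (>= 1; default 100).
#' @return List with `series` (data.frame year, volume, increment) and
#'   `mean_annual_increase`.
#' @export
#' @examples
#' m <- growth_model("gompertz", 1.54, 8.434, 0.034)
#' project_stock(m, 100)$mean_annual_increase
project_stock <- function(model, horizon = 100) {
  assert_scalar(horizon, "horizon", 1)
  horizon <- as.integer(horizon)
  v <- predict(model, 0:horizon)
  series <- data.frame(year = 1:horizon, volume = v[-1], increment = diff(v))
  list(series = series,
       mean_annual_increase = (v[horizon + 1] - v[1]) / horizon)
}

#' Predict whole-farm stock growth from per-species rates
#'
#' Sum over species of (mean annual per-area increase) x (species area) x
#' (number of years).
#'
#' @param increase named numeric vector: mean annual stock increase per unit
#'   area, m3/ha/yr, by species.
#' @param areas named numeric vector of species areas, ha.
#' @param years projection length in years.
#' @return Total predicted stock growth, m3.
#' @export
predict_farm_growth <- function(increase, areas, years = 100) {
  missing <- setdiff(names(increase), names(areas))
  if (length(missing))
    stopf("no area given for species: %s", paste(missing, collapse = ", "))
  sum(increase * areas[names(increase)] * years)
}

#' Packaged best-growth-model registry
#'
#' The published per-species optimal growth curves for the study farms'
#' dominant species (all Gompertz), as a data.frame.
#'
#' @return data.frame with columns species, family, a, b, c.
#' @export
default_growth_registry <- function() {
  utils::read.csv(fc_extdata("growth_models_table.csv"),
                  stringsAsFactors = FALSE)
}

#' Growth model for a species from a registry table
#'
#' @param species species name (normalized match).
#' @param registry data.frame as from [default_growth_registry()].
#' @return A `growth_model`.
#' @export
growth_model_for_species <- function(species,
                                     registry = default_growth_registry()) {
  i <- match(norm_key(species), norm_key(registry$species))
  if (is.na(i))
    stopf("no growth model registered for species '%s'", species)
  growth_model(registry$family[i], registry$a[i], registry$b[i],
               registry$c[i])
}
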