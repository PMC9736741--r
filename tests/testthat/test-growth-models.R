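test_that("family formulas evaluate exactly", {
  g <- growth_model("gompertz", 1.54, 8.434, 0.034)
  expect_equal(predict(g, 1e6), 1.54)             # asymptote
  g2 <- growth_model("gompertz", 2.81, 6.434, 0.124)
  expect_equal(predict(g2, 0), 2.81 * exp(-6.434))
  # degenerate logistic with b = 0 is flat at a
  l <- growth_model("logistic", a = 3, b = 0, c = 1)
  expect_equal(predict(l, c(0, 10, 200)), rep(3, 3))
  r <- growth_model("richards", 2, 0.05, 3)
  expect_equal(predict(r, 10), 2 * (1 - exp(-0.5))^3)
  k <- growth_model("korf", 2, 5, 0.5)
  expect_equal(predict(k, 4), 2 * exp(-5 * 4^-0.5))
  expect_identical(predict(k, 0), 0)              # documented limit at age 0
  m <- growth_model("mitscherlich", 2, 0.1)
  expect_equal(predict(m, 10), 2 * (1 - exp(-1)))
  expect_error(growth_model("gompertz", -1, 1, 1), "'a'")
  expect_error(growth_model("gompertz", 1, 1, -1), "'c'")
  expect_error(predict(g, -3), "age")
})

test_that("all families are non-decreasing and bounded by the asymptote", {
  ages <- seq(0, 300, by = 3)
  specs <- list(growth_model("logistic", 2, 5, 0.1),
                growth_model("richards", 2, 0.05, 2),
                growth_model("korf", 2, 8, 0.7),
                growth_model("gompertz", 2, 6, 0.08),
                growth_model("mitscherlich", 2, 0.04))
  for (m in specs) {
    v <- predict(m, ages)
    expect_true(all(diff(v) >= 0), info = m$family)
    expect_true(all(v <= 2 + 1e-12), info = m$family)
  }
})

test_that("goodness_of_fit matches brute-force sums", {
  g <- growth_model("gompertz", 2, 6, 0.1)
  age <- c(5, 20, 60); y <- predict(g, age)
  gof <- goodness_of_fit(age, y, g)
  expect_equal(gof$r2, 1)
  expect_equal(gof$sse, 0)
  # hand-computed 3-point case
  y2 <- y + c(0.1, -0.2, 0.05)
  gof <- goodness_of_fit(age, y2, g)
  sse <- sum((y2 - y)^2)
  sst <- sum((y2 - mean(y2))^2)
  expect_equal(gof$sse, sse)
  expect_equal(gof$r2, 1 - sse / sst)
  # predicting the mean exactly gives r2 = 0
  flat <- growth_model("logistic", a = mean(y2), b = 0, c = 1)
  expect_equal(goodness_of_fit(age, y2, flat)$r2, 0)
  # constant observations: SST = 0 -> undefined marker
  expect_true(is.na(goodness_of_fit(age, rep(1, 3), g)$r2))
  # algebraic identity r2 = 1 - sse/sst on random inputs
  set.seed(7)
  for (i in 1:10) {
    yy <- runif(8, 0.1, 3); aa <- sort(runif(8, 1, 90))
    gof <- goodness_of_fit(aa, yy, g)
    expect_equal(gof$r2, 1 - gof$sse / gof$sst)
    expect_lte(gof$r2, 1)
  }
})

test_that("fitting recovers noiseless parameters and tolerates degeneracy", {
  sim <- simulate_growth_series(params = c(a = 1.54, b = 8.434, c = 0.034),
                                noise_sd = 0, seed = 3)
  f <- fit_growth_model(sim$obs$age, sim$obs$volume, "gompertz", seed = 5)
  expect_true(f$converged)
  got <- c(f$model$a, f$model$b, f$model$c)
  expect_lt(max(abs(got / c(1.54, 8.434, 0.034) - 1)), 1e-4)
  expect_gte(f$r2, 0.9999)
  expect_true(f$r2 <= 1)
  # r2 = 1 iff sse = 0 (within tolerance)
  expect_lt(f$sse, 1e-10)

  # constant-volume data is reported (undefined/<=0 r2), never an exception
  fc <- fit_growth_model(c(1, 10, 20, 40), rep(2, 4), "gompertz", seed = 1)
  expect_true(is.na(fc$r2) || fc$r2 <= 0)

  # fit is invariant to observation order
  set.seed(9); perm <- sample(nrow(sim$obs))
  f2 <- fit_growth_model(sim$obs$age[perm], sim$obs$volume[perm], "gompertz",
                         seed = 5)
  expect_equal(c(f2$model$a, f2$model$b, f2$model$c), got, tolerance = 1e-8)

  expect_error(fit_growth_model(1:3, 1:3, "gompertz"), "at least 4")
  expect_error(fit_growth_model(rep(5, 6), 1:6, "gompertz"), "ages")
})

test_that("select_growth_model ranks deterministically by r2 then sse", {
  sim <- simulate_growth_series(noise_sd = 0.02, seed = 21)
  rk <- select_growth_model(sim$obs$age, sim$obs$volume, seed = 100)
  s <- attr(rk, "summary")
  expect_setequal(s$family, growth_families())
  conv <- s[s$converged, ]
  expect_true(all(diff(conv$r2) <= 1e-6))  # non-increasing up to tie tol
  # deterministic given a seed
  rk2 <- select_growth_model(sim$obs$age, sim$obs$volume, seed = 100)
  expect_identical(attr(rk2, "summary"), s)
  # single family passes through as rank 1
  rk1 <- select_growth_model(sim$obs$age, sim$obs$volume,
                             families = "gompertz", seed = 1)
  expect_equal(attr(rk1, "summary")$family, "gompertz")
  # duplicate families get a stable deterministic order
  rkd <- select_growth_model(sim$obs$age, sim$obs$volume,
                             families = c("gompertz", "gompertz"), seed = 1)
  expect_equal(nrow(attr(rkd, "summary")), 2L)
})

test_that("projection yields monotone series and the right mean increase", {
  m <- growth_model("gompertz", 1.54, 8.434, 0.034)
  pr <- project_stock(m, 100)
  expect_true(all(pr$series$increment >= 0))
  expect_equal(pr$mean_annual_increase,
               (predict(m, 100) - predict(m, 0)) / 100)
  expect_equal(round(pr$mean_annual_increase, 5), 0.01162)
  pr1 <- project_stock(m, 1)
  expect_equal(pr1$mean_annual_increase, predict(m, 1) - predict(m, 0))
})

test_that("farm growth prediction sums increase x area x years", {
  expect_identical(predict_farm_growth(c(a = 0, b = 0), c(a = 1, b = 2), 100),
                   0)
  # the published eucalyptus per-area rate as a direct product
  expect_equal(predict_farm_growth(c(eucalyptus = 2.2713),
                                   c(eucalyptus = 10), 10), 227.13)
  inc <- c(x = 1.5, y = 0.7); ar <- c(x = 3, y = 11)
  expect_equal(predict_farm_growth(inc, ar, 10),
               predict_farm_growth(inc["x"], ar, 10) +
                 predict_farm_growth(inc["y"], ar, 10))
  expect_error(predict_farm_growth(c(z = 1), c(x = 1)), "z")
})

test_that("the packaged growth registry mirrors the published best models", {
  reg <- default_growth_registry()
  expect_equal(nrow(reg), 8L)
  expect_true(all(reg$family == "gompertz"))
  m <- growth_model_for_species("Needle leaf mix")
  expect_equal(c(m$a, m$b, m$c), c(1.54, 8.434, 0.034))
  expect_error(growth_model_for_species("ghost"), "ghost")
})
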