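test_that("RK4 solver matches exact limits of the population law", {
  # p2 = 0: N = p1 t to machine precision
  sol <- simulatePopulation(50, 0, 8, 14, dt_day = 0.01)
  expect_equal(sol$N, 50 * sol$t_day, tolerance = 1e-12)
  # ts -> 0: constant-coefficient closed form (p1/p2)(1 - exp(-p2 t))
  sol <- simulatePopulation(50, 1.5, 1e-9, 14, dt_day = 1e-3)
  cf <- 50 / 1.5 * (1 - exp(-1.5 * sol$t_day))
  expect_lt(max(abs(sol$N - cf)), 1e-4 * 50 / 1.5)
})

test_that("RK4 matches the imaginary-error-function closed form", {
  # the ramped ODE has an exact solution via erfi on t <= ts and a
  # constant-coefficient relaxation beyond: an independent oracle
  tt <- seq(0, 14, by = 0.25)
  for (p in list(c(50, 1.5, 8), c(20, 0.8, 3), c(120, 3, 12))) {
    rk <- simulatePopulation(p[1], p[2], p[3], 14, dt_day = 1e-3,
                             times_day = tt)$N
    cf <- populationClosedForm(tt, p[1], p[2], p[3])
    expect_lt(max(abs(rk - cf)) / max(cf), 1e-8)
  }
})

test_that("halving the RK4 step changes the trajectory at fourth order", {
  tt <- 0:14
  n1 <- simulatePopulation(50, 1.5, 8, 14, dt_day = 0.02, times_day = tt)$N
  n2 <- simulatePopulation(50, 1.5, 8, 14, dt_day = 0.01, times_day = tt)$N
  nref <- simulatePopulation(50, 1.5, 8, 14, dt_day = 1e-4,
                             times_day = tt)$N
  e1 <- max(abs(n1 - nref)); e2 <- max(abs(n2 - nref))
  expect_lt(e2, e1 / 8)   # >= 3rd-order contraction allowing ramp kink
})

test_that("the solution stays nonnegative for positive parameters", {
  set.seed(3)
  for (i in 1:20) {
    p1 <- runif(1, 1, 200); p2 <- runif(1, 0.1, 5); ts <- runif(1, 0.5, 20)
    sol <- simulatePopulation(p1, p2, ts, 30, dt_day = 0.01)
    expect_true(all(sol$N >= 0))
  }
})

test_that("onset alignment shifts each condition to its first count", {
  hd <- simulateCountSeries(noise = "none", condition = "HD")
  ld <- simulateCountSeries(noise = "none", onsetDelay_day = 3,
                            condition = "LD")
  out <- alignOnsets(list(hd, ld))
  # HD counts from day 0: shift 0; LD zero until day 3: shift 3
  expect_equal(out[[1]]@onsetDay, 0)
  expect_equal(out[[2]]@onsetDay, 3)
  # after alignment both conditions superpose on the master curve
  d1 <- seriesData(out[[1]]); d2 <- seriesData(out[[2]])
  common <- intersect(d1$t_day, d2$t_day)
  expect_equal(d1$N[match(common, d1$t_day)],
               d2$N[match(common, d2$t_day)], tolerance = 1e-10)
  # idempotent: aligning again changes nothing
  out2 <- alignOnsets(out)
  expect_equal(seriesData(out2[[2]]), seriesData(out[[2]]))
  expect_warning(alignOnsets(new("CountSeries",
                                 data = data.frame(t_day = 0:5, N = 0,
                                                   condition = "dead"))),
                 "excluded")
})

test_that("noiseless population fit recovers (p1, p2, ts) within 1%", {
  cs <- simulateCountSeries(p1 = 50, p2 = 1.5, ts_day = 8, noise = "none")
  fit <- fitPopulation(cs, nBoot = 0)
  expect_equal(fit@p1, 50, tolerance = 0.01)
  expect_equal(fit@p2, 1.5, tolerance = 0.01)
  expect_equal(fit@ts_day, 8, tolerance = 0.01)
  expect_equal(fit@plateau, fit@p1 / fit@p2)
})

test_that("poisson-noised master-curve fits recover the parameters", {
  errs <- vapply(1:5, function(s) {
    series <- lapply(1:3, function(i)
      simulateCountSeries(noise = "poisson", seed = s * 10 + i,
                          condition = paste0("rep", i)))
    fit <- fitPopulation(series, nBoot = 0)
    max(abs(coef(fit) / c(50, 1.5, 8) - 1))
  }, numeric(1))
  expect_lt(median(errs), 0.15)
})

test_that("the fitted dynamics produce one interior maximum", {
  cs <- simulateCountSeries(noise = "poisson", seed = 21)
  fit <- fitPopulation(cs, nBoot = 0)
  sol <- simulatePopulation(fit@p1, fit@p2, fit@ts_day, 30, dt_day = 0.01)
  imax <- which.max(sol$N)
  expect_gt(imax, 1); expect_lt(imax, nrow(sol))
  expect_gt(max(sol$N), fit@plateau)
})
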