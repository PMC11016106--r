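test_that("allometric conversion and carbon fraction are exact", {
  expect_equal(bgb_allometric(0), 0)
  expect_equal(bgb_allometric(1), 0.489)
  expect_equal(agb_to_carbon(0), 0)
  expect_equal(agb_to_carbon(1), 0.5 * (1 + 0.489))       # 0.7445
  expect_equal(agb_to_carbon(1, per_km2 = TRUE), 74.45)
  expect_equal(agb_to_carbon(100), 0.5 * (100 + 0.489 * 100^0.89))
  expect_error(agb_to_carbon(-2), "non-negative")
})

test_that("carbon_to_agb inverts agb_to_carbon to near machine precision", {
  agb <- c(0, 0.3, 1, 17, 120, 450)
  expect_equal(carbon_to_agb(agb_to_carbon(agb)), agb, tolerance = 1e-10)
  rho <- c(0, 5, 74.45, 30000)
  expect_equal(agb_to_carbon(carbon_to_agb(rho, TRUE), TRUE), rho,
               tolerance = 1e-10)
})

test_that("growth calibration recovers trivial block configurations", {
  # uniform block at steady state: coarse equals the block mean -> A = 1
  fine <- matrix(80, 8, 8)
  m <- calibrate_growth(fine, matrix(80, 2, 2), V = 200, factor = 4)
  expect_equal(m$A1, matrix(1, 2, 2))
  expect_equal(m$A2, matrix(1, 2, 2), tolerance = 1e-12)
  # coarse = 2 x block mean -> first-order A = 2
  m2 <- calibrate_growth(fine, matrix(160, 2, 2), V = 200, factor = 4)
  expect_equal(m2$A1, matrix(2, 2, 2))
  # all-zero block flagged undefined
  fine0 <- fine; fine0[1:4, 1:4] <- 0
  m3 <- calibrate_growth(fine0, block_average(fine0, 4), V = 200, factor = 4)
  expect_true(m3$undefined[1, 1])
  expect_false(m3$undefined[2, 2])
  # default carrying capacity is the max block mean
  m4 <- calibrate_growth(fine, matrix(90, 2, 2), factor = 4)
  expect_equal(m4$V, 80)
})

test_that("second-order factor beats first order on forward-simulated blocks", {
  withr::with_seed(99, {
    n_better <- 0; n_blocks <- 60
    for (b in seq_len(n_blocks)) {
      V <- 20000
      Atrue <- exp(runif(1, log(1.02), log(1.3)))
      rho0 <- matrix(runif(64, 0.05 * V, 0.5 * V), 8, 8)
      rho8 <- simulate_logistic_growth(rho0, log(Atrue) / (V * 8), V, 8)
      m <- calibrate_growth(rho0, matrix(mean(rho8), 1, 1), V = V, factor = 8)
      if (abs(m$A2 - Atrue) < abs(m$A1 - Atrue)) n_better <- n_better + 1
    }
    expect_gte(n_better / n_blocks, 0.9)
  })
})

test_that("M1 is constant in time and errors on nodata", {
  fine <- matrix(runif(64, 10, 100), 8, 8)
  fine[3, 3] <- NA
  m <- calibrate_growth(fine, block_average(fine, 4), V = 200, factor = 4)
  expect_equal(density_m1(m, c(2, 5)), fine[2, 5])
  expect_equal(density_m1(m), fine)
  expect_error(density_m1(m, c(3, 3)), "nodata")
})

test_that("M2 reduces to M1 in the no-growth limits and matches closed form", {
  fine <- matrix(50, 8, 8)
  V <- 100
  m <- carbon_density_model(fine, A = 3, V = V, factor = 4)
  # dt = 0 identity
  expect_equal(density_m2(m, 2000, c(1, 1)), 50)
  # dt = 8: the 8-yr factor applied directly: 3*50*100/(2*50+100) = 75
  expect_equal(density_m2(m, 2008, c(1, 1)), 75, tolerance = 1e-12)
  # matches the generator's closed form at fractional horizons too
  expect_equal(density_m2(m, 2003, c(2, 2)),
               simulate_logistic_growth(50, log(3) / (V * 8), V, 3),
               tolerance = 1e-12)
  # A = 1 leaves density unchanged at any year
  m1 <- carbon_density_model(fine, A = 1, V = V, factor = 4)
  expect_equal(density_m2(m1, 2015, c(4, 4)), 50, tolerance = 1e-12)
  expect_equal(density_m2(m1, 2019), fine, tolerance = 1e-12)
})

test_that("M2 satisfies the logistic semigroup property", {
  withr::with_seed(3, {
    for (k in 1:20) {
      rho0 <- runif(1, 1, 180)
      A8 <- runif(1, 0.7, 3)          # declines allowed
      V <- 200
      m <- carbon_density_model(matrix(rho0, 4, 4), A8, V, factor = 4)
      dt1 <- runif(1, 0, 10); dt2 <- runif(1, 0, 9)
      one <- density_m2(m, 2000 + dt1 + dt2, c(1, 1))
      mid <- density_m2(m, 2000 + dt1, c(1, 1))
      m2 <- carbon_density_model(matrix(mid, 4, 4), A8, V, factor = 4)
      two <- density_m2(m2, 2000 + dt2, c(1, 1))
      expect_equal(two, one, tolerance = 1e-9)
    }
  })
})

test_that("M2 is increasing in time and bounded by V when A > 1", {
  V <- 100
  m <- carbon_density_model(matrix(40, 4, 4), A = 2, V = V, factor = 4)
  dts <- seq(0, 40, by = 2)
  vals <- vapply(dts, function(d) density_m2(m, 2000 + d, c(1, 1)), 0)
  expect_true(all(diff(vals) > 0))
  expect_true(all(vals <= V))
  # zero-density pixels stay at zero (logistic fixed point)
  fine0 <- matrix(40, 4, 4); fine0[2, 2] <- 0
  m0 <- carbon_density_model(fine0, A = 2, V = V, factor = 4)
  expect_equal(density_m2(m0, 2015, c(2, 2)), 0)
})

test_that("M3/M4 spatial means match brute force and aggregation identity", {
  expect_equal(density_m3(matrix(7, 5, 5)), 7)
  fine <- matrix(runif(16, 0, 100), 4, 4)
  expect_equal(density_m3(fine), sum(fine) / 16)
  roi <- matrix(FALSE, 4, 4); roi[1:2, 1:2] <- TRUE
  expect_equal(density_m3(fine, roi), mean(fine[1:2, 1:2]))
  expect_error(density_m3(fine, matrix(FALSE, 4, 4)), "no valid pixel")
  # coarse = exact block means -> identical ROI means
  coarse <- block_average(fine, 2)
  expect_equal(density_m4(coarse), density_m3(fine), tolerance = 1e-12)
})
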