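test_that("Bernoulli and pixel variances follow the closed forms", {
  expect_equal(bernoulli_variance(0), 0)
  expect_equal(bernoulli_variance(1), 0)
  expect_equal(bernoulli_variance(0.5), 0.25)
  expect_error(bernoulli_variance(1.2), "\\[0,1\\]")
  expect_equal(pixel_ece_variance(1, 0.5, 10, 2), 27)   # 0.5*(4 + 0.5*100)
  expect_equal(pixel_ece_variance(1, 1, 10, 0), 0)
  expect_equal(pixel_ece_variance(1, 0, 10, 5), 0)
  expect_error(pixel_ece_variance(-1, 0.5, 1, 1), ">= 0")
})

test_that("pixel variance equals the Goodman product identity algebraically", {
  withr::with_seed(8, {
    for (k in 1:50) {
      A <- runif(1, 0.1, 10); p <- runif(1)
      rho <- runif(1, 0, 100); s <- runif(1, 0, 50)
      # Var(XY) = E[X]^2 Var(Y) + E[Y]^2 Var(X) + Var(X) Var(Y)
      # with X ~ Bernoulli(p) scaled by A, Y mean rho, SD s
      vx <- p * (1 - p)
      goodman <- A^2 * (p^2 * s^2 + rho^2 * vx + vx * s^2)
      expect_equal(pixel_ece_variance(A, p, rho, s), goodman,
                   tolerance = 1e-12)
    }
  })
})

test_that("sigma_rho honors the per-method conventions", {
  cfg12 <- uncertainty_config("M1", cv = 0.5)
  expect_equal(sigma_rho(cfg12, rho = matrix(10, 2, 2)), matrix(5, 2, 2))
  expect_equal(sigma_rho(uncertainty_config("M2", cv = 1), rho = 7), 7)
  cfg3 <- uncertainty_config("M3")
  expect_equal(unname(sigma_rho(cfg3, rho = matrix(0, 2, 2),
                                roi_sample = c(2, 4, 6))[1, 1]),
               sd(c(2, 4, 6)))
  # uniform ROI -> zero spread
  expect_equal(sigma_rho(cfg3, roi_sample = rep(5, 10)), 0)
  expect_warning(uncertainty_config("M3", cv = 0.5), "ignored")
  # M3/M4 are forced to ROI scale
  expect_equal(uncertainty_config("M4", als = "block_500m")$als, "roi_scale")
})

test_that("block aggregation implements both correlation bounds", {
  # single-pixel blocks: both modes return the pixel variance
  sd1 <- matrix(c(2, 3), 1, 2)
  blocks <- matrix(c(1L, 2L), 1, 2)
  expect_equal(unname(block_aggregate(sd1, blocks, "sum_sd")), c(4, 9))
  expect_equal(unname(block_aggregate(sd1, blocks, "supremum")), c(4, 9))
  # two identical pixels, SD s: perfectly correlated -> (2s)^2
  sd2 <- matrix(c(3, 3), 1, 2)
  one <- matrix(1L, 1, 2)
  expect_equal(unname(block_aggregate(sd2, one, "sum_sd")), 36)
  # heterogeneous block: supremum >= sum_sd, verified by enumeration
  sd3 <- matrix(c(1, 2, 5), 1, 3)
  b3 <- matrix(1L, 1, 3)
  v_sum <- unname(block_aggregate(sd3, b3, "sum_sd"))      # (1+2+5)^2 = 64
  v_sup <- unname(block_aggregate(sd3, b3, "supremum"))    # (3*5)^2 = 225
  expect_equal(v_sum, 64)
  expect_equal(v_sup, 225)
  expect_gte(v_sup, v_sum)
  expect_error(block_aggregate(matrix(NA_real_, 2, 2), matrix(1L, 2, 2)),
               "empty")
})

test_that("block variances sum across independent blocks", {
  expect_equal(continental_variance(7)$variance, 7)
  expect_equal(continental_variance(rep(2.5, 4))$variance, 10)
  withr::with_seed(4, {
    bv <- runif(12, 0, 5)
    r <- continental_variance(bv, ece = 100)
    expect_equal(r$variance, sum(bv), tolerance = 1e-12)
    expect_equal(r$sigma, sqrt(sum(bv)))
    expect_equal(r$pct, 100 * sqrt(sum(bv)) / 100)
  })
  expect_error(continental_variance(numeric()), "block")
})

test_that("Goodman variance matches Monte-Carlo draws of the pixel product", {
  withr::with_seed(12, {
    for (p in c(0.2, 0.7)) for (cv in c(0.5, 1.25)) {
      A <- 1; rho <- 10; s <- cv * rho
      n <- 2e5
      x <- rbinom(n, 1, p)
      y <- rnorm(n, rho, s)
      v_mc <- var(A * x * y)
      v_th <- pixel_ece_variance(A, p, rho, s)
      se <- v_mc * sqrt(2 / (n - 1)) * 3   # crude 3-SE band for a variance
      expect_lt(abs(v_mc - v_th), max(se, 0.05 * v_th))
    }
  })
})

test_that("ROI-scale correlation dominates 500 m blocks", {
  sc <- mixed_scene(seed = 19, n = 32, cf = 8)
  pm <- combine_probabilities(sc$loss_year, sc$pop_density, sc$fire_years,
                              sc$landcover)
  rho <- sc$rho_fine_2000
  cfg_roi <- uncertainty_config("M1", cv = 1, als = "roi_scale")
  cfg_blk <- uncertainty_config("M1", cv = 1, als = "block_500m")
  sd_map <- sigma_rho(cfg_roi, rho = rho)
  u_roi <- roi_uncertainty(pm$p_combined, rho, sd_map, sc$spec, cfg_roi)
  u_blk <- roi_uncertainty(pm$p_combined, rho, sd_map, sc$spec, cfg_blk)
  expect_gte(u_roi$sigma, u_blk$sigma)
})

test_that("the configuration grid enumerates all 18 cases", {
  cfgs <- uncertainty_configs()
  expect_length(cfgs, 18)
  key <- vapply(cfgs, function(c) paste(c$method, c$als, c$cv), "")
  expect_equal(anyDuplicated(key), 0L)
  expect_equal(sum(vapply(cfgs, function(c) c$method %in% c("M3", "M4"), TRUE)), 2)
})
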