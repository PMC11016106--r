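test_that("logistic closed form honors fixed points and known values", {
  # carrying capacity and zero are fixed points for any horizon
  expect_equal(simulate_logistic_growth(100, 0.001, 100, 7), 100)
  expect_equal(simulate_logistic_growth(0, 0.001, 100, 7), 0)
  # zero growth rate is the identity
  expect_equal(simulate_logistic_growth(37.5, 0, 100, 13), 37.5)
  # V*alpha*dt = ln 3: rho = 3*50*100 / (2*50 + 100) = 75
  expect_equal(simulate_logistic_growth(50, log(3) / 100 / 8, 100, 8), 75)
  # rho0 > V decays toward V
  expect_lt(simulate_logistic_growth(150, 0.001, 100, 10), 150)
  expect_gt(simulate_logistic_growth(150, 0.001, 100, 10), 100)
  expect_error(simulate_logistic_growth(50, 0.001, -1, 1), "V")
})

test_that("scene generation is deterministic and honors trivial limits", {
  sp <- small_spec()
  s1 <- simulate_scene(sp, scene_params(), seed = 5)
  s2 <- simulate_scene(sp, scene_params(), seed = 5)
  expect_identical(s1, s2)
  s3 <- simulate_scene(sp, scene_params(), seed = 6)
  expect_false(identical(s1$loss_year$values, s3$loss_year$values))

  expect_error(scene_params(frac_river = -0.1), "non-negative")
  expect_error(scene_params(frac_river = 0.7, frac_urban = 0.5), "sum")
  expect_error(simulate_scene(sp, scene_params()), "seed")

  quiet <- simulate_scene(sp, scene_params(frac_river = 0, frac_urban = 0,
                                           frac_wildfire = 0, frac_landcover = 0,
                                           n_stray_fires = 0), seed = 5)
  expect_true(all(quiet$loss_year$values == 0))
  expect_equal(quiet$truth_ece, 0)
  expect_true(all(quiet$truth_cause == "none"))
})

test_that("scene invariants hold: cause/loss coupling, positivity, nesting", {
  sc <- mixed_scene(seed = 21)
  expect_identical(sc$truth_cause == "none", sc$loss_year$values == 0)
  expect_true(all(sc$biomass_fine_2000$values >= 0))
  expect_true(all(sc$biomass_coarse_2008$values >= 0))
  expect_gte(sc$truth_ece, 0)
  expect_true(grids_nested(sc$spec, sc$biomass_coarse_2008$spec))
  ly <- sc$loss_year$values
  expect_true(all(ly[ly > 0] %in% 2001:2019))
})

test_that("truth eCE equals a brute-force per-pixel summation", {
  sc <- mixed_scene(seed = 31, params = scene_params(frac_river = 0.1))
  a <- cell_area_km2(sc$spec)
  tot <- 0
  for (i in seq_len(sc$spec$n_rows)) for (j in seq_len(sc$spec$n_cols)) {
    if (sc$truth_cause[i, j] == "river")
      tot <- tot + a * sc$rho_at_loss[i, j] / sc$T_years
  }
  expect_equal(sc$truth_ece, tot, tolerance = 1e-12)
})

test_that("coarse 2008 biomass is the exact block mean of forward-simulated carbon", {
  sc <- mixed_scene(seed = 41)
  alpha_fine <- block_lookup(sc$growth$alpha,
                             grid_spec(sc$spec$n_rows, sc$spec$n_cols, 1))
  rho2008 <- simulate_logistic_growth(sc$rho_fine_2000, alpha_fine,
                                      sc$growth$V, 8)
  expected <- block_average(rho2008, sc$spec$coarse_factor)
  got <- agb_to_carbon(sc$biomass_coarse_2008$values, per_km2 = TRUE)
  expect_equal(got, expected, tolerance = 1e-9)
})

test_that("signature sample generators have the promised shapes", {
  x_ps <- sample_signature_distribution("PS", 1e4, seed = 1)
  x_ns <- sample_signature_distribution("NS", 1e4, seed = 1)
  x_bs <- sample_signature_distribution("BS", 1e4, seed = 1)
  x_mm <- sample_signature_distribution("MM", 1e4, seed = 1)
  expect_gte(e1071::skewness(x_ps, type = 2), 1)
  expect_lte(e1071::skewness(x_ns, type = 2), -1)
  expect_lt(abs(e1071::skewness(x_bs, type = 2)), 0.15)
  expect_true(all(c(x_ps, x_ns, x_bs, x_mm) >= 0))
  # MM: two histogram modes separated by a trough
  h <- hist(x_mm, breaks = seq(0, max(x_mm) + 10, by = 10), plot = FALSE)
  peaks <- which(diff(sign(diff(h$counts))) == -2) + 1
  expect_gte(length(peaks), 2)
  # determinism
  expect_identical(x_mm, sample_signature_distribution("MM", 1e4, seed = 1))
  expect_error(sample_signature_distribution("XX", 1e4, seed = 1))
  expect_error(sample_signature_distribution("BS", 50, seed = 1), ">= 100")
})
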